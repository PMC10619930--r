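## Cross-validated prediction accuracy and the time-shift permutation
## baseline. Folds are contiguous blocks in time (shuffled samples would leak
## information through autocorrelation); per fold the model is fit on 80% of
## the data, the regularization parameter is chosen on a 10% validation
## block, and accuracy (Pearson r between predicted and observed EEG) is
## reported on the remaining 10% test block.

fold_bounds <- function(n, folds) {
  b <- round(seq(0, n, length.out = folds + 1))
  lapply(seq_len(folds), function(i) if (b[i + 1] > b[i])
    (b[i] + 1L):b[i + 1] else integer(0))
}

# per-block sufficient statistics of the design/response
cv_block_stats <- function(X, Y, blocks) {
  lapply(blocks, function(rows) {
    Xb <- X[rows, , drop = FALSE]
    Yb <- Y[rows, , drop = FALSE]
    list(C = crossprod(Xb), XtY = crossprod(Xb, Yb),
         xs = colSums(Xb), ys = colSums(Yb), n = length(rows))
  })
}

safe_cor <- function(a, b) {
  if (length(a) < 3 || stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

# evaluate one fold: train on all blocks except test/validation, pick the
# ridge parameter on the validation block, score on the test block
cv_fold_eval <- function(bs, X, Y, blocks, fold, lambda_grid, score_rows) {
  folds <- length(blocks)
  val <- fold %% folds + 1L
  train <- setdiff(seq_len(folds), c(fold, val))
  C <- Reduce(`+`, lapply(bs[train], `[[`, "C"))
  XtY <- Reduce(`+`, lapply(bs[train], `[[`, "XtY"))
  xs <- Reduce(`+`, lapply(bs[train], `[[`, "xs"))
  ys <- Reduce(`+`, lapply(bs[train], `[[`, "ys"))
  n_tr <- sum(vapply(bs[train], `[[`, 0L, "n"))
  xbar <- xs / n_tr; ybar <- ys / n_tr
  Cc <- C - n_tr * tcrossprod(xbar)
  Bc <- XtY - n_tr * tcrossprod(xbar, ybar)
  sdx <- sqrt(pmax(diag(Cc), 0) / max(n_tr - 1, 1))
  scl <- ifelse(sdx > 0, sdx, 1)
  Cs <- Cc / tcrossprod(scl)
  Bs <- Bc / scl
  eig <- eigen(Cs, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  Vtb <- crossprod(eig$vectors, Bs)
  mbar <- mean(diag(Cs))
  w_for <- function(lambda) {
    ws <- eig$vectors %*% (Vtb / (ev + lambda * mbar))
    ws / scl
  }
  predict_rows <- function(w, rows) {
    sweep(X[rows, , drop = FALSE] %*% w, 2,
          as.numeric(ybar - crossprod(w, xbar)), `+`)
  }
  score <- function(w, rows) {
    rows <- intersect(rows, score_rows)
    yh <- predict_rows(w, rows)
    vapply(seq_len(ncol(Y)), function(e)
      safe_cor(yh[, e], Y[rows, e]), numeric(1))
  }
  val_rows <- blocks[[val]]
  val_mean <- vapply(lambda_grid, function(l)
    mean(score(w_for(l), val_rows)), numeric(1))
  best <- which.max(val_mean)
  w <- w_for(lambda_grid[best])
  test_rows <- intersect(blocks[[fold]], score_rows)
  list(lambda = lambda_grid[best],
       r_test = score(w, blocks[[fold]]),
       pred_test = predict_rows(w, test_rows),
       test_rows = test_rows)
}

fisher_mean <- function(r) {
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  tanh(mean(atanh(r)))
}

cv_inputs <- function(x, y, fs, exclude) {
  if (inherits(x, "trf_segments")) {
    list(pred = x$pred, eeg = x$eeg, fs = x$fs, exclude = x$gap_mask)
  } else {
    pred <- if (inherits(x, "predictor_set")) {
      fs <- x$fs
      x$data
    } else as.matrix(x)
    eeg <- if (inherits(y, "eeg_recording")) {
      fs <- y$fs
      y$data
    } else as.matrix(y)
    if (is.null(fs)) stop("fs is required for plain matrices")
    list(pred = pred, eeg = eeg, fs = fs, exclude = exclude)
  }
}

#' Cross-validated TRF prediction accuracy
#'
#' 10-fold cross-validation over contiguous time blocks. For each fold the
#' TRF is estimated on the training blocks (80% of the data), the ridge
#' parameter is selected by exhaustive search of a logarithmic grid
#' (default \eqn{10^{-7}}..\eqn{10^7}) on the fold's validation block (10%),
#' and prediction accuracy (Pearson's r between predicted and observed EEG)
#' is computed on the held-out test block (10%). Per-electrode accuracy is
#' the Fisher-z average of the per-fold r values (`aggregate = "concat"`
#' instead correlates the concatenated test predictions). Zero-padded gap
#' samples from epoch recombination are excluded from all correlations.
#'
#' @param x predictors: [predictor_set()], `trf_segments` or matrix.
#' @param y response: [eeg_recording()] or matrix (ignored for
#'   `trf_segments`).
#' @param fs sampling rate, Hz (for plain matrices).
#' @param lag_window lag window, ms.
#' @param folds number of folds (10).
#' @param lambda_grid ridge parameter grid.
#' @param exclude logical mask of samples to exclude from correlations
#'   (e.g. recombination gaps).
#' @param aggregate `"fisher"` (mean of per-fold r) or `"concat"`.
#' @return Object of class `cv_trf`: `accuracy` (per electrode), `per_fold`
#'   (folds x electrodes), `best_lambda` (per fold), `kind = "observed"`.
#' @export
cv_trf <- function(x, y = NULL, fs = NULL, lag_window = c(-150, 400),
                   folds = 10, lambda_grid = 10^seq(-7, 7),
                   exclude = NULL, aggregate = c("fisher", "concat")) {
  aggregate <- match.arg(aggregate)
  if (!length(lambda_grid)) stop("lambda_grid is empty")
  inp <- cv_inputs(x, y, fs, exclude)
  n <- nrow(inp$pred)
  min_n <- folds * (diff(lag_window) / 1000 + 1) * inp$fs
  if (n < min_n)
    stop("need at least ", ceiling(min_n), " samples for ", folds, " folds")
  X <- lag_design_matrix(inp$pred, lag_window, inp$fs)
  Y <- inp$eeg
  blocks <- fold_bounds(n, folds)
  score_rows <- if (is.null(inp$exclude)) seq_len(n) else
    which(!inp$exclude)
  bs <- cv_block_stats(X, Y, blocks)
  res <- lapply(seq_len(folds), function(i)
    cv_fold_eval(bs, X, Y, blocks, i, lambda_grid, score_rows))
  per_fold <- do.call(rbind, lapply(res, `[[`, "r_test"))
  colnames(per_fold) <- colnames(Y)
  accuracy <- if (aggregate == "fisher") {
    apply(per_fold, 2, fisher_mean)
  } else {
    yh <- do.call(rbind, lapply(res, `[[`, "pred_test"))
    rows <- unlist(lapply(res, `[[`, "test_rows"))
    vapply(seq_len(ncol(Y)), function(e)
      safe_cor(yh[, e], Y[rows, e]), numeric(1))
  }
  names(accuracy) <- colnames(Y)
  structure(list(accuracy = accuracy, per_fold = per_fold,
                 best_lambda = vapply(res, `[[`, 0, "lambda"),
                 folds = folds, lambda_grid = lambda_grid,
                 lag_window = lag_window, fs = inp$fs, kind = "observed"),
            class = "cv_trf")
}

#' @exportS3Method base::print
print.cv_trf <- function(x, ...) {
  cat("<cv_trf> ", x$kind, " accuracy, ", x$folds, "-fold CV, lag ",
      x$lag_window[1], "..", x$lag_window[2], " ms\n", sep = "")
  print(round(x$accuracy, 4))
  invisible(x)
}

#' @exportS3Method base::summary
summary.cv_trf <- function(object, ...) {
  cat("Cross-validated TRF prediction accuracy (", object$kind, ")\n",
      sep = "")
  cat("best electrode:", names(which.max(object$accuracy)), "r =",
      format(max(object$accuracy), digits = 4), "\n")
  cat("lambda per fold:", format(object$best_lambda, digits = 2), "\n")
  invisible(object)
}

#' Time-shift permutation baseline for TRF accuracy
#'
#' Chance-level accuracy under the null hypothesis of no systematic
#' relationship between predictors and EEG: for each cross-validation fold
#' the predictor time axis is circularly shifted by a random offset of at
#' least `min_shift_s` seconds (circular shifting preserves the predictor's
#' autocorrelation statistics) and the fold's fit/score procedure is rerun.
#' Baseline accuracy per electrode is the Fisher-z mean over folds (and over
#' `n_per_fold` repeats when more than one shift per fold is drawn).
#'
#' @inheritParams cv_trf
#' @param n_per_fold number of random shifts per fold.
#' @param min_shift_s minimum shift, seconds (avoids near-identity shifts).
#' @param seed optional RNG seed for reproducible shifts.
#' @return A `cv_trf` object with `kind = "baseline"` and the drawn `shifts`.
#' @export
permutation_baseline <- function(x, y = NULL, fs = NULL,
                                 lag_window = c(-150, 400), folds = 10,
                                 lambda_grid = 10^seq(-7, 7), exclude = NULL,
                                 n_per_fold = 1, min_shift_s = 5,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  inp <- cv_inputs(x, y, fs, exclude)
  n <- nrow(inp$pred)
  lo <- ceiling(min_shift_s * inp$fs)
  hi <- n - lo
  if (hi <= lo) stop("record too short for the minimum time shift")
  Y <- inp$eeg
  blocks <- fold_bounds(n, folds)
  score_rows <- if (is.null(inp$exclude)) seq_len(n) else which(!inp$exclude)
  reps <- vector("list", n_per_fold)
  shifts <- matrix(NA_integer_, n_per_fold, folds)
  for (r in seq_len(n_per_fold)) {
    per_fold <- matrix(NA_real_, folds, ncol(Y))
    lambdas <- numeric(folds)
    for (i in seq_len(folds)) {
      s <- sample.int(hi - lo + 1L, 1L) + lo - 1L
      shifts[r, i] <- s
      idx <- ((seq_len(n) - 1L - s) %% n) + 1L
      Xs <- lag_design_matrix(inp$pred[idx, , drop = FALSE], lag_window,
                              inp$fs)
      bs <- cv_block_stats(Xs, Y, blocks)
      ev <- cv_fold_eval(bs, Xs, Y, blocks, i, lambda_grid, score_rows)
      per_fold[i, ] <- ev$r_test
      lambdas[i] <- ev$lambda
    }
    reps[[r]] <- list(per_fold = per_fold, lambdas = lambdas)
  }
  per_fold <- Reduce(`+`, lapply(reps, `[[`, "per_fold")) / n_per_fold
  colnames(per_fold) <- colnames(Y)
  acc_rep <- vapply(reps, function(rp)
    apply(rp$per_fold, 2, fisher_mean), numeric(ncol(Y)))
  accuracy <- if (is.matrix(acc_rep)) rowMeans(acc_rep) else mean(acc_rep)
  names(accuracy) <- colnames(Y)
  structure(list(accuracy = accuracy, per_fold = per_fold,
                 best_lambda = reps[[1]]$lambdas, folds = folds,
                 lambda_grid = lambda_grid, lag_window = lag_window,
                 fs = inp$fs, kind = "baseline", shifts = shifts),
            class = "cv_trf")
}

#' Electrode of record
#'
#' Given a set of observed `cv_trf` results (e.g. one per participant and
#' condition), returns the electrode with the highest mean prediction
#' accuracy — the electrode used as dependent measure by the group-level
#' analyses.
#'
#' @param results list of `cv_trf` objects (kind `"observed"`).
#' @return Electrode name (character scalar).
#' @export
best_electrode <- function(results) {
  accs <- vapply(results, function(r) r$accuracy,
                 numeric(length(results[[1]]$accuracy)))
  if (is.null(dim(accs))) return(names(results[[1]]$accuracy)[1])
  names(which.max(rowMeans(accs)))
}
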