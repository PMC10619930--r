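#' Lagged (time-expanded) design matrix
#'
#' Expands a predictor matrix over a window of time lags for forward encoding
#' models. Column (lag `l`, predictor `p`) at row `t` equals predictor `p` at
#' time `t - l`; out-of-range entries are zero. Negative lags mean the
#' response precedes the predictor sample. Columns are ordered lag-major:
#' all predictors for the first lag, then all predictors for the second lag,
#' and so on.
#'
#' @param pred a [predictor_set()] or numeric matrix (samples x predictors).
#' @param lag_window length-2 numeric, lag window in ms (default
#'   `c(-150, 400)`).
#' @param fs sampling rate in Hz (taken from `pred` when it is a
#'   [predictor_set()]).
#' @return Numeric matrix, samples x (lags * predictors), with attributes
#'   `lags_samples`, `lag_window`, `fs` and `n_pred`.
#' @export
lag_design_matrix <- function(pred, lag_window = c(-150, 400), fs = NULL) {
  if (inherits(pred, "predictor_set")) {
    fs <- pred$fs
    pred <- pred$data
  }
  if (is.null(fs)) stop("fs is required when pred is a plain matrix")
  pred <- as.matrix(pred)
  if (lag_window[1] > lag_window[2])
    stop("lag window reversed: min > max")
  lags <- seq.int(round(lag_window[1] / 1000 * fs),
                  round(lag_window[2] / 1000 * fs))
  n <- nrow(pred); p <- ncol(pred)
  X <- matrix(0, n, length(lags) * p)
  for (i in seq_along(lags)) {
    l <- lags[i]
    src <- seq_len(n) - l
    ok <- src >= 1L & src <= n
    cols <- (i - 1L) * p + seq_len(p)
    X[ok, cols] <- pred[src[ok], , drop = FALSE]
  }
  nm <- colnames(pred)
  if (is.null(nm)) nm <- paste0("p", seq_len(p))
  colnames(X) <- paste0(rep(nm, length(lags)), "_lag",
                        rep(lags, each = p))
  structure(X, lags_samples = lags, lag_window = lag_window, fs = fs,
            n_pred = p)
}

#' Ridge regression on a prepared design matrix
#'
#' Solves `argmin ||Y - X w||^2 + lambda ||w||^2` by the normal equations
#' `(X'X + lambda * M) w = X'Y`, where `M` is the identity scaled by the mean
#' diagonal of `X'X` so that the regularization strength is independent of
#' the design's overall scale. Columns are centered and (by default) z-scored
#' internally; coefficients are returned in the original units together with
#' a per-response intercept.
#'
#' @param X design matrix (samples x regressors), e.g. from
#'   [lag_design_matrix()].
#' @param Y response matrix (samples x responses, e.g. electrodes).
#' @param lambda non-negative regularization scalar.
#' @param standardize z-score design columns internally (default TRUE).
#' @return List of class `ridge_fit` with `coefficients` (regressors x
#'   responses, original units), `intercept` (per response) and `lambda`.
#' @export
ridge_fit <- function(X, Y, lambda, standardize = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have equal row counts")
  if (lambda < 0) stop("lambda must be non-negative")
  n <- nrow(X)
  xbar <- colMeans(X); ybar <- colMeans(Y)
  Xc <- sweep(X, 2, xbar)
  sdx <- sqrt(colSums(Xc^2) / max(n - 1, 1))
  scale <- if (standardize) ifelse(sdx > 0, sdx, 1) else rep(1, ncol(X))
  Xs <- sweep(Xc, 2, scale, `/`)
  C <- crossprod(Xs)
  b <- crossprod(Xs, sweep(Y, 2, ybar))
  mbar <- mean(diag(C))
  A <- C + diag(lambda * mbar, ncol(C))
  ws <- tryCatch(solve(A, b), error = function(e)
    stop("normal equations are singular (collinear design); ",
         "use lambda > 0", call. = FALSE))
  w <- ws / scale
  intercept <- as.numeric(ybar - crossprod(w, xbar))
  structure(list(coefficients = w, intercept = intercept, lambda = lambda,
                 scale = scale, center = xbar, ybar = ybar),
            class = "ridge_fit")
}

#' Fit a temporal response function (TRF)
#'
#' The forward encoding model of the package: a linear kernel over a window
#' of time lags mapping stimulus predictors to the multichannel neural
#' response, estimated by ridge-regularized regression (see [ridge_fit()]).
#' The default lag window of -150 to 400 ms covers the early cortical
#' response to phonological features.
#'
#' @param x predictors: a [predictor_set()], `trf_segments` (from
#'   [epoch_reject_recombine()], in which case `y` is taken from it too) or a
#'   numeric matrix.
#' @param y response: an [eeg_recording()] or numeric matrix (samples x
#'   electrodes). Ignored when `x` is a `trf_segments`.
#' @param lambda regularization scalar.
#' @param lag_window lag window in ms.
#' @param fs sampling rate, Hz (required for plain matrices).
#' @param keep_data retain the data for [residuals()]/[fitted()] (default
#'   TRUE).
#' @return Object of class `trf`: kernel `weights` (lags x predictors x
#'   electrodes, original units), `intercept`, `lambda`, `lag_window`, `fs`,
#'   `lags_ms`, plus predictor/electrode names.
#' @seealso [cv_trf()] for cross-validated accuracy, [permutation_baseline()]
#'   for the chance floor, [simulate.trf()] to generate synthetic responses.
#' @export
#' @examples
#' set.seed(1)
#' pred <- matrix(rbinom(600, 1, 0.3), ncol = 2)
#' kern <- trf_kernel(c(-150, 400), fs = 50, peak_ms = 120)
#' y <- lag_design_matrix(pred, c(-150, 400), fs = 50) %*%
#'   cbind(c(kern, 0.5 * kern))
#' fit <- trf(pred, y, lambda = 1e-4, fs = 50)
#' fit
trf <- function(x, y = NULL, lambda = 1, lag_window = c(-150, 400), fs = NULL,
                keep_data = TRUE) {
  exclude <- NULL
  if (inherits(x, "trf_segments")) {
    fs <- x$fs
    y <- x$eeg
    exclude <- x$gap_mask
    x <- x$pred
  }
  if (inherits(y, "eeg_recording")) {
    if (!is.null(fs) && abs(fs - y$fs) > 1e-9)
      stop("EEG and predictor sampling rates differ")
    y <- y$data
  }
  pnames <- if (inherits(x, "predictor_set")) x$names else colnames(x)
  X <- lag_design_matrix(x, lag_window, fs)
  fs <- attr(X, "fs")
  lags <- attr(X, "lags_samples")
  y <- as.matrix(y)
  fit <- ridge_fit(X, y, lambda)
  p <- attr(X, "n_pred")
  if (is.null(pnames)) pnames <- paste0("p", seq_len(p))
  enames <- colnames(y)
  if (is.null(enames)) enames <- paste0("e", seq_len(ncol(y)))
  w <- aperm(array(fit$coefficients, dim = c(p, length(lags), ncol(y))),
             c(2, 1, 3))
  dimnames(w) <- list(NULL, pnames, enames)
  structure(list(weights = w, intercept = fit$intercept, lambda = lambda,
                 lag_window = lag_window, fs = fs,
                 lags_ms = lags / fs * 1000,
                 predictors = pnames, electrodes = enames,
                 data = if (keep_data) list(x = if (inherits(x, "predictor_set"))
                   x$data else as.matrix(x), y = y, exclude = exclude)),
            class = "trf")
}

#' @exportS3Method base::print
print.trf <- function(x, ...) {
  cat("Temporal response function (ridge forward model)\n")
  cat("  lag window : ", x$lag_window[1], "..", x$lag_window[2], " ms (",
      length(x$lags_ms), " lags @ ", x$fs, " Hz)\n", sep = "")
  cat("  predictors : ", length(x$predictors), " (",
      paste(utils::head(x$predictors, 5), collapse = ", "),
      if (length(x$predictors) > 5) ", ...", ")\n", sep = "")
  cat("  electrodes : ", length(x$electrodes), "\n", sep = "")
  cat("  lambda     : ", format(x$lambda), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method base::summary
summary.trf <- function(object, ...) {
  w <- object$weights
  peak <- apply(abs(w), c(2, 3), function(v) object$lags_ms[which.max(v)])
  amp <- apply(w, c(2, 3), function(v) v[which.max(abs(v))])
  out <- list(trf = object, peak_lag_ms = peak, peak_amplitude = amp)
  class(out) <- "summary.trf"
  out
}

#' @exportS3Method base::print
print.summary.trf <- function(x, ...) {
  print(x$trf)
  cat("\nPeak |kernel| lag (ms) per predictor x electrode:\n")
  print(round(x$peak_lag_ms, 1))
  invisible(x)
}

#' @export
coef.trf <- function(object, ...) object$weights

#' Predict the neural response from a fitted TRF
#'
#' @param object a [trf()] fit.
#' @param newdata predictors (matrix or [predictor_set()]); defaults to the
#'   training predictors.
#' @param ... unused.
#' @return Matrix of predicted responses (samples x electrodes).
#' @export
predict.trf <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    if (is.null(object$data)) stop("fit was made with keep_data = FALSE")
    newdata <- object$data$x
  }
  X <- lag_design_matrix(newdata, object$lag_window, object$fs)
  p <- attr(X, "n_pred")
  L <- length(attr(X, "lags_samples"))
  w <- matrix(aperm(object$weights, c(2, 1, 3)), L * p,
              length(object$electrodes))
  out <- X %*% w
  sweep(out, 2, object$intercept, `+`)
}

#' @export
fitted.trf <- function(object, ...) predict.trf(object)

#' @export
residuals.trf <- function(object, ...) {
  if (is.null(object$data)) stop("fit was made with keep_data = FALSE")
  object$data$y - predict.trf(object)
}

#' Plot TRF kernels
#'
#' Kernel amplitude against time lag, one line per predictor, for a chosen
#' electrode.
#'
#' @param x a [trf()] fit.
#' @param electrode electrode name or index (default 1).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.trf <- function(x, electrode = 1, ...) {
  w <- x$weights[, , electrode, drop = FALSE][, , 1]
  w <- as.matrix(w)
  graphics::matplot(x$lags_ms, w, type = "l", lty = 1,
                    xlab = "lag (ms)", ylab = "kernel weight",
                    main = paste0("TRF kernels (",
                                  x$electrodes[[electrode]], ")"), ...)
  graphics::abline(v = 0, h = 0, col = "grey70", lty = 3)
  invisible(x)
}

#' Simulate responses from a TRF
#'
#' Generates synthetic neural responses by driving the fitted kernels with
#' predictors and adding noise at a given signal-to-noise ratio; the same
#' forward model used by the synthetic-data generator.
#'
#' @param object a [trf()] fit.
#' @param nsim number of simulated response matrices.
#' @param seed optional RNG seed.
#' @param newdata predictors (defaults to training predictors).
#' @param snr_db signal-to-noise ratio in dB; `Inf` gives the noise-free
#'   forward prediction.
#' @param noise `"pink"` (1/f, default) or `"white"`.
#' @param ... unused.
#' @return A list of `nsim` response matrices (samples x electrodes).
#' @export
simulate.trf <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                         snr_db = Inf, noise = c("pink", "white"), ...) {
  noise <- match.arg(noise)
  if (!is.null(seed)) set.seed(seed)
  mu <- predict.trf(object, newdata)
  lapply(seq_len(nsim), function(i) {
    if (!is.finite(snr_db)) return(mu)
    sig_sd <- apply(mu, 2, stats::sd)
    sig_sd[sig_sd == 0] <- max(sig_sd)
    noise_sd <- sig_sd * 10^(-snr_db / 20)
    nz <- vapply(noise_sd, function(s) {
      if (noise == "pink") pink_noise(nrow(mu)) * s
      else stats::rnorm(nrow(mu), 0, s)
    }, numeric(nrow(mu)))
    mu + nz
  })
}
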