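test_that("lagged design matrix shifts predictors as specified", {
  # single predictor, lags {0, +1 sample}
  X <- lag_design_matrix(matrix(c(1, 0, 0), 3), c(0, 1000), fs = 1)
  expect_equal(unname(X[, 1]), c(1, 0, 0))
  expect_equal(unname(X[, 2]), c(0, 1, 0))

  # [0, 0] window reproduces the predictor matrix
  p <- matrix(rnorm(20), 10, 2)
  X0 <- lag_design_matrix(p, c(0, 0), fs = 100)
  expect_equal(unname(X0[, 1:2]), p)

  # 2 predictors x 3 lags: 6 columns, lag-major order
  X2 <- lag_design_matrix(matrix(rnorm(30), 15, 2), c(0, 20), fs = 100)
  expect_equal(ncol(X2), 6L)
  expect_match(colnames(X2)[1], "p1_lag0")
  expect_match(colnames(X2)[2], "p2_lag0")
  expect_match(colnames(X2)[3], "p1_lag1")

  # negative lag: the response precedes the predictor sample, so the lag -1
  # column carries the impulse one row early
  Xn <- lag_design_matrix(matrix(c(0, 0, 1, 0, 0), 5), c(-10, -10), fs = 100)
  expect_equal(unname(Xn[, 1]), c(0, 1, 0, 0, 0))

  expect_error(lag_design_matrix(p, c(100, -100), fs = 100), "reversed")
  # default window at 100 Hz spans 56 lags
  expect_length(attr(lag_design_matrix(p, fs = 100), "lags_samples"), 56L)
})

test_that("ridge at lambda 0 equals OLS; large lambda shrinks to zero", {
  set.seed(1)
  X <- matrix(rnorm(200 * 6), 200)
  B <- matrix(rnorm(12), 6)
  Y <- X %*% B + matrix(rnorm(400, 0, 0.5), 200)
  rf <- ridge_fit(X, Y, 0)
  ols <- qr.solve(cbind(1, X), Y)
  expect_lt(max(abs(rf$coefficients - ols[-1, ])), 1e-8)
  expect_lt(max(abs(rf$intercept - ols[1, ])), 1e-8)

  big <- ridge_fit(X, Y, 1e12)
  expect_lt(max(abs(big$coefficients)), 1e-8)

  # exact recovery of noiseless coefficients
  Yc <- X %*% B
  rf0 <- ridge_fit(X, Yc, 0)
  expect_lt(max(abs(rf0$coefficients - B)), 1e-6)

  # collinear design at lambda 0: error advising regularization
  Xc <- cbind(X, X[, 1])
  expect_error(ridge_fit(Xc, Y, 0), "lambda > 0")
})

test_that("ridge matches pseudoinverse and gradient-descent oracles", {
  set.seed(2)
  for (rep in 1:10) {
    n <- sample(50:120, 1)
    p <- sample(3:8, 1)
    X <- matrix(rnorm(n * p), n)
    Y <- matrix(rnorm(n * 2), n)
    lambda <- 10^runif(1, -4, 2)
    rf <- ridge_fit(X, Y, lambda, standardize = FALSE)
    Xc <- sweep(X, 2, colMeans(X))
    Yc <- sweep(Y, 2, colMeans(Y))
    lam_abs <- lambda * mean(diag(crossprod(Xc)))
    # oracle 1: augmented least squares via pseudoinverse
    Xa <- rbind(Xc, sqrt(lam_abs) * diag(p))
    Ya <- rbind(Yc, matrix(0, p, ncol(Y)))
    W1 <- qr.solve(Xa, Ya)
    expect_lt(max(abs(rf$coefficients - W1)) / max(abs(W1)), 1e-6)
    # oracle 2: gradient descent
    W2 <- ridge_gd_oracle(Xc, Yc, lam_abs)
    expect_lt(max(abs(rf$coefficients - W2)) / max(abs(W2)), 1e-5)
  }
})

test_that("trf objects expose kernels through the standard S3 interface", {
  set.seed(3)
  fix <- small_signal_fixture(duration_s = 60, seed = 5)
  y <- lag_design_matrix(fix$pred) %*% as.vector(t(fix$kernels))
  y <- cbind(y, 0.5 * y)
  colnames(y) <- c("FC5", "FC6")
  fit <- trf(fix$pred, y, lambda = 1e-6)
  expect_s3_class(fit, "trf")
  expect_equal(dim(coef(fit)), c(56L, 2L, 2L))
  expect_equal(fit$electrodes, c("FC5", "FC6"))
  # noiseless recovery
  expect_gt(cor(as.vector(fit$weights[, , 1]), as.vector(fix$kernels)),
            0.999)
  # predictions reproduce the response
  expect_gt(cor(predict(fit)[, 1], y[, 1]), 0.999)
  expect_lt(sd(residuals(fit)[, 1]), 0.05 * sd(y[, 1]))
  expect_output(print(fit), "Temporal response function")
  expect_output(print(summary(fit)), "Peak")
  s <- summary(fit)
  expect_true(all(s$peak_lag_ms >= -150 & s$peak_lag_ms <= 400))
  # simulate: noise-free equals prediction; finite SNR adds noise
  sim <- simulate(fit, nsim = 1, seed = 1, snr_db = Inf)[[1]]
  expect_equal(sim, predict(fit))
  noisy <- simulate(fit, nsim = 1, seed = 1, snr_db = 0)[[1]]
  expect_gt(sd(noisy - predict(fit)), 0)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit, electrode = 1))
})

test_that("prediction accuracy is invariant to affine rescaling of the EEG", {
  fix <- small_signal_fixture(duration_s = 60, seed = 7)
  set.seed(11)
  eeg <- simulate_eeg(fix$pred, fix$kernels, fix$cfg, gain = 1, snr_db = 5)
  cv1 <- cv_trf(fix$pred, eeg$data, fs = 100)
  cv2 <- cv_trf(fix$pred, eeg$data * 3.7 + 12, fs = 100)
  expect_equal(cv1$accuracy, cv2$accuracy, tolerance = 1e-8)
})

test_that("cross-validation is deterministic and finds coupled signal", {
  fix <- small_signal_fixture(duration_s = 90, seed = 8)
  set.seed(12)
  eeg <- simulate_eeg(fix$pred, fix$kernels, fix$cfg, gain = 1, snr_db = 0)
  a <- cv_trf(fix$pred, eeg$data, fs = 100)
  b <- cv_trf(fix$pred, eeg$data, fs = 100)
  expect_identical(a$accuracy, b$accuracy)
  expect_identical(a$best_lambda, b$best_lambda)
  expect_equal(nrow(a$per_fold), 10L)
  expect_true(all(a$per_fold >= -1 & a$per_fold <= 1))
  # SNR 0 dB still gives held-out accuracy above 0.3 at the driven electrode
  expect_gt(max(a$accuracy), 0.3)
  expect_error(cv_trf(fix$pred$data[1:100, ], eeg$data[1:100, ], fs = 100),
               "at least")
  expect_error(cv_trf(fix$pred, eeg$data, fs = 100, lambda_grid = numeric(0)),
               "empty")
})

test_that("accuracy decreases monotonically as noise grows", {
  fix <- small_signal_fixture(duration_s = 60, seed = 9)
  snrs <- c(15, 5, -5, -15)
  set.seed(13)
  accs <- sapply(snrs, function(s) {
    eeg <- simulate_eeg(fix$pred, fix$kernels, fix$cfg, gain = 1, snr_db = s)
    max(cv_trf(fix$pred, eeg$data, fs = 100)$accuracy)
  })
  expect_true(all(diff(accs) < 0))
})

test_that("permutation baseline reproduces chance and detects coupling", {
  fix <- small_signal_fixture(duration_s = 90, seed = 10)
  set.seed(14)
  eeg <- simulate_eeg(fix$pred, fix$kernels, fix$cfg, gain = 1, snr_db = 5)
  bl <- permutation_baseline(fix$pred, eeg$data, fs = 100, seed = 15)
  cv <- cv_trf(fix$pred, eeg$data, fs = 100)
  expect_equal(bl$kind, "baseline")
  # strong true coupling: observed far above baseline
  expect_gt(max(cv$accuracy) - max(bl$accuracy), 0.3)
  # all shifts at least 5 s away from identity
  expect_true(all(bl$shifts >= 5 * 100))
  expect_true(all(bl$shifts <= nrow(fix$pred$data) - 5 * 100))
  # seeded reruns are identical
  bl2 <- permutation_baseline(fix$pred, eeg$data, fs = 100, seed = 15)
  expect_identical(bl$accuracy, bl2$accuracy)
  # record too short for the minimum shift
  expect_error(permutation_baseline(fix$pred$data[1:900, ],
                                    eeg$data[1:900, ], fs = 100, seed = 1),
               "short")
})

test_that("gap samples are excluded from scoring but kept in training", {
  fix <- small_signal_fixture(duration_s = 90, seed = 16)
  set.seed(17)
  eeg <- simulate_eeg(fix$pred, fix$kernels, fix$cfg, gain = 1, snr_db = 10)
  rec <- eeg_recording(eeg$data * 20, 100, eeg$channel_names)
  # inject artifacts so epochs drop and gaps appear
  rec$data[2050, ] <- 300
  rec$data[5050, ] <- 300
  seg <- suppressWarnings(epoch_reject_recombine(
    rec, fix$pred, band = c(1, 10), transition = 1, min_retained_s = 0))
  expect_gt(sum(seg$gap_mask), 0)
  cv <- cv_trf(seg)
  expect_gt(max(cv$accuracy), 0.3)
  fit <- trf(seg, lambda = 1e-3)
  expect_s3_class(fit, "trf")
})

test_that("best_electrode picks the highest mean observed accuracy", {
  mk <- function(v) structure(list(accuracy = v), class = "cv_trf")
  res <- list(mk(c(FC5 = 0.3, Fz = 0.05)), mk(c(FC5 = 0.2, Fz = 0.4)))
  expect_equal(best_electrode(res), "FC5")
})
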