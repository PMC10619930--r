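# shared fixtures, built in code

# tiny 3-phoneme lexicon over 2 features
toy_lexicon <- function() {
  tab <- rbind(a = c(1, 0), b = c(1, 1), s = c(0, 1))
  colnames(tab) <- c("voiced", "strident")
  feature_lexicon(tab)
}

# annotation with a silence gap: a(0-0.1) b(0.1-0.2) <gap> s(0.35-0.45)
toy_annotation <- function() {
  phoneme_annotation(c("a", "b", "s"), c(0, 0.1, 0.35), c(0.1, 0.2, 0.45),
                     total_duration = 0.5)
}

# small two-feature generator configuration for signal-level tests
small_signal_cfg <- function(duration_s = 120, seed = 1, ...) {
  generator_config(
    duration_s = duration_s, seed = seed,
    features = c("voiced", "nasal"),
    duration_targets_ms = c(voiced = 228, nasal = 70),
    occurrence_ranks = c(voiced = 2, nasal = 1),
    pitch_ranks = c(voiced = 2, nasal = 1),
    n_electrodes = 2L, ...)
}

# feature step predictors + matching ground-truth kernels from a stream
small_signal_fixture <- function(duration_s = 120, seed = 1, ...) {
  cfg <- small_signal_cfg(duration_s, seed, ...)
  ps <- generate_phoneme_stream(cfg)
  spans <- expand_features(ps$annotation, ps$lexicon)
  n <- round(cfg$duration_s * cfg$fs)
  pred <- build_feature_predictor(spans, cfg$fs, n)
  kernels <- cbind(trf_kernel(fs = cfg$fs, peak_ms = 120),
                   trf_kernel(fs = cfg$fs, peak_ms = 180))
  list(cfg = cfg, pred = pred, kernels = kernels, stream = ps)
}

# spatially smooth multichannel field on the default cap (for spline tests)
smooth_field <- function(n = 1500, seed = 1, noise = 0.1, scale = 2) {
  set.seed(seed)
  cap <- default_cap()
  pos <- standard_montage(cap)
  k <- 6
  u <- matrix(rnorm(3 * k), k)
  u <- u / sqrt(rowSums(u^2))
  pat <- exp(scale * (pos %*% t(u) - 1))
  dat <- matrix(rnorm(n * k), n, k) %*% t(pat) +
    noise * matrix(rnorm(n * 28), n, 28)
  colnames(dat) <- cap
  dat
}

# independent gradient-descent ridge oracle (fixed step, many iterations)
ridge_gd_oracle <- function(X, Y, lambda_abs, iters = 20000) {
  p <- ncol(X)
  W <- matrix(0, p, ncol(Y))
  C <- crossprod(X)
  B <- crossprod(X, Y)
  step <- 1 / (max(eigen(C, symmetric = TRUE, only.values = TRUE)$values) +
                 lambda_abs)
  for (i in seq_len(iters)) {
    W <- W - step * (C %*% W + lambda_abs * W - B)
  }
  W
}

# attenuation (dB) of a pure sinusoid through a filtering function
sine_attenuation <- function(freq, filter_fun, fs = 500, dur = 30) {
  t <- seq(1 / fs, dur, 1 / fs)
  s <- sin(2 * pi * freq * t)
  m <- cbind(s, s, s, s)
  colnames(m) <- c("Fz", "Cz", "C3", "C4")
  out <- filter_fun(eeg_recording(m, fs))$data[, 1]
  mid <- seq(round(length(s) * 0.3), round(length(s) * 0.7))
  20 * log10(stats::sd(out[mid]) / stats::sd(s[mid]))
}

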