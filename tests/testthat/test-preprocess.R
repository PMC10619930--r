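test_that("band filters match their frequency-response oracle", {
  # drift (0.1 Hz) and line noise (50 Hz) attenuated > 20 dB,
  # passband (10 Hz) within 1 dB
  expect_lt(sine_attenuation(0.1, bandpass_filters), -20)
  expect_lt(sine_attenuation(50, bandpass_filters), -20)
  expect_lt(abs(sine_attenuation(10, bandpass_filters)), 1)
  # oracle: measured response equals the designed FIR transfer function
  h_lp <- signal::fir1(332, 47.5 / 250, type = "low")
  oracle_db <- function(f, h) {
    w <- exp(-2i * pi * f / 500 * (seq_along(h) - 1))
    20 * log10(Mod(sum(h * w)))
  }
  lp_only <- function(rec) eeg_recording(
    phonotrf:::fir_zerophase_mat(rec$data, h_lp), rec$fs, rec$channel_names)
  for (f in c(10, 45, 50))
    expect_equal(sine_attenuation(f, lp_only), oracle_db(f, h_lp),
                 tolerance = 0.5)
  # zero-phase: passband sinusoid not delayed
  t <- seq(1 / 500, 30, 1 / 500)
  s <- sin(2 * pi * 10 * t)
  m <- cbind(Fz = s, Cz = s, C3 = s, C4 = s)
  filt <- bandpass_filters(eeg_recording(m, 500))$data[, 1]
  cc <- stats::ccf(filt, s, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # too-short recording is a padding error
  expect_error(bandpass_filters(eeg_recording(m[1:1000, ], 500)), "short")
  expect_error(bandpass_filters(eeg_recording(m, 250)), "500 Hz")
})

test_that("the three bad-channel rules flag their fixtures and nothing else", {
  set.seed(3)
  fs <- 500
  n <- fs * 70
  chans <- sapply(1:8, function(i) as.numeric(arima.sim(list(ar = 0.97), n)))
  colnames(chans) <- c("Fz", "Cz", "Pz", "C3", "C4", "F3", "F4", "P3")
  chans[1000:(1000 + 31 * fs), "C4"] <- 5        # flat 31 s
  chans[, "F3"] <- rnorm(n)                      # white noise: Hurst ~ 0.5
  chans[, "P3"] <- chans[, "P3"] * 100           # 100x power
  bads <- detect_bad_channels(eeg_recording(chans, fs))
  crit <- attr(bads, "criteria")
  expect_setequal(as.character(bads), c("C4", "F3", "P3"))
  expect_true(crit["C4", "flat"])
  expect_true(crit["F3", "hurst"])
  expect_true(crit["P3", "power"])
  expect_false(any(crit[c("Fz", "Cz", "Pz", "C3", "F4"), ]))
  expect_error(detect_bad_channels(
    eeg_recording(chans[, 1:3], fs)), "4 channels")
})

test_that("R/S Hurst estimates separate persistent from white noise", {
  set.seed(4)
  h_white <- hurst_rs(rnorm(8192))
  h_pink <- hurst_rs(as.numeric(arima.sim(list(ar = 0.98), 8192)))
  expect_lt(h_white, 0.65)
  expect_gt(h_pink, 0.8)
  skip_if_not_installed("pracma")
  # independent oracle: pracma's R/S corrected estimate orders them the same
  o_white <- pracma::hurstexp(rnorm(8192), display = FALSE)$Hs
  expect_lt(abs(h_white - o_white), 0.15)
})

test_that("wavelet thresholding removes spikes, keeps oscillations", {
  set.seed(5)
  fs <- 500
  t <- seq(1 / fs, 20, 1 / fs)
  clean <- 10 * sin(2 * pi * 5 * t)
  spiky <- clean
  spiky[5000] <- spiky[5000] + 500
  m <- cbind(a = spiky, b = clean, c = clean + rnorm(length(t)), d = clean)
  wt <- wavelet_threshold(eeg_recording(m, fs))
  expect_equal(dim(wt$data), dim(m))
  # spike attenuated by at least half
  expect_lt(abs(wt$data[5000, 1] - clean[5000]), 250)
  # oscillation preserved
  expect_gt(cor(wt$data[, 1], clean), 0.95)
  # contraction: output variance never exceeds input variance
  for (j in 1:4)
    expect_lte(var(wt$data[, j]), var(m[, j]) + 1e-12)
  # zero in, zero out
  z <- eeg_recording(matrix(0, 2^13, 4), fs)
  expect_equal(max(abs(wavelet_threshold(z)$data)), 0)
  expect_error(wavelet_threshold(eeg_recording(matrix(0, 100, 4), fs)),
               "2\\^13")
})

test_that("periodized DWT is orthogonal: perfect reconstruction and energy", {
  set.seed(6)
  x <- rnorm(2^13)
  dec <- phonotrf:::dwt_analysis(x, 13)
  expect_equal(phonotrf:::dwt_synthesis(dec), x, tolerance = 1e-10)
  energy <- sum(dec$approx^2) + sum(vapply(dec$details,
                                           function(d) sum(d^2), 0))
  expect_equal(energy, sum(x^2), tolerance = 1e-10)
})

test_that("spherical splines reconstruct smooth fields and respect symmetry", {
  dat <- smooth_field(seed = 7)
  nb <- c("FC5", "FC1", "CP5", "CP1", "T7", "Cz")
  dat[, "C3"] <- rowMeans(dat[, nb])
  rec <- eeg_recording(dat, 100)
  # no bads: identity
  expect_identical(interpolate_channels(rec, character())$data, rec$data)
  ip <- interpolate_channels(rec, "C3")
  expect_gt(cor(ip$data[, "C3"], dat[, "C3"]), 0.9)
  # untouched channels stay identical
  expect_identical(ip$data[, "Fz"], dat[, "Fz"])

  # left/right mirror symmetry of montage and data implies mirror estimates
  sym <- smooth_field(seed = 8)
  pairs <- rbind(c("C3", "C4"), c("F3", "F4"), c("F7", "F8"),
                 c("FC5", "FC6"), c("FC1", "FC2"), c("T7", "T8"),
                 c("CP5", "CP6"), c("CP1", "CP2"), c("P3", "P4"),
                 c("P7", "P8"), c("O1", "O2"), c("M1", "M2"))
  for (k in seq_len(nrow(pairs))) sym[, pairs[k, 2]] <- sym[, pairs[k, 1]]
  r2 <- eeg_recording(sym, 100)
  a <- interpolate_channels(r2, "C3")$data[, "C3"]
  b <- interpolate_channels(r2, "C4")$data[, "C4"]
  expect_equal(a, b, tolerance = 1e-6)

  expect_error(interpolate_channels(rec, default_cap()[1:20]), "half")
})

test_that("linked-mastoid referencing subtracts the mastoid mean", {
  cap <- default_cap()
  m <- matrix(rnorm(200 * 28), 200, 28)
  colnames(m) <- cap
  # zero mastoids: identity
  m0 <- m; m0[, c("M1", "M2")] <- 0
  expect_equal(rereference_mastoids(eeg_recording(m0, 100))$data, m0)
  # constant offset on all channels cancels
  expect_equal(max(abs(rereference_mastoids(
    eeg_recording(m0 + 7, 100))$data - m0)), 0)
  # mastoids at 2 and 4 uV shift every channel by -3
  m2 <- m; m2[, "M1"] <- 2; m2[, "M2"] <- 4
  rr <- rereference_mastoids(eeg_recording(m2, 100))
  expect_equal(rr$data[, "Fz"], m2[, "Fz"] - 3)
  expect_error(rereference_mastoids(
    eeg_recording(m[, 1:26, drop = FALSE], 100)), "mastoid")
})

test_that("epoch rejection drops threshold violations and pads gaps", {
  set.seed(9)
  fs <- 100
  n <- 3000
  eeg <- matrix(rnorm(n * 4, 0, 20), n, 4)
  colnames(eeg) <- c("Fz", "Cz", "C3", "C4")
  pred <- matrix(rbinom(n * 2, 1, 0.3), n, 2)
  # clean data: nothing dropped, no padding
  seg0 <- suppressWarnings(epoch_reject_recombine(
    eeg_recording(eeg, fs), pred, band = c(1, 10), transition = 2,
    min_retained_s = 0))
  expect_true(all(seg0$keep))
  expect_equal(nrow(seg0$eeg), n)
  expect_equal(sum(seg0$gap_mask), 0)

  # one epoch at 250 uV: dropped from EEG and predictors, 1-s zero gap
  eeg2 <- eeg
  eeg2[1550, 2] <- 250
  seg <- suppressWarnings(epoch_reject_recombine(
    eeg_recording(eeg2, fs), pred, band = c(1, 10), transition = 2,
    min_retained_s = 0))
  expect_equal(which(!seg$keep), 16L)
  expect_equal(sum(seg$keep) + sum(!seg$keep), 30L)
  expect_equal(sum(seg$gap_mask), fs)
  expect_equal(nrow(seg$eeg), n)
  expect_equal(nrow(seg$pred), n)
  gap_rows <- which(seg$gap_mask)
  expect_equal(max(abs(seg$eeg[gap_rows, ])), 0)
  expect_equal(max(abs(seg$pred[gap_rows, ])), 0)
  expect_equal(seg$retained_s, 29)

  # retained below the minimum flags exclusion (a signal, not an error)
  expect_warning(
    s2 <- epoch_reject_recombine(eeg_recording(eeg2, fs), pred,
                                 band = NULL, min_retained_s = 30),
    "excluded")
  expect_true(s2$excluded)
  seg349 <- suppressWarnings(epoch_reject_recombine(
    eeg_recording(eeg, fs), pred, band = NULL, min_retained_s = 350))
  expect_true(seg349$excluded)
})

test_that("preprocessing is deterministic end to end", {
  set.seed(10)
  fs <- 500
  n <- fs * 70
  cap <- default_cap()
  m <- sapply(seq_len(28), function(i) pink_noise(n, exponent = 1.5) * 20)
  colnames(m) <- cap
  rec <- eeg_recording(m, fs)
  a <- preprocess_recording(rec)
  b <- preprocess_recording(rec)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$log$bad_channels, b$log$bad_channels)
  expect_equal(a$recording$reference, "linked-mastoids")
})
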