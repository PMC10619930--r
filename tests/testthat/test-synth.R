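test_that("generator configuration validates its options", {
  cfg <- generator_config()
  expect_s3_class(cfg, "synth_config")
  expect_equal(cfg$n_participants, 66L)
  expect_equal(cfg$n_female, 40L)
  expect_equal(unname(cfg$duration_targets_ms["voiced"]), 228)
  expect_error(generator_config(bogus = 1), "unknown")
  expect_error(generator_config(snr_db = Inf), "finite")
  expect_error(generator_config(rank_link = "size"), "rank_link")
})

test_that("phoneme streams hit their duration targets and are reproducible", {
  cfg <- generator_config(duration_s = 450, seed = 42)
  ps <- generate_phoneme_stream(cfg)
  ref <- feature_timing_reference()
  # the headline contract: voiced-run median within 228 +/- 35 ms
  expect_lt(abs(ps$realized_ms["voiced"] - 228), 35)
  # all features within the 15% generator tolerance
  rel <- abs(ps$realized_ms[ref$feature] - ref$median_ms) / ref$median_ms
  expect_true(all(rel < 0.15))
  # phoneme rate matches child-directed speech (~20 phonemes/s)
  durs <- ps$annotation$offset - ps$annotation$onset
  expect_lt(abs(mean(durs) - 0.05), 0.01)
  # identical seed, identical stream
  ps2 <- generate_phoneme_stream(cfg)
  expect_identical(ps$annotation, ps2$annotation)
  expect_identical(ps$lexicon$table, ps2$lexicon$table)
})

test_that("degenerate single-phoneme stream yields one full-length run", {
  cfg <- generator_config(
    features = "voiced", duration_targets_ms = c(voiced = Inf),
    occupancy = 1, silence_prob = 0, duration_s = 10, seed = 2,
    occurrence_ranks = c(voiced = 1), pitch_ranks = c(voiced = 1))
  ps <- generate_phoneme_stream(cfg, calibrate = FALSE)
  expect_equal(nrow(ps$lexicon$table), 1L)
  sp <- expand_features(ps$annotation, ps$lexicon)
  expect_equal(nrow(sp$voiced), 1L)
  expect_equal(sp$voiced$offset - sp$voiced$onset, 10)
})

test_that("infeasible duration targets are a configuration error", {
  cfg <- generator_config(duration_targets_ms = stats::setNames(
    c(30, rep(100, 16)), phonological_features()))
  expect_error(generate_phoneme_stream(cfg), "infeasible")
})

test_that("pitch generator couples voicing and stays below 4 Hz", {
  fix <- small_signal_fixture(duration_s = 120, seed = 21)
  voiced <- fix$pred$data[, "voiced"]
  nasal <- fix$pred$data[, "nasal"]
  set.seed(1)
  p1 <- generate_pitch(fix$cfg, voiced)
  # coupling 1: pitch gated by voicing, so voiced is more similar than nasal
  s_voiced <- abs(as.numeric(pitch_similarity(voiced, p1$data[, 1], 100)))
  s_nasal <- abs(as.numeric(pitch_similarity(nasal, p1$data[, 1], 100)))
  expect_gt(s_voiced, s_nasal)
  expect_gt(s_voiced, 0.5)

  # coupling 0: similarity near zero
  cfg0 <- fix$cfg
  cfg0$pitch_coupling <- 0
  set.seed(2)
  p0 <- generate_pitch(cfg0, voiced)
  expect_lt(abs(as.numeric(pitch_similarity(voiced, p0$data[, 1], 100))), 0.15)

  # spectral centroid of the F0 modulation below 4 Hz
  f0 <- p1$data[p1$data > 0]
  mod <- p1$data[, 1] - mean(p1$data[, 1])
  sp <- Mod(fft(mod))^2
  freqs <- (seq_along(sp) - 1) * 100 / length(sp)
  half <- freqs <= 50
  centroid <- sum(freqs[half] * sp[half]) / sum(sp[half])
  expect_lt(centroid, 4)
})

test_that("simulated EEG follows the forward model and carries ground truth", {
  fix <- small_signal_fixture(duration_s = 60, seed = 22)
  set.seed(3)
  eeg <- simulate_eeg(fix$pred, fix$kernels, fix$cfg, gain = 1, snr_db = 200)
  truth <- attr(eeg, "truth")
  expect_equal(truth$kernels, fix$kernels)
  # near-noiseless: the estimator recovers the kernels and accuracy ~ 1
  cv <- cv_trf(fix$pred, eeg$data, fs = 100)
  expect_gt(max(cv$accuracy), 0.99)
  # kernel length must match the window
  expect_error(simulate_eeg(fix$pred, fix$kernels[1:30, ], fix$cfg),
               "window")
  # injected spike lands in its epoch; flat channel goes flat
  set.seed(4)
  art <- simulate_eeg(fix$pred, fix$kernels, fix$cfg, gain = 1, snr_db = 0,
                      artifacts = list(spike_epochs = 7, spike_uv = 250,
                                       flat_channels = "F3"))
  rec <- eeg_recording(art$data, 100, art$channel_names)
  seg <- suppressWarnings(epoch_reject_recombine(
    rec, fix$pred, band = c(1, 10), transition = 1, min_retained_s = 0))
  expect_equal(which(!seg$keep), 7L)
  expect_equal(stats::sd(art$data[, "F3"]), 0)
})

test_that("gain zero makes observed accuracy indistinguishable from baseline", {
  fix <- small_signal_fixture(duration_s = 120, seed = 23)
  set.seed(5)
  eeg <- simulate_eeg(fix$pred, fix$kernels, fix$cfg, gain = 0, snr_db = 0)
  cv <- cv_trf(fix$pred, eeg$data, fs = 100)
  bl <- permutation_baseline(fix$pred, eeg$data, fs = 100, seed = 6)
  expect_lt(abs(mean(cv$accuracy) - mean(bl$accuracy)), 0.1)
  expect_lt(abs(mean(cv$accuracy)), 0.1)
})

test_that("record-level cohorts mirror the configured study design", {
  cfg <- generator_config(seed = 31)
  co <- generate_cohort(cfg)
  r <- co$records
  expect_equal(length(unique(r$participant)), 66L)
  expect_equal(sum(co$truth$sex == "f"), 40L)
  expect_setequal(unique(r$condition), c("native", "nonnative"))
  expect_setequal(unique(r$condition_code), c(-0.5, 0.5))
  expect_true(all(r$age_months >= 3 & r$age_months <= 54))
  fr <- co$feature_records
  expect_equal(nrow(fr), 66L * 17L)
  expect_setequal(unique(fr$duration_rank), 1:17)
  # provenance: regeneration is bit-identical
  co2 <- generate_cohort(cfg)
  expect_identical(co$records, co2$records)
  expect_identical(co$feature_records, co2$feature_records)
})

test_that("signal-level cohorts produce analyzable participant data", {
  cfg <- small_signal_cfg(duration_s = 60, seed = 32,
                          n_participants = 2L, n_female = 1L)
  co <- generate_cohort(cfg, level = "signals")
  expect_length(co$participants, 2L)
  p1 <- co$participants[[1]]
  expect_s3_class(p1$native$eeg, "eeg_recording")
  expect_equal(nrow(p1$native$pred$data), 60 * 100)
  expect_equal(dim(co$kernels), c(56L, 2L))
})

test_that("realized corpus statistics reproduce well-separated rank order", {
  cfg <- generator_config(
    duration_s = 300, seed = 33,
    features = c("voiced", "continuant", "high", "nasal"),
    duration_targets_ms = c(voiced = 240, continuant = 170, high = 115,
                            nasal = 75),
    occurrence_ranks = c(voiced = 4, continuant = 3, high = 2, nasal = 1),
    pitch_ranks = c(voiced = 4, continuant = 3, high = 2, nasal = 1))
  ps <- generate_phoneme_stream(cfg)
  st <- feature_stats(ps$annotation, ps$lexicon)
  got <- st$duration_rank[match(c("nasal", "high", "continuant", "voiced"),
                                st$feature)]
  expect_equal(got, 1:4)
})
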