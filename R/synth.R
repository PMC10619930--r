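#' Reference feature-timing statistics for German child-directed speech
#'
#' Per-feature median duration of feature-continuous stretches (ms) and the
#' derived duration, pitch-similarity and occurrence ranks in German
#' child-directed speech, used as the default calibration targets of the
#' synthetic-data generator. Ranks run 1..17 from smallest/least to
#' largest/most.
#'
#' @return data.frame: feature, median_ms, duration_rank,
#'   pitch_similarity_rank, occurrence_rank.
#' @export
feature_timing_reference <- function() {
  data.frame(
    feature = phonological_features(),
    median_ms = c(228, 197, 178, 132, 121, 120, 116, 116, 110, 109, 109,
                  102, 92, 90, 70, 69, 68),
    duration_rank = c(17L, 16L, 15L, 14L, 13L, 12L, 11L, 10L, 9L, 8L, 7L,
                      6L, 5L, 4L, 3L, 2L, 1L),
    pitch_similarity_rank = c(17L, 15L, 16L, 5L, 10L, 12L, 2L, 13L, 6L, 14L,
                              4L, 8L, 9L, 11L, 7L, 3L, 1L),
    occurrence_rank = c(17L, 15L, 16L, 5L, 8L, 11L, 4L, 14L, 2L, 12L, 3L,
                        9L, 10L, 13L, 6L, 7L, 1L),
    stringsAsFactors = FALSE)
}

#' 1/f ("pink") noise
#'
#' Gaussian noise with power spectral density proportional to
#' `1/f^exponent`, generated in the frequency domain, unit variance. The
#' slow-dominated background of the developing EEG is well approximated by
#' `exponent = 1`.
#'
#' @param n number of samples.
#' @param exponent spectral exponent (0 gives white noise).
#' @return Numeric vector of length `n`, sd 1.
#' @export
pink_noise <- function(n, exponent = 1) {
  if (n < 2) return(stats::rnorm(n))
  nf <- n %/% 2
  f <- seq_len(nf)
  amp <- f^(-exponent / 2)
  ph <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- complex(real = numeric(n))
  full[2:(nf + 1)] <- spec
  if (n %% 2 == 0) {
    full[nf + 1] <- complex(real = Mod(spec[nf]))
    full[(nf + 2):n] <- Conj(spec[(nf - 1):1])
  } else {
    full[(nf + 2):n] <- Conj(spec[nf:1])
  }
  x <- Re(stats::fft(full, inverse = TRUE))
  as.numeric(scale(x))
}

#' Difference-of-gammas TRF kernel
#'
#' A smooth, biphasic response kernel on the positive-lag part of the lag
#' window (zero at negative lags): a gamma-shaped peak minus a delayed,
#' scaled gamma-shaped trough, resembling infant auditory cortical responses
#' peaking at 100--250 ms. Normalized to unit Euclidean norm.
#'
#' @param lag_window lag window, ms.
#' @param fs sampling rate, Hz.
#' @param peak_ms,trough_ms latencies of the positive peak and the negative
#'   trough.
#' @param trough_scale relative amplitude of the trough.
#' @return Numeric vector over the lag grid of [lag_design_matrix()].
#' @export
trf_kernel <- function(lag_window = c(-150, 400), fs = 100, peak_ms = 120,
                       trough_ms = 250, trough_scale = 0.5) {
  lags <- seq.int(round(lag_window[1] / 1000 * fs),
                  round(lag_window[2] / 1000 * fs)) / fs * 1000
  g <- function(t, peak, shape = 4) {
    s <- peak / (shape - 1)
    out <- ifelse(t > 0, (t / s)^(shape - 1) * exp(-(t - peak) / s), 0)
    out / max(out)
  }
  k <- g(lags, peak_ms) - trough_scale * g(lags, trough_ms, shape = 6)
  k / sqrt(sum(k^2))
}

#' Synthetic-data generator configuration
#'
#' Bundles every knob of the synthetic cohort: cohort composition, signal
#' timing, feature run-length targets (defaulting to the reference
#' statistics of [feature_timing_reference()]), the forward-model kernel,
#' the noise model, and the accuracy-scale effect sizes of the record-level
#' generator. The seed is part of the configuration; regeneration from an
#' identical configuration is bit-identical.
#'
#' @param ... overrides of the defaults listed below.
#' @return Classed list (`synth_config`).
#' @export
generator_config <- function(...) {
  ref <- feature_timing_reference()
  cfg <- list(
    # cohort
    n_participants = 66L, n_female = 40L, age_range_months = c(3, 54),
    # signals
    fs = 100, duration_s = 450,
    features = ref$feature,
    duration_targets_ms = stats::setNames(ref$median_ms, ref$feature),
    occurrence_ranks = stats::setNames(ref$occurrence_rank, ref$feature),
    pitch_ranks = stats::setNames(ref$pitch_similarity_rank, ref$feature),
    occupancy = NULL,                 # derived from occurrence ranks if NULL
    mean_phoneme_s = 0.05, phoneme_shape = 4,
    silence_prob = 0.06, silence_range_s = c(0.1, 0.4),
    # forward model
    lag_window = c(-150, 400), kernel_peak_ms = 120, kernel_trough_ms = 250,
    kernel_trough_scale = 0.5, n_electrodes = 8L,
    noise_exponent = 1, snr_db = 0,
    # pitch
    f0_mean = 220, f0_depth = 40, pitch_coupling = 1,
    # record-level effect sizes (prediction-accuracy scale)
    r0 = 0.01, beta_condition = 0.0015, beta_baseline = 0.0015,
    crossover_condition = 28, crossover_baseline = 14,
    sd_participant = 0.01, sd_resid = 0.012,
    slope_mean = 0.001, slope_per_rank = 5e-5,
    rank_link = "duration",           # "duration", "pitch" or "none"
    decouple_ranks = FALSE,
    sd_feature = 0.005, sd_resid_feature = 0.02,
    sd_baseline_feature = 0.005,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown generator option(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(cfg, over)
  if (any(cfg$duration_targets_ms <= 0)) stop("duration targets must be > 0")
  if (!is.finite(cfg$snr_db)) stop("snr_db must be finite")
  if (!cfg$rank_link %in% c("duration", "pitch", "none"))
    stop("rank_link must be 'duration', 'pitch' or 'none'")
  structure(cfg, class = "synth_config")
}

# simulate one stream of phoneme slots given per-feature persistence
sample_stream <- function(cfg, stay_on, stay_off, occ) {
  n_f <- length(cfg$features)
  t <- 0; onsets <- c(); offsets <- c(); states <- list()
  state <- stats::rbinom(n_f, 1, occ)
  i <- 0L
  while (t < cfg$duration_s) {
    i <- i + 1L
    dur <- stats::rgamma(1, shape = cfg$phoneme_shape,
                         rate = cfg$phoneme_shape / cfg$mean_phoneme_s)
    dur <- max(dur, 0.01)
    onsets[i] <- t; offsets[i] <- t + dur
    states[[i]] <- state
    t <- t + dur
    if (cfg$silence_prob > 0 && stats::runif(1) < cfg$silence_prob)
      t <- t + stats::runif(1, cfg$silence_range_s[1], cfg$silence_range_s[2])
    keep <- stats::runif(n_f) < ifelse(state == 1, stay_on, stay_off)
    state <- ifelse(keep, state, 1 - state)
  }
  # truncate the final slot so the stream has exactly the configured length
  keep_i <- onsets < cfg$duration_s - 1e-9
  onsets <- onsets[keep_i]
  offsets <- pmin(offsets[keep_i], cfg$duration_s)
  states <- states[keep_i]
  pat <- vapply(states, paste, "", collapse = "")
  labels <- paste0("s", pat)
  upat <- !duplicated(pat)
  tab <- do.call(rbind, states[upat])
  rownames(tab) <- labels[upat]
  colnames(tab) <- cfg$features
  lex <- feature_lexicon(tab)
  ann <- phoneme_annotation(labels, onsets, offsets,
                            total_duration = cfg$duration_s)
  list(annotation = ann, lexicon = lex)
}

#' Generate a speech-like phoneme stream
#'
#' Samples a stream of phoneme-sized slots (gamma-distributed durations,
#' mean ~50 ms, matching the ~20 phonemes/s rate of child-directed speech,
#' with occasional silent pauses) whose binary feature trajectories follow
#' independent two-state Markov chains. Each slot's label encodes its feature
#' bundle, so the returned annotation and lexicon are mutually consistent.
#' Per-feature persistence is calibrated iteratively so that the realized
#' median durations of merged feature runs (silence-appended, as measured by
#' [expand_features()]) match the configured targets within tolerance;
#' infeasible targets (shorter than the mean phoneme) are an error.
#'
#' @param cfg a [generator_config()].
#' @param calibrate run the median-duration calibration loop (default TRUE).
#' @param tolerance relative tolerance of the calibration (0.15).
#' @return List: `annotation` ([phoneme_annotation()]), `lexicon`
#'   ([feature_lexicon()]), `realized_ms` (named medians), `persistence`
#'   (calibrated stay-probabilities), `config`.
#' @export
generate_phoneme_stream <- function(cfg = generator_config(),
                                    calibrate = TRUE, tolerance = 0.15) {
  set.seed(cfg$seed)
  n_f <- length(cfg$features)
  targets <- cfg$duration_targets_ms
  fin <- is.finite(targets)
  if (any(targets[fin] / 1000 < cfg$mean_phoneme_s))
    stop("infeasible duration target(s): shorter than the mean phoneme (",
         paste(names(targets)[fin & targets / 1000 < cfg$mean_phoneme_s],
               collapse = ", "), ")")
  occ <- cfg$occupancy
  if (is.null(occ)) {
    occ <- if (n_f > 1)
      0.15 + 0.5 * (cfg$occurrence_ranks[cfg$features] - 1) / (n_f - 1)
    else 0.5
  }
  occ <- rep_len(occ, n_f)
  ell <- ifelse(fin, pmax(0.4, targets / 1000 / cfg$mean_phoneme_s), Inf)
  persistence <- function(ell) ifelse(is.finite(ell), 0.5^(1 / ell), 1)
  off_persistence <- function(q) {
    p <- 1 - (1 - q) * occ / pmax(1 - occ, 1e-6)
    pmin(pmax(p, 0.02), 0.995)
  }
  measure <- function(stream) {
    spans <- expand_features(stream$annotation, stream$lexicon)
    median_feature_duration(spans)
  }
  if (calibrate && any(fin)) {
    # common random numbers: the same calibration stream is redrawn each
    # iteration, making realized-vs-requested run length a smooth monotone
    # function of the persistence parameter
    cal_cfg <- cfg
    cal_cfg$duration_s <- max(min(cfg$duration_s, 300), 120)
    for (iter in 1:15) {
      q <- persistence(ell)
      set.seed(cfg$seed + 7919L)
      stream <- sample_stream(cal_cfg, q, off_persistence(q), occ)
      got <- measure(stream)
      ratio <- targets / got
      ok <- fin & is.finite(ratio)
      if (all(abs(got[ok] - targets[ok]) / targets[ok] < tolerance * 0.6))
        break
      ell[ok] <- pmin(pmax(ell[ok] * ratio[ok]^0.9, 0.25), 120)
    }
  }
  # rejection step: redraw until the realized medians meet tolerance
  q <- persistence(ell)
  best <- NULL; best_err <- Inf
  for (attempt in 0:5) {
    set.seed(cfg$seed + attempt)
    stream <- sample_stream(cfg, q, off_persistence(q), occ)
    got <- measure(stream)
    err <- max(abs(got[fin] - targets[fin]) / targets[fin], 0, na.rm = TRUE)
    if (err < best_err) {
      best <- list(stream = stream, got = got)
      best_err <- err
    }
    if (!calibrate || best_err < tolerance) break
  }
  list(annotation = best$stream$annotation, lexicon = best$stream$lexicon,
       realized_ms = best$got, persistence = q, config = cfg)
}

#' Generate a prosody-like pitch track
#'
#' A fundamental-frequency contour whose modulation power is concentrated
#' below 4 Hz (a sum of slow random sinusoids around `f0_mean`), gated by a
#' voicing mask. With `pitch_coupling = 1` the mask is the voiced-feature
#' step function itself; with 0 it is an independent (circularly shifted)
#' mask with the same occupancy; intermediate values blend the two.
#'
#' @param cfg a [generator_config()].
#' @param voiced_mask 0/1 vector: the voiced-feature step function at
#'   `cfg$fs`. Required.
#' @return A [predictor_set()] of kind `"pitch"`.
#' @export
generate_pitch <- function(cfg = generator_config(), voiced_mask) {
  n <- length(voiced_mask)
  tt <- seq_len(n) / cfg$fs
  k <- 8
  fr <- stats::runif(k, 0.3, 3.5)
  ph <- stats::runif(k, 0, 2 * pi)
  am <- 1 / sqrt(fr)
  slow <- colSums(am * sin(outer(fr, 2 * pi * tt) + ph))
  slow <- slow / max(stats::sd(slow), 1e-12) * 0.5
  cpl <- cfg$pitch_coupling
  v <- as.numeric(voiced_mask)
  if (cpl >= 1) {
    mask <- v
  } else {
    shifted <- v[((seq_len(n) - 1 + n %/% 3) %% n) + 1]
    zs <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x
    s <- cpl * zs(v) + (1 - cpl) * zs(shifted)
    mask <- as.numeric(s >= stats::quantile(s, 1 - mean(v)))
  }
  f0 <- (cfg$f0_mean + cfg$f0_depth * pmax(pmin(slow, 1), -1)) * mask
  predictor_set(matrix(f0, ncol = 1), cfg$fs, names = "F0", kind = "pitch")
}

#' Simulate EEG from predictors and ground-truth kernels
#'
#' The forward model mirrors the TRF estimator: the response at the driven
#' electrode is the sum over predictors of the lagged convolution with each
#' predictor's kernel, scaled by a participant gain; electrodes receive the
#' signal through a fixed exponentially decaying mixing profile, plus
#' independent 1/f noise scaled to the requested SNR. Optional artifacts
#' (amplitude spikes, flat channels) support preprocessing tests.
#'
#' @param pred a [predictor_set()] (or matrix with `cfg$fs`).
#' @param kernels matrix (lags x predictors) of generating kernels on the
#'   lag grid of `cfg$lag_window`; an error is raised when the kernel length
#'   does not match the window.
#' @param cfg a [generator_config()].
#' @param gain scalar participant gain multiplying all kernels.
#' @param snr_db signal-to-noise ratio (dB) per electrode; defaults to
#'   `cfg$snr_db`.
#' @param artifacts optional list: `spike_epochs` (1-based 1-s epoch indices
#'   receiving a `spike_uv` deflection on every channel, default 250),
#'   `flat_channels` (labels set to constant zero).
#' @return An [eeg_recording()] with attributes `truth` (kernels, gain,
#'   mixing) for downstream comparison.
#' @export
simulate_eeg <- function(pred, kernels, cfg = generator_config(), gain = 1,
                         snr_db = cfg$snr_db, artifacts = NULL) {
  pm <- if (inherits(pred, "predictor_set")) pred$data else as.matrix(pred)
  kernels <- as.matrix(kernels)
  lags <- seq.int(round(cfg$lag_window[1] / 1000 * cfg$fs),
                  round(cfg$lag_window[2] / 1000 * cfg$fs))
  if (nrow(kernels) != length(lags))
    stop("kernel length ", nrow(kernels), " does not fit the ",
         cfg$lag_window[1], "..", cfg$lag_window[2], " ms window (",
         length(lags), " lags)")
  if (ncol(kernels) != ncol(pm))
    stop("one kernel column per predictor is required")
  X <- lag_design_matrix(pm, cfg$lag_window, cfg$fs)
  drive <- as.numeric(X %*% as.vector(t(kernels))) * gain
  E <- cfg$n_electrodes
  mix <- exp(-(seq_len(E) - 1) / 2)
  labels <- attr(standard_montage(), "analysis_set")[seq_len(E)]
  n <- nrow(pm)
  sig <- outer(drive, mix)
  ref_sd <- stats::sd(drive)
  if (ref_sd == 0) ref_sd <- 1
  out <- sig
  for (e in seq_len(E)) {
    s_sd <- stats::sd(sig[, e])
    if (s_sd == 0) s_sd <- ref_sd * mix[e]
    out[, e] <- sig[, e] + pink_noise(n, cfg$noise_exponent) *
      s_sd * 10^(-snr_db / 20)
  }
  if (!is.null(artifacts)) {
    L <- round(cfg$fs)
    for (ep in artifacts$spike_epochs) {
      amp <- if (is.null(artifacts$spike_uv)) 250 else artifacts$spike_uv
      at <- (ep - 1L) * L + L %/% 2L
      if (at <= n) out[at, ] <- out[at, ] + amp
    }
    for (chn in artifacts$flat_channels) {
      out[, match(chn, labels)] <- 0
    }
  }
  rec <- eeg_recording(out, cfg$fs, channel_names = labels)
  attr(rec, "truth") <- list(kernels = kernels, gain = gain, mix = mix,
                             lag_window = cfg$lag_window)
  rec
}

#' Generate a simulated cross-sectional cohort
#'
#' The cohort generator has two tiers. The default record level draws
#' per-participant, per-condition prediction accuracies (and per-feature
#' baseline-corrected accuracies) directly from the configured accuracy-scale
#' model: native-condition accuracy grows linearly with age while non-native
#' accuracy stays flat, the native-minus-non-native difference crosses zero
#' at `crossover_condition` months and the native-minus-baseline difference
#' at `crossover_baseline` months; per-feature developmental slopes are tied
#' to the configured rank link (duration rank, pitch-similarity rank, or
#' none). The signal level (`level = "signals"`) instead synthesizes
#' predictor streams and EEG per participant via
#' [generate_phoneme_stream()] and [simulate_eeg()] with age-dependent gains,
#' for end-to-end pipeline tests at small problem sizes.
#'
#' When `decouple_ranks = TRUE` the non-linked rank column is replaced by an
#' independent random permutation, which is the dissociation design for
#' separating duration from pitch-similarity effects.
#'
#' @param cfg a [generator_config()].
#' @param level `"records"` or `"signals"`.
#' @return For `"records"`: list with `records` (participant x condition
#'   rows: participant, age_months, sex, condition, condition_code,
#'   r_observed, r_baseline), `feature_records` (participant x feature rows
#'   adding feature, ranks, r_observed, r_baseline) and `truth` (true slopes,
#'   ranks, config). For `"signals"`: list with `participants` (each holding
#'   predictors, EEG and gain per condition), `kernels`, `truth`.
#' @export
generate_cohort <- function(cfg = generator_config(),
                            level = c("records", "signals")) {
  level <- match.arg(level)
  set.seed(cfg$seed)
  n <- cfg$n_participants
  ages <- stats::runif(n, cfg$age_range_months[1], cfg$age_range_months[2])
  sex <- sample(rep(c("f", "m"), c(cfg$n_female, n - cfg$n_female)))
  pid <- sprintf("p%03d", seq_len(n))
  if (level == "signals") return(generate_cohort_signals(cfg, pid, ages, sex))
  u <- stats::rnorm(n, 0, cfg$sd_participant)
  r_non <- cfg$r0 + u + stats::rnorm(n, 0, cfg$sd_resid)
  r_nat <- cfg$r0 + u +
    cfg$beta_condition * (ages - cfg$crossover_condition) +
    stats::rnorm(n, 0, cfg$sd_resid)
  base_nat <- r_nat -
    (cfg$beta_baseline * (ages - cfg$crossover_baseline) +
       stats::rnorm(n, 0, cfg$sd_resid))
  base_non <- stats::rnorm(n, 0, cfg$sd_resid)
  records <- data.frame(
    participant = rep(pid, 2),
    age_months = rep(ages, 2),
    sex = rep(sex, 2),
    condition = rep(c("native", "nonnative"), each = n),
    r_observed = c(r_nat, r_non),
    r_baseline = c(base_nat, base_non),
    stringsAsFactors = FALSE)
  records$condition_code <- condition_code(records$condition)
  # per-feature tier
  ref <- feature_timing_reference()
  ref <- ref[match(cfg$features, ref$feature), ]
  dur_rank <- ref$duration_rank
  pit_rank <- ref$pitch_similarity_rank
  occ_rank <- ref$occurrence_rank
  if (anyNA(dur_rank)) {  # non-canonical feature sets: rank by target
    dur_rank <- as.integer(rank_features(cfg$duration_targets_ms))
    pit_rank <- dur_rank
    occ_rank <- as.integer(rank_features(cfg$occurrence_ranks))
  }
  if (cfg$decouple_ranks) {
    if (cfg$rank_link == "pitch") dur_rank <- sample(dur_rank)
    else pit_rank <- sample(pit_rank)
  }
  link <- switch(cfg$rank_link, duration = dur_rank, pitch = pit_rank,
                 none = rep(mean(dur_rank), length(dur_rank)))
  slopes <- cfg$slope_mean + cfg$slope_per_rank * (link - mean(link))
  n_f <- length(cfg$features)
  v_f <- stats::rnorm(n_f, 0, cfg$sd_feature)
  u2 <- stats::rnorm(n, 0, cfg$sd_participant)
  fr <- expand.grid(fi = seq_len(n_f), i = seq_len(n))
  y <- slopes[fr$fi] * (ages[fr$i] - cfg$crossover_baseline) +
    v_f[fr$fi] + u2[fr$i] +
    stats::rnorm(nrow(fr), 0, cfg$sd_resid_feature)
  base_f <- stats::rnorm(nrow(fr), 0, cfg$sd_baseline_feature)
  feature_records <- data.frame(
    participant = pid[fr$i],
    age_months = ages[fr$i],
    sex = sex[fr$i],
    condition = "native",
    feature = cfg$features[fr$fi],
    duration_rank = dur_rank[fr$fi],
    occurrence_rank = occ_rank[fr$fi],
    pitch_similarity_rank = pit_rank[fr$fi],
    r_observed = base_f + y,
    r_baseline = base_f,
    stringsAsFactors = FALSE)
  truth <- list(slopes = stats::setNames(slopes, cfg$features),
                duration_rank = dur_rank, pitch_rank = pit_rank,
                occurrence_rank = occ_rank, ages = ages, sex = sex,
                config = cfg)
  list(records = records, feature_records = feature_records, truth = truth)
}

generate_cohort_signals <- function(cfg, pid, ages, sex) {
  stream_cfg <- cfg
  stream <- generate_phoneme_stream(stream_cfg)
  spans <- expand_features(stream$annotation, stream$lexicon)
  n_samp <- round(cfg$duration_s * cfg$fs)
  pred_nat <- build_feature_predictor(spans, cfg$fs, n_samp)
  stream_cfg$seed <- cfg$seed + 5000L
  stream2 <- generate_phoneme_stream(stream_cfg)
  spans2 <- expand_features(stream2$annotation, stream2$lexicon)
  pred_non <- build_feature_predictor(spans2, cfg$fs, n_samp)
  L <- length(seq.int(round(cfg$lag_window[1] / 1000 * cfg$fs),
                      round(cfg$lag_window[2] / 1000 * cfg$fs)))
  n_f <- length(cfg$features)
  kernels <- vapply(seq_len(n_f), function(f)
    trf_kernel(cfg$lag_window, cfg$fs,
               peak_ms = cfg$kernel_peak_ms + 10 * (f - 1) %% 50,
               trough_ms = cfg$kernel_trough_ms,
               trough_scale = cfg$kernel_trough_scale),
    numeric(L))
  g_nat <- pmax(0.1 + 0.9 * (ages - cfg$crossover_baseline) /
                  diff(cfg$age_range_months), 0)
  g_non <- rep(mean(g_nat), length(ages))
  participants <- lapply(seq_along(pid), function(i) {
    list(id = pid[i], age_months = ages[i], sex = sex[i],
         native = list(pred = pred_nat,
                       eeg = simulate_eeg(pred_nat, kernels, cfg,
                                          gain = g_nat[i])),
         nonnative = list(pred = pred_non,
                          eeg = simulate_eeg(pred_non, kernels, cfg,
                                             gain = g_non[i])))
  })
  list(participants = participants, kernels = kernels,
       truth = list(gain_native = g_nat, gain_nonnative = g_non,
                    ages = ages, sex = sex, config = cfg))
}
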