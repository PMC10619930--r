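## Automated cleaning for developmental continuous-speech EEG: zero-phase FIR
## filtering, three-rule bad-channel detection, level-13 wavelet thresholding,
## spherical-spline interpolation, linked-mastoid referencing and
## amplitude-based 1-s epoch rejection with zero-padded recombination.

# zero-phase application of a linear-phase FIR filter (odd tap count):
# reflect-pad by the group delay, FFT-convolve, compensate the delay
fir_zerophase <- function(x, h) {
  L <- length(h)
  if (L %% 2L == 0L) stop("filter must have odd length (even order)")
  d <- (L - 1L) %/% 2L
  n <- length(x)
  if (n < 3L * (L - 1L))
    stop("signal too short to pad for filter order ", L - 1L)
  xp <- c(rev(x[2:(d + 1L)]), x, rev(x[(n - d):(n - 1L)]))
  z <- stats::convolve(xp, rev(h), type = "open")
  z[(2L * d + 1L):(2L * d + n)]
}

fir_zerophase_mat <- function(mat, h) {
  apply(mat, 2, fir_zerophase, h = h)
}

#' High-pass and low-pass FIR filtering of a recording
#'
#' Zero-phase (noncausal, delay-compensated) Hamming-window FIR filters:
#' a high-pass of order 1650 with -6 dB cutoff 0.5 Hz (removes slow drifts,
#' which are typically artifactual in infant data) followed by a low-pass of
#' order 332 with -6 dB cutoff 47.5 Hz (removes line noise). The stated
#' orders are defined at the native 500 Hz sampling rate.
#'
#' @param rec an [eeg_recording()] at 500 Hz.
#' @param hp_order,hp_cutoff,lp_order,lp_cutoff filter parameters (order in
#'   taps minus one; cutoffs in Hz at the -6 dB point).
#' @return The filtered [eeg_recording()].
#' @export
bandpass_filters <- function(rec, hp_order = 1650, hp_cutoff = 0.5,
                             lp_order = 332, lp_cutoff = 47.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (abs(rec$fs - 500) > 1e-9)
    stop("filter orders are defined at fs = 500 Hz; resample first or pass ",
         "orders appropriate for ", rec$fs, " Hz")
  nyq <- rec$fs / 2
  h_hp <- signal::fir1(hp_order, hp_cutoff / nyq, type = "high")
  h_lp <- signal::fir1(lp_order, lp_cutoff / nyq, type = "low")
  out <- fir_zerophase_mat(rec$data, h_hp)
  out <- fir_zerophase_mat(out, h_lp)
  eeg_recording(out, rec$fs, rec$channel_names, rec$bad_channels,
                rec$reference)
}

#' Rescaled-range (R/S) Hurst exponent estimate
#'
#' Classic R/S estimator over dyadic window sizes: for each window length the
#' rescaled range (range of the cumulative mean-corrected sum divided by the
#' window standard deviation) is averaged over blocks, and the Hurst exponent
#' is the log-log slope. Long signals are truncated to `max_n` samples.
#'
#' @param x numeric vector.
#' @param max_n cap on the number of samples used (speed).
#' @return Scalar Hurst estimate (about 0.5 for white noise, near 1 for
#'   strongly persistent signals).
#' @export
hurst_rs <- function(x, max_n = 16384L) {
  x <- as.numeric(x)
  if (length(x) > max_n) x <- x[seq_len(max_n)]
  n <- length(x)
  if (n < 64L) stop("too few samples for an R/S estimate")
  sizes <- 2^(3:floor(log2(n / 2)))
  rs <- vapply(sizes, function(m) {
    k <- floor(n / m)
    vals <- vapply(seq_len(k), function(b) {
      seg <- x[((b - 1L) * m + 1L):(b * m)]
      s <- stats::sd(seg)
      if (!is.finite(s) || s == 0) return(NA_real_)
      y <- cumsum(seg - mean(seg))
      (max(y) - min(y)) / s
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(rs) & rs > 0
  if (sum(ok) < 2L) return(NA_real_)
  unname(stats::coef(stats::lm(log(rs[ok]) ~ log(sizes[ok])))[2])
}

# Welch average log power per channel over a frequency band
welch_log_power <- function(mat, fs, band = c(1, 100)) {
  n <- nrow(mat)
  seg <- min(n, round(2 * fs))
  seg <- 2L * (seg %/% 2L)
  step <- seg %/% 2L
  starts <- seq(1L, n - seg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg) / (seg + 1))
  freqs <- (0:(seg %/% 2L)) * fs / seg
  sel <- freqs >= band[1] & freqs <= min(band[2], fs / 2)
  psd <- matrix(0, sum(sel), ncol(mat))
  for (s in starts) {
    block <- mat[s:(s + seg - 1L), , drop = FALSE] * win
    sp <- Mod(stats::mvfft(block)[1:(seg %/% 2L + 1L), , drop = FALSE])^2
    psd <- psd + sp[sel, , drop = FALSE]
  }
  psd <- psd / length(starts)
  colMeans(log(psd + 1e-300))
}

#' Detect noisy channels
#'
#' A channel is flagged when it meets any of three criteria:
#' (i) flat (constant) for longer than `flat_s` consecutive seconds;
#' (ii) R/S Hurst exponent below `hurst_threshold` (see [hurst_rs()]);
#' (iii) its average log power from 1 to 100 Hz deviates from the
#' across-channel mean by more than `power_sd` standard deviations.
#'
#' @param rec an [eeg_recording()] (>= 4 channels; power z-scoring is
#'   undefined otherwise).
#' @param flat_s flat-run criterion, seconds.
#' @param hurst_threshold minimum acceptable Hurst exponent.
#' @param power_sd z-score criterion on average log band power.
#' @return Character vector of flagged channel labels (possibly empty), with
#'   attribute `"criteria"`: a logical matrix channels x rule.
#' @export
detect_bad_channels <- function(rec, flat_s = 30, hurst_threshold = 0.7,
                                power_sd = 2.75) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (ncol(rec$data) < 4L)
    stop("need at least 4 channels to z-score channel power")
  mat <- rec$data
  flat <- apply(mat, 2, function(x) {
    r <- rle(c(abs(diff(x)) < 1e-12, FALSE))
    runs <- r$lengths[r$values] + 1L
    length(runs) && max(runs) > flat_s * rec$fs
  })
  hur <- apply(mat, 2, function(x) {
    h <- hurst_rs(x)
    is.finite(h) && h < hurst_threshold
  })
  lp <- welch_log_power(mat, rec$fs, band = c(1, 100))
  # robust z: an extreme channel must not mask itself by inflating the SD
  s <- stats::mad(lp)
  if (!is.finite(s) || s == 0) s <- stats::sd(lp)
  z <- (lp - stats::median(lp)) / s
  pow <- is.finite(z) & abs(z) > power_sd
  crit <- cbind(flat = flat, hurst = hur, power = pow)
  rownames(crit) <- rec$channel_names
  out <- rec$channel_names[rowSums(crit) > 0]
  attr(out, "criteria") <- crit
  out
}

# --- orthogonal periodized DWT ------------------------------------------------
# Coiflet-4 analysis filters (24 taps, orthonormal). The synthesis step uses
# the adjoint of the analysis operator, which is exact for orthonormal
# filter banks.
coif4_lo <- c(
  -1.7849909144933469e-06, -3.2596479400307510e-06, 3.1229861599195265e-05,
  6.2338854312787192e-05, -2.5997433712225682e-04, -5.8902022463321654e-04,
  1.2665610789256603e-03, 3.7514346971460866e-03, -5.6582838001308835e-03,
  -1.5211728187697211e-02, 2.5082253337949612e-02, 3.9334422605589149e-02,
  -9.6220424535952642e-02, -6.6627472366817167e-02, 4.3438603311435653e-01,
  7.8223893442428261e-01, 4.1530842700068227e-01, -5.6077319603569258e-02,
  -8.1266710249193727e-02, 2.6682304669604830e-02, 1.6068947131575029e-02,
  -7.3461679362680507e-03, -1.6294924252267860e-03, 8.9231390253700297e-04)
coif4_hi <- rev(coif4_lo) * rep_len(c(1, -1), length(coif4_lo))

# fold a filter modulo n (periodization; exact for any even subband length)
fold_filter <- function(f, n) {
  fp <- numeric(n)
  idx <- ((seq_along(f) - 1L) %% n) + 1L
  for (j in seq_along(f)) fp[idx[j]] <- fp[idx[j]] + f[j]
  fp
}

circ_conv_fft <- function(x, f) {
  n <- length(x)
  Re(stats::fft(stats::fft(x) * stats::fft(fold_filter(f, n)),
                inverse = TRUE)) / n
}

circ_corr_fft <- function(u, f) {
  n <- length(u)
  Re(stats::fft(stats::fft(u) * Conj(stats::fft(fold_filter(f, n))),
                inverse = TRUE)) / n
}

dwt_analysis <- function(x, level) {
  details <- vector("list", level)
  a <- x
  for (j in seq_len(level)) {
    n <- length(a)
    details[[j]] <- circ_conv_fft(a, coif4_hi)[seq(2L, n, 2L)]
    a <- circ_conv_fft(a, coif4_lo)[seq(2L, n, 2L)]
  }
  list(approx = a, details = details)
}

dwt_synthesis <- function(dec) {
  a <- dec$approx
  for (j in rev(seq_along(dec$details))) {
    d <- dec$details[[j]]
    n <- 2L * length(d)
    ua <- numeric(n); ua[seq(2L, n, 2L)] <- a
    ud <- numeric(n); ud[seq(2L, n, 2L)] <- d
    a <- circ_corr_fft(ua, coif4_lo) + circ_corr_fft(ud, coif4_hi)
  }
  a
}

#' Wavelet thresholding of large artifacts
#'
#' Level-13 periodized orthogonal wavelet decomposition (coiflet-4) of every
#' channel; at each level, detail coefficients are compared with the
#' level-wise universal threshold `sigma_j * sqrt(2 log n_j)` (noise scale
#' `sigma_j` from the median absolute detail coefficient) and the artifact --
#' the soft-thresholded part, i.e. the suprathreshold excess of each
#' coefficient -- is removed before reconstruction, so that coefficients are
#' clamped at the threshold (`rule = "soft"`, default) or zeroed where they
#' exceed it (`rule = "hard"`). The approximation band is untouched: slow
#' content and the mean are preserved while large transient artifacts are
#' strongly attenuated and band-limited physiological oscillations (whose
#' coefficients sit below their level's threshold) pass through.
#'
#' @param rec an [eeg_recording()] with at least `2^level` samples.
#' @param level decomposition depth (13).
#' @param rule `"soft"` (clamp; remove the excess) or `"hard"` (zero
#'   suprathreshold coefficients).
#' @return The thresholded [eeg_recording()] (same length).
#' @export
wavelet_threshold <- function(rec, level = 13L, rule = c("soft", "hard")) {
  rule <- match.arg(rule)
  stopifnot(inherits(rec, "eeg_recording"))
  n0 <- nrow(rec$data)
  if (n0 < 2^level)
    stop("need at least 2^", level, " samples for a level-", level,
         " decomposition")
  block <- 2^level
  n_pad <- ceiling(n0 / block) * block
  out <- apply(rec$data, 2, function(x) {
    xp <- c(x, rev(x)[seq_len(n_pad - n0)])   # symmetric extension
    dec <- dwt_analysis(xp, level)
    dec$details <- lapply(dec$details, function(d) {
      sigma <- stats::median(abs(d)) / 0.6745
      thr <- sigma * sqrt(2 * log(max(length(d), 2L)))
      if (rule == "soft") sign(d) * pmin(abs(d), thr)   # x - soft(x)
      else d * (abs(d) <= thr)
    })
    dwt_synthesis(dec)[seq_len(n0)]
  })
  eeg_recording(out, rec$fs, rec$channel_names, rec$bad_channels,
                rec$reference)
}

# --- spherical splines --------------------------------------------------------

# Perrin-style spherical spline kernel g(cos angle), order m, truncated series
spline_g <- function(cosang, m = 4, n_terms = 50L) {
  x <- pmin(pmax(cosang, -1), 1)
  p_prev <- rep(1, length(x))   # P_0
  p_cur <- x                    # P_1
  acc <- (2 * 1 + 1) / (1 * 2)^m * p_cur
  for (n in 2:n_terms) {
    p_next <- ((2 * n - 1) * x * p_cur - (n - 1) * p_prev) / n
    acc <- acc + (2 * n + 1) / (n * (n + 1))^m * p_next
    p_prev <- p_cur
    p_cur <- p_next
  }
  matrix(acc / (4 * pi), nrow = nrow(cosang))
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces each flagged channel by a spherical-spline estimate (spline order
#' `m = 4`) computed from the good channels at their standard 10/10
#' positions, the method of choice for low-density montages.
#'
#' @param rec an [eeg_recording()].
#' @param bads channel labels to interpolate; defaults to `rec$bad_channels`.
#' @param m spline order.
#' @param n_terms Legendre series truncation.
#' @param reg ridge regularization added to the spline system diagonal.
#' @return An [eeg_recording()] with interpolated channels and an empty bad
#'   set.
#' @export
interpolate_channels <- function(rec, bads = NULL, m = 4, n_terms = 50L,
                                 reg = 1e-8) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(bads)) bads <- rec$bad_channels
  if (!length(bads)) return(rec)
  if (!all(bads %in% rec$channel_names))
    stop("unknown channel(s): ",
         paste(setdiff(bads, rec$channel_names), collapse = ", "))
  n_chan <- ncol(rec$data)
  if (length(bads) > n_chan / 2)
    stop("refusing to interpolate more than half of the channels (",
         length(bads), "/", n_chan, ")")
  good <- setdiff(rec$channel_names, bads)
  if (length(good) < 4L) stop("need at least 4 good channels")
  pos <- standard_montage(rec$channel_names)
  pg <- pos[good, , drop = FALSE]
  pb <- pos[bads, , drop = FALSE]
  G <- spline_g(pg %*% t(pg), m, n_terms)
  Gb <- spline_g(pb %*% t(pg), m, n_terms)
  ng <- length(good)
  A <- rbind(cbind(G + diag(reg, ng), rep(1, ng)), c(rep(1, ng), 0))
  Z <- rbind(t(rec$data[, good, drop = FALSE]), 0)
  C <- solve(A, Z)
  est <- t(Gb %*% C[seq_len(ng), , drop = FALSE] +
             matrix(C[ng + 1L, ], length(bads), ncol(C), byrow = TRUE))
  out <- rec$data
  out[, bads] <- est
  eeg_recording(out, rec$fs, rec$channel_names, character(), rec$reference)
}

#' Re-reference to linked mastoids
#'
#' Subtracts the mean of the two mastoid channels from every channel.
#'
#' @param rec an [eeg_recording()].
#' @param mastoids labels of the two mastoid channels.
#' @return The re-referenced [eeg_recording()] (reference set to
#'   `"linked-mastoids"`).
#' @export
rereference_mastoids <- function(rec, mastoids = c("M1", "M2")) {
  stopifnot(inherits(rec, "eeg_recording"))
  missing <- setdiff(mastoids, rec$channel_names)
  if (length(missing))
    stop("mastoid channel(s) missing: ", paste(missing, collapse = ", "))
  ref <- rowMeans(rec$data[, mastoids, drop = FALSE])
  out <- rec$data - ref
  eeg_recording(out, rec$fs, rec$channel_names, rec$bad_channels,
                reference = "linked-mastoids")
}

#' Epoch rejection and recombination for TRF estimation
#'
#' The cleaned EEG is band-pass filtered (default 1--10 Hz, zero-phase FIR)
#' and cut into consecutive epochs of `epoch_s` seconds. Epochs in which the
#' *unfiltered* input amplitude exceeds `threshold` microvolts on any channel
#' are dropped from both the EEG and the time-aligned predictors; the
#' surviving epochs are concatenated, with `epoch_s` seconds of zeros
#' inserted wherever dropped epochs created a discontinuity. The inserted
#' samples are flagged in `gap_mask` so that prediction-accuracy computations
#' can exclude them (they are deterministic zeros, not data).
#'
#' @param rec an [eeg_recording()] (cleaned, not yet 1--10 Hz filtered).
#' @param pred a [predictor_set()] (or matrix) time-aligned with `rec` at the
#'   same sampling rate.
#' @param threshold amplitude criterion, microvolts.
#' @param epoch_s epoch length, seconds.
#' @param min_retained_s minimum artifact-free duration for the
#'   participant/condition to be usable; falling short sets `excluded = TRUE`
#'   (with a warning), it is not an error.
#' @param band band-pass edges, Hz; `NULL` skips filtering (useful when `rec`
#'   is already band-limited).
#' @param transition FIR transition width, Hz (sets the filter order).
#' @return Object of class `trf_segments`: list with `eeg` (samples x
#'   channels), `pred` (samples x predictors), `fs`, `gap_mask` (logical),
#'   `keep` (logical per epoch), `retained_s`, `excluded`.
#' @export
epoch_reject_recombine <- function(rec, pred, threshold = 200, epoch_s = 1,
                                   min_retained_s = 350, band = c(1, 10),
                                   transition = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  pmat <- if (inherits(pred, "predictor_set")) {
    if (abs(pred$fs - rec$fs) > 1e-9)
      stop("predictors and EEG must share a sampling rate")
    pred$data
  } else as.matrix(pred)
  n <- min(nrow(rec$data), nrow(pmat))
  raw <- rec$data[seq_len(n), , drop = FALSE]
  pmat <- pmat[seq_len(n), , drop = FALSE]
  filt <- raw
  if (!is.null(band)) {
    ord <- 2L * ceiling(3.3 * rec$fs / transition / 2)
    h <- signal::fir1(ord, band / (rec$fs / 2), type = "pass")
    filt <- fir_zerophase_mat(raw, h)
  }
  L <- round(epoch_s * rec$fs)
  n_ep <- floor(n / L)
  if (n_ep < 1L) stop("recording shorter than one epoch")
  keep <- vapply(seq_len(n_ep), function(e) {
    idx <- ((e - 1L) * L + 1L):(e * L)
    max(abs(raw[idx, ])) <= threshold
  }, logical(1))
  kept <- which(keep)
  eeg_blocks <- list(); pred_blocks <- list(); gap_blocks <- list()
  if (length(kept)) {
    run_id <- cumsum(c(1L, diff(kept) != 1L))
    for (r in unique(run_id)) {
      eps <- kept[run_id == r]
      idx <- ((min(eps) - 1L) * L + 1L):(max(eps) * L)
      if (r > 1L) {   # a discontinuity precedes this run
        eeg_blocks <- c(eeg_blocks, list(matrix(0, L, ncol(raw))))
        pred_blocks <- c(pred_blocks, list(matrix(0, L, ncol(pmat))))
        gap_blocks <- c(gap_blocks, list(rep(TRUE, L)))
      }
      eeg_blocks <- c(eeg_blocks, list(filt[idx, , drop = FALSE]))
      pred_blocks <- c(pred_blocks, list(pmat[idx, , drop = FALSE]))
      gap_blocks <- c(gap_blocks, list(rep(FALSE, length(idx))))
    }
  }
  eeg_out <- do.call(rbind, eeg_blocks)
  pred_out <- do.call(rbind, pred_blocks)
  gap <- unlist(gap_blocks)
  if (is.null(eeg_out)) {
    eeg_out <- matrix(0, 0, ncol(raw))
    pred_out <- matrix(0, 0, ncol(pmat))
    gap <- logical(0)
  }
  colnames(eeg_out) <- rec$channel_names
  colnames(pred_out) <- colnames(pmat)
  retained <- sum(keep) * epoch_s
  excluded <- retained < min_retained_s
  if (excluded)
    warning(sprintf(
      "only %.0f s retained (< %.0f s): participant/condition excluded",
      retained, min_retained_s))
  structure(list(eeg = eeg_out, pred = pred_out, fs = rec$fs,
                 gap_mask = gap, keep = keep, retained_s = retained,
                 excluded = excluded),
            class = "trf_segments")
}

#' @exportS3Method base::print
print.trf_segments <- function(x, ...) {
  cat("<trf_segments> ", nrow(x$eeg), " samples @ ", x$fs, " Hz; ",
      sum(x$keep), "/", length(x$keep), " epochs kept (",
      format(x$retained_s), " s retained)",
      if (x$excluded) " [EXCLUDED]", "\n", sep = "")
  invisible(x)
}

#' One-call automatic preprocessing pipeline
#'
#' Chains the cleaning stages in their canonical order: band filtering
#' ([bandpass_filters()]), bad-channel detection ([detect_bad_channels()],
#' run on the high-passed but not low-passed signal so that the 1--100 Hz
#' power criterion sees the full band), wavelet thresholding
#' ([wavelet_threshold()]), spherical-spline interpolation of the detected
#' channels ([interpolate_channels()]) and linked-mastoid re-referencing
#' ([rereference_mastoids()]). Returns the cleaned recording together with a
#' structured log.
#'
#' @param rec an [eeg_recording()] at 500 Hz.
#' @param config optional named list (or path to a JSON file) overriding
#'   thresholds: `flat_s`, `hurst_threshold`, `power_sd`, `wavelet_level`,
#'   `mastoids`, `analysis_channels`.
#' @return List with `recording` (cleaned, restricted to the analysis
#'   channels if configured) and `log` (removed channels per rule, settings).
#' @export
preprocess_recording <- function(rec, config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  cfg <- utils::modifyList(
    list(flat_s = 30, hurst_threshold = 0.7, power_sd = 2.75,
         wavelet_level = 13L, mastoids = c("M1", "M2"),
         analysis_channels = NULL),
    config)
  nyq <- rec$fs / 2
  hp <- eeg_recording(
    fir_zerophase_mat(rec$data, signal::fir1(1650, 0.5 / nyq, type = "high")),
    rec$fs, rec$channel_names, rec$bad_channels, rec$reference)
  bads <- detect_bad_channels(hp, cfg$flat_s, cfg$hurst_threshold, cfg$power_sd)
  lowpassed <- eeg_recording(
    fir_zerophase_mat(hp$data, signal::fir1(332, 47.5 / nyq, type = "low")),
    rec$fs, rec$channel_names, as.character(bads), rec$reference)
  cleaned <- wavelet_threshold(lowpassed, level = cfg$wavelet_level)
  cleaned <- interpolate_channels(cleaned, as.character(bads))
  cleaned <- rereference_mastoids(cleaned, cfg$mastoids)
  if (!is.null(cfg$analysis_channels)) {
    sel <- cfg$analysis_channels
    cleaned <- eeg_recording(cleaned$data[, sel, drop = FALSE], cleaned$fs,
                             sel, character(), cleaned$reference)
  }
  list(recording = cleaned,
       log = list(bad_channels = as.character(bads),
                  criteria = attr(bads, "criteria"),
                  settings = cfg))
}
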