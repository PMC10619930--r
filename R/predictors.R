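#' Construct a predictor set
#'
#' A predictor set is a time-aligned multichannel regressor matrix at the
#' analysis sampling rate. Three kinds are used: binary feature step
#' functions (`"features"`), non-negative spectrogram band envelopes
#' (`"spectrogram"`, 16 columns) and a fundamental-frequency track
#' (`"pitch"`, one column, 0 where unvoiced).
#'
#' @param data numeric matrix, samples x predictors.
#' @param fs sampling rate, Hz.
#' @param names predictor labels; defaults to the column names.
#' @param kind one of `"features"`, `"spectrogram"`, `"pitch"`.
#' @return Object of class `predictor_set`.
#' @export
predictor_set <- function(data, fs, names = NULL,
                          kind = c("features", "spectrogram", "pitch")) {
  kind <- match.arg(kind)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  if (is.null(names)) names <- colnames(data)
  if (is.null(names)) names <- paste0(kind, seq_len(ncol(data)))
  if (length(names) != ncol(data)) stop("names length must match columns")
  if (kind == "features" && !all(data %in% c(0, 1)))
    stop("feature predictors must be binary step functions (0/1)")
  if (kind == "spectrogram") {
    if (ncol(data) != 16L) stop("spectrogram predictors must have 16 bands")
    if (any(data < 0)) stop("spectrogram envelopes must be non-negative")
  }
  if (kind == "pitch" && ncol(data) != 1L)
    stop("pitch predictor must be a single column")
  colnames(data) <- names
  structure(list(data = data, fs = as.numeric(fs), names = names, kind = kind),
            class = "predictor_set")
}

#' @exportS3Method base::print
print.predictor_set <- function(x, ...) {
  cat("<predictor_set> kind=", x$kind, ", ", nrow(x$data), " samples x ",
      ncol(x$data), " predictors @ ", x$fs, " Hz (",
      format(nrow(x$data) / x$fs, digits = 4), " s)\n", sep = "")
  invisible(x)
}

#' Rasterize feature spans into step-function predictors
#'
#' Each feature column is 1 at samples whose time lies inside any active span
#' of that feature and 0 elsewhere; sample `i` (1-based) covers time
#' `(i-1)/fs`, and spans are onset-inclusive, offset-exclusive.
#'
#' @param spans a `feature_intervals` object from [expand_features()], or a
#'   named list of data.frames with `onset`/`offset` columns (seconds).
#' @param fs analysis sampling rate, Hz.
#' @param n_samples number of samples of the output; spans must lie within
#'   `[0, n_samples/fs]`.
#' @return A [predictor_set()] of kind `"features"` (one column per feature,
#'   lexicon order).
#' @export
build_feature_predictor <- function(spans, fs, n_samples) {
  if (fs <= 0) stop("fs must be positive")
  n_samples <- as.integer(n_samples)
  limit <- n_samples / fs
  mat <- matrix(0, n_samples, length(spans))
  for (k in seq_along(spans)) {
    sp <- spans[[k]]
    if (!nrow(sp)) next
    if (any(sp$offset > limit + 1e-9) || any(sp$onset < -1e-9))
      stop("feature span exceeds signal range [0, ", format(limit), "] s")
    for (r in seq_len(nrow(sp))) {
      i0 <- ceiling(sp$onset[r] * fs - 1e-9) + 1L
      i1 <- ceiling(sp$offset[r] * fs - 1e-9)
      if (i1 >= i0) mat[i0:min(i1, n_samples), k] <- 1
    }
  }
  predictor_set(mat, fs, names = names(spans), kind = "features")
}

#' Log-spaced spectrogram predictor
#'
#' Short-time Fourier band-power envelopes pooled into `n_bands` channels
#' whose center frequencies are logarithmically spaced between `flo` and
#' `fhi`; band edges sit at the geometric midpoints between neighbouring
#' centers. Envelopes (root band power per frame) are non-negative and
#' sampled at the analysis rate `fs_out`.
#'
#' @param wave numeric waveform vector.
#' @param fs_audio audio sampling rate, Hz (>= 16 kHz).
#' @param fs_out analysis sampling rate of the output, Hz.
#' @param n_bands number of bands (16 by default).
#' @param flo,fhi band center range, Hz.
#' @param compress optional compressive nonlinearity applied to the
#'   envelopes: `"none"` (default) or `"log"` (`log(1 + x)`).
#' @return A [predictor_set()] of kind `"spectrogram"`.
#' @export
build_spectrogram <- function(wave, fs_audio, fs_out = 100, n_bands = 16,
                              flo = 250, fhi = 8000,
                              compress = c("none", "log")) {
  compress <- match.arg(compress)
  if (fs_audio < 16000) stop("audio sample rate must be >= 16 kHz")
  hop <- round(fs_audio / fs_out)
  nfft <- 2^ceiling(log2(0.025 * fs_audio))   # ~25 ms analysis frames
  if (length(wave) < nfft) stop("audio shorter than one analysis frame")
  centers <- flo * (fhi / flo)^((seq_len(n_bands) - 1) / (n_bands - 1))
  r <- (fhi / flo)^(1 / (n_bands - 1))
  edges <- c(centers[1] / sqrt(r), sqrt(centers[-n_bands] * centers[-1]),
             centers[n_bands] * sqrt(r))
  half <- nfft %/% 2
  freqs <- (0:half) * fs_audio / nfft
  band_of <- findInterval(freqs, edges)   # k: freqs in [edges[k], edges[k+1])
  pool <- matrix(0, half + 1L, n_bands)   # bin -> band aggregation
  for (b in seq_len(n_bands)) pool[band_of == b, b] <- 1
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nfft) / (nfft + 1))  # hann
  n_frames <- max(1L, floor(length(wave) / hop))
  padded <- c(numeric(half), wave, numeric(nfft))
  out <- matrix(0, n_frames, n_bands)
  starts <- (seq_len(n_frames) - 1L) * hop + 1L  # centered windows
  chunk <- 256L
  for (c0 in seq(1L, n_frames, by = chunk)) {
    fr <- c0:min(c0 + chunk - 1L, n_frames)
    seg <- vapply(starts[fr],
                  function(i) padded[i:(i + nfft - 1L)] * win,
                  numeric(nfft))
    pw <- Mod(stats::mvfft(seg)[1:(half + 1L), , drop = FALSE])^2
    out[fr, ] <- sqrt(crossprod(pw, pool))
  }
  if (compress == "log") out <- log1p(out)
  predictor_set(out, fs_out, names = sprintf("band_%04.0fHz", centers),
                kind = "spectrogram")
}

#' Autocorrelation pitch track predictor
#'
#' Frame-based fundamental-frequency (F0) estimation by the normalized
#' autocorrelation method with parabolic peak refinement, searching a
#' plausible range of 75--600 Hz. Frames whose autocorrelation peak falls
#' below the voicing threshold (or whose energy is negligible) are unvoiced
#' and set to 0.
#'
#' @inheritParams build_spectrogram
#' @param fmin,fmax F0 search range, Hz.
#' @param frame_s analysis frame length, seconds.
#' @param voicing_threshold minimum normalized autocorrelation peak for a
#'   frame to count as voiced.
#' @return A [predictor_set()] of kind `"pitch"` (F0 in Hz, 0 = unvoiced).
#' @export
build_pitch_track <- function(wave, fs_audio, fs_out = 100, fmin = 75,
                              fmax = 600, frame_s = 0.04,
                              voicing_threshold = 0.3) {
  if (fs_audio < 16000) stop("audio sample rate must be >= 16 kHz")
  flen <- round(frame_s * fs_audio)
  hop <- round(fs_audio / fs_out)
  lag_min <- max(2L, floor(fs_audio / fmax))
  lag_max <- ceiling(fs_audio / fmin)
  nfft <- 2^ceiling(log2(flen + lag_max + 1))
  n_frames <- max(1L, floor(length(wave) / hop))
  half <- flen %/% 2
  padded <- c(numeric(half), wave, numeric(flen + lag_max))
  glob_rms <- sqrt(mean(wave^2))
  f0 <- numeric(n_frames)
  for (f in seq_len(n_frames)) {
    i0 <- (f - 1L) * hop + 1L
    seg <- padded[i0:(i0 + flen - 1L)]
    seg <- seg - mean(seg)
    e0 <- sum(seg^2)
    if (e0 <= (1e-4 * glob_rms)^2 * flen || glob_rms == 0) next
    ac <- Re(stats::fft(Mod(stats::fft(c(seg, numeric(nfft - flen))))^2,
                        inverse = TRUE))[1:(lag_max + 1L)] / nfft
    r <- ac / ac[1]
    sel <- (lag_min:lag_max) + 1L
    k <- sel[which.max(r[sel])]
    if (r[k] < voicing_threshold) next
    # parabolic refinement around the peak
    tau <- k - 1L
    if (k > 2L && k < length(r)) {
      y1 <- r[k - 1L]; y2 <- r[k]; y3 <- r[k + 1L]
      den <- y1 - 2 * y2 + y3
      if (abs(den) > 1e-12) tau <- tau + 0.5 * (y1 - y3) / den
    }
    hz <- fs_audio / tau
    f0[f] <- min(max(hz, fmin), fmax)
  }
  predictor_set(matrix(f0, ncol = 1), fs_out, names = "F0", kind = "pitch")
}

#' Read a RIFF/WAVE audio file
#'
#' Minimal PCM reader: 16/24/32-bit integer and 32-bit float, mono or
#' multichannel (channels are averaged to mono). Samples are returned in
#' `[-1, 1]`.
#'
#' @param path file path.
#' @return List with `wave` (numeric vector) and `fs` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a RIFF/WAVE file")
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || !nzchar(id)) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "raw", sz)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + (sz %% 2L)))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV: missing chunk")
  u16 <- function(i) sum(as.integer(fmt[i:(i + 1)]) * c(1, 256))
  u32 <- function(i) sum(as.integer(fmt[i:(i + 3)]) * 256^(0:3))
  audio_fmt <- u16(1); n_chan <- u16(3); fs <- u32(5); bits <- u16(15)
  if (audio_fmt == 3 && bits == 32) {
    x <- readBin(data_raw, "double", length(data_raw) / 4, 4, endian = "little")
  } else if (audio_fmt == 1 && bits == 16) {
    x <- readBin(data_raw, "integer", length(data_raw) / 2, 2, signed = TRUE,
                 endian = "little") / 32768
  } else if (audio_fmt == 1 && bits == 32) {
    x <- readBin(data_raw, "integer", length(data_raw) / 4, 4,
                 endian = "little") / 2147483648
  } else if (audio_fmt == 1 && bits == 24) {
    b <- as.integer(data_raw)
    n <- length(b) %/% 3
    v <- b[seq(1, 3 * n, 3)] + 256 * b[seq(2, 3 * n, 3)] +
      65536 * b[seq(3, 3 * n, 3)]
    v <- ifelse(v >= 2^23, v - 2^24, v)
    x <- v / 2^23
  } else stop("unsupported WAV encoding (fmt ", audio_fmt, ", ", bits, " bit)")
  if (n_chan > 1) x <- rowMeans(matrix(x, ncol = n_chan, byrow = TRUE))
  list(wave = as.numeric(x), fs = fs)
}
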