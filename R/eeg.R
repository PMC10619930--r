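#' Construct an EEG recording
#'
#' @param data numeric matrix, samples x channels, microvolts.
#' @param fs sampling rate, Hz (500 for the native acquisition rate).
#' @param channel_names unique channel labels (10/10 montage names).
#' @param bad_channels character subset of `channel_names` flagged as noisy.
#' @param reference label of the (online) reference channel, default `"Cz"`.
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_names = NULL,
                          bad_channels = character(), reference = "Cz") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  if (is.null(channel_names)) channel_names <- colnames(data)
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(ncol(data)))
  if (length(channel_names) != ncol(data))
    stop("channel_names length must match columns")
  if (anyDuplicated(channel_names)) stop("channel names must be unique")
  if (!all(bad_channels %in% channel_names))
    stop("bad_channels must be a subset of channel_names")
  colnames(data) <- channel_names
  structure(list(data = data, fs = as.numeric(fs),
                 channel_names = channel_names,
                 bad_channels = as.character(bad_channels),
                 reference = reference),
            class = "eeg_recording")
}

#' @exportS3Method base::print
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$data), " samples x ", ncol(x$data),
      " channels @ ", x$fs, " Hz (", format(nrow(x$data) / x$fs, digits = 4),
      " s), reference ", x$reference, "\n", sep = "")
  if (length(x$bad_channels))
    cat("bad channels:", paste(x$bad_channels, collapse = ", "), "\n")
  invisible(x)
}

# spherical position from inclination (deg from vertex) and azimuth
# (deg, 0 = right ear, 90 = nasion), unit radius
sph_xyz <- function(incl, azim) {
  i <- incl * pi / 180; a <- azim * pi / 180
  c(x = sin(i) * cos(a), y = sin(i) * sin(a), z = cos(i))
}

slerp_mid <- function(p, q) {
  m <- (p + q) / 2
  m / sqrt(sum(m^2))
}

#' Standard 10/10 electrode positions
#'
#' Unit-sphere positions for the montage used by the preprocessing functions.
#' Anchor 10/20 electrodes are placed at their standard inclination/azimuth;
#' intermediate 10/10 labels (FC/CP rows) are constructed as spherical
#' midpoints of their neighbours. Mastoids (`M1`, `M2`) sit below the equator
#' behind the ears. Positions approximate the idealized spherical head and
#' are intended for spherical-spline interpolation, not source analysis.
#'
#' @param channels optional character vector to subset/order the result.
#' @return Matrix (channels x 3) of x/y/z unit coordinates, rownames =
#'   labels; attribute `"analysis_set"` carries the default 19-channel
#'   fronto-central analysis whitelist.
#' @export
standard_montage <- function(channels = NULL) {
  anchors <- list(
    Cz = c(0, 0), Fz = c(46, 90), Pz = c(46, -90), Oz = c(92, -90),
    C3 = c(46, 180), C4 = c(46, 0), T7 = c(92, 180), T8 = c(92, 0),
    Fp1 = c(92, 108), Fp2 = c(92, 72), O1 = c(92, -108), O2 = c(92, -72),
    F7 = c(92, 144), F8 = c(92, 36), P7 = c(92, -144), P8 = c(92, -36),
    F3 = c(60, 129), F4 = c(60, 51), P3 = c(60, -129), P4 = c(60, -51),
    M1 = c(110, -160), M2 = c(110, -20))
  pos <- t(vapply(anchors, function(a) sph_xyz(a[1], a[2]), numeric(3)))
  mid <- function(a, b) slerp_mid(pos[a, ], pos[b, ])
  pos <- rbind(pos,
    FCz = mid("Fz", "Cz"), CPz = mid("Cz", "Pz"),
    FC3 = mid("F3", "C3"), FC4 = mid("F4", "C4"),
    CP3 = mid("C3", "P3"), CP4 = mid("C4", "P4"),
    FT7 = mid("F7", "T7"), FT8 = mid("F8", "T8"),
    TP7 = mid("T7", "P7"), TP8 = mid("T8", "P8"))
  mid <- function(a, b) slerp_mid(pos[a, ], pos[b, ])
  pos <- rbind(pos,
    FC5 = mid("FC3", "FT7"), FC6 = mid("FC4", "FT8"),
    FC1 = mid("FCz", "FC3"), FC2 = mid("FCz", "FC4"),
    CP5 = mid("CP3", "TP7"), CP6 = mid("CP4", "TP8"),
    CP1 = mid("CPz", "CP3"), CP2 = mid("CPz", "CP4"))
  colnames(pos) <- c("x", "y", "z")
  if (!is.null(channels)) {
    missing <- setdiff(channels, rownames(pos))
    if (length(missing))
      stop("no position for channel(s): ", paste(missing, collapse = ", "))
    pos <- pos[channels, , drop = FALSE]
  }
  attr(pos, "analysis_set") <-
    c("Fz", "F3", "F4", "F7", "F8", "FC5", "FC6", "C3", "C4", "Cz",
      "T7", "T8", "CP5", "CP6", "Pz", "P3", "P4", "P7", "P8")
  pos
}

#' Default 28-channel infant cap layout
#'
#' Channel labels of the 28-electrode recording layout assumed by the
#' preprocessing defaults: the 19-channel fronto-central analysis set plus
#' fronto-polar, centro-parietal midline, occipital and mastoid electrodes.
#'
#' @return Character vector of 28 labels.
#' @export
default_cap <- function() {
  c("F7", "F3", "Fz", "F4", "F8", "FC5", "FC1", "FC2", "FC6",
    "T7", "C3", "Cz", "C4", "T8", "CP5", "CP1", "CP2", "CP6",
    "P7", "P3", "Pz", "P4", "P8", "O1", "Oz", "O2", "M1", "M2")
}

#' Read a BrainVision EEG file
#'
#' Reads the `.vhdr` header plus its data file. Supported data formats:
#' ASCII (vectorized or multiplexed) and binary `IEEE_FLOAT_32` /
#' `INT_16` multiplexed. Channel resolution (unit scaling) is applied.
#'
#' @param vhdr path to the `.vhdr` header file.
#' @return An [eeg_recording()].
#' @export
read_brainvision <- function(vhdr) {
  lines <- readLines(vhdr, warn = FALSE)
  get1 <- function(key) {
    ln <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (!length(ln)) return(NA_character_)
    sub(paste0("^", key, "="), "", ln[1])
  }
  datafile <- get1("DataFile")
  fmt <- get1("DataFormat")
  orient <- get1("DataOrientation")
  n_chan <- as.integer(get1("NumberOfChannels"))
  interval_us <- as.numeric(get1("SamplingInterval"))
  fs <- 1e6 / interval_us
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  ch_parts <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",")
  ch_names <- vapply(ch_parts, `[[`, "", 1L)
  resol <- vapply(ch_parts, function(p)
    if (length(p) >= 3 && nzchar(p[3])) as.numeric(p[3]) else 1, numeric(1))
  path <- file.path(dirname(vhdr), datafile)
  if (identical(toupper(fmt), "ASCII")) {
    dat <- as.matrix(utils::read.table(path, header = FALSE))
    if (identical(toupper(orient), "VECTORIZED")) dat <- t(dat)
  } else {
    bt <- get1("BinaryFormat")
    raw <- readBin(path, "raw", file.info(path)$size)
    if (identical(bt, "IEEE_FLOAT_32")) {
      v <- readBin(raw, "double", length(raw) / 4, 4, endian = "little")
    } else if (identical(bt, "INT_16")) {
      v <- readBin(raw, "integer", length(raw) / 2, 2, signed = TRUE,
                   endian = "little")
    } else stop("unsupported BinaryFormat: ", bt)
    if (identical(toupper(orient), "VECTORIZED")) {
      dat <- matrix(v, ncol = n_chan, byrow = FALSE)
    } else {
      dat <- matrix(v, ncol = n_chan, byrow = TRUE)
    }
  }
  dat <- sweep(dat[, seq_len(n_chan), drop = FALSE], 2, resol, `*`)
  eeg_recording(dat, fs, channel_names = ch_names)
}

#' Resample an EEG recording
#'
#' Polyphase resampling (via `signal::resample`) of every channel to a new
#' rate, used to bring filtered EEG to the analysis rate of the predictors.
#'
#' @param rec an [eeg_recording()].
#' @param fs_new target rate, Hz.
#' @return An [eeg_recording()] at `fs_new`.
#' @export
resample_recording <- function(rec, fs_new) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (fs_new == rec$fs) return(rec)
  fr <- as.integer(round(fs_new * 1000))
  to <- as.integer(round(rec$fs * 1000))
  g <- gcd_int(fr, to)
  p <- fr / g; q <- to / g
  out <- apply(rec$data, 2, function(x) signal::resample(x, p, q))
  n_new <- ceiling(nrow(rec$data) * p / q)
  out <- out[seq_len(min(nrow(out), n_new)), , drop = FALSE]
  eeg_recording(out, fs_new, rec$channel_names, rec$bad_channels,
                rec$reference)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)
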