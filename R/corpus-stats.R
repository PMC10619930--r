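#' Median feature duration
#'
#' The duration of a feature is measured per feature-continuous stretch, from
#' feature onset to offset (silence-appended, see [expand_features()]); the
#' summary per feature is the median over stretches, in milliseconds.
#'
#' @param spans a `feature_intervals` object from [expand_features()].
#' @return Named numeric vector of medians (ms); features with no spans are
#'   `NA`.
#' @export
median_feature_duration <- function(spans) {
  vapply(spans, function(sp) {
    if (!nrow(sp)) return(NA_real_)
    stats::median((sp$offset - sp$onset) * 1000)
  }, numeric(1))
}

#' Rank features by a statistic
#'
#' Rank 1 is assigned to the smallest value ("from shortest to longest",
#' "from least to most frequent", "from least to most similar"). Ties are
#' broken deterministically by the order of the input vector, which for the
#' canonical feature set is the fixed feature order of
#' [phonological_features()].
#'
#' @param values named numeric vector, one value per feature.
#' @return Named integer vector of ranks `1..length(values)` (a permutation).
#' @export
rank_features <- function(values) {
  if (anyNA(values)) {
    nm <- names(values)[which(is.na(values))]
    stop("missing value for feature(s): ",
         paste(if (is.null(nm)) which(is.na(values)) else nm, collapse = ", "))
  }
  r <- rank(values, ties.method = "first")
  storage.mode(r) <- "integer"
  names(r) <- names(values)
  r
}

#' Per-feature phoneme token counts
#'
#' Counts how many phoneme tokens in the annotation carry each feature; a
#' phoneme carrying several features contributes one token to each. Feed the
#' result to [rank_features()] for the occurrence rank.
#'
#' @inheritParams expand_features
#' @return Named numeric vector of token counts, one per lexicon feature.
#' @export
occurrence_counts <- function(ann, lex) {
  stopifnot(inherits(ann, "phoneme_annotation"), inherits(lex, "feature_lexicon"))
  unknown <- setdiff(unique(ann$label), rownames(lex$table))
  if (length(unknown))
    stop("phoneme label(s) not in lexicon: ", paste(unknown, collapse = ", "))
  if (!nrow(ann)) {
    out <- numeric(length(lex$features))
    names(out) <- lex$features
    return(out)
  }
  colSums(lex$table[ann$label, , drop = FALSE])
}

#' Similarity between a feature step function and the pitch track
#'
#' Both series are z-scored and the score is the maximum absolute normalized
#' cross-correlation over lags within `max_lag_s` (default +/- 500 ms, the
#' prosodic, <4 Hz scale). A zero-lag-only variant is available. The lag at
#' which the maximum occurs is returned as attribute `"lag_s"` (positive lag
#' means the pitch series is delayed relative to the feature).
#'
#' @param feature_col numeric vector, feature step function.
#' @param pitch_col numeric vector of equal length, F0 track.
#' @param fs sampling rate, Hz.
#' @param max_lag_s lag range in seconds; `0` gives the zero-lag variant.
#' @param interpolate_unvoiced linearly interpolate the F0 track through
#'   unvoiced (zero) frames before correlating (default FALSE: raw track).
#' @return Scalar in `[-1, 1]` (the signed correlation whose magnitude is
#'   maximal), with attribute `lag_s`.
#' @export
pitch_similarity <- function(feature_col, pitch_col, fs, max_lag_s = 0.5,
                             interpolate_unvoiced = FALSE) {
  x <- as.numeric(feature_col)
  y <- as.numeric(pitch_col)
  if (length(x) != length(y)) stop("series must have equal length")
  n <- length(x)
  if (interpolate_unvoiced && any(y > 0) && any(y == 0)) {
    vi <- which(y > 0)
    y <- stats::approx(vi, y[vi], xout = seq_len(n), rule = 2)$y
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant series")
  x <- (x - mean(x)) / stats::sd(x)
  y <- (y - mean(y)) / stats::sd(y)
  max_lag <- min(n - 2L, round(max_lag_s * fs))
  if (max_lag <= 0) {
    score <- sum(x * y) / (n - 1)
    attr(score, "lag_s") <- 0
    return(score)
  }
  # linear cross-correlation via FFT, overlap-normalized
  nfft <- 2^ceiling(log2(2 * n))
  cc <- Re(stats::fft(stats::fft(c(x, numeric(nfft - n))) *
                        Conj(stats::fft(c(y, numeric(nfft - n)))),
                      inverse = TRUE)) / nfft
  # cc[1 + k] = sum x[t] y[t - k]; negative k wraps to the tail
  lags <- -max_lag:max_lag
  vals <- cc[ifelse(lags <= 0, 1 - lags, nfft + 1 - lags)]
  vals <- vals / pmax(n - abs(lags) - 1, 1)
  best <- which.max(abs(vals))
  score <- vals[best]
  # vals[i] pairs x[t] with y[t + lags[i]]: positive lag = pitch delayed
  attr(score, "lag_s") <- lags[best] / fs
  score
}

#' Feature timing statistics table
#'
#' Produces the per-feature summary used by the group-level models: median
#' stretch duration (ms), duration rank, token occurrence count and rank, and
#' (when a pitch track is supplied) the pitch-similarity score and rank.
#' All ranks run 1..n from smallest to largest. Features absent from the
#' corpus are excluded from ranking with a warning.
#'
#' @inheritParams expand_features
#' @param pitch optional [predictor_set()] of kind `"pitch"` aligned with the
#'   annotation timeline.
#' @param fs analysis rate used to rasterize features for the similarity
#'   score; taken from `pitch` when given.
#' @return data.frame with one row per feature present in the corpus.
#' @export
feature_stats <- function(ann, lex, pitch = NULL, fs = 100) {
  spans <- expand_features(ann, lex)
  med <- median_feature_duration(spans)
  occ <- occurrence_counts(ann, lex)
  present <- !is.na(med) & occ > 0
  if (any(!present)) {
    warning("feature(s) with no occurrences excluded from ranking: ",
            paste(names(med)[!present], collapse = ", "))
  }
  med <- med[present]; occ <- occ[present]
  out <- data.frame(feature = names(med), median_ms = as.numeric(med),
                    duration_rank = as.integer(rank_features(med)),
                    occurrence = as.numeric(occ),
                    occurrence_rank = as.integer(rank_features(occ)),
                    stringsAsFactors = FALSE)
  if (!is.null(pitch)) {
    stopifnot(inherits(pitch, "predictor_set"), pitch$kind == "pitch")
    fs <- pitch$fs
    n <- nrow(pitch$data)
    fp <- build_feature_predictor(spans[present], fs, n)
    sim <- vapply(seq_len(ncol(fp$data)), function(j) {
      as.numeric(pitch_similarity(fp$data[, j], pitch$data[, 1], fs))
    }, numeric(1))
    out$pitch_similarity <- sim
    out$pitch_similarity_rank <- as.integer(rank_features(
      stats::setNames(sim, out$feature)))
  }
  rownames(out) <- NULL
  out
}
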