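#' Construct a phoneme annotation
#'
#' A phoneme annotation is a timed sequence of labelled phoneme intervals, the
#' source of all categorical predictors. Intervals must be non-overlapping and
#' are stored sorted by onset; gaps between intervals represent silence.
#'
#' @param label character vector of phoneme labels.
#' @param onset,offset numeric vectors, seconds. `offset > onset` is required
#'   for every interval.
#' @param total_duration total duration of the annotated signal in seconds;
#'   defaults to the last offset.
#' @return Object of class `phoneme_annotation`: a data.frame with columns
#'   `label`, `onset`, `offset` and attribute `total_duration`.
#' @export
phoneme_annotation <- function(label, onset, offset, total_duration = NULL) {
  label <- as.character(label)
  onset <- as.numeric(onset)
  offset <- as.numeric(offset)
  n <- length(label)
  if (length(onset) != n || length(offset) != n)
    stop("label, onset and offset must have equal length")
  if (any(!is.finite(onset)) || any(!is.finite(offset)))
    stop("non-finite interval times")
  bad <- which(offset <= onset)
  if (length(bad))
    stop("offset <= onset for interval ", bad[1], " ('", label[bad[1]], "', ",
         onset[bad[1]], "-", offset[bad[1]], ")")
  ord <- order(onset, offset)
  label <- label[ord]; onset <- onset[ord]; offset <- offset[ord]
  if (n > 1) {
    # tiny negative gaps are float noise from forced-alignment output
    ovl <- which(onset[-1] < offset[-n] - 1e-9)
    if (length(ovl)) {
      i <- ovl[1]
      stop("overlapping intervals: '", label[i], "' (", onset[i], "-",
           offset[i], ") and '", label[i + 1], "' (", onset[i + 1], "-",
           offset[i + 1], ")")
    }
  }
  if (is.null(total_duration)) total_duration <- if (n) max(offset) else 0
  if (n && total_duration < max(offset) - 1e-9)
    stop("total_duration shorter than last interval offset")
  out <- data.frame(label = label, onset = onset, offset = offset,
                    stringsAsFactors = FALSE)
  attr(out, "total_duration") <- as.numeric(total_duration)
  class(out) <- c("phoneme_annotation", "data.frame")
  out
}

#' @exportS3Method base::print
print.phoneme_annotation <- function(x, ...) {
  cat("<phoneme_annotation> ", nrow(x), " intervals, ",
      format(attr(x, "total_duration"), digits = 4), " s\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 8L))
  if (nrow(x) > 8L) cat("... (", nrow(x) - 8L, " more)\n", sep = "")
  invisible(x)
}

#' Read a phoneme annotation file
#'
#' Ingests forced-alignment output: either a Praat TextGrid (long or short
#' format, one interval tier selected by name) or a 3-column TSV
#' (`label`, `onset`, `offset`, seconds; a header line is detected and
#' skipped). Intervals whose label is empty or a pause marker (`<p:>`, `sil`,
#' `sp`, ...) become silence gaps, not phoneme intervals.
#'
#' @param path file path.
#' @param tier for TextGrids, the name of the interval tier to read; defaults
#'   to the first interval tier.
#' @param format `"auto"` (by extension/content), `"tsv"` or `"textgrid"`.
#' @return A [phoneme_annotation()].
#' @export
read_annotation <- function(path, tier = NULL, format = c("auto", "tsv", "textgrid")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (format == "auto") {
    format <- if (any(grepl("ooTextFile", lines[seq_len(min(3, length(lines)))])))
      "textgrid" else "tsv"
  }
  if (format == "tsv") read_annotation_tsv(lines) else
    read_annotation_textgrid(lines, tier)
}

read_annotation_tsv <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty annotation file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3))
    stop("annotation format error: expected 3 tab-separated columns")
  first <- parts[[1]]
  if (is.na(suppressWarnings(as.numeric(first[2])))) parts <- parts[-1]
  lab <- vapply(parts, `[[`, "", 1L)
  on <- as.numeric(vapply(parts, `[[`, "", 2L))
  off <- as.numeric(vapply(parts, `[[`, "", 3L))
  if (anyNA(on) || anyNA(off)) stop("annotation format error: non-numeric times")
  total <- if (length(off)) max(off) else 0
  keep <- !(lab %in% silence_labels())
  phoneme_annotation(lab[keep], on[keep], off[keep], total_duration = total)
}

# minimal Praat TextGrid parser handling both the long ("xmin = 0") and the
# short (bare values) dialects; interval tiers only
read_annotation_textgrid <- function(lines, tier = NULL) {
  txt <- trimws(lines)
  is_long <- any(grepl("^item\\s*\\[", txt))
  tiers <- list()
  if (is_long) {
    idx <- grep("^item\\s*\\[[0-9]+\\]", txt)
    if (!length(idx)) stop("annotation format error: no tiers found")
    bounds <- c(idx, length(txt) + 1L)
    for (k in seq_along(idx)) {
      block <- txt[idx[k]:(bounds[k + 1L] - 1L)]
      cls <- sub(".*class\\s*=\\s*\"([^\"]*)\".*", "\\1",
                 grep("class\\s*=", block, value = TRUE)[1])
      nm <- sub(".*name\\s*=\\s*\"([^\"]*)\".*", "\\1",
                grep("^name\\s*=", block, value = TRUE)[1])
      if (!identical(cls, "IntervalTier")) next
      gv <- function(pat, x) as.numeric(sub(paste0(".*", pat, "\\s*=\\s*([-0-9.eE+]+).*"),
                                            "\\1", x))
      xmins <- gv("xmin", grep("^xmin\\s*=", block, value = TRUE)[-1])
      xmaxs <- gv("xmax", grep("^xmax\\s*=", block, value = TRUE)[-1])
      labs <- sub(".*text\\s*=\\s*\"(.*)\"\\s*$", "\\1",
                  grep("^text\\s*=", block, value = TRUE))
      tiers[[nm]] <- list(xmin = xmins, xmax = xmaxs, lab = labs,
                          total = gv("xmax", grep("^xmax\\s*=", block,
                                                  value = TRUE)[1]))
    }
  } else {
    # short format: after the 6 header lines, tiers follow as
    # "IntervalTier", name, xmin, xmax, n, then n (xmin, xmax, text) triples
    i <- grep("^\"IntervalTier\"$", txt)
    if (!length(i)) stop("annotation format error: no interval tiers found")
    for (k in i) {
      nm <- gsub("\"", "", txt[k + 1L])
      n <- as.integer(txt[k + 4L])
      rows <- txt[(k + 5L):(k + 4L + 3L * n)]
      m <- matrix(rows, ncol = 3L, byrow = TRUE)
      tiers[[nm]] <- list(xmin = as.numeric(m[, 1]), xmax = as.numeric(m[, 2]),
                          lab = gsub("\"", "", m[, 3]),
                          total = as.numeric(txt[k + 3L]))
    }
  }
  if (!length(tiers)) stop("annotation format error: no interval tiers found")
  if (is.null(tier)) tier <- names(tiers)[1]
  if (!tier %in% names(tiers))
    stop("tier '", tier, "' not found; available: ",
         paste(names(tiers), collapse = ", "))
  tr <- tiers[[tier]]
  keep <- !(trimws(tr$lab) %in% silence_labels())
  phoneme_annotation(tr$lab[keep], tr$xmin[keep], tr$xmax[keep],
                     total_duration = tr$total)
}

#' Write a phoneme annotation as TSV
#'
#' Columns `label`, `onset`, `offset` (seconds, microsecond precision), with
#' header. [read_annotation()] round-trips the result.
#'
#' @param ann a [phoneme_annotation()].
#' @param path output path.
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "phoneme_annotation"))
  df <- data.frame(label = ann$label,
                   onset = sprintf("%.6f", ann$onset),
                   offset = sprintf("%.6f", ann$offset))
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Expand a phoneme annotation into feature spans
#'
#' For every feature in the lexicon, maximal runs of temporally adjacent
#' phonemes carrying that feature are merged into single active spans
#' (a feature-continuous stretch typically spans several phonemes). A silence
#' gap terminates the run and, following the rationale that silence carries no
#' new phonological information, the silent duration up to the next phoneme
#' onset (or the end of the signal) is appended to the ending span when
#' `append_silence = TRUE`.
#'
#' @param ann a [phoneme_annotation()].
#' @param lex a [feature_lexicon()]; every label in `ann` must be present.
#' @param tol adjacency tolerance in seconds: boundary gaps smaller than this
#'   are treated as exact abutment (guards float noise in aligner output).
#' @param append_silence append trailing silence to each span (default TRUE).
#' @return Object of class `feature_intervals`: a named list (one element per
#'   feature) of data.frames with columns `onset`, `offset`, `raw_offset`
#'   (span end before silence appending), seconds.
#' @export
expand_features <- function(ann, lex, tol = 1e-3, append_silence = TRUE) {
  stopifnot(inherits(ann, "phoneme_annotation"), inherits(lex, "feature_lexicon"))
  unknown <- setdiff(unique(ann$label), rownames(lex$table))
  if (length(unknown))
    stop("phoneme label(s) not in lexicon: ", paste(unknown, collapse = ", "))
  total <- attr(ann, "total_duration")
  n <- nrow(ann)
  # silence appended to a span: from span raw end to the next phoneme onset
  next_onset <- if (n) c(ann$onset[-1], total) else numeric(0)
  out <- lapply(lex$features, function(f) {
    act <- lex$table[ann$label, f] == 1
    if (!any(act)) {
      return(data.frame(onset = numeric(0), offset = numeric(0),
                        raw_offset = numeric(0)))
    }
    idx <- which(act)
    # a run continues while the next interval is feature-positive AND abuts
    brk <- c(TRUE, diff(idx) != 1L |
               ann$onset[idx[-1]] - ann$offset[idx[-length(idx)]] >= tol)
    run_id <- cumsum(brk)
    onset <- tapply(ann$onset[idx], run_id, min)
    raw_off <- tapply(ann$offset[idx], run_id, max)
    last_in_run <- tapply(idx, run_id, max)
    off <- raw_off
    if (append_silence) {
      gap_end <- pmin(next_onset[last_in_run], total)
      off <- pmax(raw_off, gap_end)
    }
    data.frame(onset = as.numeric(onset), offset = as.numeric(off),
               raw_offset = as.numeric(raw_off))
  })
  names(out) <- lex$features
  structure(out, class = "feature_intervals", total_duration = total)
}

#' @exportS3Method base::print
print.feature_intervals <- function(x, ...) {
  cat("<feature_intervals> ", length(x), " features, ",
      format(attr(x, "total_duration"), digits = 4), " s\n", sep = "")
  counts <- vapply(x, nrow, 0L)
  print(counts)
  invisible(x)
}
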