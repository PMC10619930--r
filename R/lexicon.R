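#' Canonical phonological feature inventory
#'
#' The 17 binary Chomsky--Halle-style phonological features used throughout
#' the package, in canonical order. This order is also the deterministic
#' tie-break order for feature rankings (see [rank_features()]).
#'
#' @return Character vector of 17 feature names.
#' @export
#' @examples
#' phonological_features()
phonological_features <- function() {
  c("voiced", "continuant", "sonorant", "low", "tense", "back", "strident",
    "consonantal", "long", "syllabic", "round", "high", "coronal", "anterior",
    "nasal", "labial", "lateral")
}

#' Construct a feature lexicon
#'
#' A feature lexicon maps phoneme labels to binary feature bundles. Each
#' phoneme corresponds to exactly one bundle; every entry must be 0 or 1.
#'
#' @param table numeric matrix or data.frame of 0/1 entries, one row per
#'   phoneme; row names (or a `phoneme` column) give phoneme labels.
#' @param features character vector of feature names; defaults to the column
#'   names of `table`. Need not be the canonical 17 (synthetic lexicons may
#'   use subsets), but duplicates are rejected.
#' @return An object of class `feature_lexicon`: a list with elements
#'   `features` (character) and `table` (phonemes x features 0/1 matrix).
#' @seealso [german_lexicon()], [read_feature_lexicon()], [expand_features()]
#' @export
feature_lexicon <- function(table, features = NULL) {
  if (is.data.frame(table)) {
    if ("phoneme" %in% names(table)) {
      rn <- as.character(table[["phoneme"]])
      table <- table[, setdiff(names(table), "phoneme"), drop = FALSE]
      table <- as.matrix(table)
      rownames(table) <- rn
    } else {
      table <- as.matrix(table)
    }
  }
  storage.mode(table) <- "double"
  if (is.null(features)) features <- colnames(table)
  if (is.null(features)) stop("feature names are required")
  features <- as.character(features)
  if (anyDuplicated(features)) stop("duplicated feature names")
  if (ncol(table) != length(features))
    stop("table has ", ncol(table), " columns but ", length(features),
         " feature names were given")
  colnames(table) <- features
  if (is.null(rownames(table))) stop("phoneme labels (row names) are required")
  if (anyDuplicated(rownames(table)))
    stop("duplicated phoneme labels: ",
         paste(unique(rownames(table)[duplicated(rownames(table))]),
               collapse = ", "))
  if (!all(table %in% c(0, 1)))
    stop("lexicon entries must all be 0 or 1")
  structure(list(features = features, table = table),
            class = "feature_lexicon")
}

#' @exportS3Method base::print
print.feature_lexicon <- function(x, ...) {
  cat("<feature_lexicon> ", nrow(x$table), " phonemes x ",
      length(x$features), " features\n", sep = "")
  cat("features:", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}

#' Read / write a feature lexicon as CSV
#'
#' The on-disk format is a CSV with a header row naming the features and a
#' leading `phoneme` column, one row per phoneme; entries are 0/1.
#'
#' @param path file path.
#' @return `read_feature_lexicon()` returns a [feature_lexicon()].
#' @export
read_feature_lexicon <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"phoneme" %in% names(df))
    stop("lexicon CSV must have a 'phoneme' column")
  feature_lexicon(df)
}

#' @rdname read_feature_lexicon
#' @param lex a [feature_lexicon()].
#' @export
write_feature_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "feature_lexicon"))
  df <- data.frame(phoneme = rownames(lex$table), lex$table,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' German SAMPA feature lexicon
#'
#' Feature assignments for the German SAMPA phoneme inventory over the
#' canonical 17 features, following Chomsky--Halle-style conventions.
#' Diphthongs are single phoneme labels with their own bundles. The table is
#' shipped as a plain CSV under `extdata` and can be replaced by the user via
#' [read_feature_lexicon()]; assignments for edge cases (e.g. tenseness of
#' long low vowels) follow common practice for German.
#'
#' @return A [feature_lexicon()] with the canonical 17 features.
#' @export
german_lexicon <- function() {
  path <- system.file("extdata", "german_sampa_features.csv",
                      package = "phonotrf", mustWork = TRUE)
  lex <- read_feature_lexicon(path)
  stopifnot(identical(lex$features, phonological_features()))
  lex
}

# labels treated as silence/pause in annotation files
silence_labels <- function() {
  c("", "<p:>", "<p>", "sil", "sp", "pause", "#", "_", "<sil>")
}
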