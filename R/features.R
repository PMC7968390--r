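#' Word length in letters
#'
#' Counts alphabetic characters only; apostrophes and other punctuation do not
#' count, so "toil'd" has length 5.
#'
#' @param word Character vector of words.
#' @return Integer vector of letter counts.
#' @export
word_length <- function(word) {
  stringr::str_count(word, "[[:alpha:]]")
}

#' Log word frequency against a reference lexicon
#'
#' Base-10 logarithm of the word's token count in the reference corpus. Words
#' absent from the lexicon are floored at count 1, so unseen words get 0; the
#' base only rescales the feature and standardization removes the scale.
#'
#' @param word Character vector of words (matched lowercased).
#' @param lexicon A [reference_lexicon()].
#' @param base Logarithm base, default 10.
#' @param floor_count Minimum count substituted for unseen words, default 1.
#' @return Numeric vector of log counts.
#' @export
log_frequency <- function(word, lexicon, base = 10, floor_count = 1) {
  cnt <- pmax(lexicon_count(word, lexicon), floor_count)
  log(cnt, base = base)
}

#' Levenshtein edit distance
#'
#' Minimal number of single-character insertions, deletions and substitutions
#' turning `a` into `b` (unit costs). Symmetric; 0 iff the strings are equal.
#'
#' @param a,b Character vectors (recycled to common length).
#' @return Integer vector of distances.
#' @examples
#' levenshtein("cat", "cab")
#' @export
levenshtein <- function(a, b) {
  stopifnot(!anyNA(a), !anyNA(b))
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  vapply(seq_len(n), function(i) {
    as.integer(utils::adist(a[i], b[i]))
  }, integer(1))
}

neighbor_types <- function(word, lexicon) {
  w <- tolower(word)
  types <- names(lexicon$entries)
  cand <- types[nchar(types) == nchar(w) & types != w]
  if (length(cand) == 0) return(character(0))
  wl <- strsplit(w, "", fixed = TRUE)[[1]]
  ham1 <- vapply(strsplit(cand, "", fixed = TRUE),
                 function(cc) sum(cc != wl) == 1L, logical(1))
  cand[ham1]
}

#' Orthographic neighborhood density
#'
#' The number of lexicon word types of the same length as the target that
#' differ from it by exactly one letter (Hamming distance 1); e.g. "bat",
#' "fat" and "cab" are neighbors of "cat".
#'
#' @inheritParams log_frequency
#' @return Integer vector of neighbor counts.
#' @export
orthographic_neighbors <- function(word, lexicon) {
  vapply(word, function(w) length(neighbor_types(w, lexicon)),
         integer(1), USE.NAMES = FALSE)
}

#' Higher-frequency orthographic neighbors
#'
#' The number of orthographic neighbors whose token count in the lexicon is
#' strictly greater than the target word's own count. Ties do not count, so
#' the value is always at most the neighborhood density.
#'
#' @inheritParams log_frequency
#' @return Integer vector of counts.
#' @export
higher_frequency_neighbors <- function(word, lexicon) {
  vapply(word, function(w) {
    nb <- neighbor_types(w, lexicon)
    if (length(nb) == 0) return(0L)
    sum(lexicon_count(nb, lexicon) > lexicon_count(w, lexicon))
  }, integer(1), USE.NAMES = FALSE)
}

#' Orthographic dissimilarity (mean Levenshtein distance)
#'
#' The target word's mean Levenshtein distance to all *other* word types in
#' the reference lexicon (unweighted over types, the target itself excluded).
#' Generalizes neighborhood density to words of different lengths; larger
#' values mean a more orthographically isolated word.
#'
#' @inheritParams log_frequency
#' @return Numeric vector of mean distances.
#' @export
orth_dissimilarity <- function(word, lexicon) {
  types <- names(lexicon$entries)
  if (length(types) < 2) {
    stop("`lexicon` must contain at least 2 word types for odc.", call. = FALSE)
  }
  vapply(tolower(word), function(w) {
    others <- types[types != w]
    mean(utils::adist(w, others))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Consonant-vowel quotient
#'
#' Number of consonant letters divided by number of vowel letters. Vowels
#' default to a, e, i, o, u; words with no vowel under the chosen set (such as
#' "myth" with the default) are undefined and return `NA` — callers decide
#' whether to impute or exclude.
#'
#' @param word Character vector of words.
#' @param vowels Characters treated as vowels, default `c("a","e","i","o","u")`.
#' @return Numeric vector; `NA` where the word has no vowel.
#' @export
consonant_vowel_quotient <- function(word, vowels = c("a", "e", "i", "o", "u")) {
  vapply(tolower(word), function(w) {
    chars <- strsplit(w, "", fixed = TRUE)[[1]]
    chars <- chars[grepl("[[:alpha:]]", chars)]
    nv <- sum(chars %in% vowels)
    if (nv == 0) return(NA_real_)
    sum(!chars %in% vowels) / nv
  }, numeric(1), USE.NAMES = FALSE)
}

#' Compute the seven lexical surface features for word types
#'
#' Builds one row per unique word type with word length (`wl`), log frequency
#' (`logf`), orthographic neighborhood density (`on`), higher-frequency
#' neighbors (`hfn`), mean Levenshtein orthographic dissimilarity (`odc`),
#' consonant-vowel quotient (`cvq`) and sonority score (`sonscore`).
#' Duplicated input types are collapsed; words where a feature is undefined
#' are flagged in the `flags` column rather than dropped.
#'
#' @param words Character vector of word tokens or types (lowercased,
#'   deduplicated internally).
#' @param lexicon A [reference_lexicon()].
#' @param sonority A [sonority_table()].
#' @param vowels Vowel set for `cvq`.
#' @return A tibble with columns `word`, `wl`, `logf`, `on`, `hfn`, `odc`,
#'   `cvq`, `sonscore`, `flags`.
#' @examples
#' lex <- reference_lexicon(c(rep("cat", 5), "bat", "fat", "cab", "art"))
#' word_features(c("cat", "art"), lex)
#' @export
word_features <- function(words, lexicon, sonority = sonority_table(),
                          vowels = c("a", "e", "i", "o", "u")) {
  stopifnot(length(words) > 0)
  types <- unique(tolower(words))
  out <- tibble::tibble(
    word = types,
    wl = word_length(types),
    logf = log_frequency(types, lexicon),
    on = orthographic_neighbors(types, lexicon),
    hfn = higher_frequency_neighbors(types, lexicon),
    odc = orth_dissimilarity(types, lexicon),
    cvq = consonant_vowel_quotient(types, vowels = vowels),
    sonscore = sonority_score(types, table = sonority)
  )
  out$flags <- dplyr::if_else(is.na(out$cvq), "cvq_undefined", "")
  out
}

feature_names <- function() {
  c("wl", "logf", "on", "hfn", "odc", "cvq", "sonscore")
}

#' Standardize feature columns to z-scores
#'
#' Column-wise centering and scaling using the sample standard deviation
#' (denominator n - 1). The means and SDs used are stored as attributes
#' `feature_center` and `feature_scale` so [unstandardize_features()] can
#' reproduce the originals. Standardizing an already-standardized table is a
#' no-op.
#'
#' @param data A data frame.
#' @param cols Columns to standardize; defaults to the seven feature columns
#'   present in `data`.
#' @return A tibble with the chosen columns z-scored and attribute
#'   `standardized = TRUE`.
#' @export
standardize_features <- function(data, cols = intersect(feature_names(), names(data))) {
  stopifnot(nrow(data) >= 2, length(cols) > 0)
  if (isTRUE(attr(data, "standardized"))) return(data)
  out <- tibble::as_tibble(data)
  center <- vapply(cols, function(cl) mean(out[[cl]], na.rm = TRUE), numeric(1))
  scale <- vapply(cols, function(cl) stats::sd(out[[cl]], na.rm = TRUE), numeric(1))
  if (any(scale == 0 | is.na(scale))) {
    stop("Zero-variance column(s): ",
         paste(cols[scale == 0 | is.na(scale)], collapse = ", "), call. = FALSE)
  }
  for (cl in cols) out[[cl]] <- (out[[cl]] - center[[cl]]) / scale[[cl]]
  attr(out, "feature_center") <- center
  attr(out, "feature_scale") <- scale
  attr(out, "standardized") <- TRUE
  out
}

#' Undo standardization using the stored means and SDs
#'
#' @param data A tibble produced by [standardize_features()].
#' @return The table on its original scale.
#' @export
unstandardize_features <- function(data) {
  center <- attr(data, "feature_center")
  scale <- attr(data, "feature_scale")
  if (is.null(center) || is.null(scale)) {
    stop("`data` carries no stored standardization parameters.", call. = FALSE)
  }
  out <- data
  for (cl in names(center)) out[[cl]] <- out[[cl]] * scale[[cl]] + center[[cl]]
  attr(out, "standardized") <- FALSE
  out
}

#' Pearson correlations between feature columns
#'
#' @param data A data frame of features.
#' @param cols Columns to correlate; defaults to the seven feature columns.
#' @param use Observation handling passed to [stats::cor()]; default pairwise
#'   deletion of missing values.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
feature_correlations <- function(data,
                                 cols = intersect(feature_names(), names(data)),
                                 use = "pairwise.complete.obs") {
  stopifnot(nrow(data) >= 3)
  stats::cor(as.data.frame(data)[, cols, drop = FALSE],
             use = use, method = "pearson")
}
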