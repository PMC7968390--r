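#' Letter sonority table
#'
#' Sonority ranks the relative acoustic energy of speech sounds. The default
#' table encodes a 10-rank hierarchy, from open vowels down to voiceless
#' stops, applied to letters:
#' a = 10; e, o = 9; i, u, j, w = 8; r = 7; l = 6; m, n = 5; z, v = 4;
#' f, s = 3; b, d, g = 2; p, t, k = 1.
#'
#' Letters without a rank in that hierarchy receive documented defaults based
#' on their most common English pronunciation: c = 1 (as /k/), q = 1, x = 3
#' (/ks/, sibilant-like), y = 8 (as the glide \[j\]), h = 3 (fricative-like).
#' All defaults can be overridden.
#'
#' @param overrides Optional named numeric vector of rank overrides,
#'   e.g. `c(c = 3)`. Ranks must lie in 1..10.
#' @param unknown_policy What to do with symbols absent from the table:
#'   `"error"` (default), `"skip"` (ignore the symbol), or `"default"`
#'   (use `default_rank`).
#' @param default_rank Rank used under `unknown_policy = "default"`.
#' @return An object of class `sonority_table`.
#' @examples
#' tab <- sonority_table()
#' tab$rank[c("a", "r", "t")]
#' @export
sonority_table <- function(overrides = NULL,
                           unknown_policy = c("error", "skip", "default"),
                           default_rank = 5) {
  unknown_policy <- match.arg(unknown_policy)
  rank <- c(
    a = 10,
    e = 9, o = 9,
    i = 8, u = 8, j = 8, w = 8,
    r = 7,
    l = 6,
    m = 5, n = 5,
    z = 4, v = 4,
    f = 3, s = 3,
    b = 2, d = 2, g = 2,
    p = 1, t = 1, k = 1,
    # letters outside the printed hierarchy, ranked by usual pronunciation
    c = 1, q = 1, x = 3, y = 8, h = 3
  )
  if (!is.null(overrides)) {
    stopifnot(!is.null(names(overrides)), all(nzchar(names(overrides))))
    rank[tolower(names(overrides))] <- as.numeric(overrides)
  }
  if (any(rank < 1 | rank > 10)) {
    stop("Sonority ranks must lie in 1..10.", call. = FALSE)
  }
  structure(
    list(rank = rank, unknown_policy = unknown_policy,
         default_rank = default_rank),
    class = "sonority_table"
  )
}

#' Read a sonority table from a two-column text file
#'
#' The file format is `symbol<TAB>rank`, one entry per line; lines starting
#' with `#` are comments. Entries override the default table.
#'
#' @param path File path.
#' @inheritParams sonority_table
#' @return A [sonority_table()].
#' @export
read_sonority_table <- function(path, unknown_policy = "error",
                                default_rank = 5) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ov <- stats::setNames(
    vapply(parts, function(p) as.numeric(p[2]), numeric(1)),
    vapply(parts, function(p) p[1], character(1))
  )
  sonority_table(overrides = ov, unknown_policy = unknown_policy,
                 default_rank = default_rank)
}

sonority_symbols <- function(word) {
  chars <- strsplit(tolower(word), "", fixed = TRUE)[[1]]
  chars[grepl("[[:alpha:]]", chars)]
}

#' Unnormalized sonority rank sum of a word
#'
#' Sum of the per-letter sonority ranks, before length normalization. For
#' "art" this is 10 + 7 + 1 = 18.
#'
#' @param word A word (single string); only alphabetic characters are scored.
#' @param table A [sonority_table()].
#' @return The rank sum (numeric scalar).
#' @export
sonority_rank_sum <- function(word, table = sonority_table()) {
  stopifnot(inherits(table, "sonority_table"))
  chars <- sonority_symbols(word)
  ranks <- table$rank[chars]
  if (anyNA(ranks)) {
    unknown <- unique(chars[is.na(ranks)])
    switch(table$unknown_policy,
      error = stop("Unknown sonority symbol(s): ",
                   paste(unknown, collapse = ", "), call. = FALSE),
      skip = ranks <- ranks[!is.na(ranks)],
      default = ranks[is.na(ranks)] <- table$default_rank
    )
  }
  sum(ranks)
}

#' Sonority score of a word
#'
#' The sum of the letters' sonority ranks divided by the square root of the
#' word length in letters. "art" scores (10 + 7 + 1) / sqrt(3) = 10.39.
#'
#' @param word A character vector of words.
#' @param table A [sonority_table()].
#' @return Numeric vector of sonority scores.
#' @examples
#' sonority_score("art")
#' @export
sonority_score <- function(word, table = sonority_table()) {
  vapply(word, function(w) {
    wl <- word_length(w)
    if (wl == 0) return(NA_real_)
    sonority_rank_sum(w, table) / sqrt(wl)
  }, numeric(1), USE.NAMES = FALSE)
}
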