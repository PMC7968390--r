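#' Tokenize raw text into word tokens
#'
#' Splits text on whitespace, lowercases, and strips punctuation from token
#' edges while keeping word-internal apostrophes (elided Early-Modern forms
#' such as "toil'd" stay single tokens) and hyphens (hyphenated compounds stay
#' single tokens). Token order is preserved.
#'
#' @param text A character vector of raw text (concatenated before splitting).
#' @param lowercase Lowercase tokens? Default `TRUE`.
#' @return A character vector of tokens, in order of appearance.
#' @examples
#' tokenize("Weary with toil, I haste me to my bed")
#' tokenize("toil'd")
#' @export
tokenize <- function(text, lowercase = TRUE) {
  if (length(text) == 0 || all(!nzchar(trimws(text)))) {
    stop("`text` is empty: nothing to tokenize.", call. = FALSE)
  }
  txt <- paste(text, collapse = "\n")
  if (lowercase) txt <- tolower(txt)
  raw <- unlist(strsplit(txt, "[[:space:]]+"))
  raw <- raw[nzchar(raw)]
  # strip non-word characters at the edges; apostrophes/hyphens survive only
  # word-internally
  toks <- gsub("^[^[:alnum:]]+|[^[:alnum:]]+$", "", raw)
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0) {
    stop("Tokenization produced no tokens: input is unusable.", call. = FALSE)
  }
  toks
}

#' Build a reference lexicon of word-type counts
#'
#' A reference lexicon maps each word type to its token count in a reference
#' corpus and backs the frequency, neighborhood and dissimilarity features.
#'
#' @param x One of: a character vector of tokens (counted), a named numeric
#'   vector of counts, or a data frame with columns `word` and `count`.
#' @return An object of class `reference_lexicon`: a list with `entries`
#'   (named integer vector of counts), `total_tokens` and `n_types`.
#' @examples
#' lex <- reference_lexicon(c("cat", "cat", "bat", "dog"))
#' lex$total_tokens
#' @export
reference_lexicon <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("word", "count") %in% names(x)))
    counts <- stats::setNames(as.numeric(x$count), tolower(as.character(x$word)))
    counts <- tapply(counts, names(counts), sum)
    counts <- stats::setNames(as.numeric(counts), names(counts))
  } else if (!is.null(names(x)) && is.numeric(x)) {
    counts <- stats::setNames(as.numeric(x), tolower(names(x)))
  } else if (is.character(x)) {
    tab <- table(tolower(x))
    counts <- stats::setNames(as.numeric(tab), names(tab))
  } else {
    stop("`x` must be tokens, named counts, or a word/count data frame.",
         call. = FALSE)
  }
  bad <- !nzchar(names(counts)) | grepl("[[:space:]]", names(counts))
  if (any(bad)) {
    stop("Lexicon keys must be non-empty and contain no whitespace.",
         call. = FALSE)
  }
  if (any(counts < 0)) stop("Lexicon counts must be non-negative.", call. = FALSE)
  structure(
    list(
      entries = counts[order(names(counts))],
      total_tokens = sum(counts),
      n_types = length(counts)
    ),
    class = "reference_lexicon"
  )
}

#' @export
print.reference_lexicon <- function(x, ...) {
  cat("<reference_lexicon> ", x$n_types, " types, ",
      format(x$total_tokens, big.mark = ","), " tokens\n", sep = "")
  invisible(x)
}

#' Read a reference lexicon from disk
#'
#' Accepts either raw UTF-8 plain text (tokenized internally) or a two-column
#' tab-separated file `word<TAB>count` (no header, or a header line
#' `word\tcount`).
#'
#' @param path File path.
#' @param format `"auto"` (sniff: a first line with exactly two tab-separated
#'   fields, the second numeric, is treated as TSV), `"text"`, or `"tsv"`.
#' @return A [reference_lexicon()].
#' @export
read_lexicon <- function(path, format = c("auto", "text", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  if (format == "auto") {
    first <- readLines(path, n = 2L, warn = FALSE)
    first <- first[nzchar(first)][1]
    fields <- strsplit(first, "\t", fixed = TRUE)[[1]]
    format <- if (length(fields) == 2 &&
                  (!is.na(suppressWarnings(as.numeric(fields[2]))) ||
                   identical(tolower(fields), c("word", "count")))) "tsv" else "text"
  }
  if (format == "tsv") {
    df <- utils::read.delim(path, header = FALSE, col.names = c("word", "count"),
                            stringsAsFactors = FALSE, quote = "")
    if (identical(tolower(df$word[1]), "word")) df <- df[-1, , drop = FALSE]
    df$count <- as.numeric(df$count)
    reference_lexicon(df)
  } else {
    reference_lexicon(tokenize(readLines(path, warn = FALSE)))
  }
}

lexicon_count <- function(word, lexicon) {
  stopifnot(inherits(lexicon, "reference_lexicon"))
  cnt <- lexicon$entries[tolower(word)]
  cnt[is.na(cnt)] <- 0
  unname(cnt)
}
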