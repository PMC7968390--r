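# independent oracles used to check the package's operations

# dynamic-programming edit distance, written independently of the package
dp_levenshtein <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  d <- matrix(0L, na + 1, nb + 1)
  d[, 1] <- 0:na
  d[1, ] <- 0:nb
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L,
                             d[i + 1, j] + 1L,
                             d[i, j] + (ca[i] != cb[j]))
    }
  }
  d[na + 1, nb + 1]
}

# exhaustive neighbor scan: same length, exactly one differing position
brute_neighbors <- function(word, types) {
  sum(vapply(types, function(t) {
    if (t == word || nchar(t) != nchar(word)) return(FALSE)
    sum(strsplit(t, "")[[1]] != strsplit(word, "")[[1]]) == 1
  }, logical(1)))
}

# all strings over an alphabet up to a maximum length
all_strings <- function(alphabet, max_len) {
  out <- ""
  for (len in seq_len(max_len)) {
    grids <- do.call(expand.grid, rep(list(alphabet), len))
    out <- c(out, apply(grids, 1, paste, collapse = ""))
  }
  out
}

# random lexicon of unique lowercase types with integer counts
random_lexicon <- function(n_types, seed, min_len = 2, max_len = 6) {
  withr::with_seed(seed, {
    words <- character(0)
    while (length(words) < n_types) {
      len <- sample(min_len:max_len, n_types, replace = TRUE)
      new <- vapply(len, function(l) {
        paste(sample(letters[1:8], l, replace = TRUE), collapse = "")
      }, character(1))
      words <- unique(c(words, new))
    }
    words <- words[seq_len(n_types)]
    reference_lexicon(stats::setNames(sample(1:500, n_types, replace = TRUE),
                                      words))
  })
}

# small deterministic fixation-event fixture: one participant, one item,
# AOI visit sequence 1,2,2,1 with durations 200,150,100,180
trace_events <- function(participant = "p1", item = "i1") {
  tibble::tibble(
    participant = participant,
    item = item,
    aoi_index = c(1L, 2L, 2L, 1L),
    word = c("weary", "with", "with", "weary"),
    order = 1:4,
    duration = c(200, 150, 100, 180)
  )
}
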