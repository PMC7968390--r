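#' Parse a fixation / interest-area report
#'
#' Reads a tab-separated fixation report (one row per fixation) and validates
#' it into the canonical event table. Interest areas (AOIs) are 1-based word
#' positions within an item; pixel geometry is out of scope.
#'
#' @param path Path to a TSV file with a header row.
#' @param col_map Named character vector mapping the canonical column names
#'   `participant`, `item`, `aoi_index`, `word`, `order`, `duration` to the
#'   column names used in the file.
#' @return A tibble of fixation events sorted by participant, item, order,
#'   with columns `participant`, `item`, `aoi_index` (integer >= 1), `word`,
#'   `order` (integer >= 1, unique within participant x item) and `duration`
#'   (ms, > 0).
#' @export
parse_fixation_report <- function(path,
                                  col_map = c(participant = "participant",
                                              item = "item",
                                              aoi_index = "aoi_index",
                                              word = "word",
                                              order = "order",
                                              duration = "duration")) {
  required <- c("participant", "item", "aoi_index", "word", "order", "duration")
  stopifnot(all(required %in% names(col_map)))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(unname(col_map[required]), names(df))
  if (length(missing) > 0) {
    stop("Fixation report is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ev <- tibble::tibble(
    participant = as.character(df[[col_map[["participant"]]]]),
    item = as.character(df[[col_map[["item"]]]]),
    aoi_index = as.integer(df[[col_map[["aoi_index"]]]]),
    word = as.character(df[[col_map[["word"]]]]),
    order = as.integer(df[[col_map[["order"]]]]),
    duration = as.numeric(df[[col_map[["duration"]]]])
  )
  validate_fixation_events(ev)
}

validate_fixation_events <- function(ev) {
  if (any(ev$duration <= 0 | is.na(ev$duration))) {
    stop("All fixation durations must be positive.", call. = FALSE)
  }
  if (any(ev$aoi_index < 1 | is.na(ev$aoi_index))) {
    stop("AOI indices must be integers >= 1.", call. = FALSE)
  }
  dup <- ev |>
    dplyr::count(.data$participant, .data$item, .data$order) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("Duplicate fixation order within participant x item (e.g. ",
         dup$participant[1], "/", dup$item[1], " order ", dup$order[1], ").",
         call. = FALSE)
  }
  dplyr::arrange(ev, .data$participant, .data$item, .data$order)
}

#' Write fixation events back to a TSV report
#'
#' @param events A fixation event tibble (see [parse_fixation_report()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fixation_report <- function(events, path) {
  readr::write_tsv(events, path, progress = FALSE)
  invisible(path)
}

#' Word-token reading measures from fixation events
#'
#' Computes, for every participant x item x word token, the four duration
#' measures and a fixation indicator:
#' \describe{
#'   \item{ffd}{first fixation duration — duration of the first fixation on
#'     the token.}
#'   \item{gaze}{gaze duration — sum of fixation durations during first pass,
#'     the initial maximal run of consecutive fixations on the token (a visit
#'     to any other token ends first pass).}
#'   \item{rereading}{re-reading time — sum of fixation durations on the token
#'     after first pass; 0 when the token is never revisited.}
#'   \item{trt}{total reading time — gaze + rereading, the sum of all
#'     fixations on the token.}
#' }
#' Tokens a participant never fixates are skips: `fixated = FALSE` with all
#' duration measures missing (`NA`), never zero.
#'
#' @param events A fixation event tibble.
#' @param item_words Optional tibble (`item`, `aoi_index`, `word`) giving the
#'   complete token inventory per item, so that fully skipped tokens appear in
#'   the output. Defaults to the tokens observed in `events` (tokens no
#'   participant fixated are then invisible).
#' @param participants Optional character vector of all participants; defaults
#'   to those present in `events`.
#' @return A tibble with one row per participant x token: `participant`,
#'   `item`, `aoi_index`, `word`, `ffd`, `gaze`, `rereading`, `trt`,
#'   `fixated`.
#' @export
token_measures <- function(events, item_words = NULL, participants = NULL) {
  ev <- validate_fixation_events(events)
  if (is.null(item_words)) {
    item_words <- ev |>
      dplyr::distinct(.data$item, .data$aoi_index, .data$word) |>
      dplyr::arrange(.data$item, .data$aoi_index)
  } else {
    item_words <- tibble::as_tibble(item_words) |>
      dplyr::mutate(item = as.character(.data$item),
                    aoi_index = as.integer(.data$aoi_index),
                    word = as.character(.data$word))
  }
  if (is.null(participants)) participants <- unique(ev$participant)

  fixated <- ev |>
    dplyr::group_by(.data$participant, .data$item) |>
    dplyr::arrange(.data$order, .by_group = TRUE) |>
    dplyr::mutate(run = cumsum(.data$aoi_index !=
                                 dplyr::lag(.data$aoi_index,
                                            default = -1L))) |>
    dplyr::group_by(.data$participant, .data$item, .data$aoi_index) |>
    dplyr::summarise(
      ffd = .data$duration[.data$run == min(.data$run)][1],
      gaze = sum(.data$duration[.data$run == min(.data$run)]),
      rereading = sum(.data$duration[.data$run > min(.data$run)]),
      .groups = "drop"
    ) |>
    dplyr::mutate(trt = .data$gaze + .data$rereading, fixated = TRUE)

  grid <- tidyr::expand_grid(
    participant = participants,
    item_words
  )
  grid |>
    dplyr::left_join(fixated,
                     by = c("participant", "item", "aoi_index")) |>
    dplyr::mutate(fixated = !is.na(.data$fixated) & .data$fixated) |>
    dplyr::arrange(.data$participant, .data$item, .data$aoi_index)
}

#' Fixation probability per word token
#'
#' The fraction of participants who fixated each token at least once; the
#' complement of skipping. A token fixated by all participants has
#' probability 1.
#'
#' @param tokens Token measures from [token_measures()].
#' @return A tibble with `item`, `aoi_index`, `word`, `fix_prob`,
#'   `n_participants`.
#' @export
fixation_probability <- function(tokens) {
  tokens |>
    dplyr::group_by(.data$item, .data$aoi_index, .data$word) |>
    dplyr::summarise(fix_prob = mean(.data$fixated),
                     n_participants = dplyr::n(), .groups = "drop")
}

#' Aggregate token measures to word types
#'
#' First averages each duration measure over participants within a token
#' (skips excluded from duration means, but counted in the fixation
#' probability denominator), then collapses tokens of the same word type into
#' an unweighted mean across occurrences: lexical features are identical for
#' repeated words, so their reading measures are pooled.
#'
#' @param tokens Token measures from [token_measures()].
#' @return A tibble with one row per word type: `word`, `mean_ffd`,
#'   `mean_gaze`, `mean_rereading`, `mean_trt`, `fix_prob`, `n_tokens`,
#'   `n_participants`. Duration means are `NA` for all-skipped words.
#' @export
aggregate_to_type <- function(tokens) {
  na_mean <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) NA_real_ else mean(x)
  }
  per_token <- tokens |>
    dplyr::group_by(.data$item, .data$aoi_index, .data$word) |>
    dplyr::summarise(
      ffd = na_mean(.data$ffd),
      gaze = na_mean(.data$gaze),
      rereading = na_mean(.data$rereading),
      trt = na_mean(.data$trt),
      fix_prob = mean(.data$fixated),
      n_fix = sum(.data$fixated),
      n_participants = dplyr::n_distinct(.data$participant),
      .groups = "drop"
    )
  per_token |>
    dplyr::group_by(.data$word) |>
    dplyr::summarise(
      mean_ffd = na_mean(.data$ffd),
      mean_gaze = na_mean(.data$gaze),
      mean_rereading = na_mean(.data$rereading),
      mean_trt = na_mean(.data$trt),
      fix_prob = mean(.data$fix_prob),
      n_tokens = dplyr::n(),
      n_participants = max(.data$n_participants),
      low_n = sum(.data$n_fix) < 2,
      .groups = "drop"
    )
}

#' Correlations between the five word-level reading measures
#'
#' Pearson correlations between mean first fixation duration, gaze duration,
#' re-reading time, total reading time and fixation probability across word
#' types, with pairwise deletion of missing values.
#'
#' @param types Word-type measures from [aggregate_to_type()].
#' @return A symmetric 5 x 5 correlation matrix.
#' @export
measure_correlations <- function(types) {
  cols <- c("mean_ffd", "mean_gaze", "mean_rereading", "mean_trt", "fix_prob")
  stopifnot(all(cols %in% names(types)), nrow(types) >= 3)
  stats::cor(as.data.frame(types)[, cols], use = "pairwise.complete.obs",
             method = "pearson")
}

#' Skipping rate per participant
#'
#' Proportion of word tokens each participant never fixated, plus the grand
#' mean and SD across participants.
#'
#' @param tokens Token measures from [token_measures()].
#' @return A list with `by_participant` (tibble `participant`, `skip_rate`),
#'   `mean` and `sd`.
#' @export
skipping_rate <- function(tokens) {
  by_p <- tokens |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(skip_rate = mean(!.data$fixated), .groups = "drop")
  list(by_participant = by_p,
       mean = mean(by_p$skip_rate),
       sd = stats::sd(by_p$skip_rate))
}
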