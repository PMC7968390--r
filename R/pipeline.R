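#' Read a pipeline configuration file
#'
#' YAML configuration with optional sections `paths` (corpus, stimuli,
#' fixation_report, output_dir), `tokenization`, `sonority` (table overrides,
#' unknown policy), `modeling` (n_iterations, train_fraction, families,
#' fi_threshold, hyperparameters) and `synthetic` (any [synth_config()]
#' argument), plus a global `seed`.
#'
#' @param path Path to a YAML file.
#' @return A named list.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  yaml::read_yaml(path)
}

write_manifest <- function(out_dir, command, config, seed, inputs = character(0)) {
  checksums <- if (length(inputs) > 0) {
    as.list(tools::md5sum(inputs[file.exists(inputs)]))
  } else list()
  manifest <- list(command = command, seed = seed,
                   timestamp = format(Sys.time(), tz = "UTC"),
                   config = config, input_md5 = checksums)
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0(command, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}

#' Compute and write the feature table for a stimulus word list
#'
#' Reads the reference corpus (raw text or word/count TSV) and the stimulus
#' words (one token per line, or raw text), computes the seven surface
#' features per unique word type, optionally standardizes them, and writes a
#' TSV plus a run manifest.
#'
#' @param corpus Path to the reference corpus, or a [reference_lexicon()].
#' @param stimuli Path to the stimulus text/word list, or a character vector
#'   of words.
#' @param out Output TSV path; its directory receives the manifest.
#' @param standardize Also z-score the feature columns? Default `FALSE` (the
#'   raw features are written; modeling standardizes internally).
#' @param sonority A [sonority_table()].
#' @return The feature tibble, invisibly.
#' @export
run_features <- function(corpus, stimuli, out, standardize = FALSE,
                         sonority = sonority_table()) {
  lexicon <- if (inherits(corpus, "reference_lexicon")) corpus else read_lexicon(corpus)
  words <- if (is.character(stimuli) && length(stimuli) == 1 &&
               file.exists(stimuli)) {
    tokenize(readLines(stimuli, warn = FALSE))
  } else {
    as.character(stimuli)
  }
  feats <- word_features(words, lexicon, sonority = sonority)
  if (standardize) feats <- standardize_features(feats)
  dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(feats, out, progress = FALSE)
  message(nrow(feats), " word types; ",
          sum(feats$flags != ""), " flagged.")
  write_manifest(dirname(out), "features",
                 list(standardize = standardize),
                 seed = NA,
                 inputs = c(if (is.character(corpus)) corpus,
                            if (is.character(stimuli) && length(stimuli) == 1 &&
                                file.exists(stimuli)) stimuli))
  invisible(feats)
}

#' Aggregate a fixation report and write token and type measures
#'
#' Parses the report, computes token-level measures, and aggregates them to
#' word types; writes `token_measures.tsv` and `type_measures.tsv` into
#' `out_dir` plus a manifest.
#'
#' @param report Path to a fixation report TSV.
#' @param out_dir Output directory.
#' @param item_words Optional token inventory (`item`, `aoi_index`, `word`)
#'   tibble or TSV path, so fully skipped words are represented.
#' @param col_map Column mapping passed to [parse_fixation_report()].
#' @return A list with `tokens` and `types` tibbles, invisibly.
#' @export
run_aggregate <- function(report, out_dir, item_words = NULL,
                          col_map = c(participant = "participant",
                                      item = "item", aoi_index = "aoi_index",
                                      word = "word", order = "order",
                                      duration = "duration")) {
  events <- parse_fixation_report(report, col_map = col_map)
  if (is.character(item_words)) {
    item_words <- readr::read_tsv(item_words, show_col_types = FALSE,
                                  progress = FALSE)
  }
  tokens <- token_measures(events, item_words = item_words)
  types <- aggregate_to_type(tokens)
  sr <- skipping_rate(tokens)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(tokens, file.path(out_dir, "token_measures.tsv"),
                   progress = FALSE)
  readr::write_tsv(types, file.path(out_dir, "type_measures.tsv"),
                   progress = FALSE)
  message(nrow(types), " word types from ", nrow(events),
          " fixations; skipping rate M = ", round(sr$mean, 3),
          ", SD = ", round(sr$sd, 3), ".")
  write_manifest(out_dir, "aggregate", list(col_map = as.list(col_map)),
                 seed = NA, inputs = report)
  invisible(list(tokens = tokens, types = types, skipping = sr))
}

#' Run the model comparison for each response and write summaries
#'
#' Joins a feature table and a word-type measures table on `word`, then for
#' each requested response runs the repeated-holdout comparison of the three
#' model families with total-effect importances, and the follow-up simple
#' regressions for every feature flagged important. Writes a tidy TSV of
#' summary statistics, a JSON summary, and a manifest.
#'
#' @param features Feature tibble or TSV path (raw or standardized).
#' @param measures Word-type measures tibble or TSV path (from
#'   [run_aggregate()] or [generate_study()]).
#' @param out_dir Output directory.
#' @param responses Response columns to model, default
#'   `c("mean_ffd", "mean_trt", "fix_prob")`.
#' @param n_iterations Holdout repetitions, default 1000.
#' @param seed Master seed.
#' @param fi_threshold Importance cut-off, default 0.1.
#' @param families Model families to compare.
#' @param hyperparameters Per-family hyperparameter overrides.
#' @return A list (per response) of `sg_cv` objects plus simple-regression
#'   tibbles, invisibly.
#' @export
run_model <- function(features, measures, out_dir,
                      responses = c("mean_ffd", "mean_trt", "fix_prob"),
                      n_iterations = 1000, seed = 1L, fi_threshold = 0.1,
                      families = c("least_squares", "neural_net",
                                   "bootstrap_forest"),
                      hyperparameters = list()) {
  if (is.character(features)) {
    features <- readr::read_tsv(features, show_col_types = FALSE, progress = FALSE)
  }
  if (is.character(measures)) {
    measures <- readr::read_tsv(measures, show_col_types = FALSE, progress = FALSE)
  }
  unmatched <- union(setdiff(features$word, measures$word),
                     setdiff(measures$word, features$word))
  joined <- dplyr::inner_join(tibble::as_tibble(features),
                              tibble::as_tibble(measures), by = "word")
  if (nrow(joined) == 0) {
    stop("No words in common between features and measures.", call. = FALSE)
  }
  if (length(unmatched) > 0) {
    message("Join dropped ", length(unmatched), " unmatched word(s): ",
            paste(utils::head(unmatched, 10), collapse = ", "),
            if (length(unmatched) > 10) ", ...")
  }
  responses <- intersect(responses, names(joined))
  seeds <- derive_seeds(seed, length(responses))
  results <- list()
  summary_rows <- list()
  for (ri in seq_along(responses)) {
    resp <- responses[ri]
    cv <- evaluate_models(joined, response = resp,
                          families = families,
                          n_iterations = n_iterations, seed = seeds[ri],
                          compute_importance = TRUE,
                          importance_threshold = fi_threshold,
                          hyperparameters = hyperparameters)
    important <- cv$importance |>
      dplyr::filter(.data$family == "neural_net", .data$important)
    simple <- purrr::map(important$feature, function(ft) {
      simple_regression(joined, ft, resp, n_iterations = n_iterations,
                        seed = seeds[ri])
    }) |> dplyr::bind_rows()
    results[[resp]] <- list(cv = cv, simple = simple)
    summary_rows[[resp]] <- cv$summary
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  all_summaries <- dplyr::bind_rows(summary_rows)
  readr::write_tsv(all_summaries, file.path(out_dir, "model_summaries.tsv"),
                   progress = FALSE)
  all_importance <- purrr::imap(results, function(r, resp) {
    dplyr::mutate(r$cv$importance, response = resp)
  }) |> dplyr::bind_rows()
  readr::write_tsv(all_importance, file.path(out_dir, "importances.tsv"),
                   progress = FALSE)
  all_simple <- purrr::map(results, "simple") |> dplyr::bind_rows()
  if (nrow(all_simple) > 0) {
    readr::write_tsv(all_simple, file.path(out_dir, "simple_regressions.tsv"),
                     progress = FALSE)
  }
  jsonlite::write_json(
    list(summaries = all_summaries, importances = all_importance,
         simple_regressions = all_simple),
    file.path(out_dir, "model_results.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  write_manifest(out_dir, "model",
                 list(responses = responses, n_iterations = n_iterations,
                      families = families, fi_threshold = fi_threshold),
                 seed = seed)
  invisible(results)
}

#' Generate and write a full synthetic dataset
#'
#' Runs [generate_study()] and writes the feature table, word-level measures,
#' fixation report, token inventory, ground truth and the resolved
#' configuration into `out_dir`.
#'
#' @param out_dir Output directory.
#' @param config A [synth_config()] or a YAML path whose `synthetic` section
#'   overrides the defaults.
#' @param seed Master seed.
#' @param mode `"direct"` or `"lexical"` (see [generate_study()]).
#' @return The study list, invisibly.
#' @export
run_simulate <- function(out_dir, config = synth_config(), seed = 1L,
                         mode = "direct") {
  if (is.character(config)) {
    raw <- read_config(config)
    config <- do.call(synth_config, raw$synthetic %||% list())
  }
  study <- generate_study(config, seed = seed, mode = mode)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(study$features, file.path(out_dir, "features.tsv"),
                   progress = FALSE)
  readr::write_tsv(study$measures, file.path(out_dir, "measures.tsv"),
                   progress = FALSE)
  readr::write_tsv(study$item_words, file.path(out_dir, "item_words.tsv"),
                   progress = FALSE)
  write_fixation_report(study$report$events,
                        file.path(out_dir, "fixation_report.tsv"))
  readr::write_tsv(study$report$tokens,
                   file.path(out_dir, "true_token_measures.tsv"),
                   progress = FALSE)
  truth <- study$truth
  truth_json <- purrr::map(truth, function(t) {
    list(weights = as.list(t$weights), interaction = t$interaction,
         important = t$important, noise_sd = t$noise_sd)
  })
  jsonlite::write_json(truth_json, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  cfg_out <- study$config
  cfg_out$feature_correlations <- NULL
  write_manifest(out_dir, "simulate",
                 c(cfg_out, list(mode = mode)), seed = seed)
  invisible(study)
}
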