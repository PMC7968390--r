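#' Default correlation structure of the seven surface features
#'
#' The target correlation matrix the synthetic generator aims at: the
#' empirical intercorrelations observed between the seven features in the
#' sonnet stimuli (strong negative word-length/neighborhood-density and
#' word-length/frequency correlations, strong positive length/dissimilarity
#' and length/sonority correlations). Symmetric positive definite, so it can
#' be used directly as a Gaussian-copula target.
#'
#' @return A 7 x 7 correlation matrix with dimnames `wl`, `logf`, `on`,
#'   `hfn`, `odc`, `cvq`, `sonscore`.
#' @export
qna_feature_correlations <- function() {
  fn <- feature_names()
  R <- matrix(c(
     1.00, -0.75, -0.81, -0.31,  0.74,  0.19,  0.72,
    -0.75,  1.00,  0.68,  0.00, -0.48, -0.10, -0.55,
    -0.81,  0.68,  1.00,  0.36, -0.39, -0.24, -0.57,
    -0.31,  0.00,  0.36,  1.00, -0.18, -0.05, -0.28,
     0.74, -0.48, -0.39, -0.18,  1.00,  0.10,  0.62,
     0.19, -0.10, -0.24, -0.05,  0.10,  1.00,  0.00,
     0.72, -0.55, -0.57, -0.28,  0.62,  0.00,  1.00
  ), 7, 7, dimnames = list(fn, fn))
  R
}

#' Synthetic-study configuration
#'
#' Bundles every tunable of the synthetic-data generator. The defaults emulate
#' the study conditions the pipeline targets: 205 word types read by 15
#' participants; feature intercorrelations as in
#' [qna_feature_correlations()]; reading-measure effects carried by word
#' length (+), log frequency (-), neighborhood density (-) and sonority score
#' (+) with the remaining three features inert; a signal fraction of 0.60
#' (noise chosen so ordinary least squares reaches a validation R-squared of
#' about .50 at n = 205); and a logistic skipping process calibrated to a
#' marginal skipping rate of about 13 percent, skipping being most likely for
#' short, frequent words.
#'
#' @param n_word_types Number of stimulus word types, default 205.
#' @param n_lexicon_types Reference-lexicon size for the lexical generation
#'   mode, default 2000.
#' @param length_lambda Poisson rate for (length - 1) in the lexical mode.
#' @param wl_logf_coupling How strongly log counts decrease with word length
#'   in the lexical mode (log10 counts per letter), default 0.35.
#' @param feature_correlations Copula target correlation matrix (must be
#'   symmetric positive semi-definite).
#' @param weights Named per-feature linear effect weights on the latent
#'   response (standardized feature scale).
#' @param interaction Optional interaction term: a list with `features` (two
#'   feature names) and `weight`, or `NULL` (default).
#' @param signal_fraction Fraction of latent-response variance carried by the
#'   signal; the noise SD is derived from it, default 0.60.
#' @param noise_sd Explicit Gaussian noise SD overriding `signal_fraction`
#'   (`NULL` by default).
#' @param fixprob_intercept,fixprob_scale Logistic-link parameters mapping the
#'   latent response to a fixation probability in (0, 1).
#' @param n_participants Number of simulated readers, default 15.
#' @param skip Named coefficients of the logistic skip model:
#'   `intercept`, `wl`, `logf` (on standardized features) and
#'   `participant_sd`, the SD of a per-reader normal intercept shift.
#' @param fixation Duration model parameters: `base_ms` (grand mean first
#'   fixation), `slope_ms` (ms per SD of the latent difficulty), `participant_sd`
#'   (between-reader SD of the base), `sd_ms` (within-cell noise), `refix_prob`
#'   (second first-pass fixation), `regress_prob` (re-reading visit),
#'   `reread_ms` (mean re-reading fixation duration).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_word_types = 205,
                         n_lexicon_types = 2000,
                         length_lambda = 3.2,
                         wl_logf_coupling = 0.35,
                         feature_correlations = qna_feature_correlations(),
                         weights = c(wl = 0.40, logf = -0.42, on = -0.45,
                                     hfn = 0, odc = 0, cvq = 0,
                                     sonscore = 0.55),
                         interaction = NULL,
                         signal_fraction = 0.60,
                         noise_sd = NULL,
                         fixprob_intercept = 1.1,
                         fixprob_scale = 1.0,
                         n_participants = 15,
                         skip = c(intercept = -2.55, wl = -0.75, logf = 0.75,
                                  participant_sd = 0.35),
                         fixation = list(base_ms = 215, slope_ms = 30,
                                         participant_sd = 20, sd_ms = 35,
                                         refix_prob = 0.15,
                                         regress_prob = 0.2,
                                         reread_ms = 180)) {
  R <- feature_correlations
  stopifnot(isSymmetric(unname(R)), all(eigen(R, only.values = TRUE)$values > -1e-8))
  stopifnot(n_participants >= 1, signal_fraction > 0, signal_fraction < 1)
  if (!is.null(noise_sd)) stopifnot(noise_sd > 0)
  cfg <- list(n_word_types = n_word_types,
              n_lexicon_types = n_lexicon_types,
              length_lambda = length_lambda,
              wl_logf_coupling = wl_logf_coupling,
              feature_correlations = R,
              weights = weights,
              interaction = interaction,
              signal_fraction = signal_fraction,
              noise_sd = noise_sd,
              fixprob_intercept = fixprob_intercept,
              fixprob_scale = fixprob_scale,
              n_participants = n_participants,
              skip = skip,
              fixation = fixation)
  class(cfg) <- "synth_config"
  cfg
}

#' Generate random word forms and a reference lexicon
#'
#' Draws a reference lexicon of unique letter strings whose lengths follow a
#' shifted Poisson distribution and whose token counts are heavy-tailed
#' (log-normal) and decrease with word length, so that computed word length
#' and log frequency are negatively correlated as in natural lexicons. The
#' stimulus word types are sampled from the lexicon with probability
#' proportional to count (frequent words are more likely to occur in a text).
#'
#' @param config A [synth_config()].
#' @param seed Integer seed; output is a pure function of (config, seed).
#' @return A list with `words` (character vector of `n_word_types` stimulus
#'   types) and `lexicon` (a [reference_lexicon()] of `n_lexicon_types`
#'   types).
#' @export
generate_word_forms <- function(config = synth_config(), seed = 1L) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(seed, {
    n_lex <- config$n_lexicon_types
    lens <- 1L + stats::rpois(n_lex, config$length_lambda)
    # letter pool weighted toward common English letters so neighborhoods form
    pool <- c(a = 8, b = 2, c = 3, d = 4, e = 12, f = 2, g = 2, h = 5, i = 7,
              k = 1, l = 4, m = 3, n = 7, o = 8, p = 2, r = 6, s = 6, t = 9,
              u = 3, v = 1, w = 2, y = 2)
    draw <- function(len) paste(sample(names(pool), len, replace = TRUE,
                                       prob = pool), collapse = "")
    words <- vapply(lens, draw, character(1))
    while (anyDuplicated(words)) {
      dup <- which(duplicated(words))
      words[dup] <- vapply(lens[dup], draw, character(1))
    }
    log_counts <- stats::rnorm(n_lex,
                               mean = 3 - config$wl_logf_coupling * (lens - mean(lens)),
                               sd = 0.8)
    counts <- pmax(1, round(10^log_counts))
    lex <- reference_lexicon(stats::setNames(counts, words))
    stim <- sample(words, config$n_word_types, replace = FALSE,
                   prob = counts^0.5)
    list(words = stim, lexicon = lex)
  })
}

#' Generate a feature table with a known correlation structure
#'
#' Gaussian-copula draw: latent multivariate normal scores with the configured
#' target correlation matrix are mapped through monotone marginal transforms
#' to plausible feature ranges (integer lengths and neighbor counts,
#' non-negative frequencies, positive quotients). Monotone transforms
#' approximately preserve the target Pearson correlations; the empirical
#' correlations approach the target as n grows. `hfn` is truncated at `on`
#' so the neighborhood invariant holds by construction.
#'
#' @inheritParams generate_word_forms
#' @param n Number of rows; defaults to `config$n_word_types`.
#' @return A tibble with columns `word` (synthetic labels `w0001`, ...) and
#'   the seven features.
#' @export
generate_feature_matrix <- function(config = synth_config(), seed = 1L,
                                    n = config$n_word_types) {
  stopifnot(inherits(config, "synth_config"))
  R <- config$feature_correlations
  withr::with_seed(seed, {
    Z <- MASS::mvrnorm(n, mu = rep(0, 7), Sigma = R)
    colnames(Z) <- feature_names()
    u <- stats::pnorm(Z)
    tibble::tibble(
      word = sprintf("w%04d", seq_len(n)),
      wl = 1L + stats::qpois(u[, "wl"], lambda = 3.2),
      logf = pmax(0, 2.2 + 1.1 * Z[, "logf"]),
      on = stats::qnbinom(u[, "on"], size = 1.5, mu = 2.5),
      hfn = pmin(stats::qnbinom(u[, "hfn"], size = 1.5, mu = 1.2),
                 stats::qnbinom(u[, "on"], size = 1.5, mu = 2.5)),
      odc = pmax(1, 4.8 + 1.1 * Z[, "odc"]),
      cvq = exp(0.35 + 0.35 * Z[, "cvq"]),
      sonscore = pmax(0.5, 9.5 + 2.4 * Z[, "sonscore"])
    )
  })
}

latent_response <- function(features, config) {
  X <- as.matrix(as.data.frame(features)[, feature_names()])
  # z-score each feature; cells where a feature is undefined (e.g. cvq of a
  # vowelless word) contribute the average effect, i.e. zero on the z-scale
  Xs <- apply(X, 2, function(x) {
    s <- stats::sd(x, na.rm = TRUE)
    z <- if (is.na(s) || s == 0) rep(0, length(x)) else
      (x - mean(x, na.rm = TRUE)) / s
    z[is.na(z)] <- 0
    z
  })
  w <- config$weights[feature_names()]
  w[is.na(w)] <- 0
  latent <- as.numeric(Xs %*% w)
  if (!is.null(config$interaction)) {
    ia <- config$interaction
    latent <- latent + ia$weight * Xs[, ia$features[1]] * Xs[, ia$features[2]]
  }
  latent
}

signal_variance <- function(config) {
  R <- config$feature_correlations
  w <- config$weights[feature_names()]
  w[is.na(w)] <- 0
  v <- as.numeric(t(w) %*% R %*% w)
  if (!is.null(config$interaction)) {
    ia <- config$interaction
    r <- R[ia$features[1], ia$features[2]]
    v <- v + ia$weight^2 * (1 + r^2)  # product of correlated standard normals
  }
  v
}

#' Generate word-level reading responses with known ground truth
#'
#' The latent response is the configured linear combination of the
#' standardized features (plus an optional interaction), and Gaussian noise is
#' added so that the signal carries `signal_fraction` of the total variance
#' (or with the explicit `noise_sd` when set). With `link = "logistic"` the
#' noisy latent value is passed through a logistic function, yielding a
#' fixation-probability-like response in (0, 1) with the asymmetric,
#' ceiling-heavy distribution real fixation probabilities show.
#'
#' @inheritParams generate_word_forms
#' @param features A feature tibble (raw scale) with the seven feature
#'   columns, e.g. from [generate_feature_matrix()] or [word_features()].
#' @param link `"identity"` (reading-time-like) or `"logistic"`
#'   (probability-like).
#' @return A list with `response` (numeric vector aligned with
#'   `features$word`), and `truth`: the effect `weights`, the `interaction`
#'   spec, the `important` feature set (nonzero weights or interaction
#'   parents), the noise-free `latent` values and the `noise_sd` used.
#' @export
generate_measures <- function(features, config = synth_config(), seed = 1L,
                              link = c("identity", "logistic")) {
  link <- match.arg(link)
  stopifnot(inherits(config, "synth_config"))
  latent <- latent_response(features, config)
  noise_sd <- config$noise_sd %||%
    sqrt(signal_variance(config) *
           (1 - config$signal_fraction) / config$signal_fraction)
  withr::with_seed(seed, {
    y <- latent + stats::rnorm(length(latent), 0, noise_sd)
  })
  if (link == "logistic") {
    y <- stats::plogis(config$fixprob_intercept + config$fixprob_scale * y)
  }
  important <- names(which(config$weights != 0))
  if (!is.null(config$interaction)) {
    important <- union(important, config$interaction$features)
  }
  list(
    response = y,
    truth = list(weights = config$weights,
                 interaction = config$interaction,
                 important = important[order(match(important, feature_names()))],
                 latent = latent,
                 noise_sd = noise_sd)
  )
}

#' Generate a fixation report with constructive ground truth
#'
#' Simulates, for every participant and item, an ordered fixation sequence
#' over the item's words: each word is first skipped or fixated according to a
#' logistic model on standardized word length (short words skipped more) and
#' log frequency (frequent words skipped more); fixated words receive a
#' first-pass run of one or (with probability `refix_prob`) two fixations
#' whose durations increase with the word's latent difficulty, and with
#' probability `regress_prob` a later re-reading fixation. Re-reading
#' fixations are emitted after the full first pass, so first-pass runs are
#' maximal consecutive runs by construction and the implied token measures are
#' exact.
#'
#' @inheritParams generate_word_forms
#' @param item_words Tibble (`item`, `aoi_index`, `word`) listing the word
#'   tokens of each item in reading order.
#' @param features Feature tibble covering every word in `item_words` (columns
#'   `word`, `wl`, `logf` at least; the latent difficulty uses all available
#'   feature columns via the configured weights).
#' @return A list with `events` (a fixation event tibble as
#'   [parse_fixation_report()] returns) and `tokens` (the ground-truth token
#'   measures the aggregator must reproduce exactly).
#' @export
generate_fixation_report <- function(item_words, features,
                                     config = synth_config(), seed = 1L) {
  stopifnot(inherits(config, "synth_config"))
  iw <- tibble::as_tibble(item_words) |>
    dplyr::mutate(item = as.character(.data$item),
                  aoi_index = as.integer(.data$aoi_index),
                  word = as.character(.data$word))
  stopifnot(all(iw$word %in% features$word))
  fs <- tibble::as_tibble(features)
  zs <- function(x) as.numeric(scale(x))
  fs$z_wl <- zs(fs$wl)
  fs$z_logf <- zs(fs$logf)
  fs$difficulty <- zs(latent_response(fs, config))
  iw <- dplyr::left_join(iw, fs[, c("word", "z_wl", "z_logf", "difficulty")],
                         by = "word")
  fx <- config$fixation
  sk <- config$skip
  participants <- sprintf("p%02d", seq_len(config$n_participants))

  withr::with_seed(seed, {
    base_p <- stats::rnorm(config$n_participants, fx$base_ms, fx$participant_sd)
    skip_sd <- if ("participant_sd" %in% names(sk)) sk[["participant_sd"]] else 0
    skip_shift <- stats::rnorm(config$n_participants, 0, skip_sd)
    all_events <- list()
    all_tokens <- list()
    for (pi in seq_along(participants)) {
      for (it in unique(iw$item)) {
        tw <- iw[iw$item == it, ]
        tw <- tw[order(tw$aoi_index), ]
        k <- nrow(tw)
        p_skip <- stats::plogis(sk[["intercept"]] + skip_shift[pi] +
                                  sk[["wl"]] * tw$z_wl +
                                  sk[["logf"]] * tw$z_logf)
        fixated <- stats::runif(k) > p_skip
        mu <- base_p[pi] + fx$slope_ms * tw$difficulty
        dur1 <- pmax(60, round(stats::rnorm(k, mu, fx$sd_ms)))
        refix <- fixated & stats::runif(k) < fx$refix_prob
        dur2 <- pmax(60, round(stats::rnorm(k, mu * 0.8, fx$sd_ms)))
        regress <- fixated & stats::runif(k) < fx$regress_prob
        dur3 <- pmax(60, round(stats::rnorm(k, fx$reread_ms, fx$sd_ms)))
        # first pass in word order, then re-reading visits
        seq_aoi <- integer(0); seq_dur <- numeric(0)
        for (j in seq_len(k)[fixated]) {
          seq_aoi <- c(seq_aoi, tw$aoi_index[j])
          seq_dur <- c(seq_dur, dur1[j])
          if (refix[j]) {
            seq_aoi <- c(seq_aoi, tw$aoi_index[j])
            seq_dur <- c(seq_dur, dur2[j])
          }
        }
        reread_idx <- which(regress)
        if (length(reread_idx) > 1) reread_idx <- sample(reread_idx)
        # a regression is only a re-reading if some other word intervenes;
        # with word-ordered first pass that holds unless the regressed word
        # is the last one fixated, so visit them in shuffled order and drop
        # a would-be immediate repeat
        for (j in reread_idx) {
          if (length(seq_aoi) > 0 &&
              seq_aoi[length(seq_aoi)] == tw$aoi_index[j]) next
          seq_aoi <- c(seq_aoi, tw$aoi_index[j])
          seq_dur <- c(seq_dur, dur3[j])
        }
        if (length(seq_aoi) > 0) {
          all_events[[length(all_events) + 1]] <- tibble::tibble(
            participant = participants[pi],
            item = it,
            aoi_index = seq_aoi,
            word = tw$word[match(seq_aoi, tw$aoi_index)],
            order = seq_along(seq_aoi),
            duration = seq_dur
          )
        }
        # ground-truth measures implied by the construction
        if (length(seq_aoi) > 0) {
          # recompute from the emitted sequence to stay exact
          first_run_sum <- tapply_first_run(seq_aoi, seq_dur)
          tok <- tibble::tibble(
            participant = participants[pi],
            item = it,
            aoi_index = tw$aoi_index,
            word = tw$word,
            ffd = first_run_sum$ffd[match(tw$aoi_index, first_run_sum$aoi)],
            gaze = first_run_sum$gaze[match(tw$aoi_index, first_run_sum$aoi)],
            rereading = first_run_sum$rereading[match(tw$aoi_index, first_run_sum$aoi)],
            fixated = tw$aoi_index %in% seq_aoi
          )
        } else {
          tok <- tibble::tibble(
            participant = participants[pi], item = it,
            aoi_index = tw$aoi_index, word = tw$word,
            ffd = NA_real_, gaze = NA_real_, rereading = NA_real_,
            fixated = FALSE
          )
        }
        tok$trt <- tok$gaze + tok$rereading
        all_tokens[[length(all_tokens) + 1]] <- tok
      }
    }
    events <- dplyr::bind_rows(all_events)
    tokens <- dplyr::bind_rows(all_tokens) |>
      dplyr::select("participant", "item", "aoi_index", "word",
                    "ffd", "gaze", "rereading", "trt", "fixated") |>
      dplyr::arrange(.data$participant, .data$item, .data$aoi_index)
    list(events = validate_fixation_events(events), tokens = tokens)
  })
}

# first-pass decomposition of one trial's fixation sequence
tapply_first_run <- function(seq_aoi, seq_dur) {
  run <- cumsum(seq_aoi != dplyr::lag(seq_aoi, default = -1L))
  aois <- unique(seq_aoi)
  ffd <- gaze <- rereading <- numeric(length(aois))
  for (i in seq_along(aois)) {
    sel <- seq_aoi == aois[i]
    fr <- min(run[sel])
    ffd[i] <- seq_dur[sel & run == fr][1]
    gaze[i] <- sum(seq_dur[sel & run == fr])
    rereading[i] <- sum(seq_dur[sel & run > fr])
  }
  list(aoi = aois, ffd = ffd, gaze = gaze, rereading = rereading)
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper producing everything the pipeline consumes, in one of
#' two modes: `"direct"` draws the feature matrix from the Gaussian copula
#' (fast, exact correlation control), `"lexical"` draws word forms and a
#' reference lexicon and computes the features through the same code path real
#' corpora go through. Both modes then generate the three word-level responses
#' (mean first fixation duration and mean total reading time on the identity
#' link, fixation probability on the logistic link) and a fixation report.
#'
#' @inheritParams generate_word_forms
#' @param mode `"direct"` (default) or `"lexical"`.
#' @return A list: `features` (raw-scale feature tibble), `measures` (tibble
#'   `word`, `mean_ffd`, `mean_trt`, `fix_prob`), `truth` (per-response ground
#'   truth), `item_words`, `report` (events + ground-truth tokens), and
#'   `lexicon` (lexical mode only).
#' @export
generate_study <- function(config = synth_config(), seed = 1L,
                           mode = c("direct", "lexical")) {
  mode <- match.arg(mode)
  seeds <- derive_seeds(seed, 6)
  if (mode == "direct") {
    features <- generate_feature_matrix(config, seed = seeds[1])
    lexicon <- NULL
  } else {
    wf <- generate_word_forms(config, seed = seeds[1])
    features <- word_features(wf$words, wf$lexicon)
    lexicon <- wf$lexicon
  }
  trt <- generate_measures(features, config, seed = seeds[2], link = "identity")
  ffd_cfg <- config
  # first fixation durations carry a weaker, length/frequency-only signal
  ffd_cfg$weights <- c(wl = 0.25, logf = -0.3, on = 0, hfn = 0, odc = 0,
                       cvq = 0, sonscore = 0)
  ffd_cfg$signal_fraction <- 0.15
  ffd_cfg$interaction <- NULL
  class(ffd_cfg) <- "synth_config"
  ffd <- generate_measures(features, ffd_cfg, seed = seeds[3], link = "identity")
  fp <- generate_measures(features, config, seed = seeds[4], link = "logistic")
  measures <- tibble::tibble(
    word = features$word,
    mean_ffd = 230 + 25 * ffd$response,
    mean_trt = 320 + 80 * trt$response,
    fix_prob = fp$response
  )
  # split the words over three items of roughly equal length, in order
  n <- nrow(features)
  item_words <- tibble::tibble(
    item = sort(rep_len(c("i1", "i2", "i3"), n)),
    word = features$word
  ) |>
    dplyr::group_by(.data$item) |>
    dplyr::mutate(aoi_index = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("item", "aoi_index", "word")
  report <- generate_fixation_report(item_words, features, config,
                                     seed = seeds[5])
  list(features = features, measures = measures,
       truth = list(mean_ffd = ffd$truth, mean_trt = trt$truth,
                    fix_prob = fp$truth),
       item_words = item_words, report = report, lexicon = lexicon,
       config = config, seed = seed)
}
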