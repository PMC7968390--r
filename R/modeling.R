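#' Repeated random 90/10 holdout splits
#'
#' Generates `n_iterations` independent random partitions of `1:n` into a
#' training set of `round(train_fraction * n)` indices and a validation set of
#' the rest (always at least 1 row each). With n = 205 and the default
#' fraction the validation sets hold about 20 words. Reproducible from the
#' master seed.
#'
#' @param n Number of observations.
#' @param train_fraction Fraction assigned to training, strictly in (0, 1).
#' @param n_iterations Number of splits, default 1000.
#' @param seed Master seed (integer).
#' @return A list of length `n_iterations`; each element has `train` and
#'   `validation` integer index vectors.
#' @export
repeated_holdout <- function(n, train_fraction = 0.9, n_iterations = 1000,
                             seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1, n >= 2)
  n_train <- round(train_fraction * n)
  n_train <- min(max(n_train, 1L), n - 1L)
  withr::with_seed(seed, {
    lapply(seq_len(n_iterations), function(i) {
      tr <- sort(sample.int(n, n_train))
      list(train = tr, validation = setdiff(seq_len(n), tr))
    })
  })
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`, with the total sum of squares taken about the mean
#' of the evaluated observations themselves. On held-out data the value can be
#' negative: predictions worse than the constant mean.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 2).
#' @return A single numeric R-squared value.
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("Zero total sum of squares: R^2 undefined.", call. = FALSE)
  1 - sum((observed - predicted)^2) / ss_tot
}

new_sg_fit <- function(family, model, response, features, seed = NA_integer_) {
  structure(list(family = family, model = model, response = response,
                 features = features, seed = seed),
            class = "sg_fit")
}

#' @export
print.sg_fit <- function(x, ...) {
  cat("<sg_fit> family:", x$family, "| response:", x$response,
      "| features:", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}

#' Predict from a fitted model
#'
#' @param object An `sg_fit` from [fit_least_squares()], [fit_neural_net()] or
#'   [fit_bootstrap_forest()].
#' @param newdata Data frame containing the feature columns.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.sg_fit <- function(object, newdata, ...) {
  nd <- as.data.frame(newdata)[, object$features, drop = FALSE]
  switch(object$family,
    least_squares = unname(stats::predict(object$model, newdata = nd)),
    neural_net = as.numeric(stats::predict(object$model, newdata = nd)),
    bootstrap_forest = unname(stats::predict(object$model, newdata = nd))
  )
}

#' Ordinary least squares on the main effects
#'
#' Fits the response on the seven features as additive main effects (no
#' interactions). Rank deficiency (e.g. duplicated predictor columns) is an
#' error.
#'
#' @param data Data frame holding the response and feature columns
#'   (standardized upstream).
#' @param response Response column name.
#' @param features Feature column names.
#' @return An `sg_fit`.
#' @export
fit_least_squares <- function(data, response, features = feature_names()) {
  stopifnot(nrow(data) > length(features))
  f <- stats::reformulate(features, response = response)
  m <- stats::lm(f, data = as.data.frame(data))
  if (m$rank < length(features) + 1L) {
    stop("Rank-deficient design: predictors are linearly dependent.",
         call. = FALSE)
  }
  new_sg_fit("least_squares", m, response, features)
}

#' Small multi-layer perceptron
#'
#' A single-hidden-layer network (default 3 sigmoid units, linear output) with
#' weight decay as L2 regularization, refit from `restarts` random weight
#' initializations; the restart with the lowest training error wins.
#' Deterministic given `seed`. Inputs should be standardized.
#'
#' @inheritParams fit_least_squares
#' @param size Hidden units, default 3.
#' @param decay L2 weight decay, default 12: a deliberately strong penalty
#'   (about 0.065 per training row at the package's typical scale of ~200
#'   standardized observations) that stabilizes fits when features are highly
#'   collinear. Lower it (0.1-1) when the signal of interest is a nonlinear
#'   interaction the penalty would smooth away.
#' @param restarts Random restarts, default 5.
#' @param maxit Optimizer iteration cap per restart.
#' @param seed Integer seed.
#' @return An `sg_fit`.
#' @export
fit_neural_net <- function(data, response, features = feature_names(),
                           size = 3, decay = 12, restarts = 5,
                           maxit = 400, seed = 1L) {
  df <- as.data.frame(data)
  f <- stats::reformulate(features, response = response)
  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(restarts)) {
      m <- nnet::nnet(f, data = df, size = size, decay = decay,
                      linout = TRUE, maxit = maxit, trace = FALSE)
      if (is.null(best) || m$value < best$value) best <- m
    }
  })
  new_sg_fit("neural_net", best, response, features, seed)
}

#' Bagged regression trees (bootstrap forest)
#'
#' An ensemble of regression trees, each grown on a bootstrap resample of the
#' training rows with a random subset of candidate predictors at every split;
#' the prediction is the mean over trees. Deterministic given `seed`.
#'
#' @inheritParams fit_neural_net
#' @param ntree Number of trees, default 100.
#' @param mtry Candidate predictors per split; default `ceiling(p / 3)`.
#' @param nodesize Minimum terminal node size, default 5.
#' @return An `sg_fit`.
#' @export
fit_bootstrap_forest <- function(data, response, features = feature_names(),
                                 ntree = 100, mtry = ceiling(length(features) / 3),
                                 nodesize = 5, seed = 1L) {
  df <- as.data.frame(data)
  x <- df[, features, drop = FALSE]
  y <- df[[response]]
  m <- withr::with_seed(seed, {
    randomForest::randomForest(x = x, y = y, ntree = ntree, mtry = mtry,
                               nodesize = nodesize)
  })
  new_sg_fit("bootstrap_forest", m, response, features, seed)
}

fit_family <- function(family, data, response, features, seed,
                       hyperparameters = list()) {
  hp <- hyperparameters[[family]] %||% list()
  switch(family,
    least_squares = fit_least_squares(data, response, features),
    neural_net = do.call(fit_neural_net,
                         c(list(data = data, response = response,
                                features = features, seed = seed), hp)),
    bootstrap_forest = do.call(fit_bootstrap_forest,
                               c(list(data = data, response = response,
                                      features = features, seed = seed), hp)),
    stop("Unknown model family: ", family, call. = FALSE)
  )
}

#' Compare model families under repeated holdout validation
#'
#' For each family and each of `n_iterations` random 90/10 splits, fits on the
#' training rows and scores R-squared on both the training and validation
#' rows, then averages. By default the same split list is reused across
#' families (paired comparison, reducing between-family variance); set
#' `paired_splits = FALSE` for independent splits per family. Optionally
#' averages total-effect feature importances over iterations.
#'
#' All variables are standardized internally (z-scores) before modeling unless
#' `standardize = FALSE`.
#'
#' @param data Data frame with the response and feature columns; rows with
#'   missing values in those columns are dropped with a message.
#' @param response Response column name.
#' @param features Feature column names (default the seven surface features).
#' @param families Character vector drawn from `"least_squares"`,
#'   `"neural_net"`, `"bootstrap_forest"`.
#' @param n_iterations Number of holdout repetitions, default 1000.
#' @param train_fraction Training fraction, default 0.9.
#' @param seed Master seed controlling splits, model fits and importance
#'   resampling.
#' @param standardize Standardize all columns first? Default `TRUE`.
#' @param paired_splits Reuse the same splits across families? Default `TRUE`.
#' @param compute_importance Also compute total-effect feature importances,
#'   averaged over iterations? Default `FALSE`.
#' @param importance_samples Resampling replicates per feature per iteration
#'   for the importance estimator.
#' @param importance_threshold FI cut-off for the "important" flag, default 0.1.
#' @param hyperparameters Optional named list of per-family argument lists,
#'   e.g. `list(neural_net = list(size = 5))`.
#' @return An object of class `sg_cv` with elements `outcomes` (tibble: one
#'   row per family x iteration with `r2_train`, `r2_val`), `summary` (tibble:
#'   mean/SD per family), `importance` (tibble or `NULL`), `response`,
#'   `n_iterations`, `seed`. Use [tidy()], [glance()] and
#'   [ggplot2::autoplot()].
#' @export
evaluate_models <- function(data, response, features = feature_names(),
                            families = c("least_squares", "neural_net",
                                         "bootstrap_forest"),
                            n_iterations = 1000, train_fraction = 0.9,
                            seed = 1L, standardize = TRUE,
                            paired_splits = TRUE,
                            compute_importance = FALSE,
                            importance_samples = 20,
                            importance_threshold = 0.1,
                            hyperparameters = list()) {
  cols <- c(response, features)
  stopifnot(all(cols %in% names(data)))
  df <- tibble::as_tibble(data)[, cols]
  complete <- stats::complete.cases(df)
  if (!all(complete)) {
    message("Dropping ", sum(!complete), " row(s) with missing values.")
    df <- df[complete, ]
  }
  if (standardize) df <- standardize_features(df, cols = cols)
  n <- nrow(df)
  # one sub-seed per family x iteration, all derived from the master seed
  seed_pool <- withr::with_seed(seed, {
    matrix(sample.int(.Machine$integer.max,
                      length(families) * (n_iterations + 1L)),
           nrow = length(families))
  })
  outcomes <- list()
  importance <- list()
  for (fi in seq_along(families)) {
    family <- families[fi]
    split_seed <- if (paired_splits) seed else seed_pool[fi, n_iterations + 1L]
    splits <- repeated_holdout(n, train_fraction, n_iterations, split_seed)
    fi_acc <- NULL
    res <- purrr::map(seq_len(n_iterations), function(it) {
      sp <- splits[[it]]
      fit <- fit_family(family, df[sp$train, ], response, features,
                        seed = seed_pool[fi, it],
                        hyperparameters = hyperparameters)
      out <- tibble::tibble(
        family = family,
        iteration = it,
        r2_train = r_squared(df[[response]][sp$train],
                             predict(fit, df[sp$train, ])),
        r2_val = r_squared(df[[response]][sp$validation],
                           predict(fit, df[sp$validation, ]))
      )
      if (compute_importance) {
        imp <- total_effect_importance(fit, df, features,
                                       n_samples = importance_samples,
                                       seed = seed_pool[fi, it],
                                       threshold = importance_threshold,
                                       normalize = "variance")
        out$fi <- list(imp$fi_raw)
      }
      out
    })
    res <- dplyr::bind_rows(res)
    if (compute_importance) {
      # mean raw total effects over iterations, then share-normalized
      fi_mean <- colMeans(do.call(rbind, res$fi))
      fi_norm <- if (sum(fi_mean) > 0) fi_mean / sum(fi_mean) else fi_mean
      importance[[family]] <- tibble::tibble(
        family = family,
        feature = features,
        fi = unname(fi_norm),
        fi_raw = unname(fi_mean),
        important = unname(fi_norm) > importance_threshold
      )
      res$fi <- NULL
    }
    outcomes[[family]] <- res
  }
  outcomes <- dplyr::bind_rows(outcomes)
  summary <- outcomes |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(
      response = response,
      mean_r2_train = mean(.data$r2_train),
      sd_r2_train = stats::sd(.data$r2_train),
      mean_r2_val = mean(.data$r2_val),
      sd_r2_val = stats::sd(.data$r2_val),
      n_iterations = dplyr::n(),
      .groups = "drop"
    )
  structure(
    list(outcomes = outcomes,
         summary = summary,
         importance = if (compute_importance) dplyr::bind_rows(importance) else NULL,
         response = response,
         features = features,
         n_iterations = n_iterations,
         train_fraction = train_fraction,
         seed = seed),
    class = "sg_cv"
  )
}

#' @export
print.sg_cv <- function(x, ...) {
  cat("<sg_cv> response:", x$response, "|", x$n_iterations,
      "holdout iterations\n")
  print(x$summary)
  invisible(x)
}

#' Simple linear regression of one feature under repeated holdout
#'
#' Univariate ordinary least squares of the response on a single feature,
#' refit over the same repeated 90/10 holdout scheme, reporting mean/SD of
#' training and validation R-squared plus the mean slope and its sign. Used as
#' a follow-up on features flagged important, for comparability with classical
#' single-predictor reading studies (predictor intercorrelations are not
#' removed).
#'
#' @inheritParams evaluate_models
#' @param feature The single feature column name.
#' @return A one-row tibble: `feature`, `response`, mean/SD train and
#'   validation R-squared, `mean_slope`, `slope_sign`, `n_iterations`.
#' @export
simple_regression <- function(data, feature, response, n_iterations = 1000,
                              train_fraction = 0.9, seed = 1L,
                              standardize = TRUE) {
  cols <- c(response, feature)
  df <- tibble::as_tibble(data)[, cols]
  df <- df[stats::complete.cases(df), ]
  if (standardize) df <- standardize_features(df, cols = cols)
  n <- nrow(df)
  splits <- repeated_holdout(n, train_fraction, n_iterations, seed)
  f <- stats::reformulate(feature, response = response)
  res <- purrr::map(splits, function(sp) {
    m <- stats::lm(f, data = as.data.frame(df[sp$train, ]))
    tibble::tibble(
      r2_train = r_squared(df[[response]][sp$train],
                           unname(stats::predict(m))),
      r2_val = r_squared(df[[response]][sp$validation],
                         unname(stats::predict(m, df[sp$validation, ]))),
      slope = stats::coef(m)[[feature]]
    )
  }) |> dplyr::bind_rows()
  tibble::tibble(
    feature = feature,
    response = response,
    mean_r2_train = mean(res$r2_train),
    sd_r2_train = stats::sd(res$r2_train),
    mean_r2_val = mean(res$r2_val),
    sd_r2_val = stats::sd(res$r2_val),
    mean_slope = mean(res$slope),
    slope_sign = sign(mean(res$slope)),
    n_iterations = n_iterations
  )
}
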