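#' Total-effect feature importance by resampled-input sensitivity analysis
#'
#' A variance-based total-effect index per feature: the share of the model's
#' output variance attributable to a feature alone and in combination with
#' other features. Estimated by Monte-Carlo perturbation — the target
#' feature's column is replaced by values resampled (permuted) from the
#' observed rows, all other columns held at their observed values, and the
#' Jansen-type estimator
#' \deqn{FI_j = E[(f(x) - f(x^{(j)}))^2] / (2\,\mathrm{Var}\, f(x))}
#' is averaged over `n_samples` resamplings and clipped to \[0, 1\]. A feature
#' the model ignores scores 0; a feature that alone drives the output scores
#' 1. Values above `threshold` (default .1) are flagged important.
#'
#' With `normalize = "sum"` (the default) the raw variance-scaled indices are
#' additionally normalized to sum to 1 across features, so each value reads as
#' the feature's share of the model's total sensitivity — the scale on which
#' reported feature-importance vectors of this kind sum to about one. With
#' `normalize = "variance"` the raw indices are returned.
#'
#' @param fit An `sg_fit` predictor.
#' @param data Data frame of observed (standardized) feature rows on which
#'   sensitivity is evaluated.
#' @param features Feature column names; defaults to the fit's features.
#' @param n_samples Number of resampling replicates per feature, default 20.
#' @param seed Integer seed for the resampling.
#' @param threshold Importance cut-off, default 0.1.
#' @param normalize `"sum"` (share of total sensitivity, default) or
#'   `"variance"` (raw total-effect index).
#' @return A tibble with `feature`, `fi` (in \[0, 1\]), `fi_raw` (the
#'   variance-scaled index before any share normalization) and `important`.
#' @export
total_effect_importance <- function(fit, data, features = fit$features,
                                    n_samples = 20, seed = 1L,
                                    threshold = 0.1,
                                    normalize = c("sum", "variance")) {
  normalize <- match.arg(normalize)
  df <- as.data.frame(data)[, features, drop = FALSE]
  n <- nrow(df)
  stopifnot(n >= 3)
  f0 <- predict(fit, df)
  var_f <- stats::var(f0)
  if (!is.finite(var_f) || var_f <= 0) {
    stop("Model output has zero variance over `data`: FI undefined.",
         call. = FALSE)
  }
  perms <- withr::with_seed(seed, {
    replicate(n_samples, sample.int(n), simplify = FALSE)
  })
  fi <- vapply(features, function(j) {
    d2 <- vapply(perms, function(p) {
      dj <- df
      dj[[j]] <- dj[[j]][p]
      mean((f0 - predict(fit, dj))^2)
    }, numeric(1))
    mean(d2) / (2 * var_f)
  }, numeric(1))
  fi_raw <- pmin(pmax(unname(fi), 0), 1)
  fi <- if (normalize == "sum" && sum(fi_raw) > 0) fi_raw / sum(fi_raw) else fi_raw
  tibble::tibble(feature = features, fi = fi, fi_raw = fi_raw,
                 important = fi > threshold)
}
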