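test_that("the default feature correlation target is a valid copula target", {
  R <- qna_feature_correlations()
  expect_identical(dim(R), c(7L, 7L))
  expect_identical(rownames(R), feature_names())
  expect_equal(R, t(R))
  expect_equal(unname(diag(R)), rep(1, 7))
  expect_true(all(eigen(R, only.values = TRUE)$values > 0))
})

test_that("synth_config validates its arguments", {
  expect_s3_class(synth_config(), "synth_config")
  bad <- qna_feature_correlations()
  bad[1, 2] <- 0.5  # breaks symmetry
  expect_error(synth_config(feature_correlations = bad))
  expect_error(synth_config(signal_fraction = 0))
  expect_error(synth_config(signal_fraction = 1))
  expect_error(synth_config(noise_sd = -1))
  expect_error(synth_config(n_participants = 0))
})

test_that("generate_word_forms is reproducible and lexically plausible", {
  cfg <- synth_config(n_word_types = 50, n_lexicon_types = 400)
  wf1 <- generate_word_forms(cfg, seed = 2)
  wf2 <- generate_word_forms(cfg, seed = 2)
  expect_identical(wf1$words, wf2$words)
  expect_length(wf1$words, 50)
  expect_identical(wf1$lexicon$n_types, 400L)
  expect_true(all(wf1$words %in% names(wf1$lexicon$entries)))
  expect_false(anyDuplicated(names(wf1$lexicon$entries)) > 0)
  # longer words are rarer: negative length/log-count correlation
  lens <- nchar(names(wf1$lexicon$entries))
  lf <- log10(wf1$lexicon$entries)
  expect_lt(cor(lens, lf), -0.3)
})

test_that("generate_feature_matrix approaches the target correlations", {
  cfg <- synth_config()
  f <- generate_feature_matrix(cfg, seed = 1, n = 4000)
  expect_identical(nrow(f), 4000L)
  expect_true(all(f$hfn <= f$on))
  expect_true(all(f$wl >= 1))
  expect_true(all(f$logf >= 0))
  got <- feature_correlations(f)
  target <- qna_feature_correlations()
  # monotone marginals attenuate Pearson correlations (discretized margins
  # lose up to ~0.2 of the latent correlation); every strong target entry
  # must be reproduced in sign and rough size
  strong <- abs(target) > 0.3 & target != 1
  expect_true(all(sign(got[strong]) == sign(target[strong])))
  expect_lt(max(abs(got[strong] - target[strong])), 0.25)
  expect_true(all(abs(got[strong]) > 0.2))
})

test_that("generate_measures hits the configured signal fraction", {
  cfg <- synth_config(n_word_types = 3000, signal_fraction = 0.6)
  f <- generate_feature_matrix(cfg, seed = 4)
  m <- generate_measures(f, cfg, seed = 5)
  expect_length(m$response, 3000)
  # empirical signal share = var(latent) / var(response)
  share <- stats::var(m$truth$latent) / stats::var(m$response)
  expect_equal(share, 0.6, tolerance = 0.1)
  expect_identical(m$truth$important, c("wl", "logf", "on", "sonscore"))
  # explicit noise_sd overrides the fraction
  cfg2 <- synth_config(n_word_types = 200, noise_sd = 0.01)
  f2 <- generate_feature_matrix(cfg2, seed = 4)
  m2 <- generate_measures(f2, cfg2, seed = 5)
  expect_gt(cor(m2$truth$latent, m2$response), 0.999)
})

test_that("interactions enter the latent response and the important set", {
  cfg <- synth_config(n_word_types = 500,
                      interaction = list(features = c("hfn", "cvq"),
                                         weight = 0.7))
  f <- generate_feature_matrix(cfg, seed = 6)
  m <- generate_measures(f, cfg, seed = 7)
  expect_identical(m$truth$important,
                   c("wl", "logf", "on", "hfn", "cvq", "sonscore"))
  # removing the interaction changes the latent values
  cfg0 <- synth_config(n_word_types = 500)
  m0 <- generate_measures(f, cfg0, seed = 7)
  expect_false(isTRUE(all.equal(m$truth$latent, m0$truth$latent)))
})

test_that("the logistic link yields probabilities in (0, 1)", {
  cfg <- synth_config(n_word_types = 300)
  f <- generate_feature_matrix(cfg, seed = 8)
  m <- generate_measures(f, cfg, seed = 9, link = "logistic")
  expect_true(all(m$response > 0 & m$response < 1))
  # intercept 1.1 puts the bulk above .5 (fixation is the common outcome)
  expect_gt(mean(m$response > 0.5), 0.6)
})

test_that("generate_fixation_report's ground truth is exact", {
  cfg <- synth_config(n_word_types = 60, n_participants = 8)
  study <- generate_study(cfg, seed = 11)
  rep <- study$report
  got <- token_measures(rep$events, item_words = study$item_words,
                        participants = unique(rep$tokens$participant))
  cols <- c("participant", "item", "aoi_index", "word",
            "ffd", "gaze", "rereading", "trt", "fixated")
  expect_equal(as.data.frame(got[, cols]),
               as.data.frame(rep$tokens[, cols]))
})

test_that("the simulated skipping rate matches its calibration target", {
  rates <- vapply(1:6, function(s) {
    study <- generate_study(synth_config(), seed = s)
    tok <- token_measures(study$report$events,
                          item_words = study$item_words,
                          participants = sprintf("p%02d", 1:15))
    skipping_rate(tok)$mean
  }, numeric(1))
  expect_equal(mean(rates), 0.13, tolerance = 0.025)
  expect_true(all(rates > 0.06 & rates < 0.22))
})

test_that("generate_study returns a coherent bundle in both modes", {
  cfg <- synth_config(n_word_types = 45, n_lexicon_types = 300,
                      n_participants = 4)
  st <- generate_study(cfg, seed = 13)
  expect_identical(nrow(st$features), 45L)
  expect_identical(sort(names(st$measures)),
                   sort(c("word", "mean_ffd", "mean_trt", "fix_prob")))
  expect_identical(st$item_words$word, st$features$word)
  expect_identical(sort(unique(st$item_words$item)), c("i1", "i2", "i3"))
  expect_null(st$lexicon)
  expect_true(all(st$measures$fix_prob > 0 & st$measures$fix_prob < 1))
  expect_true(all(st$measures$mean_ffd > 0))
  # reproducible
  st2 <- generate_study(cfg, seed = 13)
  expect_equal(st$measures, st2$measures)
  expect_equal(st$report$events, st2$report$events)

  lx <- generate_study(cfg, seed = 13, mode = "lexical")
  expect_s3_class(lx$lexicon, "reference_lexicon")
  expect_identical(nrow(lx$features), 45L)
  expect_true(all(lx$features$word %in% names(lx$lexicon$entries)))
})

test_that("lexical-mode features really come from the feature code path", {
  cfg <- synth_config(n_word_types = 30, n_lexicon_types = 200,
                      n_participants = 2)
  st <- generate_study(cfg, seed = 3, mode = "lexical")
  recomputed <- word_features(st$features$word, st$lexicon)
  expect_equal(st$features, recomputed)
})
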