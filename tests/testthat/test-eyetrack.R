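test_that("token_measures decomposes a fixation sequence by hand", {
  # AOI visit sequence 1, 2, 2, 1 with durations 200, 150, 100, 180
  tok <- token_measures(trace_events())
  w1 <- tok[tok$aoi_index == 1, ]
  expect_equal(w1$ffd, 200)        # first fixation on AOI 1
  expect_equal(w1$gaze, 200)       # first pass ended by the visit to AOI 2
  expect_equal(w1$rereading, 180)  # the return visit
  expect_equal(w1$trt, 380)
  w2 <- tok[tok$aoi_index == 2, ]
  expect_equal(w2$ffd, 150)        # first of the two consecutive fixations
  expect_equal(w2$gaze, 250)       # both belong to the maximal first-pass run
  expect_equal(w2$rereading, 0)    # never revisited after first pass
  expect_equal(w2$trt, 250)
  expect_true(all(tok$fixated))
})

test_that("skipped tokens are NA, never zero", {
  iw <- tibble::tibble(item = "i1", aoi_index = 1:3,
                       word = c("weary", "with", "toil"))
  tok <- token_measures(trace_events(), item_words = iw)
  skipped <- tok[tok$aoi_index == 3, ]
  expect_false(skipped$fixated)
  expect_true(all(is.na(c(skipped$ffd, skipped$gaze,
                          skipped$rereading, skipped$trt))))
  # a participant with no events at all is all-skips
  tok2 <- token_measures(trace_events(), item_words = iw,
                         participants = c("p1", "p2"))
  expect_identical(nrow(tok2), 6L)
  expect_true(all(!tok2$fixated[tok2$participant == "p2"]))
})

test_that("trt always equals gaze + rereading for fixated tokens", {
  study <- generate_study(synth_config(n_word_types = 40, n_participants = 5),
                          seed = 42)
  tok <- token_measures(study$report$events, item_words = study$item_words)
  fx <- tok[tok$fixated, ]
  expect_equal(fx$trt, fx$gaze + fx$rereading)
  expect_true(all(fx$ffd <= fx$gaze))
  expect_true(all(fx$rereading >= 0))
})

test_that("event validation rejects malformed reports", {
  ev <- trace_events()
  bad_dur <- ev; bad_dur$duration[1] <- 0
  expect_error(token_measures(bad_dur), "positive")
  bad_aoi <- ev; bad_aoi$aoi_index[1] <- 0L
  expect_error(token_measures(bad_aoi), ">= 1")
  bad_ord <- ev; bad_ord$order[2] <- 1L
  expect_error(token_measures(bad_ord), "Duplicate fixation order")
})

test_that("fixation report round-trips through write/parse", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fixation_report(trace_events(), path)
  back <- parse_fixation_report(path)
  expect_equal(as.data.frame(back), as.data.frame(trace_events()))
})

test_that("parse_fixation_report maps custom column names and checks them", {
  ev <- trace_events()
  names(ev) <- c("subj", "trial", "ia", "token", "idx", "ms")
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(ev, path)
  cmap <- c(participant = "subj", item = "trial", aoi_index = "ia",
            word = "token", order = "idx", duration = "ms")
  back <- parse_fixation_report(path, col_map = cmap)
  expect_identical(names(back)[1:3], c("participant", "item", "aoi_index"))
  expect_error(parse_fixation_report(path), "missing required column")
})

test_that("fixation_probability is the share of fixating participants", {
  iw <- tibble::tibble(item = "i1", aoi_index = 1:2,
                       word = c("weary", "with"))
  ev <- dplyr::bind_rows(
    trace_events("p1"),
    trace_events("p2")[1, ]  # p2 fixates only AOI 1
  )
  tok <- token_measures(ev, item_words = iw)
  fp <- fixation_probability(tok)
  expect_equal(fp$fix_prob[fp$aoi_index == 1], 1)
  expect_equal(fp$fix_prob[fp$aoi_index == 2], 0.5)
  expect_equal(fp$n_participants, c(2L, 2L))
})

test_that("aggregate_to_type averages participants first, then tokens", {
  # word "the" occurs twice in the item; p1 and p2 fixate token 1 with
  # different durations, only p1 fixates token 3
  ev <- tibble::tibble(
    participant = c("p1", "p1", "p2"),
    item = "i1",
    aoi_index = c(1L, 3L, 1L),
    word = "the",
    order = c(1L, 2L, 1L),
    duration = c(100, 300, 200)
  )
  iw <- tibble::tibble(item = "i1", aoi_index = c(1L, 3L), word = "the")
  tok <- token_measures(ev, item_words = iw)
  ty <- aggregate_to_type(tok)
  # token 1 mean ffd = (100+200)/2 = 150; token 3 mean = 300 (p2 skip excluded)
  # type mean = unweighted mean over the two tokens = 225
  expect_equal(ty$mean_ffd, 225)
  expect_equal(ty$fix_prob, mean(c(1, 0.5)))
  expect_identical(ty$n_tokens, 2L)
  expect_false(ty$low_n)  # three fixated cells in total
})

test_that("all-skipped words aggregate to NA durations and low_n flags", {
  iw <- tibble::tibble(item = "i1", aoi_index = 1:3,
                       word = c("weary", "with", "toil"))
  tok <- token_measures(trace_events(), item_words = iw)
  ty <- aggregate_to_type(tok)
  toil <- ty[ty$word == "toil", ]
  expect_true(is.na(toil$mean_ffd) && is.na(toil$mean_trt))
  expect_equal(toil$fix_prob, 0)
  expect_true(toil$low_n)
})

test_that("skipping_rate reports per-participant and grand statistics", {
  iw <- tibble::tibble(item = "i1", aoi_index = 1:4,
                       word = c("w1", "w2", "w3", "w4"))
  ev <- dplyr::bind_rows(
    trace_events("p1"),                # fixates 2 of 4 tokens
    trace_events("p2")[1, ]            # fixates 1 of 4 tokens
  )
  tok <- token_measures(ev, item_words = iw)
  sr <- skipping_rate(tok)
  expect_equal(sr$by_participant$skip_rate, c(0.5, 0.75))
  expect_equal(sr$mean, 0.625)
  expect_equal(sr$sd, stats::sd(c(0.5, 0.75)))
})

test_that("measure_correlations returns the 5x5 matrix", {
  study <- generate_study(synth_config(n_word_types = 40, n_participants = 6),
                          seed = 9)
  tok <- token_measures(study$report$events, item_words = study$item_words)
  r <- measure_correlations(aggregate_to_type(tok))
  expect_identical(dim(r), c(5L, 5L))
  expect_equal(unname(diag(r)), rep(1, 5))
  # gaze and total reading time are strongly positively related
  expect_gt(r["mean_gaze", "mean_trt"], 0.5)
})
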