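test_that("episode expansion matches the hand-derived toy table", {
  fx <- make_fixture("toy-3-subjects")
  ep <- expand_to_episodes(fx$subjects, fx$graph)
  expect_equal(as.data.frame(ep), fx$expected$episodes)
  # competing rows of a subject-state share the at-risk interval and carry
  # at most one event
  for (id in unique(ep$id)) {
    sub <- ep[ep$id == id, ]
    for (s in unique(sub$from)) {
      blk <- sub[sub$from == s, ]
      expect_equal(length(unique(blk$tstart)), 1L)
      expect_equal(length(unique(blk$tstop)), 1L)
      expect_lte(sum(blk$status), 1L)
    }
  }
  expect_true(all(ep$tstart < ep$tstop))
})

test_that("invalid subject histories are rejected by name", {
  fx <- make_fixture("toy-3-subjects")
  bad <- fx$subjects
  # ill -> healthy is not a path: claim dead entered before ill
  bad$dead_time[1] <- 2
  expect_error(expand_to_episodes(bad, fx$graph), "subject 1")

  bad2 <- fx$subjects
  bad2$dead_time[1] <- 3  # tied with ill entry: zero-length stay
  expect_error(expand_to_episodes(bad2, fx$graph), "tied entry times")

  bad3 <- fx$subjects
  bad3$ill_time[1] <- 0
  expect_error(expand_to_episodes(bad3, fx$graph), "non-positive entry")
})

test_that("transition counts track events and distinct subjects at risk", {
  fx <- make_fixture("toy-3-subjects")
  ep <- expand_to_episodes(fx$subjects, fx$graph)
  ct <- transition_counts(ep)
  expect_equal(ct$nevent[match(c("healthy->ill", "healthy->dead", "ill->dead"),
                               ct$trans)], c(1L, 1L, 1L))
  expect_equal(ct$nrisk[match(c("healthy->ill", "healthy->dead", "ill->dead"),
                              ct$trans)], c(3L, 3L, 1L))
  # invariance under row shuffling
  set.seed(1)
  shuffled <- ep[sample(nrow(ep)), ]
  ct2 <- transition_counts(shuffled)
  expect_equal(ct2[order(ct2$trans), ], ct[order(ct$trans), ],
               ignore_attr = TRUE)
  # empty table
  empty <- ep[0, ]
  expect_equal(nrow(transition_counts(empty)), 0L)
})

test_that("the five-events-per-coefficient rule flags transitions", {
  counts <- data.frame(trans = c("a->b", "a->c", "b->c"),
                       nevent = c(4L, 10L, 9L), nrisk = c(20L, 20L, 10L))
  subjects <- data.frame(id = 1:6, g3 = factor(rep(c("x", "y", "z"), 2)),
                         z1 = rnorm(6), z2 = rnorm(6))
  warns <- capture_warnings(
    res <- epv_check(counts,
                     list("a->b" = "z1", "a->c" = c("z1", "z2"),
                          "b->c" = "g3"),
                     subjects))
  expect_length(warns, 2L)
  expect_match(warns[1L], "a->b")
  expect_match(warns[2L], "b->c")
  expect_equal(res$warned, c(TRUE, FALSE, TRUE))   # 4<5, 10>=10, 9<10
  expect_equal(res$ncoef, c(1L, 2L, 2L))
})

test_that("length of stay summaries follow the 1.5 IQR rule", {
  g <- two_state_graph()
  mk <- function(stays) data.frame(
    id = seq_along(stays), start_state = "alive",
    dead_time = stays, dead_status = 1L)
  los <- length_of_stay(mk(c(2, 3, 14)), g)
  expect_equal(los$median[los$state == "alive"], 3)

  # quartiles (2, 6): the 97-day stay lies beyond 6 + 1.5 * 4 = 12
  stays <- c(2, 2, 2, 4, 6, 6, 97)
  los2 <- length_of_stay(mk(stays), g)
  out <- attr(los2, "outliers")
  expect_equal(out$stay, 97)
  expect_equal(los2$n_outliers, 1L)
  expect_equal(los2$whisker_high, 6)

  los3 <- length_of_stay(mk(5), g)
  expect_equal(los3$median, 5)
  expect_equal(los3$n_outliers, 0L)

  # censored stays only enter when requested
  cens1 <- data.frame(id = 1:2, start_state = "alive",
                      dead_time = c(3, 9), dead_status = c(1L, 0L))
  expect_equal(length_of_stay(cens1, g)$n, 1L)
  expect_equal(length_of_stay(cens1, g, uncensored_only = FALSE)$n, 2L)
})

test_that("covariate filters validate names and preserve structure", {
  fx <- make_fixture("toy-3-subjects")
  sub <- fx$subjects
  sub$wave <- c(1, 5, 5)
  expect_equal(filter_subjects(sub, wave == 5)$id, 2:3)
  expect_equal(filter_subjects(sub, TRUE), sub)
  expect_equal(nrow(filter_subjects(sub, FALSE)), 0L)
  expect_error(filter_subjects(sub, cohort == 2), "unknown covariate")
  expect_error(fit_msm(expand_to_episodes(filter_subjects(sub, FALSE),
                                          fx$graph)[0, ], fx$graph),
               "empty")
})

test_that("simulate -> write -> read -> expand round-trips event counts", {
  fx <- make_fixture("illness-death-500")
  path <- withr::local_tempfile(fileext = ".csv")
  write_subjects(fx$subjects, path)
  back <- read_subjects(path)
  ep <- expand_to_episodes(back, fx$graph)
  ct <- transition_counts(ep)
  tally <- attr(fx$subjects, "transition_tally")
  expect_equal(setNames(ct$nevent, ct$trans)[names(tally)],
               tally[names(tally)], ignore_attr = TRUE)
  # total events = total observed transitions
  expect_equal(sum(ep$status), sum(tally))
})
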