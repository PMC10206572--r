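# Brute-force residual oracles evaluated by naive loops at the fitted
# coefficients, independent of the package's vectorized computations.
naive_residuals <- function(ep, beta) {
  w <- exp(beta * ep$x)
  et <- sort(unique(ep$tstop[ep$status == 1L]))
  S0 <- vapply(et, function(t) sum(w[ep$tstart < t & t <= ep$tstop]), 0)
  zbar <- vapply(seq_along(et), function(j) {
    r <- ep$tstart < et[j] & et[j] <= ep$tstop
    sum(w[r] * ep$x[r]) / S0[j]
  }, 0)
  d <- vapply(et, function(t) sum(ep$status == 1L & ep$tstop == t), 0)
  mart <- vapply(seq_len(nrow(ep)), function(i) {
    inj <- et > ep$tstart[i] & et <= ep$tstop[i]
    ep$status[i] - w[i] * sum(d[inj] / S0[inj])
  }, 0)
  scho <- ep$x[ep$status == 1L] - zbar[match(ep$tstop[ep$status == 1L], et)]
  list(martingale = mart, schoenfeld = scho)
}

test_that("martingale residuals match the brute-force oracle and sum to zero", {
  ep <- influence_table()
  f <- fit_transition_cox(ep, "a->b", "x")
  mr <- martingale_residuals(f, ep)
  oracle <- naive_residuals(ep, f$coef[["x"]])
  expect_equal(mr$residual, oracle$martingale, tolerance = 1e-10)
  expect_lt(abs(sum(mr$residual)), 1e-6)
  expect_true(all(mr$residual <= 1))
  # a censored episode that accumulates no hazard has residual zero
  ep2 <- rbind(ep, data.frame(id = 31L, from = "a", to = "b",
                              trans = "a->b", tstart = 0, tstop = 0.5,
                              status = 0L, x = 1))
  class(ep2) <- class(ep)
  f2 <- fit_transition_cox(ep2, "a->b", "x")
  mr2 <- martingale_residuals(f2, ep2)
  expect_equal(mr2$residual[mr2$id == 31L], 0)
})

test_that("martingale residuals on a null fit use the Nelson-Aalen mass", {
  fx <- make_fixture("toy-3-subjects")
  ep <- expand_to_episodes(fx$subjects, fx$graph)
  f0 <- fit_transition_cox(ep, "healthy->ill")
  mr <- martingale_residuals(f0, ep)
  # healthy->ill has its single jump of 1/3 at t=3; all three episodes span it
  expect_equal(mr$residual, c(1 - 1 / 3, -1 / 3, -1 / 3))
})

test_that("schoenfeld residuals match the oracle and sum to zero", {
  ep <- influence_table()
  f <- fit_transition_cox(ep, "a->b", "x")
  sr <- schoenfeld_residuals(f, ep, scaled = FALSE)
  oracle <- naive_residuals(ep, f$coef[["x"]])
  expect_equal(sr$x, oracle$schoenfeld, tolerance = 1e-10)
  expect_lt(abs(sum(sr$x)), 1e-6)
  # scaling by d * V is a fixed linear map
  sc <- schoenfeld_residuals(f, ep, scaled = TRUE)
  expect_equal(sc$x, f$nevent * drop(f$vcov) * sr$x)
  expect_equal(sc$time, sort(ep$tstop[ep$status == 1L]))
})

test_that("residuals are invariant to covariate location shifts", {
  ep <- influence_table()
  f <- fit_transition_cox(ep, "a->b", "x")
  shifted <- ep
  shifted$x <- shifted$x + 100
  fs <- fit_transition_cox(shifted, "a->b", "x")
  expect_equal(fs$coef, f$coef, tolerance = 1e-8)
  expect_equal(martingale_residuals(fs, shifted)$residual,
               martingale_residuals(f, ep)$residual, tolerance = 1e-8)
  expect_equal(schoenfeld_residuals(fs, shifted)$x,
               schoenfeld_residuals(f, ep)$x, tolerance = 1e-8)
  expect_equal(unclass(dfbetas_residuals(fs, shifted)),
               unclass(dfbetas_residuals(f, ep)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("approximate dfbetas track the exact leave-one-out oracle", {
  ep <- influence_table()
  f <- fit_transition_cox(ep, "a->b", "x")
  da <- dfbetas_residuals(f, ep, "approximate")
  de <- dfbetas_residuals(f, ep, "exact")
  expect_true(all(abs(da - de) <= pmax(0.2 * abs(de), 0.02)))
  # the most influential episode is the one whose deletion moves the fit most
  expect_equal(which.max(abs(da)), which.max(abs(de)))
  # duplicated balanced data dilute every influence
  dup <- rbind(ep, transform(ep, id = id + 100L))
  class(dup) <- class(ep)
  fd <- fit_transition_cox(dup, "a->b", "x")
  dd <- dfbetas_residuals(fd, dup, "approximate")
  expect_lt(max(abs(dd)), max(abs(da)))
  expect_error(dfbetas_residuals(f, ep, "exact", exact_cap = 10L), "cap")
})

test_that("the scaled-schoenfeld trend test detects a reversing effect", {
  # groups with crossing hazards: decreasing (weibull shape 0.5) for x=1,
  # increasing (shape 2) for x=0 -- a gross proportional-hazards violation
  reject <- 0L
  for (s in 1:20) {
    set.seed(4000 + s)
    n <- 300
    x <- rep(0:1, n / 2)
    tt <- ifelse(x == 1, rweibull(n, 0.5, 8), rweibull(n, 2, 8))
    status <- as.integer(tt < 15)
    ep <- data.frame(id = 1:n, from = "a", to = "b", trans = "a->b",
                     tstart = 0, tstop = pmin(tt, 15), status = status,
                     x = x)
    class(ep) <- c("msm_episodes", "data.frame")
    f <- fit_transition_cox(ep, "a->b", "x")
    trend <- attr(schoenfeld_residuals(f, ep), "trend")
    reject <- reject + (trend$p_value < 0.05)
  }
  expect_gte(reject, 15L)
})
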