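test_that("profile hazards scale the baseline by exp(beta' z)", {
  fx <- make_fixture("illness-death-500")
  ep <- expand_to_episodes(fx$subjects, fx$graph)
  fit <- fit_msm(ep, fx$graph, list("healthy->ill" = "sev"))
  f <- fit$fits[["healthy->ill"]]
  hz1 <- profile_hazards(fit, list(start_state = "healthy", sev = 1))
  hz0 <- profile_hazards(fit, list(start_state = "healthy", sev = 0))
  expect_equal(hz1[["healthy->ill"]]$dhaz,
               f$baseline$hazard * exp(f$coef[["sev"]]))
  expect_equal(hz0[["healthy->ill"]]$dhaz, f$baseline$hazard)
  # transitions fitted as null models ignore the profile
  expect_equal(hz1[["ill->dead"]]$dhaz, hz0[["ill->dead"]]$dhaz)
  expect_error(profile_hazards(fit, list(start_state = "healthy")),
               "missing covariate.*sev")

  # a null fit reproduces Nelson-Aalen regardless of the profile
  fit0 <- fit_msm(ep, fx$graph)
  hz <- profile_hazards(fit0, list(start_state = "healthy", sev = 99))
  na <- nelson_aalen(ep, "healthy->ill")
  expect_equal(hz[["healthy->ill"]]$dhaz, na$dhaz)
})

test_that("the product integral reduces to Kaplan-Meier in two states", {
  skip_if_not_installed("survival")
  sub <- simulate_paths(two_state_spec(weibull = c(1.3, 12), cens = 25),
                        300, seed = 11)
  g <- two_state_graph()
  ep <- expand_to_episodes(sub, g)
  fit <- fit_msm(ep, g)
  pt <- aalen_johansen(profile_hazards(fit, list(start_state = "alive")),
                       g$states)
  km <- survival::survfit(survival::Surv(tstop, status) ~ 1, data = ep)
  evt <- km$time[km$n.event > 0]
  p11 <- pt$P[1, 1, match(evt, pt$times)]
  expect_lt(max(abs(p11 - km$surv[km$n.event > 0])), 1e-12)
})

test_that("transition probability matrices are row-stochastic step functions", {
  fx <- make_fixture("illness-death-500")
  ep <- expand_to_episodes(fx$subjects, fx$graph)
  fit <- fit_msm(ep, fx$graph, list("healthy->ill" = "sev"))
  hz <- profile_hazards(fit, list(start_state = "healthy", sev = 1))
  pt <- aalen_johansen(hz, fx$graph$states)
  expect_lt(max(abs(apply(pt$P, 3L, rowSums) - 1)), 1e-9)
  expect_true(all(pt$P >= 0 & pt$P <= 1 + 1e-12))
  # P(t0, t0) is the identity, absorbing rows stay unit vectors
  expect_equal(pt$P[, , 1L], diag(3), ignore_attr = TRUE)
  expect_equal(pt$P[3, , dim(pt$P)[3L]], c(0, 0, 1), ignore_attr = TRUE)
  # no events in (t0, t]: identity
  empty <- aalen_johansen(list("healthy->ill" = data.frame(
    time = numeric(0), dhaz = numeric(0))), fx$graph$states)
  expect_equal(dim(empty$P)[3L], 1L)
  expect_equal(empty$P[, , 1L], diag(3), ignore_attr = TRUE)
})

test_that("Chapman-Kolmogorov holds exactly on the jump grid", {
  fx <- make_fixture("illness-death-500")
  ep <- expand_to_episodes(fx$subjects, fx$graph)
  fit <- fit_msm(ep, fx$graph, list("healthy->ill" = "sev"))
  hz <- profile_hazards(fit, list(start_state = "healthy", sev = 0))
  pt <- aalen_johansen(hz, fx$graph$states)
  t1 <- pt$times[round(length(pt$times) / 2)]
  t2 <- max(pt$times)
  P02 <- probtrans_at(pt, t2)[, , 1L]
  P01 <- probtrans_at(pt, t1)[, , 1L]
  pt12 <- aalen_johansen(hz, fx$graph$states, t0 = t1)
  P12 <- probtrans_at(pt12, t2)[, , 1L]
  expect_lt(max(abs(P02 - P01 %*% P12)), 1e-10)
})

test_that("over-unit jump mass is clamped, renormalized and flagged", {
  hz <- list("a->b" = data.frame(time = 5, dhaz = 0.8),
             "a->c" = data.frame(time = 5, dhaz = 0.6))
  expect_warning(pt <- aalen_johansen(hz, c("a", "b", "c")),
                 "jump mass > 1 leaving state a at t=5")
  P <- pt$P[, , 2L]
  expect_equal(sum(P[1L, ]), 1)
  expect_equal(P[1L, 1L], 0)
  expect_equal(P[1L, 2L] / P[1L, 3L], 0.8 / 0.6)
})

test_that("occupancy summarises the start-state row at the horizon", {
  fx <- make_fixture("illness-death-500")
  ep <- expand_to_episodes(fx$subjects, fx$graph)
  fit <- fit_msm(ep, fx$graph, list("healthy->ill" = "sev"))
  occ <- occupancy(fit, list(start_state = "healthy", sev = 1), horizon = 20)
  expect_equal(sum(occ$probs), 1, tolerance = 1e-9)
  expect_equal(names(occ$probs), fx$graph$states)
  expect_false(occ$extrapolated)
  # per-time curves are row-stochastic too
  sums <- tapply(occ$curve$prob, occ$curve$time, sum)
  expect_lt(max(abs(sums - 1)), 1e-9)
  # starting in an absorbing state keeps probability 1 there forever
  occ_d <- occupancy(fit, list(start_state = "dead", sev = 1), horizon = 20)
  expect_equal(unname(occ_d$probs["dead"]), 1)
  expect_equal(occ_d$most_likely, "dead")
  # a horizon beyond the last event time is flagged and held constant
  occ_far <- occupancy(fit, list(start_state = "healthy", sev = 1),
                       horizon = 500)
  expect_true(occ_far$extrapolated)
  last <- max(occ_far$curve$time[occ_far$curve$time < 500])
  expect_equal(occ_far$probs,
               with(occ_far$curve,
                    setNames(prob[time == last], state[time == last])))
  expect_error(occupancy(fit, list(start_state = "healthy", sev = 1),
                         horizon = 0), "after the prediction origin")
})

test_that("a cohort mixture start is the weighted sum of single starts", {
  fx <- make_fixture("illness-death-500")
  ep <- expand_to_episodes(fx$subjects, fx$graph)
  fit <- fit_msm(ep, fx$graph)
  oh <- occupancy(fit, list(sev = 0, start_state = "healthy"), horizon = 15)
  oi <- occupancy(fit, list(sev = 0, start_state = "ill"), horizon = 15)
  om <- occupancy(fit, list(sev = 0), horizon = 15,
                  init = c(healthy = 0.6, ill = 0.4))
  expect_equal(om$probs, 0.6 * oh$probs + 0.4 * oi$probs, tolerance = 1e-12)
})

test_that("the most likely state breaks ties deterministically", {
  expect_equal(most_likely_state(c(a = 0.1, b = 0.2, c = 0.7)), "c")
  expect_equal(most_likely_state(c(a = 0.5, b = 0.5)), "a")
  p <- c(s1 = 0.2, s2 = 0.5, s3 = 0.3)
  expect_equal(most_likely_state(p), most_likely_state(sqrt(p)))
})
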