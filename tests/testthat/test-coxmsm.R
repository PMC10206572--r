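test_that("a covariate-free Breslow baseline is the Nelson-Aalen estimator", {
  fx <- make_fixture("toy-3-subjects")
  ep <- expand_to_episodes(fx$subjects, fx$graph)
  for (key in fx$graph$transitions$key) {
    f0 <- fit_transition_cox(ep, key)
    na <- nelson_aalen(ep, key)
    expect_equal(f0$baseline$time, na$time)
    expect_lt(max(abs(f0$baseline$cumhaz - na$cumhaz)), 1e-14)
    expect_equal(unname(f0$loglik["null"]), unname(f0$loglik["fitted"]))
  }
})

test_that("a simulated hazard ratio of 2 is recovered within 3 SEs", {
  sub <- simulate_paths(two_state_spec(rate = 0.08, beta = log(2), cens = 20),
                        2000, seed = 314)
  ep <- expand_to_episodes(sub, two_state_graph())
  f <- fit_transition_cox(ep, "alive->dead", "x")
  expect_lt(abs(f$coef[["x"]] - log(2)), 3 * f$se[["x"]])
  expect_lt(f$grad_norm, 1e-6)
  expect_true(f$converged)
  # covariance is symmetric positive definite, loglik improved
  expect_equal(f$vcov, t(f$vcov))
  expect_gte(f$loglik[["fitted"]], f$loglik[["null"]])
})

test_that("duplicating every episode leaves the estimate unchanged", {
  ep <- influence_table()
  f1 <- fit_transition_cox(ep, "a->b", "x")
  dup <- rbind(ep, transform(ep, id = id + 100L))
  class(dup) <- class(ep)
  f2 <- fit_transition_cox(dup, "a->b", "x")
  expect_equal(f2$coef, f1$coef, tolerance = 1e-8)
})

test_that("coefficients agree with survival::coxph on shared cases", {
  skip_if_not_installed("survival")
  library(survival)
  # continuous + binary covariates, tied integer event times
  set.seed(77)
  n <- 150
  x1 <- rnorm(n, 60, 10)
  x2 <- rbinom(n, 1, 0.4)
  tt <- pmax(1, round(rexp(n, 0.05 * exp(0.02 * (x1 - 60) + 0.5 * x2))))
  status <- as.integer(tt < 30)
  tt <- pmin(tt, 30)
  ep <- data.frame(id = 1:n, from = "a", to = "b", trans = "a->b",
                   tstart = 0, tstop = as.numeric(tt), status = status,
                   x1 = x1, x2 = x2)
  class(ep) <- c("msm_episodes", "data.frame")
  for (tie in c("breslow", "efron")) {
    own <- fit_transition_cox(ep, "a->b", c("x1", "x2"), ties = tie)
    ref <- coxph(Surv(tstop, status) ~ x1 + x2, data = ep, ties = tie)
    expect_lt(max(abs(own$coef - coef(ref))), 1e-6)
    expect_lt(max(abs(own$vcov - vcov(ref))), 1e-6)
    expect_lt(max(abs(own$loglik - ref$loglik)), 1e-6)
  }
})

test_that("degenerate designs are refused with actionable errors", {
  ep <- influence_table()
  # zero events
  cen <- ep; cen$status <- 0L
  expect_error(fit_transition_cox(cen, "a->b"), "no events")
  # collinear columns
  ep$x_dup <- ep$x
  expect_error(fit_transition_cox(ep, "a->b", c("x", "x_dup")),
               "rank deficient.*x_dup")
  # monotone likelihood: the event subject always has the largest covariate
  sep <- data.frame(id = 1:10, from = "a", to = "b", trans = "a->b",
                    tstart = 0, tstop = as.numeric(1:10), status = 1L,
                    z = -(1:10))
  class(sep) <- c("msm_episodes", "data.frame")
  expect_error(fit_transition_cox(sep, "a->b", "z"), "monotone")
})

test_that("the multistate likelihood factorizes over transitions", {
  fx <- make_fixture("illness-death-500")
  ep <- expand_to_episodes(fx$subjects, fx$graph)
  fit <- fit_msm(ep, fx$graph, list("healthy->ill" = "sev"))
  # per-transition assignment: unassigned transitions are null fits
  expect_equal(length(fit$fits[["healthy->dead"]]$coef), 0L)
  expect_equal(length(fit$fits[["ill->dead"]]$coef), 0L)
  expect_equal(names(fit$fits[["healthy->ill"]]$coef), "sev")
  # totals are sums; separate fits agree with the joint fit
  single <- fit_transition_cox(ep, "healthy->ill", "sev")
  expect_equal(fit$fits[["healthy->ill"]]$coef, single$coef)
  expect_equal(unname(fit$loglik["fitted"]),
               sum(vapply(fit$fits, function(f) f$loglik[["fitted"]], 0)))
  # null assignment everywhere: fitted equals null
  fit0 <- fit_msm(ep, fx$graph)
  expect_equal(unname(fit0$loglik["fitted"]), unname(fit0$loglik["null"]))
  lik <- likelihood_table(fit0)
  expect_equal(lik$loglik_fitted, lik$loglik_null)
})

test_that("hazard-ratio rows follow the closed form with optional rescaling", {
  fx <- make_fixture("illness-death-500")
  ep <- expand_to_episodes(fx$subjects, fx$graph)
  fit <- fit_msm(ep, fx$graph, list("healthy->ill" = "sev"))
  f <- fit$fits[["healthy->ill"]]
  tab <- hazard_ratio_table(fit, level = 0.95)
  expect_equal(tab$HR, exp(unname(f$coef)))
  expect_equal(tab$lower, exp(unname(f$coef) - qnorm(0.975) * unname(f$se)))
  expect_equal(tab$upper, exp(unname(f$coef) + qnorm(0.975) * unname(f$se)))
  expect_equal(tab$p_value, 2 * pnorm(-abs(unname(f$coef / f$se))))
  # CI is symmetric around the estimate on the log scale
  expect_equal(log(tab$HR) - log(tab$lower), log(tab$upper) - log(tab$HR))
  # a 10-unit rescale multiplies the log quantities by 10
  tab10 <- hazard_ratio_table(fit, scale = c(sev = 10))
  expect_equal(log(tab10$HR), 10 * log(tab$HR))
  expect_equal(tab10$p_value, tab$p_value)  # p-value is unscaled
  expect_error(hazard_ratio_table(fit, scale = c(bmi = 10)), "unknown")
})

test_that("likelihood-ratio, Wald and score tests detect a strong effect", {
  sub <- simulate_paths(two_state_spec(rate = 0.06, beta = log(3), cens = 25),
                        500, seed = 2718)
  ep <- expand_to_episodes(sub, two_state_graph())
  f <- fit_transition_cox(ep, "alive->dead", "x")
  g <- gof_tests(f)
  expect_equal(g$test, c("likelihood ratio", "wald", "score"))
  expect_true(all(g$statistic > qchisq(0.95, df = 1)))
  expect_equal(g$df, rep(1L, 3L))
  expect_true(all(g$p_value < 0.05))
  # null model: empty table with a note
  f0 <- fit_transition_cox(ep, "alive->dead")
  g0 <- gof_tests(f0)
  expect_equal(nrow(g0), 0L)
  expect_match(attr(g0, "note"), "null model")
})

test_that("AIC identities hold", {
  fx <- make_fixture("illness-death-500")
  ep <- expand_to_episodes(fx$subjects, fx$graph)
  fit0 <- fit_msm(ep, fx$graph)
  a0 <- aic_table(fit0)
  expect_equal(a0$AIC[a0$trans != "total"],
               -2 * a0$loglik[a0$trans != "total"])
  expect_equal(a0$AIC[a0$trans == "total"],
               sum(a0$AIC[a0$trans != "total"]))
  # adding a pure-noise covariate changes AIC by 2 - LRT
  set.seed(5)
  ep$noise <- rnorm(nrow(ep))[match(ep$id, unique(ep$id))]
  fitn <- fit_msm(ep, fx$graph, list("healthy->ill" = "noise"))
  lrt <- gof_tests(fitn$fits[["healthy->ill"]])$statistic[1L]
  expect_equal(fitn$aic - fit0$aic, 2 - lrt, tolerance = 1e-8)
})
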