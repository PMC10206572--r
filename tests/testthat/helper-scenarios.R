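# Shared simulation scenarios and hand-built tables used across tests.

two_state_graph <- function() {
  msm_graph(c("alive", "dead"), list(c("alive", "dead")))
}

# two-state alive -> dead with an optional binary covariate effect
two_state_spec <- function(rate = 0.1, beta = NULL, cens = Inf, p = 0.5,
                           weibull = NULL, cens_rate = NULL) {
  hz <- if (is.null(weibull))
    list("alive->dead" = list(dist = "constant", rate = rate))
  else
    list("alive->dead" = list(dist = "weibull",
                              shape = weibull[1L], scale = weibull[2L]))
  eff <- if (is.null(beta)) list() else list("alive->dead" = c(x = beta))
  cov <- if (is.null(beta)) list() else list(x = list(type = "binary", p = p))
  msm_sim_spec(two_state_graph(), hz, effects = eff, covariates = cov,
               cens_time = cens, cens_rate = cens_rate)
}

illness_death_graph <- function() {
  msm_graph(c("healthy", "ill", "dead"),
            list(c("healthy", "ill"), c("healthy", "dead"),
                 c("ill", "dead")))
}

illness_death_spec <- function(l12 = 0.1, l13 = 0.05, l23 = 0.2,
                               beta = NULL, cens = 30) {
  g <- illness_death_graph()
  eff <- if (is.null(beta)) list() else list("healthy->ill" = c(sev = beta))
  cov <- if (is.null(beta)) list() else list(sev = list(type = "binary", p = 0.5))
  msm_sim_spec(g,
               hazards = list(
                 "healthy->ill" = list(dist = "constant", rate = l12),
                 "healthy->dead" = list(dist = "constant", rate = l13),
                 "ill->dead" = list(dist = "constant", rate = l23)),
               effects = eff, covariates = cov,
               init = c(healthy = 1), cens_time = cens)
}

# closed-form occupancy of the constant-intensity illness-death model
# started in `healthy` (Kolmogorov forward equations)
illness_death_closed_form <- function(t, l12 = 0.1, l13 = 0.05, l23 = 0.2) {
  l1 <- l12 + l13
  p11 <- exp(-l1 * t)
  p12 <- l12 * (exp(-l1 * t) - exp(-l23 * t)) / (l23 - l1)
  cbind(healthy = p11, ill = p12, dead = 1 - p11 - p12)
}

# deterministic 30-episode single-transition table for influence
# diagnostics: balanced binary covariate, 10 events at days 1..10, 20
# administratively censored at day 12 (fixed-horizon follow-up keeps every
# risk set large, the regularity condition of the one-step approximation)
influence_table <- function() {
  ep <- data.frame(id = 1:30, from = "a", to = "b", trans = "a->b",
                   tstart = 0,
                   tstop = c(1:10, rep(12, 20)),
                   status = c(rep(1L, 10), rep(0L, 20)),
                   x = rep(c(0, 1), 15))
  class(ep) <- c("msm_episodes", "data.frame")
  ep
}

# state occupied at time t along a simulated truth path
state_at <- function(path, t) {
  path$state[max(which(path$time <= t))]
}

# empirical occupancy of simulated subjects (uncensored by time t)
empirical_occupancy <- function(subjects, states, t) {
  paths <- attr(subjects, "paths")
  occ <- table(factor(vapply(paths, state_at, "", t = t), levels = states))
  as.numeric(occ) / length(paths)
}
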