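#' Nelson-Aalen estimator of a cumulative transition intensity
#'
#' Jumps exactly at the event times of the transition; each increment is
#' `dN_kl(t) / Y_k(t)`, the number of `k -> l` transitions at `t` divided by
#' the number of subjects in state `k` just before `t` (tied events are
#' aggregated).  Because an episode row exists for every subject at risk for
#' the transition, the risk set depends only on the origin state `k`.
#'
#' @param episodes an `msm_episodes` table.
#' @param transition `c(from, to)` or a `"from->to"` key.
#' @return An object of class `msm_hazard`: data frame `time`, `nevent`,
#'   `nrisk`, `dhaz`, `cumhaz` with the transition key as attribute
#'   `"trans"`.
#' @export
nelson_aalen <- function(episodes, transition) {
  key <- transition_key(transition)
  rows <- episodes[episodes$trans == key, , drop = FALSE]
  if (!nrow(rows)) fail("no episodes for transition %s", key)
  et <- sort(unique(rows$tstop[rows$status == 1L]))
  if (!length(et)) {
    out <- data.frame(time = numeric(0), nevent = integer(0),
                      nrisk = numeric(0), dhaz = numeric(0),
                      cumhaz = numeric(0))
  } else {
    d <- tabulate(match(rows$tstop[rows$status == 1L], et), nbins = length(et))
    Y <- drop(risk_sums(et, rows$tstart, rows$tstop,
                        matrix(1, nrow(rows), 1L)))
    if (any(Y < d)) fail("internal error: fewer at risk than events for %s", key)
    out <- data.frame(time = et, nevent = d, nrisk = Y, dhaz = d / Y,
                      cumhaz = cumsum(d / Y))
  }
  structure(out, trans = key, class = c("msm_hazard", "data.frame"))
}

# closed-form mass of the Epanechnikov kernel K_b centred at t inside
# [lo, hi]; used for boundary renormalization
epan_mass <- function(t, b, lo, hi) {
  G <- function(z) 0.5 + 0.75 * (z - z^3 / 3)   # CDF of K on [-1, 1]
  z1 <- pmax(-1, (lo - t) / b)
  z2 <- pmin(1, (hi - t) / b)
  pmax(G(z2) - G(z1), 0)
}

#' Kernel-smoothed instantaneous hazard
#'
#' Smooths the Nelson-Aalen increments with an Epanechnikov kernel,
#' `lambda(t) = sum_j K_b(t - t_j) dHaz(t_j)`, renormalized at the window
#' boundaries so that kernel mass lost outside `window` is restored.  The
#' default bandwidth is one eighth of the jump-time range.
#'
#' @param estimate an [nelson_aalen()] result.
#' @param bandwidth kernel half-width (> 0); default `(max(t) - min(t)) / 8`.
#' @param grid evaluation times; default 101 equispaced points over the
#'   window.
#' @param window numeric length-2: support of the observation window used
#'   for boundary correction; default `c(0, max(jump times))`.
#' @return Data frame `time`, `hazard` with attributes `"trans"` and
#'   `"bandwidth"`.
#' @export
smoothed_hazard <- function(estimate, bandwidth = NULL, grid = NULL,
                            window = NULL) {
  stopifnot(inherits(estimate, "msm_hazard"))
  if (!nrow(estimate)) {
    warning("no events: returning an empty hazard curve", call. = FALSE)
    out <- data.frame(time = numeric(0), hazard = numeric(0))
    return(structure(out, trans = attr(estimate, "trans"),
                     bandwidth = bandwidth))
  }
  window <- window %||% c(0, max(estimate$time))
  if (is.null(bandwidth)) {
    span <- diff(range(estimate$time))
    bandwidth <- if (span > 0) span / 8 else max(estimate$time) / 8
  }
  if (bandwidth <= 0) fail("bandwidth must be > 0")
  grid <- grid %||% seq(window[1L], window[2L], length.out = 101L)
  u <- outer(grid, estimate$time, "-") / bandwidth
  K <- ifelse(abs(u) <= 1, 0.75 * (1 - u^2) / bandwidth, 0)
  mass <- epan_mass(grid, bandwidth, window[1L], window[2L])
  val <- drop(K %*% estimate$dhaz) / ifelse(mass > 0, mass, 1)
  structure(data.frame(time = grid, hazard = val),
            trans = attr(estimate, "trans"), bandwidth = bandwidth)
}

#' Stratified smoothed hazards
#'
#' Per-level smoothed hazard curves of one transition, computed by filtering
#' the episodes on each level of a categorical covariate and smoothing each
#' subset (equivalent to estimate-on-filtered-data by construction).
#'
#' @param episodes an `msm_episodes` table.
#' @param transition transition key or pair.
#' @param by name of a categorical (factor/character or few-valued) column.
#' @inheritParams smoothed_hazard
#' @return Data frame `time`, `hazard`, `stratum`.
#' @export
smoothed_hazard_strata <- function(episodes, transition, by,
                                   bandwidth = NULL, grid = NULL,
                                   window = NULL) {
  if (!by %in% names(episodes)) fail("unknown stratification covariate: %s", by)
  levs <- sort(unique(as.character(episodes[[by]])))
  out <- list()
  for (lv in levs) {
    sub <- episodes[as.character(episodes[[by]]) == lv, , drop = FALSE]
    key <- transition_key(transition)
    if (!nrow(sub[sub$trans == key, ])) {
      warning(sprintf("stratum %s=%s is empty for %s", by, lv, key),
              call. = FALSE)
      next
    }
    sm <- smoothed_hazard(nelson_aalen(sub, transition),
                          bandwidth = bandwidth, grid = grid, window = window)
    if (nrow(sm)) out[[lv]] <- cbind(sm, stratum = lv)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(time = numeric(0), hazard = numeric(0), stratum = character(0))
  rownames(res) <- NULL
  res
}

#' Cumulative incidence of an absorbing state
#'
#' State-occupancy probability of an absorbing state over time: the
#' Aalen-Johansen product integral of the Nelson-Aalen increments of all
#' transitions, started from the empirical distribution of starting states.
#' In a two-state alive/dead model this equals one minus the Kaplan-Meier
#' survival curve.
#'
#' @param episodes an `msm_episodes` table.
#' @param graph an [msm_graph].
#' @param absorbing_state an absorbing state label.
#' @return Data frame `time`, `prob` (nondecreasing, in `[0, 1]`), starting
#'   at `(0, p0)` where `p0` is the initial mass in the absorbing state
#'   (normally 0).
#' @export
cumulative_incidence <- function(episodes, graph, absorbing_state) {
  stopifnot(inherits(graph, "msm_graph"))
  if (!absorbing_state %in% graph$states)
    fail("unknown state: %s", absorbing_state)
  if (graph$roles[[absorbing_state]] != "absorbing")
    fail("%s is not an absorbing state", absorbing_state)
  hazards <- empirical_hazards(episodes, graph)
  pt <- aalen_johansen(hazards, graph$states, t0 = 0)
  # empirical starting distribution: origin state of each subject's first episode
  first <- episodes[episodes$tstart == 0, c("id", "from")]
  first <- first[!duplicated(first$id), , drop = FALSE]
  p0 <- table(factor(first$from, levels = graph$states)) / nrow(first)
  probs <- vapply(seq_along(pt$times), function(g)
    drop(as.numeric(p0) %*% pt$P[, , g])[match(absorbing_state, graph$states)],
    0)
  data.frame(time = pt$times, prob = probs)
}

# Nelson-Aalen increments of every transition, as the hazard-list contract
# consumed by aalen_johansen()
empirical_hazards <- function(episodes, graph) {
  hz <- list()
  for (key in graph$transitions$key) {
    rows <- episodes[episodes$trans == key, , drop = FALSE]
    if (!nrow(rows)) {
      hz[[key]] <- data.frame(time = numeric(0), dhaz = numeric(0))
      next
    }
    na <- nelson_aalen(episodes, key)
    hz[[key]] <- data.frame(time = na$time, dhaz = na$dhaz)
  }
  hz
}
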