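#' Profile-specific cumulative transition hazards
#'
#' For a new individual's covariate profile, multiplies each transition's
#' Breslow baseline hazard increments by `exp(beta' z)` with `z` the profile
#' restricted to that transition's covariates.  Transitions that could not
#' be fitted (zero events) contribute zero hazard.
#'
#' @param fit an [fit_msm()] result.
#' @param profile a one-row data frame, or named list, holding every
#'   covariate used anywhere in the fit (and optionally `start_state`).
#' @return Named list per transition: data frame `time`, `dhaz`.
#' @export
profile_hazards <- function(fit, profile) {
  stopifnot(inherits(fit, "msm_fit"))
  profile <- as.data.frame(as.list(profile), stringsAsFactors = FALSE)
  hz <- list()
  for (key in fit$graph$transitions$key) {
    f <- fit$fits[[key]]
    if (is.null(f)) {
      hz[[key]] <- data.frame(time = numeric(0), dhaz = numeric(0))
      next
    }
    risk <- profile_risk(f, profile)
    hz[[key]] <- data.frame(time = f$baseline$time,
                            dhaz = f$baseline$hazard * risk)
  }
  hz
}

# exp(beta' z) for one transition fit and a one-row profile
profile_risk <- function(f, profile) {
  if (!length(f$coef)) return(1)
  vars <- all.vars(f$formula)
  miss <- setdiff(vars, names(profile))
  if (length(miss)) fail("profile is missing covariate(s): %s",
                         paste(miss, collapse = ", "))
  mf <- model.frame(f$formula, profile, xlev = f$xlev)
  x <- model.matrix(attr(mf, "terms"), mf)[1L, -1L]
  exp(sum(f$coef * x))
}

#' Aalen-Johansen transition probability matrices
#'
#' Builds `P(t0, t)` over all states as the product integral
#' `prod_{t0 < t_j <= t} (I + dLambda(t_j))` over the pooled jump times of
#' the supplied per-transition cumulative hazard increments, with
#' off-diagonal entries `dLambda_kl` and diagonal `-sum_l dLambda_kl`.
#' Matrices are multiplied in time order; rows are left stochastic by
#' construction.  If the total jump mass leaving a state exceeds 1 at some
#' time (possible for extreme covariate profiles), the factor's diagonal is
#' clamped at 0 and the row's off-diagonal entries are rescaled to sum to 1,
#' with a warning identifying the time and state.
#'
#' @param hazards named list per `"from->to"` transition: data frames
#'   `time`, `dhaz` (as from [profile_hazards()]).
#' @param states state labels in model order (or an [msm_graph]).
#' @param t0 prediction origin (default 0); jumps at or before `t0` are
#'   ignored.
#' @param times optional extra evaluation times to include in the grid.
#' @return An object of class `msm_probtrans`: `states`, `times` (starting
#'   at `t0`), and `P`, an `R x R x length(times)` array with
#'   `P[, , 1] = I`.
#' @export
aalen_johansen <- function(hazards, states, t0 = 0, times = NULL) {
  if (inherits(states, "msm_graph")) states <- states$states
  R <- length(states)
  idx <- lapply(names(hazards), split_key)
  ki <- vapply(idx, function(x) match(x[1L], states), 0L)
  li <- vapply(idx, function(x) match(x[2L], states), 0L)
  if (anyNA(ki) || anyNA(li)) fail("hazard list names use unknown states")

  jumps <- sort(unique(unlist(lapply(hazards, function(h) h$time))))
  jumps <- jumps[jumps > t0]
  extra <- if (is.null(times)) numeric(0) else times[times > t0]
  grid <- sort(unique(c(jumps, extra)))
  Tn <- length(grid)

  # increments aligned to the grid, one column per transition
  inc <- matrix(0, Tn, length(hazards))
  for (m in seq_along(hazards)) {
    h <- hazards[[m]]
    keep <- h$time > t0
    if (any(keep))
      inc[match(h$time[keep], grid), m] <- h$dhaz[keep]
  }

  P <- array(0, dim = c(R, R, Tn + 1L),
             dimnames = list(states, states, NULL))
  cur <- diag(R)
  P[, , 1L] <- cur
  for (g in seq_len(Tn)) {
    act <- which(inc[g, ] > 0)
    if (length(act)) {
      A <- diag(R)
      for (m in act) {
        A[ki[m], li[m]] <- A[ki[m], li[m]] + inc[g, m]
        A[ki[m], ki[m]] <- A[ki[m], ki[m]] - inc[g, m]
      }
      low <- which(diag(A) < 0)
      for (k in low) {
        warning(sprintf(
          "jump mass > 1 leaving state %s at t=%g: clamped and renormalized",
          states[k], grid[g]), call. = FALSE)
        A[k, k] <- 0
        s <- sum(A[k, -k])
        A[k, -k] <- A[k, -k] / s
      }
      cur <- cur %*% A
    }
    P[, , g + 1L] <- cur
  }
  structure(list(states = states, times = c(t0, grid), t0 = t0, P = P),
            class = "msm_probtrans")
}

#' Evaluate a transition probability matrix at arbitrary times
#'
#' `P(t0, t)` is a right-continuous step function constant between jumps.
#'
#' @param pt an [aalen_johansen()] result.
#' @param t numeric vector of times `>= t0`.
#' @return An `R x R x length(t)` array.
#' @export
probtrans_at <- function(pt, t) {
  stopifnot(inherits(pt, "msm_probtrans"))
  if (any(t < pt$t0)) fail("evaluation before the prediction origin t0")
  gi <- findInterval(t, pt$times)
  pt$P[, , gi, drop = FALSE]
}

#' State occupancy for a covariate profile
#'
#' The start-state row of the Aalen-Johansen matrix `P(t0, t)` for one
#' profile: per-state probabilities at the horizon, the full occupancy
#' curves on the pooled jump grid, and the most likely state.  A horizon
#' beyond the last observed event time is allowed -- probabilities are held
#' constant from the last jump -- and flagged.
#'
#' @param fit an [fit_msm()] result.
#' @param profile named list / one-row data frame with the covariates used
#'   in the fit and a `start_state` (initial or transient), unless `init`
#'   is given.
#' @param horizon prediction horizon `tau > t0` (days).
#' @param t0 prediction origin (default 0).
#' @param init optional named initial distribution over states, replacing
#'   the single `start_state` row (cohort-style mixture).
#' @return An object of class `msm_occupancy`: `probs` (named vector at the
#'   horizon), `curve` (long data frame `time`, `state`, `prob`),
#'   `most_likely`, `horizon`, `start`, and `extrapolated`.
#' @export
occupancy <- function(fit, profile, horizon, t0 = 0, init = NULL) {
  stopifnot(inherits(fit, "msm_fit"))
  if (horizon <= t0) fail("horizon must be after the prediction origin t0")
  states <- fit$graph$states
  profile <- as.data.frame(as.list(profile), stringsAsFactors = FALSE)
  if (is.null(init)) {
    if (is.null(profile$start_state)) fail("profile needs a start_state")
    start <- profile$start_state
    if (!start %in% states) fail("unknown start state: %s", start)
    p0 <- as.numeric(states == start)
  } else {
    unknown <- setdiff(names(init), states)
    if (length(unknown)) fail("init over unknown state(s): %s",
                              paste(unknown, collapse = ", "))
    if (abs(sum(init) - 1) > 1e-8) fail("init must sum to 1")
    p0 <- as.numeric(init[match(states, names(init))])
    p0[is.na(p0)] <- 0
    start <- NA_character_
  }
  hz <- profile_hazards(fit, profile)
  pt <- aalen_johansen(hz, states, t0 = t0, times = horizon)
  occ <- t(apply(pt$P, 3L, function(M) drop(p0 %*% M)))
  colnames(occ) <- states
  last_jump <- max(c(t0, unlist(lapply(hz, function(h) h$time))))
  at_tau <- occ[findInterval(horizon, pt$times), ]
  curve <- data.frame(time = rep(pt$times, length(states)),
                      state = rep(states, each = length(pt$times)),
                      prob = as.vector(occ))
  structure(list(probs = at_tau, curve = curve,
                 most_likely = most_likely_state(at_tau),
                 horizon = horizon, t0 = t0, start = start,
                 extrapolated = horizon > last_jump),
            class = "msm_occupancy")
}

#' @export
print.msm_occupancy <- function(x, ...) {
  cat(sprintf("State occupancy at t = %g (from %s, t0 = %g)%s\n", x$horizon,
              if (is.na(x$start)) "initial mixture" else x$start, x$t0,
              if (x$extrapolated) " [beyond last event time]" else ""))
  print(round(x$probs, 4))
  cat("most likely state:", x$most_likely, "\n")
  invisible(x)
}

#' Most likely state of an occupancy vector
#'
#' Argmax of the per-state probabilities; exact ties are broken by the
#' smallest state index (the order of the vector), deterministically.
#'
#' @param occupancy_at_tau a named probability vector, or an
#'   [occupancy()] result.
#' @return A state label.
#' @export
most_likely_state <- function(occupancy_at_tau) {
  if (inherits(occupancy_at_tau, "msm_occupancy"))
    occupancy_at_tau <- occupancy_at_tau$probs
  names(occupancy_at_tau)[which.max(occupancy_at_tau)]
}
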