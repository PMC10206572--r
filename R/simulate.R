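#' Specify transition intensities and covariates for simulation
#'
#' Defines the data-generating mechanism for [simulate_paths()]: a
#' clock-forward Markov process whose transition intensities are constant
#' (exponential) or Weibull in time since the common origin, multiplied by
#' proportional covariate effects `exp(beta' z)`.
#'
#' @param graph an [msm_graph].
#' @param hazards named list, one entry per transition key `"from->to"`,
#'   each either `list(dist = "constant", rate = )` or
#'   `list(dist = "weibull", shape = , scale = )` (hazard
#'   `(a/b) * (t/b)^(a-1)`).  Every transition in the graph must appear,
#'   with strictly positive parameters.
#' @param effects named list keyed by transition: named numeric vectors of
#'   log hazard ratios per covariate (absent transitions have no covariate
#'   effect).
#' @param covariates named list of covariate generators:
#'   `list(type = "binary", p = , labels = NULL)` (0/1, or a two-level
#'   factor when `labels` has length 2; the effect applies to the second
#'   level) or `list(type = "normal", mean = , sd = )`.
#' @param init named probability vector over starting states (defaults to
#'   uniform over the graph's initial states); must sum to 1.
#' @param cens_time administrative censoring time (default `Inf`).
#' @param cens_rate optional rate of an independent exponential censoring
#'   time, for censored-data experiments.
#' @return An object of class `msm_sim_spec`.
#' @export
msm_sim_spec <- function(graph, hazards, effects = list(),
                         covariates = list(), init = NULL,
                         cens_time = Inf, cens_rate = NULL) {
  stopifnot(inherits(graph, "msm_graph"))
  keys <- graph$transitions$key
  missing_h <- setdiff(keys, names(hazards))
  if (length(missing_h)) fail("no hazard specified for transition(s): %s",
                              paste(missing_h, collapse = ", "))
  extra <- setdiff(names(hazards), keys)
  if (length(extra)) fail("hazard for unknown transition(s): %s",
                          paste(extra, collapse = ", "))
  for (k in keys) {
    h <- hazards[[k]]
    if (identical(h$dist, "constant")) {
      if (!is.numeric(h$rate) || h$rate <= 0) fail("rate for %s must be > 0", k)
    } else if (identical(h$dist, "weibull")) {
      if (!is.numeric(h$shape) || h$shape <= 0 ||
          !is.numeric(h$scale) || h$scale <= 0)
        fail("weibull shape/scale for %s must be > 0", k)
    } else fail("unknown hazard family for %s (use constant or weibull)", k)
  }
  bad_eff <- setdiff(names(effects), keys)
  if (length(bad_eff)) fail("effects on unknown transition(s): %s",
                            paste(bad_eff, collapse = ", "))
  for (k in names(effects)) {
    unknown <- setdiff(names(effects[[k]]), names(covariates))
    if (length(unknown)) fail("effect on undeclared covariate(s) in %s: %s",
                              k, paste(unknown, collapse = ", "))
  }
  for (cv in names(covariates)) {
    cc <- covariates[[cv]]
    if (identical(cc$type, "binary")) {
      if (!is.numeric(cc$p) || cc$p < 0 || cc$p > 1)
        fail("prevalence of %s must be in [0,1]", cv)
    } else if (identical(cc$type, "normal")) {
      if (!is.numeric(cc$sd) || cc$sd < 0) fail("sd of %s must be >= 0", cv)
    } else fail("unknown covariate type for %s (use binary or normal)", cv)
  }
  if (is.null(init)) {
    ini <- names(graph$roles)[graph$roles == "initial"]
    init <- setNames(rep(1 / length(ini), length(ini)), ini)
  }
  if (abs(sum(init) - 1) > 1e-8) fail("initial-state distribution must sum to 1")
  if (any(init < 0)) fail("initial-state probabilities must be >= 0")
  unknown_s <- setdiff(names(init), graph$states)
  if (length(unknown_s)) fail("initial distribution over unknown state(s): %s",
                              paste(unknown_s, collapse = ", "))
  if (!is.infinite(cens_time) && cens_time <= 0) fail("cens_time must be > 0")
  if (!is.null(cens_rate) && cens_rate <= 0) fail("cens_rate must be > 0")
  structure(list(graph = graph, hazards = hazards, effects = effects,
                 covariates = covariates, init = init,
                 cens_time = cens_time, cens_rate = cens_rate),
            class = "msm_sim_spec")
}

# cumulative hazard of one transition between calendar times t0 < t1 (baseline)
cum_haz_between <- function(h, t0, t1) {
  if (identical(h$dist, "constant")) h$rate * (t1 - t0)
  else (t1 / h$scale)^h$shape - (t0 / h$scale)^h$shape
}

haz_at <- function(h, t) {
  if (identical(h$dist, "constant")) h$rate
  else (h$shape / h$scale) * (t / h$scale)^(h$shape - 1)
}

#' Simulate multistate paths with known truth
#'
#' Draws `n` subjects from the mechanism in `spec`: covariates first, then a
#' clock-forward Markov path.  From the state occupied at time `t` the next
#' event time is drawn by inverting the total exit cumulative hazard (closed
#' form when all outgoing hazards are constant, otherwise bracketed
#' root-finding to 1e-10), and the destination is chosen with probability
#' proportional to the transition intensities at that time.  The path stops
#' at an absorbing state or at the censoring time.
#'
#' @param spec an [msm_sim_spec].
#' @param n number of subjects.
#' @param seed optional integer seed; identical `(seed, n, spec)` give
#'   bit-identical output.
#' @return A wide-format subject table (see [expand_to_episodes()] for the
#'   layout) with attributes `paths` (list of per-subject data frames of
#'   `state`, `time` plus a `censored` flag) and `transition_tally` (named
#'   count of realized transitions).
#' @export
simulate_paths <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "msm_sim_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  graph <- spec$graph

  covs <- draw_covariates(spec$covariates, n)
  covnum <- covs$numeric        # numeric design used in the hazards
  covdata <- covs$data          # reported values (factors kept as factors)

  start <- sample(names(spec$init), n, replace = TRUE, prob = spec$init)
  cens <- rep(spec$cens_time, n)
  if (!is.null(spec$cens_rate))
    cens <- pmin(cens, rexp(n, rate = spec$cens_rate))

  paths <- vector("list", n)
  keys <- graph$transitions$key
  tally <- setNames(integer(length(keys)), keys)

  # per-subject proportional-hazard weights for every transition
  W <- matrix(1, n, length(keys), dimnames = list(NULL, keys))
  for (k in names(spec$effects)) {
    eff <- spec$effects[[k]]
    W[, k] <- exp(drop(covnum[, names(eff), drop = FALSE] %*% eff))
  }
  # per-state outgoing structure, resolved once
  out_to <- lapply(graph$states, function(s)
    graph$transitions$to[graph$transitions$from == s])
  out_key <- lapply(graph$states, function(s)
    keys[graph$transitions$from == s])
  names(out_to) <- names(out_key) <- graph$states
  out_hz <- lapply(out_key, function(kk) spec$hazards[kk])
  all_const <- lapply(out_hz, function(hh)
    vapply(hh, function(h) identical(h$dist, "constant"), TRUE))
  const_rates <- lapply(out_hz, function(hh)
    vapply(hh, function(h) if (identical(h$dist, "constant")) h$rate else NA_real_, 0))
  absorbing <- graph$roles == "absorbing"

  for (i in seq_len(n)) {
    state <- start[i]
    t <- 0
    st_v <- state; tm_v <- 0
    censored <- FALSE
    while (!absorbing[[state]]) {
      kk <- out_key[[state]]
      w <- W[i, kk]
      if (all(all_const[[state]])) {
        rates <- const_rates[[state]] * w
        tot <- sum(rates)
        if (tot <= 0) fail("state has outgoing transitions but zero total hazard")
        u <- t + rexp(1) / tot
        lam <- rates
      } else {
        u <- draw_event_time(out_hz[[state]], w, t)
        lam <- vapply(seq_along(kk),
                      function(j) haz_at(out_hz[[state]][[j]], u) * w[j], 0)
      }
      if (u > cens[i]) { censored <- TRUE; t <- cens[i]; break }
      dest_j <- if (length(lam) == 1L) 1L else
        sample.int(length(lam), 1L, prob = lam)
      key <- kk[dest_j]
      tally[key] <- tally[key] + 1L
      state <- out_to[[state]][dest_j]
      t <- u
      st_v <- c(st_v, state); tm_v <- c(tm_v, t)
    }
    path <- data.frame(state = st_v, time = tm_v, stringsAsFactors = FALSE)
    attr(path, "censored") <- censored
    attr(path, "end_time") <- if (censored) t else tm_v[length(tm_v)]
    paths[[i]] <- path
  }

  subjects <- paths_to_wide(paths, graph, covdata)
  attr(subjects, "paths") <- paths
  attr(subjects, "transition_tally") <- tally
  subjects
}

draw_covariates <- function(covariates, n) {
  data <- list()
  num <- list()
  for (cv in names(covariates)) {
    cc <- covariates[[cv]]
    if (identical(cc$type, "binary")) {
      x <- rbinom(n, 1L, cc$p)
      num[[cv]] <- x
      data[[cv]] <- if (!is.null(cc$labels))
        factor(cc$labels[x + 1L], levels = cc$labels) else x
    } else {
      x <- rnorm(n, cc$mean %||% 0, cc$sd %||% 1)
      num[[cv]] <- x
      data[[cv]] <- x
    }
  }
  nummat <- if (length(num)) do.call(cbind, num) else
    matrix(0, n, 0)
  datadf <- if (length(data)) as.data.frame(data, stringsAsFactors = FALSE) else
    data.frame(row.names = seq_len(n))
  list(numeric = nummat, data = datadf)
}

# next event time from calendar time t given outgoing hazards and PH weights
draw_event_time <- function(hz, w, t) {
  e <- rexp(1)
  const <- vapply(hz, function(h) identical(h$dist, "constant"), TRUE)
  if (all(const)) {
    tot <- sum(vapply(seq_along(hz), function(j) hz[[j]]$rate * w[j], 0))
    if (tot <= 0) fail("state has outgoing transitions but zero total hazard")
    return(t + e / tot)
  }
  f <- function(u) {
    sum(vapply(seq_along(hz),
               function(j) w[j] * cum_haz_between(hz[[j]], t, u), 0)) - e
  }
  upper <- t + 1
  while (f(upper) < 0) {
    upper <- t + (upper - t) * 2
    if (upper > 1e9) fail("event-time inversion failed to bracket (hazard ~ 0)")
  }
  stats::uniroot(f, lower = t, upper = upper, tol = 1e-10)$root
}

# wide layout: id, start_state, <state>_time/<state>_status for every
# non-initial state, then covariates.  For unentered states the time column
# carries the subject's last observation time (status 0).
paths_to_wide <- function(paths, graph, covdata) {
  non_initial <- graph$states[graph$roles != "initial"]
  n <- length(paths)
  out <- data.frame(id = seq_len(n),
                    start_state = vapply(paths, function(p) p$state[1L], ""),
                    stringsAsFactors = FALSE)
  for (s in non_initial) {
    tm <- numeric(n); st <- integer(n)
    for (i in seq_len(n)) {
      p <- paths[[i]]
      if (s %in% p$state) {
        tm[i] <- p$time[match(s, p$state)]
        st[i] <- 1L
      } else {
        tm[i] <- attr(p, "end_time")
        st[i] <- 0L
      }
    }
    out[[paste0(s, "_time")]] <- tm
    out[[paste0(s, "_status")]] <- st
  }
  # start state is recorded via start_state; its *_time/_status columns (when
  # the start state is itself non-initial) read entry at time 0
  if (ncol(covdata)) out <- cbind(out, covdata)
  rownames(out) <- NULL
  out
}
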