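#' Logarithmic score of probabilistic state forecasts
#'
#' Mean negative log probability assigned to each subject's realized state:
#' 0 for perfect forecasts, `log(R)` for uniform forecasts over `R` states,
#' unbounded above.  Probabilities are floored at `floor` before the log;
#' when the floor fires the result carries attribute `"floored"` with the
#' count.
#'
#' @param predicted_probs matrix (subjects x states, column names = state
#'   labels) of occupancy forecasts, each row summing to 1.
#' @param observed_states character vector of realized states.
#' @param floor lower truncation of forecast probabilities (default 1e-12).
#' @return The score (a single number `>= 0`).
#' @export
log_score <- function(predicted_probs, observed_states, floor = 1e-12) {
  predicted_probs <- as.matrix(predicted_probs)
  n <- nrow(predicted_probs)
  if (length(observed_states) != n)
    fail("need one observed state per forecast row")
  ji <- match(observed_states, colnames(predicted_probs))
  if (anyNA(ji)) fail("observed state(s) not among forecast columns: %s",
                      paste(unique(observed_states[is.na(ji)]), collapse = ", "))
  if (any(abs(rowSums(predicted_probs) - 1) > 1e-6))
    fail("forecast rows must sum to 1")
  pr <- predicted_probs[cbind(seq_len(n), ji)]
  n_floor <- sum(pr < floor)
  if (n_floor) warning(sprintf("%d forecast probability(ies) floored at %g",
                               n_floor, floor), call. = FALSE)
  score <- -mean(log(pmax(pr, floor))) + 0   # + 0 avoids negative zero
  if (n_floor) attr(score, "floored") <- n_floor
  score
}

# realized state at t1 for each subject, or NA when censored before t1
realized_states <- function(subjects, graph, t1) {
  non_initial <- graph$states[graph$roles != "initial"]
  n <- nrow(subjects)
  time_m <- as.matrix(subjects[, paste0(non_initial, "_time"), drop = FALSE])
  stat_m <- as.matrix(subjects[, paste0(non_initial, "_status"), drop = FALSE])
  starts <- subjects$start_state
  absorbing <- graph$roles == "absorbing"
  out <- character(n)
  for (i in seq_len(n)) {
    ent <- which(stat_m[i, ] == 1L & non_initial != starts[i])
    times <- time_m[i, ent]; states <- non_initial[ent]
    by_t1 <- times <= t1
    last <- if (any(by_t1)) states[by_t1][which.max(times[by_t1])] else starts[i]
    if (absorbing[[last]]) { out[i] <- last; next }
    final_state <- if (length(states)) states[which.max(times)] else starts[i]
    unent <- which(!(non_initial %in% c(starts[i], states)))
    obs_end <- if (absorbing[[final_state]]) Inf
      else if (length(unent)) max(time_m[i, unent])
      else max(times, 0)
    out[i] <- if (obs_end >= t1) last else NA_character_
  }
  out
}

#' Predicted vs realized states: log score, confusion matrix, accuracy
#'
#' Evaluates a fitted multistate Cox model at a follow-up time `t1`: for
#' each subject the model predicts the occupancy vector given the subject's
#' own baseline profile and starting state (origin `t0 = 0`); the predicted
#' state is the most likely one, the realized state is the last state
#' entered at or before `t1`.  Subjects censored before `t1` cannot be
#' evaluated and are excluded with a count.
#'
#' @param fit an [fit_msm()] result.
#' @param subjects the wide subject table to evaluate (in-sample by
#'   default; pass held-out subjects for out-of-sample assessment).
#' @param t1 follow-up horizon.
#' @return An object of class `msm_score_report`: `horizon`, `n_evaluated`,
#'   `n_excluded`, `log_score`, `confusion` (rows = predicted, columns =
#'   real), `accuracy` (per realized state: diagonal / column total), and
#'   `predicted_probs`.
#' @export
score_report <- function(fit, subjects, t1) {
  stopifnot(inherits(fit, "msm_fit"))
  graph <- fit$graph
  states <- graph$states
  realized <- realized_states(subjects, graph, t1)
  keep <- !is.na(realized)
  n_excl <- sum(!keep)
  if (!any(keep)) {
    out <- structure(list(horizon = t1, n_evaluated = 0L, n_excluded = n_excl,
                          log_score = NA_real_, confusion = NULL,
                          accuracy = NULL,
                          reason = "no subject observable at the horizon"),
                     class = "msm_score_report")
    return(out)
  }
  eval_sub <- subjects[keep, , drop = FALSE]
  realized <- realized[keep]

  used <- unique(unlist(lapply(fit$fits, function(f) all.vars(f$formula))))
  prof_cols <- c("start_state", intersect(used, names(eval_sub)))
  prof <- eval_sub[, prof_cols, drop = FALSE]
  key <- do.call(paste, c(prof, sep = "\r"))
  ukey <- !duplicated(key)
  probs <- matrix(NA_real_, nrow(eval_sub), length(states),
                  dimnames = list(NULL, states))
  for (i in which(ukey)) {
    occ <- occupancy(fit, prof[i, , drop = FALSE], horizon = t1)
    probs[key == key[i], ] <- rep(occ$probs, each = sum(key == key[i]))
  }
  predicted <- states[apply(probs, 1L, which.max)]

  conf <- table(predicted = factor(predicted, levels = states),
                real = factor(realized, levels = states))
  acc <- diag(conf) / colSums(conf)
  structure(list(horizon = t1, n_evaluated = nrow(eval_sub),
                 n_excluded = n_excl,
                 log_score = as.numeric(log_score(probs, realized)),
                 confusion = conf, accuracy = acc,
                 predicted_probs = probs, realized = realized,
                 predicted = predicted),
            class = "msm_score_report")
}

#' @export
print.msm_score_report <- function(x, ...) {
  cat(sprintf("Predictive performance at t = %g: %d evaluated, %d excluded (censored)\n",
              x$horizon, x$n_evaluated, x$n_excluded))
  if (!is.null(x$log_score) && !is.na(x$log_score))
    cat(sprintf("  logarithmic score: %.4f\n", x$log_score))
  if (!is.null(x$confusion)) {
    cat("  confusion matrix (rows predicted, columns real):\n")
    print(x$confusion)
    cat("  per-state accuracy:\n")
    print(round(x$accuracy, 3))
  }
  invisible(x)
}

#' A comparison registry of fitted models
#'
#' Stores one labelled row per fitted model (total log likelihood, total
#' AIC, and optionally the log score of a [score_report()]) so that
#' alternative covariate assignments can be compared; the registry can be
#' saved to, and reloaded from, a self-describing JSON file with no loss of
#' numeric precision.
#'
#' @return `msm_registry()` returns an empty registry.
#' @export
msm_registry <- function() {
  structure(new.env(parent = emptyenv()), class = "msm_registry")
}

#' @rdname msm_registry
#' @param registry an `msm_registry`.
#' @param label unique model label; adding a duplicate label is an error.
#' @param fit an [fit_msm()] result.
#' @param score optional [score_report()] for the same model.
#' @export
registry_add <- function(registry, label, fit, score = NULL) {
  stopifnot(inherits(registry, "msm_registry"))
  if (exists(label, envir = registry, inherits = FALSE))
    fail("a model labelled '%s' is already registered", label)
  assign(label, list(label = label,
                     loglik = unname(fit$loglik[["fitted"]]),
                     npar = fit$npar,
                     aic = fit$aic,
                     log_score = if (is.null(score)) NA_real_ else score$log_score,
                     horizon = if (is.null(score)) NA_real_ else score$horizon),
         envir = registry)
  invisible(registry)
}

#' @rdname msm_registry
#' @export
registry_table <- function(registry) {
  stopifnot(inherits(registry, "msm_registry"))
  labs <- sort(ls(registry))
  if (!length(labs))
    return(data.frame(label = character(0), loglik = numeric(0),
                      npar = integer(0), aic = numeric(0),
                      log_score = numeric(0), horizon = numeric(0)))
  out <- do.call(rbind, lapply(labs, function(l) {
    e <- get(l, envir = registry)
    data.frame(label = e$label, loglik = e$loglik, npar = e$npar,
               aic = e$aic, log_score = e$log_score, horizon = e$horizon,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @rdname msm_registry
#' @param path JSON file path.
#' @export
registry_save <- function(registry, path) {
  entries <- lapply(sort(ls(registry)), function(l) get(l, envir = registry))
  # 17 significant digits: doubles survive the JSON round trip exactly
  jsonlite::write_json(list(format = "msmcox-registry", version = 1L,
                            models = entries),
                       path, auto_unbox = TRUE, digits = I(17), na = "null")
  invisible(path)
}

#' @rdname msm_registry
#' @export
registry_load <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(x$format, "msmcox-registry"))
    fail("%s is not a registry file", path)
  reg <- msm_registry()
  for (e in x$models) {
    e$log_score <- e$log_score %||% NA_real_
    e$horizon <- e$horizon %||% NA_real_
    assign(e$label, e, envir = reg)
  }
  reg
}
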