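#' Fit a Cox proportional hazards model for one transition
#'
#' Maximizes the partial likelihood of the episodes of a single transition
#' `k -> l` (competing episodes of other transitions out of `k` act only
#' through censoring), by Newton-Raphson with step halving, to a relative
#' tolerance of 1e-9.  Covariates are centred internally at their
#' transition-specific means for numerical stability; reported coefficients
#' and the Breslow baseline cumulative hazard are on the original covariate
#' scale.  With Breslow tie handling and no covariates the baseline equals
#' the Nelson-Aalen estimator of the transition exactly.
#'
#' @param episodes an `msm_episodes` table (see [expand_to_episodes()]).
#' @param transition `c(from, to)` or a `"from->to"` key.
#' @param covariates character vector of covariate column names (possibly
#'   empty or `NULL` for a null model).  Factor/character columns are
#'   expanded to reference-coded indicators (reference = first sorted
#'   level).
#' @param ties `"breslow"` (default) or `"efron"`.  The baseline hazard is
#'   always of Breslow form.
#' @param tol,max_iter convergence control of the Newton-Raphson iteration.
#' @return An object of class `msm_cox_fit`: coefficients, covariance
#'   (inverse observed information), log partial likelihoods at the estimate
#'   and at zero, Breslow baseline hazard increments, and convergence
#'   diagnostics.
#' @export
fit_transition_cox <- function(episodes, transition, covariates = NULL,
                               ties = c("breslow", "efron"),
                               tol = 1e-9, max_iter = 50L) {
  ties <- match.arg(ties)
  key <- transition_key(transition)
  rows <- episodes[episodes$trans == key, , drop = FALSE]
  if (!nrow(rows)) fail("no episodes for transition %s", key)
  if (length(covariates)) {
    miss <- setdiff(covariates, names(rows))
    if (length(miss)) fail("unknown covariate(s) for %s: %s", key,
                           paste(miss, collapse = ", "))
    cc <- complete.cases(rows[, covariates, drop = FALSE])
    if (!all(cc)) {
      message(sprintf("transition %s: dropping %d episode(s) with missing covariates",
                      key, sum(!cc)))
      rows <- rows[cc, , drop = FALSE]
    }
  }
  nev <- sum(rows$status)
  if (nev == 0L) fail("transition %s has no events; cannot fit", key)

  if (length(covariates)) {
    form <- reformulate(covariates)
    mf <- model.frame(form, rows)
    xlev <- .getXlevels(attr(mf, "terms"), mf)
    mm <- model.matrix(attr(mf, "terms"), mf)
    asn <- attr(mm, "assign")[-1L]
    X <- mm[, -1L, drop = FALSE]
    term_labels <- attr(attr(mf, "terms"), "term.labels")
    source_var <- term_labels[asn]
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
      fail("design for %s is rank deficient; collinear column(s): %s", key,
           paste(bad, collapse = ", "))
    }
  } else {
    form <- NULL; xlev <- NULL; X <- matrix(0, nrow(rows), 0L)
    source_var <- character(0)
  }

  xbar <- if (ncol(X)) colMeans(X) else numeric(0)
  Xc <- if (ncol(X)) sweep(X, 2L, xbar) else X

  eng <- cox_engine(rows$tstart, rows$tstop, rows$status, Xc,
                    ties = ties, tol = tol, max_iter = max_iter)

  # Breslow baseline on the original covariate scale (Z = 0):
  # S0_orig(t) = S0_centred(t) * exp(beta' xbar)
  shift <- if (length(eng$coef)) exp(sum(eng$coef * xbar)) else 1
  h0 <- eng$event$d / (eng$event$S0 * shift)
  baseline <- data.frame(time = eng$event$time, nevent = eng$event$d,
                         hazard = h0, cumhaz = cumsum(h0))

  coefs <- eng$coef
  names(coefs) <- colnames(X)
  vc <- eng$vcov
  dimnames(vc) <- list(colnames(X), colnames(X))

  structure(list(
    transition = split_key(key), trans = key,
    covariates = covariates %||% character(0),
    formula = form, xlev = xlev, source_var = source_var,
    coef = coefs, vcov = vc, se = sqrt(diag(vc)),
    means = xbar,
    loglik = c(null = eng$loglik0, fitted = eng$loglik),
    score0 = eng$score0, info0 = eng$info0,
    n = nrow(rows), nevent = nev,
    baseline = baseline, ties = ties,
    iter = eng$iter, grad_norm = eng$grad_norm, converged = eng$converged,
    event = eng$event),
    class = "msm_cox_fit")
}

#' @export
print.msm_cox_fit <- function(x, ...) {
  cat(sprintf("Cox fit for transition %s: %d episodes, %d events (%s ties)\n",
              x$trans, x$n, x$nevent, x$ties))
  if (length(x$coef)) {
    tab <- data.frame(coef = x$coef, `exp(coef)` = exp(x$coef), se = x$se,
                      z = x$coef / x$se,
                      p = 2 * pnorm(-abs(x$coef / x$se)),
                      check.names = FALSE)
    print(tab, digits = 4)
  } else cat("  null model (no covariates)\n")
  cat(sprintf("  log partial likelihood: %.4f (null %.4f)\n",
              x$loglik["fitted"], x$loglik["null"]))
  invisible(x)
}

#' Fit a Markovian multistate Cox model
#'
#' Fits one Cox model per transition of the graph, each with its own
#' covariate subset.  Under the Markov model the likelihood factorizes over
#' transitions, so the total log likelihood and AIC are sums of the
#' per-transition quantities.  Subjects with missing values in any covariate
#' used anywhere in the model are dropped (complete case) with a message.
#' Transitions with zero events are reported as unfit rather than failing
#' the whole model.
#'
#' @param episodes an `msm_episodes` table.
#' @param graph an [msm_graph].
#' @param covariate_assignment named list keyed by `"from->to"`: covariate
#'   names per transition.  Transitions absent from the list are fitted as
#'   null models.
#' @param ties,tol,max_iter passed to [fit_transition_cox()].
#' @return An object of class `msm_fit`: per-transition fits, the graph, the
#'   assignment, total fitted/null log likelihood and total AIC, and the
#'   keys of unfit (zero-event) transitions.
#' @export
fit_msm <- function(episodes, graph, covariate_assignment = list(),
                    ties = c("breslow", "efron"), tol = 1e-9, max_iter = 50L) {
  stopifnot(inherits(graph, "msm_graph"))
  ties <- match.arg(ties)
  if (!nrow(episodes)) fail("episode table is empty; nothing to fit")
  unknown <- setdiff(names(covariate_assignment), graph$transitions$key)
  if (length(unknown)) fail("covariates assigned to unknown transition(s): %s",
                            paste(unknown, collapse = ", "))
  used <- unique(unlist(covariate_assignment))
  if (length(used)) {
    miss <- setdiff(used, names(episodes))
    if (length(miss)) fail("assigned covariate(s) not in the data: %s",
                           paste(miss, collapse = ", "))
    bad_id <- unique(episodes$id[!complete.cases(episodes[, used, drop = FALSE])])
    if (length(bad_id)) {
      message(sprintf(
        "dropping %d subject(s) with missing values in model covariates",
        length(bad_id)))
      episodes <- episodes[!episodes$id %in% bad_id, , drop = FALSE]
      if (!nrow(episodes)) fail("no subjects left after complete-case filtering")
    }
  }

  fits <- list(); unfit <- character(0)
  for (key in graph$transitions$key) {
    rows <- episodes[episodes$trans == key, , drop = FALSE]
    if (!nrow(rows) || sum(rows$status) == 0L) {
      unfit <- c(unfit, key)
      next
    }
    fits[[key]] <- fit_transition_cox(episodes, key,
                                      covariates = covariate_assignment[[key]],
                                      ties = ties, tol = tol,
                                      max_iter = max_iter)
  }
  loglik <- sum(vapply(fits, function(f) f$loglik[["fitted"]], 0))
  loglik0 <- sum(vapply(fits, function(f) f$loglik[["null"]], 0))
  npar <- sum(vapply(fits, function(f) length(f$coef), 0L))
  structure(list(fits = fits, graph = graph,
                 assignment = covariate_assignment,
                 loglik = c(null = loglik0, fitted = loglik),
                 npar = npar, aic = -2 * loglik + 2 * npar,
                 unfit = unfit, ties = ties),
            class = "msm_fit")
}

#' @export
print.msm_fit <- function(x, ...) {
  cat(sprintf("Multistate Cox model: %d fitted transition(s), %d coefficient(s)\n",
              length(x$fits), x$npar))
  cat(sprintf("  total log likelihood: %.4f (null %.4f), AIC %.4f\n",
              x$loglik["fitted"], x$loglik["null"], x$aic))
  if (length(x$unfit))
    cat("  unfit (zero events):", paste(x$unfit, collapse = ", "), "\n")
  invisible(x)
}

#' Coefficient and hazard-ratio table
#'
#' One row per transition and covariate, in the conventional layout
#' `covar (k -> l)`, with the estimated coefficient, the (optionally
#' rescaled) hazard ratio `exp(c * beta)`, its Wald confidence interval on
#' the log scale, and the unscaled Wald p-value for `beta = 0`.  Rescaling
#' by `c` units (e.g. 10) expresses the risk of a `c`-unit increase of a
#' numeric covariate.
#'
#' @param fit an [msm_fit].
#' @param level confidence level (default 0.95).
#' @param scale named numeric: multiplier per covariate (default 1 for all).
#' @return Data frame `covariate`, `trans`, `scale`, `coef`, `se`, `HR`,
#'   `lower`, `upper`, `p_value`.
#' @export
hazard_ratio_table <- function(fit, level = 0.95, scale = NULL) {
  stopifnot(inherits(fit, "msm_fit"))
  all_vars <- unique(unlist(lapply(fit$fits, `[[`, "source_var")))
  if (length(scale)) {
    unknown <- setdiff(names(scale), all_vars)
    if (length(unknown)) fail("scale given for unknown covariate(s): %s",
                              paste(unknown, collapse = ", "))
  }
  z <- qnorm(1 - (1 - level) / 2)
  rows <- list()
  for (f in fit$fits) {
    if (!length(f$coef)) next
    for (j in seq_along(f$coef)) {
      cl <- if (!is.null(scale) && f$source_var[j] %in% names(scale))
        scale[[f$source_var[j]]] else 1
      b <- f$coef[j]; s <- f$se[j]
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = names(f$coef)[j], trans = f$trans, scale = cl,
        coef = unname(b), se = unname(s),
        HR = exp(cl * b),
        lower = exp(cl * b - z * cl * s),
        upper = exp(cl * b + z * cl * s),
        p_value = 2 * pnorm(-abs(b / s)),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(covariate = character(0), trans = character(0),
                      scale = numeric(0), coef = numeric(0), se = numeric(0),
                      HR = numeric(0), lower = numeric(0), upper = numeric(0),
                      p_value = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Goodness-of-fit tests for one transition
#'
#' Likelihood-ratio, Wald and score tests of the fitted model against the
#' null model of the same transition, each on `p` degrees of freedom
#' (p = number of coefficients) with chi-square upper-tail p-values.
#'
#' @param fit_transition an [fit_transition_cox()] result.
#' @return Data frame `test`, `statistic`, `df`, `p_value`; for a null model
#'   an empty table with a `"note"` attribute.
#' @export
gof_tests <- function(fit_transition) {
  stopifnot(inherits(fit_transition, "msm_cox_fit"))
  p <- length(fit_transition$coef)
  if (p == 0L) {
    out <- data.frame(test = character(0), statistic = numeric(0),
                      df = integer(0), p_value = numeric(0))
    attr(out, "note") <- "null model: no covariates to test"
    return(out)
  }
  lrt <- 2 * (fit_transition$loglik[["fitted"]] - fit_transition$loglik[["null"]])
  wald <- drop(t(fit_transition$coef) %*%
                 solve(fit_transition$vcov, fit_transition$coef))
  score <- drop(t(fit_transition$score0) %*%
                  solve(fit_transition$info0, fit_transition$score0))
  data.frame(test = c("likelihood ratio", "wald", "score"),
             statistic = c(lrt, wald, score),
             df = rep(p, 3L),
             p_value = pchisq(c(lrt, wald, score), df = p, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Per-transition and total AIC
#'
#' `AIC = -2 loglik + 2 p` per transition; the total is the sum, usable to
#' compare non-nested covariate assignments.
#'
#' @param fit an [msm_fit] or a single `msm_cox_fit`.
#' @return Data frame `trans`, `npar`, `loglik`, `AIC` with a final `total`
#'   row for an `msm_fit`.
#' @export
aic_table <- function(fit) {
  one <- function(f) data.frame(trans = f$trans, npar = length(f$coef),
                                loglik = unname(f$loglik[["fitted"]]),
                                AIC = -2 * f$loglik[["fitted"]] + 2 * length(f$coef),
                                stringsAsFactors = FALSE)
  if (inherits(fit, "msm_cox_fit")) return(one(fit))
  stopifnot(inherits(fit, "msm_fit"))
  out <- do.call(rbind, lapply(fit$fits, one))
  out <- rbind(out, data.frame(trans = "total", npar = fit$npar,
                               loglik = unname(fit$loglik[["fitted"]]),
                               AIC = fit$aic, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Likelihood table
#'
#' Fitted and null log partial likelihood per transition (they match for a
#' null model) plus per-transition AIC.
#'
#' @param fit an [msm_fit].
#' @return Data frame `trans`, `loglik_fitted`, `loglik_null`, `npar`, `AIC`.
#' @export
likelihood_table <- function(fit) {
  stopifnot(inherits(fit, "msm_fit"))
  out <- do.call(rbind, lapply(fit$fits, function(f)
    data.frame(trans = f$trans,
               loglik_fitted = unname(f$loglik[["fitted"]]),
               loglik_null = unname(f$loglik[["null"]]),
               npar = length(f$coef),
               AIC = -2 * f$loglik[["fitted"]] + 2 * length(f$coef),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
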