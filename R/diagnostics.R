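# Residual diagnostics for a single transition's Cox fit: linearity
# (martingale), influence (dfbetas), proportional hazards (Schoenfeld).

# rebuild the (uncentred) design matrix and episode rows used by a fit
fit_design <- function(fit, episodes) {
  rows <- episodes[episodes$trans == fit$trans, , drop = FALSE]
  if (length(fit$covariates)) {
    cc <- complete.cases(rows[, fit$covariates, drop = FALSE])
    rows <- rows[cc, , drop = FALSE]
    mf <- model.frame(fit$formula, rows, xlev = fit$xlev)
    X <- model.matrix(attr(mf, "terms"), mf)[, -1L, drop = FALSE]
  } else {
    X <- matrix(0, nrow(rows), 0L)
  }
  if (nrow(rows) != fit$n)
    fail("episode table does not match the one the model was fitted on")
  list(rows = rows, X = X)
}

# cumulative baseline mass (centred scale) over each episode's at-risk
# interval, plus the event-time bookkeeping shared by the residuals
episode_hazard_parts <- function(fit, rows, X) {
  et <- fit$event$time
  h <- fit$event$d / fit$event$S0              # centred-scale increments
  Xc <- if (ncol(X)) sweep(X, 2L, fit$means) else X
  w <- if (ncol(X)) exp(drop(Xc %*% fit$coef)) else rep(1, nrow(rows))
  G0 <- c(0, cumsum(h))
  lookup <- function(t) G0[findInterval(t, et) + 1L]
  dG0 <- lookup(rows$tstop) - lookup(rows$tstart)
  list(et = et, h = h, Xc = Xc, w = w, dG0 = dG0)
}

#' Martingale residuals of a transition fit
#'
#' `r_i = status_i - Lambda0(interval_i) * exp(beta' z_i)` per episode,
#' where the cumulative baseline hazard is accumulated over the episode's
#' own at-risk interval.  Residuals lie in `(-Inf, 1]` and sum to zero at
#' the Breslow-tie estimate.  A loess curve (span 0.75) over each
#' continuous covariate is attached to assess linearity.
#'
#' @param fit an [fit_transition_cox()] result.
#' @param episodes the episode table the fit was computed from.
#' @return Data frame of class `msm_residuals` with `id`, `tstart`, `tstop`,
#'   `status`, `residual` and the fit's covariates; attribute `"smooth"` is
#'   a named list of `(x, y, se)` curves per continuous covariate,
#'   attribute `"kind"` is `"martingale"`.
#' @export
martingale_residuals <- function(fit, episodes) {
  stopifnot(inherits(fit, "msm_cox_fit"))
  d <- fit_design(fit, episodes)
  parts <- episode_hazard_parts(fit, d$rows, d$X)
  res <- d$rows$status - parts$w * parts$dG0
  out <- cbind(d$rows[, c("id", "tstart", "tstop", "status")],
               residual = res)
  if (length(fit$covariates))
    out <- cbind(out, d$rows[, fit$covariates, drop = FALSE])
  smooths <- list()
  for (cv in fit$covariates) {
    x <- d$rows[[cv]]
    if (!is.numeric(x) || length(unique(x)) < 5L) next
    lo <- loess(res ~ x, span = 0.75,
                control = stats::loess.control(surface = "direct"))
    gx <- seq(min(x), max(x), length.out = 50L)
    pr <- predict(lo, newdata = data.frame(x = gx), se = TRUE)
    smooths[[cv]] <- data.frame(x = gx, y = pr$fit, se = pr$se.fit)
  }
  structure(out, kind = "martingale", trans = fit$trans, smooth = smooths,
            class = c("msm_residuals", "data.frame"))
}

#' Standardized influence (dfbetas) of each episode
#'
#' The standardized change of each coefficient when one episode is left
#' out.  The default `"approximate"` method uses the score-residual
#' one-step approximation `dfbeta_i = I(beta)^-1 s_i`, divided by the
#' coefficient's standard error; the `"exact"` method refits the model
#' without each episode and differences the coefficient vectors (kept as a
#' brute-force oracle, refused above `exact_cap` episodes).
#'
#' @param fit an [fit_transition_cox()] result with at least one covariate.
#' @param episodes the episode table the fit was computed from.
#' @param method `"approximate"` (default) or `"exact"`.
#' @param exact_cap refuse the exact method above this many episodes.
#' @return Matrix (episodes x coefficients) of standardized dfbetas, with
#'   attributes `"kind" = "dfbetas"`, `"id"`, `"trans"`, and `"method"`.
#' @export
dfbetas_residuals <- function(fit, episodes,
                              method = c("approximate", "exact"),
                              exact_cap = 2000L) {
  stopifnot(inherits(fit, "msm_cox_fit"))
  method <- match.arg(method)
  p <- length(fit$coef)
  if (!p) fail("dfbetas need at least one fitted covariate")
  d <- fit_design(fit, episodes)
  n <- nrow(d$rows)
  if (method == "exact") {
    if (n > exact_cap)
      fail("exact dfbetas refused for %d episodes (cap %d); use method = \"approximate\"",
           n, exact_cap)
    vals <- matrix(0, n, p)
    for (i in seq_len(n)) {
      sub <- d$rows[-i, , drop = FALSE]
      class(sub) <- class(episodes)
      refit <- fit_transition_cox(sub, fit$trans, fit$covariates,
                                  ties = fit$ties)
      vals[i, ] <- (fit$coef - refit$coef) / fit$se
    }
  } else {
    s <- score_residuals(fit, d$rows, d$X)
    dfb <- s %*% fit$vcov
    vals <- sweep(dfb, 2L, fit$se, "/")
  }
  dimnames(vals) <- list(NULL, names(fit$coef))
  structure(vals, kind = "dfbetas", id = d$rows$id, trans = fit$trans,
            method = method)
}

# per-episode score residuals at beta-hat (centred scale; residuals are
# invariant to centring)
score_residuals <- function(fit, rows, X) {
  parts <- episode_hazard_parts(fit, rows, X)
  et <- parts$et
  zbar <- fit$event$zbar            # event-time risk-set means (centred)
  h <- parts$h
  # cumulative sums of zbar * dLambda0 for interval lookups
  G1 <- rbind(0, apply(zbar * h, 2L, cumsum))
  look1 <- function(t) G1[findInterval(t, et) + 1L, , drop = FALSE]
  dG1 <- look1(rows$tstop) - look1(rows$tstart)
  ev <- rows$status == 1L
  Zev_centered <- parts$Xc
  s <- matrix(0, nrow(rows), ncol(X))
  # event part: Z_i - zbar(T_i) at the episode's event time
  zb_at <- zbar[match(rows$tstop, et), , drop = FALSE]
  s[ev, ] <- Zev_centered[ev, , drop = FALSE] - zb_at[ev, , drop = FALSE]
  # accumulation part over the at-risk interval
  s <- s - parts$w * (Zev_centered * parts$dG0 - dG1)
  s
}

#' Scaled Schoenfeld residuals of a transition fit
#'
#' The unscaled residual at the `j`-th event is `Z_(j) - Zbar(t_j)`: the
#' covariate of the transitioning episode minus the risk-set mean weighted
#' by `exp(beta' z)`.  The scaled residual multiplies it by `d * V(beta)`
#' with `d` the number of events and `V` the coefficient covariance.  Per
#' covariate the residuals sum to zero at the estimate; a systematic trend
#' in time signals non-proportional hazards.  A loess smooth (span 0.75)
#' with a pointwise `+/- 2 se` band and a linear-trend test (slope of
#' residual on event time) are attached.
#'
#' @inheritParams martingale_residuals
#' @param scaled return scaled (default) or unscaled residuals.
#' @return Data frame of class `msm_residuals`: `id`, `time`, one column per
#'   coefficient; attributes `"kind" = "schoenfeld"`, `"smooth"` (per-coef
#'   curves with `se`), and `"trend"` (data frame `covariate`, `slope`,
#'   `p_value`).
#' @export
schoenfeld_residuals <- function(fit, episodes, scaled = TRUE) {
  stopifnot(inherits(fit, "msm_cox_fit"))
  p <- length(fit$coef)
  if (!p) fail("Schoenfeld residuals need at least one fitted covariate")
  d <- fit_design(fit, episodes)
  rows <- d$rows
  ev <- which(rows$status == 1L)
  Xc <- sweep(d$X, 2L, fit$means)
  et <- fit$event$time
  zb <- fit$event$zbar[match(rows$tstop[ev], et), , drop = FALSE]
  r <- Xc[ev, , drop = FALSE] - zb
  if (scaled) r <- fit$nevent * (r %*% fit$vcov)
  dimnames(r) <- list(NULL, names(fit$coef))
  tt <- rows$tstop[ev]
  ord <- order(tt)
  out <- data.frame(id = rows$id[ev][ord], time = tt[ord])
  out <- cbind(out, as.data.frame(r[ord, , drop = FALSE]))

  smooths <- list(); trend <- list()
  for (j in seq_len(p)) {
    y <- r[ord, j]
    x <- tt[ord]
    if (length(unique(x)) >= 4L) {
      lo <- loess(y ~ x, span = 0.75,
                  control = stats::loess.control(surface = "direct"))
      gx <- seq(min(x), max(x), length.out = 50L)
      pr <- predict(lo, newdata = data.frame(x = gx), se = TRUE)
      smooths[[names(fit$coef)[j]]] <- data.frame(x = gx, y = pr$fit,
                                                  se = pr$se.fit)
    } else {
      warning("too few distinct event times to smooth Schoenfeld residuals",
              call. = FALSE)
    }
    if (length(x) >= 3L && sd(x) > 0) {
      fitlm <- lm(y ~ x)
      sm <- summary(fitlm)$coefficients
      trend[[names(fit$coef)[j]]] <- data.frame(
        covariate = names(fit$coef)[j],
        slope = sm["x", "Estimate"], p_value = sm["x", "Pr(>|t|)"],
        stringsAsFactors = FALSE)
    }
  }
  trend_df <- if (length(trend)) do.call(rbind, trend) else
    data.frame(covariate = character(0), slope = numeric(0),
               p_value = numeric(0))
  rownames(trend_df) <- NULL
  structure(out, kind = "schoenfeld", trans = fit$trans, scaled = scaled,
            smooth = smooths, trend = trend_df,
            class = c("msm_residuals", "data.frame"))
}
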