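# Cox partial-likelihood engine for counting-process episodes
# (tstart, tstop] at-risk intervals, Breslow or Efron tie handling,
# Newton-Raphson with step halving.  Internal: the user-facing surface is
# fit_transition_cox() / fit_msm().

# For each time t in `times`, the column sums of W over the risk set
# {i : tstart_i < t <= tstop_i}, via sorted cumulative sums.
risk_sums <- function(times, tstart, tstop, W) {
  W <- as.matrix(W)
  os <- order(tstop)
  oa <- order(tstart)
  cs_stop <- rbind(0, apply(W[os, , drop = FALSE], 2, cumsum))
  cs_start <- rbind(0, apply(W[oa, , drop = FALSE], 2, cumsum))
  i_stop <- findInterval(times, tstop[os], left.open = TRUE)   # #{tstop < t}
  i_start <- findInterval(times, tstart[oa], left.open = TRUE) # #{tstart < t}
  # sum over risk set = sum_{tstart < t} W - sum_{tstop < t} W
  cs_start[i_start + 1L, , drop = FALSE] - cs_stop[i_stop + 1L, , drop = FALSE]
}

# log partial likelihood, score U, observed information I at beta,
# plus per-event-time quantities reused for baselines and residuals.
# X is the (centred) design matrix; may have 0 columns.
cox_plq <- function(beta, tstart, tstop, status, X, ties = "breslow") {
  n <- length(tstop)
  p <- ncol(X)
  ev <- status == 1L
  eta <- if (p) drop(X %*% beta) else numeric(n)
  w <- exp(eta)

  etimes <- sort(unique(tstop[ev]))
  D <- length(etimes)
  grp <- match(tstop[ev], etimes)
  d <- tabulate(grp, nbins = D)

  ij <- if (p) which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE) else NULL
  Wmat <- cbind(w, if (p) w * X,
                if (p) X[, ij[, 1L], drop = FALSE] * X[, ij[, 2L], drop = FALSE] * w)
  RS <- risk_sums(etimes, tstart, tstop, Wmat)
  S0 <- unname(RS[, 1L])
  S1 <- if (p) RS[, 1L + seq_len(p), drop = FALSE] else NULL
  S2c <- if (p) RS[, 1L + p + seq_len(nrow(ij)), drop = FALSE] else NULL

  # per-event-time sums over the tied events themselves (for Efron)
  if (ties == "efron") {
    Wev <- Wmat[ev, , drop = FALSE]
    Dsum <- rowsum(Wev, grp, reorder = TRUE)
    idx <- rep(seq_len(D), d)
    frac <- unlist(lapply(d, function(dd) (seq_len(dd) - 1) / dd), use.names = FALSE)
  } else {
    idx <- rep(seq_len(D), d)
    frac <- numeric(length(idx))
    Dsum <- NULL
  }

  S0k <- S0[idx] - if (is.null(Dsum)) 0 else frac * Dsum[idx, 1L]
  loglik <- sum(eta[ev]) - sum(log(S0k))

  U <- NULL; Info <- NULL
  if (p) {
    S1k <- S1[idx, , drop = FALSE] -
      if (is.null(Dsum)) 0 else frac * Dsum[idx, 1L + seq_len(p), drop = FALSE]
    S2k <- S2c[idx, , drop = FALSE] -
      if (is.null(Dsum)) 0 else frac * Dsum[idx, 1L + p + seq_len(nrow(ij)), drop = FALSE]
    zbar_k <- S1k / S0k
    U <- colSums(X[ev, , drop = FALSE]) - colSums(zbar_k)
    Info <- matrix(0, p, p)
    s2term <- colSums(S2k / S0k)
    cross <- crossprod(zbar_k)          # sum over rows of zbar zbar'
    for (r in seq_len(nrow(ij))) {
      a <- ij[r, 1L]; b <- ij[r, 2L]
      Info[a, b] <- Info[a, b] + s2term[r]
      if (a != b) Info[b, a] <- Info[b, a] + s2term[r]
    }
    Info <- Info - cross
  }

  list(loglik = loglik, U = U, I = Info,
       etimes = etimes, d = d, S0 = S0,
       zbar = if (p) S1 / S0 else NULL,
       w = w)
}

# Newton-Raphson maximization.  X must be centred by the caller.
cox_engine <- function(tstart, tstop, status, X,
                       ties = "breslow", tol = 1e-9, max_iter = 50L) {
  p <- ncol(X)
  q0 <- cox_plq(numeric(p), tstart, tstop, status, X, ties)
  if (p == 0L) {
    return(list(coef = numeric(0), vcov = matrix(0, 0, 0),
                loglik0 = q0$loglik, loglik = q0$loglik,
                score0 = numeric(0), info0 = matrix(0, 0, 0),
                iter = 0L, grad_norm = 0, converged = TRUE,
                event = list(time = q0$etimes, d = q0$d, S0 = q0$S0,
                             zbar = NULL)))
  }
  colsd <- apply(X, 2, sd)
  beta <- numeric(p)
  q <- q0
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(q$I, q$U), error = function(e)
      fail("information matrix is singular at iteration %d", iter))
    beta_new <- beta + step
    q_new <- cox_plq(beta_new, tstart, tstop, status, X, ties)
    halves <- 0L
    while ((!is.finite(q_new$loglik) || q_new$loglik < q$loglik) && halves < 30L) {
      halves <- halves + 1L
      beta_new <- beta + step / 2^halves
      q_new <- cox_plq(beta_new, tstart, tstop, status, X, ties)
    }
    # the log partial likelihood is a product of probabilities (<= 0);
    # a positive value is catastrophic cancellation from a diverging
    # linear predictor, and |beta| * sd(Z) > 10 is a per-SD hazard ratio
    # beyond e^10 -- both signal a perfectly separating covariate
    if (q_new$loglik > 1e-8 || any(abs(beta_new * pmax(colsd, 1e-12)) > 10))
      fail(paste0("monotone partial likelihood (a covariate perfectly ",
                  "separates events); remove it from this transition"))
    done <- abs(q_new$loglik - q$loglik) <= tol * (abs(q$loglik) + tol)
    beta <- beta_new
    q <- q_new
    if (done) { converged <- TRUE; break }
  }
  if (!converged)
    fail("Newton-Raphson did not converge in %d iterations (last loglik %.6f)",
         max_iter, q$loglik)
  vc <- solve(q$I)
  list(coef = beta, vcov = vc,
       loglik0 = q0$loglik, loglik = q$loglik,
       score0 = q0$U, info0 = q0$I,
       iter = iter, grad_norm = sqrt(sum(q$U^2)), converged = converged,
       event = list(time = q$etimes, d = q$d, S0 = q$S0, zbar = q$zbar))
}
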