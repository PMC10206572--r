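#' Read / write wide-format event-history data
#'
#' The wide layout has one row per subject: an `id` column, a `start_state`
#' column (the state occupied at the time origin, day 0), then for every
#' non-initial state `S` of the model a pair `S_time` / `S_status`
#' (`S_status = 1` when the state was entered at `S_time` days, `S_status =
#' 0` when it was not, `S_time` then being the time at which entry into `S`
#' was censored, i.e. the subject's last observation time), followed by
#' baseline covariates.  Comma-separated, header row, UTF-8, missing values
#' as empty fields.
#'
#' @param path file path.
#' @param subjects a wide subject table as produced by [simulate_paths()].
#' @return `read_subjects` returns a data frame; `write_subjects` returns
#'   `path` invisibly.
#' @export
read_subjects <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "start_state") %in% names(x)))
    fail("subject file must have 'id' and 'start_state' columns")
  if (anyDuplicated(x$id)) fail("duplicate subject id(s): %s",
    paste(unique(x$id[duplicated(x$id)]), collapse = ", "))
  x
}

#' @rdname read_subjects
#' @export
write_subjects <- function(subjects, path) {
  write.csv(subjects, path, row.names = FALSE)
  invisible(path)
}

#' Expand wide subject data to counting-process episodes
#'
#' Converts a wide subject table into the long "episode" format on which all
#' estimation is based: one at-risk row per subject and per reachable
#' transition, with `(tstart, tstop, status)`.  While a subject occupies a
#' non-absorbing state, one row per outgoing transition shares the same
#' at-risk interval; the row for the transition actually taken has
#' `status = 1`, all others (the competing transitions, or all rows when the
#' subject is censored in the state) have `status = 0`.
#'
#' A subject's entered states, ordered by entry time, must form a directed
#' path in `graph` starting at `start_state`; entry times must strictly
#' increase (zero-length stays are rejected -- merge or jitter pass-through
#' states before import).
#'
#' @param subjects wide subject table (see [read_subjects()]).
#' @param graph an [msm_graph].
#' @return A data frame of class `msm_episodes` with columns `id`, `from`,
#'   `to`, `trans` (transition key), `tstart`, `tstop`, `status`, plus all
#'   covariate columns.
#' @examples
#' fx <- make_fixture("toy-3-subjects")
#' expand_to_episodes(fx$subjects, fx$graph)
#' @export
expand_to_episodes <- function(subjects, graph) {
  stopifnot(inherits(graph, "msm_graph"))
  non_initial <- graph$states[graph$roles != "initial"]
  need <- c(paste0(non_initial, "_time"), paste0(non_initial, "_status"))
  miss <- setdiff(need, names(subjects))
  if (length(miss)) fail("missing column(s) in subject table: %s",
                         paste(miss, collapse = ", "))
  covars <- setdiff(names(subjects), c("id", "start_state", need))

  n <- nrow(subjects)
  time_m <- as.matrix(subjects[, paste0(non_initial, "_time"), drop = FALSE])
  stat_m <- as.matrix(subjects[, paste0(non_initial, "_status"), drop = FALSE])
  ids <- subjects$id
  starts <- subjects$start_state
  # outgoing transitions per state, in declaration order
  out_to <- lapply(graph$states, function(s)
    graph$transitions$to[graph$transitions$from == s])
  out_key <- lapply(graph$states, function(s)
    graph$transitions$key[graph$transitions$from == s])
  names(out_to) <- names(out_key) <- graph$states
  absorbing <- graph$roles == "absorbing"
  edge_keys <- graph$transitions$key

  acc <- vector("list", n)
  counts <- integer(n)
  for (i in seq_len(n)) {
    id <- ids[i]; start <- starts[i]
    if (!start %in% graph$states)
      fail("subject %s: unknown start state '%s'", id, start)
    ent <- which(stat_m[i, ] == 1L & non_initial != start)
    ent_states <- non_initial[ent]; ent_times <- time_m[i, ent]
    ord <- order(ent_times)
    ent_states <- ent_states[ord]; ent_times <- ent_times[ord]
    if (length(ent_times) && any(ent_times <= 0))
      fail("subject %s: non-positive entry time into %s", id,
           ent_states[which(ent_times <= 0)[1L]])
    if (anyDuplicated(ent_times))
      fail("subject %s: tied entry times (zero-length stay) at t=%g", id,
           ent_times[duplicated(ent_times)][1L])
    path_states <- c(start, ent_states)
    path_times <- c(0, ent_times)
    m <- length(path_states)
    if (m > 1L) {
      steps <- paste0(path_states[-m], "->", path_states[-1L])
      bad <- which(!steps %in% edge_keys)
      if (length(bad))
        fail("subject %s: step %s is not a transition of the model", id,
             steps[bad[1L]])
    }
    last <- path_states[m]
    if (absorbing[[last]]) {
      cens_time <- NA_real_
    } else {
      unent <- !(non_initial %in% path_states)
      if (!any(unent))
        fail("subject %s: censored in %s but no censoring time is recoverable",
             id, last)
      cens_time <- max(time_m[i, unent])
      if (cens_time <= path_times[m])
        fail("subject %s: censoring time %g not after entry into %s", id,
             cens_time, last)
    }
    from_v <- character(0); to_v <- character(0); key_v <- character(0)
    t0_v <- numeric(0); t1_v <- numeric(0); st_v <- integer(0)
    for (j in seq_len(m)) {
      s <- path_states[j]
      if (absorbing[[s]]) break
      tos <- out_to[[s]]
      tstop <- if (j < m) path_times[j + 1L] else cens_time
      taken <- if (j < m) path_states[j + 1L] else NA_character_
      from_v <- c(from_v, rep(s, length(tos)))
      to_v <- c(to_v, tos)
      key_v <- c(key_v, out_key[[s]])
      t0_v <- c(t0_v, rep(path_times[j], length(tos)))
      t1_v <- c(t1_v, rep(tstop, length(tos)))
      st_v <- c(st_v, as.integer(!is.na(taken) & tos == taken))
    }
    counts[i] <- length(from_v)
    acc[[i]] <- list(from_v, to_v, key_v, t0_v, t1_v, st_v)
  }
  if (sum(counts) == 0L) {
    ep <- data.frame(id = ids[0], from = character(0), to = character(0),
                     trans = character(0), tstart = numeric(0),
                     tstop = numeric(0), status = integer(0),
                     stringsAsFactors = FALSE)
    class(ep) <- c("msm_episodes", "data.frame")
    return(ep)
  }
  ep <- data.frame(
    id = rep(ids, counts),
    from = unlist(lapply(acc, `[[`, 1L)),
    to = unlist(lapply(acc, `[[`, 2L)),
    trans = unlist(lapply(acc, `[[`, 3L)),
    tstart = unlist(lapply(acc, `[[`, 4L)),
    tstop = unlist(lapply(acc, `[[`, 5L)),
    status = unlist(lapply(acc, `[[`, 6L)),
    stringsAsFactors = FALSE)
  if (length(covars))
    ep <- cbind(ep, subjects[rep(seq_len(n), counts), covars, drop = FALSE])
  rownames(ep) <- NULL
  class(ep) <- c("msm_episodes", "data.frame")
  ep
}

#' Per-transition event and at-risk counts
#'
#' @param episodes an `msm_episodes` table.
#' @return Data frame with one row per transition present in the episode
#'   table: `trans`, `nevent` (status-1 rows; equal to the number of
#'   individuals making the transition, since loops are excluded) and
#'   `nrisk` (distinct subjects ever at risk for the transition).
#' @export
transition_counts <- function(episodes) {
  keys <- unique(episodes$trans)
  data.frame(
    trans = keys,
    nevent = vapply(keys, function(k)
      sum(episodes$status[episodes$trans == k]), 0L),
    nrisk = vapply(keys, function(k)
      length(unique(episodes$id[episodes$trans == k])), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Events-per-variable check
#'
#' Flags transitions whose event count is below five events per estimated
#' coefficient, the usual rule of thumb for stable Cox estimation.  Fitting
#' is never blocked, only flagged.
#'
#' @param counts output of [transition_counts()].
#' @param covariate_assignment named list keyed by transition: character
#'   vectors of covariate names assigned to that transition.
#' @param subjects optional subject table used to count the coefficients of
#'   categorical covariates (number of non-reference levels); without it
#'   every covariate counts as one coefficient.
#' @return Data frame `trans`, `nevent`, `ncoef`, `required`, `warned`.
#' @export
epv_check <- function(counts, covariate_assignment, subjects = NULL) {
  ncoef_of <- function(cv) {
    if (!is.null(subjects) && cv %in% names(subjects) &&
        (is.factor(subjects[[cv]]) || is.character(subjects[[cv]]))) {
      max(length(unique(stats::na.omit(subjects[[cv]]))) - 1L, 0L)
    } else 1L
  }
  ncoef <- vapply(counts$trans, function(k) {
    cvs <- covariate_assignment[[k]]
    if (is.null(cvs)) 0L else sum(vapply(cvs, ncoef_of, 0L))
  }, 0L)
  out <- data.frame(trans = counts$trans, nevent = counts$nevent,
                    ncoef = ncoef, required = 5L * ncoef,
                    warned = counts$nevent < 5L * ncoef,
                    row.names = NULL, stringsAsFactors = FALSE)
  for (i in which(out$warned))
    warning(sprintf(
      "transition %s has %d events for %d coefficient(s); at least %d advised",
      out$trans[i], out$nevent[i], out$ncoef[i], out$required[i]), call. = FALSE)
  out
}

#' Length of stay in initial and transient states
#'
#' Five-number summaries of the time spent in each non-absorbing state, with
#' outliers flagged by the 1.5 * IQR rule (quartiles of type 7).
#'
#' @param subjects wide subject table.
#' @param graph an [msm_graph].
#' @param uncensored_only when `TRUE` (default) only stays that ended in a
#'   transition are summarized; when `FALSE`, stays cut short by censoring
#'   are included at their observed length.
#' @return Data frame with one row per initial/transient state: `state`,
#'   `n`, `whisker_low`, `q1`, `median`, `q3`, `whisker_high`, `n_outliers`;
#'   attribute `"outliers"` lists `(state, id, stay)` beyond the fences.
#'   States never visited yield `n = 0` rows.
#' @export
length_of_stay <- function(subjects, graph, uncensored_only = TRUE) {
  ep <- expand_to_episodes(subjects, graph)
  states <- graph$states[graph$roles != "absorbing"]
  res <- list(); outl <- list()
  for (s in states) {
    rows <- ep[ep$from == s, , drop = FALSE]
    # one stay per subject: shared (tstart, tstop) across competing rows
    per <- unique(rows[, c("id", "tstart", "tstop")])
    completed <- vapply(seq_len(nrow(per)), function(i) {
      any(rows$status[rows$id == per$id[i] & rows$tstart == per$tstart[i]] == 1L)
    }, TRUE)
    if (uncensored_only) per <- per[completed, , drop = FALSE]
    stays <- per$tstop - per$tstart
    if (!length(stays)) {
      res[[s]] <- data.frame(state = s, n = 0L, whisker_low = NA_real_,
                             q1 = NA_real_, median = NA_real_, q3 = NA_real_,
                             whisker_high = NA_real_, n_outliers = 0L,
                             stringsAsFactors = FALSE)
      next
    }
    q <- unname(quantile(stays, c(.25, .5, .75), type = 7))
    iqr <- q[3L] - q[1L]
    lo_f <- q[1L] - 1.5 * iqr; hi_f <- q[3L] + 1.5 * iqr
    out_idx <- which(stays < lo_f | stays > hi_f)
    inr <- stays[stays >= lo_f & stays <= hi_f]
    res[[s]] <- data.frame(state = s, n = length(stays),
                           whisker_low = min(inr), q1 = q[1L],
                           median = q[2L], q3 = q[3L],
                           whisker_high = max(inr),
                           n_outliers = length(out_idx),
                           stringsAsFactors = FALSE)
    if (length(out_idx))
      outl[[s]] <- data.frame(state = s, id = per$id[out_idx],
                              stay = stays[out_idx], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "outliers") <- if (length(outl)) {
    o <- do.call(rbind, outl); rownames(o) <- NULL; o
  } else data.frame(state = character(0), id = integer(0), stay = numeric(0))
  out
}

#' Filter subjects by a covariate predicate
#'
#' @param subjects wide subject table.
#' @param expr an unquoted logical expression over covariate columns, e.g.
#'   `wave == 5`.  Every variable used must be a column of `subjects`.
#' @return The matching row subset (rows where the predicate is `NA` are
#'   dropped).
#' @export
filter_subjects <- function(subjects, expr) {
  e <- substitute(expr)
  vars <- all.vars(e)
  unknown <- setdiff(vars, names(subjects))
  if (length(unknown)) fail("predicate uses unknown covariate(s): %s",
                            paste(unknown, collapse = ", "))
  keep <- eval(e, subjects, parent.frame())
  if (length(keep) == 1L) keep <- rep(keep, nrow(subjects))
  out <- subjects[keep %in% TRUE, , drop = FALSE]
  rownames(out) <- NULL
  out
}
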