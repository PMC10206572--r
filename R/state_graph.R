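#' Define a multistate transition structure
#'
#' Builds the labelled directed graph of states and transitions that every
#' other function in the package consumes.  State roles are derived from the
#' edge set: a state with in-degree 0 is *initial*, a state with out-degree 0
#' is *absorbing*, and any other state is *transient*.  The graph must be
#' acyclic -- an individual can never traverse the same transition twice --
#' and must contain at least one absorbing state so that follow-up horizons
#' are meaningful.  Isolated states (in no transition at all) are rejected
#' rather than given an ambiguous role.
#'
#' @param states character vector of unique state labels.  Internal state
#'   indices follow this declaration order, so all outputs are reported in
#'   the user's ordering.
#' @param transitions the directed transitions, as a list of length-2
#'   character vectors, a two-column matrix/data frame, or a character vector
#'   of `"from->to"` strings.  Self-transitions and duplicates are rejected.
#' @return An object of class `msm_graph`: a list with elements `states`,
#'   `transitions` (data frame `from`, `to`, `key`, indexed in declaration
#'   order), and `roles` (named character vector,
#'   `"initial"`/`"transient"`/`"absorbing"`).
#' @examples
#' g <- msm_graph(c("healthy", "ill", "dead"),
#'                list(c("healthy", "ill"), c("healthy", "dead"),
#'                     c("ill", "dead")))
#' g$roles
#' @export
msm_graph <- function(states, transitions) {
  states <- as.character(states)
  if (anyDuplicated(states)) fail("duplicate state labels: %s",
    paste(unique(states[duplicated(states)]), collapse = ", "))
  tr <- normalize_transitions(transitions)
  unknown <- setdiff(c(tr$from, tr$to), states)
  if (length(unknown)) fail("transition endpoint(s) not declared as states: %s",
    paste(unique(unknown), collapse = ", "))
  if (any(tr$from == tr$to)) {
    bad <- tr[tr$from == tr$to, ][1L, ]
    fail("self-transition not allowed: %s->%s", bad$from, bad$to)
  }
  tr$key <- paste0(tr$from, "->", tr$to)
  if (anyDuplicated(tr$key)) fail("duplicate transition(s): %s",
    paste(unique(tr$key[duplicated(tr$key)]), collapse = ", "))

  cyc <- find_cycle(states, tr)
  if (!is.null(cyc)) fail("transition structure contains a cycle: %s",
    paste(cyc, collapse = " -> "))

  indeg <- table(factor(tr$to, levels = states))
  outdeg <- table(factor(tr$from, levels = states))
  isolated <- states[indeg == 0L & outdeg == 0L]
  if (length(isolated)) fail(
    "state(s) in no transition (would be both initial and absorbing): %s",
    paste(isolated, collapse = ", "))

  roles <- setNames(ifelse(indeg == 0L, "initial",
                           ifelse(outdeg == 0L, "absorbing", "transient"))[
                      seq_along(states)],
                    states)
  dim(roles) <- NULL
  names(roles) <- states
  if (!any(roles == "absorbing"))
    fail("the model needs at least one absorbing state")

  rownames(tr) <- NULL
  structure(list(states = states,
                 transitions = tr[, c("from", "to", "key")],
                 roles = roles),
            class = "msm_graph")
}

normalize_transitions <- function(transitions) {
  if (is.data.frame(transitions)) {
    tr <- data.frame(from = as.character(transitions[[1L]]),
                     to = as.character(transitions[[2L]]),
                     stringsAsFactors = FALSE)
  } else if (is.matrix(transitions)) {
    tr <- data.frame(from = as.character(transitions[, 1L]),
                     to = as.character(transitions[, 2L]),
                     stringsAsFactors = FALSE)
  } else if (is.character(transitions)) {
    parts <- lapply(transitions, split_key)
    tr <- data.frame(from = vapply(parts, `[`, "", 1L),
                     to = vapply(parts, `[`, "", 2L),
                     stringsAsFactors = FALSE)
  } else if (is.list(transitions)) {
    keyish <- vapply(transitions, function(x)
      is.character(x) && length(x) == 1L && grepl("->", x, fixed = TRUE), TRUE)
    if (all(keyish)) return(normalize_transitions(unlist(transitions)))
    bad <- vapply(transitions, function(x) length(x) != 2L, TRUE)
    if (any(bad)) fail("every transition must name exactly two states")
    tr <- data.frame(from = vapply(transitions, function(x) as.character(x[[1L]]), ""),
                     to = vapply(transitions, function(x) as.character(x[[2L]]), ""),
                     stringsAsFactors = FALSE)
  } else fail("unsupported transitions format")
  if (nrow(tr) == 0L) fail("at least one transition is required")
  tr
}

# Kahn topological elimination; on failure a cycle is recovered by walking
# successors inside the irreducible remainder.
find_cycle <- function(states, tr) {
  remaining <- states
  edges <- tr
  repeat {
    indeg <- table(factor(edges$to, levels = remaining))
    src <- remaining[indeg == 0L]
    if (!length(src)) break
    remaining <- setdiff(remaining, src)
    edges <- edges[!(edges$from %in% src), , drop = FALSE]
    if (!length(remaining)) return(NULL)
  }
  # every remaining node has an incoming edge within `remaining`: walk until repeat
  succ <- function(s) edges$to[edges$from == s][1L]
  path <- remaining[1L]
  repeat {
    nxt <- succ(path[length(path)])
    if (nxt %in% path) {
      cyc <- c(path[which(path == nxt):length(path)], nxt)
      return(cyc)
    }
    path <- c(path, nxt)
  }
}

#' Remove a transition from a graph
#'
#' Returns a new graph without the given transition; roles are recomputed
#' from the remaining edge set and any state left in no transition is
#' dropped.  This mirrors pruning transitions with too few events before
#' model fitting.
#'
#' @param graph an [msm_graph].
#' @param from,to state labels of the transition to remove, or `from` may be
#'   a single `"from->to"` key with `to` missing.
#' @return A new `msm_graph`.
#' @export
remove_transition <- function(graph, from, to) {
  stopifnot(inherits(graph, "msm_graph"))
  key <- if (missing(to)) transition_key(from) else transition_key(c(from, to))
  if (!key %in% graph$transitions$key)
    fail("transition %s is not in the graph", key)
  tr <- graph$transitions[graph$transitions$key != key, , drop = FALSE]
  keep <- graph$states[graph$states %in% c(tr$from, tr$to)]
  msm_graph(keep, tr[, c("from", "to")])
}

#' @export
print.msm_graph <- function(x, ...) {
  cat("Multistate structure:", length(x$states), "states,",
      nrow(x$transitions), "transitions\n")
  for (role in c("initial", "transient", "absorbing")) {
    s <- names(x$roles)[x$roles == role]
    if (length(s)) cat(sprintf("  %-9s %s\n", paste0(role, ":"),
                               paste(s, collapse = ", ")))
  }
  cat("  edges:   ", paste(x$transitions$key, collapse = ", "), "\n")
  invisible(x)
}

# transitions leaving a state, in declaration order
out_transitions <- function(graph, state) {
  graph$transitions[graph$transitions$from == state, , drop = FALSE]
}

is_absorbing <- function(graph, state) graph$roles[[state]] == "absorbing"
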