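# small shared helpers

#' Canonical transition label
#'
#' Transitions are identified throughout the package by the string
#' `"from->to"`.  This helper accepts a length-2 character vector, a
#' one-row two-column structure, or an already-formatted key.
#'
#' @param transition character vector `c(from, to)` or a `"from->to"` string.
#' @return A single string `"from->to"`.
#' @export
transition_key <- function(transition) {
  if (is.character(transition) && length(transition) == 1L) {
    if (!grepl("->", transition, fixed = TRUE))
      stop("transition must be \"from->to\" or c(from, to)", call. = FALSE)
    return(transition)
  }
  transition <- as.character(unlist(transition))
  if (length(transition) != 2L)
    stop("transition must have exactly two states", call. = FALSE)
  paste0(transition[1L], "->", transition[2L])
}

split_key <- function(key) {
  parts <- strsplit(key, "->", fixed = TRUE)[[1L]]
  if (length(parts) != 2L) stop("malformed transition key: ", key, call. = FALSE)
  parts
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# stop() with sprintf-style formatting, never showing the call
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
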