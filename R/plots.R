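# Base-graphics visualizations mirroring the usual multistate displays.

#' Plot state-occupancy curves
#'
#' Non-stacked (one line per state) or stacked (cumulative shaded bands)
#' occupancy probabilities over time for one predicted profile.
#'
#' @param x an [occupancy()] result.
#' @param stacked draw stacked bands instead of lines.
#' @param col colours, one per state.
#' @param ... passed to the underlying plot call.
#' @export
plot.msm_occupancy <- function(x, stacked = FALSE,
                               col = grDevices::hcl.colors(
                                 length(unique(x$curve$state)), "Dark 3"),
                               ...) {
  states <- unique(x$curve$state)
  wide <- sapply(states, function(s)
    x$curve$prob[x$curve$state == s])
  tt <- x$curve$time[x$curve$state == states[1L]]
  if (stacked) {
    cum <- apply(wide, 1L, cumsum)          # states x time
    graphics::plot(range(tt), c(0, 1), type = "n", xlab = "time (days)",
                   ylab = "occupancy probability", ...)
    lower <- rep(0, length(tt))
    for (j in seq_along(states)) {
      upper <- cum[j, ]
      graphics::polygon(c(tt, rev(tt)), c(lower, rev(upper)),
                        col = col[j], border = NA)
      lower <- upper
    }
  } else {
    graphics::matplot(tt, wide, type = "s", lty = 1, col = col,
                      xlab = "time (days)", ylab = "occupancy probability",
                      ylim = c(0, 1), ...)
  }
  graphics::legend("topright", legend = states, col = col,
                   lty = 1, lwd = if (stacked) 6 else 1, bty = "n")
  invisible(x)
}

#' Plot a Nelson-Aalen cumulative intensity
#'
#' @param x an [nelson_aalen()] result.
#' @param ... passed to `plot`.
#' @export
plot.msm_hazard <- function(x, ...) {
  graphics::plot(c(0, x$time), c(0, x$cumhaz), type = "s",
                 xlab = "time (days)", ylab = "cumulative intensity",
                 main = attr(x, "trans"), ...)
  invisible(x)
}

#' Diagram of a multistate structure
#'
#' States on a circle, arrows along the declared transitions, colour-coded
#' by role (initial, transient, absorbing).
#'
#' @param x an [msm_graph].
#' @param ... ignored.
#' @export
plot.msm_graph <- function(x, ...) {
  R <- length(x$states)
  th <- pi / 2 - 2 * pi * (seq_len(R) - 1L) / R
  px <- cos(th); py <- sin(th)
  role_col <- c(initial = "#E69F00", transient = "#56B4E9",
                absorbing = "#9966CC")
  graphics::plot(px, py, xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4),
                 axes = FALSE, xlab = "", ylab = "", pch = 21, cex = 5,
                 bg = role_col[x$roles])
  for (i in seq_len(nrow(x$transitions))) {
    a <- match(x$transitions$from[i], x$states)
    b <- match(x$transitions$to[i], x$states)
    dx <- px[b] - px[a]; dy <- py[b] - py[a]
    len <- sqrt(dx^2 + dy^2)
    sh <- 0.18 / len
    graphics::arrows(px[a] + dx * sh, py[a] + dy * sh,
                     px[b] - dx * sh, py[b] - dy * sh,
                     length = 0.08, col = "grey30")
  }
  graphics::text(px * 1.22, py * 1.22, x$states, cex = 0.9)
  invisible(x)
}
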