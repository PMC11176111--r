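#' Plot methods
#'
#' Base-graphics views of the package objects: time series for
#' trajectories, bifurcation diagrams for equilibrium and periodic-orbit
#' branches (solid/dashed for stable/unstable, following the usual
#' convention), parameter-plane curves for two-parameter Hopf curves and
#' regime maps.
#'
#' @param x the object.
#' @param vars trajectory columns to draw (default `"c"`).
#' @param ... passed to [graphics::plot()].
#' @return the object, invisibly.
#' @export
plot.ca_trajectory <- function(x, vars = "c", ...) {
  plot(x$time, x[[vars[1]]], type = "l", xlab = "time (s)",
       ylab = paste(vars, collapse = ", "), ...)
  if (length(vars) > 1)
    for (i in seq_along(vars)[-1])
      lines(x$time, x[[vars[i]]], lty = i)
  invisible(x)
}

#' @rdname plot.ca_trajectory
#' @param po optional `ca_po_branch` overlaid on an equilibrium diagram.
#' @export
plot.ca_eq_branch <- function(x, po = NULL, ...) {
  pn <- attr(x, "par_name")
  yl <- range(x$c, if (!is.null(po)) c(po$c_max, po$c_min))
  plot(x[[pn]], x$c, type = "n", xlab = pn, ylab = "c (uM)", ylim = yl, ...)
  st <- x$stable
  lines(x[[pn]][st], x$c[st], lwd = 2)
  lines(x[[pn]][!st], x$c[!st], lty = 2)
  pts <- attr(x, "points")
  if (nrow(pts)) points(pts$par, pts$c, pch = 19)
  if (!is.null(po)) {
    for (col in c("c_max", "c_min")) {
      lines(po[[pn]][po$stable], po[[col]][po$stable], lwd = 2, col = 2)
      lines(po[[pn]][!po$stable], po[[col]][!po$stable], lty = 2, col = 2)
    }
  }
  invisible(x)
}

#' @rdname plot.ca_trajectory
#' @export
plot.ca_hopf_curve <- function(x, ...) {
  p1 <- attr(x, "p1_name"); p2 <- attr(x, "p2_name")
  plot(x[[p1]], x[[p2]], type = "l", xlab = p1, ylab = p2, ...)
  invisible(x)
}

#' @rdname plot.ca_trajectory
#' @export
plot.ca_region_map <- function(x, ...) {
  p1 <- attr(x, "p1_name"); p2 <- attr(x, "p2_name")
  regs <- sort(unique(x$regime))
  cols <- setNames(seq_along(regs) + 1, regs)
  plot(x[[p1]], x[[p2]], pch = 15, col = cols[x$regime],
       xlab = p1, ylab = p2, ...)
  legend("topright", legend = regs, col = cols, pch = 15, cex = 0.8)
  invisible(x)
}
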