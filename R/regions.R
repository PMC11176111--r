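# Regime occupancy maps in two-parameter planes, and the analysis of the
# overlap between the CRAC-mediated and IP3R-mediated oscillatory
# regions in the (delta, V_PLC) plane.

#' Regime occupancy grid in a two-parameter plane
#'
#' Simulates the model from its unstimulated equilibrium at every node of
#' a parameter grid and labels the attractor with [classify_regime()].
#' Used to determine which side of a Hopf curve is oscillatory and to
#' find intersections of oscillatory regions.
#'
#' @param params a [ca_params()] object (values of the gridded
#'   parameters are overridden).
#' @param p1_name,p1_grid,p2_name,p2_grid parameter names and grid values
#'   (at most 100 points each).
#' @param model `"open"` or `"closed"`.
#' @param t_end,dt_out integration horizon and sampling per cell.
#' @param transient_fraction passed to [oscillation_features()].
#' @return a data frame of class `ca_region_map` with columns `p1_name`,
#'   `p2_name`, `regime`, `period`, `amplitude`, `s_max_fraction`; cells
#'   whose integration fails are labelled `"failed"`.
#' @examples
#' \donttest{
#' p <- ca_params()
#' rm <- region_map(p, "delta", c(0.01, 2), "V_PLC", c(0.05, 0.1, 0.2),
#'                  t_end = 300)
#' }
#' @export
region_map <- function(params, p1_name, p1_grid, p2_name, p2_grid,
                       model = c("open", "closed"),
                       t_end = 400, dt_out = 0.05,
                       transient_fraction = 0.5) {
  model <- match.arg(model)
  stopifnot(length(p1_grid) <= 100, length(p2_grid) <= 100)
  grid <- expand.grid(a = p1_grid, b = p2_grid)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    pl <- params
    pl[[p1_name]] <- grid$a[i]
    pl[[p2_name]] <- grid$b[i]
    out <- tryCatch({
      tr <- ca_integrate(pl, t_end = t_end, dt_out = dt_out, model = model)
      ft <- oscillation_features(tr, pl,
                                 transient_fraction = transient_fraction)
      data.frame(regime = ft$regime,
                 period = ft$period,
                 amplitude = ft$amplitude_ptp,
                 s_max_fraction = ft$s_max_fraction)
    }, error = function(e)
      data.frame(regime = "failed", period = NA_real_,
                 amplitude = NA_real_, s_max_fraction = NA_real_))
    out
  })
  df <- cbind(setNames(grid, c(p1_name, p2_name)), do.call(rbind, res))
  structure(df, class = c("ca_region_map", "data.frame"),
            p1_name = p1_name, p2_name = p2_name, model = model)
}

#' Overlap of the CRAC- and spike-type oscillatory regions
#'
#' The open-cell model has two families of oscillation in the
#' `(delta, V_PLC)` plane: CRAC-mediated cycles at plasma-membrane
#' transport rates `delta` of order one and IP3R-mediated spikes near
#' `delta = 0`, each bounded by its own Hopf curve.  This function
#' continues both Hopf-point families in `(delta, V_PLC)` (seeding them
#' from one-parameter sweeps at a high and a low `delta`) and measures,
#' slice by slice in `V_PLC`, the `delta` intervals enclosed by each
#' curve.  It reports whether the two regions overlap and the smallest
#' `delta` at which they do.
#'
#' @param params a [ca_params()] object (set `K_e` as desired; at the
#'   reference 800 uM the regions are disjoint, at 400 uM they overlap).
#' @param delta_hi a `delta` value safely inside the CRAC family.
#' @param delta_lo a `delta` value near 0 inside the spike family.
#' @param V_range `V_PLC` window for the one-parameter sweeps.
#' @param delta_box `delta` window for the two-parameter continuation.
#' @param n_slices number of `V_PLC` slices for the overlap measurement.
#' @param ... passed to [continue_hopf_2par()].
#' @return a list of class `ca_region_overlap`: logical `overlap`,
#'   `delta_intersect` (smallest overlapping `delta`, `NA` if disjoint),
#'   `V_PLC_at_intersect`, and the two Hopf curves (`crac_curve`,
#'   `spike_curve`).
#' @export
region_overlap_delta <- function(params, delta_hi = 2, delta_lo = 0.01,
                                 V_range = c(0.01, 0.45),
                                 delta_box = c(1e-4, 3),
                                 n_slices = 201, ...) {
  box <- c(V_range[1], V_range[2], delta_box[1], delta_box[2])
  curves <- lapply(c(delta_hi, delta_lo), function(d0) {
    pl <- set_params(params, delta = d0, V_PLC = V_range[1])
    br <- continue_equilibria(pl, "V_PLC", V_range, model = "open",
                              step0 = 0.01, max_step = 0.05)
    hb <- branch_points(br, "HB")
    if (!nrow(hb))
      stop("region_overlap_delta: no Hopf point found at delta = ", d0)
    continue_hopf_2par(pl, "V_PLC", "delta", hb[1, ], box = box,
                       model = "open", ...)
  })
  crac <- curves[[1]]; spike <- curves[[2]]

  # per-V_PLC slice: delta levels at which each Hopf curve is crossed.
  # The CRAC region lies above its curve (high delta), the spike region
  # between delta = 0 and its curve, so at a slice the regions overlap
  # when min(crac crossings) <= max(spike crossings).
  vs <- seq(V_range[1], V_range[2], length.out = n_slices)
  crossings_at <- function(curve, v) {
    x <- curve$V_PLC; y <- curve$delta
    hits <- numeric(0)
    for (i in seq_len(length(x) - 1)) {
      if ((x[i] - v) * (x[i + 1] - v) <= 0 && x[i] != x[i + 1]) {
        w <- (v - x[i]) / (x[i + 1] - x[i])
        hits <- c(hits, y[i] + w * (y[i + 1] - y[i]))
      }
    }
    hits
  }
  best <- NULL
  for (v in vs) {
    hc <- crossings_at(crac, v)
    hs <- crossings_at(spike, v)
    if (!length(hc) || !length(hs)) next
    lo_crac <- min(hc)
    hi_spike <- max(hs)
    if (lo_crac <= hi_spike) {
      cand <- list(delta = lo_crac, V = v)
      if (is.null(best) || cand$delta < best$delta) best <- cand
    }
  }
  structure(list(overlap = !is.null(best),
                 delta_intersect = if (is.null(best)) NA_real_ else best$delta,
                 V_PLC_at_intersect = if (is.null(best)) NA_real_ else best$V,
                 crac_curve = crac, spike_curve = spike),
            class = "ca_region_overlap")
}

#' @export
print.ca_region_overlap <- function(x, ...) {
  if (x$overlap)
    cat(sprintf("oscillatory regions overlap; first contact at delta = %.3f (V_PLC = %.3f)\n",
                x$delta_intersect, x$V_PLC_at_intersect))
  else cat("oscillatory regions are disjoint in the scanned window\n")
  invisible(x)
}
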