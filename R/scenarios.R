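# Scripted reproduction of the model's reference figures as data.
#
# Each pipeline is fully determined by its configuration; outputs are
# CSV files plus a JSON summary of the checkable quantities (periods,
# amplitudes, detected bifurcation points).  Rendering is left to the
# plot methods.

.figure_ids <- c("3A", "3B", "3C", "3D", "4", "5A", "5B", "5C", "5D",
                 "5F", "6", "7", "8A", "8C", "8E", "9", "10", "11", "12")

#' Reproduce a reference figure's underlying data
#'
#' Runs the simulation/continuation pipeline behind one of the model's
#' reference figures and returns (and optionally writes) its data and a
#' summary of the checkable quantities.  Supported ids:
#' \describe{
#'   \item{3A-3D}{the four oscillation regimes (CRAC-mediated,
#'     narrow spike, wide spike, wide spike with oscillatory plateau).}
#'   \item{4}{open-cell bifurcation diagram in `V_PLC` at `delta = 2`
#'     plus the `V_PLC = 0.1` attractor traces.}
#'   \item{5A, 5C}{one-parameter diagrams in `s1` and `tau_s`.}
#'   \item{5B, 5D, 5F}{two-parameter Hopf curves in the `s1-V_PLC`,
#'     `tau_s-V_PLC` and `s1-tau_s` planes.}
#'   \item{6}{IP3R open-probability comparison between the CRAC cycle
#'     and a narrow spike.}
#'   \item{7}{ER-load scenarios (transient spiking).}
#'   \item{8A, 8C, 8E}{closed-cell diagrams at `C_t` = 140, 95, 75 with
#'     periodic-orbit branches and their bifurcations.}
#'   \item{9}{closed-cell two-parameter bifurcation set in
#'     `(V_PLC, C_t)` (Hopf curve by continuation; PD/SNPO/TR loci
#'     collected from one-parameter cuts).}
#'   \item{10}{open-cell diagrams and traces at `delta` = 2 and 0.01.}
#'   \item{11, 12}{`(delta, V_PLC)` region analysis at `K_e` = 800
#'     and 400.}
#' }
#'
#' @param figure_id one of the ids above.
#' @param out_dir optional directory; when given, trajectory/branch CSVs
#'   and a `summary.json` are written there.
#' @param config named list of overrides (`params`, `t_end`, and for the
#'   heavy continuation figures `ct_cuts`, `nseg`, `max_steps`).
#' @return the summary list, invisibly when writing, with the underlying
#'   data objects attached in `$data`.
#' @export
reproduce_figure <- function(figure_id, out_dir = NULL, config = list()) {
  figure_id <- match.arg(as.character(figure_id), .figure_ids)
  base <- config$params %||% ca_params()
  res <- switch(
    figure_id,
    "3A" = .fig_regime(set_params(base, delta = 2, V_PLC = 0.1), "open",
                       config$t_end %||% 800),
    "3B" = .fig_regime(set_params(base, V_PLC = 0.1, C_t = 140), "closed",
                       config$t_end %||% 200),
    "3C" = .fig_regime(set_params(base, V_PLC = 0.1, C_t = 75), "closed",
                       config$t_end %||% 300),
    "3D" = .fig_regime(set_params(base, V_PLC = 0.195, C_t = 95), "closed",
                       config$t_end %||% 600),
    "4" = .fig_open_diagram(set_params(base, delta = 2), config),
    "5A" = .fig_par_diagram(set_params(base, delta = 2, V_PLC = 0.1),
                            "s1", c(0.3, 0.1), config),
    "5C" = .fig_par_diagram(set_params(base, delta = 2, V_PLC = 0.1),
                            "tau_s", c(2, 250), config),
    "5B" = .fig_hopf2(set_params(base, delta = 2), "V_PLC", "s1",
                      c(0.01, 0.45, 0.05, 0.45), config),
    "5D" = .fig_hopf2(set_params(base, delta = 2), "V_PLC", "tau_s",
                      c(0.01, 0.45, 0.5, 400), config),
    "5F" = .fig_hopf2(set_params(base, delta = 2, V_PLC = 0.1),
                      "s1", "tau_s", c(0.05, 0.6, 0.5, 120), config,
                      sweep_par = "s1", sweep_range = c(0.3, 0.1)),
    "6" = .fig_p0_comparison(base, config),
    "7" = .fig_er_load(set_params(base, delta = 2), config),
    "8A" = .fig_closed_diagram(set_params(base, C_t = 140), config, 0.10),
    "8C" = .fig_closed_diagram(set_params(base, C_t = 95), config, 0.09),
    "8E" = .fig_closed_diagram(set_params(base, C_t = 75),
                               # stiff wide spikes: finer shooting mesh and
                               # longer branch to resolve both folds
                               modifyList(list(nseg = 40, max_steps = 350,
                                               step0 = 0.03, max_step = 0.12),
                                          config),
                               0.06),
    "9" = .fig_closed_2par(base, config),
    "10" = .fig_delta_compare(base, config),
    "11" = .fig_region(set_params(base, K_e = 800), config),
    "12" = .fig_region(set_params(base, K_e = 400), config))
  res$figure <- figure_id
  res$schema_version <- 1L
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(res$data)) {
      d <- res$data[[nm]]
      if (inherits(d, "data.frame"))
        write.csv(d, file.path(out_dir, paste0(nm, ".csv")),
                  row.names = FALSE)
    }
    summ <- res[setdiff(names(res), "data")]
    jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(res))
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.fig_regime <- function(p, model, t_end) {
  tr <- ca_integrate(p, t_end = t_end, dt_out = 0.01, model = model,
                     fluxes = TRUE)
  ft <- oscillation_features(tr, p)
  list(summary = list(regime = ft$regime, period = ft$period,
                      period_principal = ft$period_principal,
                      amplitude = ft$amplitude,
                      amplitude_ptp = ft$amplitude_ptp,
                      er_depletion_per_cycle = ft$er_depletion_per_cycle,
                      s_max_fraction = ft$s_max_fraction),
       data = list(trajectory = as.data.frame(tr)))
}

.fig_open_diagram <- function(p, config) {
  br <- continue_equilibria(set_params(p, V_PLC = 0.01), "V_PLC",
                            c(0.01, 0.3), model = "open",
                            step0 = 0.01, max_step = 0.04)
  hb <- branch_points(br, "HB")
  tr <- ca_integrate(set_params(p, V_PLC = 0.1), t_end = 800,
                     dt_out = 0.02, model = "open")
  ft <- oscillation_features(tr, p)
  list(summary = list(n_hopf = nrow(hb), hopf_V_PLC = hb$par,
                      period_at_0.1 = ft$period,
                      regime = ft$regime),
       data = list(branch = as.data.frame(br), hopf = hb,
                   trace = as.data.frame(tr)))
}

.fig_par_diagram <- function(p, par, range, config) {
  br <- continue_equilibria(p, par, range, model = "open",
                            step0 = 0.02, max_step = 0.08)
  hb <- branch_points(br, "HB")
  list(summary = list(parameter = par, n_hopf = nrow(hb),
                      hopf_values = hb$par),
       data = list(branch = as.data.frame(br), hopf = hb))
}

.fig_hopf2 <- function(p, p1, p2, box, config,
                       sweep_par = "V_PLC", sweep_range = c(0.01, 0.3)) {
  pl <- p; pl[[sweep_par]] <- sweep_range[1]
  validate_ca_params(pl)
  br <- continue_equilibria(pl, sweep_par, sweep_range, model = "open",
                            step0 = 0.01, max_step = 0.04)
  hb <- branch_points(br, "HB")
  if (!nrow(hb)) stop("no Hopf point found for the two-parameter start")
  cv <- continue_hopf_2par(pl, p1, p2, hb[1, ], box = box, model = "open",
                           max_steps = config$max_steps %||% 300)
  closed <- sqrt(((cv[[p1]][1] - cv[[p1]][nrow(cv)]) / diff(box[1:2]))^2 +
                 ((cv[[p2]][1] - cv[[p2]][nrow(cv)]) / diff(box[3:4]))^2) < 0.05
  list(summary = list(plane = c(p1, p2), n_points = nrow(cv),
                      p2_min = min(cv[[p2]]), p2_max = max(cv[[p2]]),
                      p1_min = min(cv[[p1]]), p1_max = max(cv[[p1]]),
                      region_bounded = closed),
       data = list(curve = as.data.frame(cv)))
}

.fig_p0_comparison <- function(base, config) {
  crac <- ca_integrate(set_params(base, delta = 2, V_PLC = 0.1),
                       t_end = 600, dt_out = 0.02, model = "open",
                       fluxes = TRUE)
  spike <- ca_integrate(set_params(base, V_PLC = 0.1, C_t = 140),
                        t_end = 200, dt_out = 0.005, model = "closed",
                        fluxes = TRUE)
  half <- function(x) x[x$time >= max(x$time) / 2, ]
  p0c <- half(crac)$P0
  p0s <- half(spike)$P0
  # contrast of interest: the IP3R opens and closes sharply during a
  # CICR spike but stays moderately open throughout the CRAC cycle, so
  # the within-cycle modulation (max/min) separates the two mechanisms
  list(summary = list(p0_max_crac = max(p0c), p0_max_spike = max(p0s),
                      max_ratio = max(p0s) / max(p0c),
                      pulsatility_crac = max(p0c) / min(p0c),
                      pulsatility_spike = max(p0s) / min(p0s)),
       data = list(crac = as.data.frame(crac),
                   spike = as.data.frame(spike)))
}

.fig_er_load <- function(p, config) {
  lo <- run_er_load_scenario(809, p, t_end = config$t_end %||% 600)
  hi <- run_er_load_scenario(850, p, t_end = config$t_end %||% 600)
  list(summary = list(
         low_load = list(c_e = 809, n_transient_spikes = lo$transient$n_spikes,
                         period = lo$features$period),
         high_load = list(c_e = 850, n_transient_spikes = hi$transient$n_spikes,
                          spike_duration = hi$transient$duration,
                          period = hi$features$period)),
       data = list(low = as.data.frame(lo$trajectory),
                   high = as.data.frame(hi$trajectory)))
}

.fig_closed_diagram <- function(p, config, start_V = 0.1) {
  br <- continue_equilibria(set_params(p, V_PLC = 0.005), "V_PLC",
                            c(0.005, 0.4), model = "closed",
                            step0 = 0.01, max_step = 0.03)
  hb <- branch_points(br, "HB")
  summary <- list(C_t = p$C_t, n_hopf = nrow(hb), hopf_V_PLC = hb$par)
  data <- list(branch = as.data.frame(br), hopf = hb)
  # Periodic-orbit branch, started from the attractor on the stable
  # segment (robust for both the supercritical and subcritical cases).
  po <- tryCatch({
    pv <- set_params(p, V_PLC = config$start_V %||% start_V)
    tr <- ca_integrate(pv, t_end = config$t_end %||% 200, dt_out = 0.002,
                       model = "closed")
    start <- po_from_simulation(tr, pv, "closed",
                                nseg = config$nseg %||% 30)
    continue_periodic_orbits(p, "V_PLC", c(0.005, 0.4), start,
                             start_par = pv$V_PLC, model = "closed",
                             step0 = config$step0 %||% 0.05,
                             max_step = config$max_step %||% 0.25,
                             max_steps = config$max_steps %||% 120,
                             hopf_ends = hb$par)
  }, error = function(e) NULL)
  pts <- if (!is.null(po)) branch_points(po) else NULL
  # The bifurcations flanking the upper (subcritical) Hopf sit on a
  # violently unstable sheet when approached from the attractor side;
  # trace them from the upper Hopf point instead when missing.
  if (!is.null(pts) && nrow(hb) >= 2 &&
      (sum(pts$kind == "SNPO") < 2 || sum(pts$kind == "PD") < 2)) {
    po2 <- tryCatch({
      h2 <- hb[which.max(hb$par), ]
      st2 <- po_from_hopf(p, "V_PLC", h2, model = "closed",
                          nseg = config$nseg %||% 30, amplitude = 0.05)
      continue_periodic_orbits(p, "V_PLC", c(0.005, 0.4), st2,
                               model = "closed",
                               max_steps = config$max_steps2 %||% 60,
                               hopf_ends = hb$par)
    }, error = function(e) NULL)
    if (!is.null(po2)) {
      pts <- .po_clean_points(rbind(pts, branch_points(po2)))
      data$po_branch_upper <- as.data.frame(po2)
    }
  }
  if (!is.null(po)) {
    summary$po_points <- pts
    summary$n_snpo <- sum(pts$kind == "SNPO")
    summary$n_pd <- sum(pts$kind == "PD")
    data$po_branch <- as.data.frame(po)
  }
  list(summary = summary, data = data)
}

.fig_closed_2par <- function(base, config) {
  # Hopf curve in (V_PLC, C_t) by two-parameter continuation
  p <- set_params(base, C_t = 140, V_PLC = 0.005)
  br <- continue_equilibria(p, "V_PLC", c(0.005, 0.4), model = "closed",
                            step0 = 0.01, max_step = 0.03)
  hb <- branch_points(br, "HB")
  cv <- continue_hopf_2par(p, "V_PLC", "C_t", hb[1, ],
                           box = c(0.005, 0.5, 40, 200), model = "closed",
                           max_steps = config$max_steps %||% 250)
  # PD / SNPO / TR loci from one-parameter cuts at a few C_t values
  cuts <- config$ct_cuts %||% c(75, 95)
  loci <- list()
  for (ct in cuts) {
    fig <- tryCatch(
      .fig_closed_diagram(set_params(base, C_t = ct), config),
      error = function(e) NULL)
    if (!is.null(fig) && !is.null(fig$summary$po_points) &&
        nrow(fig$summary$po_points))
      loci[[as.character(ct)]] <- cbind(C_t = ct, fig$summary$po_points)
  }
  loci_df <- if (length(loci)) do.call(rbind, loci) else
    data.frame(C_t = numeric(), kind = character(), par = numeric(),
               T = numeric())
  kinds <- unique(loci_df$kind)
  list(summary = list(hopf_curve_points = nrow(cv),
                      C_t_range = range(cv$C_t),
                      loci_kinds = kinds,
                      has_pd = "PD" %in% kinds,
                      has_snpo = "SNPO" %in% kinds,
                      has_tr = "TR" %in% kinds),
       data = list(hopf_curve = as.data.frame(cv), loci = loci_df))
}

.fig_delta_compare <- function(base, config) {
  out <- lapply(c(2, 0.01), function(d) {
    p <- set_params(base, delta = d, V_PLC = 0.01)
    br <- continue_equilibria(p, "V_PLC", c(0.01, 0.3), model = "open",
                              step0 = 0.01, max_step = 0.04)
    tr <- ca_integrate(set_params(base, delta = d, V_PLC = 0.1),
                       t_end = if (d > 1) 800 else 400, dt_out = 0.02,
                       model = "open")
    list(branch = br, features = oscillation_features(tr, base), tr = tr)
  })
  list(summary = list(
         delta2 = list(n_hopf = nrow(branch_points(out[[1]]$branch, "HB")),
                       period = out[[1]]$features$period,
                       er_swing = out[[1]]$features$er_depletion_per_cycle),
         delta001 = list(n_hopf = nrow(branch_points(out[[2]]$branch, "HB")),
                         period = out[[2]]$features$period,
                         er_swing = out[[2]]$features$er_depletion_per_cycle)),
       data = list(branch_delta2 = as.data.frame(out[[1]]$branch),
                   branch_delta001 = as.data.frame(out[[2]]$branch),
                   trace_delta2 = as.data.frame(out[[1]]$tr),
                   trace_delta001 = as.data.frame(out[[2]]$tr)))
}

.fig_region <- function(p, config) {
  ov <- region_overlap_delta(p, max_steps = config$max_steps %||% 300)
  summary <- list(K_e = p$K_e, overlap = ov$overlap,
                  delta_intersect = ov$delta_intersect)
  data <- list(crac_hopf = as.data.frame(ov$crac_curve),
               spike_hopf = as.data.frame(ov$spike_curve))
  if (ov$overlap) {
    tr <- ca_integrate(set_params(p, delta = 0.62, V_PLC = 0.1),
                       t_end = config$t_end %||% 600, dt_out = 0.02,
                       model = "open")
    ft <- oscillation_features(tr, p)
    summary$hybrid_regime <- ft$regime
    data$hybrid_trace <- as.data.frame(tr)
  }
  list(summary = summary, data = data)
}
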