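#' Extract oscillation features from a trajectory
#'
#' Discards an initial transient, then measures the limit cycle: period
#' (mean spacing of upward crossings of `c` through its midrange level,
#' with linear interpolation between samples), peak amplitude (the
#' post-transient maximum of `c`; the peak-to-trough swing is reported
#' alongside), ER swing per cycle, the CRAC utilisation `max(s)/V_SOCE`,
#' the duty cycle (fraction of the period spent above the midline) and
#' spike statistics used by [classify_regime()].  A trajectory whose
#' post-transient peak-to-trough swing of `c` is below `flat_tol` is
#' reported as non-oscillating.
#'
#' For spiking waveforms with secondary structure (bursting on a raised
#' plateau) the midline-crossing period can subdivide a burst, so the
#' period between principal spikes (peaks rising above 75% of the swing)
#' is reported as `period_principal`.
#'
#' @param traj a `ca_trajectory` from [ca_integrate()].
#' @param params a [ca_params()] object; defaults to the trajectory's.
#' @param transient_fraction fraction of the record discarded as
#'   transient (default 0.5).
#' @param flat_tol peak-to-trough threshold (uM) below which the
#'   trajectory counts as steady.
#' @param spike_prominence prominence threshold for spike counting, as a
#'   fraction of the peak-to-trough swing.
#' @param secondary_prominence prominence threshold for secondary maxima
#'   on the elevated phase.
#' @return an object of class `ca_features`; see Details.
#' @examples
#' p <- ca_params(V_PLC = 0.1, delta = 2)
#' tr <- ca_integrate(p, t_end = 600, dt_out = 0.05)
#' oscillation_features(tr)
#' @export
oscillation_features <- function(traj, params = attr(traj, "params"),
                                 transient_fraction = 0.5,
                                 flat_tol = 1e-3,
                                 spike_prominence = 0.25,
                                 secondary_prominence = 0.025) {
  stopifnot(inherits(traj, "data.frame"), nrow(traj) >= 2)
  keep <- traj$time >= transient_fraction * max(traj$time)
  tt <- traj$time[keep]
  cc <- traj$c[keep]
  ce <- if ("c_e" %in% names(traj)) traj$c_e[keep] else NULL
  ss <- if ("s" %in% names(traj)) traj$s[keep] else NULL

  ptp <- max(cc) - min(cc)
  ft <- list(oscillating = ptp >= flat_tol,
             period = NA_real_, period_principal = NA_real_,
             c_max = max(cc), c_min = min(cc),
             amplitude = max(cc), amplitude_ptp = ptp,
             ce_max = if (!is.null(ce)) max(ce) else NA_real_,
             ce_min = if (!is.null(ce)) min(ce) else NA_real_,
             er_depletion_per_cycle = if (!is.null(ce)) max(ce) - min(ce)
                                      else NA_real_,
             s_max_fraction = if (!is.null(ss)) max(ss) / params$V_SOCE
                              else 0,
             s_ptp_fraction = if (!is.null(ss))
                                (max(ss) - min(ss)) / params$V_SOCE else 0,
             duty_cycle = NA_real_, duty_low = NA_real_,
             n_spikes_per_cycle = NA_real_,
             n_secondary = 0, regime = "steady")
  if (!ft$oscillating) {
    ft$regime <- "steady"
    return(structure(ft, class = "ca_features"))
  }

  mid <- (min(cc) + max(cc)) / 2
  below <- cc[-length(cc)] < mid & cc[-1] >= mid
  iu <- which(below)
  if (length(iu) < 2) {
    ft$oscillating <- FALSE
    ft$regime <- "steady"
    return(structure(ft, class = "ca_features"))
  }
  crossings <- tt[iu] + (mid - cc[iu]) / (cc[iu + 1] - cc[iu]) *
    (tt[iu + 1] - tt[iu])
  ft$period <- mean(diff(crossings))
  ft$duty_cycle <- mean(cc > mid)
  # quarter-height duty: the midline sits above a raised plateau, so a
  # lower reference level is needed to see the elevated phase at all
  qlevel <- min(cc) + 0.25 * ptp
  ft$duty_low <- mean(cc > qlevel)

  pk <- .peaks(cc)
  prom <- .prominence(cc, pk)
  principal <- pk[cc[pk] > min(cc) + 0.75 * ptp]
  ft$period_principal <- if (length(principal) >= 3)
    mean(diff(tt[principal])) else ft$period
  spikes <- pk[prom >= spike_prominence * ptp]
  ft$n_spikes_per_cycle <- length(spikes) / max(1, length(crossings) - 1)
  elevated <- pk[cc[pk] > qlevel & prom >= secondary_prominence * ptp]
  ft$n_secondary <- max(0, (length(elevated) - length(principal)) /
                             max(1, length(principal)))
  if (!is.null(ce) && length(principal) >= 3) {
    # ER swing over a single (principal) cycle, averaged across cycles
    sw <- vapply(seq_len(length(principal) - 1), function(i) {
      j <- principal[i]:principal[i + 1]
      max(ce[j]) - min(ce[j])
    }, numeric(1))
    ft$er_depletion_per_cycle <- mean(sw)
  }
  ft$regime <- classify_regime(ft)
  structure(ft, class = "ca_features")
}

# indices of strict local maxima
.peaks <- function(x) which(diff(sign(diff(x))) == -2) + 1

# topographic prominence of each peak
.prominence <- function(x, pk) {
  vapply(pk, function(i) {
    v <- x[i]
    left <- x[seq_len(i)]
    hi <- which(left > v)
    lmin <- if (length(hi)) min(left[max(hi):i]) else min(left)
    right <- x[i:length(x)]
    hi <- which(right > v)
    rmin <- if (length(hi)) min(right[1:min(hi)]) else min(right)
    v - max(lmin, rmin)
  }, numeric(1))
}

#' Classify the oscillation regime
#'
#' Deterministic rules mapping waveform statistics to a regime label,
#' applied in order:
#' \itemize{
#'   \item `steady` - not oscillating;
#'   \item `hybrid` - fast spikes (midline duty cycle below
#'     `narrow_duty`) riding on a slow CRAC cycle (`s` swinging by more
#'     than `s_swing_min` of `V_SOCE` peak to trough);
#'   \item `crac_sinusoidal` - midline duty cycle in `crac_duty` with
#'     appreciable CRAC influx (`s_max_fraction > s_active_min`);
#'   \item `wide_spike_plateau` - at least `n_secondary_min` secondary
#'     local maxima per cycle on the elevated phase (above quarter
#'     height);
#'   \item `wide_spike` - secondary structure per cycle (a broad
#'     shoulder, `n_secondary >= n_secondary_wide`) or a long elevated
#'     phase (`duty_low >= wide_duty_low`);
#'   \item `narrow_spike` - a plain brief spike (midline duty below
#'     `narrow_max_duty`);
#'   \item `other` - fallback.
#' }
#' The waveform references matter: a broad spike carries its shoulder
#' below the midline, and a burster's plateau also sits below it, so
#' spike-family discrimination uses the quarter-height level while the
#' sinusoidal test uses the midline.  All thresholds are exposed.
#'
#' @param features a `ca_features` object (or compatible list).
#' @param narrow_duty,crac_duty,s_active_min,s_swing_min threshold of
#'   the CRAC-related rules.
#' @param n_secondary_min,n_secondary_wide,wide_duty_low,narrow_max_duty
#'   thresholds of the spike-family rules.
#' @return a regime label (character scalar).
#' @export
classify_regime <- function(features,
                            narrow_duty = 0.25,
                            crac_duty = c(0.4, 0.6),
                            s_active_min = 0.1,
                            s_swing_min = 0.2,
                            n_secondary_min = 2,
                            n_secondary_wide = 0.5,
                            wide_duty_low = 0.5,
                            narrow_max_duty = 0.4) {
  f <- features
  if (!isTRUE(f$oscillating)) return("steady")
  if (f$s_max_fraction > s_active_min &&
      f$s_ptp_fraction > s_swing_min && f$duty_cycle < narrow_duty)
    return("hybrid")
  if (f$s_max_fraction > s_active_min &&
      f$duty_cycle >= crac_duty[1] && f$duty_cycle <= crac_duty[2])
    return("crac_sinusoidal")
  if (f$n_secondary >= n_secondary_min) return("wide_spike_plateau")
  if (f$n_secondary >= n_secondary_wide || f$duty_low >= wide_duty_low)
    return("wide_spike")
  if (f$duty_cycle < narrow_max_duty) return("narrow_spike")
  "other"
}

#' @export
print.ca_features <- function(x, ...) {
  if (!x$oscillating) {
    cat("steady state (no oscillation); c =", format(x$c_max), "uM\n")
    return(invisible(x))
  }
  cat(sprintf("%s oscillation: T = %.3g s (principal %.3g s)\n",
              x$regime, x$period, x$period_principal))
  cat(sprintf("  c in [%.3g, %.3g] uM (peak amplitude %.3g)\n",
              x$c_min, x$c_max, x$amplitude))
  if (is.finite(x$ce_max))
    cat(sprintf("  c_e in [%.4g, %.4g] uM; ER swing/cycle %.3g uM\n",
                x$ce_min, x$ce_max, x$er_depletion_per_cycle))
  if (x$s_max_fraction > 0)
    cat(sprintf("  max s = %.1f%% of V_SOCE\n", 100 * x$s_max_fraction))
  invisible(x)
}
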