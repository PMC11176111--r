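#' Integrate the model
#'
#' Stiff-capable adaptive integration of the open- or closed-cell model
#' with [deSolve::ode()] (`lsoda`), sampled on a regular output grid.
#' Default tolerances are `rtol = 1e-8`, `atol = 1e-10`; runs are
#' deterministic for fixed inputs.
#'
#' @param params a [ca_params()] object.
#' @param init named initial state (see [open_state()]); defaults to the
#'   unstimulated (`V_PLC = 0`) equilibrium of the model.
#' @param t_end end time (s).
#' @param dt_out output sampling step (s).
#' @param model `"open"` or `"closed"`.
#' @param rtol,atol integrator tolerances.
#' @param fluxes if `TRUE`, append flux and open-probability columns
#'   (`J_SOCE`, `J_IP3R`, `P0`, ...) to the trajectory.
#' @param allow_s_outside passed to [validate_state()].
#' @param compiled use the compiled right-hand side (default); the pure-R
#'   right-hand side gives identical results and is kept for reference.
#' @return a `ca_trajectory`: a data frame with column `time`, the state
#'   columns, a `c_e` column for closed-cell runs (reconstructed from the
#'   conservation law), and optionally flux columns.  Attributes carry the
#'   parameters and model type.
#' @examples
#' p <- ca_params(V_PLC = 0.1, delta = 2)
#' tr <- ca_integrate(p, t_end = 100, dt_out = 0.1)
#' range(tr$c)
#' @export
ca_integrate <- function(params, init = NULL, t_end, dt_out = 0.05,
                         model = c("open", "closed"),
                         rtol = 1e-8, atol = 1e-10,
                         fluxes = FALSE, allow_s_outside = FALSE,
                         compiled = TRUE) {
  model <- match.arg(model)
  stopifnot(t_end > 0, dt_out > 0)
  if (is.null(init)) init <- unstimulated_equilibrium(params, model)
  init <- validate_state(init, params, model, allow_s_outside)
  times <- seq(0, t_end, by = dt_out)
  out <- if (compiled) {
    .ode_c(init, times, params, model, rtol = rtol, atol = atol)
  } else {
    fun <- if (model == "open") rhs_open else rhs_closed
    deSolve::ode(y = init, times = times, func = fun, parms = params,
                 method = "lsoda", rtol = rtol, atol = atol)
  }
  out <- as.data.frame(out)
  names(out)[-1] <- .state_names(model)
  names(out)[1] <- "time"
  if (nrow(out) < length(times) || any(!is.finite(as.matrix(out))))
    stop("integration failed; last valid time ",
         max(out$time[apply(is.finite(as.matrix(out)), 1, all)]))
  if (model == "closed")
    out$c_e <- params$gamma * (params$C_t - out$c)
  if (fluxes) {
    out$J_SOCE <- j_soce(out$c_e, params)
    out$J_PM <- .j_pm(out$c, params)
    out$J_SERCA <- .j_serca(out$c, out$c_e, params)
    out$P0 <- p_open(out$c, out$p, out$h, params)
    out$J_IP3R <- params$k_f * out$P0 * (out$c_e - out$c)
    out$J_deg <- j_deg(out$c, out$p, params)
  }
  structure(out, class = c("ca_trajectory", "data.frame"),
            params = params, model = model)
}

#' @export
print.ca_trajectory <- function(x, ...) {
  cat(sprintf("Ca2+ %s-cell trajectory: %d samples over %g s (dt = %g s)\n",
              attr(x, "model"), nrow(x), max(x$time), x$time[2] - x$time[1]))
  cat(sprintf("  c in [%.4g, %.4g] uM; c_e in [%.4g, %.4g] uM\n",
              min(x$c), max(x$c), min(x$c_e), max(x$c_e)))
  invisible(x)
}

#' Find an equilibrium by damped Newton iteration
#'
#' Solves `f(x) = 0` for the open- or closed-cell vector field starting
#' from `guess`, with step-halving damping (at most 50 outer iterations).
#' Eigenvalues of the Jacobian at the solution are returned for stability
#' assessment.
#'
#' @param params a [ca_params()] object.
#' @param guess named initial state.
#' @param model `"open"` or `"closed"`.
#' @param tol convergence tolerance on the residual max-norm.
#' @return a list of class `ca_equilibrium`: `state`, `eigenvalues`,
#'   `stable` (all real parts negative), `residual`.
#' @examples
#' p <- ca_params(V_PLC = 0, delta = 2)
#' eq <- find_equilibrium(p, open_state(0.1, 800, 0.9, 0, 0.4))
#' eq$stable
#' @export
find_equilibrium <- function(params, guess, model = c("open", "closed"),
                             tol = 1e-11) {
  model <- match.arg(model)
  nm <- .state_names(model)
  if (any(!is.finite(guess))) stop("find_equilibrium: non-finite guess")
  x <- setNames(as.numeric(guess[nm]), nm)
  f <- function(y) .vf(setNames(y, nm), params, model)
  r <- f(x)
  for (it in seq_len(50)) {
    if (max(abs(r)) < tol) break
    J <- .fd_jacobian(f, x)
    step <- tryCatch(solve(J, r), error = function(e) NULL)
    if (is.null(step)) stop("find_equilibrium: singular Jacobian")
    lam <- 1
    repeat {
      xn <- x - lam * step
      rn <- tryCatch(f(xn), error = function(e) rep(Inf, length(x)))
      if (max(abs(rn)) < max(abs(r)) || lam < 2^-20) break
      lam <- lam / 2
    }
    x <- xn; r <- rn
  }
  if (max(abs(r)) >= tol)
    stop("find_equilibrium: Newton did not converge in 50 iterations ",
         "(residual ", format(max(abs(r))), ")")
  ev <- eigen(.fd_jacobian(f, x), only.values = TRUE)$values
  structure(list(state = x, eigenvalues = ev,
                 stable = all(Re(ev) < 0), residual = max(abs(r))),
            class = "ca_equilibrium")
}

#' @export
print.ca_equilibrium <- function(x, ...) {
  cat("equilibrium:", paste(sprintf("%s = %.6g", names(x$state), x$state),
                            collapse = ", "), "\n")
  cat("  leading eigenvalue:", format(x$eigenvalues[which.max(Re(x$eigenvalues))]),
      if (x$stable) "(stable)" else "(unstable)", "\n")
  invisible(x)
}

#' Unstimulated equilibrium (V_PLC = 0)
#'
#' In the unstimulated cell IP3 decays to zero, so the IP3R flux vanishes
#' and the SERCA balance `J_SERCA = 0` pins `c = sqrt(K_bar) * c_e`.  For
#' the open cell the remaining balance `s = J_PM(c) = J_SOCE(c_e)` is a
#' one-dimensional root problem in `c_e`; for the closed cell the
#' conservation law `C_t = c + c_e/gamma` fixes the state directly.  The
#' result is the exact equilibrium of the model with `V_PLC = 0` and is
#' the canonical initial condition of the oscillation scenarios.
#'
#' @param params a [ca_params()] object (its `V_PLC` is ignored; 0 is used).
#' @param model `"open"` or `"closed"`.
#' @return a named state vector.
#' @examples
#' unstimulated_equilibrium(ca_params(delta = 2), "open")
#' @export
unstimulated_equilibrium <- function(params, model = c("open", "closed")) {
  model <- match.arg(model)
  sk <- sqrt(params$K_bar)
  if (model == "closed") {
    c0 <- sk * params$gamma * params$C_t / (1 + sk * params$gamma)
    return(closed_state(c = c0, h = h_inf(c0, params), p = 0))
  }
  g <- function(ce) j_soce(ce, params) - .j_pm(sk * ce, params)
  hi <- params$K_e + 40 / params$s1
  ce <- uniroot(g, c(1e-6, hi), tol = 1e-13)$root
  c0 <- sk * ce
  open_state(c = c0, c_e = ce, h = h_inf(c0, params), p = 0,
             s = .j_pm(c0, params))
}

# Equilibrium of the stimulated model, found by warm-started Newton
# along a short homotopy in V_PLC from the (semi-analytic) rest state.
# Newton straight from the rest state fails at biological stimulation
# levels because the equilibrium moves far and the rest state sits in a
# nearly singular region (p = 0).
.equilibrium_ramped <- function(params, model, nramp = 8) {
  target <- params$V_PLC
  st <- unstimulated_equilibrium(params, model)
  if (target == 0) return(st)
  for (v in seq(0, target, length.out = nramp + 1)[-1]) {
    pl <- params; pl$V_PLC <- v
    st <- find_equilibrium(pl, st, model)$state
  }
  st
}

#' Unstimulated partial equilibrium at fixed ER load
#'
#' For a prescribed ER concentration `c_e`, solves the ER balance
#' `J_SERCA(c, c_e) = J_IP3R = 0` (the cell is unstimulated, so `p = 0`)
#' for the cytosolic concentration `c`, and the CRAC balance `ds/dt = 0`
#' for `s = J_SOCE(c_e)`.  This constructs the initial conditions of the
#' ER-load experiments: at `c_e = 850` the CRAC channel is fully off
#' (`s` essentially 0), at `c_e = 809` it is partially formed.
#'
#' @param c_e ER Ca2+ concentration (uM), `> 0`.
#' @param params a [ca_params()] object.
#' @return named vector `c(c = ..., s = ...)`.
#' @examples
#' unstimulated_partial_equilibrium(850, ca_params(delta = 2))
#' @export
unstimulated_partial_equilibrium <- function(c_e, params) {
  stopifnot(is.finite(c_e), c_e > 0)
  g <- function(c) .j_serca(c, c_e, params) - .j_ip3r(c, c_e,
                                                      h_inf(c, params),
                                                      0, params)
  up <- max(c_e, 1)
  if (g(1e-12) * g(up) > 0)
    stop("unstimulated_partial_equilibrium: no root bracketed in c")
  c0 <- uniroot(g, c(1e-12, up), tol = 1e-13)$root
  c(c = c0, s = j_soce(c_e, params))
}

#' ER-load stimulation scenario
#'
#' Prepares the cell at the unstimulated partial equilibrium for a given
#' initial ER load, then applies the stimulus as an instantaneous step of
#' `V_PLC` (0 to `V_PLC_final`) at `t = 0` and integrates the open-cell
#' model.  A transient report counts the sharp CICR spikes fired before
#' the trajectory settles onto the CRAC-mediated limit cycle, and their
#' total duration: a replete ER (load above the SOCE midpoint `K_e`)
#' starts with CRAC fully off and fires transient narrow spikes for
#' roughly the CRAC formation time, while a partially depleted ER starts
#' close to the limit cycle and shows none.
#'
#' @param c_e_init initial ER Ca2+ load (uM).
#' @param params a [ca_params()] object (`delta` as desired; `V_PLC` is
#'   overridden by the step protocol).
#' @param V_PLC_final stimulation strength after the step (uM/s).
#' @param t_end integration horizon (s).
#' @param dt_out output step (s).
#' @param spike_factor a post-transient cycle counts as a transient spike
#'   while `c` exceeds `spike_factor` times the limit-cycle maximum.
#' @return a list of class `ca_scenario`: `trajectory`, and
#'   `transient` with elements `n_spikes`, `duration` (time of the last
#'   transient spike, s), `spike_times`, plus the limit-cycle `features`.
#' @examples
#' \donttest{
#' sc <- run_er_load_scenario(850, ca_params(delta = 2), t_end = 300)
#' sc$transient$n_spikes
#' }
#' @export
run_er_load_scenario <- function(c_e_init, params, V_PLC_final = 0.1,
                                 t_end = 600, dt_out = 0.02,
                                 spike_factor = 1.25) {
  stopifnot(c_e_init > 0)
  pe <- unstimulated_partial_equilibrium(c_e_init, params)
  init <- open_state(c = pe[["c"]], c_e = c_e_init,
                     h = h_inf(pe[["c"]], params), p = 0, s = pe[["s"]])
  pstim <- set_params(params, V_PLC = V_PLC_final)
  tr <- ca_integrate(pstim, init, t_end = t_end, dt_out = dt_out,
                     model = "open")
  ft <- oscillation_features(tr, pstim)
  # transient spikes: peaks in the first half that overshoot the
  # converged cycle's maximum
  cc <- tr$c; tt <- tr$time
  pk <- which(diff(sign(diff(cc))) == -2) + 1
  thr <- spike_factor * ft$c_max
  sp <- pk[cc[pk] > thr]
  structure(list(trajectory = tr,
                 transient = list(n_spikes = length(sp),
                                  duration = if (length(sp)) max(tt[sp]) else 0,
                                  spike_times = tt[sp]),
                 features = ft),
            class = "ca_scenario")
}

#' @export
print.ca_scenario <- function(x, ...) {
  cat(sprintf("ER-load scenario: %d transient spike(s) over %.1f s, then %s cycle (T = %.2f s)\n",
              x$transient$n_spikes, x$transient$duration,
              x$features$regime, x$features$period))
  invisible(x)
}
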