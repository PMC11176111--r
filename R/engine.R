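# Low-level bridge to the compiled model right-hand sides.
#
# The C implementations (src/tcellosc.c) are the work-horses for long
# integrations, shooting and monodromy computation; the R implementations
# in model.R are the readable reference and the two are cross-checked in
# the test suite.

.param_vector <- function(p) {
  as.numeric(unlist(p[c("V_PLC", "delta", "C_t", "gamma", "V_PM", "K_PM",
                        "V_SOCE", "s1", "K_e", "tau_s", "V_SERCA",
                        "K_SERCA", "K_bar", "k_f", "k_beta", "K_p", "K_c",
                        "K_h", "tau_max", "K_tau", "tau_p", "V_deg",
                        "K_deg")]))
}

# integrate the plain model with the compiled RHS
.ode_c <- function(y, times, params, model, rtol = 1e-8, atol = 1e-10,
                   maxsteps = 100000) {
  fn <- if (model == "open") "tco_open" else "tco_closed"
  deSolve::ode(y = y, times = times, func = fn, parms = .param_vector(params),
               dllname = "tcellosc", initfunc = "tco_init",
               method = "lsoda", rtol = rtol, atol = atol,
               maxsteps = maxsteps)
}

.ode_ok <- function(out, ntimes) {
  nrow(out) == ntimes && all(is.finite(out))
}

# flow map: advance state by time h, compiled
.flow <- function(x, h, params, model, rtol = 1e-10, atol = 1e-12) {
  out <- .ode_c(unname(x), c(0, h), params, model, rtol = rtol, atol = atol)
  if (!.ode_ok(out, 2)) stop("flow map integration failed")
  as.numeric(out[2, -1])
}

# Flow map together with the transition (variational) matrix over [0, h].
# The transition-matrix entries can grow to 1e10 and beyond on strongly
# unstable orbit segments, so they get their own (coarser) absolute
# tolerance; a short relaxation ladder handles stiff spiking segments.
.flow_var <- function(x, h, params, model, rtol = 1e-10, atol = 1e-12,
                      atol_M = 1e-8) {
  n <- length(x)
  fn <- if (model == "open") "tco_open_var" else "tco_closed_var"
  y0 <- c(unname(x), as.numeric(diag(n)))
  for (relax in c(1, 100)) {
    out <- suppressWarnings(
      deSolve::ode(y = y0, times = c(0, h), func = fn,
                   parms = .param_vector(params), dllname = "tcellosc",
                   initfunc = "tco_init", method = "lsoda",
                   rtol = rtol * relax,
                   atol = c(rep(atol * relax, n), rep(atol_M * relax, n * n)),
                   maxsteps = 20000))
    if (.ode_ok(out, 2)) {
      yT <- as.numeric(out[2, -1])
      return(list(x = yT[seq_len(n)], M = matrix(yT[-seq_len(n)], n, n)))
    }
  }
  stop("variational integration failed")
}
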