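#' Store-operated Ca2+ entry (SOCE) flux
#'
#' Activation of the CRAC channel as a decreasing sigmoid of the ER Ca2+
#' concentration:
#' \deqn{J_{SOCE}(c_e) = \frac{V_{SOCE}}{1 + e^{s_1 (c_e - K_e)}}.}
#' The flux saturates at `V_SOCE` for a depleted ER and switches off for a
#' replete ER; `K_e` is the midpoint and `s1` the steepness.
#'
#' @param c_e ER Ca2+ concentration (uM); vectorised.
#' @param params a [ca_params()] object.
#' @return flux in uM/s, in `(0, V_SOCE)`.
#' @examples
#' p <- ca_params()
#' j_soce(p$K_e, p)  # half-maximal at the midpoint
#' @export
j_soce <- function(c_e, params) {
  if (any(!is.finite(c_e))) stop("j_soce: non-finite c_e")
  if (any(c_e < 0)) stop("j_soce: c_e must be >= 0")
  params$V_SOCE / (1 + exp(params$s1 * (c_e - params$K_e)))
}

#' Ca2+-dependent IP3 degradation flux
#'
#' Degradation of IP3 by a Ca2+/calmodulin-stimulated 3-kinase:
#' \deqn{J_{deg}(c, p) = V_{deg} \frac{c^2}{c^2 + K_{deg}^2}\, p,}
#' linear in the IP3 concentration and switched on by cytosolic Ca2+.
#'
#' @param c cytosolic Ca2+ (uM).
#' @param p IP3 concentration (uM).
#' @param params a [ca_params()] object.
#' @return degradation rate in uM/s.
#' @export
j_deg <- function(c, p, params) {
  if (any(!is.finite(c)) || any(!is.finite(p)))
    stop("j_deg: non-finite input")
  if (any(c < 0) || any(p < 0)) stop("j_deg: inputs must be >= 0")
  params$V_deg * c^2 / (c^2 + params$K_deg^2) * p
}

#' IP3 receptor gating functions
#'
#' Steady-state inactivation `h_inf`, its Ca2+-modulated relaxation
#' timescale `tau_h`, and the channel open probability `P0` of the modal
#' IP3R model.  The receptor opens when IP3 and Ca2+ are bound and the
#' slow gate `h` is available:
#' \deqn{\beta = \phi_p \phi_c h, \quad
#'       \alpha = \phi_p^- (1 - \phi_c h_\infty), \quad
#'       P_0 = \frac{\beta}{\beta + k_\beta(\beta + \alpha)},}
#' with Hill functions
#' \eqn{\phi_c = c^4/(c^4 + K_c^4)}, \eqn{\phi_p = p^2/(p^2 + K_p^2)},
#' \eqn{\phi_p^- = K_p^2/(p^2 + K_p^2)},
#' \eqn{h_\infty = K_h^4/(c^4 + K_h^4)} and
#' \eqn{\tau_h = \tau_{max} K_\tau^4/(K_\tau^4 + c^4)}.
#' High cytosolic Ca2+ both inactivates the gate (`h_inf` falls) and makes
#' the inactivation fast (`tau_h` collapses from `tau_max` to near zero),
#' which terminates CICR spikes.
#'
#' @param c cytosolic Ca2+ (uM).
#' @param p IP3 (uM).
#' @param h gate variable in `[0, 1]`.
#' @param params a [ca_params()] object.
#' @return `h_inf`, `tau_h` and `p_open` return numeric vectors.
#' @export
h_inf <- function(c, params) {
  params$K_h^4 / (c^4 + params$K_h^4)
}

#' @rdname h_inf
#' @export
tau_h <- function(c, params) {
  params$tau_max * params$K_tau^4 / (params$K_tau^4 + c^4)
}

#' @rdname h_inf
#' @export
p_open <- function(c, p, h, params) {
  phi_c <- c^4 / (c^4 + params$K_c^4)
  phi_p <- p^2 / (p^2 + params$K_p^2)
  phi_pm <- params$K_p^2 / (p^2 + params$K_p^2)
  beta <- phi_p * phi_c * h
  alpha <- phi_pm * (1 - phi_c * h_inf(c, params))
  beta / (beta + params$k_beta * (beta + alpha))
}

# internal scalar fluxes ----------------------------------------------------

.j_ip3r <- function(c, c_e, h, p, params) {
  params$k_f * p_open(c, p, h, params) * (c_e - c)
}

.j_serca <- function(c, c_e, params) {
  # bidirectional pump: forward Hill-2 in c, weak reverse term in c_e
  params$V_SERCA * (c^2 - params$K_bar * c_e^2) / (c^2 + params$K_SERCA^2)
}

.j_pm <- function(c, params) {
  params$V_PM * c^2 / (c^2 + params$K_PM^2)
}

#' Evaluate every model flux at a state
#'
#' Computes the full flux breakdown of the model at a single state: the
#' IP3R release flux, the SERCA and PMCA pump fluxes, the SOCE flux, the
#' IP3 degradation flux, the IP3R open probability and the gate functions.
#' For the closed-cell model the ER concentration is reconstructed from
#' the conservation law `c_e = gamma * (C_t - c)`; the open- and
#' closed-cell evaluations agree exactly under that substitution.
#'
#' @param state named numeric state vector: `c(c, c_e, h, p, s)` for the
#'   open cell or `c(c, h, p)` for the closed cell.
#' @param params a [ca_params()] object.
#' @param model `"open"` or `"closed"`.
#' @return a list of class `ca_fluxes` with elements `J_IP3R`, `J_SERCA`,
#'   `J_PM`, `J_SOCE`, `J_deg`, `P0`, `h_inf`, `tau_h` and the `c_e` used.
#' @examples
#' p <- ca_params(V_PLC = 0.1, delta = 2)
#' flux_breakdown(open_state(0.085, 850, 0.95, 0, 0), p)
#' @export
flux_breakdown <- function(state, params, model = c("open", "closed")) {
  model <- match.arg(model)
  state <- validate_state(state, params, model)
  c <- state[["c"]]; h <- state[["h"]]; p <- state[["p"]]
  c_e <- if (model == "open") state[["c_e"]] else
    params$gamma * (params$C_t - c)
  out <- list(J_IP3R = .j_ip3r(c, c_e, h, p, params),
              J_SERCA = .j_serca(c, c_e, params),
              J_PM = .j_pm(c, params),
              J_SOCE = j_soce(c_e, params),
              J_deg = j_deg(c, p, params),
              P0 = p_open(c, p, h, params),
              h_inf = h_inf(c, params),
              tau_h = tau_h(c, params),
              c_e = c_e)
  structure(out, class = "ca_fluxes")
}

#' @export
print.ca_fluxes <- function(x, ...) {
  cat("Ca2+ model fluxes (uM/s) at c_e =", format(x$c_e), "uM\n")
  for (nm in c("J_IP3R", "J_SERCA", "J_PM", "J_SOCE", "J_deg"))
    cat(sprintf("  %-7s %12.6g\n", nm, x[[nm]]))
  cat(sprintf("  P0 = %.4g, h_inf = %.4g, tau_h = %.4g s\n",
              x$P0, x$h_inf, x$tau_h))
  invisible(x)
}
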