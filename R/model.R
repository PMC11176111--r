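#' State constructors
#'
#' Build and validate state vectors.  The open-cell state is
#' `(c, c_e, h, p, s)`: cytosolic Ca2+, ER Ca2+, IP3R gate, IP3, and the
#' CRAC influx rate variable `s` (a rate in uM/s relaxing towards
#' `J_SOCE`, so its natural range is `[0, V_SOCE]`).  The closed-cell
#' state is `(c, h, p)` with the ER slaved to the conservation law
#' `c_e = gamma * (C_t - c)`.
#'
#' @param c,c_e,h,p,s state components (uM, uM, dimensionless in `[0,1]`,
#'   uM, uM/s).
#' @return a named numeric vector.
#' @examples
#' open_state(0.1, 800, 0.9, 0.3, 1)
#' closed_state(0.08, 0.95, 0)
#' @export
open_state <- function(c, c_e, h, p, s) {
  c(c = c, c_e = c_e, h = h, p = p, s = s)
}

#' @rdname open_state
#' @export
closed_state <- function(c, h, p) {
  c(c = c, h = h, p = p)
}

#' Validate a state vector
#'
#' Checks finiteness, component names and the physical bounds
#' `c >= 0`, `c_e >= 0`, `0 <= h <= 1`, `p >= 0`; for the closed cell also
#' `c <= C_t` (so that the implied `c_e` is non-negative).  `s` outside
#' `[0, V_SOCE]` is permitted (the region is attracting, not invariant for
#' arbitrary user-chosen initial data) but negative `s` is rejected unless
#' `allow_s_outside = TRUE`.
#'
#' @param state named numeric vector.
#' @param params a [ca_params()] object.
#' @param model `"open"` or `"closed"`.
#' @param allow_s_outside allow `s` outside `[0, V_SOCE]`.
#' @return the state, invisibly reordered to canonical component order.
#' @export
validate_state <- function(state, params, model = c("open", "closed"),
                           allow_s_outside = FALSE) {
  model <- match.arg(model)
  want <- if (model == "open") c("c", "c_e", "h", "p", "s") else
    c("c", "h", "p")
  if (is.null(names(state)) && length(state) == length(want))
    names(state) <- want
  if (!all(want %in% names(state)))
    stop(model, "-cell state needs components: ", paste(want, collapse = ", "))
  state <- state[want]
  if (any(!is.finite(state))) stop("non-finite state")
  if (state[["c"]] < 0) stop("c must be >= 0")
  if (state[["h"]] < -1e-12 || state[["h"]] > 1 + 1e-12)
    stop("h must lie in [0, 1]")
  if (state[["p"]] < 0) stop("p must be >= 0")
  if (model == "open") {
    if (state[["c_e"]] < 0) stop("c_e must be >= 0")
    if (!allow_s_outside &&
        (state[["s"]] < -1e-12 || state[["s"]] > params$V_SOCE + 1e-12))
      stop("s outside [0, V_SOCE]; set allow_s_outside = TRUE to override")
  } else {
    if (state[["c"]] > params$C_t)
      stop("closed cell requires c <= C_t (implied c_e >= 0)")
  }
  state
}

#' Model right-hand sides
#'
#' Time derivatives of the open-cell model
#' \deqn{dc/dt = J_{IP3R} - J_{SERCA} + \delta (s - J_{PM})}
#' \deqn{dc_e/dt = \gamma (J_{SERCA} - J_{IP3R})}
#' \deqn{\tau_h \, dh/dt = h_\infty - h}
#' \deqn{\tau_p \, dp/dt = V_{PLC} - J_{deg}}
#' \deqn{\tau_s \, ds/dt = J_{SOCE} - s}
#' and of the closed-cell reduction (`delta = 0`,
#' `c_e = gamma (C_t - c)`, `s` decoupled):
#' \deqn{dc/dt = J_{IP3R} - J_{SERCA}, \quad
#'       \tau_h dh/dt = h_\infty - h, \quad
#'       \tau_p dp/dt = V_{PLC} - J_{deg}.}
#' The signatures follow [deSolve::ode()].
#'
#' @param t time (unused; the system is autonomous).
#' @param state named state vector (see [open_state()]).
#' @param params a [ca_params()] object.
#' @return a list whose first element is the derivative vector.
#' @examples
#' p <- ca_params(V_PLC = 0.1, delta = 2)
#' rhs_open(0, open_state(0.1, 800, 0.9, 0.3, 1), p)
#' @export
rhs_open <- function(t, state, params) {
  if (any(!is.finite(state))) stop("rhs_open: non-finite state")
  c <- state[["c"]]; c_e <- state[["c_e"]]
  h <- state[["h"]]; p <- state[["p"]]; s <- state[["s"]]
  jip <- .j_ip3r(c, c_e, h, p, params)
  jser <- .j_serca(c, c_e, params)
  list(c(jip - jser + params$delta * (s - .j_pm(c, params)),
         params$gamma * (jser - jip),
         (h_inf(c, params) - h) / tau_h(c, params),
         (params$V_PLC - j_deg(c, p, params)) / params$tau_p,
         (j_soce(c_e, params) - s) / params$tau_s))
}

#' @rdname rhs_open
#' @export
rhs_closed <- function(t, state, params) {
  if (any(!is.finite(state))) stop("rhs_closed: non-finite state")
  c <- state[["c"]]; h <- state[["h"]]; p <- state[["p"]]
  if (c > params$C_t) stop("rhs_closed: c > C_t")
  c_e <- params$gamma * (params$C_t - c)
  jip <- .j_ip3r(c, c_e, h, p, params)
  jser <- .j_serca(c, c_e, params)
  list(c(jip - jser,
         (h_inf(c, params) - h) / tau_h(c, params),
         (params$V_PLC - j_deg(c, p, params)) / params$tau_p))
}

# plain vector field f(y) for root-finding / continuation ------------------
# (no domain validation: Newton and finite-difference probes may step
# slightly outside the physical region)

.vf <- function(state, params, model) {
  c <- state[["c"]]; h <- state[["h"]]; p <- state[["p"]]
  c_e <- if (model == "open") state[["c_e"]] else
    params$gamma * (params$C_t - c)
  jip <- .j_ip3r(c, c_e, h, p, params)
  jser <- .j_serca(c, c_e, params)
  dh <- (h_inf(c, params) - h) / tau_h(c, params)
  jdeg <- params$V_deg * c^2 / (c^2 + params$K_deg^2) * p
  dp <- (params$V_PLC - jdeg) / params$tau_p
  if (model == "closed") return(c(jip - jser, dh, dp))
  s <- state[["s"]]
  jsoce <- params$V_SOCE / (1 + exp(params$s1 * (c_e - params$K_e)))
  c(jip - jser + params$delta * (s - .j_pm(c, params)),
    params$gamma * (jser - jip),
    dh, dp,
    (jsoce - s) / params$tau_s)
}

.state_names <- function(model) {
  if (model == "open") c("c", "c_e", "h", "p", "s") else c("c", "h", "p")
}

# central finite-difference Jacobian, step 1e-7 * (1 + |x|)
.fd_jacobian <- function(f, x, rel = 1e-7) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(0, length(f0), n)
  for (j in seq_len(n)) {
    d <- rel * (1 + abs(x[j]))
    xp <- x; xp[j] <- x[j] + d
    xm <- x; xm[j] <- x[j] - d
    J[, j] <- (f(xp) - f(xm)) / (2 * d)
  }
  J
}

#' Jacobian of the vector field
#'
#' Central finite-difference Jacobian of the open- or closed-cell vector
#' field at a state, with step `1e-7 * (1 + |x_j|)` per component.
#'
#' @inheritParams rhs_open
#' @param model `"open"` or `"closed"`.
#' @return the `n x n` Jacobian matrix.
#' @export
ca_jacobian <- function(state, params, model = c("open", "closed")) {
  model <- match.arg(model)
  nm <- .state_names(model)
  x <- setNames(as.numeric(state[nm]), nm)
  .fd_jacobian(function(y) .vf(setNames(y, nm), params, model), x)
}
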