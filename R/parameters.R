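#' Model parameters
#'
#' Construct the parameter set of the T-cell Ca2+ model.  Defaults are the
#' published reference values for the kinetic constants; the stimulation
#' strength `V_PLC`, the plasma-membrane transport ratio `delta` and (for
#' the closed cell) the total free Ca2+ `C_t` are scenario-dependent and
#' must be chosen per run.
#'
#' @param V_PLC maximal rate of IP3 production by PLC (uM/s); the usual
#'   bifurcation parameter.  Default 0 (unstimulated).
#' @param delta dimensionless ratio of plasma-membrane to ER flux rates.
#'   `delta = 0` closes the cell; `delta = 2` is the reference open cell.
#' @param C_t total free Ca2+ `c + c_e/gamma` (uM), used by the closed-cell
#'   model only.
#' @param gamma cytoplasm:ER volume ratio (dimensionless).
#' @param V_PM,K_PM PMCA pump maximal rate (uM/s) and half-activation (uM).
#' @param V_SOCE maximal CRAC influx rate (uM/s).
#' @param s1 steepness of the SOCE activation curve (1/uM).
#' @param K_e midpoint of the SOCE activation curve (uM of ER Ca2+).
#' @param tau_s timescale of CRAC channel formation (s).
#' @param V_SERCA,K_SERCA,K_bar SERCA pump maximal rate (uM/s),
#'   half-activation (uM) and reverse-mode constant (dimensionless).
#' @param k_f maximal IP3R flux scale (uM... effectively 1/s once
#'   multiplied by the ER-cytosol concentration difference).
#' @param k_beta dimensionless IP3R gating constant.
#' @param K_p IP3 half-activation of the IP3R (uM).
#' @param K_c Ca2+ half-activation of the IP3R (uM).
#' @param K_h Ca2+ half-inactivation of the IP3R gate h (uM).
#' @param tau_max maximal timescale of h relaxation (s).
#' @param K_tau Ca2+ scale of the tau_h modulation (uM).
#' @param tau_p IP3 turnover timescale (s).
#' @param V_deg,K_deg maximal IP3 degradation rate (1/s, per uM of p) and
#'   its Ca2+ half-activation (uM).
#'
#' @return An object of class `ca_params`: a named list of the 23 model
#'   parameters.
#' @examples
#' p <- ca_params(V_PLC = 0.1, delta = 2)
#' p$K_e
#' @export
ca_params <- function(V_PLC = 0, delta = 2, C_t = 140,
                      gamma = 5.5,
                      V_PM = 3, K_PM = 0.2,
                      V_SOCE = 3, s1 = 0.2, K_e = 800, tau_s = 15,
                      V_SERCA = 2, K_SERCA = 0.19, K_bar = 1e-8,
                      k_f = 1.6, k_beta = 0.4,
                      K_p = 10, K_c = 0.16, K_h = 0.168,
                      tau_max = 7.5, K_tau = 0.095,
                      tau_p = 2, V_deg = 6, K_deg = 0.5) {
  p <- list(V_PLC = V_PLC, delta = delta, C_t = C_t, gamma = gamma,
            V_PM = V_PM, K_PM = K_PM,
            V_SOCE = V_SOCE, s1 = s1, K_e = K_e, tau_s = tau_s,
            V_SERCA = V_SERCA, K_SERCA = K_SERCA, K_bar = K_bar,
            k_f = k_f, k_beta = k_beta,
            K_p = K_p, K_c = K_c, K_h = K_h,
            tau_max = tau_max, K_tau = K_tau,
            tau_p = tau_p, V_deg = V_deg, K_deg = K_deg)
  validate_ca_params(p)
  structure(p, class = "ca_params")
}

#' Validate a parameter set
#'
#' Checks positivity constraints: all rates, concentrations and timescales
#' must be strictly positive; `delta`, `V_PLC` and `K_bar` must be
#' non-negative.
#'
#' @param p a list or `ca_params` object.
#' @return `p`, invisibly; errors describe the offending field.
#' @export
validate_ca_params <- function(p) {
  required <- c("V_PLC", "delta", "C_t", "gamma", "V_PM", "K_PM", "V_SOCE",
                "s1", "K_e", "tau_s", "V_SERCA", "K_SERCA", "K_bar", "k_f",
                "k_beta", "K_p", "K_c", "K_h", "tau_max", "K_tau", "tau_p",
                "V_deg", "K_deg")
  missing <- setdiff(required, names(p))
  if (length(missing))
    stop("parameter set is missing field(s): ", paste(missing, collapse = ", "))
  vals <- unlist(p[required])
  if (any(!is.finite(vals)))
    stop("non-finite parameter(s): ",
         paste(required[!is.finite(vals)], collapse = ", "))
  nonneg <- c("V_PLC", "delta", "K_bar")
  pos <- setdiff(required, nonneg)
  bad <- pos[unlist(p[pos]) <= 0]
  if (length(bad))
    stop("parameter(s) must be strictly positive: ", paste(bad, collapse = ", "))
  bad <- nonneg[unlist(p[nonneg]) < 0]
  if (length(bad))
    stop("parameter(s) must be non-negative: ", paste(bad, collapse = ", "))
  invisible(p)
}

#' Modify a parameter set
#'
#' Returns a copy of `p` with the named fields replaced, after validation.
#'
#' @param p a `ca_params` object.
#' @param ... name = value pairs of fields to change.
#' @return a new `ca_params` object.
#' @examples
#' p <- set_params(ca_params(), V_PLC = 0.1, s1 = 0.25)
#' @export
set_params <- function(p, ...) {
  upd <- list(...)
  unknown <- setdiff(names(upd), names(p))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(upd)] <- upd
  validate_ca_params(p)
  structure(p, class = "ca_params")
}

#' Read / write parameter sets as JSON
#'
#' Parameter files are flat JSON objects keyed by the exact field names of
#' [ca_params()].  A bundled default file with the reference values ships
#' in `system.file("extdata", "params_reference.json", package =
#' "tcellosc")`.
#'
#' @param path file path.
#' @return `read_ca_params` returns a `ca_params` object.
#' @export
read_ca_params <- function(path) {
  p <- jsonlite::fromJSON(path)
  p <- lapply(p, as.numeric)
  validate_ca_params(p)
  structure(p, class = "ca_params")
}

#' @rdname read_ca_params
#' @param p a `ca_params` object to write.
#' @export
write_ca_params <- function(p, path) {
  validate_ca_params(p)
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.ca_params <- function(x, ...) {
  cat("T-cell Ca2+ model parameters\n")
  cat(sprintf("  scenario : V_PLC = %g uM/s, delta = %g, C_t = %g uM\n",
              x$V_PLC, x$delta, x$C_t))
  kin <- setdiff(names(x), c("V_PLC", "delta", "C_t"))
  cat("  kinetics :", paste(sprintf("%s = %g", kin, unlist(x[kin])),
                            collapse = ", "), "\n")
  invisible(x)
}
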