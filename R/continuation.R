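# Pseudo-arclength continuation of equilibria and two-parameter
# continuation of Hopf points.
#
# All computations are deterministic.  The arclength metric is taken in
# scaled coordinates (states divided by a typical magnitude) so that the
# ER concentration, three orders of magnitude larger than the cytosolic
# one, does not dominate the step control.

.typ_scale <- function(x, floor = 1e-2) pmax(abs(x), floor)

# damped Newton for a square system
.newton <- function(f, x, tol = 1e-10, maxit = 25) {
  r <- f(x)
  for (it in seq_len(maxit)) {
    if (max(abs(r)) < tol) return(list(x = x, res = max(abs(r)), it = it))
    J <- .fd_jacobian(f, x)
    step <- tryCatch(solve(J, r), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lam <- 1
    repeat {
      xn <- x - lam * step
      rn <- tryCatch(f(xn), error = function(e) rep(Inf, length(r)))
      if (max(abs(rn)) < max(abs(r)) || lam < 2^-16) break
      lam <- lam / 2
    }
    if (max(abs(rn)) >= max(abs(r))) return(NULL)
    x <- xn; r <- rn
  }
  if (max(abs(r)) < tol) list(x = x, res = max(abs(r)), it = maxit) else NULL
}

# signed Hopf test function: largest real part among complex eigenvalues
.hopf_test <- function(ev) {
  cplx <- ev[abs(Im(ev)) > 1e-9]
  if (!length(cplx)) return(-Inf)
  max(Re(cplx))
}

#' Continue an equilibrium branch in one parameter
#'
#' Pseudo-arclength continuation of the equilibrium curve of the open- or
#' closed-cell model, with adaptive step length, eigenvalues at every
#' accepted point, and detection plus bisection refinement of Hopf (HB)
#' and saddle-node (SN) bifurcations.  A Hopf point is localised until
#' the real part of the critical eigenvalue pair changes sign within a
#' parameter interval of `tol_par`.
#'
#' @param params a [ca_params()] object (the value of `par_name` inside
#'   is overridden by `par_range[1]`).
#' @param par_name name of the continuation parameter (a [ca_params()]
#'   field, e.g. `"V_PLC"`, `"s1"`, `"tau_s"`, `"delta"`, `"C_t"`).
#' @param par_range numeric length-2; continuation runs from the first
#'   value towards the second and stops at the boundary.
#' @param start equilibrium state at `par_range[1]`; found by Newton from
#'   [unstimulated_equilibrium()] if omitted.
#' @param model `"open"` or `"closed"`.
#' @param step0 initial arclength step; `max_step` caps growth.
#' @param max_steps maximum number of accepted branch points.
#' @param tol_par localisation tolerance for detected points.
#' @return a `ca_eq_branch`: data frame with the parameter, state
#'   columns, leading eigenvalue (`re_lead`, `im_lead`), the number of
#'   unstable eigenvalues and a stability flag.  Attribute `points` holds
#'   the detected bifurcations (kind `"HB"` or `"SN"`, parameter value,
#'   state, angular frequency `omega` for HB).
#' @examples
#' \donttest{
#' p <- ca_params(V_PLC = 0.02, delta = 2)
#' br <- continue_equilibria(p, "V_PLC", c(0.02, 0.3), model = "open")
#' attr(br, "points")
#' }
#' @export
continue_equilibria <- function(params, par_name, par_range, start = NULL,
                                model = c("open", "closed"),
                                step0 = 0.02, max_step = 0.1,
                                max_steps = 500, tol_par = 1e-6) {
  model <- match.arg(model)
  nm <- .state_names(model)
  n <- length(nm)
  params[[par_name]] <- par_range[1]
  validate_ca_params(params)
  if (is.null(start)) start <- .equilibrium_ramped(params, model)
  fxa <- function(x, a) {
    pl <- params; pl[[par_name]] <- a
    .vf(setNames(x, nm), pl, model)
  }
  eq0 <- .newton(function(x) fxa(x, par_range[1]), as.numeric(start[nm]))
  if (is.null(eq0)) stop("continue_equilibria: start point did not converge")
  x <- eq0$x; a <- par_range[1]
  sc <- c(.typ_scale(x), max(abs(par_range[2] - par_range[1]), 1e-3) / 10)
  dirn <- sign(par_range[2] - par_range[1])

  eig_of <- function(x, a) {
    J <- .fd_jacobian(function(y) fxa(y, a), x)
    eigen(J, only.values = TRUE)$values
  }
  rec <- function(x, a) {
    ev <- eig_of(x, a)
    lead <- ev[which.max(Re(ev))]
    c(a, x, Re(lead), abs(Im(lead)), sum(Re(ev) > 1e-9))
  }

  rows <- list(rec(x, a))
  evs <- list(eig_of(x, a))
  tang <- c(rep(0, n), dirn)          # initial tangent: straight in parameter
  h <- step0
  pts <- list()

  solve_at_par <- function(a, xg) .newton(function(y) fxa(y, a), xg)

  locate_hb <- function(a1, x1, a2, x2) {
    t1 <- .hopf_test(eig_of(x1, a1))
    for (k in seq_len(60)) {
      am <- (a1 + a2) / 2
      sol <- solve_at_par(am, (x1 + x2) / 2)
      if (is.null(sol)) return(NULL)
      tm <- .hopf_test(eig_of(sol$x, am))
      if (sign(tm) == sign(t1)) { a1 <- am; x1 <- sol$x; t1 <- tm }
      else { a2 <- am; x2 <- sol$x }
      if (abs(a2 - a1) < tol_par) break
    }
    am <- (a1 + a2) / 2
    sol <- solve_at_par(am, (x1 + x2) / 2)
    if (is.null(sol)) return(NULL)
    ev <- eig_of(sol$x, am)
    cplx <- ev[abs(Im(ev)) > 1e-9]
    lead <- cplx[which.max(Re(cplx))]
    list(kind = "HB", par = am, state = setNames(sol$x, nm),
         omega = abs(Im(lead)))
  }

  for (stepi in seq_len(max_steps)) {
    # tangent from bordered system in scaled coordinates
    u <- c(x, a)
    Ju <- .fd_jacobian(function(v) fxa(v[seq_len(n)], v[n + 1]), u)
    A <- rbind(cbind(Ju %*% diag(sc)), tang)
    tn <- tryCatch(solve(A, c(rep(0, n), 1)), error = function(e) NULL)
    if (is.null(tn)) break
    tn <- tn / sqrt(sum(tn^2))
    if (sum(tn * tang) < 0) tn <- -tn
    tang <- tn

    accepted <- FALSE
    for (half in 0:5) {
      hh <- h / 2^half
      upred <- u + hh * (sc * tang)
      G <- function(v) c(fxa(v[seq_len(n)], v[n + 1]),
                         sum(tang * ((v - upred) / sc)))
      sol <- .newton(G, upred, tol = 1e-9, maxit = 12)
      if (!is.null(sol)) {
        if (sol$it <= 4 && half == 0) h <- min(h * 1.4, max_step)
        if (half > 0) h <- hh
        accepted <- TRUE
        break
      }
    }
    if (!accepted) {
      warning("continue_equilibria: step failure after 5 halvings; ",
              "branch truncated at ", par_name, " = ", format(a))
      break
    }
    xn <- sol$x[seq_len(n)]; an <- sol$x[n + 1]
    # clamp at the range boundary
    lo <- min(par_range); hi <- max(par_range)
    outside <- an < lo - 1e-12 || an > hi + 1e-12
    if (outside) {
      an <- min(max(an, lo), hi)
      solb <- solve_at_par(an, xn)
      if (!is.null(solb)) xn <- solb$x
    }
    ev_prev <- evs[[length(evs)]]
    ev_new <- eig_of(xn, an)
    # Hopf: sign change of the complex-pair test function
    t_prev <- .hopf_test(ev_prev); t_new <- .hopf_test(ev_new)
    if (is.finite(t_prev) && is.finite(t_new) &&
        sign(t_prev) != sign(t_new) && abs(an - a) > 0) {
      hb <- locate_hb(a, x, an, xn)
      if (!is.null(hb)) pts[[length(pts) + 1]] <- hb
    }
    # saddle-node: real eigenvalue through zero (determinant sign change)
    det_prev <- Re(prod(ev_prev)); det_new <- Re(prod(ev_new))
    if (sign(det_prev) != sign(det_new)) {
      pts[[length(pts) + 1]] <- list(kind = "SN", par = (a + an) / 2,
                                     state = setNames((x + xn) / 2, nm),
                                     omega = NA_real_)
    }
    x <- xn; a <- an
    rows[[length(rows) + 1]] <- rec(x, a)
    evs[[length(evs) + 1]] <- ev_new
    if (outside) break
  }

  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- c(par_name, nm, "re_lead", "im_lead", "n_unstable")
  df$stable <- df$n_unstable == 0
  ptdf <- if (length(pts)) {
    do.call(rbind, lapply(pts, function(q)
      data.frame(kind = q$kind, par = q$par, omega = q$omega,
                 t(q$state))))
  } else {
    data.frame(kind = character(), par = numeric(), omega = numeric())
  }
  structure(df, class = c("ca_eq_branch", "data.frame"),
            par_name = par_name, model = model, params = params,
            points = ptdf)
}

#' Detected bifurcation points of a branch
#'
#' @param branch a `ca_eq_branch` or `ca_po_branch`.
#' @param kind optional filter (`"HB"`, `"SN"`, `"SNPO"`, `"PD"`, `"TR"`).
#' @return the `points` attribute (data frame), optionally filtered.
#' @export
branch_points <- function(branch, kind = NULL) {
  pts <- attr(branch, "points")
  if (!is.null(kind) && nrow(pts)) pts <- pts[pts$kind %in% kind, ]
  pts
}

#' @export
print.ca_eq_branch <- function(x, ...) {
  pn <- attr(x, "par_name")
  cat(sprintf("equilibrium branch in %s over [%g, %g]: %d points\n",
              pn, min(x[[pn]]), max(x[[pn]]), nrow(x)))
  pts <- attr(x, "points")
  if (nrow(pts))
    for (i in seq_len(nrow(pts)))
      cat(sprintf("  %s at %s = %.6g\n", pts$kind[i], pn, pts$par[i]))
  invisible(x)
}

# ---------------------------------------------------------------------------
# two-parameter Hopf continuation

#' Continue a Hopf point in two parameters
#'
#' Continues the extended Hopf defining system (equilibrium condition
#' plus a purely imaginary eigenpair, written in real form with the
#' eigenvector normalised and its rotation phase fixed) through the
#' `(p1, p2)` plane by pseudo-arclength, starting from a Hopf point
#' detected by [continue_equilibria()].  The curve is traced in both
#' directions until it leaves the parameter `box`, closes on itself, or
#' `max_steps` points are accepted per direction.
#'
#' @param params a [ca_params()] object.
#' @param p1_name,p2_name the two continuation parameters.
#' @param hb a Hopf point: one row of [branch_points()] (needs the state
#'   columns, `par` and `omega`), from a branch continued in `p1_name`.
#' @param box numeric length-4 `c(p1_min, p1_max, p2_min, p2_max)`.
#' @param model `"open"` or `"closed"`.
#' @param step0,max_step arclength step control.
#' @param max_steps per-direction cap on accepted points.
#' @return a `ca_hopf_curve`: data frame with columns `p1_name`,
#'   `p2_name`, `omega` and the state columns, ordered along the curve.
#' @examples
#' \donttest{
#' p <- ca_params(V_PLC = 0.02, delta = 2)
#' br <- continue_equilibria(p, "V_PLC", c(0.02, 0.3), model = "open")
#' hb <- branch_points(br, "HB")[1, ]
#' cv <- continue_hopf_2par(p, "V_PLC", "s1", hb,
#'                          box = c(0.01, 0.4, 0.1, 0.4), model = "open")
#' }
#' @export
continue_hopf_2par <- function(params, p1_name, p2_name, hb,
                               box, model = c("open", "closed"),
                               step0 = 0.02, max_step = 0.08,
                               max_steps = 400) {
  model <- match.arg(model)
  nm <- .state_names(model)
  n <- length(nm)
  stopifnot(length(box) == 4)

  fxab <- function(x, a, b) {
    pl <- params; pl[[p1_name]] <- a; pl[[p2_name]] <- b
    .vf(setNames(x, nm), pl, model)
  }
  # unknown vector u = (x, va, vb, omega, a, b); the eigenpair equations
  # use the per-component central-difference Jacobian (accurate to ~1e-9)
  resid <- function(u) {
    x <- u[seq_len(n)]
    va <- u[n + seq_len(n)]
    vb <- u[2 * n + seq_len(n)]
    om <- u[3 * n + 1]; a <- u[3 * n + 2]; b <- u[3 * n + 3]
    J <- .fd_jacobian(function(y) fxab(y, a, b), x)
    c(fxab(x, a, b),
      as.numeric(J %*% va) + om * vb,
      as.numeric(J %*% vb) - om * va,
      sum(va^2) + sum(vb^2) - 1,
      sum(va * vb))
  }

  # seed from the one-parameter HB point
  x0 <- as.numeric(hb[1, nm])
  a0 <- hb$par[1]
  b0 <- params[[p2_name]]
  J0 <- .fd_jacobian(function(y) fxab(y, a0, b0), x0)
  ev <- eigen(J0)
  cplx <- which(abs(Im(ev$values)) > 1e-8)
  k <- cplx[which.max(Re(ev$values[cplx]))]
  om0 <- abs(Im(ev$values[k]))
  v <- ev$vectors[, k]
  if (Im(ev$values[k]) < 0) v <- Conj(v)
  va <- Re(v); vb <- Im(v)
  # rotate the eigenvector so that va . vb = 0, then normalise
  th <- 0.5 * atan2(2 * sum(va * vb), sum(va^2) - sum(vb^2))
  va2 <- cos(th) * va + sin(th) * vb
  vb2 <- -sin(th) * va + cos(th) * vb
  nrm <- sqrt(sum(va2^2) + sum(vb2^2))
  # seed: solve with p2 frozen (square system in x, va, vb, omega, p1)
  u17 <- c(x0, va2 / nrm, vb2 / nrm, om0, a0)
  sol <- .newton(function(v) resid(c(v, b0)), u17, tol = 5e-8, maxit = 30)
  if (is.null(sol)) stop("continue_hopf_2par: seed Hopf point did not converge")
  u <- c(sol$x, b0)

  sc <- c(.typ_scale(u[seq_len(n)]), rep(1, 2 * n), max(u[3 * n + 1], 0.05),
          max(abs(box[2] - box[1]) / 10, 1e-3),
          max(abs(box[4] - box[3]) / 10, 1e-3))
  N <- length(u)
  ia <- 3 * n + 2; ib <- 3 * n + 3

  trace_dir <- function(u, dirsign) {
    tang <- rep(0, N); tang[ib] <- dirsign
    h <- step0
    out <- list()
    for (stepi in seq_len(max_steps)) {
      Ju <- .fd_jacobian(resid, u)
      A <- rbind(Ju %*% diag(sc), tang)
      tn <- tryCatch(solve(A, c(rep(0, N - 1), 1)), error = function(e) NULL)
      if (is.null(tn)) break
      tn <- tn / sqrt(sum(tn^2))
      if (sum(tn * tang) < 0) tn <- -tn
      tang <- tn
      ok <- FALSE
      for (half in 0:5) {
        hh <- h / 2^half
        upred <- u + hh * (sc * tang)
        G <- function(v) c(resid(v)[seq_len(N - 1)],
                           sum(tang * ((v - upred) / sc)))
        sol <- .newton(G, upred, tol = 5e-8, maxit = 12)
        if (!is.null(sol)) { if (half > 0) h <- hh
          else if (sol$it <= 4) h <- min(h * 1.4, max_step)
          ok <- TRUE; break }
      }
      if (!ok) break
      u <- sol$x
      out[[length(out) + 1]] <- c(u[ia], u[ib], u[3 * n + 1], u[seq_len(n)])
      if (u[ia] < box[1] || u[ia] > box[2] ||
          u[ib] < box[3] || u[ib] > box[4]) break
      if (stepi > 10 &&
          abs(u[ia] - a0) < h * sc[ia] && abs(u[ib] - b0) < h * sc[ib])
        break  # curve closed on itself
    }
    out
  }

  fw <- trace_dir(u, +1)
  bw <- trace_dir(u, -1)
  rows <- c(rev(bw), list(c(u[ia], u[ib], u[3 * n + 1], u[seq_len(n)])), fw)
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- c(p1_name, p2_name, "omega", nm)
  structure(df, class = c("ca_hopf_curve", "data.frame"),
            p1_name = p1_name, p2_name = p2_name, model = model,
            params = params, box = box)
}

#' @export
print.ca_hopf_curve <- function(x, ...) {
  p1 <- attr(x, "p1_name"); p2 <- attr(x, "p2_name")
  cat(sprintf("Hopf curve in (%s, %s): %d points; %s in [%.4g, %.4g], %s in [%.4g, %.4g]\n",
              p1, p2, nrow(x), p1, min(x[[p1]]), max(x[[p1]]),
              p2, min(x[[p2]]), max(x[[p2]])))
  invisible(x)
}
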