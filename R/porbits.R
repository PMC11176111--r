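# Periodic-orbit continuation by multiple shooting.
#
# An orbit is represented by the states at m equispaced phases
# (the columns of X), its period T and the parameter value.  The defining
# system is the cyclic matching of the m segment flows plus an anchor
# phase condition <x_1 - x_ref, f(x_ref)> = 0.  Segment transition
# matrices come from the compiled variational equations and multiply up
# to the monodromy matrix, whose eigenvalues are the Floquet multipliers.

.po_phase_names <- c("SNPO", "PD", "TR")

# residual and (optionally) Jacobian blocks of the shooting system at a
# fixed parameter value.  z = (vec(X), T).
.po_system <- function(z, n, m, params, model, xref, fref, with_jac = TRUE) {
  X <- matrix(z[seq_len(n * m)], n, m)
  T <- z[n * m + 1]
  if (!is.finite(T) || T <= 0) return(NULL)
  h <- T / m
  r <- numeric(n * m + 1)
  Ms <- vector("list", m)
  fend <- matrix(0, n, m)
  for (i in seq_len(m)) {
    nxt <- if (i == m) 1 else i + 1
    if (with_jac) {
      fl <- tryCatch(.flow_var(X[, i], h, params, model),
                     error = function(e) NULL)
      if (is.null(fl) || any(!is.finite(fl$x))) return(NULL)
      Ms[[i]] <- fl$M
      xe <- fl$x
    } else {
      xe <- tryCatch(.flow(X[, i], h, params, model),
                     error = function(e) NULL)
      if (is.null(xe) || any(!is.finite(xe))) return(NULL)
    }
    r[(i - 1) * n + seq_len(n)] <- xe - X[, nxt]
    fend[, i] <- .vf(setNames(xe, .state_names(model)), params, model)
  }
  r[n * m + 1] <- sum((X[, 1] - xref) * fref)
  if (!with_jac) return(list(r = r))
  # assemble dense Jacobian wrt (vec(X), T)
  N <- n * m + 1
  A <- matrix(0, N, N)
  for (i in seq_len(m)) {
    nxt <- if (i == m) 1 else i + 1
    ri <- (i - 1) * n + seq_len(n)
    A[ri, (i - 1) * n + seq_len(n)] <- Ms[[i]]
    A[ri, (nxt - 1) * n + seq_len(n)] <-
      A[ri, (nxt - 1) * n + seq_len(n)] - diag(n)
    A[ri, N] <- fend[, i] / m
  }
  A[N, seq_len(n)] <- fref
  list(r = r, A = A, Ms = Ms)
}

# Newton solve of the shooting system at fixed parameter
.po_newton <- function(X, T, params, model, tol = 1e-9, maxit = 15) {
  n <- nrow(X); m <- ncol(X)
  xref <- X[, 1]
  fref <- .vf(setNames(xref, .state_names(model)), params, model)
  z <- c(as.numeric(X), T)
  sys <- .po_system(z, n, m, params, model, xref, fref)
  if (is.null(sys)) return(NULL)
  for (it in seq_len(maxit)) {
    if (max(abs(sys$r)) < tol) break
    step <- tryCatch(solve(sys$A, sys$r), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lam <- 1
    repeat {
      zn <- z - lam * step
      sysn <- .po_system(zn, n, m, params, model, xref, fref)
      if (!is.null(sysn) && max(abs(sysn$r)) < max(abs(sys$r))) break
      lam <- lam / 2
      if (lam < 2^-10) return(NULL)
    }
    z <- zn; sys <- sysn
  }
  if (max(abs(sys$r)) >= tol) return(NULL)
  M <- Reduce(`%*%`, rev(sys$Ms))   # monodromy at x_1
  list(X = matrix(z[seq_len(n * m)], n, m), T = z[n * m + 1],
       monodromy = M, resid = max(abs(sys$r)), Ms = sys$Ms)
}

#' Floquet multipliers of a periodic orbit solution
#'
#' Eigenvalues of the monodromy matrix.  One multiplier of an autonomous
#' system is trivially 1; `po_stable()` drops the multiplier closest to 1
#' and tests the rest against the unit circle.
#'
#' @param sol a solved orbit as returned in the rows of
#'   [continue_periodic_orbits()] (a list with a `monodromy` element).
#' @return complex vector of multipliers, ordered by decreasing modulus.
#' @export
floquet_multipliers <- function(sol) {
  mu <- eigen(sol$monodromy, only.values = TRUE)$values
  mu[order(-Mod(mu))]
}

.po_stable <- function(mu, tol = 1e-3) {
  i <- which.min(Mod(mu - 1))
  all(Mod(mu[-i]) < 1 + tol)
}

# test functions along a PO branch
.po_tests <- function(mu) {
  i <- which.min(Mod(mu - 1))
  rest <- mu[-i]
  realneg <- Re(rest[abs(Im(rest)) < 1e-8 & Re(rest) < 0])
  pd <- if (length(realneg)) min(realneg) + 1 else 1
  cplx <- rest[abs(Im(rest)) > 1e-8]
  tr <- if (length(cplx)) max(Mod(cplx)) - 1 else -1
  c(pd = pd, tr = tr)
}

# dense max/min of c over one period (for diagram output)
.po_extrema <- function(X, T, params, model) {
  out <- .ode_c(X[, 1], seq(0, T, length.out = 201), params, model,
                rtol = 1e-9, atol = 1e-11)
  c(max(out[, 2]), min(out[, 2]))
}

#' Seed a periodic orbit near a Hopf point
#'
#' Solves for a small periodic orbit emerging from a Hopf point with the
#' amplitude pinned and the continuation parameter left free (the
#' well-conditioned formulation near a Hopf, where fixing the parameter
#' makes the shooting system nearly singular).  The orbit is seeded on
#' the linearised eigenplane with period `2*pi/omega`; Newton then
#' adjusts the states, the period and the parameter so that the orbit's
#' projection on the eigenplane has the requested amplitude.
#'
#' @param params a [ca_params()] object.
#' @param par_name continuation parameter of the branch the Hopf point
#'   came from.
#' @param hb one row of [branch_points()] with kind `"HB"`.
#' @param model `"open"` or `"closed"`.
#' @param nseg number of shooting segments.
#' @param amplitude pinned amplitude of the orbit in scaled coordinates
#'   (roughly the relative size of the oscillation).
#' @param dpar unused except to choose the initial parameter guess
#'   offset; the converged parameter is determined by the amplitude.
#' @return a solved orbit: list with `X`, `T`, `par`, `monodromy`.
#' @export
po_from_hopf <- function(params, par_name, hb, dpar = 0,
                         model = c("open", "closed"), nseg = 30,
                         amplitude = 0.05) {
  model <- match.arg(model)
  nm <- .state_names(model)
  n <- length(nm)
  m <- nseg
  a0 <- hb$par[1]
  pl0 <- params; pl0[[par_name]] <- a0
  eq <- find_equilibrium(pl0, setNames(as.numeric(hb[1, nm]), nm), model,
                         tol = 1e-10)
  J <- .fd_jacobian(function(y) .vf(setNames(y, nm), pl0, model), eq$state)
  ev <- eigen(J)
  cplx <- which(abs(Im(ev$values)) > 1e-8)
  k <- cplx[which.max(Re(ev$values[cplx]))]
  om <- abs(Im(ev$values[k]))
  v <- ev$vectors[, k]
  if (Im(ev$values[k]) < 0) v <- Conj(v)
  sc <- .typ_scale(eq$state)
  vs <- v / sc
  vs <- vs / sqrt(sum(Mod(vs)^2))
  va <- Re(vs); vb <- Im(vs)
  xeq <- eq$state

  local_params <- function(a) { pl <- params; pl[[par_name]] <- a; pl }
  # unknowns u = (vec(X), T, a); equations: nm matching rows, pinned
  # eigenplane projections of x_1 - x_eq (amplitude and phase)
  sys_at <- function(u, with_jac = TRUE) {
    X <- matrix(u[seq_len(n * m)], n, m)
    T <- u[n * m + 1]; a <- u[n * m + 2]
    pla <- local_params(a)
    sys <- .po_system(c(as.numeric(X), T), n, m, pla, model, xeq,
                      rep(0, n), with_jac = with_jac)
    if (is.null(sys)) return(NULL)
    d1 <- (X[, 1] - xeq) / sc
    r <- c(sys$r[seq_len(n * m)], sum(d1 * va) - amplitude, sum(d1 * vb))
    if (!with_jac) return(list(r = r))
    da <- 1e-6 * (1 + abs(a))
    sysp <- .po_system(c(as.numeric(X), T), n, m, local_params(a + da),
                       model, xeq, rep(0, n), with_jac = FALSE)
    if (is.null(sysp)) return(NULL)
    N <- n * m + 2
    A <- matrix(0, N, N)
    A[seq_len(n * m), seq_len(n * m + 1)] <-
      sys$A[seq_len(n * m), seq_len(n * m + 1)]
    A[seq_len(n * m), N] <-
      (sysp$r[seq_len(n * m)] - sys$r[seq_len(n * m)]) / da
    A[n * m + 1, seq_len(n)] <- va / sc
    A[n * m + 2, seq_len(n)] <- vb / sc
    list(r = r, A = A, Ms = sys$Ms)
  }

  th <- 2 * pi * (seq_len(m) - 1) / m
  X <- sapply(th, function(t)
    xeq + amplitude * sc * (va * cos(t) - vb * sin(t)))
  u <- c(as.numeric(X), 2 * pi / om, a0 + dpar)
  sys <- sys_at(u)
  for (it in seq_len(30)) {
    if (is.null(sys)) break
    if (max(abs(sys$r)) < 1e-9) {
      sol <- list(X = matrix(u[seq_len(n * m)], n, m), T = u[n * m + 1],
                  par = u[n * m + 2],
                  monodromy = Reduce(`%*%`, rev(sys$Ms)),
                  omega_hopf = om, eq_state = xeq)
      return(sol)
    }
    step <- tryCatch(solve(sys$A, sys$r), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      un <- u - lam * step
      sysn <- sys_at(un)
      if (!is.null(sysn) && max(abs(sysn$r)) < max(abs(sys$r))) break
      lam <- lam / 2
      if (lam < 2^-12) break
    }
    if (lam < 2^-12) break
    u <- un; sys <- sysn
  }
  stop("po_from_hopf: could not converge a small orbit near the Hopf point")
}

#' Extract a periodic orbit from a converged simulation
#'
#' Takes the final cycle of a (post-transient) trajectory on an
#' attractor, resamples it at `nseg` phases and polishes it with shooting
#' Newton.  Used to start continuation on branches that are not
#' connected to a Hopf point of the equilibrium (e.g. isolated branches
#' located by simulation).
#'
#' @param traj a `ca_trajectory`.
#' @param params parameters the trajectory was produced with.
#' @param model `"open"` or `"closed"`.
#' @param nseg shooting segments.
#' @return a solved orbit (list with `X`, `T`, `monodromy`).
#' @export
po_from_simulation <- function(traj, params = attr(traj, "params"),
                               model = attr(traj, "model"), nseg = 30) {
  ft <- oscillation_features(traj, params)
  if (!ft$oscillating) stop("po_from_simulation: trajectory not oscillatory")
  Tg <- if (is.finite(ft$period_principal)) ft$period_principal else ft$period
  nm <- .state_names(model)
  tt <- traj$time
  tend <- max(tt)
  t0 <- tend - Tg
  ph <- t0 + Tg * (seq_len(nseg) - 1) / nseg
  X <- sapply(ph, function(tq)
    vapply(nm, function(v) approx(tt, traj[[v]], tq)$y, numeric(1)))
  sol <- .po_newton(X, Tg, params, model)
  if (is.null(sol)) stop("po_from_simulation: shooting Newton failed")
  sol
}

#' Continue a branch of periodic orbits
#'
#' Pseudo-arclength continuation of periodic orbits of the open- or
#' closed-cell model in one parameter, by multiple shooting with
#' `nseg` segments.  Floquet multipliers are computed at every accepted
#' orbit; folds of cycles (SNPO), period doublings (PD, a multiplier
#' through -1) and torus bifurcations (TR, a complex pair through the
#' unit circle) are detected from test-function sign changes and
#' refined (PD/TR by bisection at fixed parameter, SNPO by a local
#' quadratic fit of the parameter along the branch).
#'
#' @param params a [ca_params()] object.
#' @param par_name continuation parameter.
#' @param par_range numeric length-2 parameter window; continuation
#'   starts inside and stops at the boundary (both directions are
#'   explored from the starting orbit).
#' @param start a solved orbit from [po_from_hopf()] or
#'   [po_from_simulation()] (fields `X`, `T`), with `start_par` giving
#'   its parameter value if not present as `start$par`.
#' @param model `"open"` or `"closed"`.
#' @param nseg shooting segments (the orbit is re-used as given if its
#'   `X` already has `nseg` columns).
#' @param step0,max_step arclength step control.
#' @param max_steps cap on accepted orbits per direction.
#' @param T_max period at which the branch is terminated with a
#'   near-homoclinic flag.
#' @param amp_tol orbit amplitude (peak-to-trough of `c`) below which a
#'   parameter fold is interpreted as the amplitude passing through zero
#'   at a Hopf endpoint (recorded as `kind = "HB"`, direction stops)
#'   rather than a fold of cycles; bifurcation tests are suppressed for
#'   such near-degenerate orbits.
#' @param hopf_ends optional parameter values of equilibrium Hopf points
#'   terminating the branch; a fold close to one of them (within
#'   `hopf_tol`) at moderate amplitude (< `amp_hopf`) is also classified
#'   as the Hopf endpoint.  With coarse steps the continuation can jump
#'   across the zero-amplitude point, so the amplitude test alone can
#'   miss a supercritical endpoint.
#' @param hopf_tol,amp_hopf thresholds for the `hopf_ends` rule.
#' @return a `ca_po_branch`: data frame with the parameter, period `T`,
#'   orbit extrema `c_max`/`c_min`, leading nontrivial multiplier
#'   modulus, trivial-multiplier error and stability flag, ordered along
#'   the branch.  Attribute `points` lists detected SNPO/PD/TR points;
#'   attribute `orbits` keeps the solved orbit of every row.
#' @examples
#' \donttest{
#' p <- ca_params(V_PLC = 0.02, delta = 2)
#' br <- continue_equilibria(p, "V_PLC", c(0.02, 0.3), model = "open")
#' hb <- branch_points(br, "HB")
#' po <- po_from_hopf(p, "V_PLC", hb[1, ], dpar = 0.005, model = "open")
#' pb <- continue_periodic_orbits(p, "V_PLC", c(0.03, 0.12), po,
#'                                start_par = po$par, model = "open")
#' }
#' @export
continue_periodic_orbits <- function(params, par_name, par_range, start,
                                     model = c("open", "closed"),
                                     start_par = start$par,
                                     nseg = ncol(start$X),
                                     step0 = 0.05, max_step = 0.25,
                                     max_steps = 150, T_max = 1000,
                                     amp_tol = 2e-3, hopf_ends = NULL,
                                     hopf_tol = 1e-3, amp_hopf = 0.05) {
  model <- match.arg(model)
  nm <- .state_names(model)
  n <- length(nm)
  m <- ncol(start$X)
  a0 <- start_par
  stopifnot(is.finite(a0))
  pl <- params; pl[[par_name]] <- a0

  sol0 <- .po_newton(start$X, start$T, pl, model)
  if (is.null(sol0)) stop("continue_periodic_orbits: start orbit did not converge")

  xsc <- .typ_scale(apply(abs(sol0$X), 1, max))
  sc <- c(rep(xsc, m), max(sol0$T / 10, 1),
          max(abs(diff(par_range)) / 20, 1e-3))
  N <- n * m + 2

  mkrow <- function(sol, a) {
    mu <- floquet_multipliers(sol)
    i1 <- which.min(Mod(mu - 1))
    ex <- .po_extrema(sol$X, sol$T, local_params(a), model)
    list(row = c(a, sol$T, ex[1], ex[2],
                 if (length(mu) > 1) max(Mod(mu[-i1])) else NA_real_,
                 abs(mu[i1] - 1), as.numeric(.po_stable(mu))),
         mu = mu)
  }
  local_params <- function(a) { pl <- params; pl[[par_name]] <- a; pl }

  solve_fixed <- function(X, T, a) .po_newton(X, T, local_params(a), model)

  # one pseudo-arclength direction
  trace_dir <- function(sol, a, dirsign) {
    u <- c(as.numeric(sol$X), sol$T, a)
    tang <- rep(0, N); tang[N] <- dirsign
    h <- step0
    rows <- list(); mus <- list(); orbits <- list(); pts <- list()
    prev_mu <- floquet_multipliers(sol)
    prev_a <- a; prev_sol <- sol
    prev_amp <- {
      ex0 <- .po_extrema(sol$X, sol$T, local_params(a), model)
      ex0[1] - ex0[2]
    }
    for (stepi in seq_len(max_steps)) {
      # tangent from the bordered shooting system
      X <- matrix(u[seq_len(n * m)], n, m); T <- u[n * m + 1]; a <- u[N]
      pla <- local_params(a)
      xref <- X[, 1]
      fref <- .vf(setNames(xref, nm), pla, model)
      sys <- .po_system(c(as.numeric(X), T), n, m, pla, model, xref, fref)
      if (is.null(sys)) break
      da <- 1e-6 * (1 + abs(a))
      sysp <- .po_system(c(as.numeric(X), T), n, m, local_params(a + da),
                         model, xref, fref, with_jac = FALSE)
      if (is.null(sysp)) break
      dr_da <- (sysp$r - sys$r) / da
      A <- rbind(cbind(sys$A, dr_da) %*% diag(sc), tang)
      tn <- tryCatch(solve(A, c(rep(0, N - 1), 1)), error = function(e) NULL)
      if (is.null(tn)) break
      tn <- tn / sqrt(sum(tn^2))
      if (sum(tn * tang) < 0) tn <- -tn
      tang <- tn

      ok <- FALSE
      for (half in 0:5) {
        hh <- h / 2^half
        upred <- u + hh * (sc * tang)
        soln <- .po_corrector(upred, tang, sc, n, m, par_name, params,
                              model, xref, fref)
        if (!is.null(soln)) { if (half > 0) h <- hh
          else if (soln$it <= 4) h <- min(h * 1.5, max_step)
          ok <- TRUE; break }
      }
      if (!ok) break
      u <- soln$u
      a <- u[N]; T <- u[n * m + 1]
      sol <- list(X = matrix(u[seq_len(n * m)], n, m), T = T,
                  monodromy = soln$monodromy)
      mu <- floquet_multipliers(sol)
      rr <- mkrow(sol, a)
      rows[[length(rows) + 1]] <- rr$row
      mus[[length(mus) + 1]] <- mu
      orbits[[length(orbits) + 1]] <- c(sol, list(par = a))

      # --- bifurcation tests against the previous orbit (suppressed on
      # near-zero-amplitude orbits where the multipliers cluster at 1)
      amp_prev <- prev_amp; amp_now <- rr$row[3] - rr$row[4]
      big_enough <- amp_prev > amp_tol && amp_now > amp_tol
      tp <- .po_tests(prev_mu); tc <- .po_tests(mu)
      if (big_enough && sign(tp["pd"]) != sign(tc["pd"])) {
        loc <- .po_bisect(prev_sol, prev_a, sol, a, "pd", solve_fixed)
        if (!is.null(loc)) pts[[length(pts) + 1]] <-
            data.frame(kind = "PD", par = loc$par, T = loc$T)
      }
      # TR requires resolvable small multipliers: on violently unstable
      # orbits (max |mu| >> 1) the small eigenvalues of the monodromy
      # matrix are numerical noise
      mu_ok <- max(Mod(prev_mu)) < 1e6 && max(Mod(mu)) < 1e6
      if (big_enough && mu_ok && sign(tp["tr"]) != sign(tc["tr"]) &&
          max(abs(tp["tr"]), abs(tc["tr"])) > 2e-3) {
        loc <- .po_bisect(prev_sol, prev_a, sol, a, "tr", solve_fixed)
        if (!is.null(loc)) pts[[length(pts) + 1]] <-
            data.frame(kind = "TR", par = loc$par, T = loc$T)
      }
      # fold in the parameter: an SNPO at finite amplitude, the Hopf
      # endpoint (amplitude through zero) otherwise
      stop_dir <- FALSE
      if (length(rows) >= 3) {
        k <- length(rows)
        a3 <- c(rows[[k - 2]][1], rows[[k - 1]][1], rows[[k]][1])
        if ((a3[2] - a3[1]) * (a3[3] - a3[2]) < 0) {
          s3 <- c(-1, 0, 1)
          b <- coef(lm(a3 ~ s3 + I(s3^2)))
          sstar <- -b[2] / (2 * b[3])
          astar <- b[1] + b[2] * sstar + b[3] * sstar^2
          mid_amp <- rows[[k - 1]][3] - rows[[k - 1]][4]
          at_hopf <- mid_amp < amp_tol ||
            (!is.null(hopf_ends) && mid_amp < amp_hopf &&
             any(abs(astar - hopf_ends) < hopf_tol * (1 + abs(astar))))
          pts[[length(pts) + 1]] <-
            data.frame(kind = if (at_hopf) "HB" else "SNPO",
                       par = astar, T = rows[[k - 1]][2])
          if (at_hopf) stop_dir <- TRUE
        }
      }
      prev_mu <- mu; prev_a <- a; prev_sol <- sol; prev_amp <- amp_now
      if (stop_dir) break
      if (T > T_max) {
        attr(rows, "homoclinic_flag") <- TRUE
        break
      }
      if (a < min(par_range) || a > max(par_range)) break
    }
    list(rows = rows, mus = mus, orbits = orbits, pts = pts)
  }

  fw <- trace_dir(sol0, a0, +1)
  bw <- trace_dir(sol0, a0, -1)
  r0 <- mkrow(sol0, a0)
  allrows <- c(rev(bw$rows), list(r0$row), fw$rows)
  df <- as.data.frame(do.call(rbind, allrows))
  names(df) <- c(par_name, "T", "c_max", "c_min", "mu_lead",
                 "trivial_err", "stable")
  df$stable <- df$stable > 0.5
  pts <- c(bw$pts, fw$pts)
  ptdf <- if (length(pts)) do.call(rbind, pts) else
    data.frame(kind = character(), par = numeric(), T = numeric())
  ptdf <- .po_clean_points(ptdf)
  orbits <- c(rev(bw$orbits), list(c(sol0, list(par = a0))), fw$orbits)
  structure(df, class = c("ca_po_branch", "data.frame"),
            par_name = par_name, model = model, params = params,
            points = ptdf, orbits = orbits)
}

# corrector step of the PO continuation: Newton on the bordered system
.po_corrector <- function(upred, tang, sc, n, m, par_name, params, model,
                          xref, fref, tol = 1e-8, maxit = 12) {
  N <- length(upred)
  local_params <- function(a) { pl <- params; pl[[par_name]] <- a; pl }
  u <- upred
  for (it in seq_len(maxit)) {
    a <- u[N]
    sys <- .po_system(u[seq_len(N - 1)], n, m, local_params(a), model,
                      xref, fref)
    if (is.null(sys)) return(NULL)
    r <- c(sys$r, sum(tang * ((u - upred) / sc)))
    if (max(abs(r)) < tol)
      return(list(u = u, it = it,
                  monodromy = Reduce(`%*%`, rev(sys$Ms))))
    da <- 1e-6 * (1 + abs(a))
    sysp <- .po_system(u[seq_len(N - 1)], n, m, local_params(a + da),
                       model, xref, fref, with_jac = FALSE)
    if (is.null(sysp)) return(NULL)
    A <- rbind(cbind(sys$A, (sysp$r - sys$r) / da), tang / sc)
    step <- tryCatch(solve(A, r), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    u <- u - step
  }
  NULL
}

# Deduplicate detected points: a branch that folds back passes the same
# bifurcation twice, and at a PD/SNPO the eigenvalue pairing can let the
# torus test fire spuriously, so (i) points of one kind closer than tol
# in the parameter are merged and (ii) TR points coinciding with a PD or
# SNPO are dropped.
.po_clean_points <- function(pts, tol = 2e-3) {
  if (!nrow(pts)) return(pts)
  out <- list()
  for (kind in unique(pts$kind)) {
    sub <- pts[pts$kind == kind, , drop = FALSE]
    sub <- sub[order(sub$par), , drop = FALSE]
    keep <- !logical(nrow(sub))
    for (i in seq_len(nrow(sub))[-1])
      if (sub$par[i] - sub$par[max(which(keep[seq_len(i - 1)]))] <
          tol * (1 + abs(sub$par[i]))) keep[i] <- FALSE
    out[[kind]] <- sub[keep, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  if ("TR" %in% res$kind) {
    other <- res$par[res$kind %in% c("PD", "SNPO")]
    drop <- res$kind == "TR" &
      vapply(res$par, function(a)
        length(other) > 0 && any(abs(a - other) < tol * (1 + abs(a))),
        logical(1))
    res <- res[!drop, , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}

# bisection localisation of PD/TR points between two solved orbits
.po_bisect <- function(sol1, a1, sol2, a2, what, solve_fixed,
                       tol_par = 1e-4, maxit = 30) {
  t1 <- .po_tests(floquet_multipliers(sol1))[what]
  for (k in seq_len(maxit)) {
    am <- (a1 + a2) / 2
    Xm <- (sol1$X + sol2$X) / 2
    Tm <- (sol1$T + sol2$T) / 2
    sm <- solve_fixed(Xm, Tm, am)
    if (is.null(sm)) return(NULL)
    tm <- .po_tests(floquet_multipliers(sm))[what]
    if (sign(tm) == sign(t1)) { a1 <- am; sol1 <- sm; t1 <- tm }
    else { a2 <- am; sol2 <- sm }
    if (abs(a2 - a1) < tol_par) break
  }
  list(par = (a1 + a2) / 2, T = sol1$T)
}

#' @export
print.ca_po_branch <- function(x, ...) {
  pn <- attr(x, "par_name")
  cat(sprintf("periodic-orbit branch in %s: %d orbits, %s in [%.5g, %.5g], T in [%.3g, %.3g] s\n",
              pn, nrow(x), pn, min(x[[pn]]), max(x[[pn]]), min(x$T), max(x$T)))
  pts <- attr(x, "points")
  if (nrow(pts))
    for (i in seq_len(nrow(pts)))
      cat(sprintf("  %s at %s = %.6g\n", pts$kind[i], pn, pts$par[i]))
  invisible(x)
}
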