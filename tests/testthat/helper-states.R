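# shared fixtures: random physically valid states at a fixed seed

random_open_states <- function(n, params, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    open_state(c = runif(1, 0.01, 1),
               c_e = runif(1, 100, 900),
               h = runif(1),
               p = runif(1, 0, 2),
               s = runif(1, 0, params$V_SOCE)))
}

random_closed_states <- function(n, params, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    closed_state(c = runif(1, 0.01, min(1, params$C_t / 2)),
                 h = runif(1),
                 p = runif(1, 0, 2)))
}

# independent bisection oracle for a Hopf point: sign change in the real
# part of the leading complex eigenvalue pair along a parameter interval,
# using only find_equilibrium + ca_jacobian (not the continuation code)
oracle_hopf <- function(params, par_name, lo, hi, guess, model,
                        tol = 1e-7) {
  testfun <- function(a) {
    pl <- params; pl[[par_name]] <- a
    eq <- find_equilibrium(pl, guess, model)
    ev <- eq$eigenvalues
    cplx <- ev[abs(Im(ev)) > 1e-9]
    max(Re(cplx))
  }
  uniroot(testfun, c(lo, hi), tol = tol)$root
}
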