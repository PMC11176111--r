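p0 <- ca_params(V_PLC = 0.1, delta = 2, C_t = 140)

test_that("total Ca2+ is conserved by construction when delta = 0", {
  p <- set_params(p0, delta = 0)
  for (st in random_open_states(50, p)) {
    d <- rhs_open(0, st, p)[[1]]
    expect_lt(abs(d[1] + d[2] / p$gamma), 1e-14)
  }
})

test_that("closed-cell RHS equals the reduced open-cell RHS", {
  p <- set_params(p0, delta = 0)
  for (st in random_closed_states(100, p)) {
    ce <- p$gamma * (p$C_t - st[["c"]])
    do <- rhs_open(0, open_state(st[["c"]], ce, st[["h"]], st[["p"]], 0),
                   p)[[1]]
    dc <- rhs_closed(0, st, p)[[1]]
    expect_lt(max(abs(dc - do[c(1, 3, 4)])), 1e-12)
  }
})

test_that("CRAC relaxation rate at the replete-ER state matches the flux law", {
  # with s = 0 and V_PLC = 0, ds/dt = J_SOCE(c_e)/tau_s
  p <- set_params(p0, V_PLC = 0)
  d <- rhs_open(0, open_state(0.850, 850, 0.95, 0, 0), p)[[1]]
  expected <- (3 / (1 + exp(0.2 * 50))) / 15
  expect_equal(d[5], expected, tolerance = 1e-12)
  expect_equal(expected, 9.08e-6, tolerance = 2e-3)
})

test_that("compiled and R right-hand sides produce identical trajectories", {
  p <- set_params(p0, V_PLC = 0.1)
  init <- open_state(0.12, 805, 0.9, 0.3, 0.8)
  a <- ca_integrate(p, init, t_end = 20, dt_out = 0.5, compiled = TRUE)
  b <- ca_integrate(p, init, t_end = 20, dt_out = 0.5, compiled = FALSE)
  expect_lt(max(abs(as.matrix(a[-1]) - as.matrix(b[-1]))), 1e-7)
})

test_that("the Jacobian matches directional derivatives of the RHS", {
  p <- p0
  st <- open_state(0.12, 805, 0.9, 0.3, 0.8)
  J <- ca_jacobian(st, p, "open")
  v <- c(1, -2, 0.5, 0.3, -1) / 10
  d <- 1e-6
  num <- (unlist(rhs_open(0, st + d * v, p)) -
          unlist(rhs_open(0, st - d * v, p))) / (2 * d)
  expect_lt(max(abs(J %*% v - num)), 1e-5)
})

test_that("state validation enforces the physical domain", {
  expect_error(rhs_open(0, open_state(0.1, NaN, 0.5, 0.1, 1), p0),
               "non-finite")
  expect_error(rhs_closed(0, closed_state(200, 0.5, 0.1), p0), "c > C_t")
  expect_error(validate_state(open_state(0.1, 800, 1.5, 0.1, 1), p0,
                              "open"), "h must lie")
  expect_error(validate_state(open_state(0.1, 800, 0.5, 0.1, 9), p0,
                              "open"), "V_SOCE")
  expect_silent(validate_state(open_state(0.1, 800, 0.5, 0.1, 9), p0,
                               "open", allow_s_outside = TRUE))
})
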