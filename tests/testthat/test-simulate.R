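test_that("a closed cell conserves total Ca2+ over 1000 s", {
  p <- ca_params(V_PLC = 0.1, delta = 0)
  init <- open_state(0.077, 770, 0.95, 0, 0)
  Ct0 <- init[["c"]] + init[["c_e"]] / p$gamma
  tr <- ca_integrate(p, init, t_end = 1000, dt_out = 1, model = "open")
  drift <- max(abs(tr$c + tr$c_e / p$gamma - Ct0))
  expect_lt(drift, 1e-6)
})

test_that("the unstimulated equilibrium is a fixed point and is stable", {
  p <- ca_params(V_PLC = 0, delta = 2)
  eq <- unstimulated_equilibrium(p, "open")
  expect_lt(max(abs(unlist(rhs_open(0, eq, p)))), 1e-10)
  st <- find_equilibrium(p, eq, "open")
  expect_lt(st$residual, 1e-10)
  expect_true(st$stable)
  # the trajectory stays put...
  tr <- ca_integrate(p, eq, t_end = 200, dt_out = 1, model = "open")
  expect_lt(max(abs(as.matrix(tr[-1]) -
                    matrix(eq, nrow(tr), 5, byrow = TRUE))), 1e-6)
  # ...and a perturbed one returns
  pert <- eq + c(1e-3, 0.1, -1e-3, 1e-3, 1e-3)
  tr2 <- ca_integrate(p, pert, t_end = 400, dt_out = 1, model = "open")
  endd <- abs(as.numeric(tr2[nrow(tr2), -1]) - as.numeric(eq))
  expect_lt(max(endd / pmax(abs(eq), 1e-3)), 1e-4)
})

test_that("closed- and open-cell trajectories agree when delta = 0", {
  p <- ca_params(V_PLC = 0.1, delta = 0, C_t = 140)
  eqc <- unstimulated_equilibrium(p, "closed")
  ce0 <- p$gamma * (p$C_t - eqc[["c"]])
  tro <- ca_integrate(p, open_state(eqc[["c"]], ce0, eqc[["h"]],
                                    eqc[["p"]], 0),
                      t_end = 50, dt_out = 0.01, model = "open")
  trc <- ca_integrate(p, eqc, t_end = 50, dt_out = 0.01, model = "closed")
  expect_lt(max(abs(tro$c - trc$c)), 1e-6)
})

test_that("integration is deterministic for identical inputs", {
  p <- ca_params(V_PLC = 0.1, delta = 2)
  a <- ca_integrate(p, t_end = 50, dt_out = 0.1)
  b <- ca_integrate(p, t_end = 50, dt_out = 0.1)
  expect_identical(as.matrix(a), as.matrix(b))
})

test_that("the unstimulated balance solver recovers the ER-load states", {
  p <- ca_params(V_PLC = 0, delta = 2)
  # replete ER: CRAC off
  hi <- unstimulated_partial_equilibrium(850, p)
  expect_lt(hi[["s"]], 1e-3)
  expect_equal(hi[["c"]], sqrt(p$K_bar) * 850, tolerance = 1e-9)
  # partially depleted ER: CRAC partially formed; s is j_soce by definition
  lo <- unstimulated_partial_equilibrium(809, p)
  expect_equal(lo[["s"]], j_soce(809, p), tolerance = 1e-12)
  expect_equal(lo[["s"]], 0.421, tolerance = 0.02)
  expect_equal(lo[["c"]], sqrt(p$K_bar) * 809, tolerance = 1e-9)
  # the full unstimulated equilibrium reproduces the printed pair
  eq <- unstimulated_equilibrium(p, "open")
  expect_equal(eq[["c_e"]], 809, tolerance = 0.02)
  expect_equal(eq[["s"]], 0.421, tolerance = 0.02)
})

test_that("integration failure is reported with the last valid time", {
  p <- ca_params(V_PLC = 0.1, delta = 2)
  expect_error(ca_integrate(p, t_end = -5), "t_end > 0")
})
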