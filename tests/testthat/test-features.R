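# Feature extraction and regime classification on the four reference
# oscillation types, plus degenerate inputs.

crac_traj <- NULL  # shared across blocks; computed once

test_that("a steady trajectory is reported as non-oscillating", {
  p <- ca_params(V_PLC = 0, delta = 2)
  tr <- ca_integrate(p, t_end = 100, dt_out = 0.1)
  ft <- oscillation_features(tr, p)
  expect_false(ft$oscillating)
  expect_identical(ft$regime, "steady")
  expect_true(is.na(ft$period))
})

test_that("the CRAC-mediated cycle is sinusoidal with period in the tens of seconds", {
  p <- ca_params(V_PLC = 0.1, delta = 2)
  crac_traj <<- ca_integrate(p, t_end = 800, dt_out = 0.05)
  ft <- oscillation_features(crac_traj, p)
  expect_true(ft$oscillating)
  expect_identical(ft$regime, "crac_sinusoidal")
  expect_gt(ft$period, 25)
  expect_lt(ft$period, 60)
  expect_gt(ft$duty_cycle, 0.4)
  expect_lt(ft$duty_cycle, 0.6)
  expect_gt(ft$s_max_fraction, 0.25)
  expect_lt(ft$s_max_fraction, 0.55)
})

test_that("the period estimate is invariant to the output sampling step", {
  p <- ca_params(V_PLC = 0.1, delta = 2)
  coarse <- ca_integrate(p, t_end = 800, dt_out = 0.25)
  f1 <- oscillation_features(crac_traj, p)
  f2 <- oscillation_features(coarse, p)
  expect_lt(abs(f1$period - f2$period) / f1$period, 0.005)
})

test_that("the three closed-cell regimes get their descriptive labels", {
  sets <- list(list(C_t = 140, V_PLC = 0.1, t_end = 200,
                    regime = "narrow_spike"),
               list(C_t = 75, V_PLC = 0.1, t_end = 300,
                    regime = "wide_spike"),
               list(C_t = 95, V_PLC = 0.195, t_end = 600,
                    regime = "wide_spike_plateau"))
  for (s in sets) {
    p <- ca_params(V_PLC = s$V_PLC, C_t = s$C_t)
    tr <- ca_integrate(p, t_end = s$t_end, dt_out = 0.01, model = "closed")
    ft <- oscillation_features(tr, p)
    expect_identical(ft$regime, s$regime,
                     info = sprintf("C_t=%g V_PLC=%g", s$C_t, s$V_PLC))
    expect_true(ft$oscillating)
  }
})

test_that("spikes riding a large CRAC swing classify as hybrid", {
  # in the overlap region of the two oscillation families (reduced CRAC
  # activation threshold) spikes coexist with slow store cycling
  p <- ca_params(K_e = 400, delta = 1.0, V_PLC = 0.1)
  tr <- ca_integrate(p, t_end = 1000, dt_out = 0.02)
  ft <- oscillation_features(tr, p)
  expect_identical(ft$regime, "hybrid")
  expect_gt(ft$s_ptp_fraction, 0.2)
  expect_lt(ft$duty_cycle, 0.25)
})

test_that("ER depletion per cycle separates the two oscillation families", {
  p <- ca_params(V_PLC = 0.1, delta = 2)
  f_crac <- oscillation_features(crac_traj, p)
  pn <- ca_params(V_PLC = 0.1, C_t = 140)
  f_spike <- oscillation_features(
    ca_integrate(pn, t_end = 200, dt_out = 0.01, model = "closed"), pn)
  expect_gt(f_crac$er_depletion_per_cycle, 10)
  expect_lt(f_spike$er_depletion_per_cycle, 5)
})
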