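# Periodic-orbit machinery: Hopf-emergence period, Floquet structure,
# and agreement between continued orbits and direct simulation.

p0 <- ca_params(V_PLC = 0.01, delta = 2)
br <- continue_equilibria(p0, "V_PLC", c(0.01, 0.3), model = "open",
                          step0 = 0.01, max_step = 0.04)
hb <- branch_points(br, "HB")

test_that("the emergent orbit period approaches 2*pi/Im(lambda) at the Hopf", {
  po <- po_from_hopf(p0, "V_PLC", hb[1, ], model = "open", nseg = 24,
                     amplitude = 0.02)
  expect_lt(abs(po$T - 2 * pi / hb$omega[1]) / po$T, 0.02)
  expect_lt(abs(po$par - hb$par[1]), 2e-3)
})

test_that("orbits carry the trivial Floquet multiplier and correct stability", {
  po <- po_from_hopf(p0, "V_PLC", hb[1, ], model = "open", nseg = 24,
                     amplitude = 0.05)
  pb <- suppressWarnings(
    continue_periodic_orbits(p0, "V_PLC", c(0.05, 0.12), po,
                             model = "open", max_steps = 40,
                             hopf_ends = hb$par))
  d <- as.data.frame(pb)
  finite_amp <- (d$c_max - d$c_min) > 2e-3
  expect_true(all(d$trivial_err[finite_amp] < 1e-3))
  expect_true(all(d$stable[finite_amp]))
  # boundary-value residual enforced by the shooting Newton tolerance
  orb <- attr(pb, "orbits")[[which(finite_amp)[1]]]
  mu <- floquet_multipliers(orb)
  expect_lt(min(Mod(mu - 1)), 1e-3)
})

test_that("continued orbits match direct simulation on the stable segment", {
  po <- po_from_hopf(p0, "V_PLC", hb[1, ], model = "open", nseg = 24,
                     amplitude = 0.05)
  pb <- suppressWarnings(
    continue_periodic_orbits(p0, "V_PLC", c(0.05, 0.12), po,
                             model = "open", max_steps = 60,
                             hopf_ends = hb$par))
  d <- as.data.frame(pb)
  i <- which.min(abs(d$V_PLC - 0.1))
  pl <- set_params(p0, V_PLC = d$V_PLC[i])
  tr <- ca_integrate(pl, t_end = 800, dt_out = 0.05, model = "open")
  ft <- oscillation_features(tr, pl)
  expect_lt(abs(ft$period_principal - d$T[i]) / d$T[i], 0.01)
  expect_lt(abs(ft$c_max - d$c_max[i]), 5e-3)
})

test_that("an orbit polished from simulation closes to shooting tolerance", {
  p <- ca_params(V_PLC = 0.1, C_t = 140)
  tr <- ca_integrate(p, t_end = 150, dt_out = 0.002, model = "closed")
  sol <- po_from_simulation(tr, p, "closed", nseg = 30)
  expect_lt(sol$resid, 1e-9)
  mu <- floquet_multipliers(sol)
  expect_lt(min(Mod(mu - 1)), 1e-3)   # trivial multiplier
  # the attractor is stable: nontrivial multipliers inside the circle
  i <- which.min(Mod(mu - 1))
  expect_true(all(Mod(mu[-i]) < 1))
  # and its period matches the waveform
  ft <- oscillation_features(tr, p)
  expect_lt(abs(sol$T - ft$period) / ft$period, 0.01)
})
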