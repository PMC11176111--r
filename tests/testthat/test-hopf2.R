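# Two-parameter Hopf curves: consistency with one-parameter
# localisation, and the geometry of the oscillatory regions.

p0 <- ca_params(V_PLC = 0.01, delta = 2)
br <- continue_equilibria(p0, "V_PLC", c(0.01, 0.3), model = "open",
                          step0 = 0.01, max_step = 0.04)
hb <- branch_points(br, "HB")
curve_s1 <- continue_hopf_2par(p0, "V_PLC", "s1", hb[1, ],
                               box = c(0.005, 0.45, 0.05, 0.45),
                               model = "open", max_steps = 300)

test_that("the Hopf curve passes through the one-parameter Hopf point", {
  # at the reference steepness the curve must cross the V_PLC of the
  # one-parameter diagram's Hopf
  i <- which(abs(curve_s1$s1 - p0$s1) < 2e-3)
  expect_gt(length(i), 0)
  expect_lt(min(abs(curve_s1$V_PLC[i] - hb$par[1])), 2e-3)
})

test_that("sampled curve points re-verify by one-parameter localisation", {
  idx <- round(seq(5, nrow(curve_s1) - 5, length.out = 4))
  nm <- c("c", "c_e", "h", "p", "s")
  for (i in idx) {
    pl <- set_params(p0, s1 = curve_s1$s1[i])
    guess <- setNames(as.numeric(curve_s1[i, nm]), nm)
    a_star <- oracle_hopf(pl, "V_PLC", curve_s1$V_PLC[i] - 5e-3,
                          curve_s1$V_PLC[i] + 5e-3, guess, "open")
    expect_lt(abs(curve_s1$V_PLC[i] - a_star), 1e-4)
  }
})

test_that("the eigenpair on the curve is purely imaginary to tolerance", {
  nm <- c("c", "c_e", "h", "p", "s")
  idx <- round(seq(1, nrow(curve_s1), length.out = 8))
  for (i in idx) {
    pl <- set_params(p0, s1 = curve_s1$s1[i], V_PLC = curve_s1$V_PLC[i])
    st <- setNames(as.numeric(curve_s1[i, nm]), nm)
    ev <- eigen(ca_jacobian(st, pl, "open"), only.values = TRUE)$values
    cplx <- ev[abs(Im(ev)) > 1e-6]
    expect_lt(min(abs(Re(cplx))), 1e-6)
  }
})

test_that("a minimum CRAC steepness is required for oscillation", {
  expect_gt(min(curve_s1$s1), 0.1)
  expect_lt(min(curve_s1$s1), 0.2)
})
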