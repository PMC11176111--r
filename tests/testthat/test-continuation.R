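# Equilibrium continuation: Hopf detection against an independent
# bisection oracle, stability bookkeeping, and step-halving invariance.

p_open <- ca_params(V_PLC = 0.01, delta = 2)
br <- continue_equilibria(p_open, "V_PLC", c(0.01, 0.3), model = "open",
                          step0 = 0.01, max_step = 0.04)

test_that("the open-cell equilibrium branch has exactly two Hopf points", {
  hb <- branch_points(br, "HB")
  expect_identical(nrow(hb), 2L)
  expect_true(all(hb$par > 0.01 & hb$par < 0.3))
  expect_lt(hb$par[1], 0.1)
  expect_gt(hb$par[2], 0.1)
  # stable outside the Hopf window, unstable inside
  inside <- br$V_PLC > min(hb$par) + 1e-3 & br$V_PLC < max(hb$par) - 1e-3
  outside <- br$V_PLC < min(hb$par) - 1e-3 | br$V_PLC > max(hb$par) + 1e-3
  expect_true(all(!br$stable[inside]))
  expect_true(all(br$stable[outside]))
})

test_that("every accepted branch point satisfies the equilibrium equations", {
  nm <- c("c", "c_e", "h", "p", "s")
  idx <- seq(1, nrow(br), length.out = 12)
  for (i in round(idx)) {
    pl <- set_params(p_open, V_PLC = br$V_PLC[i])
    st <- setNames(as.numeric(br[i, nm]), nm)
    expect_lt(max(abs(unlist(rhs_open(0, st, pl)))), 1e-8)
  }
})

test_that("Hopf localisation agrees with an independent eigenvalue bisection", {
  hb <- branch_points(br, "HB")
  guess <- open_state(0.1, 806, 0.87, 0.2, 0.7)
  for (i in 1:2) {
    a_star <- oracle_hopf(p_open, "V_PLC", hb$par[i] - 0.01,
                          hb$par[i] + 0.01, guess, "open")
    expect_lt(abs(hb$par[i] - a_star), 1e-5)
  }
})

test_that("detected Hopf positions are invariant under step halving", {
  br2 <- continue_equilibria(p_open, "V_PLC", c(0.01, 0.3), model = "open",
                             step0 = 0.005, max_step = 0.02)
  h1 <- branch_points(br, "HB")$par
  h2 <- branch_points(br2, "HB")$par
  expect_identical(length(h1), length(h2))
  expect_lt(max(abs(sort(h1) - sort(h2))), 1e-4)
})

test_that("the closed-cell branch at high total Ca2+ has two Hopf points", {
  p <- ca_params(V_PLC = 0.005, C_t = 140)
  brc <- continue_equilibria(p, "V_PLC", c(0.005, 0.4), model = "closed",
                             step0 = 0.01, max_step = 0.03)
  hb <- branch_points(brc, "HB")
  expect_identical(nrow(hb), 2L)
  expect_gt(hb$omega[1], 0)
})

test_that("the steepness continuation loses stability at the low-s1 Hopf", {
  p <- ca_params(V_PLC = 0.1, delta = 2, s1 = 0.3)
  brs <- continue_equilibria(p, "s1", c(0.3, 0.1), model = "open",
                             step0 = 0.02, max_step = 0.08)
  hb <- branch_points(brs, "HB")
  expect_gte(nrow(hb), 1)
  s1_hb <- max(hb$par)
  expect_gt(s1_hb, 0.14)
  expect_lt(s1_hb, 0.2)
  # equilibrium stable below the Hopf (oscillation lost), unstable above
  expect_true(all(br <- brs$stable[brs$s1 < s1_hb - 1e-3]))
  expect_true(all(!brs$stable[brs$s1 > s1_hb + 1e-3]))
})
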