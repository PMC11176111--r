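p0 <- ca_params(V_PLC = 0.1, delta = 2)

test_that("SOCE flux: midpoint, saturation and an independent evaluation", {
  expect_equal(j_soce(p0$K_e, p0), p0$V_SOCE / 2)
  expect_lt(abs(j_soce(0, p0) - p0$V_SOCE), 1e-6)
  # independent scalar evaluation of the sigmoid at c_e = 850
  pv <- set_params(p0, V_SOCE = 3, s1 = 0.2, K_e = 800)
  expect_equal(j_soce(850, pv), 3 / (1 + exp(0.2 * 50)), tolerance = 1e-12)
  expect_error(j_soce(NaN, p0), "non-finite")
  expect_error(j_soce(-5, p0), ">= 0")
})

test_that("SOCE flux is monotone decreasing and bounded on a fine grid", {
  # far into the tails the sigmoid saturates to the bounds at double
  # precision, so strictness is asserted where doubles resolve it
  ce <- seq(0, 1200, length.out = 1000)
  v <- j_soce(ce, p0)
  expect_true(all(diff(v) <= 0))
  expect_true(all(v >= 0 & v <= p0$V_SOCE))
  ce2 <- seq(650, 950, length.out = 1000)
  v2 <- j_soce(ce2, p0)
  expect_true(all(diff(v2) < 0))
  expect_true(all(v2 > 0 & v2 < p0$V_SOCE))
})

test_that("IP3 degradation: zero at c = 0, half-saturation, linear in p", {
  expect_equal(j_deg(0, 5, p0), 0)
  expect_equal(j_deg(p0$K_deg, 1, p0), p0$V_deg / 2)
  expect_equal(j_deg(1e6, 1, p0), p0$V_deg, tolerance = 1e-10)
  expect_equal(j_deg(0.3, 2, p0), 2 * j_deg(0.3, 1, p0))
  expect_error(j_deg(-1, 1, p0), ">= 0")
  expect_error(j_deg(1, -1, p0), ">= 0")
})

test_that("IP3R gating stays within probability bounds on random states", {
  sts <- random_open_states(10000, p0)
  c <- vapply(sts, `[[`, numeric(1), "c")
  p <- vapply(sts, `[[`, numeric(1), "p")
  h <- vapply(sts, `[[`, numeric(1), "h")
  P0 <- p_open(c, p, h, p0)
  expect_true(all(P0 >= 0 & P0 <= 1))
  expect_true(all(h_inf(c, p0) >= 0 & h_inf(c, p0) <= 1))
  expect_true(all(tau_h(c, p0) > 0 & tau_h(c, p0) <= p0$tau_max))
})

test_that("open- and closed-cell flux forms agree under substitution", {
  p <- set_params(p0, C_t = 140)
  sts <- random_closed_states(100, p)
  for (st in sts) {
    fc <- flux_breakdown(st, p, "closed")
    fo <- flux_breakdown(open_state(st[["c"]], fc$c_e, st[["h"]],
                                    st[["p"]], 0), p, "open")
    for (nm in c("J_IP3R", "J_SERCA", "J_PM", "J_SOCE", "J_deg", "P0"))
      expect_lt(abs(fc[[nm]] - fo[[nm]]), 1e-12)
  }
})

test_that("SOCE is fully off at the replete-ER unstimulated state", {
  # c_e = 850 sits 50 uM above the activation midpoint
  fb <- flux_breakdown(open_state(0.0850, 850, 0.95, 0, 0),
                       set_params(p0, V_PLC = 0), "open")
  expect_lt(fb$J_SOCE, 1e-3)
  expect_gt(fb$J_SOCE, 0)
})

test_that("SERCA reverses only through its reverse-mode term", {
  # forward for any c with an empty ER; reversed only when the reverse
  # term K_bar * c_e^2 dominates c^2
  expect_gt(tcellosc:::.j_serca(0.1, 0, p0), 0)
  expect_lt(tcellosc:::.j_serca(0.05, 850, p0), 0)
  cstar <- sqrt(p0$K_bar) * 850
  expect_equal(tcellosc:::.j_serca(cstar, 850, p0), 0, tolerance = 1e-15)
})
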