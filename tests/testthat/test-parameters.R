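test_that("default constructor reproduces the reference parameter set", {
  p <- ca_params()
  ref <- c(gamma = 5.5, V_PM = 3, K_PM = 0.2, V_SOCE = 3, s1 = 0.2,
           tau_s = 15, K_e = 800, V_SERCA = 2, K_bar = 1e-8,
           K_SERCA = 0.19, V_deg = 6, K_deg = 0.5, k_f = 1.6,
           k_beta = 0.4, K_p = 10, K_c = 0.16, K_h = 0.168,
           tau_max = 7.5, K_tau = 0.095, tau_p = 2)
  for (nm in names(ref))
    expect_identical(p[[nm]], unname(ref[nm]), info = nm)
})

test_that("the bundled reference JSON matches the constructor defaults", {
  path <- system.file("extdata", "params_reference.json",
                      package = "tcellosc")
  expect_true(nzchar(path))
  pj <- read_ca_params(path)
  p <- ca_params(V_PLC = pj$V_PLC, delta = pj$delta, C_t = pj$C_t)
  expect_equal(unclass(pj), unclass(p))
})

test_that("JSON round-trip preserves every field exactly", {
  p <- ca_params(V_PLC = 0.1234, delta = 0.62, s1 = 0.1468)
  f <- withr::local_tempfile(fileext = ".json")
  write_ca_params(p, f)
  expect_equal(unclass(read_ca_params(f)), unclass(p))
})

test_that("validation rejects non-physical parameter sets", {
  expect_error(ca_params(V_SOCE = -1), "strictly positive")
  expect_error(ca_params(delta = -0.1), "non-negative")
  expect_error(ca_params(tau_s = 0), "strictly positive")
  expect_error(set_params(ca_params(), nonsense = 1), "unknown parameter")
  expect_error(validate_ca_params(list(V_PLC = 1)), "missing field")
  expect_error(ca_params(K_e = NaN), "non-finite")
})
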