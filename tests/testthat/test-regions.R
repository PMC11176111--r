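test_that("the regime map labels the two oscillation families", {
  p <- ca_params()
  rm <- region_map(p, "delta", c(0.01, 2), "V_PLC", c(0.1, 0.3),
                   model = "open", t_end = 500, dt_out = 0.05)
  expect_identical(nrow(rm), 4L)
  expect_false(any(rm$regime == "failed"))
  get <- function(d, v) rm$regime[rm$delta == d & rm$V_PLC == v]
  expect_identical(get(2, 0.1), "crac_sinusoidal")
  expect_true(get(0.01, 0.1) %in% c("narrow_spike", "wide_spike"))
  expect_identical(get(2, 0.3), "steady")
})

test_that("grid limits are enforced", {
  p <- ca_params()
  expect_error(region_map(p, "delta", seq(0, 1, length.out = 150),
                          "V_PLC", 0.1), "100")
})
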