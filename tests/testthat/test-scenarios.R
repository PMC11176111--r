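test_that("regime pipelines write reproducible data and a stable summary", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- reproduce_figure("3B", out_dir = d1)
  r2 <- reproduce_figure("3B", out_dir = d2)
  expect_identical(r1$summary, r2$summary)
  expect_true(file.exists(file.path(d1, "trajectory.csv")))
  expect_true(file.exists(file.path(d1, "summary.json")))
  expect_identical(unname(tools::md5sum(file.path(d1, "trajectory.csv"))),
                   unname(tools::md5sum(file.path(d2, "trajectory.csv"))))
  js <- jsonlite::fromJSON(file.path(d1, "summary.json"))
  expect_identical(js$figure, "3B")
  expect_identical(js$schema_version, 1L)
  expect_identical(js$summary$regime, "narrow_spike")
})

test_that("the ER-load scenario separates high and low initial loads", {
  sc <- reproduce_figure("7")
  expect_identical(sc$summary$low_load$n_transient_spikes, 0L)
  expect_gt(sc$summary$high_load$n_transient_spikes, 2L)
  expect_gt(sc$summary$high_load$spike_duration, 10)
  expect_lt(sc$summary$high_load$spike_duration, 60)
  # both runs converge to the same limit cycle
  expect_lt(abs(sc$summary$low_load$period - sc$summary$high_load$period) /
              sc$summary$low_load$period, 0.01)
})

test_that("fast CICR gating is absent during CRAC cycling", {
  r <- reproduce_figure("6")
  # narrow spikes open and shut the IP3R sharply within each cycle;
  # the CRAC cycle keeps it moderately open throughout
  expect_gte(r$summary$pulsatility_spike, 5)
  expect_lte(r$summary$pulsatility_crac, 3)
  expect_gt(r$summary$pulsatility_spike / r$summary$pulsatility_crac, 2)
})

test_that("unknown figure ids are rejected", {
  expect_error(reproduce_figure("99"))
})
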