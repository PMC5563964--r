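# Bulk rate estimation from 13C-DIC series, fold changes, headspace
# partitioning and delta-notation conversions.

test_that("rate estimator inverts the series generator exactly", {
  ser <- simulate_incubation_series(2.7, 2000, 20, times = seq(0, 16, 2))
  fit <- mox_rate(ser)
  expect_equal(fit$rate, 2.7, tolerance = 1e-10)
  expect_false(fit$negative_slope)
  # flat series -> rate 0
  flat <- simulate_incubation_series(0, 2000, 20, times = 0:6)
  expect_equal(mox_rate(flat)$rate, 0)
  # declining label -> truncated to 0 with flag
  dec <- data.frame(time_d = 0:4, atpct_dic = c(1.5, 1.4, 1.3, 1.2, 1.1))
  fit_dec <- mox_rate(dec, dic = 2000, labeling_atpct = 20)
  expect_equal(fit_dec$rate, 0)
  expect_true(fit_dec$negative_slope)
})

test_that("rate scales with DIC and inversely with labeling; offset-invariant", {
  ser <- simulate_incubation_series(2.7, 2000, 20, seq(0, 16, 2),
                                    noise_sd_atpct = 0.02, seed = 3)
  base <- mox_rate(ser)$rate
  expect_equal(mox_rate(ser, dic = 4000)$rate, 2 * base)
  expect_equal(mox_rate(ser, labeling_atpct = 40)$rate, base / 2)
  shifted <- ser
  shifted$atpct_dic <- shifted$atpct_dic + 0.5
  expect_equal(mox_rate(shifted)$rate, base)
})

test_that("explicit linear-phase windows restrict the fit", {
  ser <- simulate_incubation_series(2.7, 2000, 20, times = 0:9)
  bent <- ser
  bent$atpct_dic[8:10] <- bent$atpct_dic[8]  # substrate exhausted, plateau
  full <- mox_rate(bent)
  early <- mox_rate(bent, window = 1:7)
  expect_equal(early$rate, 2.7, tolerance = 1e-10)
  expect_lt(full$rate, 2.7)
  expect_error(mox_rate(ser, window = 1), "two time")
})

test_that("rate errors on invalid inputs", {
  ser <- simulate_incubation_series(2.7, 2000, 20, 0:5)
  bare <- data.frame(time_d = ser$time_d, atpct_dic = ser$atpct_dic)
  expect_error(mox_rate(bare), "must be supplied")
  expect_error(mox_rate(ser, dic = 2000, labeling_atpct = 0), "> 0")
  bad <- data.frame(time_d = 0:2, atpct_dic = c(1, 150, 2))
  expect_error(mox_rate(bad, dic = 2000, labeling_atpct = 20), "\\[0, 100\\]")
})

test_that("treatment/control fold change matches the reported contrast", {
  expect_equal(round(fold_change(2.7, 0.234), 1), 11.5)
  expect_gte(fold_change(2.7, 0.234), 10)
  expect_equal(fold_change(1, 1), 1)
  expect_error(fold_change(1, 0), "> 0")
  t_fit <- mox_rate(simulate_incubation_series(2.7, 2000, 20, seq(0, 16, 2)))
  c_fit <- mox_rate(simulate_incubation_series(0.234, 2000, 20, seq(0, 16, 2)))
  expect_equal(fold_change(t_fit, c_fit), 2.7 / 0.234, tolerance = 1e-9)
})

test_that("dissolved methane partitioning closes its mass balance", {
  # zero pressure -> zero everywhere
  z <- dissolved_ch4(30, 120, 279.15, ch4_atm = 0)
  expect_equal(z$total_umol, 0)
  # closed-system partition recovers the planned spike to < 0.1%
  for (spike in c(5, 200, 5000)) {
    eq <- equilibrate_headspace(spike, headspace_ml = 30, liquid_ml = 120,
                                temperature_K = 279.15)
    expect_lt(abs(eq$total_umol - spike) / spike, 1e-3)
    expect_equal(eq$aqueous_umol + eq$headspace_umol, eq$total_umol)
  }
  # colder water holds strictly more methane at equal pressure
  expect_gt(ch4_solubility(279.15), ch4_solubility(298.15))
  # ~1.4 mmol/l at 25 degC and 1 atm (handbook magnitude)
  expect_lt(abs(ch4_solubility(298.15) - 1400) / 1400, 0.05)
  expect_error(ch4_solubility(320), "validity")
})

test_that("delta13C to at% conversion and round trip", {
  expect_equal(delta13c_to_atpct(0), 1.1056, tolerance = 1e-4)
  expect_error(delta13c_to_atpct(-1000), "-1000")
  d <- c(-500, -50, 0, 50, 500, 5000)
  expect_equal(atpct_to_delta13c(delta13c_to_atpct(d)), d)
  a <- c(0.5, 1.11, 10, 50, 99)
  expect_equal(delta13c_to_atpct(atpct_to_delta13c(a)), a)
})

test_that("series CSV round trips with pool metadata", {
  ser <- simulate_incubation_series(2.7, 2000, 20, seq(0, 16, 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_series_csv(ser, path)
  back <- read_series_csv(path, dic = 2000, labeling_atpct = 20)
  expect_equal(back$atpct_dic, ser$atpct_dic)
  expect_equal(mox_rate(back)$rate, 2.7, tolerance = 1e-10)
})
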