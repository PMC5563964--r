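# ROI quantification: alignment, accumulation, isotope ratios, counting
# statistics, background comparison and the ratio floor.

test_that("at% <-> ratio round trip is exact", {
  a <- c(0.001, 1.11, 8.68, 22, 50, 99.9)
  expect_equal(atpct_from_ratio(ratio_from_atpct(a)), a)
  expect_equal(atpct_from_ratio(0.015), 100 * 0.015 / 1.015)
  expect_error(ratio_from_atpct(100), "\\[0, 100\\)")
  expect_error(atpct_from_ratio(-0.1), ">= 0")
})

test_that("alignment recovers planned drift and is identity without drift", {
  # drift-free: all shifts zero
  fld0 <- simulate_field(simple_filament_plan(0.22, seed = 31))
  al0 <- align_planes(fld0$stacks$s32, max_shift = 4)
  expect_true(all(al0$shifts == 0L))
  # planned drift (+2, -1) on plane 3 recovered as corrective (-2, +1)
  drift <- rbind(c(0, 0), c(0, 0), c(2, -1), c(0, 0), c(0, 0))
  fld <- simulate_field(simple_filament_plan(0.22, drift = drift, seed = 32))
  al <- align_field(fld$stacks, max_shift = 4)
  expect_equal(al$shifts, matrix(-drift, ncol = 2L,
                                 dimnames = list(NULL, c("dx", "dy"))),
               ignore_attr = TRUE)
  # out-of-frame pixels are NA-masked in the aligned planes
  expect_true(anyNA(al$stacks$c12$planes[, , 3]))
  # single plane: identity
  one <- ion_stack(list(matrix(1L, 8, 8)), "12C")
  expect_true(all(align_planes(one)$shifts == 0L))
})

test_that("accumulate equals the brute-force per-pixel loop", {
  set.seed(77)
  planes <- lapply(1:4, function(i) matrix(rpois(30 * 20, 7), 30, 20))
  st <- ion_stack(planes, "12C")
  expect_equal(accumulate(st), oracle_accumulate(planes),
               ignore_attr = TRUE)
  # three planes of ones -> all threes
  ones <- ion_stack(lapply(1:3, function(i) matrix(1L, 5, 5)), "12C")
  expect_equal(accumulate(ones), matrix(3, 5, 5), ignore_attr = TRUE)
  # masked pixels are excluded and coverage-flagged
  p <- list(matrix(2L, 4, 4), matrix(2L, 4, 4))
  p[[2]][1, 1] <- NA
  acc <- accumulate(ion_stack(p, "12C"))
  expect_equal(acc[1, 1], 2)
  expect_equal(attr(acc, "planes_per_pixel")[1, 1], 1)
  expect_equal(attr(acc, "planes_per_pixel")[2, 2], 2)
})

test_that("measure_roi computes the arithmetic identities and Poisson SE", {
  c12 <- matrix(0, 2, 2); c13 <- matrix(0, 2, 2)
  mask <- matrix(c(1L, 1L, 0L, 0L), 2, 2)
  c12[mask == 1L] <- c(8000, 900)
  c13[mask == 1L] <- c(90, 10)
  m <- measure_roi(c12, c13, mask, 1L)
  expect_equal(m$atpct, 100 * 100 / 9000)
  expect_equal(m$ratio, 100 / 8900)
  expect_equal(m$atpct_se, 100 * sqrt(100 * 8900 / 9000^3))
  expect_equal(m$atpct, atpct_from_ratio(m$ratio))
  # errors and edge cases
  expect_error(measure_roi(c12, c13, mask, 7L), "not present")
  expect_error(measure_roi(matrix(0, 2, 2), matrix(0, 2, 2), mask, 1L),
               "zero total")
  z <- measure_roi(matrix(0, 2, 2), matrix(c(5, 5, 0, 0), 2, 2), mask, 1L)
  expect_true(z$undefined_ratio)
  expect_equal(z$atpct, 100)
})

test_that("SE(at%) scales as 1/sqrt(total counts)", {
  # doubling planes halves the variance: SE ratio sqrt(2) within 5%
  f10 <- simulate_field(simple_filament_plan(0.1, density = 500,
                                             n_planes = 10, seed = 41))
  f20 <- simulate_field(simple_filament_plan(0.1, density = 500,
                                             n_planes = 20, seed = 41))
  m10 <- measure_roi(accumulate(f10$stacks$c12), accumulate(f10$stacks$c13),
                     f10$mask, 1L)
  m20 <- measure_roi(accumulate(f20$stacks$c12), accumulate(f20$stacks$c13),
                     f20$mask, 1L)
  expect_lt(abs(m10$atpct_se / m20$atpct_se - sqrt(2)), 0.05 * sqrt(2))
})

test_that("background evaluation flags exactly the enriched object", {
  plan <- scene_plan(
    shape = c(48L, 64L), pixel_size_um = 0.5,
    objects = list(
      coccus_object(c(6, 6), 4, atom_fraction = 0.10, density = 200),
      coccus_object(c(16, 6), 4, atom_fraction = 0.0111, density = 200)
    ),
    n_planes = 10L, background_density = 100, seed = 55
  )
  fld <- simulate_field(plan)
  mask <- fld$mask
  mask[mask == 0L] <- 99L  # cell-free filter as background ROI
  m <- measure_rois(accumulate(fld$stacks$c12), accumulate(fld$stacks$c13),
                    mask, background_labels = 99L)
  ev <- evaluate_background(m)
  flags <- ev$measurements
  expect_true(flags$enriched[flags$roi_id == 1L])
  expect_false(flags$enriched[flags$roi_id == 2L])
  expect_true(is.na(flags$enriched[flags$roi_id == 99L]))
  expect_lt(abs(ev$background_atpct - 1.11), 5 * ev$background_se)
  # no background ROI -> error
  expect_error(evaluate_background(m[!m$background, ]), "background")
})

test_that("ratio floor retains, records, and is idempotent", {
  m <- data.frame(roi_id = 1:6,
                  ratio = c(0.02, 0.0149, 0.3, 0.015, 0.001, 0.111))
  kept <- apply_ratio_floor(m)
  expect_equal(kept$roi_id, c(1L, 3L, 4L, 6L))
  expect_equal(attr(kept, "n_excluded"), 2L)
  again <- apply_ratio_floor(kept)
  expect_equal(again$roi_id, kept$roi_id)
  expect_equal(attr(again, "n_excluded"), 0L)
  # order independence
  perm <- apply_ratio_floor(m[sample(6), ])
  expect_setequal(perm$roi_id, kept$roi_id)
  # floor 0 retains everything; all-below retains none
  expect_equal(nrow(apply_ratio_floor(m, 0)), 6L)
  none <- apply_ratio_floor(m, 1)
  expect_equal(nrow(none), 0L)
  expect_equal(attr(none, "n_excluded"), 6L)
})

test_that("cohort at% summary uses mean and n-1 s.d.", {
  s <- summarize_population_atpct(c(20, 22, 24))
  expect_equal(s$mean_atpct, 22)
  expect_equal(s$sd_atpct, 2)
  one <- summarize_population_atpct(data.frame(atpct = 9.3))
  expect_equal(one$sd_atpct, 0)
  expect_true(one$single)
  expect_error(summarize_population_atpct(numeric(0)), "no measurements")
})

test_that("measurement CSV round trips", {
  fld <- simulate_field(simple_filament_plan(0.22, seed = 61))
  m <- measure_rois(accumulate(fld$stacks$c12), accumulate(fld$stacks$c13),
                    fld$mask)
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements_csv(m, path)
  back <- read_measurements_csv(path)
  expect_equal(back$atpct, m$atpct)
  expect_equal(back$c12, m$c12)
})
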