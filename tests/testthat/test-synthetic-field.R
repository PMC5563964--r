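# Synthetic nanoSIMS field generator: measurement model, determinism,
# ground truth and serialization.

test_that("seed determinism gives bit-identical fields", {
  f1 <- simulate_field(simple_filament_plan(0.22, seed = 11))
  f2 <- simulate_field(simple_filament_plan(0.22, seed = 11))
  f3 <- simulate_field(simple_filament_plan(0.22, seed = 12))
  expect_identical(f1$stacks$c13$planes, f2$stacks$c13$planes)
  expect_identical(f1$stacks$c12$planes, f2$stacks$c12$planes)
  expect_false(identical(f1$stacks$c13$planes, f3$stacks$c13$planes))
})

test_that("expected 12C+13C counts per pixel match the planned density", {
  # >= 1e4 pixels at density 100: empirical mean within 1% of plan
  plan <- scene_plan(
    shape = c(104L, 104L), pixel_size_um = 0.5,
    objects = list(coccus_object(c(26, 26), 50, atom_fraction = 0.2,
                                 density = 100)),
    n_planes = 2L, background_density = 100, seed = 42
  )
  fld <- simulate_field(plan)
  total <- fld$stacks$c12$planes + fld$stacks$c13$planes
  expect_gt(length(total), 1e4)
  expect_lt(abs(mean(total) - 100) / 100, 0.01)
})

test_that("ROI at% recovers a natural-abundance and an enriched truth", {
  for (f in c(0.0111, 0.22)) {
    fld <- simulate_field(simple_filament_plan(f, density = 1000,
                                               n_planes = 20, seed = 5))
    m <- measure_roi(accumulate(fld$stacks$c12), accumulate(fld$stacks$c13),
                     fld$mask, 1L)
    expect_lt(abs(m$atpct - 100 * f), 2 * m$atpct_se)
  }
})

test_that("ground-truth biovolume equals the morphometry formulas", {
  plan <- scene_plan(
    shape = c(64L, 64L), pixel_size_um = 0.5,
    objects = list(
      filament_object(c(4, 8), c(4 + 45, 8), width_um = 1.5,
                      atom_fraction = 0.1, density = 50),
      coccus_object(c(10, 20), diameter_um = 2, atom_fraction = 0.1,
                    density = 50)
    ),
    n_planes = 1L, seed = 1
  )
  # 45 um filament sticks out of the 32 um field; geometry truth is analytic
  expect_equal(simulate_field(plan)$truth$biovolume_um3,
               c(cylinder_biovolume(45, 1.5), sphere_biovolume(2)))
})

test_that("label mask labels exactly the rendered object pixels", {
  fld <- simulate_field(simple_filament_plan(0.22, seed = 2))
  expect_identical(sort(unique(as.vector(fld$mask))), c(0L, 1L))
  expect_identical(sum(fld$mask == 1L), fld$truth$n_pixels[1])
  # 32S signal concentrates on object pixels
  s <- accumulate(fld$stacks$s32)
  expect_gt(mean(s[fld$mask == 1L]), 10 * max(mean(s[fld$mask == 0L]), 0.01))
})

test_that("invalid plans are rejected", {
  expect_error(simple_filament_plan(1.2), "atom fraction")
  expect_error(simple_filament_plan(0.2, density = -5), "densities")
  expect_error(simple_filament_plan(0.2, n_planes = 0), "positive integer")
  expect_error(simple_filament_plan(0.2, drift = rbind(c(0, 0), c(99, 0)),
                                    n_planes = 2),
               "smaller than the image shape")
  # overlapping objects with conflicting atom fractions
  plan_args <- list(
    shape = c(32L, 32L), pixel_size_um = 0.5,
    objects = list(coccus_object(c(8, 8), 4, 0.1, 50),
                   coccus_object(c(8.5, 8), 4, 0.3, 50)),
    n_planes = 1L, seed = 1
  )
  expect_error(simulate_field(do.call(scene_plan, plan_args)),
               "overlap")
})

test_that("stacks and masks survive a TIFF round trip", {
  fld <- simulate_field(simple_filament_plan(0.22, seed = 3))
  dir <- withr::local_tempdir()
  write_sim_field(fld, dir)
  back <- read_ion_stack(file.path(dir, "c13.tif"))
  expect_equal(back$planes, fld$stacks$c13$planes)
  expect_identical(back$mass, "13C")
  expect_equal(back$pixel_size_um, 0.5)
  expect_identical(read_label_mask(file.path(dir, "mask.tif")), fld$mask)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$truth$biovolume_um3, fld$truth$biovolume_um3)
})

test_that("incubation series generator matches its linear model", {
  flat <- simulate_incubation_series(0, 2000, 20, times = 0:5)
  expect_equal(flat$atpct_dic, rep(1.11, 6))
  ser <- simulate_incubation_series(2.7, 2000, 20, times = seq(0, 16, 2))
  expect_equal(diff(ser$atpct_dic) / diff(ser$time_d),
               rep(100 * 2.7 * 0.2 / 2000, 8))
  # reproducibility under seed
  n1 <- simulate_incubation_series(2.7, 2000, 20, 0:8, noise_sd_atpct = 0.05,
                                   seed = 9)
  n2 <- simulate_incubation_series(2.7, 2000, 20, 0:8, noise_sd_atpct = 0.05,
                                   seed = 9)
  expect_identical(n1$atpct_dic, n2$atpct_dic)
  expect_error(simulate_incubation_series(2.7, 0, 20, 0:5), "dic")
  expect_error(simulate_incubation_series(2.7, 2000, 20, 0:5,
                                          noise_sd_atpct = -1), "noise_sd")
  expect_error(simulate_incubation_series(2.7, 2000, 20, times = 1), "two time")
})

test_that("probe target construction plants exact best-window distances", {
  probe <- "GCCTTCCCACATCGTTT"
  counts <- c(0, 1, 5)
  tg <- simulate_probe_targets(probe, counts, seed = 21)
  for (i in seq_along(counts)) {
    expect_identical(oracle_min_mismatch(probe, tg[[i]]), counts[i])
  }
  expect_error(simulate_probe_targets(probe, nchar(probe) + 1),
               "exceeds the probe length")
  # determinism
  expect_identical(as.character(simulate_probe_targets(probe, c(2), seed = 4)),
                   as.character(simulate_probe_targets(probe, c(2), seed = 4)))
})
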