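# Seed-controlled recovery experiments: run the full synthetic chain many
# times and score how often the estimator's counting-statistics error bars
# cover the planned truth. These are the package's calibration checks for
# the ROI at% estimator and the bulk rate estimator.

#' ROI at% and drift recovery over many simulated fields
#'
#' Simulates `n_fields` single-cell fields (one coccoid ROI each, total
#' carbon count depth above 10^4), applies random integer stage drift of up
#' to `max_drift` px per plane, runs the full quantification chain
#' (alignment on the 32S channel, accumulation, ROI measurement) and scores
#' each field for (a) the at% estimate falling within 2 counting-statistics
#' SE of the planned truth and (b) exact recovery of the planned drift.
#'
#' @param n_fields number of simulated fields.
#' @param true_atpct vector of true at% values cycled over fields; defaults
#'   to natural abundance plus two enrichment levels typical of labelled
#'   methanotroph cells.
#' @param seed base seed; field i uses `seed + i`.
#' @param n_planes acquisition planes per field.
#' @param density expected total carbon counts per pixel per plane.
#' @param max_drift maximum |dx|, |dy| of the random per-plane drift (px).
#' @return data frame with one row per field: `field`, `true_atpct`,
#'   `atpct`, `atpct_se`, `total_counts`, `within_2se`, `drift_exact`.
#' @export
atpct_recovery_experiment <- function(n_fields = 100,
                                      true_atpct = c(1.11, 9.26, 22.0),
                                      seed = 1L, n_planes = 5L,
                                      density = 50, max_drift = 5L) {
  rows <- vector("list", n_fields)
  for (i in seq_len(n_fields)) {
    f_true <- true_atpct[(i - 1L) %% length(true_atpct) + 1L] / 100
    drift <- with_seed(seed + i, {
      d <- matrix(sample(-max_drift:max_drift, 2L * n_planes, replace = TRUE),
                  ncol = 2L)
      d[1, ] <- 0L  # reference plane defines the frame
      d
    })
    plan <- scene_plan(
      shape = c(40L, 40L), pixel_size_um = 0.5,
      objects = list(coccus_object(c(10, 10), diameter_um = 4,
                                   atom_fraction = f_true,
                                   density = density,
                                   s_density = density / 2)),
      n_planes = n_planes, drift = drift, seed = seed + i
    )
    fld <- simulate_field(plan)
    al <- align_field(fld$stacks, max_shift = max_drift + 1L)
    m <- measure_roi(accumulate(al$stacks$c12), accumulate(al$stacks$c13),
                     fld$mask, 1L)
    rows[[i]] <- data.frame(
      field = i, true_atpct = 100 * f_true, atpct = m$atpct,
      atpct_se = m$atpct_se, total_counts = m$c12 + m$c13,
      within_2se = abs(m$atpct - 100 * f_true) <= 2 * m$atpct_se,
      drift_exact = all(al$shifts == -drift)
    )
  }
  do.call(rbind, rows)
}

#' Rate estimator recovery over replicated noisy tracer series
#'
#' Simulates `n_reps` 13C-DIC series at a known oxidation rate with Gaussian
#' measurement noise, fits each with [mox_rate()], and scores whether the
#' recovered rate lies within 2 fitted standard errors of the truth.
#'
#' @param n_reps number of replicate series.
#' @param rate true methane oxidation rate (\eqn{\mu mol\,l^{-1}\,d^{-1}}).
#' @param dic DIC pool (\eqn{\mu mol\,l^{-1}}).
#' @param labeling_atpct methane pool labeling (at%).
#' @param times sampling days.
#' @param noise_sd_atpct Gaussian noise s.d. on the DIC at%.
#' @param seed base seed; replicate i uses `seed + i`.
#' @return data frame: `rep`, `rate_hat`, `rate_se`, `within_2se`.
#' @export
rate_recovery_experiment <- function(n_reps = 100, rate = 2.7, dic = 2000,
                                     labeling_atpct = 20,
                                     times = seq(0, 16, 1),
                                     noise_sd_atpct = 0.01, seed = 1L) {
  rows <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    ser <- simulate_incubation_series(rate, dic, labeling_atpct, times,
                                      noise_sd_atpct = noise_sd_atpct,
                                      seed = seed + i)
    fit <- mox_rate(ser)
    rows[[i]] <- data.frame(
      rep = i, rate_hat = fit$rate, rate_se = fit$rate_se,
      within_2se = abs(fit$rate - rate) <= 2 * fit$rate_se
    )
  }
  do.call(rbind, rows)
}
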