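#' Simulate a 13C-DIC tracer time series
#'
#' Forward model of a bulk methane-oxidation incubation: oxidation of
#' \eqn{^{13}}CH\eqn{_4} transfers label into the dissolved inorganic carbon
#' (DIC) pool, so the DIC atom percent rises linearly at
#' \deqn{at\%(t) = at\%_0 + 100 \cdot \frac{rate \cdot L}{DIC} \cdot t}
#' where `L` is the labeling fraction of the methane pool
#' (`labeling_atpct`/100). Optional Gaussian measurement noise is added to
#' each point. The inverse of this model is [mox_rate()].
#'
#' @param rate methane oxidation rate (\eqn{\mu mol\,l^{-1}\,d^{-1}}, >= 0).
#' @param dic DIC pool size (\eqn{\mu mol\,l^{-1}}, > 0).
#' @param labeling_atpct at% 13C of the methane pool (0 < x <= 100).
#' @param times sampling times in days (>= 2 points).
#' @param noise_sd_atpct s.d. of Gaussian noise on at% (>= 0).
#' @param atpct0 initial DIC at%; default natural abundance 1.11.
#' @param seed integer seed; same seed reproduces the series exactly.
#' @return data frame of class `incubation_series` with columns `time_d`,
#'   `atpct_dic`; the pool size and labeling travel as attributes `dic` and
#'   `labeling_atpct`.
#' @export
simulate_incubation_series <- function(rate, dic, labeling_atpct, times,
                                       noise_sd_atpct = 0, atpct0 = 1.11,
                                       seed = NULL) {
  stop_if_not_scalar_number(rate, "rate", nonnegative = TRUE)
  stop_if_not_scalar_number(dic, "dic", positive = TRUE)
  stop_if_not_scalar_number(labeling_atpct, "labeling_atpct", positive = TRUE)
  if (labeling_atpct > 100) stop("`labeling_atpct` must be <= 100", call. = FALSE)
  if (length(times) < 2L) stop("need at least two time points", call. = FALSE)
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  stop_if_not_scalar_number(noise_sd_atpct, "noise_sd_atpct", nonnegative = TRUE)
  stop_if_not_scalar_number(atpct0, "atpct0", nonnegative = TRUE)

  slope_atpct <- 100 * rate * (labeling_atpct / 100) / dic
  at <- atpct0 + slope_atpct * times
  if (noise_sd_atpct > 0) {
    at <- at + with_seed(seed, rnorm(length(times), 0, noise_sd_atpct))
  }
  out <- data.frame(time_d = times, atpct_dic = at)
  attr(out, "dic") <- dic
  attr(out, "labeling_atpct") <- labeling_atpct
  class(out) <- c("incubation_series", "data.frame")
  out
}
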