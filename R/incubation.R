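# Bulk methane oxidation rates from 13C-DIC tracer time series.
#
# Oxidized 13CH4 accumulates as 13CO2 in the DIC pool, so the labelled
# fraction of DIC rises linearly while substrate is in excess. The rate is
# the least-squares slope of that fraction, scaled by the pool size and
# divided by the labeling fraction of the methane pool:
#   rate = slope(at%/100) * DIC / (labeling/100)   [umol l^-1 d^-1]

#' Estimate a bulk methane oxidation rate from a 13C-DIC series
#'
#' Fits an ordinary least-squares line to the labelled DIC fraction
#' (at%/100) over time (the full series by default, or an explicit
#' `window` of point indices covering the initial linear phase) and converts
#' the slope into a methane oxidation rate. A negative fitted slope is
#' truncated to rate 0 and flagged.
#'
#' @param series data frame with columns `time_d` and `atpct_dic`, e.g. from
#'   [simulate_incubation_series()] or [read_series_csv()].
#' @param dic DIC pool size (\eqn{\mu mol\,l^{-1}}); defaults to the
#'   series attribute when present.
#' @param labeling_atpct at% 13C of the methane pool; defaults to the series
#'   attribute when present.
#' @param window optional integer vector of point indices to fit.
#' @return object of class `mox_fit`: `rate` and `rate_se`
#'   (\eqn{\mu mol\,l^{-1}\,d^{-1}}), `slope` and `slope_se` (fraction
#'   d\eqn{^{-1}}), `n`, `dic`, `labeling_atpct`, `negative_slope` flag and
#'   the underlying `lm` fit.
#' @export
mox_rate <- function(series, dic = attr(series, "dic"),
                     labeling_atpct = attr(series, "labeling_atpct"),
                     window = NULL) {
  if (!all(c("time_d", "atpct_dic") %in% names(series))) {
    stop("`series` needs columns `time_d` and `atpct_dic`", call. = FALSE)
  }
  if (is.null(dic) || is.null(labeling_atpct)) {
    stop("`dic` and `labeling_atpct` must be supplied", call. = FALSE)
  }
  stop_if_not_scalar_number(dic, "dic", positive = TRUE)
  stop_if_not_scalar_number(labeling_atpct, "labeling_atpct", positive = TRUE)
  d <- as.data.frame(series)[, c("time_d", "atpct_dic")]
  if (!is.null(window)) d <- d[window, , drop = FALSE]
  if (nrow(d) < 2L) stop("need at least two time points", call. = FALSE)
  if (any(diff(order(d$time_d)) < 0)) d <- d[order(d$time_d), ]
  if (any(d$atpct_dic < 0 | d$atpct_dic > 100)) {
    stop("at% values must lie in [0, 100]", call. = FALSE)
  }

  fit <- lm(I(atpct_dic / 100) ~ time_d, data = d)
  slope <- unname(coef(fit)[2])
  # suppressWarnings: summary.lm warns on noise-free (perfect) fits
  slope_se <- if (nrow(d) > 2L) suppressWarnings(sqrt(vcov(fit)[2, 2]))
              else NA_real_
  scale <- dic / (labeling_atpct / 100)
  negative <- slope < 0
  structure(list(
    rate = if (negative) 0 else slope * scale,
    rate_se = slope_se * scale,
    slope = slope, slope_se = slope_se,
    n = nrow(d), dic = dic, labeling_atpct = labeling_atpct,
    negative_slope = negative, window = window, fit = fit
  ), class = "mox_fit")
}

#' @export
print.mox_fit <- function(x, ...) {
  cat(sprintf("Methane oxidation rate: %.4g umol l^-1 d^-1", x$rate))
  if (!is.na(x$rate_se)) cat(sprintf(" (SE %.3g)", x$rate_se))
  cat(sprintf("\n  slope %.4g d^-1 over %d points; DIC %.4g umol/l; labeling %.4g at%%\n",
              x$slope, x$n, x$dic, x$labeling_atpct))
  if (x$negative_slope) cat("  note: negative fitted slope truncated to 0\n")
  invisible(x)
}

#' @export
coef.mox_fit <- function(object, ...) {
  c(rate = object$rate, slope = object$slope)
}

#' Treatment-versus-control fold change of oxidation rates
#'
#' @param treatment,control rates (\eqn{\mu mol\,l^{-1}\,d^{-1}}) or
#'   `mox_fit` objects; control must be > 0.
#' @return `treatment / control`.
#' @examples
#' fold_change(2.7, 0.234) # ~11.5
#' @export
fold_change <- function(treatment, control) {
  if (inherits(treatment, "mox_fit")) treatment <- treatment$rate
  if (inherits(control, "mox_fit")) control <- control$rate
  stop_if_not_scalar_number(treatment, "treatment", nonnegative = TRUE)
  if (!is.numeric(control) || length(control) != 1L || control <= 0) {
    stop("`control` rate must be > 0", call. = FALSE)
  }
  treatment / control
}

#' Read / write a tracer time series CSV (`time_d`, `atpct_dic`)
#'
#' @param path CSV path.
#' @param series data frame with columns `time_d`, `atpct_dic`.
#' @param dic,labeling_atpct optional pool metadata attached as attributes
#'   on read so [mox_rate()] can pick them up.
#' @return the series data frame (read) or `path` (write).
#' @export
read_series_csv <- function(path, dic = NULL, labeling_atpct = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_d", "atpct_dic") %in% names(d))) {
    stop("series CSV needs columns `time_d` and `atpct_dic`", call. = FALSE)
  }
  attr(d, "dic") <- dic
  attr(d, "labeling_atpct") <- labeling_atpct
  d
}

#' @rdname read_series_csv
#' @export
write_series_csv <- function(series, path) {
  write.csv(as.data.frame(series)[, c("time_d", "atpct_dic")], path,
            row.names = FALSE)
  invisible(path)
}
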