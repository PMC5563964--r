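# From single-cell 13C enrichment to methane-carbon uptake: atom-percent
# excess, biovolume-based carbon content (6.4 fmol C per um^3), correction
# for the labeling percentage of the methane pool and the incubation time,
# and upscaling to population rates via cell densities.

#' Isotope and incubation parameters for uptake calculations
#'
#' @param labeling_atpct at% 13C of the supplied methane pool (0 < x <= 100);
#'   e.g. 50 for a half-labelled pool, ~20 for a 1:4 spike.
#' @param incubation_d incubation time in days (> 0).
#' @param natural_atpct natural-abundance 13C at% subtracted before the
#'   labeling correction (default 1.11).
#' @param carbon_fmol_per_um3 biovolume-to-carbon conversion factor
#'   (default 6.4 fmol C per cubic micrometre).
#' @return an object of class `isotope_params`.
#' @export
isotope_params <- function(labeling_atpct, incubation_d,
                           natural_atpct = 1.11,
                           carbon_fmol_per_um3 = 6.4) {
  stop_if_not_scalar_number(labeling_atpct, "labeling_atpct", positive = TRUE)
  if (labeling_atpct > 100) stop("`labeling_atpct` must be <= 100", call. = FALSE)
  stop_if_not_scalar_number(incubation_d, "incubation_d", positive = TRUE)
  stop_if_not_scalar_number(natural_atpct, "natural_atpct", nonnegative = TRUE)
  stop_if_not_scalar_number(carbon_fmol_per_um3, "carbon_fmol_per_um3",
                            positive = TRUE)
  structure(list(labeling_atpct = labeling_atpct, incubation_d = incubation_d,
                 natural_atpct = natural_atpct,
                 carbon_fmol_per_um3 = carbon_fmol_per_um3),
            class = "isotope_params")
}

#' Atom percent excess over natural abundance
#'
#' The label-derived fraction of cell carbon: measured at% minus the natural
#' abundance at%, floored at zero. Values below natural abundance are
#' reported as zero excess with a `depleted` flag attribute.
#'
#' @param measured_atpct measured at% (>= 0); vectorised.
#' @param natural_atpct natural-abundance at% (default 1.11).
#' @return excess at%, with logical attribute `depleted`.
#' @examples
#' atpct_excess(22.00) # 20.89
#' @export
atpct_excess <- function(measured_atpct, natural_atpct = 1.11) {
  if (any(measured_atpct < 0, na.rm = TRUE)) {
    stop("measured at% must be >= 0", call. = FALSE)
  }
  ex <- pmax(measured_atpct - natural_atpct, 0)
  attr(ex, "depleted") <- !is.na(measured_atpct) &
    measured_atpct < natural_atpct
  ex
}

#' Per-cell methane-carbon uptake rate
#'
#' Converts the at% excess of an average-biovolume cell into a carbon uptake
#' rate:
#' \deqn{uptake = \frac{excess}{100} \cdot c \cdot V \,/\,
#'       \frac{labeling}{100} \,/\, t}
#' with carbon content \eqn{c \cdot V} (c = 6.4 fmol C \eqn{\mu m^{-3}}),
#' labeling percentage of the methane pool and incubation time t (days).
#' Rates are per average-biovolume filament (or cell), in
#' fmol C cell\eqn{_{avg}^{-1}} d\eqn{^{-1}}.
#'
#' @param excess_atpct at% excess (from [atpct_excess()]); vectorised.
#' @param biovolume_um3 average cell/filament biovolume (\eqn{\mu m^3}).
#' @param params an [isotope_params()].
#' @return uptake in fmol C per average cell per day.
#' @export
percell_uptake <- function(excess_atpct, biovolume_um3, params) {
  stopifnot(inherits(params, "isotope_params"))
  if (any(excess_atpct < 0, na.rm = TRUE)) {
    stop("excess at% must be >= 0", call. = FALSE)
  }
  if (any(biovolume_um3 < 0, na.rm = TRUE)) {
    stop("biovolume must be >= 0", call. = FALSE)
  }
  (excess_atpct / 100) * params$carbon_fmol_per_um3 * biovolume_um3 /
    (params$labeling_atpct / 100) / params$incubation_d
}

#' Upscale per-cell uptake to a population rate
#'
#' Multiplies the per-cell rate by the cell density and converts units:
#' 1 fmol ml\eqn{^{-1}} d\eqn{^{-1}} = 10\eqn{^{-6}} \eqn{\mu}mol
#' l\eqn{^{-1}} d\eqn{^{-1}} (10\eqn{^{-15}} mol/10\eqn{^{-3}} l =
#' 10\eqn{^{-12}} mol l\eqn{^{-1}} = 10\eqn{^{-6}} \eqn{\mu}mol l\eqn{^{-1}}).
#'
#' @param percell_fmol_d per-cell uptake (fmol cell\eqn{^{-1}} d\eqn{^{-1}}).
#' @param count_per_ml cells (filaments) per millilitre.
#' @return population uptake in \eqn{\mu mol\,l^{-1}\,d^{-1}}.
#' @examples
#' population_uptake(128.0, 9.2e3) # 1.18
#' @export
population_uptake <- function(percell_fmol_d, count_per_ml) {
  if (any(percell_fmol_d < 0, na.rm = TRUE) ||
      any(count_per_ml < 0, na.rm = TRUE)) {
    stop("uptake and count must be >= 0", call. = FALSE)
  }
  percell_fmol_d * count_per_ml * 1e-6
}

#' Ratio of two population uptake (or oxidation) rates
#'
#' @param a,b rates in the same units; `b` must be > 0.
#' @return `a / b`.
#' @examples
#' fold_difference(1.73, 0.27) # ~6.4
#' @export
fold_difference <- function(a, b) {
  stop_if_not_scalar_number(a, "a", nonnegative = TRUE)
  stop_if_not_scalar_number(b, "b", positive = TRUE)
  a / b
}

#' Build the population uptake overview table
#'
#' The full derivation for one or more populations: at% excess, per-cell
#' uptake (with the measured-at% relative s.d. carried multiplicatively),
#' total population biovolume and population uptake. Populations with
#' missing inputs yield `NA` derived fields.
#'
#' @param populations data frame with one row per population and columns
#'   `label`, `atpct_mean`, `atpct_sd`, `atpct_n`, `biovol_um3`,
#'   `biovol_sd`, `biovol_n`, `count_per_ml`, `labeling_atpct`,
#'   `incubation_d`; optionally `natural_atpct` (default 1.11) and
#'   `carbon_fmol_per_um3` (default 6.4).
#' @return data frame of class `population_table`: inputs plus
#'   `excess_atpct`, `percell_fmol_d`, `percell_sd`, `total_biovol_um3_ml`,
#'   `population_umol_l_d`, at full precision. Use
#'   [format_population_table()] for a 2-significant-figure display view.
#' @export
build_population_table <- function(populations) {
  req <- c("label", "atpct_mean", "atpct_sd", "biovol_um3", "count_per_ml",
           "labeling_atpct", "incubation_d")
  miss <- setdiff(req, names(populations))
  if (length(miss) > 0L) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  n <- nrow(populations)
  out <- populations
  if (is.null(out$natural_atpct)) out$natural_atpct <- rep(1.11, n)
  if (is.null(out$carbon_fmol_per_um3)) out$carbon_fmol_per_um3 <- rep(6.4, n)
  out$excess_atpct <- rep(NA_real_, n)
  out$percell_fmol_d <- rep(NA_real_, n)
  out$percell_sd <- rep(NA_real_, n)
  out$total_biovol_um3_ml <- rep(NA_real_, n)
  out$population_umol_l_d <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    r <- out[i, ]
    if (!is.na(r$biovol_um3) && !is.na(r$count_per_ml)) {
      out$total_biovol_um3_ml[i] <-
        total_population_biovolume(r$biovol_um3, r$count_per_ml)
    }
    if (is.na(r$atpct_mean) || is.na(r$biovol_um3) ||
        is.na(r$labeling_atpct) || is.na(r$incubation_d)) next
    p <- isotope_params(r$labeling_atpct, r$incubation_d,
                        natural_atpct = r$natural_atpct,
                        carbon_fmol_per_um3 = r$carbon_fmol_per_um3)
    ex <- atpct_excess(r$atpct_mean, r$natural_atpct)
    out$excess_atpct[i] <- ex
    pc <- percell_uptake(as.numeric(ex), r$biovol_um3, p)
    out$percell_fmol_d[i] <- pc
    # relative spread of the measured at% carried multiplicatively
    if (!is.na(r$atpct_sd) && r$atpct_mean > 0) {
      out$percell_sd[i] <- pc * r$atpct_sd / r$atpct_mean
    }
    if (!is.na(r$count_per_ml)) {
      out$population_umol_l_d[i] <- population_uptake(pc, r$count_per_ml)
    }
  }
  class(out) <- c("population_table", "data.frame")
  out
}

#' Display view of a population table, rounded like a report
#'
#' Upscaled quantities (counts, total biovolume, population uptake) are shown
#' at 2 significant figures; per-cell rates and at% at one decimal.
#'
#' @param tab a `population_table` from [build_population_table()].
#' @return data frame of formatted character columns.
#' @export
format_population_table <- function(tab) {
  f2 <- function(x) ifelse(is.na(x), "NA", format(signif(x, 2), trim = TRUE))
  f1 <- function(x) ifelse(is.na(x), "NA", sprintf("%.1f", x))
  data.frame(
    population = tab$label,
    atpct = ifelse(is.na(tab$atpct_mean), "NA",
                   paste0(sprintf("%.2f", tab$atpct_mean), " ± ",
                          sprintf("%.1f", tab$atpct_sd))),
    avg_biovolume_um3 = f1(tab$biovol_um3),
    percell_fmol_d = ifelse(is.na(tab$percell_fmol_d), "NA",
                            paste0(f1(tab$percell_fmol_d), " ± ",
                                   f1(tab$percell_sd))),
    count_per_ml = f2(tab$count_per_ml),
    total_biovol_um3_ml = f2(tab$total_biovol_um3_ml),
    population_umol_l_d = f2(tab$population_umol_l_d),
    stringsAsFactors = FALSE
  )
}
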