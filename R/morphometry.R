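#' Biovolume of a cylindrical filament
#'
#' Filamentous cells are modelled as cylinders whose diameter is the measured
#' filament width: \eqn{V = \pi (w/2)^2 L}. Width is the full diameter, not
#' the radius; treating it as a radius inflates volumes fourfold and is
#' inconsistent with reported filament volumes of 70--90 \eqn{\mu m^3} for
#' ca. 45 x 1.5 \eqn{\mu m} filaments.
#'
#' @param length_um filament length in micrometres (> 0); vectorised.
#' @param width_um filament width (= cylinder diameter) in micrometres (> 0).
#' @return biovolume in cubic micrometres.
#' @examples
#' cylinder_biovolume(45, 1.5) # ~79.5 um^3
#' @export
cylinder_biovolume <- function(length_um, width_um) {
  if (!is.numeric(length_um) || !is.numeric(width_um)) {
    stop("length and width must be numeric", call. = FALSE)
  }
  if (any(!is.finite(length_um)) || any(!is.finite(width_um)) ||
      any(length_um <= 0) || any(width_um <= 0)) {
    stop("length and width must be finite and > 0", call. = FALSE)
  }
  pi * (width_um / 2)^2 * length_um
}

#' Biovolume of a spherical (coccoid) cell
#'
#' Unicellular methanotrophs are modelled as spheres of the given diameter:
#' \eqn{V = \pi d^3 / 6}. The conventional average diameter for unicellular
#' gamma-MOB in lake samples is 2 \eqn{\mu m}, giving 4.19 \eqn{\mu m^3}.
#'
#' @param diameter_um cell diameter in micrometres (> 0); vectorised.
#' @return biovolume in cubic micrometres.
#' @examples
#' sphere_biovolume(2) # 4.19 um^3
#' @export
sphere_biovolume <- function(diameter_um) {
  if (!is.numeric(diameter_um) || any(!is.finite(diameter_um)) ||
      any(diameter_um <= 0)) {
    stop("diameter must be finite and > 0", call. = FALSE)
  }
  pi * diameter_um^3 / 6
}

#' Average filament biovolume from a morphometry table
#'
#' Converts per-filament length/width measurements into cylinder biovolumes
#' and summarises them as mean, sample standard deviation (n - 1 denominator)
#' and n. With a single filament the s.d. is reported as 0 and flagged.
#'
#' @param measures data frame with numeric columns `length_um` and `width_um`
#'   (one row per filament), or a numeric vector of lengths when `width_um`
#'   is given separately.
#' @param width_um optional vector of widths when `measures` is a vector.
#' @return list with `mean_um3`, `sd_um3`, `n`, `single` (TRUE when n = 1)
#'   and the per-filament `biovolumes_um3`.
#' @export
average_biovolume <- function(measures, width_um = NULL) {
  if (is.data.frame(measures)) {
    if (!all(c("length_um", "width_um") %in% names(measures))) {
      stop("`measures` needs columns `length_um` and `width_um`", call. = FALSE)
    }
    lens <- measures$length_um
    wids <- measures$width_um
  } else {
    lens <- measures
    wids <- width_um
  }
  if (length(lens) == 0L) stop("no filament measurements supplied", call. = FALSE)
  if (length(lens) != length(wids)) {
    stop("lengths and widths must have equal length", call. = FALSE)
  }
  v <- cylinder_biovolume(lens, wids)
  list(
    mean_um3 = mean(v),
    sd_um3 = sd_or_zero(v),
    n = length(v),
    single = length(v) == 1L,
    biovolumes_um3 = v
  )
}

#' Objects per millilitre from filter counts
#'
#' Standard epifluorescence upscaling: the mean count per microscope field of
#' view is scaled by the ratio of effective filter area to field-of-view area
#' and divided by the filtered water volume.
#'
#' @param counts_per_fov integer vector, objects counted in each field of view.
#' @param fov_area_um2 area of one field of view (\eqn{\mu m^2}).
#' @param filter_area_um2 effective filtration area of the filter (\eqn{\mu m^2}).
#' @param volume_ml water volume filtered (ml).
#' @return objects per millilitre.
#' @export
counts_per_ml <- function(counts_per_fov, fov_area_um2, filter_area_um2,
                          volume_ml) {
  if (length(counts_per_fov) == 0L || any(counts_per_fov < 0)) {
    stop("`counts_per_fov` must be a non-empty vector of counts >= 0",
         call. = FALSE)
  }
  stop_if_not_scalar_number(fov_area_um2, "fov_area_um2", positive = TRUE)
  stop_if_not_scalar_number(filter_area_um2, "filter_area_um2", positive = TRUE)
  stop_if_not_scalar_number(volume_ml, "volume_ml", positive = TRUE)
  mean(counts_per_fov) * (filter_area_um2 / fov_area_um2) / volume_ml
}

#' Total population biovolume per millilitre
#'
#' Product of the average per-object biovolume and the object density, giving
#' the standing biovolume of the population (\eqn{\mu m^3\,ml^{-1}}).
#'
#' @param avg_biovolume_um3 average biovolume per filament or cell (\eqn{\mu m^3}).
#' @param count_per_ml objects per millilitre.
#' @return total biovolume in \eqn{\mu m^3\,ml^{-1}}.
#' @examples
#' total_population_biovolume(73.7, 9.2e3)
#' @export
total_population_biovolume <- function(avg_biovolume_um3, count_per_ml) {
  stop_if_not_scalar_number(avg_biovolume_um3, "avg_biovolume_um3",
                            nonnegative = TRUE)
  stop_if_not_scalar_number(count_per_ml, "count_per_ml", nonnegative = TRUE)
  avg_biovolume_um3 * count_per_ml
}
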