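# ROI quantification of accumulated ion images: drift alignment, plane
# accumulation, isotope ratios and atom percent with Poisson counting
# statistics, background comparison and the ratio-floor exclusion filter.

#' Convert between isotope ratio and atom percent
#'
#' `atpct_from_ratio()` maps the measured ratio \eqn{R = {}^{13}C/{}^{12}C}
#' to atom percent, \eqn{at\% = 100 R / (1 + R)}; `ratio_from_atpct()` is
#' the exact inverse.
#'
#' @param ratio isotope ratio (>= 0); vectorised.
#' @param atpct atom percent in `[0, 100)`; vectorised.
#' @return atom percent, resp. ratio.
#' @examples
#' atpct_from_ratio(0.015)  # 1.4778
#' ratio_from_atpct(1.11)
#' @export
atpct_from_ratio <- function(ratio) {
  if (any(ratio < 0, na.rm = TRUE)) stop("ratio must be >= 0", call. = FALSE)
  ifelse(is.infinite(ratio), 100, 100 * ratio / (1 + ratio))
}

#' @rdname atpct_from_ratio
#' @export
ratio_from_atpct <- function(atpct) {
  if (any(atpct < 0 | atpct >= 100, na.rm = TRUE)) {
    stop("atom percent must lie in [0, 100)", call. = FALSE)
  }
  atpct / (100 - atpct)
}

# Pearson correlation of the reference against a candidate-shifted plane,
# over their overlap. NA (no variance) scores as -Inf so flat candidates
# never beat the identity shift.
shift_score <- function(ref, plane, dx, dy) {
  shifted <- shift_matrix(plane, dx, dy, fill = NA)
  ok <- !is.na(shifted) & !is.na(ref)
  if (sum(ok) < 9L) return(-Inf)
  s <- suppressWarnings(stats::cor(ref[ok], shifted[ok]))
  if (is.na(s)) -Inf else s
}

#' Drift-correct an ion image stack by integer-pixel alignment
#'
#' Estimates, for every plane, the integer (dx, dy) translation that best
#' aligns it with a reference plane (maximum Pearson cross-correlation over
#' the overlap, searched exhaustively within `max_shift`), and applies it.
#' Structure-rich channels (32S, or the total-carbon image) should be used
#' for estimation; apply the same shifts to all masses of the acquisition
#' with [align_field()]. Pixels translated out of frame become `NA` and are
#' excluded from subsequent accumulation.
#'
#' Ties favour the smallest shift, so a featureless or drift-free plane is
#' returned unchanged with shift (0, 0).
#'
#' @param stack an [ion_stack()].
#' @param reference_plane index of the reference plane (default 1).
#' @param max_shift maximum |dx|, |dy| searched (default 10 px).
#' @param shifts optionally, a precomputed `n_planes x 2` integer matrix of
#'   corrective shifts to apply instead of estimating them.
#' @return list with `stack` (aligned [ion_stack()]) and `shifts`
#'   (`n_planes x 2` matrix of applied (dx, dy)).
#' @export
align_planes <- function(stack, reference_plane = 1L, max_shift = 10L,
                         shifts = NULL) {
  stopifnot(inherits(stack, "ion_stack"))
  np <- n_planes(stack)
  if (reference_plane < 1L || reference_plane > np) {
    stop("`reference_plane` out of range", call. = FALSE)
  }
  if (is.null(shifts)) {
    ref <- stack$planes[, , reference_plane]
    cand <- expand.grid(dx = -max_shift:max_shift, dy = -max_shift:max_shift)
    cand <- cand[order(abs(cand$dx) + abs(cand$dy), abs(cand$dx)), ]
    shifts <- matrix(0L, nrow = np, ncol = 2L,
                     dimnames = list(NULL, c("dx", "dy")))
    for (k in seq_len(np)) {
      if (k == reference_plane) next
      plane <- stack$planes[, , k]
      best <- -Inf; best_s <- c(0L, 0L)
      for (i in seq_len(nrow(cand))) {
        s <- shift_score(ref, plane, cand$dx[i], cand$dy[i])
        if (s > best) { best <- s; best_s <- c(cand$dx[i], cand$dy[i]) }
      }
      shifts[k, ] <- best_s
    }
  } else {
    shifts <- as.matrix(shifts)
    if (!identical(dim(shifts), c(np, 2L))) {
      stop("`shifts` must be an n_planes x 2 matrix", call. = FALSE)
    }
    colnames(shifts) <- c("dx", "dy")
  }
  aligned <- stack$planes
  for (k in seq_len(np)) {
    if (shifts[k, 1] != 0L || shifts[k, 2] != 0L) {
      aligned[, , k] <- shift_matrix(stack$planes[, , k],
                                     shifts[k, 1], shifts[k, 2], fill = NA)
    }
  }
  out <- stack
  out$planes <- aligned
  list(stack = out, shifts = shifts)
}

#' Drift-correct all masses of an acquisition with shared shifts
#'
#' Estimates per-plane shifts on the structure-rich channel (`32S` when
#' present and non-empty, otherwise the summed carbon image) and applies the
#' same shifts to every mass, as the masses are recorded simultaneously.
#'
#' @param stacks named list of [ion_stack()] objects (e.g. `c12`, `c13`,
#'   `s32`), all with the same plane count.
#' @param reference_plane,max_shift passed to [align_planes()].
#' @return list with `stacks` (aligned, same names) and `shifts`.
#' @export
align_field <- function(stacks, reference_plane = 1L, max_shift = 10L) {
  if (length(stacks) == 0L) stop("no stacks supplied", call. = FALSE)
  guide <- NULL
  if (!is.null(stacks$s32) && sum(stacks$s32$planes, na.rm = TRUE) > 0) {
    guide <- stacks$s32
  } else {
    total <- stacks[[1]]$planes
    if (length(stacks) > 1L) {
      for (s in stacks[-1]) total <- total + s$planes
    }
    guide <- stacks[[1]]
    guide$planes <- total
  }
  est <- align_planes(guide, reference_plane, max_shift)
  out <- lapply(stacks, function(s) {
    align_planes(s, reference_plane, shifts = est$shifts)$stack
  })
  list(stacks = out, shifts = est$shifts)
}

#' Accumulate an aligned stack into one count image
#'
#' Per-pixel sum over planes. Pixels missing in some planes (shifted out of
#' frame) are summed over the available planes only; the per-pixel plane
#' coverage is attached as attribute `planes_per_pixel` so counting
#' statistics stay interpretable.
#'
#' @param stack an [ion_stack()] (aligned if drift was present).
#' @return numeric matrix of summed counts with attribute
#'   `planes_per_pixel`; pixels covered by no plane are `NA`.
#' @export
accumulate <- function(stack) {
  stopifnot(inherits(stack, "ion_stack"))
  planes <- stack$planes
  cover <- apply(!is.na(planes), c(1, 2), sum)
  total <- apply(planes, c(1, 2), function(v) sum(v, na.rm = TRUE))
  total[cover == 0L] <- NA_real_
  attr(total, "planes_per_pixel") <- cover
  total
}

#' Measure one ROI: summed counts, isotope ratio, at% and Poisson SE
#'
#' Sums the accumulated 12C and 13C counts over the ROI pixels and derives
#' the isotope ratio \eqn{R = {}^{13}C/{}^{12}C}, the atom percent
#' \eqn{at\% = 100\,{}^{13}C/({}^{12}C + {}^{13}C)} and the counting-statistics
#' standard error of at% by Poisson error propagation on the two summed
#' counts: \eqn{SE(at\%) = 100\sqrt{N_{13} N_{12} / (N_{13}+N_{12})^3}}.
#'
#' @param c12,c13 accumulated count matrices (from [accumulate()]).
#' @param mask integer ROI label matrix of the same shape.
#' @param roi_id label to measure (must occur in `mask`).
#' @param morphotype,probe optional annotations carried into the row.
#' @param background logical; TRUE marks a cell-free background ROI.
#' @return one-row data frame with `roi_id`, `morphotype`, `probe`,
#'   `n_pixels`, `c12`, `c13`, `ratio`, `atpct`, `atpct_se`, `background`,
#'   `undefined_ratio` (TRUE when 12C = 0 with nonzero 13C; at% fixed at 100).
#' @export
measure_roi <- function(c12, c13, mask, roi_id, morphotype = NA_character_,
                        probe = NA_character_, background = FALSE) {
  if (!identical(dim(c12), dim(c13)) || !identical(dim(c12), dim(mask))) {
    stop("count matrices and mask must share one shape", call. = FALSE)
  }
  sel <- which(mask == roi_id)
  if (length(sel) == 0L) {
    stop(sprintf("ROI id %s not present in mask", format(roi_id)), call. = FALSE)
  }
  a <- sum(c13[sel], na.rm = TRUE)  # 13C
  b <- sum(c12[sel], na.rm = TRUE)  # 12C
  tot <- a + b
  if (tot == 0) {
    stop(sprintf("ROI %s has zero total carbon counts", format(roi_id)),
         call. = FALSE)
  }
  undefined <- b == 0 && a > 0
  ratio <- if (undefined) Inf else a / b
  atpct <- 100 * a / tot
  se <- if (undefined) NA_real_ else 100 * sqrt(a * b / tot^3)
  data.frame(roi_id = roi_id, morphotype = morphotype, probe = probe,
             n_pixels = length(sel), c12 = b, c13 = a, ratio = ratio,
             atpct = atpct, atpct_se = se, background = background,
             undefined_ratio = undefined, stringsAsFactors = FALSE)
}

#' Measure every ROI of a label mask
#'
#' @inheritParams measure_roi
#' @param morphotypes optional character vector (or named vector by label)
#'   of morphotypes per ROI.
#' @param background_labels labels to flag as cell-free background ROIs.
#' @return data frame with one [measure_roi()] row per label (> 0) in the
#'   mask, ordered by label.
#' @export
measure_rois <- function(c12, c13, mask, morphotypes = NULL,
                         probe = NA_character_,
                         background_labels = integer(0)) {
  labels <- sort(unique(mask[mask > 0]))
  if (length(labels) == 0L) stop("mask contains no ROIs", call. = FALSE)
  rows <- lapply(seq_along(labels), function(i) {
    lab <- labels[i]
    mt <- if (is.null(morphotypes)) NA_character_
          else if (!is.null(names(morphotypes))) morphotypes[[as.character(lab)]]
          else morphotypes[[i]]
    measure_roi(c12, c13, mask, lab, morphotype = mt, probe = probe,
                background = lab %in% background_labels)
  })
  do.call(rbind, rows)
}

#' Compare ROI enrichment against the cell-free background
#'
#' Pools the counts of all background ROIs (cell-free filter in the same
#' field of view) into one background at% with Poisson SE, then flags a cell
#' ROI as `enriched` when its at% exceeds the background by more than
#' `k` pooled standard errors,
#' \eqn{at\% > at\%_{bg} + k\sqrt{SE_{bg}^2 + SE_{ROI}^2}} (default k = 3,
#' the conventional detection threshold).
#'
#' @param measurements data frame from [measure_rois()]; must contain at
#'   least one row with `background = TRUE`.
#' @param k detection threshold in pooled standard errors.
#' @return list with `background_atpct`, `background_se`, `n_background`,
#'   `k`, and `measurements` (input with an `enriched` column; `NA` for the
#'   background rows themselves).
#' @export
evaluate_background <- function(measurements, k = 3) {
  bg <- measurements[measurements$background, , drop = FALSE]
  if (nrow(bg) == 0L) {
    stop("no background ROI supplied; cannot evaluate enrichment", call. = FALSE)
  }
  a <- sum(bg$c13); b <- sum(bg$c12)
  bg_at <- 100 * a / (a + b)
  bg_se <- 100 * sqrt(a * b / (a + b)^3)
  cells <- !measurements$background
  thresh <- bg_at + k * sqrt(bg_se^2 + measurements$atpct_se^2)
  measurements$enriched <- ifelse(cells, measurements$atpct > thresh, NA)
  list(background_atpct = bg_at, background_se = bg_se,
       n_background = nrow(bg), k = k, measurements = measurements)
}

#' Exclude ROIs below an isotope-ratio floor
#'
#' Filters out measurements whose ratio \eqn{{}^{13}C/{}^{12}C} falls below
#' `floor` before cohort statistics are computed (default 0.015, the
#' reported exclusion applied to weakly labelled filaments). The operation
#' is idempotent and order-independent; the number of exclusions is recorded
#' in attribute `n_excluded`.
#'
#' @param measurements data frame with a `ratio` column.
#' @param floor minimum retained ratio (>= 0).
#' @return the retained rows, with attributes `n_excluded` and
#'   `excluded_ids`.
#' @export
apply_ratio_floor <- function(measurements, floor = 0.015) {
  stop_if_not_scalar_number(floor, "floor", nonnegative = TRUE)
  keep <- measurements$ratio >= floor
  out <- measurements[keep, , drop = FALSE]
  attr(out, "n_excluded") <- sum(!keep)
  attr(out, "excluded_ids") <- measurements$roi_id[!keep]
  out
}

#' Cohort mean and s.d. of ROI atom percent
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of the
#' per-ROI at% values, as reported for population-level enrichment. A single
#' ROI yields s.d. 0 with `single = TRUE`.
#'
#' @param measurements data frame with an `atpct` column, or a numeric
#'   vector of at% values.
#' @return list with `mean_atpct`, `sd_atpct`, `n`, `single`.
#' @export
summarize_population_atpct <- function(measurements) {
  x <- if (is.data.frame(measurements)) measurements$atpct else measurements
  if (length(x) == 0L) stop("no measurements to summarise", call. = FALSE)
  list(mean_atpct = mean(x), sd_atpct = sd_or_zero(x), n = length(x),
       single = length(x) == 1L)
}

#' Write / read ROI measurements as CSV
#'
#' @param measurements data frame from [measure_rois()] (possibly filtered).
#' @param path CSV path.
#' @return `path` (write) or the data frame (read).
#' @export
write_measurements_csv <- function(measurements, path) {
  write.csv(measurements, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements_csv
#' @export
read_measurements_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
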