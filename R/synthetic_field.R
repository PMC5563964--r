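# Synthetic nanoSIMS field generator.
#
# The measurement model: each pixel of each acquisition plane collects
# independent Poisson counts. For carbon, the expected total count density D
# (counts/px/plane) splits between the two isotopes by the local true 13C
# atom fraction f: 13C ~ Poisson(D * f), 12C ~ Poisson(D * (1 - f)). Sulphur
# (32S) counts follow the object's own density and are absent outside cells.
# Per-plane stage drift is an integer-pixel translation of the expected image
# applied before the noise.

#' Describe a filament (capsule) object for a synthetic scene
#'
#' The filament is rendered as a capsule: all pixels within `width_um/2` of
#' the axis segment from `start_um` to `end_um`. Its ground-truth biovolume
#' is the cylinder formula applied to the axis length and width.
#'
#' @param start_um,end_um numeric length-2 axis endpoints, micrometres (x, y).
#' @param width_um filament width (cylinder diameter), micrometres.
#' @param atom_fraction true 13C atom fraction in `[0, 1]`.
#' @param density expected total carbon counts per pixel per plane.
#' @param s_density expected 32S counts per pixel per plane.
#' @return an object description used by [scene_plan()].
#' @export
filament_object <- function(start_um, end_um, width_um, atom_fraction,
                            density, s_density = density / 10) {
  structure(list(morphotype = "filament", start_um = start_um, end_um = end_um,
                 width_um = width_um, atom_fraction = atom_fraction,
                 density = density, s_density = s_density),
            class = "scene_object")
}

#' Describe a coccoid (spherical) cell for a synthetic scene
#'
#' @param center_um numeric length-2 centre, micrometres (x, y).
#' @param diameter_um cell diameter, micrometres.
#' @inheritParams filament_object
#' @return an object description used by [scene_plan()].
#' @export
coccus_object <- function(center_um, diameter_um, atom_fraction, density,
                          s_density = density / 10) {
  structure(list(morphotype = "coccus", center_um = center_um,
                 diameter_um = diameter_um, atom_fraction = atom_fraction,
                 density = density, s_density = s_density),
            class = "scene_object")
}

#' Plan a synthetic ion-image field
#'
#' Collects and validates everything [simulate_field()] needs: image shape,
#' pixel size, cell objects, cell-free filter background, plane count,
#' per-plane drift and the random seed. The same plan and seed always yield
#' bit-identical images.
#'
#' @param shape image shape in pixels, `c(rows, cols)`.
#' @param pixel_size_um pixel edge length (micrometres per pixel).
#' @param objects list of [filament_object()] / [coccus_object()] descriptions.
#' @param n_planes number of acquisition planes (>= 1).
#' @param background_atom_fraction true 13C atom fraction of the cell-free
#'   filter background; default natural abundance 0.0111.
#' @param background_density expected total carbon counts per pixel per plane
#'   on cell-free filter.
#' @param drift integer matrix `n_planes x 2` of per-plane (dx, dy) pixel
#'   offsets, or `NULL` for no drift.
#' @param seed integer random seed.
#' @return an object of class `scene_plan`.
#' @export
scene_plan <- function(shape, pixel_size_um, objects, n_planes,
                       background_atom_fraction = 0.0111,
                       background_density = 20, drift = NULL, seed = 1L) {
  if (length(shape) != 2L || any(shape < 4) || any(shape != round(shape))) {
    stop("`shape` must be two integers >= 4", call. = FALSE)
  }
  stop_if_not_scalar_number(pixel_size_um, "pixel_size_um", positive = TRUE)
  if (!is.list(objects) || length(objects) == 0L ||
      !all(vapply(objects, inherits, logical(1), "scene_object"))) {
    stop("`objects` must be a non-empty list of scene objects", call. = FALSE)
  }
  for (ob in objects) {
    if (ob$atom_fraction < 0 || ob$atom_fraction > 1) {
      stop("object atom fractions must lie in [0, 1]", call. = FALSE)
    }
    if (ob$density < 0 || ob$s_density < 0) {
      stop("count densities must be >= 0", call. = FALSE)
    }
  }
  if (background_atom_fraction < 0 || background_atom_fraction > 1) {
    stop("background atom fraction must lie in [0, 1]", call. = FALSE)
  }
  stop_if_not_scalar_number(background_density, "background_density",
                            nonnegative = TRUE)
  if (length(n_planes) != 1L || n_planes != round(n_planes) || n_planes < 1) {
    stop("`n_planes` must be a positive integer", call. = FALSE)
  }
  if (is.null(drift)) drift <- matrix(0L, nrow = n_planes, ncol = 2L)
  drift <- as.matrix(drift)
  if (!identical(dim(drift), c(as.integer(n_planes), 2L)) ||
      any(drift != round(drift))) {
    stop("`drift` must be an integer n_planes x 2 matrix", call. = FALSE)
  }
  if (any(abs(drift[, 1]) >= shape[2]) || any(abs(drift[, 2]) >= shape[1])) {
    stop("drift magnitudes must be smaller than the image shape", call. = FALSE)
  }
  structure(list(shape = as.integer(shape), pixel_size_um = pixel_size_um,
                 objects = objects, n_planes = as.integer(n_planes),
                 background_atom_fraction = background_atom_fraction,
                 background_density = background_density,
                 drift = drift, seed = as.integer(seed)),
            class = "scene_plan")
}

# Pixel membership of an object: logical matrix over the image grid.
# Pixel centres sit at ((col - 0.5) * px, (row - 0.5) * px).
object_pixels <- function(ob, shape, pixel_size_um) {
  xs <- (seq_len(shape[2]) - 0.5) * pixel_size_um
  ys <- (seq_len(shape[1]) - 0.5) * pixel_size_um
  X <- matrix(xs, nrow = shape[1], ncol = shape[2], byrow = TRUE)
  Y <- matrix(ys, nrow = shape[1], ncol = shape[2])
  if (ob$morphotype == "coccus") {
    d2 <- (X - ob$center_um[1])^2 + (Y - ob$center_um[2])^2
    d2 <= (ob$diameter_um / 2)^2
  } else {
    p1 <- ob$start_um; p2 <- ob$end_um
    v <- p2 - p1
    len2 <- sum(v^2)
    if (len2 == 0) {
      d2 <- (X - p1[1])^2 + (Y - p1[2])^2
    } else {
      t <- pmin(pmax(((X - p1[1]) * v[1] + (Y - p1[2]) * v[2]) / len2, 0), 1)
      d2 <- (X - (p1[1] + t * v[1]))^2 + (Y - (p1[2] + t * v[2]))^2
    }
    d2 <= (ob$width_um / 2)^2
  }
}

object_biovolume <- function(ob) {
  if (ob$morphotype == "coccus") {
    sphere_biovolume(ob$diameter_um)
  } else {
    cylinder_biovolume(sqrt(sum((ob$end_um - ob$start_um)^2)), ob$width_um)
  }
}

# Integer translation of a matrix by (dx, dy) pixels; vacated pixels filled.
shift_matrix <- function(m, dx, dy, fill = 0) {
  out <- matrix(fill, nrow = nrow(m), ncol = ncol(m))
  nr <- nrow(m); nc <- ncol(m)
  src_r <- seq_len(nr) - dy
  src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1L & src_r <= nr
  ok_c <- src_c >= 1L & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

#' Simulate a multi-mass nanoSIMS field with ground truth
#'
#' Renders the planned scene into expected count images, applies per-plane
#' drift, and draws independent Poisson counts for the three recorded masses
#' (12C, 13C, 32S). Overlapping objects with different true atom fractions
#' are rejected: their isotopic ground truth would be undefined.
#'
#' @param plan a [scene_plan()].
#' @return a list of class `sim_field` with elements `stacks` (named list of
#'   [ion_stack()] for `c12`, `c13`, `s32`), `mask` (ROI label matrix over
#'   the undrifted scene; label i = i-th object), `truth` (data frame with
#'   per-object label, morphotype, true atom fraction / at%, biovolume and
#'   pixel count) and `plan`.
#' @export
simulate_field <- function(plan) {
  stopifnot(inherits(plan, "scene_plan"))
  shape <- plan$shape
  px <- plan$pixel_size_um

  density <- matrix(plan$background_density, shape[1], shape[2])
  s_density <- matrix(0, shape[1], shape[2])
  atfrac <- matrix(plan$background_atom_fraction, shape[1], shape[2])
  mask <- matrix(0L, shape[1], shape[2])

  for (i in seq_along(plan$objects)) {
    ob <- plan$objects[[i]]
    inside <- object_pixels(ob, shape, px)
    overlap <- inside & mask > 0L
    if (any(overlap)) {
      prev_f <- unique(atfrac[overlap])
      if (length(prev_f) > 1L || any(prev_f != ob$atom_fraction)) {
        stop("objects with different atom fractions overlap; rejecting plan",
             call. = FALSE)
      }
    }
    density[inside] <- ob$density
    s_density[inside] <- ob$s_density
    atfrac[inside] <- ob$atom_fraction
    mask[inside] <- i
  }

  e13 <- density * atfrac
  e12 <- density * (1 - atfrac)
  bg13 <- plan$background_density * plan$background_atom_fraction
  bg12 <- plan$background_density * (1 - plan$background_atom_fraction)

  draw <- function(expected, k, fill) {
    shifted <- shift_matrix(expected, plan$drift[k, 1], plan$drift[k, 2],
                            fill = fill)
    matrix(rpois(length(shifted), shifted), nrow = shape[1])
  }

  stacks <- with_seed(plan$seed, {
    c12 <- lapply(seq_len(plan$n_planes), function(k) draw(e12, k, bg12))
    c13 <- lapply(seq_len(plan$n_planes), function(k) draw(e13, k, bg13))
    s32 <- lapply(seq_len(plan$n_planes), function(k) draw(s_density, k, 0))
    list(c12 = ion_stack(c12, "12C", px),
         c13 = ion_stack(c13, "13C", px),
         s32 = ion_stack(s32, "32S", px))
  })

  truth <- data.frame(
    label = seq_along(plan$objects),
    morphotype = vapply(plan$objects, `[[`, character(1), "morphotype"),
    atom_fraction = vapply(plan$objects, `[[`, numeric(1), "atom_fraction"),
    atpct = 100 * vapply(plan$objects, `[[`, numeric(1), "atom_fraction"),
    biovolume_um3 = vapply(plan$objects, object_biovolume, numeric(1)),
    n_pixels = vapply(seq_along(plan$objects),
                      function(i) sum(mask == i), integer(1))
  )

  structure(list(stacks = stacks, mask = mask, truth = truth, plan = plan),
            class = "sim_field")
}

#' @export
print.sim_field <- function(x, ...) {
  cat(sprintf("<sim_field> %d x %d px, %d plane(s), %d object(s), seed %d\n",
              x$plan$shape[1], x$plan$shape[2], x$plan$n_planes,
              nrow(x$truth), x$plan$seed))
  print(x$truth[, c("label", "morphotype", "atpct", "biovolume_um3",
                    "n_pixels")])
  invisible(x)
}

#' Write a simulated field to disk (TIFF stacks, mask, JSON ground truth)
#'
#' One multi-page TIFF per mass plus `mask.tif` and `truth.json` in `dir`.
#'
#' @param field a `sim_field` from [simulate_field()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_field <- function(field, dir) {
  stopifnot(inherits(field, "sim_field"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(field$stacks)) {
    write_ion_stack(field$stacks[[nm]], file.path(dir, paste0(nm, ".tif")))
  }
  write_label_mask(field$mask, file.path(dir, "mask.tif"))
  jsonlite::write_json(
    list(truth = field$truth,
         plan = list(shape = field$plan$shape,
                     pixel_size_um = field$plan$pixel_size_um,
                     n_planes = field$plan$n_planes,
                     seed = field$plan$seed,
                     drift = field$plan$drift)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
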