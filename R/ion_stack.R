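#' Ion image stack
#'
#' Container for a per-mass stack of secondary-ion count images: one integer
#' count matrix per acquisition plane, all of identical shape, with the pixel
#' size and mass label. `NA` pixels mark data shifted out of frame by drift
#' correction; they are excluded from all downstream sums.
#'
#' @param planes a 3-D array (rows x cols x planes) or list of matrices of
#'   non-negative integer counts; `NA` allowed for missing pixels.
#' @param mass mass label, e.g. `"12C"`, `"13C"`, `"32S"`.
#' @param pixel_size_um pixel edge length in micrometres.
#' @return an object of class `ion_stack`.
#' @export
ion_stack <- function(planes, mass, pixel_size_um = 1) {
  if (is.list(planes)) {
    if (length(planes) == 0L) stop("stack must contain at least one plane", call. = FALSE)
    shp <- dim(planes[[1]])
    if (is.null(shp)) stop("planes must be matrices", call. = FALSE)
    if (!all(vapply(planes, function(p) identical(dim(p), shp), logical(1)))) {
      stop("all planes must have the same shape", call. = FALSE)
    }
    planes <- array(unlist(planes, use.names = FALSE),
                    dim = c(shp, length(planes)))
  }
  if (!is.array(planes) || length(dim(planes)) != 3L) {
    stop("`planes` must be a 3-D array or list of matrices", call. = FALSE)
  }
  if (dim(planes)[3] < 1L) stop("stack must contain at least one plane", call. = FALSE)
  vals <- planes[!is.na(planes)]
  if (any(vals < 0) || any(vals != round(vals))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  stop_if_not_scalar_number(pixel_size_um, "pixel_size_um", positive = TRUE)
  structure(
    list(planes = planes, mass = as.character(mass),
         pixel_size_um = pixel_size_um),
    class = "ion_stack"
  )
}

#' @export
print.ion_stack <- function(x, ...) {
  d <- dim(x$planes)
  cat(sprintf("<ion_stack> mass %s: %d x %d px, %d plane(s), %.3g um/px\n",
              x$mass, d[1], d[2], d[3], x$pixel_size_um))
  tot <- sum(x$planes, na.rm = TRUE)
  cat(sprintf("  total counts %.4g; missing pixels %d\n",
              tot, sum(is.na(x$planes))))
  invisible(x)
}

#' @export
dim.ion_stack <- function(x) dim(x$planes)

n_planes <- function(stack) dim(stack$planes)[3]

# --- serialization: one multi-page 16-bit TIFF per mass + JSON sidecar ------

TIFF_MAX <- 65535L

#' Write an ion image stack to a multi-page TIFF with a JSON sidecar
#'
#' Pages are acquisition planes stored as 16-bit unsigned integers (counts per
#' plane must be below 65536; raw nanoSIMS plane counts are orders of
#' magnitude below this). Metadata (mass, pixel size, plane count) goes to
#' `<path>.json`. `NA` pixels are not representable in TIFF and are rejected;
#' serialize stacks before alignment.
#'
#' @param stack an [ion_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_ion_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ion_stack"))
  if (anyNA(stack$planes)) {
    stop("stacks with missing (NA) pixels cannot be serialized", call. = FALSE)
  }
  if (max(stack$planes) > TIFF_MAX) {
    stop("per-plane counts exceed the 16-bit TIFF range", call. = FALSE)
  }
  pages <- lapply(seq_len(n_planes(stack)),
                  function(k) stack$planes[, , k] / TIFF_MAX)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(mass = stack$mass, pixel_size_um = stack$pixel_size_um,
               n_planes = n_planes(stack), format = "counts-16bit")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an ion image stack written by [write_ion_stack()]
#'
#' @param path TIFF path; the `<path>.json` sidecar must exist.
#' @return an [ion_stack()].
#' @export
read_ion_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  planes <- lapply(pages, function(p) round(p * TIFF_MAX))
  ion_stack(planes, mass = meta$mass, pixel_size_um = meta$pixel_size_um)
}

#' Write / read an ROI label mask as a single-page TIFF
#'
#' Labels are small positive integers (0 = unlabelled background).
#'
#' @param mask integer matrix of ROI labels.
#' @param path TIFF path.
#' @return `path` (write) or the label matrix (read).
#' @export
write_label_mask <- function(mask, path) {
  if (!is.matrix(mask) || any(mask < 0) || any(mask != round(mask))) {
    stop("`mask` must be a matrix of non-negative integer labels", call. = FALSE)
  }
  if (max(mask) > TIFF_MAX) stop("label values exceed the 16-bit range", call. = FALSE)
  tiff::writeTIFF(mask / TIFF_MAX, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  p <- tiff::readTIFF(path)
  matrix(as.integer(round(p * TIFF_MAX)), nrow = nrow(p))
}
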