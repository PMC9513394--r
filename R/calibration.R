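#' Pixel-to-physical calibration from an in-image scale reference
#'
#' ABUS export images carry a scale annotation (a bar of known physical
#' length, or equivalently a square of known physical area). Calibration
#' converts that reference into a length ratio (cm per pixel) and an area
#' ratio (cm^2 per pixel), which every downstream planimetric measurement
#' multiplies by.
#'
#' @param bar_pixel_length extent of the scale bar in pixels (sub-pixel
#'   values allowed, e.g. from fractional endpoint coordinates).
#' @param bar_physical_length physical length of the bar in cm.
#' @return An object of class \code{abus_calibration}: a list with
#'   \code{length_ratio} (cm/px) and \code{area_ratio} (cm^2/px).
#' @examples
#' calibrate_from_bar(500, 5)   # 0.01 cm/px, 1e-4 cm^2/px
#' @seealso [calibrate_from_square()], [cross_section_area()]
#' @export
calibrate_from_bar <- function(bar_pixel_length, bar_physical_length) {
  if (!is.numeric(bar_pixel_length) || length(bar_pixel_length) != 1L ||
      !is.finite(bar_pixel_length) || bar_pixel_length <= 0)
    stop("invalid calibration: bar_pixel_length must be a single positive number")
  if (!is.numeric(bar_physical_length) || length(bar_physical_length) != 1L ||
      !is.finite(bar_physical_length) || bar_physical_length <= 0)
    stop("invalid calibration: bar_physical_length must be a single positive number")
  lr <- bar_physical_length / bar_pixel_length
  new_calibration(length_ratio = lr, area_ratio = lr^2, source = "bar")
}

#' Calibration from a reference square of known area
#'
#' The area ratio is the known physical area divided by the pixel count
#' inside the reference square; the length ratio is its square root.
#'
#' @param pixel_count number of pixels counted inside the reference square.
#' @param known_area physical area of the square in cm^2.
#' @return An \code{abus_calibration} object.
#' @examples
#' cal <- calibrate_from_square(70756, 25)
#' cal$area_ratio  # ~3.533e-4 cm^2 per pixel
#' @export
calibrate_from_square <- function(pixel_count, known_area) {
  if (!is.numeric(pixel_count) || length(pixel_count) != 1L ||
      !is.finite(pixel_count) || pixel_count < 1)
    stop("invalid calibration: pixel_count must be a single number >= 1")
  if (!is.numeric(known_area) || length(known_area) != 1L ||
      !is.finite(known_area) || known_area <= 0)
    stop("invalid calibration: known_area must be a single positive number")
  ar <- known_area / pixel_count
  new_calibration(length_ratio = sqrt(ar), area_ratio = ar, source = "square")
}

new_calibration <- function(length_ratio, area_ratio, source = "manual") {
  stopifnot(length_ratio > 0, area_ratio > 0)
  structure(
    list(length_ratio = length_ratio, area_ratio = area_ratio, source = source),
    class = "abus_calibration"
  )
}

#' @export
print.abus_calibration <- function(x, ...) {
  cat("ABUS pixel calibration (from ", x$source, ")\n", sep = "")
  cat(sprintf("  length ratio: %.6g cm/px\n", x$length_ratio))
  cat(sprintf("  area ratio:   %.6g cm^2/px\n", x$area_ratio))
  invisible(x)
}

#' Read / write calibration JSON
#'
#' Calibrations are serialized with explicit unit-bearing keys
#' (\code{length_ratio_cm_per_px}, \code{area_ratio_cm2_per_px}) so files
#' remain self-describing outside the package.
#'
#' @param cal an \code{abus_calibration} object.
#' @param path file path of the JSON document.
#' @return \code{read_calibration} returns an \code{abus_calibration};
#'   \code{write_calibration} returns \code{path} invisibly.
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "abus_calibration"))
  jsonlite::write_json(
    list(length_ratio_cm_per_px = cal$length_ratio,
         area_ratio_cm2_per_px = cal$area_ratio,
         source = cal$source),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$length_ratio_cm_per_px) || is.null(x$area_ratio_cm2_per_px))
    stop("invalid calibration file: missing ratio keys")
  new_calibration(x$length_ratio_cm_per_px, x$area_ratio_cm2_per_px,
                  source = if (is.null(x$source)) "file" else x$source)
}
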