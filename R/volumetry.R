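#' Ordered per-slice cross-section areas
#'
#' A slice series holds the coronal cross-sectional areas of one tumor,
#' one value per slice, at a fixed inter-slice spacing. ABUS coronal
#' reconstructions are sectioned at 0.1-cm intervals, the default here.
#'
#' @param areas numeric vector of areas in cm^2, ordered along the stack;
#'   may be empty.
#' @param thickness slice spacing in cm (default 0.1).
#' @return An object of class \code{abus_slices}.
#' @export
slice_series <- function(areas = numeric(), thickness = 0.1) {
  areas <- as.numeric(areas)
  if (any(!is.finite(areas)) || any(areas < 0))
    stop("invalid series: areas must be finite and >= 0")
  if (!is.numeric(thickness) || length(thickness) != 1L ||
      !is.finite(thickness) || thickness <= 0)
    stop("invalid series: thickness must be a single positive number")
  structure(list(areas = areas, thickness = thickness), class = "abus_slices")
}

#' @export
print.abus_slices <- function(x, ...) {
  cat(sprintf("Slice series: %d slices at %.3g cm, total volume %.4g cm^3\n",
              length(x$areas), x$thickness, cavalieri_volume(x)))
  invisible(x)
}

#' Pixel-method (Cavalieri) tumor volume
#'
#' The Cavalieri estimate: the sum of per-slice cross-sectional areas times
#' the slice thickness. No end correction is applied — each slice
#' contributes area x thickness, exactly the layer model of the
#' pixel method. An empty series has volume 0.
#'
#' @param series an \code{abus_slices}, or a numeric vector of areas (cm^2).
#' @param thickness slice spacing in cm, used when \code{series} is a bare
#'   numeric vector.
#' @return volume in cm^3.
#' @examples
#' cavalieri_volume(slice_series(c(1.0, 1.2, 0.8)))  # 0.3 cm^3
#' @export
cavalieri_volume <- function(series, thickness = 0.1) {
  if (!inherits(series, "abus_slices")) series <- slice_series(series, thickness)
  sum(series$areas) * series$thickness
}

#' Caliper measurement of a tumor
#'
#' The three caliper diameters of the traditional method: length (largest
#' diameter on the coronal plane), width (largest diameter perpendicular to
#' the length, same plane) and height (anteroposterior diameter). Length
#' must be at least the width.
#'
#' @param length,width,height diameters in cm.
#' @return An object of class \code{abus_calipers}.
#' @export
caliper_measurement <- function(length, width, height) {
  vals <- c(length = length, width = width, height = height)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("invalid measurement: all dimensions must be positive")
  if (length < width)
    stop("invalid measurement: length must be >= width")
  structure(as.list(vals), class = "abus_calipers")
}

#' @export
print.abus_calipers <- function(x, ...) {
  cat(sprintf("Calipers: L %.3g x W %.3g x H %.3g cm (traditional volume %.4g cm^3)\n",
              x$length, x$width, x$height, traditional_volume(x)))
  invisible(x)
}

#' Traditional caliper tumor volume
#'
#' The ellipsoid-style approximation used clinically:
#' volume = length x width x height / 2.
#'
#' @param m an \code{abus_calipers}, or the length in cm when \code{width}
#'   and \code{height} are given.
#' @param width,height diameters in cm (ignored when \code{m} is an
#'   \code{abus_calipers}).
#' @return volume in cm^3.
#' @examples
#' traditional_volume(2, 1.5, 1)  # 1.5 cm^3
#' @export
traditional_volume <- function(m, width = NULL, height = NULL) {
  if (!inherits(m, "abus_calipers")) m <- caliper_measurement(m, width, height)
  m$length * m$width * m$height / 2
}

#' Measure calipers from a coronal mask stack
#'
#' Derives the traditional method's inputs from a stack of binary coronal
#' cross-sections: the length is the largest pixel-center-to-pixel-center
#' chord over all slices (rotating over the convex hull of each mask), the
#' width is the largest extent perpendicular to the length direction on the
#' slice where the length is attained, and the height is the number of
#' slices spanned by non-empty masks times the slice thickness.
#'
#' @param mask_stack list of \code{abus_mask}, ordered along the stack.
#' @param cal an \code{abus_calibration}.
#' @param thickness slice spacing in cm.
#' @return An \code{abus_calipers}.
#' @export
measure_calipers <- function(mask_stack, cal, thickness = 0.1) {
  stopifnot(inherits(cal, "abus_calibration"), length(mask_stack) >= 1L)
  occupied <- vapply(mask_stack, function(m) m$pixel_count > 0L, logical(1L))
  if (!any(occupied)) stop("empty tumor: all masks in the stack are empty")

  best <- list(len = -1, dir = c(1, 0), pts = NULL)
  for (m in mask_stack[occupied]) {
    p <- mask_pixel_centers(m)
    h <- if (nrow(p) > 2L) p[grDevices::chull(p), , drop = FALSE] else p
    d <- as.matrix(stats::dist(h))
    ij <- which(d == max(d), arr.ind = TRUE)[1L, ]
    len <- d[ij[1L], ij[2L]]
    if (len > best$len) {
      dir <- h[ij[2L], ] - h[ij[1L], ]
      nd <- sqrt(sum(dir^2))
      best <- list(len = len, dir = if (nd > 0) dir / nd else c(1, 0), pts = p)
    }
  }
  # width: extent of the length-attaining slice perpendicular to the length
  perp <- c(-best$dir[2L], best$dir[1L])
  proj <- best$pts %*% perp
  width_px <- max(proj) - min(proj)
  idx <- which(occupied)
  height <- (max(idx) - min(idx) + 1L) * thickness

  length_cm <- best$len * cal$length_ratio
  width_cm <- width_px * cal$length_ratio
  # a single-pixel or collinear mask can give width 0 or length 0
  if (length_cm <= 0 || width_cm <= 0)
    stop("degenerate tumor: caliper extent is zero")
  caliper_measurement(max(length_cm, width_cm), min(length_cm, width_cm), height)
}

# pixel centers (x, y) = (col - 0.5, row - 0.5) of all set pixels
mask_pixel_centers <- function(mask) {
  w <- which(mask$bitmap, arr.ind = TRUE)
  cbind(x = w[, 2L] - 0.5, y = w[, 1L] - 0.5)
}

#' Slice series from a mask stack
#'
#' Converts each mask's pixel count to a physical area and assembles the
#' ordered series used by [cavalieri_volume()].
#'
#' @inheritParams measure_calipers
#' @return An \code{abus_slices}.
#' @export
slice_series_from_masks <- function(mask_stack, cal, thickness = 0.1) {
  areas <- vapply(mask_stack, cross_section_area, numeric(1L), cal = cal)
  slice_series(areas, thickness)
}

#' Slice series CSV I/O
#'
#' Areas travel as CSV with columns \code{slice_index}, \code{area_cm2};
#' the slice thickness is stored in a JSON sidecar (same path with
#' \code{.json} appended) so the CSV stays a plain area table.
#'
#' @param series an \code{abus_slices}.
#' @param path CSV file path.
#' @export
write_slice_series_csv <- function(series, path) {
  stopifnot(inherits(series, "abus_slices"))
  utils::write.csv(
    data.frame(slice_index = seq_along(series$areas), area_cm2 = series$areas),
    path, row.names = FALSE
  )
  jsonlite::write_json(list(thickness_cm = series$thickness),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_slice_series_csv
#' @param thickness fallback slice spacing in cm when no sidecar exists.
#' @export
read_slice_series_csv <- function(path, thickness = 0.1) {
  d <- utils::read.csv(path)
  if (!all(c("slice_index", "area_cm2") %in% names(d)))
    stop("slice series CSV must have columns slice_index and area_cm2")
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    t <- jsonlite::read_json(side, simplifyVector = TRUE)$thickness_cm
    if (!is.null(t)) thickness <- t
  }
  slice_series(d$area_cm2[order(d$slice_index)], thickness)
}
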