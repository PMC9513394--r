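#' Tumor outline as an ordered polygon contour
#'
#' A contour is the manually drawn outline of a tumor cross-section,
#' stored as ordered (x, y) pixel coordinates (sub-pixel values allowed)
#' and implicitly closed: the last vertex connects back to the first.
#' Self-intersecting outlines are accepted with a warning; area semantics
#' then follow the even-odd fill rule.
#'
#' @param x,y numeric vertex coordinates in pixel units, or \code{x} may be
#'   a two-column matrix/data frame of vertices.
#' @return An object of class \code{abus_contour}: a list with a
#'   \code{vertices} matrix (columns \code{x}, \code{y}).
#' @examples
#' sq <- contour_polygon(c(0, 10, 10, 0), c(0, 0, 10, 10))
#' @export
contour_polygon <- function(x, y = NULL) {
  if (is.null(y)) {
    m <- as.matrix(x)
    if (ncol(m) != 2L) stop("invalid contour: need two columns (x, y)")
    x <- m[, 1L]; y <- m[, 2L]
  }
  if (length(x) != length(y)) stop("invalid contour: x and y lengths differ")
  # drop an explicitly repeated closing vertex
  n <- length(x)
  if (n >= 2L && x[1L] == x[n] && y[1L] == y[n]) {
    x <- x[-n]; y <- y[-n]; n <- n - 1L
  }
  if (n < 3L) stop("invalid contour: fewer than 3 vertices")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("invalid contour: non-finite coordinates")
  v <- cbind(x = as.numeric(x), y = as.numeric(y))
  ct <- structure(list(vertices = v), class = "abus_contour")
  if (contour_self_intersects(ct))
    warning("contour is self-intersecting; area follows the even-odd rule")
  ct
}

#' @export
print.abus_contour <- function(x, ...) {
  v <- x$vertices
  cat(sprintf("Closed contour, %d vertices, bbox [%.1f, %.1f] x [%.1f, %.1f] px\n",
              nrow(v), min(v[, 1]), max(v[, 1]), min(v[, 2]), max(v[, 2])))
  invisible(x)
}

# proper-crossing test between non-adjacent edges (shared endpoints ignored);
# vectorized over all edge pairs
contour_self_intersects <- function(ct) {
  v <- ct$vertices
  n <- nrow(v)
  x1 <- v[, 1L]; y1 <- v[, 2L]
  x2 <- c(x1[-1L], x1[1L]); y2 <- c(y1[-1L], y1[1L])
  ex <- x2 - x1; ey <- y2 - y1
  # D1[j, i] = cross(edge j, start of edge i); D2[j, i] = cross(edge j, end)
  D1 <- outer(ex, y1) - ex * y1 - outer(ey, x1) + ey * x1
  D2 <- outer(ex, y2) - ex * y1 - outer(ey, x2) + ey * x1
  crossing <- (D1 * D2 < 0) & t(D1 * D2 < 0)
  idx <- seq_len(n)
  adj <- cbind(rep(idx, 3L), c(idx, idx %% n + 1L, (idx - 2L) %% n + 1L))
  crossing[adj] <- FALSE
  any(crossing)
}

#' Signed shoelace area of a contour (diagnostic)
#'
#' Analytic polygon area in square pixels. Planimetric measurements use
#' pixel counting, not this value; it is exposed as a cross-check on the
#' rasterization (the two converge as the region grows).
#'
#' @param ct an \code{abus_contour}.
#' @return absolute polygon area in px^2.
#' @export
shoelace_area <- function(ct) {
  stopifnot(inherits(ct, "abus_contour"))
  v <- ct$vertices
  x <- v[, 1L]; y <- v[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  abs(sum(x * ys - xs * y)) / 2
}

new_region_mask <- function(bitmap) {
  stopifnot(is.logical(bitmap), is.matrix(bitmap))
  structure(
    list(bitmap = bitmap, width = ncol(bitmap), height = nrow(bitmap),
         pixel_count = sum(bitmap)),
    class = "abus_mask"
  )
}

#' @export
print.abus_mask <- function(x, ...) {
  cat(sprintf("Region mask %d x %d px, %d pixels set\n",
              x$width, x$height, x$pixel_count))
  invisible(x)
}

#' Rasterize a contour to a binary region mask
#'
#' Scanline even-odd fill: a pixel with zero-based index (i, j) is set iff
#' its center (i + 0.5, j + 0.5) lies inside the polygon under the even-odd
#' rule. Centers coincident with the boundary are resolved half-open
#' (left/top inclusive), so abutting regions tile without overlap and the
#' result is deterministic. Pixels whose centers fall outside the raster
#' are clipped.
#'
#' @param ct an \code{abus_contour}.
#' @param width,height raster dimensions in pixels.
#' @return An object of class \code{abus_mask}: logical \code{bitmap}
#'   matrix (rows = y, columns = x), \code{width}, \code{height} and the
#'   derived \code{pixel_count}.
#' @examples
#' sq <- contour_polygon(c(0, 10, 10, 0), c(0, 0, 10, 10))
#' rasterize_contour(sq, 20, 20)$pixel_count  # 100
#' @export
rasterize_contour <- function(ct, width, height) {
  stopifnot(inherits(ct, "abus_contour"))
  width <- as.integer(width); height <- as.integer(height)
  if (width < 1L || height < 1L) stop("invalid raster dimensions")
  v <- ct$vertices
  n <- nrow(v)
  x1 <- v[, 1L]; y1 <- v[, 2L]
  x2 <- c(x1[-1L], x1[1L]); y2 <- c(y1[-1L], y1[1L])
  bitmap <- matrix(FALSE, nrow = height, ncol = width)

  jlo <- max(0L, floor(min(y1) - 0.5))
  jhi <- min(height - 1L, ceiling(max(y1)))
  if (jhi < jlo) return(new_region_mask(bitmap))

  for (j in jlo:jhi) {
    yc <- j + 0.5
    # edges crossing the scanline (half-open in y: one endpoint strictly above)
    hit <- (y1 > yc) != (y2 > yc)
    if (!any(hit)) next
    xc <- sort(x1[hit] + (yc - y1[hit]) * (x2[hit] - x1[hit]) / (y2[hit] - y1[hit]))
    # inside spans are [xc[2k-1], xc[2k]) over pixel centers i + 0.5
    for (k in seq(1L, length(xc) - 1L, by = 2L)) {
      i0 <- max(0L, ceiling(xc[k] - 0.5))
      i1 <- min(width - 1L, ceiling(xc[k + 1L] - 0.5) - 1L)
      if (i1 >= i0) bitmap[j + 1L, (i0:i1) + 1L] <- TRUE
    }
  }
  new_region_mask(bitmap)
}

#' Physical cross-sectional area from a pixel count
#'
#' The planimetric area of one coronal tumor cross-section: the number of
#' pixels inside the outline times the calibrated area ratio.
#'
#' @param pixels a non-negative pixel count, or an \code{abus_mask} whose
#'   \code{pixel_count} is used.
#' @param cal an \code{abus_calibration}.
#' @return area in cm^2.
#' @examples
#' cal <- calibrate_from_square(70756, 25)
#' cross_section_area(3916, cal)  # ~1.38 cm^2
#' @export
cross_section_area <- function(pixels, cal) {
  stopifnot(inherits(cal, "abus_calibration"))
  if (inherits(pixels, "abus_mask")) pixels <- pixels$pixel_count
  if (!is.numeric(pixels) || any(pixels < 0))
    stop("pixel count must be non-negative")
  pixels * cal$area_ratio
}

#' Contour CSV I/O
#'
#' Contours travel as plain CSV with columns \code{x}, \code{y}, one vertex
#' per row in drawing order.
#'
#' @param ct an \code{abus_contour}.
#' @param path CSV file path.
#' @export
write_contour_csv <- function(ct, path) {
  stopifnot(inherits(ct, "abus_contour"))
  utils::write.csv(as.data.frame(ct$vertices), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contour_csv
#' @export
read_contour_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(d)))
    stop("contour CSV must have columns x and y")
  contour_polygon(d$x, d$y)
}

#' Region mask PNG I/O
#'
#' Masks are stored as single-channel PNG with background 0 and region 255.
#'
#' @param mask an \code{abus_mask}.
#' @param path PNG file path.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "abus_mask"))
  png::writePNG(mask$bitmap * 1.0, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  new_region_mask(img > 0.5)
}
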