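#' Specification of a synthetic tumor phantom
#'
#' A parametric 3-D shape with analytically known volume, used to validate
#' the whole measurement chain without patient data. The base shape is an
#' ellipsoid with semi-axes (a, b, c) in cm — a and b in the coronal plane,
#' c along the stack — sliced coronally at \code{slice_thickness} spacing
#' and rasterized at \code{pixel_pitch}. \code{perturbed_ellipsoid} adds
#' band-limited radial noise to each coronal contour, emulating irregular
#' lesion outlines; its ground-truth volume is then the exact polygon
#' (shoelace) area of each perturbed contour times the slice thickness,
#' since the perturbed solid is defined by those polygons. Default sizes
#' sit in the 1-5 cm diameter range typical of the lesions this method
#' targets.
#'
#' @param shape \code{"ellipsoid"} or \code{"perturbed_ellipsoid"}.
#' @param semi_axes numeric (a, b, c) in cm, all positive.
#' @param pixel_pitch raster resolution in cm per pixel.
#' @param slice_thickness coronal slice spacing in cm (0.1 as in ABUS
#'   reconstructions).
#' @param perturbation_amplitude radial noise SD as a fraction of the local
#'   radius, in [0, 0.5).
#' @param smoothness harmonic cutoff of the radial noise (higher = rougher).
#' @param seed integer; the realization is a pure function of (spec, seed).
#' @return An object of class \code{abus_phantom_spec}.
#' @export
phantom_spec <- function(shape = c("ellipsoid", "perturbed_ellipsoid"),
                         semi_axes = c(1.0, 0.8, 0.6),
                         pixel_pitch = 0.01,
                         slice_thickness = 0.1,
                         perturbation_amplitude = 0,
                         smoothness = 8L,
                         seed = 1L) {
  shape <- match.arg(shape)
  if (length(semi_axes) != 3L || any(!is.finite(semi_axes)) || any(semi_axes <= 0))
    stop("invalid phantom: semi_axes must be 3 positive numbers")
  if (pixel_pitch <= 0 || slice_thickness <= 0)
    stop("invalid phantom: pitch and thickness must be positive")
  if (perturbation_amplitude < 0 || perturbation_amplitude >= 0.5)
    stop("invalid phantom: perturbation_amplitude must be in [0, 0.5)")
  structure(list(shape = shape, semi_axes = as.numeric(semi_axes),
                 pixel_pitch = pixel_pitch, slice_thickness = slice_thickness,
                 perturbation_amplitude = perturbation_amplitude,
                 smoothness = as.integer(smoothness), seed = as.integer(seed)),
            class = "abus_phantom_spec")
}

#' Phantom spec YAML I/O
#' @param spec an \code{abus_phantom_spec}.
#' @param path YAML file path.
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "abus_phantom_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  x <- yaml::read_yaml(path)
  phantom_spec(shape = x$shape, semi_axes = unlist(x$semi_axes),
               pixel_pitch = x$pixel_pitch, slice_thickness = x$slice_thickness,
               perturbation_amplitude = x$perturbation_amplitude %||% 0,
               smoothness = x$smoothness %||% 8L, seed = x$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a phantom realization
#'
#' Slices the shape coronally: slice planes sit at z = -c + (k - 1/2) * t,
#' k = 1..ceiling(2c / t), so the stack symmetrically samples the interior
#' of (-c, c) and no plane coincides with a pole. Each slice's cross
#' section (an ellipse, optionally perturbed) becomes a polygon contour
#' rasterized at the spec's pixel pitch on a raster that encloses the
#' shape with margin.
#'
#' @param spec an \code{abus_phantom_spec}.
#' @return An object of class \code{abus_phantom} with \code{mask_stack}
#'   (list of \code{abus_mask}), \code{contours}, \code{true_volume} (cm^3;
#'   analytic (4/3) pi a b c for the ellipsoid, exact polygon-area sum for
#'   perturbed shapes), \code{true_calipers} (cm), \code{calibration} (the
#'   exact pitch) and the generating \code{spec}.
#' @examples
#' ph <- generate_phantom(phantom_spec(semi_axes = c(0.5, 0.4, 0.3),
#'                                     pixel_pitch = 0.02))
#' cavalieri_volume(slice_series_from_masks(ph$mask_stack, ph$calibration))
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "abus_phantom_spec"))
  a <- spec$semi_axes[1L]; b <- spec$semi_axes[2L]; c <- spec$semi_axes[3L]
  p <- spec$pixel_pitch; t <- spec$slice_thickness
  n_slices <- ceiling(2 * c / t)
  if (n_slices < 1L || a < p || b < p)
    stop("degenerate phantom: shape smaller than one pixel or one slice")

  margin <- 1.30  # head-room for radial perturbation (< 0.5 amplitude)
  width <- as.integer(ceiling(2 * a * margin / p)) + 4L
  height <- as.integer(ceiling(2 * b * margin / p)) + 4L
  cx <- width / 2; cy <- height / 2
  cal <- new_calibration(p, p^2, source = "phantom")

  n_vert <- 256L
  theta <- (seq_len(n_vert) - 1L) * 2 * pi / n_vert
  set.seed(spec$seed)

  contours <- vector("list", n_slices)
  masks <- vector("list", n_slices)
  areas_true <- numeric(n_slices)
  pts_all <- NULL
  for (k in seq_len(n_slices)) {
    z <- -c + (k - 0.5) * t
    s2 <- 1 - (z / c)^2
    if (s2 <= 0) { # plane beyond the pole (only when t does not divide 2c)
      masks[[k]] <- new_region_mask(matrix(FALSE, height, width))
      next
    }
    ax <- a * sqrt(s2) / p; bx <- b * sqrt(s2) / p  # in px
    r_unit <- rep(1, n_vert)
    if (spec$shape == "perturbed_ellipsoid" && spec$perturbation_amplitude > 0)
      r_unit <- 1 + band_limited_noise(n_vert, spec$smoothness,
                                       spec$perturbation_amplitude)
    vx <- cx + ax * r_unit * cos(theta)
    vy <- cy + bx * r_unit * sin(theta)
    ct <- contour_polygon(vx, vy)
    contours[[k]] <- ct
    masks[[k]] <- rasterize_contour(ct, width, height)
    areas_true[k] <- shoelace_area(ct) * p^2
    pts <- cbind((ct$vertices[, 1L] - cx) * p, (ct$vertices[, 2L] - cy) * p)
    pts_all <- rbind(pts_all, pts)
  }
  if (all(vapply(masks, function(m) m$pixel_count == 0L, logical(1L))))
    stop("degenerate phantom: no slice produced any pixels")

  if (spec$shape == "ellipsoid") {
    true_volume <- 4 / 3 * pi * a * b * c
    true_calipers <- c(L = 2 * max(a, b), W = 2 * min(a, b), H = 2 * c)
  } else {
    true_volume <- sum(areas_true) * t
    hull <- pts_all[grDevices::chull(pts_all), , drop = FALSE]
    d <- as.matrix(stats::dist(hull))
    ij <- which(d == max(d), arr.ind = TRUE)[1L, ]
    len <- d[ij[1L], ij[2L]]
    dir <- hull[ij[2L], ] - hull[ij[1L], ]; dir <- dir / sqrt(sum(dir^2))
    proj <- pts_all %*% c(-dir[2L], dir[1L])
    true_calipers <- c(L = len, W = max(proj) - min(proj), H = n_slices * t)
  }

  structure(list(mask_stack = masks, contours = contours,
                 true_volume = true_volume, true_calipers = true_calipers,
                 calibration = cal, spec = spec),
            class = "abus_phantom")
}

#' @export
print.abus_phantom <- function(x, ...) {
  cat(sprintf("Phantom (%s): %d slices at %.3g cm, pitch %.3g cm/px\n",
              x$spec$shape, length(x$mask_stack), x$spec$slice_thickness,
              x$spec$pixel_pitch))
  cat(sprintf("  true volume %.4g cm^3, calipers %.3g x %.3g x %.3g cm\n",
              x$true_volume, x$true_calipers[1L], x$true_calipers[2L],
              x$true_calipers[3L]))
  invisible(x)
}

# zero-mean radial noise: truncated random cosine series over the polar
# angle, harmonics 2..smoothness (harmonic 1 is a translation, excluded),
# rescaled to the requested SD; always a closed curve
band_limited_noise <- function(n_vert, smoothness, amplitude_sd) {
  theta <- (seq_len(n_vert) - 1L) * 2 * pi / n_vert
  h <- 2:max(2L, smoothness)
  coef_c <- stats::rnorm(length(h)); coef_s <- stats::rnorm(length(h))
  noise <- drop(cos(outer(theta, h)) %*% coef_c + sin(outer(theta, h)) %*% coef_s)
  s <- stats::sd(noise)
  if (s == 0) return(numeric(n_vert))
  pmax(noise / s * amplitude_sd, -0.9)  # keep radius positive
}

#' Perturb a contour with smoothed radial noise
#'
#' Models inter-observer outlining variability: each vertex is displaced
#' radially (from the contour centroid) by Gaussian noise smoothed
#' circularly over \code{correlation_length} neighboring vertices and
#' scaled to \code{amplitude} pixels SD. If the displaced polygon
#' self-intersects the draw is retried with the amplitude damped by half,
#' up to 10 times (then the last attempt is returned with a warning).
#' Amplitude 0 returns the input unchanged; a fixed seed gives identical
#' output.
#'
#' @param ct an \code{abus_contour}.
#' @param amplitude radial displacement SD in pixels.
#' @param correlation_length smoothing window, in vertices.
#' @param seed integer seed.
#' @return An \code{abus_contour}.
#' @export
perturb_contour <- function(ct, amplitude, correlation_length = 9L, seed = 1L) {
  stopifnot(inherits(ct, "abus_contour"), amplitude >= 0)
  if (amplitude == 0) return(ct)
  v <- ct$vertices
  n <- nrow(v)
  cx <- mean(v[, 1L]); cy <- mean(v[, 2L])
  ux <- v[, 1L] - cx; uy <- v[, 2L] - cy
  rr <- sqrt(ux^2 + uy^2)
  rr[rr == 0] <- 1e-9
  set.seed(seed)
  amp <- amplitude
  w <- max(1L, as.integer(correlation_length))
  for (try in seq_len(10L)) {
    eps <- stats::rnorm(n)
    # circular moving average
    kern <- rep(1 / w, w)
    eps_s <- stats::filter(c(eps, eps, eps), kern, sides = 2L)[(n + 1L):(2L * n)]
    s <- stats::sd(eps_s)
    disp <- if (s > 0) eps_s / s * amp else numeric(n)
    disp <- pmax(disp, -0.9 * rr)  # keep vertices on the centroid side
    scale <- (rr + disp) / rr
    out <- suppressWarnings(
      contour_polygon(cx + ux * scale, cy + uy * scale))
    if (!contour_self_intersects(out)) return(out)
    amp <- amp / 2
  }
  warning("perturbed contour still self-intersects after 10 damped retries")
  out
}

#' Render a slice image with a scale bar
#'
#' Produces the kind of input the measurement chain starts from: a
#' grayscale image (values in [0, 1]) with the region in white on black,
#' plus a reserved bottom margin holding a horizontal white scale bar of
#' known physical length whose pixel length follows from the calibration.
#' Round-tripping the image through scale-bar detection and region
#' re-extraction recovers the calibration and the exact pixel count.
#'
#' @param mask an \code{abus_mask}.
#' @param cal an \code{abus_calibration} (defines the pixel pitch).
#' @param scalebar_cm physical length of the rendered bar in cm.
#' @return numeric matrix (rows = y) in [0, 1] with attributes
#'   \code{region_rows} (rows holding the mask) and \code{bar} (row, start
#'   column, pixel length of the bar).
#' @export
render_slice_image <- function(mask, cal, scalebar_cm = 5) {
  stopifnot(inherits(mask, "abus_mask"), inherits(cal, "abus_calibration"),
            scalebar_cm > 0)
  bar_px <- scalebar_cm / cal$length_ratio
  if (ceiling(bar_px) + 2L > mask$width)
    stop("render error: scale bar longer than image width")
  margin <- 6L
  img <- matrix(0, nrow = mask$height + margin, ncol = mask$width)
  img[seq_len(mask$height), ] <- mask$bitmap * 1.0
  bar_row <- mask$height + 3L
  bar_start <- 2L
  img[bar_row, bar_start:(bar_start + round(bar_px) - 1L)] <- 1.0
  structure(img,
            region_rows = c(1L, mask$height),
            bar = c(row = bar_row, start = bar_start, length_px = round(bar_px)),
            bar_cm = scalebar_cm)
}

#' Recover calibration and region from a rendered slice image
#'
#' For self-generated images (known layout: region block on top, scale bar
#' in the bottom margin), measures the bar's pixel run length in the known
#' bar row and rebuilds the calibration and region mask.
#'
#' @param img matrix produced by [render_slice_image()].
#' @param scalebar_cm the bar's physical length; defaults to the value
#'   recorded at render time.
#' @return list with \code{calibration} and \code{mask}.
#' @export
measure_rendered_image <- function(img, scalebar_cm = attr(img, "bar_cm")) {
  bar <- attr(img, "bar")
  rr <- attr(img, "region_rows")
  if (is.null(bar) || is.null(rr)) stop("image has no recorded layout")
  run <- sum(img[bar["row"], ] > 0.5)
  cal <- calibrate_from_bar(run, scalebar_cm)
  mask <- new_region_mask(img[rr[1L]:rr[2L], , drop = FALSE] > 0.5)
  list(calibration = cal, mask = mask)
}
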