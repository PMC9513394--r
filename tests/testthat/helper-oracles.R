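# Independent oracles, deliberately coded differently from the package
# internals they check.

# brute-force even-odd point-in-polygon rasterizer: per pixel center, walk
# every edge and count ray crossings to the right (half-open in y, crossing
# strictly right of the center counts)
pip_oracle_count <- function(vertices, width, height) {
  x <- vertices[, 1L]; y <- vertices[, 2L]
  n <- length(x)
  count <- 0L
  for (j in 0:(height - 1L)) {
    py <- j + 0.5
    for (i in 0:(width - 1L)) {
      px <- i + 0.5
      crossings <- 0L
      for (e in seq_len(n)) {
        e2 <- if (e == n) 1L else e + 1L
        ylo_is_1 <- y[e] <= py && y[e2] > py
        ylo_is_2 <- y[e2] <= py && y[e] > py
        if (ylo_is_1 || ylo_is_2) {
          tt <- (py - y[e]) / (y[e2] - y[e])
          xi <- x[e] + tt * (x[e2] - x[e])
          if (xi > px) crossings <- crossings + 1L
        }
      }
      if (crossings %% 2L == 1L) count <- count + 1L
    }
  }
  count
}

# exact two-sided signed-rank p by literal enumeration of all 2^n sign vectors
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1L), function(bits) {
    signs <- bitwAnd(bits, 2^(0:(n - 1L))) > 0
    sum(r[signs])
  }, numeric(1L))
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# brute-force maximum pairwise distance between points (no hull shortcut)
brute_max_dist <- function(pts) {
  best <- 0
  for (i in seq_len(nrow(pts) - 1L))
    for (j in (i + 1L):nrow(pts))
      best <- max(best, sqrt(sum((pts[i, ] - pts[j, ])^2)))
  best
}

# random polygon (possibly self-intersecting) with vertices inside the raster
rand_polygon <- function(n_vertices, width, height) {
  suppressWarnings(contour_polygon(stats::runif(n_vertices, 1, width - 1),
                                   stats::runif(n_vertices, 1, height - 1)))
}
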