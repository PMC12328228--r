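#' Classify forest pixels from canopy cover
#'
#' A pixel is forest when its canopy cover is at or above `threshold`
#' (inclusive); nodata propagates.
#'
#' @param canopy [raster_grid()] of canopy cover in percent (0-100).
#' @param threshold forest threshold in percent; default 30.
#' @return binary [raster_grid()]: 1 forest, 0 non-forest, `NA` nodata.
#' @export
classify_forest <- function(canopy, threshold = 30) {
  stopifnot(inherits(canopy, "raster_grid"))
  v <- canopy$values
  ok <- is.finite(v)
  if (any(v[ok] < 0 | v[ok] > 100))
    stop_invalid("canopy cover must lie in [0, 100]")
  m <- matrix(NA_real_, nrow(v), ncol(v))
  m[ok] <- as.numeric(v[ok] >= threshold)
  raster_grid(m, origin = canopy$origin, pixel_size = canopy$pixel_size,
              nodata = canopy$nodata)
}

#' Signed Euclidean distance to the forest edge
#'
#' For every forest pixel, the Euclidean distance (m) between its centre and
#' the centre of the nearest non-forest pixel, with positive sign; for every
#' non-forest pixel, the negative of the distance to the nearest forest
#' pixel. Distances are exact (no approximate transform) and measured between
#' pixel centres, so the smallest attainable magnitude is one pixel.
#'
#' @param mask binary [raster_grid()] from [classify_forest()].
#' @return [raster_grid()] of signed distances in metres; `NA` at nodata.
#' @export
signed_distance_to_edge <- function(mask) {
  stopifnot(inherits(mask, "raster_grid"))
  v <- mask$values
  forest <- v == 1 & is.finite(v)
  nonforest <- v == 0 & is.finite(v)
  if (!any(forest) || !any(nonforest))
    stop_invalid("mask has a single class: distance to edge is undefined")
  d2_to_nonforest <- edt_squared(nonforest)
  d2_to_forest <- edt_squared(forest)
  out <- matrix(NA_real_, nrow(v), ncol(v))
  out[forest] <- sqrt(d2_to_nonforest[forest])
  out[nonforest] <- -sqrt(d2_to_forest[nonforest])
  out <- out * mask$pixel_size
  raster_grid(out, origin = mask$origin, pixel_size = mask$pixel_size,
              nodata = mask$nodata)
}

#' Randomly sample points from one scene-by-overpass
#'
#' Draws `n` pixels uniformly without replacement over the whole grid, then
#' applies the point-level inclusion filters in order: cloud-covered points,
#' points with missing temperature/elevation/distance, and points farther
#' than `max_dist` from the forest edge. Sampling first and filtering second
#' means the retained count varies between draws.
#'
#' @param fields list with [raster_grid()] entries `tsurf`, `elev`, `cloud`
#'   (cloud: 1 = occluded, 0 = clear).
#' @param mask binary forest mask, co-registered with `fields`.
#' @param n points to draw; default 1000. If `n` exceeds the number of
#'   pixels, all pixels are taken and a warning record is attached.
#' @param seed integer seed controlling the draw.
#' @param max_dist retention limit on `|dist_m|` in metres; default 1000.
#' @param dist optional precomputed signed-distance raster (else computed).
#' @return data.frame with columns `x`, `y`, `dist_m`, `tsurf_c`, `elev_m`;
#'   attribute `removal` holds the per-filter removal counts
#'   (`cloud`, `nodata`, `distance`) and attribute `n_sampled` the draw size.
#' @export
sample_scene_points <- function(fields, mask, n = 1000, seed = 1L,
                                max_dist = 1000, dist = NULL) {
  stopifnot(inherits(mask, "raster_grid"))
  if (is.null(dist)) dist <- signed_distance_to_edge(mask)
  npix <- length(mask$values)
  warn <- NULL
  n_draw <- n
  if (n_draw > npix) {
    warn <- sprintf("requested %d points but only %d pixels; sampling all", n, npix)
    n_draw <- npix
  }
  idx <- with_seed_(seed, sample.int(npix, n_draw, replace = FALSE))

  ctr <- pixel_centers(mask)
  ij <- arrayInd(idx, dim(mask$values))
  pts <- data.frame(
    x = ctr$x[ij[, 2]],
    y = ctr$y[ij[, 1]],
    dist_m = dist$values[idx],
    tsurf_c = fields$tsurf$values[idx],
    elev_m = fields$elev$values[idx],
    cloud = fields$cloud$values[idx]
  )

  is_cloud <- is.finite(pts$cloud) & pts$cloud > 0
  n_cloud <- sum(is_cloud)
  pts <- pts[!is_cloud, , drop = FALSE]

  is_nodata <- !is.finite(pts$tsurf_c) | !is.finite(pts$elev_m) |
    !is.finite(pts$dist_m)
  n_nodata <- sum(is_nodata)
  pts <- pts[!is_nodata, , drop = FALSE]

  too_far <- abs(pts$dist_m) > max_dist
  n_far <- sum(too_far)
  pts <- pts[!too_far, , drop = FALSE]

  pts$cloud <- NULL
  rownames(pts) <- NULL
  attr(pts, "removal") <- c(cloud = n_cloud, nodata = n_nodata,
                            distance = n_far)
  attr(pts, "n_sampled") <- n_draw
  if (!is.null(warn)) attr(pts, "warning") <- warn
  pts
}

#' Restrict points for edge-curve fitting
#'
#' Keeps points with `dist_m` up to 500 m into the forest (inclusive);
#' points outside the forest (negative distances, down to -1000 m) are kept
#' because they anchor the non-forest end of the curve.
#'
#' @param points a sample-point data.frame with a `dist_m` column.
#' @param max_inside inclusive in-forest cutoff in metres; default 500.
#' @return the filtered data.frame.
#' @export
restrict_for_curve <- function(points, max_inside = 500) {
  points[points$dist_m <= max_inside, , drop = FALSE]
}
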