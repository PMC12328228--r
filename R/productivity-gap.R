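# Comparison of observed surface temperature to the thermal optimum for
# ecosystem productivity (T_opt), by distance from the forest edge.

#' Attach thermal-optimum values to sample points
#'
#' Each point receives the value of the coarse T_opt cell containing it.
#' Cells are half-open: a point sitting exactly on a shared vertical boundary
#' belongs to the cell to its east, on a horizontal boundary to the cell to
#' its south. Points falling on cells with undefined (NA) T_opt, or outside
#' the grid, are dropped and counted.
#'
#' @param points sample-point data.frame with `x`, `y`.
#' @param grid coarse [raster_grid()] of T_opt (degC).
#' @return the points with `topt_c` filled; attribute `dropped` holds the
#'   count of points without a defined cell.
#' @export
attach_topt <- function(points, grid) {
  stopifnot(inherits(grid, "raster_grid"))
  cs <- grid$pixel_size
  col <- floor((points$x - grid$origin[1]) / cs) + 1
  row <- floor((grid$origin[2] - points$y) / cs) + 1
  inside <- col >= 1 & col <= ncol(grid$values) &
    row >= 1 & row <= nrow(grid$values)
  val <- rep(NA_real_, nrow(points))
  val[inside] <- grid$values[cbind(row[inside], col[inside])]
  ok <- is.finite(val)
  if (!any(ok)) stop_invalid("T_opt grid does not cover any point")
  out <- points[ok, , drop = FALSE]
  out$topt_c <- val[ok]
  rownames(out) <- NULL
  attr(out, "dropped") <- sum(!ok)
  out
}

#' Scene eligibility filter for the productivity-gap analysis
#'
#' Operates on in-forest points (distance in (0, `max_dist`]); points outside
#' the forest are excluded first. A scene is retained iff it has at least
#' `min_obs` in-forest observations, from at least `min_overpasses` distinct
#' overpasses, with at least one observation `min_far` metres or further into
#' the forest (all thresholds inclusive). Adding points can never flip a
#' scene from eligible to ineligible.
#'
#' @param points sample-point table.
#' @param min_obs minimum in-forest observations per scene (default 500).
#' @param min_overpasses minimum distinct overpasses (default 2).
#' @param min_far inclusive depth requirement in metres (default 800).
#' @param max_dist in-forest upper limit (default 1000).
#' @return list with `points` (in-forest points of eligible scenes) and
#'   `log` (per-scene eligibility record naming the failed criterion).
#' @export
filter_eligible_scenes <- function(points, min_obs = 500, min_overpasses = 2,
                                   min_far = 800, max_dist = 1000) {
  inf <- points[points$dist_m > 0 & points$dist_m <= max_dist, , drop = FALSE]
  recs <- lapply(split(seq_len(nrow(inf)), inf$scene_id), function(ii) {
    sub <- inf[ii, , drop = FALSE]
    n <- nrow(sub)
    nov <- length(unique(sub$overpass_id))
    far <- max(sub$dist_m)
    fails <- c(
      if (n < min_obs) sprintf("fewer than %d observations", min_obs),
      if (nov < min_overpasses) sprintf("fewer than %d overpasses", min_overpasses),
      if (far < min_far) sprintf("no observation at >= %d m", min_far)
    )
    data.frame(scene_id = sub$scene_id[1], n_obs = n, n_overpasses = nov,
               max_dist_m = far, eligible = length(fails) == 0,
               reason = if (length(fails)) paste(fails, collapse = "; ")
               else NA_character_)
  })
  log <- do.call(rbind, recs)
  rownames(log) <- NULL
  keep <- log$scene_id[log$eligible]
  list(points = inf[inf$scene_id %in% keep, , drop = FALSE], log = log)
}

#' Fit the productivity temperature-gap curve
#'
#' Reuses the edge-curve additive model with response `T_surf - T_opt` on
#' in-forest points, predicts the gap for every metre from 0 to 500 with
#' elevation at its mean and the scene effect at the most frequent unit, and
#' reports the edge-interior contrast at (30 m, 500 m) plus the wider
#' (50 m, 1000 m) variant on the gap scale.
#'
#' @param points eligible in-forest points carrying `topt_c`.
#' @param d_grid prediction grid (default every metre 0..500).
#' @param se_rule SE convention passed to [edge_interior_contrast()].
#' @param ... further arguments to [fit_edge_curve()].
#' @return object of class `gap_curve`: `curve` (data.frame `dist_m`, `gap`,
#'   `se`), `contrast`, `variant`, and the underlying `model`.
#' @export
fit_gap_curve <- function(points, d_grid = seq(0, 500, by = 1),
                          se_rule = c("as-printed", "quadrature"), ...) {
  se_rule <- match.arg(se_rule)
  if (any(!is.finite(points$topt_c)))
    stop_invalid("all points must carry a finite topt_c")
  if (any(points$dist_m <= 0))
    stop_invalid("gap curves are defined inside the forest only (dist_m > 0)")
  pts <- points
  pts$gap_c <- pts$tsurf_c - pts$topt_c
  model <- fit_edge_curve(pts, response = "gap_c", dist_range = c(0, 1000),
                          ...)
  pr <- predict_partial(model, d_grid)
  structure(
    list(curve = data.frame(dist_m = pr$dist_m, gap = pr$fit, se = pr$se),
         contrast = edge_interior_contrast(model, 30, 500, se_rule),
         variant = edge_interior_contrast(model, 50, 1000, se_rule),
         model = model),
    class = "gap_curve")
}

#' @export
print.gap_curve <- function(x, ...) {
  g <- x$curve
  cat(sprintf("gap_curve: gap(30 m) = %.2f, gap(500 m) = %.2f degC\n",
              g$gap[g$dist_m == 30], g$gap[g$dist_m == 500]))
  cat(sprintf("  contrast(30, 500) = %.3f degC (SE %.3f)\n",
              x$contrast$delta_c, x$contrast$se_delta))
  invisible(x)
}

#' Synthetic coarse thermal-optimum grid for a generated study
#'
#' Emulates a coarse-resolution productivity-optimum map over the tiled
#' synthetic scenes. In `"uniform"` mode every cell holds `value`. In
#' `"offset-from-interior"` mode, cells covering a scene hold that scene's
#' deep-interior noise-free temperature (`T_macro - A`) plus `offset`, so the
#' deep-interior gap is `-offset` by construction: `offset = 0` emulates a
#' boreal-like scene whose interior sits at the optimum, `offset = -2` a
#' tropics-like scene running 2 degC above it. Cells between scene tiles are
#' undefined.
#'
#' @param study a [generate_study()] result.
#' @param mode `"uniform"` or `"offset-from-interior"`.
#' @param value uniform-mode T_opt (degC).
#' @param offset offset-from-interior-mode shift (degC).
#' @param cell_size coarse cell edge (m); default 960 (32 Landsat pixels).
#' @return a [raster_grid()] of T_opt.
#' @export
synthetic_topt <- function(study, mode = c("uniform", "offset-from-interior"),
                           value = 25, offset = 0, cell_size = 960) {
  mode <- match.arg(mode)
  cfg <- study$config
  extent <- cfg$grid_size * cfg$pixel_size
  tr <- study$truths[!duplicated(study$truths$scene_id), , drop = FALSE]
  x_max <- max(tr$x_offset) + extent
  ncols <- ceiling(x_max / cell_size)
  nrows <- ceiling(extent / cell_size)
  vals <- matrix(NA_real_, nrows, ncols)
  if (mode == "uniform") {
    vals[] <- value
  } else {
    cx <- (seq_len(ncols) - 0.5) * cell_size
    for (s in seq_len(nrow(tr))) {
      in_scene <- cx >= tr$x_offset[s] & cx < tr$x_offset[s] + extent
      vals[, in_scene] <- (tr$T_macro[s] - tr$A[s]) + offset
    }
  }
  raster_grid(vals, origin = c(0, nrows * cell_size), pixel_size = cell_size)
}
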