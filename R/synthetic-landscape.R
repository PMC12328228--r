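#' Ground-truth edge-effect parameters for one scene
#'
#' The noise-free surface temperature at signed distance `d` from the forest
#' edge is `T(d) = T_macro - A * S(d)` with the logistic edge profile
#' `S(d) = 1 / (1 + exp(-d / lam))`: far outside the forest the field sits at
#' the scene baseline `T_macro`, deep inside it at `T_macro - A`. `A` is the
#' edge amplitude (non-forest minus deep interior, degC); negative `A`
#' encodes a winter reversal where the forest interior is the warmer side.
#'
#' @param T_macro scene baseline temperature (degC).
#' @param A edge amplitude (degC); may be negative.
#' @param lam sigmoid length scale (m); > 0. With `lam = 90` the profile has
#'   saturated (>99 percent) by about 500 m, matching the flattening of
#'   observed edge curves.
#' @param lapse elevation lapse rate (degC per m), applied relative to the
#'   scene-mean elevation.
#' @param sigma_noise per-point noise SD (degC); >= 0.
#' @param sigma_scene SD of additive per scene-by-overpass offsets (degC).
#' @param a0,a1,a2 coefficients of the macroclimate link
#'   `A = a0 + a1 * T_macro + a2 * T_macro^2` used by the default truth
#'   sampler; recorded so recovery tests can target them.
#' @return an object of class `edge_effect_truth`.
#' @export
edge_effect_truth <- function(T_macro, A, lam = 90, lapse = -0.0065,
                              sigma_noise = 1.5, sigma_scene = 2,
                              a0 = NA_real_, a1 = NA_real_, a2 = NA_real_) {
  if (!is.finite(lam) || lam <= 0) stop_invalid("lam must be > 0")
  if (!is.finite(sigma_noise) || sigma_noise < 0)
    stop_invalid("sigma_noise must be >= 0")
  if (!is.finite(sigma_scene) || sigma_scene < 0)
    stop_invalid("sigma_scene must be >= 0")
  if (!is.finite(T_macro) || !is.finite(A))
    stop_invalid("T_macro and A must be finite")
  structure(
    list(T_macro = T_macro, A = A, lam = lam, lapse = lapse,
         sigma_noise = sigma_noise, sigma_scene = sigma_scene,
         a0 = a0, a1 = a1, a2 = a2),
    class = "edge_effect_truth"
  )
}

#' Logistic edge profile
#'
#' @param d signed distance from the edge (m; positive inside the forest).
#' @param lam length scale (m).
#' @return `1 / (1 + exp(-d / lam))`.
#' @export
edge_sigmoid <- function(d, lam) 1 / (1 + exp(-d / lam))

#' Noise-free ground-truth temperature at a signed distance
#'
#' @param d signed distance (m).
#' @param truth an [edge_effect_truth()].
#' @param sxo_offset additive scene-by-overpass offset (degC).
#' @return temperature in degC.
#' @export
true_edge_temperature <- function(d, truth, sxo_offset = 0) {
  truth$T_macro - truth$A * edge_sigmoid(d, truth$lam) + sxo_offset
}

#' Study configuration
#'
#' Bundles the sampling design of a synthetic study. The defaults are the
#' study conditions the analysis targets: 30 m pixels, 1000 random points per
#' scene-by-overpass, forest at >= 30 percent canopy cover, retention within
#' 1000 m of the edge.
#'
#' @param n_scenes number of scenes.
#' @param n_overpasses overpasses per scene.
#' @param grid_size pixels per raster side.
#' @param pixel_size pixel edge (m).
#' @param n_points_per_sxo random points per scene-by-overpass.
#' @param canopy_threshold forest classification threshold (percent).
#' @param max_edge_distance retention limit on |distance| (m).
#' @param cloud_fraction share of pixels occluded by cloud, in [0, 1).
#' @param seed root integer seed; every stream below derives from it.
#' @param n_patches forest patches per scene.
#' @param patch_scale typical patch radius (m).
#' @param lat_range scene latitude band (degrees); biome labels derive from
#'   |latitude|: tropical <= 23.5, temperate <= 50, boreal beyond.
#' @param biome_bands upper |latitude| limits of the tropical and temperate
#'   bands, named numeric of length 2.
#' @param truth list of generator truth parameters: `a0`, `a1`, `a2`
#'   (macroclimate link for the edge amplitude), `lam`, `lapse`,
#'   `sigma_noise`, `sigma_scene`, `t_lat_intercept`, `t_lat_slope`,
#'   `t_noise_sd` (scene baseline `T_macro = t_lat_intercept +
#'   t_lat_slope * |lat| + noise`).
#' @param winter_reversal if `TRUE`, boreal winter overpasses have their edge
#'   amplitude shifted by `-winter_shift`, flipping the edge effect sign.
#' @param winter_shift amplitude shift (degC) for the winter reversal.
#' @return an object of class `study_config`.
#' @export
study_config <- function(n_scenes = 12, n_overpasses = 2, grid_size = 64,
                         pixel_size = 30, n_points_per_sxo = 1000,
                         canopy_threshold = 30, max_edge_distance = 1000,
                         cloud_fraction = 0.1, seed = 1L, n_patches = 4,
                         patch_scale = 500, lat_range = c(-65, 65),
                         biome_bands = c(tropical = 23.5, temperate = 50),
                         truth = list(), winter_reversal = FALSE,
                         winter_shift = 3) {
  counts <- c(n_scenes = n_scenes, n_overpasses = n_overpasses,
              grid_size = grid_size, n_points_per_sxo = n_points_per_sxo)
  if (any(counts < 1))
    stop_invalid("counts must be >= 1 (%s)",
                 paste(names(counts)[counts < 1], collapse = ", "))
  if (grid_size < 16) stop_invalid("grid_size must be >= 16")
  if (cloud_fraction < 0 || cloud_fraction >= 1)
    stop_invalid("cloud_fraction must lie in [0, 1)")
  tr_default <- list(a0 = 0.4, a1 = -0.05, a2 = 0.004, lam = 90,
                     lapse = -0.0065, sigma_noise = 1.5, sigma_scene = 2,
                     t_lat_intercept = 28, t_lat_slope = -0.35,
                     t_noise_sd = 2)
  unknown <- setdiff(names(truth), names(tr_default))
  if (length(unknown))
    stop_invalid("unknown truth parameter(s): %s", paste(unknown, collapse = ", "))
  tr <- utils::modifyList(tr_default, truth)
  structure(
    list(n_scenes = as.integer(n_scenes), n_overpasses = as.integer(n_overpasses),
         grid_size = as.integer(grid_size), pixel_size = pixel_size,
         n_points_per_sxo = as.integer(n_points_per_sxo),
         canopy_threshold = canopy_threshold,
         max_edge_distance = max_edge_distance,
         cloud_fraction = cloud_fraction, seed = as.integer(seed),
         n_patches = as.integer(n_patches), patch_scale = patch_scale,
         lat_range = lat_range, biome_bands = biome_bands, truth = tr,
         winter_reversal = isTRUE(winter_reversal), winter_shift = winter_shift),
    class = "study_config"
  )
}

#' Rasterize a union of disks by pixel-centre inclusion
#'
#' A pixel belongs to a disk when its centre lies inside or on the circle.
#'
#' @param grid_size pixels per side.
#' @param centers two-column matrix of disk centres (m).
#' @param radii disk radii (m), recycled against rows of `centers`.
#' @param pixel_size pixel edge (m).
#' @return logical matrix, `TRUE` inside the union.
#' @export
rasterize_disks <- function(grid_size, centers, radii, pixel_size = 30) {
  centers <- matrix(centers, ncol = 2)
  radii <- rep_len(radii, nrow(centers))
  cx <- (seq_len(grid_size) - 0.5) * pixel_size
  cy <- (grid_size - seq_len(grid_size) + 0.5) * pixel_size # row 1 is north
  inside <- matrix(FALSE, grid_size, grid_size)
  for (p in seq_len(nrow(centers))) {
    dx2 <- outer(rep(1, grid_size), (cx - centers[p, 1])^2)
    dy2 <- outer((cy - centers[p, 2])^2, rep(1, grid_size))
    inside <- inside | (dx2 + dy2 <= radii[p]^2)
  }
  inside
}

#' Generate a fragmented forest canopy raster
#'
#' Forest patches are a union of random disks; canopy cover is drawn high
#' (around 85 percent) inside patches and low (around 5 percent) outside, so
#' the 30 percent classification threshold reproduces the patch geometry.
#' With `n_patches >= 1` the generator guarantees both classes are present,
#' shrinking patch radii over derived seeds in the rare event a draw covers
#' the whole grid.
#'
#' @param grid_size pixels per side; >= 16.
#' @param n_patches number of patches (0 gives a pure non-forest scene).
#' @param patch_scale typical patch radius (m).
#' @param seed integer seed.
#' @param pixel_size pixel edge (m).
#' @return [raster_grid()] of canopy cover percent.
#' @export
generate_forest_mask <- function(grid_size, n_patches = 6, patch_scale = 300,
                                 seed = 1L, pixel_size = 30) {
  if (!is.finite(grid_size) || grid_size < 16)
    stop_invalid("grid_size must be >= 16")
  if (n_patches < 0) stop_invalid("n_patches must be >= 0")
  extent <- grid_size * pixel_size
  npix <- grid_size * grid_size

  inside <- matrix(FALSE, grid_size, grid_size)
  if (n_patches >= 1) {
    for (attempt in 1:25) {
      shrink <- 0.8^(attempt - 1)
      geom <- with_seed_(mix_seed(seed, attempt, 11), {
        list(
          centers = cbind(stats::runif(n_patches, 0, extent),
                          stats::runif(n_patches, 0, extent)),
          radii = pmax(pixel_size,
                       shrink * patch_scale *
                         stats::rlnorm(n_patches, 0, 0.35))
        )
      })
      inside <- rasterize_disks(grid_size, geom$centers, geom$radii,
                                pixel_size)
      nf <- sum(inside)
      if (nf > 0 && nf < npix) break
    }
    if (sum(inside) == 0 || sum(inside) == npix)
      stop_invalid("could not place patches yielding both classes")
  }

  canopy <- with_seed_(mix_seed(seed, 0, 12), {
    v <- matrix(pmin(100, pmax(0, stats::rnorm(npix, 5, 4))),
                grid_size, grid_size)
    v[inside] <- pmin(100, pmax(0, stats::rnorm(sum(inside), 85, 8)))
    v
  })
  raster_grid(canopy, origin = c(0, extent), pixel_size = pixel_size)
}

#' Generate a smooth synthetic elevation field
#'
#' A low-frequency random field: a baseline plus a few cosine plane waves
#' with wavelengths of the order of the grid extent, so elevation varies
#' smoothly and is separable from the edge signal by construction.
#'
#' @param grid_size pixels per side.
#' @param seed integer seed.
#' @param pixel_size pixel edge (m).
#' @param base mean elevation (m).
#' @param amplitude total relief scale (m).
#' @param n_waves number of cosine components.
#' @return [raster_grid()] of elevation in metres.
#' @export
generate_elevation <- function(grid_size, seed = 1L, pixel_size = 30,
                               base = 300, amplitude = 120, n_waves = 4) {
  extent <- grid_size * pixel_size
  cx <- (seq_len(grid_size) - 0.5) * pixel_size
  cy <- (grid_size - seq_len(grid_size) + 0.5) * pixel_size
  X <- outer(rep(1, grid_size), cx)
  Y <- outer(cy, rep(1, grid_size))
  with_seed_(mix_seed(seed, 0, 13), {
    z <- matrix(0, grid_size, grid_size)
    for (w in seq_len(n_waves)) {
      theta <- stats::runif(1, 0, pi)
      wavelength <- stats::runif(1, 0.5, 2) * extent
      phase <- stats::runif(1, 0, 2 * pi)
      amp <- amplitude / n_waves * stats::runif(1, 0.5, 1.5)
      z <- z + amp * cos(2 * pi * (X * cos(theta) + Y * sin(theta)) /
                           wavelength + phase)
    }
    raster_grid(base + z, origin = c(0, extent), pixel_size = pixel_size)
  })
}

#' Generate the observed fields of one scene-by-overpass
#'
#' The noise-free temperature at every pixel is
#' `T_macro - A * S(d) + lapse * (elev - mean(elev)) + sxo_offset`, to which
#' i.i.d. Gaussian noise with SD `sigma_noise` is added; a cloud raster marks
#' a `cloud_fraction` share of pixels as occluded.
#'
#' @param mask binary forest mask ([classify_forest()] output); must contain
#'   both classes.
#' @param truth an [edge_effect_truth()].
#' @param seed integer seed for noise and cloud placement.
#' @param elev optional elevation [raster_grid()]; generated when `NULL`.
#' @param cloud_fraction share of cloud-occluded pixels.
#' @param sxo_offset additive scene-by-overpass offset (degC).
#' @param dist optional precomputed signed-distance raster.
#' @return list of [raster_grid()]s: `tsurf`, `elev`, `cloud`, `dist`.
#' @export
generate_scene_fields <- function(mask, truth, seed = 1L, elev = NULL,
                                  cloud_fraction = 0, sxo_offset = 0,
                                  dist = NULL) {
  stopifnot(inherits(mask, "raster_grid"), inherits(truth, "edge_effect_truth"))
  if (is.null(dist)) dist <- signed_distance_to_edge(mask)
  gs <- nrow(mask$values)
  if (is.null(elev))
    elev <- generate_elevation(gs, seed = seed, pixel_size = mask$pixel_size)
  npix <- length(mask$values)
  base <- true_edge_temperature(dist$values, truth, sxo_offset) +
    truth$lapse * (elev$values - mean(elev$values))
  tsurf <- with_seed_(mix_seed(seed, 0, 14), {
    base + stats::rnorm(npix, 0, truth$sigma_noise)
  })
  cloud <- with_seed_(mix_seed(seed, 0, 15), {
    matrix(as.numeric(stats::runif(npix) < cloud_fraction), gs, gs)
  })
  mk <- function(v) raster_grid(v, origin = mask$origin,
                                pixel_size = mask$pixel_size)
  list(tsurf = mk(tsurf), elev = elev, cloud = mk(cloud), dist = dist)
}

#' Default macroclimate-linked truth sampler
#'
#' Scene baselines follow latitude (`T_macro = t_lat_intercept +
#' t_lat_slope * |lat| + noise`) and the edge amplitude follows the quadratic
#' macroclimate link `A = a0 + a1 * T_macro + a2 * T_macro^2`, so warmer
#' scenes carry stronger edge cooling — the structure the meta-regression is
#' designed to recover.
#'
#' @param config a [study_config()]; the link coefficients and noise scales
#'   come from `config$truth`.
#' @return function of `(scene_index, lat)` returning an
#'   [edge_effect_truth()].
#' @export
make_truth_sampler <- function(config) {
  tr <- config$truth
  seed <- config$seed
  function(scene_index, lat) {
    T_macro <- with_seed_(mix_seed(seed, scene_index, 21), {
      tr$t_lat_intercept + tr$t_lat_slope * abs(lat) +
        stats::rnorm(1, 0, tr$t_noise_sd)
    })
    A <- tr$a0 + tr$a1 * T_macro + tr$a2 * T_macro^2
    edge_effect_truth(T_macro = T_macro, A = A, lam = tr$lam,
                      lapse = tr$lapse, sigma_noise = tr$sigma_noise,
                      sigma_scene = tr$sigma_scene,
                      a0 = tr$a0, a1 = tr$a1, a2 = tr$a2)
  }
}

season_label <- function(month, lat) {
  north <- c("winter", "winter", "spring", "spring", "spring", "summer",
             "summer", "summer", "autumn", "autumn", "autumn", "winter")
  flip <- c(winter = "summer", spring = "autumn", summer = "winter",
            autumn = "spring")
  s <- north[month]
  if (lat < 0) s <- unname(flip[s])
  s
}

biome_label <- function(lat, bands = c(tropical = 23.5, temperate = 50)) {
  a <- abs(lat)
  if (a <= bands[["tropical"]]) "tropical"
  else if (a <= bands[["temperate"]]) "temperate"
  else "boreal"
}

#' Generate a complete synthetic study
#'
#' Lays out `n_scenes` independent fragmented landscapes (each scene offset
#' along x so coordinates are globally unique), generates `n_overpasses`
#' observed temperature fields per scene with per scene-by-overpass additive
#' offsets, samples points, and applies the cloud / nodata / distance
#' filters. All randomness derives from `config$seed` via per-scene streams,
#' so any scene is independently reproducible.
#'
#' @param config a [study_config()].
#' @param truth_sampler optional function `(scene_index, lat) ->`
#'   [edge_effect_truth()]; defaults to [make_truth_sampler()].
#' @return list with:
#'   * `points`: data.frame (`scene_id`, `overpass_id`, `x`, `y`, `dist_m`,
#'     `tsurf_c`, `elev_m`, `season`, `biome`, `topt_c`);
#'   * `truths`: per scene-by-overpass ground-truth record (baseline,
#'     effective amplitude, offset, latitude, labels);
#'   * `removal`: per scene-by-overpass filter-removal counts, which sum
#'     exactly to sampled minus emitted;
#'   * `config`: the configuration used.
#' @export
generate_study <- function(config, truth_sampler = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (is.null(truth_sampler)) truth_sampler <- make_truth_sampler(config)
  extent <- config$grid_size * config$pixel_size
  gap <- 3000 # metres of empty space between scene tiles
  # overpass months spread evenly around the year (n = 2 gives Jan + Jul, so
  # both solstitial seasons appear; n > 12 cycles)
  months <- if (config$n_overpasses <= 12)
    round(seq(1, 12, length.out = config$n_overpasses + 1L))[-(config$n_overpasses + 1L)]
  else (seq_len(config$n_overpasses) - 1L) %% 12L + 1L

  pts_list <- list()
  truth_rows <- list()
  removal_rows <- list()
  for (i in seq_len(config$n_scenes)) {
    lat <- with_seed_(mix_seed(config$seed, i, 1),
                      stats::runif(1, config$lat_range[1], config$lat_range[2]))
    biome <- biome_label(lat, config$biome_bands)
    truth <- truth_sampler(i, lat)
    if (!inherits(truth, "edge_effect_truth"))
      stop_invalid("truth_sampler must return an edge_effect_truth")
    canopy <- generate_forest_mask(config$grid_size, config$n_patches,
                                   config$patch_scale,
                                   seed = mix_seed(config$seed, i, 2),
                                   pixel_size = config$pixel_size)
    mask <- classify_forest(canopy, config$canopy_threshold)
    dist <- signed_distance_to_edge(mask)
    elev <- generate_elevation(config$grid_size,
                               seed = mix_seed(config$seed, i, 3),
                               pixel_size = config$pixel_size)
    x_off <- (i - 1) * (extent + gap)
    scene_id <- sprintf("S%04d", i)

    for (o in seq_len(config$n_overpasses)) {
      month <- months[o]
      season <- season_label(month, lat)
      A_eff <- truth$A
      if (config$winter_reversal && biome == "boreal" && season == "winter")
        A_eff <- A_eff - config$winter_shift
      truth_o <- truth
      truth_o$A <- A_eff
      offset <- with_seed_(mix_seed(config$seed, i, 100 + o),
                           stats::rnorm(1, 0, truth$sigma_scene))
      fields <- generate_scene_fields(mask, truth_o,
                                      seed = mix_seed(config$seed, i, 200 + o),
                                      elev = elev,
                                      cloud_fraction = config$cloud_fraction,
                                      sxo_offset = offset, dist = dist)
      pts <- sample_scene_points(fields, mask, n = config$n_points_per_sxo,
                                 seed = mix_seed(config$seed, i, 300 + o),
                                 max_dist = config$max_edge_distance,
                                 dist = dist)
      rem <- attr(pts, "removal")
      n_sampled <- attr(pts, "n_sampled") %||% config$n_points_per_sxo
      overpass_id <- sprintf("O%02d", o)
      if (nrow(pts)) {
        pts$x <- pts$x + x_off
        pts <- data.frame(scene_id = scene_id, overpass_id = overpass_id,
                          pts, season = season, biome = biome,
                          topt_c = NA_real_)
        pts_list[[length(pts_list) + 1L]] <- pts
      }
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        scene_id = scene_id, overpass_id = overpass_id, lat = lat,
        biome = biome, season = season, T_macro = truth$T_macro,
        A = truth$A, A_eff = A_eff, lam = truth$lam, lapse = truth$lapse,
        sigma_noise = truth$sigma_noise, sigma_scene = truth$sigma_scene,
        sxo_offset = offset, x_offset = x_off,
        a0 = truth$a0, a1 = truth$a1, a2 = truth$a2
      )
      removal_rows[[length(removal_rows) + 1L]] <- data.frame(
        scene_id = scene_id, overpass_id = overpass_id,
        n_sampled = n_sampled,
        cloud = rem[["cloud"]], nodata = rem[["nodata"]],
        distance = rem[["distance"]], emitted = nrow(pts)
      )
    }
  }
  points <- if (length(pts_list)) do.call(rbind, pts_list) else
    data.frame(scene_id = character(), overpass_id = character(),
               x = numeric(), y = numeric(), dist_m = numeric(),
               tsurf_c = numeric(), elev_m = numeric(), season = character(),
               biome = character(), topt_c = numeric())
  rownames(points) <- NULL
  list(points = points,
       truths = do.call(rbind, truth_rows),
       removal = do.call(rbind, removal_rows),
       config = config)
}
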