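# Per scene-by-overpass edge-effect slopes and the inverse-variance weighted
# quadratic meta-regression of slope against scene macroclimate.
#
# Sign convention: distance increases into the forest, so a scene whose
# interior is cooler than its edge has a NEGATIVE slope of temperature on
# log10(distance). Where "edge-effect strength" is meant, the negated slope
# (-beta) is used, so stronger interior cooling is a larger strength.

#' Per scene-by-overpass temperature slope on log-distance
#'
#' Ordinary least squares of temperature on `log10(dist_m)` and elevation
#' over the in-forest points (0 < dist <= 1000 m) of one scene-by-overpass.
#' The log-distance coefficient is the scene's edge-effect statistic
#' `dT/dD` (degC per log10 m). Units of at least 4 observations are required;
#' a singular distance term yields a rejection record rather than an error.
#' An aliased (constant) elevation column is dropped and the fit proceeds.
#'
#' @param points in-forest points of a single scene-by-overpass (`dist_m` in
#'   (0, 1000]).
#' @param scene_mean_t arithmetic mean temperature of *all* points sampled in
#'   the scene-by-overpass (inside and outside the forest); carried through
#'   as the macroclimate covariate.
#' @return list of class `scene_slope`: `beta`, `var_beta` (floored at
#'   machine epsilon so weights stay finite), `n_obs`, `scene_mean_t`,
#'   `kept` (logical), `reject_reason` (`NA` when kept).
#' @export
scene_slope <- function(points, scene_mean_t = mean(points$tsurf_c)) {
  n <- nrow(points)
  rej <- function(reason) structure(
    list(beta = NA_real_, var_beta = NA_real_, n_obs = n,
         scene_mean_t = scene_mean_t, kept = FALSE, reject_reason = reason),
    class = "scene_slope")
  if (n < 4) return(rej("fewer than 4 observations"))
  if (any(points$dist_m <= 0 | points$dist_m > 1000))
    stop_invalid("scene_slope expects in-forest points with 0 < dist_m <= 1000")
  df <- data.frame(t = points$tsurf_c, logd = log10(points$dist_m),
                   elev = points$elev_m)
  fit <- stats::lm(t ~ logd + elev, data = df, singular.ok = TRUE)
  cf <- stats::coef(fit)
  if (is.na(cf[["logd"]])) return(rej("singular design (distance term)"))
  if (fit$df.residual < 1) return(rej("no residual degrees of freedom"))
  vc <- suppressWarnings(stats::vcov(fit)) # exact fits are legitimate here
  var_beta <- max(vc["logd", "logd"], .Machine$double.eps)
  if (!is.finite(var_beta)) return(rej("non-finite slope variance"))
  structure(
    list(beta = unname(cf[["logd"]]), var_beta = var_beta, n_obs = n,
         scene_mean_t = scene_mean_t, kept = TRUE,
         reject_reason = NA_character_),
    class = "scene_slope")
}

#' Compute slopes for every scene-by-overpass in a point table
#'
#' Splits the table by scene-by-overpass, restricts each to its in-forest
#' points up to 1000 m, and fits [scene_slope()]. The macroclimate covariate
#' `scene_mean_t` is the mean temperature over all of the unit's retained
#' points, inside and outside the forest.
#'
#' @param points full sample-point table.
#' @param max_dist in-forest upper limit (m); default 1000.
#' @param pool_overpasses if `TRUE`, overpasses within a scene are pooled
#'   into a single regression per scene (the blocking then is per scene).
#' @return data.frame with one row per unit: `scene_id`, `overpass_id`,
#'   `beta`, `var_beta`, `n_obs`, `scene_mean_t`, `kept`, `reject_reason`.
#' @export
scene_slopes <- function(points, max_dist = 1000, pool_overpasses = FALSE) {
  unit <- if (pool_overpasses) points$scene_id
  else sxo_id(points$scene_id, points$overpass_id)
  rows <- lapply(split(seq_len(nrow(points)), unit), function(ii) {
    sub <- points[ii, , drop = FALSE]
    inf <- sub[sub$dist_m > 0 & sub$dist_m <= max_dist, , drop = FALSE]
    sl <- scene_slope(inf, scene_mean_t = mean(sub$tsurf_c))
    data.frame(scene_id = sub$scene_id[1],
               overpass_id = if (pool_overpasses) "pooled"
               else sub$overpass_id[1],
               beta = sl$beta, var_beta = sl$var_beta, n_obs = sl$n_obs,
               scene_mean_t = sl$scene_mean_t, kept = sl$kept,
               reject_reason = sl$reject_reason)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hampel outlier filter on scene slopes
#'
#' Removes slopes outside `median(beta) +/- 3 * MAD(beta)` in a single pass,
#' with the MAD taken as the unscaled median absolute deviation (no 1.4826
#' factor), the construction the Hampel identifier names. When the MAD
#' degenerates to zero, every slope different from the median is removed and
#' a degenerate-scale warning is recorded.
#'
#' @param slopes data.frame from [scene_slopes()] (only `kept` rows enter);
#'   or any data.frame with a `beta` column.
#' @param n_mad multiplier, default 3.
#' @param mad_type `"median"` (default, median absolute deviation) or
#'   `"mean"` (mean absolute deviation about the median).
#' @return list with `kept` and `removed` data.frames, `median`, `mad`, and
#'   `degenerate` flag.
#' @export
hampel_filter <- function(slopes, n_mad = 3, mad_type = c("median", "mean")) {
  mad_type <- match.arg(mad_type)
  ok <- if ("kept" %in% names(slopes)) slopes$kept & !is.na(slopes$beta)
  else !is.na(slopes$beta)
  s <- slopes[ok, , drop = FALSE]
  if (nrow(s) < 3) stop_invalid("hampel_filter needs at least 3 slopes")
  b <- s$beta
  med <- stats::median(b)
  dev <- abs(b - med)
  scale <- if (mad_type == "median") stats::median(dev) else mean(dev)
  degenerate <- scale == 0
  out <- if (degenerate) b != med else dev > n_mad * scale
  if (degenerate)
    warning("degenerate scale (MAD = 0): removing every slope off the median",
            call. = FALSE)
  list(kept = s[!out, , drop = FALSE], removed = s[out, , drop = FALSE],
       median = med, mad = scale, degenerate = degenerate)
}

#' Inverse-variance weighted quadratic meta-regression
#'
#' Weighted least squares of the per-scene slope on scene macroclimate and
#' its square, each slope weighted by the reciprocal of its sampling
#' variance, as in meta-analysis. SEs come from the weighted
#' normal-equations inverse scaled by the weighted residual variance;
#' the weighted R-squared is `1 - wRSS / wTSS` with the total sum about the
#' weighted mean. Because weights enter as reciprocals of variances,
#' rescaling every variance by a constant leaves the coefficients unchanged.
#'
#' @param slopes data.frame with `beta`, `var_beta`, `scene_mean_t` (kept
#'   slopes).
#' @param response optional replacement response column name (e.g. a
#'   strength scale `-beta`); default `"beta"`.
#' @return object of class `meta_regression_fit`: coefficients `b0`, `b1`,
#'   `b2`, their SEs, `weighted_r2`, `n_scenes`, and the underlying `lm`
#'   fit.
#' @export
ivw_quadratic <- function(slopes, response = "beta") {
  s <- slopes[!is.na(slopes[[response]]) & !is.na(slopes$var_beta), ,
              drop = FALSE]
  if (nrow(s) < 4)
    stop_invalid("ivw_quadratic needs at least 4 scenes, got %d", nrow(s))
  if (any(s$var_beta <= 0)) stop_invalid("all var_beta must be > 0")
  y <- s[[response]]
  t1 <- s$scene_mean_t
  w <- 1 / s$var_beta
  fit <- stats::lm(y ~ t1 + I(t1^2), weights = w)
  cf <- stats::coef(fit)
  se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))
  wmean <- sum(w * y) / sum(w)
  wrss <- sum(w * stats::resid(fit)^2)
  wtss <- sum(w * (y - wmean)^2)
  structure(
    list(b0 = unname(cf[1]), b1 = unname(cf[2]), b2 = unname(cf[3]),
         se_b0 = unname(se[1]), se_b1 = unname(se[2]), se_b2 = unname(se[3]),
         weighted_r2 = 1 - wrss / wtss, n_scenes = nrow(s),
         response = response, lm_fit = fit),
    class = "meta_regression_fit")
}

#' @export
print.meta_regression_fit <- function(x, ...) {
  cat(sprintf(
    "meta_regression_fit (%s ~ T + T^2, IVW, n = %d):\n", x$response,
    x$n_scenes))
  cat(sprintf("  b0 = %.4g (SE %.3g), b1 = %.4g (SE %.3g), b2 = %.4g (SE %.3g)\n",
              x$b0, x$se_b0, x$b1, x$se_b1, x$b2, x$se_b2))
  cat(sprintf("  weighted R2 = %.3f\n", x$weighted_r2))
  invisible(x)
}

#' Cooling-only subset of scene slopes
#'
#' Retains scenes whose slope indicates temperature decreasing toward the
#' forest interior (`beta < 0` under the distance-increases-inward
#' convention). `scene_mean_t` is left untouched — it remains the mean over
#' all sampled points of the unit.
#'
#' @param slopes data.frame from [scene_slopes()].
#' @return the subset data.frame.
#' @export
subset_cooling <- function(slopes) {
  slopes[!is.na(slopes$beta) & slopes$beta < 0, , drop = FALSE]
}

#' Meta-regression without outlier filtering
#'
#' The same inverse-variance weighted quadratic fit applied to the
#' unfiltered slope set, provided as a robustness variant.
#'
#' @inheritParams ivw_quadratic
#' @export
no_outlier_variant <- function(slopes, response = "beta") {
  ok <- if ("kept" %in% names(slopes)) slopes$kept else TRUE
  ivw_quadratic(slopes[ok, , drop = FALSE], response = response)
}
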