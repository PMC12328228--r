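# End-to-end orchestration: synthesize -> sample -> curves -> meta -> gap ->
# report, with a run manifest recording seeds, counts and file digests.
# Stages communicate through CSV files in the output directory, so any stage
# can be re-run individually from its inputs.

pipeline_defaults <- function() {
  list(
    study = lapply(as.list(formals(study_config))[
      setdiff(names(formals(study_config)), c("truth", "biome_bands",
                                              "lat_range"))],
      function(v) if (is.language(v)) eval(v) else v),
    truth = study_config()$truth,
    analysis = list(d_edge = 30, d_interior = 500, variant_edge = 50,
                    variant_interior = 1000, se_rule = "as-printed",
                    morans_points = 2000, group_by = c("biome", "season"),
                    k_dist = 20, k_elev = 10, method = "GCV"),
    topt = list(mode = "offset-from-interior", value = 25, offset = -2,
                cell_size = 960)
  )
}

#' Read a pipeline configuration file
#'
#' YAML with up to four blocks: `study` (arguments of [study_config()]),
#' `truth` (generator truth parameters), `analysis` (contrast distances, SE
#' rule, Moran subset size, grouping, basis dimensions) and `topt`
#' (synthetic optimum grid). Any unknown key is an error — silent
#' misconfiguration is worse than failure.
#'
#' @param path YAML file; `NULL` gives the built-in defaults.
#' @return list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path = NULL) {
  defaults <- pipeline_defaults()
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  bad_top <- setdiff(names(user), names(defaults))
  if (length(bad_top))
    stop_invalid("unknown configuration block(s): %s",
                 paste(bad_top, collapse = ", "))
  for (blk in names(user)) {
    known <- if (blk == "truth")
      names(study_config()$truth)
    else names(defaults[[blk]])
    bad <- setdiff(names(user[[blk]]), known)
    if (length(bad))
      stop_invalid("unknown key(s) in '%s': %s", blk,
                   paste(bad, collapse = ", "))
    defaults[[blk]] <- utils::modifyList(defaults[[blk]], user[[blk]])
  }
  structure(defaults, class = "pipeline_config")
}

as_study_config <- function(pc, seed = NULL) {
  args <- pc$study
  args$truth <- pc$truth
  if (!is.null(seed)) args$seed <- seed
  do.call(study_config, args)
}

write_csv_ <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  path
}

#' Synthesis stage: generate the study and write its point table
#'
#' @param config a `pipeline_config` from [read_pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param seed optional seed overriding the configured one.
#' @return paths of the files written, invisibly.
#' @export
stage_synth <- function(config, out_dir, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- as_study_config(config, seed)
  study <- generate_study(sc)
  write_csv_(study$points, file.path(out_dir, "points.csv"))
  write_csv_(study$truths, file.path(out_dir, "truths.csv"))
  write_csv_(study$removal, file.path(out_dir, "removal.csv"))
  invisible(file.path(out_dir, c("points.csv", "truths.csv", "removal.csv")))
}

read_points_ <- function(out_dir) {
  utils::read.csv(file.path(out_dir, "points.csv"),
                  colClasses = c(scene_id = "character",
                                 overpass_id = "character"))
}

group_split_ <- function(points, group_by) {
  if (!length(group_by)) return(list(all = points))
  key <- interaction(points[group_by], drop = TRUE, sep = ".")
  split(points, key)
}

#' Curve stage: fit edge curves and contrasts per group
#'
#' Fits the 500 m-restricted model (curve + 30/500 contrast) and the full
#' 1000 m model (50/1000 variant) within each biome-by-season group, and
#' runs the Moran's I residual diagnostic on a random subset. Groups with
#' fewer than 2 scene-by-overpass units or 50 points are skipped with a
#' warning record.
#'
#' @inheritParams stage_synth
#' @return invisible list of per-group fits (side effect: `curve.csv`,
#'   `contrasts.csv`, `moran.csv`, `curve_skipped.csv`).
#' @export
stage_curve <- function(config, out_dir, seed = NULL) {
  an <- config$analysis
  pts <- read_points_(out_dir)
  seed <- seed %||% config$study$seed
  groups <- group_split_(pts, an$group_by)
  curve_rows <- list(); contrast_rows <- list(); moran_rows <- list()
  skipped <- list(); fits <- list()
  for (g in names(groups)) {
    sub <- groups[[g]]
    n_sxo <- length(unique(sxo_id(sub$scene_id, sub$overpass_id)))
    if (n_sxo < 2 || nrow(sub) < 50) {
      skipped[[g]] <- data.frame(group = g, n = nrow(sub), n_sxo = n_sxo,
                                 reason = "fewer than 2 units or 50 points")
      warning(sprintf("group %s skipped: %d points, %d units", g,
                      nrow(sub), n_sxo), call. = FALSE)
      next
    }
    restricted <- restrict_for_curve(sub, an$d_interior)
    m_restricted <- fit_edge_curve(restricted, k_dist = an$k_dist,
                                   k_elev = an$k_elev, method = an$method)
    m_full <- fit_edge_curve(sub, k_dist = an$k_dist, k_elev = an$k_elev,
                             method = an$method)
    pr <- predict_partial(m_restricted)
    curve_rows[[g]] <- data.frame(group = g, pr)
    main <- edge_interior_contrast(m_restricted, an$d_edge, an$d_interior,
                                   an$se_rule)
    var <- edge_interior_contrast(m_full, an$variant_edge,
                                  an$variant_interior, an$se_rule)
    contrast_rows[[g]] <- data.frame(
      group = g,
      comparison = c(sprintf("%g_vs_%g", an$d_edge, an$d_interior),
                     sprintf("%g_vs_%g", an$variant_edge, an$variant_interior)),
      delta_c = c(main$delta_c, var$delta_c),
      se_delta = c(main$se_delta, var$se_delta),
      se_as_printed = c(main$se_as_printed, var$se_as_printed),
      se_quadrature = c(main$se_quadrature, var$se_quadrature),
      se_rule = an$se_rule)
    mi <- morans_i(m_restricted$residuals,
                   m_restricted$coords, max_points = an$morans_points,
                   seed = mix_seed(seed, 1, 41))
    moran_rows[[g]] <- data.frame(group = g, I = mi$I,
                                  expected_I = mi$expected_I, p = mi$p,
                                  n = mi$n, flag = mi$flag)
    fits[[g]] <- list(restricted = m_restricted, full = m_full)
  }
  write_csv_(do.call(rbind, curve_rows), file.path(out_dir, "curve.csv"))
  write_csv_(do.call(rbind, contrast_rows),
             file.path(out_dir, "contrasts.csv"))
  write_csv_(do.call(rbind, moran_rows), file.path(out_dir, "moran.csv"))
  write_csv_(if (length(skipped)) do.call(rbind, skipped) else
    data.frame(group = character(), n = integer(), n_sxo = integer(),
               reason = character()),
    file.path(out_dir, "curve_skipped.csv"))
  invisible(fits)
}

#' Meta-regression stage: per-unit slopes and the macroclimate fit
#'
#' Computes the per scene-by-overpass slope table, applies the Hampel
#' filter, and fits the inverse-variance weighted quadratic meta-regression
#' on both the raw slope scale (`beta`) and the edge-effect strength scale
#' (`-beta`), for the filtered set, the cooling-only subset, and the
#' unfiltered robustness variant.
#'
#' @inheritParams stage_synth
#' @return invisible list of fits (side effect: `slopes.csv`, `meta.csv`).
#' @export
stage_meta <- function(config, out_dir, seed = NULL) {
  pts <- read_points_(out_dir)
  slopes <- scene_slopes(pts, max_dist = config$study$max_edge_distance)
  hf <- hampel_filter(slopes)
  slopes$hampel_kept <- FALSE
  key <- sxo_id(slopes$scene_id, slopes$overpass_id)
  kept_key <- sxo_id(hf$kept$scene_id, hf$kept$overpass_id)
  slopes$hampel_kept <- key %in% kept_key
  write_csv_(slopes, file.path(out_dir, "slopes.csv"))

  with_strength <- function(s) { s$strength <- -s$beta; s }
  variants <- list(
    filtered = with_strength(hf$kept),
    cooling = with_strength(subset_cooling(hf$kept)),
    no_filter = with_strength(slopes[slopes$kept, , drop = FALSE])
  )
  rows <- list(); fits <- list()
  for (v in names(variants)) {
    for (scale in c("beta", "strength")) {
      fit <- tryCatch(ivw_quadratic(variants[[v]], response = scale),
                      error = function(e) NULL)
      if (is.null(fit)) next
      rows[[paste(v, scale)]] <- data.frame(
        variant = v, scale = scale, b0 = fit$b0, b1 = fit$b1, b2 = fit$b2,
        se_b0 = fit$se_b0, se_b1 = fit$se_b1, se_b2 = fit$se_b2,
        weighted_r2 = fit$weighted_r2, n_scenes = fit$n_scenes)
      fits[[paste(v, scale)]] <- fit
    }
  }
  write_csv_(do.call(rbind, rows), file.path(out_dir, "meta.csv"))
  invisible(fits)
}

#' Gap stage: thermal-optimum comparison
#'
#' Builds the synthetic coarse T_opt grid, attaches it to the points,
#' applies the scene eligibility filter, and fits the gap curve per biome.
#'
#' @inheritParams stage_synth
#' @return invisible list of per-biome gap fits (side effect:
#'   `gap_curve.csv`, `gap_contrasts.csv`, `gap_eligibility.csv`).
#' @export
stage_gap <- function(config, out_dir, seed = NULL) {
  pts <- read_points_(out_dir)
  truths <- utils::read.csv(file.path(out_dir, "truths.csv"),
                            colClasses = c(scene_id = "character",
                                           overpass_id = "character"))
  sc <- as_study_config(config, seed)
  study <- list(points = pts, truths = truths, config = sc)
  tg <- synthetic_topt(study, mode = config$topt$mode,
                       value = config$topt$value,
                       offset = config$topt$offset,
                       cell_size = config$topt$cell_size)
  pts <- attach_topt(pts, tg)
  el <- filter_eligible_scenes(pts)
  write_csv_(el$log, file.path(out_dir, "gap_eligibility.csv"))
  an <- config$analysis
  curve_rows <- list(); contrast_rows <- list(); fits <- list()
  for (b in unique(el$points$biome)) {
    sub <- el$points[el$points$biome == b, , drop = FALSE]
    n_sxo <- length(unique(sxo_id(sub$scene_id, sub$overpass_id)))
    if (n_sxo < 2 || nrow(sub) < 50) next
    gc <- fit_gap_curve(sub, se_rule = an$se_rule, k_dist = an$k_dist,
                        k_elev = an$k_elev, method = an$method)
    curve_rows[[b]] <- data.frame(biome = b, gc$curve)
    contrast_rows[[b]] <- data.frame(
      biome = b, comparison = c("30_vs_500", "50_vs_1000"),
      delta_c = c(gc$contrast$delta_c, gc$variant$delta_c),
      se_delta = c(gc$contrast$se_delta, gc$variant$se_delta),
      gap_edge = c(gc$contrast$fit_edge, gc$variant$fit_edge),
      gap_interior = c(gc$contrast$fit_interior, gc$variant$fit_interior))
    fits[[b]] <- gc
  }
  write_csv_(if (length(curve_rows)) do.call(rbind, curve_rows) else
    data.frame(biome = character(), dist_m = numeric(), gap = numeric(),
               se = numeric()), file.path(out_dir, "gap_curve.csv"))
  write_csv_(if (length(contrast_rows)) do.call(rbind, contrast_rows) else
    data.frame(biome = character(), comparison = character(),
               delta_c = numeric(), se_delta = numeric(),
               gap_edge = numeric(), gap_interior = numeric()),
    file.path(out_dir, "gap_contrasts.csv"))
  invisible(fits)
}

#' Report stage: summary tables
#'
#' Collates the per-group edge-interior contrasts, the meta-regression
#' coefficient table, and the per-biome gap contrasts into three report
#' files. Missing groups are omitted with a warning.
#'
#' @inheritParams stage_synth
#' @return invisible list of the three tables (side effect:
#'   `report_contrasts.csv`, `report_meta.csv`, `report_gap.csv`).
#' @export
stage_report <- function(config, out_dir, seed = NULL) {
  rd <- function(f) {
    p <- file.path(out_dir, f)
    if (!file.exists(p)) {
      warning(sprintf("missing stage output %s; omitted", f), call. = FALSE)
      return(NULL)
    }
    utils::read.csv(p)
  }
  contrasts <- rd("contrasts.csv")
  meta <- rd("meta.csv")
  gap <- rd("gap_contrasts.csv")
  if (!is.null(contrasts))
    write_csv_(contrasts, file.path(out_dir, "report_contrasts.csv"))
  if (!is.null(meta))
    write_csv_(meta, file.path(out_dir, "report_meta.csv"))
  if (!is.null(gap))
    write_csv_(gap, file.path(out_dir, "report_gap.csv"))
  invisible(list(contrasts = contrasts, meta = meta, gap = gap))
}

#' Run the full pipeline
#'
#' Executes synth, curve, meta, gap and report in order and writes a
#' manifest with the configuration snapshot, root seed, per-file MD5
#' digests, row counts, and the filter-removal ledger. Two runs with the
#' same configuration and seed produce byte-identical outputs.
#'
#' @param config a `pipeline_config`, or a path to a YAML file, or `NULL`
#'   for defaults.
#' @param out_dir output directory.
#' @param seed optional integer overriding the configured root seed.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = NULL, out_dir, seed = NULL) {
  if (is.null(config) || is.character(config))
    config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stages <- list(synth = stage_synth, curve = stage_curve,
                 meta = stage_meta, gap = stage_gap, report = stage_report)
  for (nm in names(stages)) {
    res <- tryCatch(stages[[nm]](config, out_dir, seed),
                    error = function(e) e)
    if (inherits(res, "error"))
      stop_invalid("stage '%s' failed: %s", nm, conditionMessage(res))
  }
  files <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
  counts <- vapply(files, function(f)
    length(readLines(f)) - 1L, 0L)
  removal <- utils::read.csv(file.path(out_dir, "removal.csv"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("forestedge")),
    seed = seed %||% config$study$seed,
    config = unclass(config),
    files = lapply(stats::setNames(files, basename(files)), function(f)
      list(md5 = unname(tools::md5sum(f)),
           rows = length(readLines(f)) - 1L)),
    removal_totals = as.list(colSums(removal[c("n_sampled", "cloud",
                                               "nodata", "distance",
                                               "emitted")]))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
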