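# Orchestration: run the full account from a scene configuration (or a
# pre-built scene) to the account table, change statistics, uncertainty
# classification and sensitivity analysis, optionally writing every
# artifact to a directory.

#' Pipeline parameters
#'
#' Bundles every tunable of the accounting pipeline with its default:
#' the 20% canopy threshold and 7.5 ha / 5% loss reference filters, the
#' 23-cell (529 ha) landscape window, the published indicator weights, the
#' region fallback map, and the Mann-Whitney sampling scheme (1000 cells,
#' 23-cell separation).
#'
#' @param canopy_threshold_pct forest/non-forest canopy threshold.
#' @param min_forest_ha minimum polygon forest area.
#' @param max_loss_fraction maximum tolerated polygon loss share.
#' @param allowed_iucn protected-area categories admitted as reference.
#' @param window_size landscape window side in cells.
#' @param weights named indicator weight vector.
#' @param fallback_map region fallback map for upper levels.
#' @param mwu_n_samples,mwu_min_separation,mwu_seed Mann-Whitney sampling.
#' @param loss_threshold_pts change-statistics loss threshold in points.
#' @param oat_factor sensitivity perturbation size.
#' @param fit_birds fit the bird richness model on the scene's table?
#' @param bird_cv_repeats CV repetitions when validating the bird model.
#' @return list of parameters.
#' @export
pipeline_params <- function(canopy_threshold_pct = 20, min_forest_ha = 7.5,
                            max_loss_fraction = 0.05,
                            allowed_iucn = c("Ia", "Ib", "II"),
                            window_size = 23, weights = default_weights(),
                            fallback_map = default_fallback_map(),
                            mwu_n_samples = 1000, mwu_min_separation = 23,
                            mwu_seed = 1L, loss_threshold_pts = 10,
                            oat_factor = 0.1, fit_birds = FALSE,
                            bird_cv_repeats = 10) {
  as.list(environment())
}

#' Run the full condition-accounting pipeline
#'
#' Stages: scene simulation (unless a scene is supplied) -> typology ->
#' reference sites -> reference levels (with region fallbacks) -> landscape
#' metrics -> indicators and condition index for both accounting years ->
#' account table -> change statistics and Mann-Whitney tests ->
#' uncertainty classification -> one-at-a-time sensitivity -> optional
#' bird-model calibration. Deterministic given the scene seed and
#' `params$mwu_seed`.
#'
#' @param scene an `fc_scene`, or a [scene_config()] to simulate from.
#' @param params a [pipeline_params()] list.
#' @param outdir optional directory; when given, every table is written as
#'   CSV, index grids as ASCII rasters, and a manifest as YAML.
#' @return an `fc_pipeline_result` list with all stage outputs.
#' @export
run_pipeline <- function(scene = scene_config(), params = pipeline_params(),
                         outdir = NULL) {
  if (inherits(scene, "fc_scene_config")) scene <- generate_scene(scene)
  stopifnot(inherits(scene, "fc_scene"))

  typology <- build_typology(scene$land_cover, scene$regions,
                             cell_area = scene$config$cell_area,
                             region_names = scene$region_names)

  forest_mask <- forest_mask_from_canopy(scene$canopy_cover,
                                         params$canopy_threshold_pct)
  pstats <- summarize_polygons(scene$reference_polygons, forest_mask,
                               scene$loss_mask, scene$config$cell_area)
  refs <- select_reference_sites(pstats, scene$reference_polygons,
                                 forest_mask, params$min_forest_ha,
                                 params$max_loss_fraction,
                                 params$allowed_iucn)

  regions_with_sites <- unique(scene$region_names[
    scene$regions[refs$mask & typology$type_id > 0]])
  fallbacks <- apply_region_fallbacks(regions_with_sites,
                                      scene$region_names,
                                      params$fallback_map)

  variables <- add_landscape_variables(scene$variables, scene$land_cover,
                                       params$window_size)
  levels <- reference_levels(variables$year0, typology, refs$mask,
                             fallbacks)

  indicators <- lapply(variables, rescale_variables, levels = levels,
                       typology = typology)
  index <- lapply(indicators, aggregate_index, weights = params$weights,
                  typology = typology)

  account <- build_account(typology, variables, levels, indicators, index)
  change <- change_stats(index$year0$index, index$year1$index,
                         loss_threshold_pts = params$loss_threshold_pts)
  mwu <- mwu_change_test(index$year0$index, index$year1$index, typology,
                         params$mwu_n_samples, params$mwu_min_separation,
                         params$mwu_seed)
  uncertainty <- uncertainty_assessment(
    typology, refs$mask,
    env = list(elevation = scene$elevation, slope = scene$slope,
               temperature = scene$temperature, rainfall = scene$rainfall),
    pnv = scene$pnv, cell_area = scene$config$cell_area)
  sensitivity <- run_oat(variables$year1, typology, levels,
                         params$weights, params$oat_factor)

  birds <- NULL
  if (isTRUE(params$fit_birds)) {
    prepared <- prepare_bird_data(scene$bird_obs,
                                  seed = scene$config$seed)
    retained <- prune_collinear(prepared, bird_predictor_names(TRUE),
                                response = "threatened_richness")
    model <- fit_stepwise_glm(prepared, retained)
    birds <- list(model = model,
                  validation = validate_model(
                    model, prepared, cv_repeats = params$bird_cv_repeats,
                    seed = scene$config$seed))
  }

  result <- structure(list(
    scene = scene, params = params, typology = typology,
    forest_mask = forest_mask, polygon_stats = pstats,
    reference = refs, fallbacks = fallbacks, variables = variables,
    levels = levels, indicators = indicators, index = index,
    account = account, change = change, mwu = mwu,
    uncertainty = uncertainty, sensitivity = sensitivity, birds = birds
  ), class = "fc_pipeline_result")

  if (!is.null(outdir)) write_pipeline_result(result, outdir)
  result
}

#' Write pipeline artifacts to a directory
#'
#' @param result an `fc_pipeline_result`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_pipeline_result <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) readr::write_csv(x, file.path(outdir, name))
  wr(result$typology$catalogue, "typology_catalogue.csv")
  wr(result$polygon_stats, "polygon_stats.csv")
  wr(result$levels, "reference_levels.csv")
  wr(result$account, "condition_account.csv")
  wr(result$change, "change_stats.csv")
  wr(result$mwu, "mwu_tests.csv")
  wr(result$uncertainty, "uncertainty.csv")
  wr(result$sensitivity, "sensitivity.csv")
  wr(tibble::tibble(indicator = names(result$params$weights),
                    weight = unname(result$params$weights)),
     "weights.csv")
  for (yr in names(result$index)) {
    write_grid_asc(result$index[[yr]]$index,
                   file.path(outdir, paste0("condition_index_", yr, ".asc")))
  }
  yaml::write_yaml(list(
    package = "forestcond",
    scene_seed = result$scene$config$seed,
    mwu_seed = result$params$mwu_seed,
    n_types = nrow(result$typology$catalogue)
  ), file.path(outdir, "manifest.yaml"))
  invisible(outdir)
}

#' @export
print.fc_pipeline_result <- function(x, ...) {
  cat("<fc_pipeline_result> ", nrow(x$typology$catalogue),
      " forest types\n", sep = "")
  for (yr in names(x$index)) {
    cat("  mean condition index, ", yr, ": ",
        round(mean(x$index[[yr]]$type_means$index, na.rm = TRUE), 3),
        "\n", sep = "")
  }
  invisible(x)
}
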