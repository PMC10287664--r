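# Scene serialisation: one directory per scene, every grid as an ESRI ASCII
# raster, polygons as GeoJSON, the bird table as CSV and a YAML manifest
# recording the configuration and seed (so every output is re-derivable).

#' Write polygons as GeoJSON
#'
#' @param polygons tibble with `polygon_id`, `origin`, `iucn_category` and
#'   a `coords` list-column of closed rings.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_polygons_geojson <- function(polygons, path) {
  features <- purrr::map(seq_len(nrow(polygons)), function(i) {
    ring <- polygons$coords[[i]]
    list(
      type = "Feature",
      properties = list(polygon_id = polygons$polygon_id[i],
                        origin = polygons$origin[i],
                        iucn_category = polygons$iucn_category[i]),
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(ring)),
                                                function(k) ring[k, ])))
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' Read polygons written by [write_polygons_geojson()]
#'
#' @param path GeoJSON file.
#' @return polygon tibble.
#' @export
read_polygons_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  tibble::tibble(
    polygon_id = vapply(feats, function(f) as.integer(
      f$properties$polygon_id), integer(1)),
    origin = vapply(feats, function(f) as.character(f$properties$origin),
                    character(1)),
    iucn_category = vapply(feats, function(f) {
      v <- f$properties$iucn_category
      if (is.null(v)) NA_character_ else as.character(v)
    }, character(1)),
    coords = lapply(feats, function(f) {
      ring <- f$geometry$coordinates[[1]]
      m <- do.call(rbind, lapply(ring, function(pt) unlist(pt)))
      colnames(m) <- c("x", "y")
      m
    })
  )
}

scene_grid_names <- function(scene) {
  c("land_cover", "regions", "canopy_cover", "loss_mask", "elevation",
    "slope", "temperature", "rainfall", "pnv")
}

#' Write a scene to a directory
#'
#' @param scene an `fc_scene`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in scene_grid_names(scene)) {
    write_grid_asc(scene[[g]] * 1, file.path(dir, paste0(g, ".asc")))
  }
  for (yr in names(scene$variables)) {
    for (v in names(scene$variables[[yr]])) {
      write_grid_asc(scene$variables[[yr]][[v]],
                     file.path(dir, paste0(v, "_", yr, ".asc")))
    }
  }
  write_polygons_geojson(scene$reference_polygons,
                         file.path(dir, "reference_polygons.geojson"))
  readr::write_csv(scene$bird_obs, file.path(dir, "bird_obs.csv"))
  manifest <- list(
    package = "forestcond",
    seed = scene$config$seed,
    grid_shape = as.integer(scene$config$grid_shape),
    cell_area = scene$config$cell_area,
    n_regions = scene$config$n_regions,
    forest_fraction = scene$config$forest_fraction,
    reference_fraction = scene$config$reference_fraction,
    loss_fraction = scene$config$loss_fraction,
    region_names = scene$region_names,
    bird_truth = list(
      coefficients = as.list(scene$bird_truth$coefficients),
      dispersion = scene$bird_truth$dispersion)
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read the grids of a scene directory back
#'
#' Round-trips the raster, polygon and bird-table artifacts written by
#' [write_scene()]. The manifest carries the configuration needed to
#' regenerate the scene from scratch instead.
#'
#' @param dir scene directory.
#' @return list with the grids, two-year variable list, polygons, bird
#'   table and manifest.
#' @export
read_scene <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  grids <- list()
  for (f in list.files(dir, pattern = "\\.asc$")) {
    grids[[sub("\\.asc$", "", f)]] <- read_grid_asc(file.path(dir, f))
  }
  vars <- list()
  for (nm in names(grids)) {
    if (grepl("_year[01]$", nm)) {
      yr <- sub("^.*_(year[01])$", "\\1", nm)
      v <- sub("_year[01]$", "", nm)
      vars[[yr]][[v]] <- grids[[nm]]
      grids[[nm]] <- NULL
    }
  }
  list(
    grids = grids, variables = vars,
    reference_polygons = read_polygons_geojson(
      file.path(dir, "reference_polygons.geojson")),
    bird_obs = readr::read_csv(file.path(dir, "bird_obs.csv"),
                               show_col_types = FALSE),
    manifest = manifest
  )
}
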