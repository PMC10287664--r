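# Forest ecosystem typology: the cross of forest land-cover classes with
# biogeographic regions. With all four classes present in all eleven regions
# this yields the full 44-type catalogue.

#' Build the forest ecosystem typology
#'
#' Intersects the four forest land-cover classes (broad-leaved, coniferous,
#' mixed, transitional woodland/shrub) with biogeographic regions. Each
#' occurring (class, region) pair becomes a forest type with the stable
#' identifier `region_index * 10 + class_index`. Forest cells whose region is
#' missing (`NA`) are dropped from the typology, mirroring accounting areas
#' without regional coverage.
#'
#' @param land_cover integer grid of land-cover codes (forest classes 1-4).
#' @param regions integer grid of region indices (may contain `NA`).
#' @param cell_area hectares per cell.
#' @param region_names optional character vector naming the region indices.
#' @return an `fc_typology` list with `type_id` (integer grid, 0 = non-forest)
#'   and `catalogue` (tibble: `type_id`, `forest_class`, `region_index`,
#'   `region`, `n_cells`, `area_ha`).
#' @export
build_typology <- function(land_cover, regions, cell_area = 1,
                           region_names = NULL) {
  assert_coregistered(land_cover, regions)
  is_forest <- matrix(land_cover %in% FOREST_CLASSES, nrow(land_cover))
  dropped <- is_forest & is.na(regions)
  if (any(dropped)) {
    message(sum(dropped),
            " forest cell(s) without region coverage dropped from typology")
  }
  keep <- is_forest & !is.na(regions)
  type_id <- matrix(0L, nrow(land_cover), ncol(land_cover))
  type_id[keep] <- as.integer(regions[keep]) * 10L +
    as.integer(land_cover[keep])

  occurring <- sort(unique(type_id[type_id > 0L]))
  n_cells <- tabulate(match(type_id, occurring), nbins = length(occurring))
  region_index <- occurring %/% 10L
  class_index <- occurring %% 10L
  catalogue <- tibble::tibble(
    type_id = occurring,
    forest_class = names(FOREST_CLASSES)[class_index],
    region_index = region_index,
    region = if (is.null(region_names)) as.character(region_index) else
      region_names[region_index],
    n_cells = n_cells,
    area_ha = n_cells * cell_area
  )
  structure(list(type_id = type_id, catalogue = catalogue,
                 cell_area = cell_area),
            class = "fc_typology")
}

#' @export
print.fc_typology <- function(x, ...) {
  cat("<fc_typology> ", nrow(x$catalogue), " forest types over ",
      sum(x$catalogue$n_cells), " cells (",
      sum(x$catalogue$area_ha), " ha)\n", sep = "")
  print(x$catalogue, n = 5)
  invisible(x)
}

#' Cells belonging to one forest type
#' @keywords internal
type_cells <- function(typology, type) which(typology$type_id == type)
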