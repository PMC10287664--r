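# Reference-site selection: undisturbed or least-disturbed forest polygons
# (primary forests, or protected areas under IUCN Ia/Ib/II) that keep at
# least a minimum treed area and have lost at most a small share of it.

#' Forest / non-forest mask from canopy cover
#'
#' Cells with canopy cover strictly above the threshold count as forest; 20%
#' canopy is commonly treated as the limit between open habitats and
#' woodlands, so a cell at exactly the threshold is non-forest.
#'
#' @param canopy_cover grid of canopy cover percentages in \[0, 100\].
#' @param threshold_pct canopy threshold (default 20).
#' @return logical grid.
#' @export
forest_mask_from_canopy <- function(canopy_cover, threshold_pct = 20) {
  stopifnot(is.matrix(canopy_cover))
  rng <- range(canopy_cover, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 100) {
    stop("canopy cover values must lie in [0, 100]", call. = FALSE)
  }
  canopy_cover > threshold_pct
}

#' Minimum treed area implied by a mapping unit and canopy threshold
#'
#' The smallest treed area a land-cover mapping unit can contain while still
#' being delineated as forest: the minimum mapping unit times the canopy
#' threshold used for delineation. With the CLC conventions (25 ha mapping
#' unit, >30% canopy) this gives the 7.5 ha floor used to discard small
#' polygons.
#'
#' @param mmu_ha minimum mapping unit in hectares (default 25).
#' @param canopy_fraction canopy-cover delineation threshold as a fraction
#'   (default 0.30).
#' @return hectares.
#' @export
min_treed_area_ha <- function(mmu_ha = 25, canopy_fraction = 0.30) {
  stopifnot(mmu_ha >= 0, canopy_fraction >= 0, canopy_fraction <= 1)
  mmu_ha * canopy_fraction
}

#' Rasterise a polygon by cell-centre containment
#'
#' @param coords closed ring, 2-column matrix of map coordinates
#'   (x east, y north; see the grid registration note in `grids.R`).
#' @param nrow,ncol grid shape.
#' @return logical grid, `TRUE` where the cell centre falls inside.
#' @keywords internal
rasterize_polygon <- function(coords, nrow, ncol) {
  out <- matrix(FALSE, nrow, ncol)
  # restrict the point-in-polygon test to the bounding box
  cmin <- max(1L, floor(min(coords[, 1]) + 0.5))
  cmax <- min(ncol, ceiling(max(coords[, 1]) + 0.5))
  rmin <- max(1L, floor(nrow - max(coords[, 2]) + 0.5))
  rmax <- min(nrow, ceiling(nrow - min(coords[, 2]) + 0.5))
  if (cmin > cmax || rmin > rmax) return(out)
  rr <- rmin:rmax; cc <- cmin:cmax
  xs <- rep(cc - 0.5, each = length(rr))
  ys <- rep(nrow - rr + 0.5, times = length(cc))
  inside <- pracma::inpolygon(xs, ys, coords[, 1], coords[, 2],
                              boundary = FALSE)
  out[rr, cc] <- matrix(inside, length(rr), length(cc))
  out
}

#' Per-polygon forest and loss statistics
#'
#' For each polygon, counts forest cells and lost forest cells among grid
#' cells whose centres fall inside the polygon, and derives the loss
#' fraction.
#'
#' @param polygons tibble with `polygon_id`, `origin`, `iucn_category` and a
#'   `coords` list-column of closed rings (as in `fc_scene$reference_polygons`).
#' @param forest_mask logical grid of forest cells.
#' @param loss_mask logical grid of tree-cover loss (any-year summary).
#' @param cell_area hectares per cell.
#' @return tibble of `polygon_id`, `origin`, `iucn_category`,
#'   `forest_area_ha`, `loss_area_ha`, `loss_fraction`.
#' @export
summarize_polygons <- function(polygons, forest_mask, loss_mask,
                               cell_area = 1) {
  assert_coregistered(forest_mask, loss_mask)
  nr <- nrow(forest_mask); nc <- ncol(forest_mask)
  stats <- purrr::map(seq_len(nrow(polygons)), function(i) {
    inside <- rasterize_polygon(polygons$coords[[i]], nr, nc)
    if (!any(inside)) {
      warning("polygon ", polygons$polygon_id[i],
              " covers no grid cell centres", call. = FALSE)
    }
    f <- sum(forest_mask & inside)
    l <- sum(forest_mask & loss_mask & inside)
    list(forest = f, loss = l)
  })
  forest_ha <- vapply(stats, function(s) s$forest, numeric(1)) * cell_area
  loss_ha <- vapply(stats, function(s) s$loss, numeric(1)) * cell_area
  tibble::tibble(
    polygon_id = polygons$polygon_id,
    origin = polygons$origin,
    iucn_category = polygons$iucn_category,
    forest_area_ha = forest_ha,
    loss_area_ha = loss_ha,
    loss_fraction = ifelse(forest_ha > 0, loss_ha / forest_ha, 0)
  )
}

#' Select reference sites
#'
#' Accepts primary-forest polygons and protected polygons in an allowed IUCN
#' category, then applies the disturbance filters: polygons with below
#' `min_forest_ha` of forest are excluded, as are polygons that lost more
#' than `max_loss_fraction` of their forest (a loss share of exactly the
#' threshold still passes, i.e. low-moderate disturbance). The reference
#' mask is the union of the rasterised accepted polygons intersected with
#' the forest mask.
#'
#' @param stats output of [summarize_polygons()].
#' @param polygons the polygon tibble the stats were computed from.
#' @param forest_mask logical forest grid.
#' @param min_forest_ha minimum forest area per polygon (default 7.5, see
#'   [min_treed_area_ha()]).
#' @param max_loss_fraction maximum tolerated loss share (default 0.05).
#' @param allowed_iucn protected-area categories admitted as reference
#'   (default strict reserves, wilderness areas and national parks).
#' @return list with `mask` (logical grid) and `accepted_polygons`
#'   (polygon ids).
#' @export
select_reference_sites <- function(stats, polygons, forest_mask,
                                   min_forest_ha = 7.5,
                                   max_loss_fraction = 0.05,
                                   allowed_iucn = c("Ia", "Ib", "II")) {
  eligible <- stats$origin == "primary" |
    (!is.na(stats$iucn_category) & stats$iucn_category %in% allowed_iucn)
  accepted <- eligible &
    stats$forest_area_ha >= min_forest_ha &
    stats$loss_fraction <= max_loss_fraction
  ids <- stats$polygon_id[accepted]
  mask <- matrix(FALSE, nrow(forest_mask), ncol(forest_mask))
  for (i in which(polygons$polygon_id %in% ids)) {
    mask <- mask | rasterize_polygon(polygons$coords[[i]],
                                     nrow(forest_mask), ncol(forest_mask))
  }
  list(mask = mask & forest_mask, accepted_polygons = ids)
}

#' Default region fallback map for upper reference levels
#'
#' Regions without reference sites of their own borrow upper levels from an
#' ecologically similar region: Arctic from the Scandinavian Alpine sites,
#' Black Sea and Steppic from the Pannonian sites.
#'
#' @return named character vector, `names` = region without sites, value =
#'   donor region.
#' @export
default_fallback_map <- function() {
  c(Arctic = "Alpine-Scandinavia", BlackSea = "Pannonian",
    Steppic = "Pannonian")
}

#' Resolve per-region sources for upper reference levels
#'
#' Every region maps to itself when it has reference area, otherwise to its
#' fallback donor; a region whose donor is also empty (or that has no
#' fallback entry) is flagged unresolvable, which feeds the uncertainty
#' assessment (no-reference-site score).
#'
#' @param regions_with_sites character vector of regions that have nonempty
#'   reference area.
#' @param all_regions character vector of all regions in the typology.
#' @param fallback_map named character vector, see [default_fallback_map()].
#' @return tibble of `region`, `source_region` (`NA` if unresolvable),
#'   `fallback_used`, `resolved`.
#' @export
apply_region_fallbacks <- function(regions_with_sites, all_regions,
                                   fallback_map = default_fallback_map()) {
  purrr::map_dfr(all_regions, function(rg) {
    if (rg %in% regions_with_sites) {
      tibble::tibble(region = rg, source_region = rg,
                     fallback_used = FALSE, resolved = TRUE)
    } else {
      donor <- unname(fallback_map[rg])
      ok <- !is.na(donor) && !is.null(donor) && donor %in% regions_with_sites
      tibble::tibble(region = rg,
                     source_region = if (ok) donor else NA_character_,
                     fallback_used = ok, resolved = ok)
    }
  })
}
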