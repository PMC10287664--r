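# Landscape-level condition variables: forest area density (FAD, the
# connectivity metric) and landscape-mosaic naturalness, both moving-window
# proportions over the 23 x 23 cell (529 ha) neighbourhood.

FAD_CLASSES <- c("rare", "patchy", "transitional", "dominant", "interior",
                 "intact")
NATURALNESS_CATEGORIES <- c(100, 95, 85, 75, 65, 55, 45, 35, 25, 15, 5, 0)

#' Forest area density
#'
#' Percentage of forest cells within the moving window centred on each
#' forest cell; non-forest cells get `NA`.
#'
#' @param forest_mask logical grid of forest cells.
#' @param size odd window side in cells (default 23, the 529 ha
#'   neighbourhood at 1 ha cells).
#' @param edge_rule see [window_proportion()].
#' @return numeric percent grid in \[0, 100\], `NA` off-forest.
#' @export
forest_area_density <- function(forest_mask, size = 23,
                                edge_rule = "shrink") {
  window_proportion(forest_mask, size, edge_rule, domain = forest_mask)
}

#' Classify forest area density into six connectivity classes
#'
#' Bin edges follow the GuidosToolbox FAD 6-class convention:
#' rare \[0,10), patchy \[10,40), transitional \[40,60), dominant \[60,90),
#' interior \[90,100), intact exactly 100.
#'
#' @param percent FAD percent grid or vector.
#' @return character grid/vector of class labels (`NA` preserved).
#' @export
classify_fad <- function(percent) {
  if (any(percent < 0 | percent > 100, na.rm = TRUE)) {
    stop("FAD percent must lie in [0, 100]", call. = FALSE)
  }
  idx <- findInterval(percent, c(0, 10, 40, 60, 90, 100),
                      rightmost.closed = FALSE)
  # findInterval maps exactly 100 to bin 6 (intact), values in [90,100) to 5
  out <- FAD_CLASSES[idx]
  if (is.matrix(percent)) matrix(out, nrow(percent)) else out
}

#' Reclassify land cover into the three-way landscape mosaic
#'
#' @param land_cover integer land-cover grid using the package codes.
#' @return character grid with values `"agriculture"`, `"natural"`,
#'   `"developed"`.
#' @export
mosaic_reclass <- function(land_cover) {
  codes <- sort(unique(as.vector(land_cover)))
  known <- c(unname(LAND_COVER_CODES), 0L)
  if (length(setdiff(codes, known)) > 0) {
    stop("unmapped land cover code(s): ",
         paste(setdiff(codes, known), collapse = ", "), call. = FALSE)
  }
  out <- matrix("natural", nrow(land_cover), ncol(land_cover))
  out[land_cover == LAND_COVER_CODES[["agriculture"]]] <- "agriculture"
  out[land_cover == LAND_COVER_CODES[["developed"]]] <- "developed"
  out  # forest classes, natural open land and nodata count as natural
}

#' Snap naturalness percentages to the twelve category labels
#'
#' Categories are the printed label list `100, 95, 85, ..., 5, 0`; each
#' percentage maps to the nearest label, ties resolved upward.
#'
#' @param percent numeric grid/vector in \[0, 100\].
#' @return numeric grid/vector of category values.
#' @export
naturalness_category <- function(percent) {
  cats <- sort(NATURALNESS_CATEGORIES)  # ascending for the search
  snap <- function(p) {
    if (is.na(p)) return(NA_real_)
    d <- abs(cats - p)
    # ties up: among minima take the largest category
    max(cats[d == min(d)])
  }
  out <- vapply(as.vector(percent), snap, numeric(1))
  if (is.matrix(percent)) matrix(out, nrow(percent)) else out
}

#' Landscape naturalness
#'
#' Proportion of natural cells (forest classes and natural open land) in the
#' moving window, snapped to the twelve naturalness categories.
#'
#' @param land_cover integer land-cover grid.
#' @param size odd window side in cells (default 23).
#' @param edge_rule see [window_proportion()].
#' @return list with `percent_natural` and `category` grids.
#' @export
naturalness <- function(land_cover, size = 23, edge_rule = "shrink") {
  mosaic <- mosaic_reclass(land_cover)
  pct <- window_proportion(mosaic == "natural", size, edge_rule)
  list(percent_natural = pct, category = naturalness_category(pct))
}

#' Append the landscape variables to a variable list
#'
#' Computes FAD and naturalness from the land cover and forest mask and adds
#' them (as `fad` and `lm`) to each year's variable set. FAD outside forest
#' is undefined; naturalness uses the snapped category value as the
#' condition variable.
#'
#' @param variables two-year variable list (`year0`, `year1`).
#' @param land_cover land-cover grid.
#' @param size window size in cells.
#' @return the augmented variable list.
#' @export
add_landscape_variables <- function(variables, land_cover, size = 23) {
  forest_mask <- matrix(land_cover %in% FOREST_CLASSES, nrow(land_cover))
  fad <- forest_area_density(forest_mask, size)
  nat <- naturalness(land_cover, size)
  for (yr in names(variables)) {
    variables[[yr]]$fad <- fad
    variables[[yr]]$lm <- nat$category
  }
  variables
}
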