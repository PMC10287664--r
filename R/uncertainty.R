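# Semi-quantitative uncertainty classification per forest type, from four
# criteria: reference-site area, environmental representativeness of
# reference sites (mean |z|-score over elevation, slope, temperature and
# rainfall), and the natural-vegetation correspondence of the type's area
# and of its reference area. Scores run 1 (low uncertainty) to 4 (high).

#' Score the reference-site area criterion
#'
#' 1 when the reference area exceeds 100 km2 AND 2% of the type's forest
#' area; 2 when exactly one of the two holds; 3 when neither holds but
#' sites exist; 4 when the type has no reference sites.
#'
#' @param ref_area_km2 reference-site area in km2 (vectorised).
#' @param ref_share_pct reference area as % of the type's forest area.
#' @return integer scores in 1..4.
#' @export
score_area <- function(ref_area_km2, ref_share_pct) {
  big <- ref_area_km2 > 100
  wide <- ref_share_pct > 2
  score <- ifelse(big & wide, 1L, ifelse(big | wide, 2L, 3L))
  score[ref_area_km2 <= 0] <- 4L
  score
}

#' Score environmental representativeness
#'
#' Bins of the mean absolute z-score of reference-site means against the
#' type's distribution: below 0.3 standard deviations scores 1, 0.3-0.7
#' scores 2, 0.7-1.2 scores 3, beyond 1.2 scores 4 (bins are left-closed).
#' `NA` (no reference sites to assess) scores 4.
#'
#' @param mean_abs_z non-negative mean absolute z-score (vectorised).
#' @return integer scores in 1..4.
#' @export
score_representativeness <- function(mean_abs_z) {
  score <- findInterval(mean_abs_z, c(0, 0.3, 0.7, 1.2))
  score[is.na(mean_abs_z)] <- 4L
  as.integer(score)
}

#' Score the natural-vegetation correspondence criterion
#'
#' Share of area whose observed forest class is the naturally occurring
#' one: above 75% scores 1, 50-75% scores 2, 25-50% scores 3, 25% or less
#' scores 4 (exact 75/50/25 fall on the higher-uncertainty side, matching
#' the strict ">75%" of the best class).
#'
#' @param share_pct share in \[0, 100\] (vectorised); `NA` scores 4.
#' @return integer scores in 1..4.
#' @export
score_natural_share <- function(share_pct) {
  score <- ifelse(share_pct > 75, 1L,
                  ifelse(share_pct > 50, 2L,
                         ifelse(share_pct > 25, 3L, 4L)))
  score[is.na(share_pct)] <- 4L
  as.integer(score)
}

#' Share of forest area matching the potential natural vegetation
#'
#' Per forest type, the percentage of cells whose observed forest class
#' equals the expected class from the potential-natural-vegetation grid,
#' optionally restricted to a mask (e.g. reference cells).
#'
#' @param typology an [build_typology()] result (the observed class is the
#'   unit digit of `type_id`).
#' @param pnv integer grid of expected forest classes (1-4).
#' @param mask optional logical grid restricting the assessment.
#' @return tibble of `type_id`, `share_pct` (`NA` when no cells qualify).
#' @export
natural_correspondence <- function(typology, pnv, mask = NULL) {
  assert_coregistered(typology$type_id, pnv, mask)
  purrr::map_dfr(typology$catalogue$type_id, function(t) {
    idx <- type_cells(typology, t)
    if (!is.null(mask)) idx <- idx[mask[idx]]
    if (length(idx) == 0) {
      return(tibble::tibble(type_id = t, share_pct = NA_real_))
    }
    observed_class <- t %% 10L
    tibble::tibble(
      type_id = t,
      share_pct = 100 * mean(pnv[idx] == observed_class, na.rm = TRUE))
  })
}

#' Combine criterion scores into an uncertainty level
#'
#' The level is the mean of the four scores rounded to the nearest integer,
#' halves rounded away from zero (a tie is resolved toward the higher
#' uncertainty).
#'
#' @param scores numeric matrix or data frame with one column per criterion
#'   and one row per type.
#' @return integer vector of levels in 1..4.
#' @export
classify_uncertainty <- function(scores) {
  m <- as.matrix(scores)
  stopifnot(all(m >= 1 & m <= 4, na.rm = TRUE))
  as.integer(floor(rowMeans(m, na.rm = TRUE) + 0.5))
}

#' Full uncertainty assessment per forest type
#'
#' Computes the four criterion inputs from pipeline outputs and combines
#' them: reference area and share, mean |z| of the reference-site means of
#' elevation, slope, temperature and rainfall against each type's
#' distribution (population standard deviation), and the natural-vegetation
#' correspondence of the type area and of its reference area.
#'
#' @param typology an [build_typology()] result.
#' @param reference_mask logical grid of accepted reference cells.
#' @param env named list of grids `elevation`, `slope`, `temperature`,
#'   `rainfall`.
#' @param pnv expected-forest-class grid.
#' @param cell_area hectares per cell.
#' @return tibble with the criterion inputs, the four `score_*` columns and
#'   the final `level`.
#' @export
uncertainty_assessment <- function(typology, reference_mask, env, pnv,
                                   cell_area = 1) {
  need <- c("elevation", "slope", "temperature", "rainfall")
  stopifnot(all(need %in% names(env)))
  cat <- typology$catalogue
  if (nrow(cat) == 0) {
    return(tibble::tibble(
      type_id = integer(), ref_area_km2 = numeric(),
      ref_share_pct = numeric(), mean_abs_z = numeric(),
      natural_share_type_pct = numeric(),
      natural_share_ref_pct = numeric(), score_area = integer(),
      score_representativeness = integer(),
      score_natural_type = integer(), score_natural_ref = integer(),
      level = integer()))
  }
  nat_type <- natural_correspondence(typology, pnv)
  nat_ref <- natural_correspondence(typology, pnv, mask = reference_mask)

  rec <- purrr::map_dfr(cat$type_id, function(t) {
    idx <- type_cells(typology, t)
    ref_idx <- idx[reference_mask[idx]]
    ref_area_km2 <- length(ref_idx) * cell_area / 100
    ref_share_pct <- 100 * length(ref_idx) / length(idx)
    mean_abs_z <- if (length(ref_idx) == 0) NA_real_ else {
      zs <- vapply(need, function(v) {
        g <- env[[v]]
        mu <- mean(g[idx]); s <- sqrt(mean((g[idx] - mu)^2))
        if (s == 0) 0 else abs(mean(g[ref_idx]) - mu) / s
      }, numeric(1))
      mean(zs)
    }
    tibble::tibble(type_id = t, ref_area_km2 = ref_area_km2,
                   ref_share_pct = ref_share_pct, mean_abs_z = mean_abs_z)
  })
  rec$natural_share_type_pct <- nat_type$share_pct[match(rec$type_id,
                                                         nat_type$type_id)]
  rec$natural_share_ref_pct <- nat_ref$share_pct[match(rec$type_id,
                                                       nat_ref$type_id)]
  rec$score_area <- score_area(rec$ref_area_km2, rec$ref_share_pct)
  rec$score_representativeness <- score_representativeness(rec$mean_abs_z)
  rec$score_natural_type <- score_natural_share(rec$natural_share_type_pct)
  rec$score_natural_ref <- score_natural_share(rec$natural_share_ref_pct)
  rec$level <- classify_uncertainty(
    rec[, c("score_area", "score_representativeness", "score_natural_type",
            "score_natural_ref")])
  rec
}
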