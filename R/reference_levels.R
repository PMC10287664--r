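# Reference levels per (forest type, variable): the lower level V_L anchors
# the degraded end of the indicator scale and comes from the ambient
# distribution of the type; the upper level V_H anchors the natural end and
# comes from reference sites. Both are measured on the first accounting
# year's grids (the reference year) and applied to all years.

#' Lower reference levels from the ambient distribution
#'
#' For each forest type and variable, the lower level is the minimum value
#' over all cells of the type in the reference-year grid. A robust floor
#' (low percentile instead of the absolute minimum) is available for grids
#' where single-cell artefacts would otherwise set the level.
#'
#' @param variables named list of variable grids for the reference year.
#' @param typology an [build_typology()] result.
#' @param percentile percentile (0-100) used as the floor; 0 (default) is
#'   the absolute minimum.
#' @return tibble of `type_id`, `variable`, `V_L`.
#' @export
lower_levels <- function(variables, typology, percentile = 0) {
  cat <- typology$catalogue
  empty <- tibble::tibble(type_id = integer(), variable = character(),
                          V_L = numeric())
  if (nrow(cat) == 0 || length(variables) == 0) return(empty)
  purrr::map_dfr(names(variables), function(v) {
    g <- variables[[v]]
    purrr::map_dfr(cat$type_id, function(t) {
      vals <- g[type_cells(typology, t)]
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0) return(NULL)
      tibble::tibble(
        type_id = t, variable = v,
        V_L = if (percentile <= 0) min(vals) else
          unname(stats::quantile(vals, percentile / 100))
      )
    })
  })
}

#' Upper reference levels from reference sites
#'
#' For each forest type, the upper level of a variable is its maximum over
#' the type's cells inside the reference mask, on the reference-year grid.
#' Types in regions without any reference area borrow the upper level of
#' the same forest class in the donor region given by the fallback
#' assignment; borrowed rows are flagged. Types that cannot be resolved get
#' `NA` upper levels (highest-uncertainty types downstream).
#'
#' @param variables named list of variable grids for the reference year.
#' @param typology an [build_typology()] result.
#' @param reference_mask logical grid of accepted reference cells.
#' @param fallbacks tibble from [apply_region_fallbacks()]; `NULL` disables
#'   borrowing.
#' @param percentile percentile (0-100) used as the ceiling; 100 (default)
#'   is the absolute maximum.
#' @return tibble of `type_id`, `variable`, `V_H`, `source_region`,
#'   `fallback_used`.
#' @export
upper_levels <- function(variables, typology, reference_mask,
                         fallbacks = NULL, percentile = 100) {
  cat <- typology$catalogue
  if (nrow(cat) == 0 || length(variables) == 0) {
    return(tibble::tibble(type_id = integer(), variable = character(),
                          V_H = numeric(), source_region = character(),
                          fallback_used = logical()))
  }
  own <- purrr::map_dfr(names(variables), function(v) {
    g <- variables[[v]]
    purrr::map_dfr(cat$type_id, function(t) {
      idx <- type_cells(typology, t)
      vals <- g[idx][reference_mask[idx]]
      vals <- vals[!is.na(vals)]
      tibble::tibble(
        type_id = t, variable = v,
        V_H = if (length(vals) == 0) NA_real_ else
          if (percentile >= 100) max(vals) else
            unname(stats::quantile(vals, percentile / 100))
      )
    })
  })
  own$source_region <- cat$region[match(own$type_id, cat$type_id)]
  own$fallback_used <- FALSE

  if (!is.null(fallbacks)) {
    for (i in which(is.na(own$V_H))) {
      t <- own$type_id[i]
      rg <- cat$region[match(t, cat$type_id)]
      cls <- cat$forest_class[match(t, cat$type_id)]
      fb <- fallbacks[fallbacks$region == rg, ]
      if (nrow(fb) == 1 && fb$resolved && fb$source_region != rg) {
        donor_type <- cat$type_id[cat$region == fb$source_region &
                                    cat$forest_class == cls]
        donor_row <- own$type_id %in% donor_type &
          own$variable == own$variable[i] & !is.na(own$V_H) &
          !own$fallback_used
        if (any(donor_row)) {
          j <- which(donor_row)[1]
          own$V_H[i] <- own$V_H[j]
          own$source_region[i] <- fb$source_region
          own$fallback_used[i] <- TRUE
        }
      }
    }
  }
  own
}

#' Derive the full reference-level table
#'
#' Joins lower and upper levels into one row per (type, variable). Where a
#' borrowed upper level falls below the type's own lower level, the upper
#' level is clipped to the lower level (the indicator becomes 0 everywhere)
#' and the row flagged `degenerate`, keeping the rescaling well defined.
#'
#' @inheritParams upper_levels
#' @param lower_percentile,upper_percentile passed to [lower_levels()] and
#'   [upper_levels()].
#' @return tibble of `type_id`, `variable`, `V_L`, `V_H`, `source_region`,
#'   `fallback_used`, `missing` (no upper level), `degenerate`.
#' @export
reference_levels <- function(variables, typology, reference_mask,
                             fallbacks = NULL, lower_percentile = 0,
                             upper_percentile = 100) {
  lo <- lower_levels(variables, typology, lower_percentile)
  hi <- upper_levels(variables, typology, reference_mask, fallbacks,
                     upper_percentile)
  tab <- dplyr::left_join(lo, hi, by = c("type_id", "variable"))
  tab$missing <- is.na(tab$V_H)
  tab$degenerate <- !tab$missing & tab$V_H < tab$V_L
  if (any(tab$degenerate)) {
    message(sum(tab$degenerate),
            " reference level(s) clipped to V_L (borrowed V_H below the ",
            "type's ambient minimum)")
    tab$V_H[tab$degenerate] <- tab$V_L[tab$degenerate]
  }
  tab
}
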