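# SEEA-style condition account tables, change statistics between accounting
# years, and the Mann-Whitney significance test on spatially thinned cell
# samples.

#' Build the condition account table
#'
#' One row per (forest type, accounting year, variable) carrying the SEEA
#' account quantities: area, the variable mean on its native scale, the
#' lower and upper reference levels, the rescaled indicator mean, and the
#' type's condition index.
#'
#' @param typology an [build_typology()] result.
#' @param variables two-year variable list (`year0`, `year1`), landscape
#'   variables included.
#' @param levels reference-level table from [reference_levels()].
#' @param indicators list per year of indicator stacks from
#'   [rescale_variables()].
#' @param index list per year of [aggregate_index()] results.
#' @return tibble: `type_id`, `forest_class`, `region`, `year`, `area_ha`,
#'   `variable`, `mean_value`, `V_L`, `V_H`, `indicator_mean`, `index`.
#' @export
build_account <- function(typology, variables, levels, indicators, index) {
  years <- names(variables)
  for (what in list(variables, indicators, index)) {
    if (!all(years %in% names(what))) {
      stop("account inputs must cover years: ",
           paste(years, collapse = ", "), call. = FALSE)
    }
  }
  cat <- typology$catalogue
  purrr::map_dfr(years, function(yr) {
    purrr::map_dfr(cat$type_id, function(t) {
      idx <- type_cells(typology, t)
      row <- cat[cat$type_id == t, ]
      idx_mean <- index[[yr]]$type_means
      purrr::map_dfr(names(variables[[yr]]), function(v) {
        lv <- levels[levels$type_id == t & levels$variable == v, ]
        tibble::tibble(
          type_id = t, forest_class = row$forest_class,
          region = row$region, year = yr, area_ha = row$area_ha,
          variable = v,
          mean_value = mean(variables[[yr]][[v]][idx], na.rm = TRUE),
          V_L = if (nrow(lv)) lv$V_L else NA_real_,
          V_H = if (nrow(lv)) lv$V_H else NA_real_,
          indicator_mean = mean(indicators[[yr]][[v]][idx], na.rm = TRUE),
          index = idx_mean$index[match(t, idx_mean$type_id)]
        )
      })
    })
  })
}

#' Condition change in absolute index points
#'
#' The change convention of the account: `100 * (index_t1 - index_t0)`,
#' i.e. an index moving from 0.566 to 0.585 is a change of +1.9 points.
#'
#' @param index_t0,index_t1 index values (scalars, vectors or grids).
#' @return change in index points x 100, same shape as the inputs.
#' @export
change_points <- function(index_t0, index_t1) {
  100 * (index_t1 - index_t0)
}

#' Area statistics of condition change
#'
#' @param index_t0,index_t1 co-registered per-cell index grids.
#' @param forest_mask optional logical grid restricting the statistics to
#'   forest cells (cells that are `NA` in either index are always skipped).
#' @param loss_threshold_pts report the share of cells losing more than
#'   this many index points (default 10).
#' @return one-row tibble: `share_increasing`, `share_decreasing`,
#'   `share_unchanged` (percentages summing to 100),
#'   `mean_change_increasing`, `mean_change_decreasing` (index points),
#'   `share_loss_gt_threshold`.
#' @export
change_stats <- function(index_t0, index_t1, forest_mask = NULL,
                         loss_threshold_pts = 10) {
  assert_coregistered(index_t0, index_t1, forest_mask)
  keep <- !is.na(index_t0) & !is.na(index_t1)
  if (!is.null(forest_mask)) keep <- keep & forest_mask
  ch <- change_points(index_t0[keep], index_t1[keep])
  n <- length(ch)
  if (n == 0) {
    return(tibble::tibble(share_increasing = NA_real_,
                          share_decreasing = NA_real_,
                          share_unchanged = NA_real_,
                          mean_change_increasing = NA_real_,
                          mean_change_decreasing = NA_real_,
                          share_loss_gt_threshold = NA_real_))
  }
  up <- ch > 0; down <- ch < 0
  tibble::tibble(
    share_increasing = 100 * sum(up) / n,
    share_decreasing = 100 * sum(down) / n,
    share_unchanged = 100 * sum(!up & !down) / n,
    mean_change_increasing = if (any(up)) mean(ch[up]) else NA_real_,
    mean_change_decreasing = if (any(down)) mean(ch[down]) else NA_real_,
    share_loss_gt_threshold = 100 * sum(ch < -loss_threshold_pts) / n
  )
}

#' Spatially thinned random cell sample
#'
#' Greedy random thinning: candidate cells are visited in random order and
#' accepted while they keep a Euclidean distance of at least
#' `min_separation` cells from every previously accepted cell (enforced via
#' a blocking disc, so the pairwise guarantee is exact).
#'
#' @param cells integer matrix of candidate (row, col) positions.
#' @param n maximum cells to accept.
#' @param min_separation minimum pairwise distance in cell units.
#' @param dims grid dimensions.
#' @return integer vector of accepted row indices into `cells`.
#' @keywords internal
thin_cells <- function(cells, n, min_separation, dims) {
  if (min_separation <= 1) {
    return(sample.int(nrow(cells), min(n, nrow(cells))))
  }
  blocked <- matrix(FALSE, dims[1], dims[2])
  rad <- ceiling(min_separation) - 1
  offs <- expand.grid(dr = -rad:rad, dc = -rad:rad)
  offs <- offs[offs$dr^2 + offs$dc^2 < min_separation^2, ]
  order <- sample.int(nrow(cells))
  accepted <- integer(0)
  for (i in order) {
    r <- cells[i, 1]; c <- cells[i, 2]
    if (blocked[r, c]) next
    accepted <- c(accepted, i)
    rr <- r + offs$dr; cc <- c + offs$dc
    ok <- rr >= 1 & rr <= dims[1] & cc >= 1 & cc <= dims[2]
    blocked[cbind(rr[ok], cc[ok])] <- TRUE
    if (length(accepted) >= n) break
  }
  accepted
}

#' Mann-Whitney test of condition change per forest type
#'
#' For each forest type, samples cells at random subject to a minimum
#' pairwise separation (to avoid spatial autocorrelation inflating the
#' test), then runs a two-sided Mann-Whitney U (rank-sum) test comparing
#' the year-0 and year-1 index values at the sampled cells as two groups
#' (normal approximation with tie correction). If fewer than `n_samples`
#' cells survive thinning, all surviving cells are used and the row is
#' flagged.
#'
#' @param index_t0,index_t1 co-registered per-cell index grids.
#' @param typology an [build_typology()] result.
#' @param n_samples target sample size per type (default 1000).
#' @param min_separation_cells minimum pairwise distance between sampled
#'   cells (default 23, the landscape window size).
#' @param seed seed for the sampling.
#' @return tibble: `type_id`, `n_used`, `thinned_short` (fewer than
#'   `n_samples` available), `U`, `p_value`, `direction`
#'   (`"increase"`/`"decrease"`/`"none"`).
#' @export
mwu_change_test <- function(index_t0, index_t1, typology, n_samples = 1000,
                            min_separation_cells = 23, seed = 1L) {
  assert_coregistered(index_t0, index_t1, typology$type_id)
  dims <- dim(index_t0)
  with_seed(seed, purrr::map_dfr(typology$catalogue$type_id, function(t) {
    idx <- type_cells(typology, t)
    idx <- idx[!is.na(index_t0[idx]) & !is.na(index_t1[idx])]
    if (length(idx) == 0) {
      warning("type ", t, " has no eligible cells; skipped", call. = FALSE)
      return(NULL)
    }
    cells <- arrayInd(idx, dims)
    take <- thin_cells(cells, n_samples, min_separation_cells, dims)
    sel <- idx[take]
    x0 <- index_t0[sel]; x1 <- index_t1[sel]
    if (length(sel) < 2 || (stats::sd(x0) == 0 && stats::sd(x1) == 0 &&
                            x0[1] == x1[1])) {
      return(tibble::tibble(type_id = t, n_used = length(sel),
                            thinned_short = length(sel) < n_samples,
                            U = NA_real_, p_value = 1, direction = "none"))
    }
    wt <- suppressWarnings(stats::wilcox.test(x1, x0, exact = FALSE,
                                              correct = TRUE))
    dir <- if (wt$p.value < 0.05) {
      if (stats::median(x1) > stats::median(x0)) "increase" else "decrease"
    } else "none"
    tibble::tibble(type_id = t, n_used = length(sel),
                   thinned_short = length(sel) < n_samples,
                   U = unname(wt$statistic), p_value = wt$p.value,
                   direction = dir)
  }))
}
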