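# The condition-index core: min-max rescaling of variables to [0,1]
# indicators between the lower and upper reference levels, rank-derived
# weights summing to one, proportional redistribution of weights for
# structurally missing indicators, and the weighted aggregation of the seven
# indicators to the forest condition index per cell and per type.

#' Default indicator weights
#'
#' The rank-derived weight vector of the seven condition indicators (NDWI
#' 0.08, soil organic carbon 0.12, threatened-bird richness 0.22, tree cover
#' density 0.21, NDVI 0.13, forest area density 0.13, landscape naturalness
#' 0.11). Overridable by a rank matrix via [weights_from_ranks()].
#'
#' @return named numeric vector summing to 1.
#' @export
default_weights <- function() {
  c(ndwi = 0.08, soc = 0.12, birds = 0.22, trees = 0.21, ndvi = 0.13,
    fad = 0.13, lm = 0.11)
}

#' Min-max rescale a variable between its reference levels
#'
#' `I = (V - V_L) / (V_H - V_L)`, clamped: values at or above the upper
#' level map to 1, values at or below the lower level map to 0. A degenerate
#' pair (`V_H == V_L`) yields 0 everywhere — an uninformative indicator is
#' flagged as degraded rather than silently granted top condition.
#'
#' @param V variable values (vector or matrix).
#' @param V_L,V_H lower and upper reference levels (scalars).
#' @return rescaled indicator values in \[0, 1\], same shape as `V`.
#' @export
rescale_indicator <- function(V, V_L, V_H) {
  if (is.na(V_L) || is.na(V_H)) {
    out <- V; out[] <- NA_real_; return(out)
  }
  if (V_H < V_L) stop("V_H must be >= V_L", call. = FALSE)
  if (V_H == V_L) {
    out <- V * 0
    return(out)
  }
  clamp((V - V_L) / (V_H - V_L), 0, 1)
}

#' Derive indicator weights from criterion ranks
#'
#' Each of the conceptual criteria ranks the indicators from 1 (lowest) to
#' `n` (highest); mid-ranks are allowed for ties. The rank sums are
#' converted to ratios so the weights sum to one.
#'
#' @param rank_matrix numeric matrix, indicators x criteria, with row names
#'   naming the indicators.
#' @return tibble of `indicator`, `rank_sum`, `weight`.
#' @export
weights_from_ranks <- function(rank_matrix) {
  stopifnot(is.matrix(rank_matrix), !is.null(rownames(rank_matrix)))
  n <- nrow(rank_matrix)
  if (any(rank_matrix < 1 | rank_matrix > n)) {
    stop("ranks must lie in [1, ", n, "]", call. = FALSE)
  }
  rs <- unname(rowSums(rank_matrix))
  tibble::tibble(indicator = rownames(rank_matrix), rank_sum = rs,
                 weight = rs / sum(rs))
}

#' Redistribute the weights of missing indicators
#'
#' When an indicator is structurally unavailable (for example soil organic
#' carbon in a region without soil data), its weight is distributed
#' proportionally over the remaining indicators so they still sum to one:
#' `w'_j = w_j / (1 - sum of missing weights)`.
#'
#' @param weights named weight vector.
#' @param missing names of missing indicators (may be empty).
#' @return named weight vector over the remaining indicators.
#' @export
redistribute_missing <- function(weights, missing = character(0)) {
  stopifnot(!is.null(names(weights)))
  missing <- intersect(missing, names(weights))
  if (length(missing) == 0) return(weights)
  if (length(missing) >= length(weights)) {
    stop("cannot redistribute: all indicators missing", call. = FALSE)
  }
  keep <- setdiff(names(weights), missing)
  weights[keep] / (1 - sum(weights[missing]))
}

#' Rescale all variables to an indicator stack
#'
#' Applies [rescale_indicator()] per forest type using that type's reference
#' levels. Types with a missing upper level for some variable get `NA` for
#' that indicator over all their cells (a structural absence, handled by
#' weight redistribution during aggregation).
#'
#' @param variables named list of variable grids (one accounting year).
#' @param levels reference-level table from [reference_levels()].
#' @param typology an [build_typology()] result.
#' @return named list of indicator grids in \[0, 1\].
#' @export
rescale_variables <- function(variables, levels, typology) {
  out <- list()
  for (v in names(variables)) {
    g <- variables[[v]]
    ind <- matrix(NA_real_, nrow(g), ncol(g))
    lv <- levels[levels$variable == v, ]
    for (k in seq_len(nrow(lv))) {
      idx <- type_cells(typology, lv$type_id[k])
      ind[idx] <- rescale_indicator(g[idx], lv$V_L[k], lv$V_H[k])
    }
    out[[v]] <- ind
  }
  out
}

#' Aggregate indicators to the forest condition index
#'
#' Per-cell weighted sum of the indicators, and per-type mean index (the
#' SEEA account entry): `index_type = sum_i sum_j w_j x_ij / n`. For types
#' where an indicator is entirely absent, its weight is redistributed
#' proportionally over the present indicators; cells with sporadic gaps in
#' otherwise-present indicators yield `NA` (a data hole, not a structural
#' absence).
#'
#' @param indicators named list of indicator grids from
#'   [rescale_variables()].
#' @param weights named weight vector (normalised).
#' @param typology an [build_typology()] result.
#' @return an `fc_condition_index` list: `index` grid, `type_means` tibble
#'   (`type_id`, `n_cells`, `index`), `weights_by_type` (list of the weight
#'   vectors actually applied).
#' @export
aggregate_index <- function(indicators, weights, typology) {
  stopifnot(abs(sum(weights) - 1) < 1e-8)
  vars <- names(weights)
  if (!all(vars %in% names(indicators))) {
    stop("indicator grid(s) missing for: ",
         paste(setdiff(vars, names(indicators)), collapse = ", "),
         call. = FALSE)
  }
  g1 <- indicators[[vars[1]]]
  index <- matrix(NA_real_, nrow(g1), ncol(g1))
  cat <- typology$catalogue
  weights_by_type <- list()
  means <- purrr::map_dfr(cat$type_id, function(t) {
    idx <- type_cells(typology, t)
    sub <- vapply(vars, function(v) indicators[[v]][idx],
                  numeric(length(idx)))
    sub <- matrix(sub, nrow = length(idx),
                  dimnames = list(NULL, vars))
    absent <- vars[apply(sub, 2, function(col) all(is.na(col)))]
    if (length(absent) >= length(vars)) {
      weights_by_type[[as.character(t)]] <<- weights[0]
      return(tibble::tibble(type_id = t, n_cells = length(idx),
                            index = NA_real_))
    }
    w <- redistribute_missing(weights, absent)
    vals <- as.vector(sub[, names(w), drop = FALSE] %*% w)
    index[idx] <<- vals
    weights_by_type[[as.character(t)]] <<- w
    tibble::tibble(type_id = t, n_cells = length(idx),
                   index = mean(vals, na.rm = TRUE))
  })
  structure(list(index = index, type_means = means,
                 weights_by_type = weights_by_type),
            class = "fc_condition_index")
}

#' @export
print.fc_condition_index <- function(x, ...) {
  cat("<fc_condition_index> ", nrow(x$type_means), " forest types, mean ",
      round(mean(x$type_means$index, na.rm = TRUE), 3), "\n", sep = "")
  invisible(x)
}
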