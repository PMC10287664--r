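# One-at-a-time parameter sensitivity: the per-type condition index depends
# on 21 parameters (V_L, V_H and w_j for each of the seven indicators).
# Each parameter is perturbed by 10% in the adverse direction used for the
# published analysis (V_L up, V_H down, w_j up with renormalisation) and
# the percentage deviation of the index recorded.

#' Perturb one reference level
#'
#' Multiplicative perturbation of a single (type, variable) level: the
#' lower level is raised (`V_L * (1 + factor)`), the upper level lowered
#' (`V_H * (1 - factor)`). A zero level is a fixed point. If the perturbed
#' pair crosses, the moved level is clipped to the other one and the row
#' flagged degenerate.
#'
#' @param levels reference-level table.
#' @param type,variable the row to perturb.
#' @param which `"lower"` or `"upper"`.
#' @param factor perturbation size (default 0.1).
#' @return the perturbed table (only the named row changed).
#' @export
perturb_reference_level <- function(levels, type, variable,
                                    which = c("lower", "upper"),
                                    factor = 0.1) {
  which <- match.arg(which)
  i <- which(levels$type_id == type & levels$variable == variable)
  if (length(i) != 1) stop("no unique row for type ", type, " / ",
                           variable, call. = FALSE)
  if (which == "lower") {
    levels$V_L[i] <- levels$V_L[i] * (1 + factor)
    if (!is.na(levels$V_H[i]) && levels$V_L[i] > levels$V_H[i]) {
      levels$V_L[i] <- levels$V_H[i]
      levels$degenerate[i] <- TRUE
    }
  } else {
    levels$V_H[i] <- levels$V_H[i] * (1 - factor)
    if (!is.na(levels$V_H[i]) && levels$V_H[i] < levels$V_L[i]) {
      levels$V_H[i] <- levels$V_L[i]
      levels$degenerate[i] <- TRUE
    }
  }
  levels
}

#' Perturb one weight, renormalising the others
#'
#' Raises `w_k` by the factor and scales the remaining weights
#' proportionally so the vector still sums to one:
#' `w'_j = w_j * (1 - (1+f) w_k) / (1 - w_k)` for `j != k`. Proportional
#' renormalisation is the unique choice preserving the relative ratios of
#' the untouched weights. A zero weight is a fixed point.
#'
#' @param weights named weight vector summing to 1.
#' @param k indicator name (or index) to perturb.
#' @param factor perturbation size (default 0.1).
#' @return perturbed named weight vector summing to 1.
#' @export
perturb_weight <- function(weights, k, factor = 0.1) {
  stopifnot(abs(sum(weights) - 1) < 1e-8)
  wk <- weights[[k]]
  if (wk == 0) return(weights)
  if ((1 + factor) * wk >= 1) {
    stop("perturbed weight would reach or exceed 1", call. = FALSE)
  }
  out <- weights * (1 - (1 + factor) * wk) / (1 - wk)
  out[[k]] <- (1 + factor) * wk
  out
}

type_index_mean <- function(variables, levels, typology, weights, type) {
  # index mean of a single type, recomputed from the variable grids
  idx <- type_cells(typology, type)
  lv <- levels[levels$type_id == type, ]
  vars <- names(weights)
  sub <- vapply(vars, function(v) {
    row <- lv[lv$variable == v, ]
    if (nrow(row) == 0 || is.na(row$V_H)) {
      rep(NA_real_, length(idx))
    } else {
      rescale_indicator(variables[[v]][idx], row$V_L, row$V_H)
    }
  }, numeric(length(idx)))
  sub <- matrix(sub, nrow = length(idx), dimnames = list(NULL, vars))
  absent <- vars[apply(sub, 2, function(col) all(is.na(col)))]
  if (length(absent) >= length(vars)) return(NA_real_)
  w <- redistribute_missing(weights, absent)
  mean(as.vector(sub[, names(w), drop = FALSE] %*% w), na.rm = TRUE)
}

#' One-at-a-time sensitivity analysis
#'
#' For every forest type, recomputes the condition index 21 times, each run
#' with exactly one parameter perturbed: each indicator's lower level
#' raised 10%, upper level lowered 10%, and weight raised 10% (with
#' proportional renormalisation of the rest). Reports the percentage
#' deviation from the nominal index; types with a nominal index of zero
#' report the absolute change instead and are flagged.
#'
#' @param variables named list of variable grids for the accounting year
#'   analysed.
#' @param typology an [build_typology()] result.
#' @param levels reference-level table.
#' @param weights named weight vector.
#' @param factor perturbation size (default 0.1).
#' @return an `fc_oat` tibble: `type_id`, `parameter`
#'   (`"lower"`/`"upper"`/`"weight"`), `indicator`, `index_nominal`,
#'   `index_perturbed`, `pct_deviation`, `absolute_deviation_flag`.
#' @export
run_oat <- function(variables, typology, levels, weights = default_weights(),
                    factor = 0.1) {
  vars <- names(weights)
  rows <- purrr::map_dfr(typology$catalogue$type_id, function(t) {
    nominal <- type_index_mean(variables, levels, typology, weights, t)
    purrr::map_dfr(vars, function(v) {
      has_row <- any(levels$type_id == t & levels$variable == v)
      pert <- purrr::map_dfr(c("lower", "upper", "weight"), function(p) {
        perturbed <- if (p == "weight") {
          # the sum-to-one constraint binds when one weight dominates;
          # the perturbation is then a no-op rather than an error
          wp <- if ((1 + factor) * weights[[v]] < 1) {
            perturb_weight(weights, v, factor)
          } else weights
          type_index_mean(variables, levels, typology, wp, t)
        } else if (has_row) {
          type_index_mean(
            variables,
            perturb_reference_level(levels, t, v, p, factor),
            typology, weights, t)
        } else {
          nominal  # structurally missing indicator: level has no effect
        }
        tibble::tibble(parameter = p, indicator = v,
                       index_perturbed = perturbed)
      })
      pert
    }) |>
      dplyr::mutate(
        type_id = t, index_nominal = nominal,
        absolute_deviation_flag = !is.na(nominal) & nominal == 0,
        pct_deviation = dplyr::if_else(
          absolute_deviation_flag,
          index_perturbed - index_nominal,
          100 * (index_perturbed - index_nominal) / index_nominal)
      ) |>
      dplyr::select(type_id, parameter, indicator, index_nominal,
                    index_perturbed, pct_deviation,
                    absolute_deviation_flag)
  })
  class(rows) <- c("fc_oat", class(rows))
  rows
}

#' Summarise a sensitivity analysis over types
#'
#' @param oat an `fc_oat` tibble from [run_oat()].
#' @return tibble of mean and extreme percentage deviation per
#'   (parameter, indicator), averaged over forest types.
#' @export
summarize_oat <- function(oat) {
  dplyr::summarise(
    dplyr::group_by(oat, .data$parameter, .data$indicator),
    mean_pct_deviation = mean(.data$pct_deviation, na.rm = TRUE),
    max_abs_pct_deviation = max(abs(.data$pct_deviation), na.rm = TRUE),
    .groups = "drop")
}
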