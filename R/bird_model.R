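# Threatened forest bird richness modelling: quality filtering, collinearity
# pruning, a forward stepwise quasi-Poisson GLM with optional quadratic
# terms, validation (hold-out and repeated k-fold CV), and projection of the
# fitted model onto predictor grids.

#' Filter and split a bird observation table
#'
#' Drops low-quality observations (total reported richness below
#' `min_total_richness` signals poor sampling effort) and excluded strata
#' (e.g. territories with incomplete reporting), then assigns a
#' train/test split label.
#'
#' @param raw tibble with `total_richness`, `threatened_richness` and
#'   predictor columns.
#' @param min_total_richness observations with fewer total species are
#'   dropped (default 3: a cell with at least three species reported is
#'   retained).
#' @param excluded_strata values of `strata_col` to drop entirely.
#' @param strata_col column holding the stratum label (ignored if absent).
#' @param split_prop share of rows assigned to the training set.
#' @param seed seed for the split.
#' @return the filtered tibble with a `.split` column (`"train"`/`"test"`);
#'   attribute `dropped_fraction` records the share of rows removed.
#' @export
prepare_bird_data <- function(raw, min_total_richness = 3,
                              excluded_strata = NULL,
                              strata_col = "stratum",
                              split_prop = 0.7, seed = 1L) {
  n0 <- nrow(raw)
  keep <- raw$total_richness >= min_total_richness
  if (!is.null(excluded_strata) && strata_col %in% names(raw)) {
    keep <- keep & !(raw[[strata_col]] %in% excluded_strata)
  }
  out <- raw[keep, , drop = FALSE]
  if (nrow(out) == 0) stop("no observations left after filtering",
                           call. = FALSE)
  out$.split <- with_seed(seed, {
    lab <- rep("test", nrow(out))
    lab[sample.int(nrow(out), round(split_prop * nrow(out)))] <- "train"
    lab
  })
  attr(out, "dropped_fraction") <- 1 - nrow(out) / n0
  out
}

#' Greedy collinearity pruning
#'
#' While any pair of predictors has `|Pearson r|` above the threshold, drops
#' the member of the worst pair with the lower absolute correlation to the
#' response (generalising the usual manual choice of discarding coordinates
#' in favour of the climate variables they proxy).
#'
#' @param data data frame containing the predictors (and response).
#' @param predictors predictor column names to consider.
#' @param response response column name used for the keep-priority; `NULL`
#'   drops the later column of each offending pair.
#' @param threshold absolute correlation above which a pair is collinear
#'   (default 0.7).
#' @return character vector of retained predictors; attribute `dropped`
#'   lists the removals.
#' @export
prune_collinear <- function(data, predictors, response = NULL,
                            threshold = 0.7) {
  stopifnot(length(predictors) >= 2)
  retained <- predictors
  dropped <- character(0)
  priority <- if (is.null(response)) {
    stats::setNames(rev(seq_along(predictors)), predictors)
  } else {
    vapply(predictors, function(p) abs(stats::cor(data[[p]],
                                                  data[[response]])),
           numeric(1))
  }
  repeat {
    cm <- abs(stats::cor(data[, retained, drop = FALSE]))
    diag(cm) <- 0
    if (max(cm) <= threshold) break
    worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    pair <- retained[worst]
    victim <- pair[which.min(priority[pair])]
    retained <- setdiff(retained, victim)
    dropped <- c(dropped, victim)
    if (length(retained) < 2) break
  }
  structure(retained, dropped = dropped)
}

pseudo_r2 <- function(fit) 1 - fit$deviance / fit$null.deviance

term_p_value <- function(fit, term) {
  ct <- summary(fit)$coefficients
  if (!term %in% rownames(ct)) return(NA_real_)
  ct[term, 4]
}

#' Forward stepwise quasi-Poisson GLM
#'
#' Candidates enter in order of decreasing absolute Pearson correlation with
#' the response. At each step the linear term is added and kept if its Wald
#' test is significant and it improves the explained deviance (pseudo-R2,
#' `1 - residual deviance / null deviance`) by more than `improvement_tol`;
#' its quadratic companion (centred before squaring, for conditioning) is
#' then tried under the same gates. Selection stops at the first candidate
#' that fails (set `scan_all = TRUE` to keep scanning the remaining
#' candidates instead).
#'
#' @param data prepared table from [prepare_bird_data()] (rows with
#'   `.split == "train"` are used if the column exists).
#' @param predictors candidate predictor names (e.g. the output of
#'   [prune_collinear()]).
#' @param response count response column (default threatened richness).
#' @param improvement_tol minimum absolute pseudo-R2 gain per accepted term
#'   (default 0.005).
#' @param alpha Wald significance level for term inclusion (default 0.05).
#' @param scan_all keep testing later candidates after a failure?
#' @param quadratic test quadratic companions?
#' @return an `fc_richness_model`: the final `glm` fit plus selected terms,
#'   quadratic centres, dispersion (from Pearson residuals), pseudo-R2 and
#'   training RMSE.
#' @export
fit_stepwise_glm <- function(data, predictors,
                             response = "threatened_richness",
                             improvement_tol = 0.005, alpha = 0.05,
                             scan_all = FALSE, quadratic = TRUE) {
  train <- if (".split" %in% names(data)) {
    data[data$.split == "train", , drop = FALSE]
  } else data
  y <- train[[response]]
  ord <- predictors[order(-abs(vapply(predictors, function(p)
    stats::cor(train[[p]], y), numeric(1))))]

  centers <- vapply(ord, function(p) mean(train[[p]]), numeric(1))
  for (p in ord) train[[paste0(p, "_sq")]] <- (train[[p]] - centers[[p]])^2

  fit_terms <- function(terms) {
    fml <- stats::reformulate(if (length(terms)) terms else "1",
                              response = response)
    stats::glm(fml, data = train, family = stats::quasipoisson())
  }
  terms <- character(0)
  linear_terms <- character(0)
  quadratic_terms <- character(0)
  current <- fit_terms(terms)
  r2 <- pseudo_r2(current)
  for (v in ord) {
    cand <- tryCatch(fit_terms(c(terms, v)), error = function(e) NULL,
                     warning = function(w) suppressWarnings(
                       fit_terms(c(terms, v))))
    if (is.null(cand) || !cand$converged) {
      warning("fit for candidate ", v, " did not converge; skipped",
              call. = FALSE)
      next
    }
    ok <- !is.na(term_p_value(cand, v)) && term_p_value(cand, v) < alpha &&
      (pseudo_r2(cand) - r2) > improvement_tol
    if (!ok) {
      if (scan_all) next else break
    }
    terms <- c(terms, v); linear_terms <- c(linear_terms, v)
    current <- cand; r2 <- pseudo_r2(current)
    if (quadratic) {
      vsq <- paste0(v, "_sq")
      cand2 <- tryCatch(fit_terms(c(terms, vsq)),
                        error = function(e) NULL)
      if (!is.null(cand2) && cand2$converged &&
          !is.na(term_p_value(cand2, vsq)) &&
          term_p_value(cand2, vsq) < alpha &&
          (pseudo_r2(cand2) - r2) > improvement_tol) {
        terms <- c(terms, vsq); quadratic_terms <- c(quadratic_terms, v)
        current <- cand2; r2 <- pseudo_r2(current)
      }
    }
  }
  mu <- stats::fitted(current)
  structure(list(
    fit = current,
    response = response,
    linear_terms = linear_terms,
    quadratic_terms = quadratic_terms,
    terms = terms,
    centers = centers[linear_terms],
    candidate_order = ord,
    pseudo_r2 = r2,
    dispersion = sum(stats::residuals(current, "pearson")^2) /
      current$df.residual,
    rmse_train = sqrt(mean((y - mu)^2)),
    n_train = nrow(train)
  ), class = "fc_richness_model")
}

#' @export
print.fc_richness_model <- function(x, ...) {
  cat("<fc_richness_model> quasi-Poisson, terms: ",
      if (length(x$terms)) paste(x$terms, collapse = " + ") else
        "(intercept only)",
      "\n  pseudo-R2 ", round(x$pseudo_r2, 3),
      ", dispersion ", round(x$dispersion, 2),
      ", train RMSE ", round(x$rmse_train, 3), "\n", sep = "")
  invisible(x)
}

model_frame <- function(model, newdata) {
  for (p in model$linear_terms) {
    if (!p %in% names(newdata)) {
      stop("predictor '", p, "' missing from new data", call. = FALSE)
    }
    newdata[[paste0(p, "_sq")]] <- (newdata[[p]] - model$centers[[p]])^2
  }
  newdata
}

#' Predict expected richness
#'
#' @param object an `fc_richness_model`.
#' @param newdata data frame with the selected predictors.
#' @param type passed to `predict.glm` (default `"response"`).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.fc_richness_model <- function(object, newdata, type = "response",
                                      ...) {
  stats::predict(object$fit, newdata = model_frame(object, newdata),
                 type = type)
}

#' Validate a fitted richness model
#'
#' Hold-out metrics on the test split plus repeated k-fold cross-validation
#' on the training split. The CV refits the selected model formula on each
#' fold (the term set itself is held fixed; re-running selection inside the
#' CV would measure a different procedure).
#'
#' @param model an `fc_richness_model`.
#' @param data the prepared table the model was fitted on.
#' @param cv_folds folds per repetition (default 10).
#' @param cv_repeats repetitions (default 100 at full scale; desk-scale
#'   analyses use fewer).
#' @param seed seed for the fold assignment.
#' @return list with `rmse_test`, `cor_test`, `cv` (per-repeat tibble) and
#'   `cv_rmse_mean`, `cv_rmse_sd`, `cv_pseudo_r2_mean`.
#' @export
validate_model <- function(model, data, cv_folds = 10, cv_repeats = 100,
                           seed = 1L) {
  test <- data[data$.split == "test", , drop = FALSE]
  train <- data[data$.split == "train", , drop = FALSE]
  y_test <- test[[model$response]]
  pred <- predict(model, test)
  rmse_test <- sqrt(mean((y_test - pred)^2))
  cor_test <- if (stats::sd(pred) > 0) stats::cor(y_test, pred) else NA_real_

  fml <- stats::formula(model$fit)
  train_mf <- model_frame(model, train)
  cv <- with_seed(seed, purrr::map_dfr(seq_len(cv_repeats), function(rep) {
    fold <- sample(rep_len(seq_len(cv_folds), nrow(train_mf)))
    res <- purrr::map_dfr(seq_len(cv_folds), function(k) {
      fitk <- stats::glm(fml, data = train_mf[fold != k, , drop = FALSE],
                         family = stats::quasipoisson())
      mu <- stats::predict(fitk, train_mf[fold == k, , drop = FALSE],
                           type = "response")
      obs <- train_mf[[model$response]][fold == k]
      tibble::tibble(rmse = sqrt(mean((obs - mu)^2)),
                     pseudo_r2 = pseudo_r2(fitk))
    })
    tibble::tibble(rep = rep, rmse = mean(res$rmse),
                   pseudo_r2 = mean(res$pseudo_r2))
  }))
  list(rmse_test = rmse_test, cor_test = cor_test, cv = cv,
       cv_rmse_mean = mean(cv$rmse), cv_rmse_sd = stats::sd(cv$rmse),
       cv_pseudo_r2_mean = mean(cv$pseudo_r2))
}

#' Project a richness model onto predictor grids
#'
#' Evaluates the inverse-link (exponential) of the linear predictor cell by
#' cell. Dynamic predictors vary by accounting year simply by passing that
#' year's grids; held-constant predictors are passed unchanged.
#'
#' @param model an `fc_richness_model`.
#' @param grids named list of matrices, one per selected linear predictor.
#' @return matrix of expected richness (strictly positive under the log
#'   link).
#' @export
project_richness <- function(model, grids) {
  need <- model$linear_terms
  miss <- setdiff(need, names(grids))
  if (length(miss) > 0) {
    stop("missing predictor grid(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (length(need) == 0) {
    template <- if (length(grids) > 0) grids[[1]] else matrix(0, 1, 1)
    out <- template * 0 + exp(stats::coef(model$fit)[["(Intercept)"]])
    return(out)
  }
  do.call(assert_coregistered, unname(grids[need]))
  nd <- as.data.frame(lapply(grids[need], as.vector))
  pred <- predict(model, nd, type = "response")
  matrix(pred, nrow(grids[[need[1]]]))
}
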