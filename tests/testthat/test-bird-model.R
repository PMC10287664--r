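make_bird_table <- function(n = 1500, seed = 51,
                            truth = generate_bird_truth()) {
  withr::with_seed(seed, forestcond:::simulate_bird_table(n, truth))
}

test_that("quality filtering keeps cells with at least three species", {
  tab <- tibble::tibble(total_richness = c(3, 2, 10, 0, 5),
                        threatened_richness = c(1, 1, 4, 0, 2))
  out <- prepare_bird_data(tab, seed = 1)
  expect_setequal(out$total_richness, c(3, 10, 5))
  expect_equal(attr(out, "dropped_fraction"), 2 / 5)
  # constructed table with exactly 5% sub-threshold rows
  tab2 <- tibble::tibble(total_richness = c(rep(5, 95), rep(2, 5)),
                         threatened_richness = 1)
  out2 <- prepare_bird_data(tab2, seed = 1)
  expect_equal(attr(out2, "dropped_fraction"), 0.05)
  expect_error(prepare_bird_data(tibble::tibble(total_richness = 1,
                                                threatened_richness = 0)),
               "no observations")
})

test_that("excluded strata are removed and the split is reproducible", {
  tab <- tibble::tibble(total_richness = rep(6, 100),
                        threatened_richness = rep(2, 100),
                        stratum = rep(c("A", "B"), each = 50))
  out <- prepare_bird_data(tab, excluded_strata = "B", seed = 3)
  expect_true(all(out$stratum == "A"))
  out2 <- prepare_bird_data(tab, excluded_strata = "B", seed = 3)
  expect_identical(out$.split, out2$.split)
  expect_equal(mean(out$.split == "train"), 0.7, tolerance = 0.01)
})

test_that("collinearity pruning removes exactly the planted pairs", {
  tab <- make_bird_table(n = 3000)
  retained <- prune_collinear(tab, bird_predictor_names(TRUE),
                              response = "threatened_richness")
  expect_length(retained, 15)
  expect_length(attr(retained, "dropped"), 2)
  # the planted collinear pairs were coordinates vs climate
  expect_true(all(attr(retained, "dropped") %in%
                    c("longitude", "latitude", "temperature_seasonality",
                      "temperature_mean")))
  # identical predictors: one removed
  df <- tibble::tibble(x = stats::rnorm(100))
  df$y <- df$x
  r2 <- prune_collinear(df, c("x", "y"))
  expect_length(r2, 1)
  # orthogonal predictors: identity
  withr::with_seed(5, {
    df3 <- tibble::as_tibble(matrix(stats::rnorm(300 * 3), 300,
                                    dimnames = list(NULL, c("a", "b", "c"))))
    expect_length(prune_collinear(df3, c("a", "b", "c")), 3)
  })
})

test_that("a pure-noise response selects no terms", {
  withr::with_seed(61, {
    tab <- tibble::tibble(
      threatened_richness = stats::rpois(600, 5),
      p1 = stats::rnorm(600), p2 = stats::rnorm(600),
      p3 = stats::rnorm(600))
    m <- fit_stepwise_glm(tab, c("p1", "p2", "p3"))
    expect_length(m$terms, 0)
    expect_lt(m$pseudo_r2, 0.02)
  })
})

test_that("the stepwise fit recovers the generating terms", {
  tab <- make_bird_table(n = 5000, seed = 72)
  prepared <- prepare_bird_data(
    dplyr::mutate(tab, total_richness = pmax(total_richness, 3)), seed = 1)
  retained <- prune_collinear(prepared, bird_predictor_names(TRUE),
                              response = "threatened_richness")
  m <- fit_stepwise_glm(prepared, retained)
  truth <- generate_bird_truth()
  expect_setequal(m$linear_terms, truth$linear_terms)
  expect_setequal(m$quadratic_terms, truth$quadratic_terms)
  expect_gt(m$dispersion, 1.3)
  # pseudo-R2 non-decreasing along the forward path is implied by
  # construction; check the final fit beats the null model
  expect_gt(m$pseudo_r2, 0.2)
  co <- tidy(m)
  for (term in truth$linear_terms) {
    row <- co[co$term == term, ]
    expect_lt(abs(row$estimate - truth$coefficients[[term]]),
              2 * row$std.error)
  }
})

test_that("model accessors and tidiers expose the fit", {
  tab <- make_bird_table(n = 1200, seed = 81)
  m <- fit_stepwise_glm(tab, generate_bird_truth()$linear_terms)
  g <- glance(m)
  expect_equal(g$nobs, 1200)
  expect_true(all(c("pseudo_r2", "dispersion", "rmse_train") %in% names(g)))
  pred <- predict(m, tab)
  expect_true(all(pred > 0))  # log link keeps projections positive
  expect_equal(sqrt(mean((tab$threatened_richness - pred)^2)),
               m$rmse_train, tolerance = 1e-10)
})

test_that("validation reports hold-out and cross-validation metrics", {
  tab <- make_bird_table(n = 1500, seed = 91)
  prepared <- prepare_bird_data(
    dplyr::mutate(tab, total_richness = pmax(total_richness, 3)), seed = 2)
  m <- fit_stepwise_glm(prepared, generate_bird_truth()$linear_terms)
  val <- validate_model(m, prepared, cv_repeats = 3, seed = 5)
  expect_gt(val$cor_test, 0.3)
  expect_equal(nrow(val$cv), 3)
  expect_true(val$cv_rmse_sd >= 0)
  val2 <- validate_model(m, prepared, cv_repeats = 3, seed = 5)
  expect_equal(val$cv_rmse_mean, val2$cv_rmse_mean)
})

test_that("projection equals the closed form and names missing grids", {
  tab <- make_bird_table(n = 1000, seed = 101)
  # single linear predictor, no quadratic
  m <- fit_stepwise_glm(tab, "share_forest", quadratic = FALSE)
  expect_equal(m$linear_terms, "share_forest")
  g <- matrix(stats::rnorm(36), 6, 6)
  proj <- project_richness(m, list(share_forest = g))
  b <- stats::coef(m$fit)
  expect_equal(proj, exp(b[["(Intercept)"]] + b[["share_forest"]] * g),
               tolerance = 1e-10)
  expect_error(project_richness(m, list(other = g)),
               "share_forest")
  # identical year grids give identical projections
  expect_identical(proj, project_richness(m, list(share_forest = g)))
})
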