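test_that("scene generation is deterministic given the seed", {
  s1 <- generate_scene(small_config(seed = 7))
  s2 <- generate_scene(small_config(seed = 7))
  expect_identical(s1$land_cover, s2$land_cover)
  expect_identical(s1$variables, s2$variables)
  expect_identical(s1$reference_polygons, s2$reference_polygons)
  expect_identical(s1$bird_obs, s2$bird_obs)
  s3 <- generate_scene(small_config(seed = 8))
  expect_false(identical(s1$variables$year0$ndwi, s3$variables$year0$ndwi))
})

test_that("generated variables respect their native ranges in both years", {
  scene <- generate_scene(small_config(seed = 2))
  rng <- variable_ranges()
  for (yr in names(scene$variables)) {
    for (v in names(scene$variables[[yr]])) {
      vals <- scene$variables[[yr]][[v]]
      expect_true(all(vals >= rng[[v]][1] & vals <= rng[[v]][2]),
                  label = paste(yr, v, "within range"))
    }
  }
  expect_true(all(scene$canopy_cover >= 0 & scene$canopy_cover <= 100))
})

test_that("forest_fraction zero yields a forest-free scene and empty typology", {
  scene <- generate_scene(small_config(seed = 3, forest_fraction = 0,
                                       reference_fraction = 0,
                                       loss_fraction = 0))
  expect_equal(sum(scene$land_cover %in% 1:4), 0)
  typ <- build_typology(scene$land_cover, scene$regions)
  expect_equal(nrow(typ$catalogue), 0)
})

test_that("all four forest classes occur whenever forest exists", {
  for (seed in 1:5) {
    scene <- generate_scene(small_config(seed = seed,
                                         forest_fraction = 0.3))
    expect_setequal(unique(scene$land_cover[scene$land_cover <= 4 &
                                              scene$land_cover >= 1]),
                    1:4)
  }
})

test_that("reference uplift raises variables inside designated reference", {
  # large scene: with many polygon clusters the mean difference between
  # reference and ambient cells converges to the configured uplift
  scene <- generate_scene(scene_config(grid_shape = c(120, 120),
                                       reference_fraction = 0.15,
                                       n_bird_cells = 10, seed = 4))
  forest <- scene$land_cover %in% 1:4
  in_ref <- scene$designated_reference
  uplift <- scene$config$reference_uplift
  for (v in c("ndwi", "soc", "trees")) {
    g <- scene$variables$year0[[v]]
    diff <- mean(g[forest & in_ref]) - mean(g[forest & !in_ref])
    expect_gt(diff, 0.3 * uplift[[v]])
    expect_lt(diff, 2.0 * uplift[[v]])
  }
  # the stored mask matches the rasterised polygon union
  union <- matrix(FALSE, 120, 120)
  for (ring in scene$reference_polygons$coords) {
    union <- union | forestcond:::rasterize_polygon(ring, 120, 120)
  }
  expect_identical(union, in_ref)
})

test_that("with zero uplift, reference and ambient distributions agree", {
  # Monte-Carlo over seeds; independent (unsmoothed) variable fields keep
  # the cellwise two-sample test exactly calibrated, so uniform p-values
  # demonstrate that no uplift leaks into the reference cells
  iid_params <- default_variable_params()
  for (v in names(iid_params)) iid_params[[v]]$range_cells <- 0
  pvals <- vapply(1:100, function(seed) {
    scene <- generate_scene(scene_config(
      grid_shape = c(28, 28), n_regions = 2, n_bird_cells = 10,
      variable_params = iid_params,
      reference_uplift = 0, loss_fraction = 0, seed = seed))
    in_ref <- scene$designated_reference
    forest <- scene$land_cover %in% 1:4
    if (sum(in_ref & forest) < 5 || sum(!in_ref & forest) < 5) {
      return(NA_real_)
    }
    g <- scene$variables$year0$ndwi
    stats::wilcox.test(g[in_ref & forest], g[!in_ref & forest],
                       exact = FALSE)$p.value
  }, numeric(1))
  pvals <- pvals[!is.na(pvals)]
  expect_gt(length(pvals), 80)
  # calibrated: rejection near nominal, mean near 1/2
  expect_lt(mean(pvals < 0.05), 0.12)
  expect_gt(mean(pvals), 0.35)
  expect_lt(mean(pvals), 0.65)
})

test_that("bird count simulation honours intercept and dispersion", {
  truth0 <- list(coefficients = c(`(Intercept)` = log(5)), dispersion = 1)
  withr::with_seed(21, {
    X <- data.frame(dummy = rep(0, 20000))
    y <- simulate_bird_counts(X, truth0)
    expect_equal(mean(y), 5, tolerance = 0.05)
    expect_equal(stats::var(y) / mean(y), 1, tolerance = 0.1)
    truth2 <- list(coefficients = c(`(Intercept)` = log(5)), dispersion = 2)
    y2 <- simulate_bird_counts(X, truth2)
    expect_equal(stats::var(y2) / mean(y2), 2, tolerance = 0.15)
  })
})

test_that("a stated slope is recovered by regression within 2 SE", {
  withr::with_seed(31, {
    truth <- generate_bird_truth()
    tab <- forestcond:::simulate_bird_table(5000, truth)
    fit <- stats::glm(
      threatened_richness ~ share_forest + ndvi_summer_mean + altitude +
        I((altitude - mean(altitude))^2),
      data = tab, family = stats::quasipoisson())
    ct <- summary(fit)$coefficients
    for (term in c("share_forest", "ndvi_summer_mean", "altitude")) {
      expect_lt(abs(ct[term, 1] - truth$coefficients[[term]]),
                2 * ct[term, 2])
    }
  })
})

test_that("over-dispersion of the default truth exceeds one", {
  withr::with_seed(41, {
    tab <- forestcond:::simulate_bird_table(4000, generate_bird_truth())
    fit <- stats::glm(threatened_richness ~ share_forest + altitude,
                      data = tab, family = stats::quasipoisson())
    expect_gt(summary(fit)$dispersion, 1.3)
  })
})

test_that("invalid configurations are rejected", {
  expect_error(scene_config(forest_fraction = 1.2), "fractions")
  expect_error(scene_config(grid_shape = c(0, 10)), "positive")
  expect_error(scene_config(n_regions = 12), "between 1 and 11")
})
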