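test_that("weight perturbation renormalises proportionally", {
  w <- c(a = 0.5, b = 0.5)
  w2 <- perturb_weight(w, "a")
  expect_equal(unname(w2), c(0.55, 0.45))
  expect_equal(sum(w2), 1)
  tw <- default_weights()
  for (k in names(tw)) {
    expect_equal(sum(perturb_weight(tw, k)), 1, tolerance = 1e-12)
  }
  # untouched weights keep their relative ratios
  w3 <- perturb_weight(tw, "birds")
  others <- setdiff(names(tw), "birds")
  expect_equal(w3[others] / tw[others],
               stats::setNames(rep((1 - 1.1 * tw[["birds"]]) /
                                     (1 - tw[["birds"]]), 6), others))
  expect_identical(perturb_weight(c(a = 0, b = 1), "a"), c(a = 0, b = 1))
  expect_error(perturb_weight(c(a = 0.95, b = 0.05), "a"), "exceed 1")
})

test_that("reference-level perturbations are local and clipped", {
  levels <- tibble::tibble(
    type_id = c(1, 1, 2), variable = c("x", "y", "x"),
    V_L = c(0, 2, 5), V_H = c(10, 4, 5.2),
    fallback_used = FALSE, missing = FALSE, degenerate = FALSE)
  up <- perturb_reference_level(levels, 1, "y", "upper")
  expect_equal(up$V_H[2], 3.6)
  expect_equal(up$V_L, levels$V_L)          # lower levels untouched
  expect_equal(up$V_H[c(1, 3)], levels$V_H[c(1, 3)])  # locality
  lo <- perturb_reference_level(levels, 1, "x", "lower")
  expect_equal(lo$V_L[1], 0)  # multiplicative: zero is a fixed point
  # crossing gets clipped and flagged
  crossed <- perturb_reference_level(levels, 2, "x", "upper")
  expect_equal(crossed$V_H[3], crossed$V_L[3])
  expect_true(crossed$degenerate[3])
})

test_that("each type gets exactly 21 parameter rows", {
  scene <- generate_scene(small_config(seed = 14))
  res <- suppressWarnings(suppressMessages(
    run_pipeline(scene, pipeline_params(mwu_n_samples = 50,
                                        mwu_min_separation = 2))))
  counts <- table(res$sensitivity$type_id)
  expect_true(all(counts == 21))
  expect_setequal(unique(res$sensitivity$parameter),
                  c("lower", "upper", "weight"))
})

test_that("weight perturbations vanish at indicator consensus", {
  nr <- 10
  typ <- banded_typology(nr, nr, 1, 1)
  vars <- stats::setNames(replicate(7, matrix(0.5, nr, nr),
                                    simplify = FALSE),
                          names(default_weights()))
  levels <- purrr::map_dfr(names(vars), function(v)
    tibble::tibble(type_id = typ$catalogue$type_id, variable = v,
                   V_L = 0, V_H = 1, fallback_used = FALSE,
                   missing = FALSE, degenerate = FALSE))
  oat <- run_oat(vars, typ, levels)
  wrows <- oat[oat$parameter == "weight", ]
  expect_equal(nrow(wrows), 7)
  expect_equal(wrows$pct_deviation, rep(0, 7), tolerance = 1e-10)
})

test_that("raising V_L of a saturated indicator changes nothing", {
  nr <- 8
  typ <- banded_typology(nr, nr, 1, 1)
  vars <- list(x = matrix(50, nr, nr))  # far above V_H
  levels <- tibble::tibble(type_id = typ$catalogue$type_id,
                           variable = "x", V_L = 1, V_H = 10,
                           fallback_used = FALSE, missing = FALSE,
                           degenerate = FALSE)
  oat <- run_oat(vars, typ, levels, weights = c(x = 1))
  low <- oat[oat$parameter == "lower", ]
  expect_equal(low$pct_deviation, 0)
})

test_that("every OAT row matches the independent recomputation", {
  scene <- generate_scene(scene_config(grid_shape = c(20, 20),
                                       n_regions = 2, n_bird_cells = 10,
                                       seed = 15))
  typ <- build_typology(scene$land_cover, scene$regions,
                        region_names = scene$region_names)
  forest <- forest_mask_from_canopy(scene$canopy_cover)
  st <- suppressWarnings(summarize_polygons(scene$reference_polygons,
                                            forest, scene$loss_mask))
  refs <- select_reference_sites(st, scene$reference_polygons, forest)
  vars <- add_landscape_variables(scene$variables, scene$land_cover,
                                  size = 11)$year0
  levels <- suppressMessages(reference_levels(vars, typ, refs$mask))
  w <- default_weights()
  oat <- run_oat(vars, typ, levels, w)
  for (i in sample(nrow(oat), 30)) {
    row <- oat[i, ]
    if (row$parameter == "weight") {
      want <- bf_type_index(vars, levels, typ,
                            perturb_weight(w, row$indicator), row$type_id)
    } else {
      pl <- perturb_reference_level(levels, row$type_id, row$indicator,
                                    row$parameter)
      want <- bf_type_index(vars, pl, typ, w, row$type_id)
    }
    expect_equal(row$index_perturbed, want, tolerance = 1e-10,
                 label = paste("row", i))
  }
})

test_that("weight perturbation moves the index toward the indicator mean", {
  withr::with_seed(47, {
    nr <- 12
    typ <- banded_typology(nr, nr, 1, 1)
    vars <- list(x = matrix(stats::runif(nr^2), nr, nr),
                 y = matrix(stats::runif(nr^2), nr, nr))
    levels <- purrr::map_dfr(c("x", "y"), function(v)
      tibble::tibble(type_id = typ$catalogue$type_id, variable = v,
                     V_L = 0, V_H = 1, fallback_used = FALSE,
                     missing = FALSE, degenerate = FALSE))
    w <- c(x = 0.3, y = 0.7)
    oat <- run_oat(vars, typ, levels, w)
    t <- typ$catalogue$type_id[1]
    nominal <- oat$index_nominal[1]
    for (k in c("x", "y")) {
      xbar <- mean(vars[[k]][typ$type_id == t])
      row <- oat[oat$parameter == "weight" & oat$indicator == k, ]
      expect_equal(sign(row$index_perturbed - nominal),
                   sign(xbar - nominal))
    }
  })
})
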