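test_that("the change metric reproduces the worked period means", {
  expect_equal(change_points(0.566, 0.585), 1.9, tolerance = 1e-9)
  expect_equal(change_points(0.648, 0.682), 3.4, tolerance = 1e-9)
  expect_equal(change_points(0.625, 0.605), -2.0, tolerance = 1e-9)
})

test_that("change statistics count shares as constructed", {
  withr::with_seed(7, {
    t0 <- matrix(stats::runif(100, 0.3, 0.7), 10, 10)
    t1 <- t0
    up <- sample(100, 63)
    t1[up] <- t1[up] + 0.05
    down <- setdiff(seq_len(100), up)[1:20]
    t1[down] <- t1[down] - 0.15
    cs <- change_stats(t0, t1)
    expect_equal(cs$share_increasing, 63)
    expect_equal(cs$share_decreasing, 20)
    expect_equal(cs$share_unchanged, 17)
    expect_equal(cs$mean_change_increasing, 5, tolerance = 1e-9)
    expect_equal(cs$share_loss_gt_threshold, 20)  # -15 points < -10
    # identical years
    cs0 <- change_stats(t0, t0)
    expect_equal(cs0$share_unchanged, 100)
    expect_equal(cs0$share_increasing, 0)
    # invariance to adding non-forest cells
    mask <- matrix(TRUE, 10, 10)
    big_t0 <- rbind(t0, matrix(0.9, 3, 10))
    big_t1 <- rbind(t1, matrix(0.1, 3, 10))
    big_mask <- rbind(mask, matrix(FALSE, 3, 10))
    expect_equal(change_stats(big_t0, big_t1, forest_mask = big_mask),
                 cs)
  })
})

test_that("account rows reproduce constants and per-type means", {
  nr <- 12
  typ <- banded_typology(nr, nr, n_classes = 2, n_regions = 1)
  vars1 <- list(soc = matrix(0.4, nr, nr))
  vars <- list(year0 = vars1, year1 = list(soc = matrix(0.5, nr, nr)))
  levels <- tibble::tibble(
    type_id = rep(typ$catalogue$type_id, each = 1),
    variable = "soc", V_L = 0, V_H = 1, source_region = "r",
    fallback_used = FALSE, missing = FALSE, degenerate = FALSE)
  ind <- lapply(vars, rescale_variables, levels = levels, typology = typ)
  idx <- lapply(ind, aggregate_index, weights = c(soc = 1), typology = typ)
  acc <- build_account(typ, vars, levels, ind, idx)
  expect_equal(nrow(acc), 2 * 2)  # 2 types x 2 years x 1 variable
  y0 <- acc[acc$year == "year0", ]
  expect_true(all(y0$mean_value == 0.4))
  expect_true(all(y0$indicator_mean == 0.4))
  expect_true(all(y0$index == 0.4))
  y1 <- acc[acc$year == "year1", ]
  expect_true(all(y1$index == 0.5))
  expect_equal(unique(acc$area_ha), typ$catalogue$area_ha[1])

  # two-type oracle with heterogeneous values
  withr::with_seed(19, {
    g <- matrix(stats::runif(nr * nr), nr, nr)
    vars2 <- list(year0 = list(soc = g), year1 = list(soc = g))
    ind2 <- lapply(vars2, rescale_variables, levels = levels,
                   typology = typ)
    idx2 <- lapply(ind2, aggregate_index, weights = c(soc = 1),
                   typology = typ)
    acc2 <- build_account(typ, vars2, levels, ind2, idx2)
    for (t in typ$catalogue$type_id) {
      expect_equal(
        acc2$mean_value[acc2$type_id == t & acc2$year == "year0"],
        mean(g[typ$type_id == t]))
    }
  })
})

test_that("an empty typology yields an empty account", {
  typ <- build_typology(matrix(5L, 4, 4), matrix(1L, 4, 4))
  acc <- build_account(typ, list(year0 = list(), year1 = list()),
                       tibble::tibble(), list(year0 = list(),
                                              year1 = list()),
                       list(year0 = list(type_means = tibble::tibble(
                         type_id = integer(), index = numeric())),
                         year1 = list(type_means = tibble::tibble(
                           type_id = integer(), index = numeric()))))
  expect_equal(nrow(acc), 0)
})

test_that("a uniform shift is detected as a significant increase", {
  withr::with_seed(37, {
    typ <- banded_typology(60, 60, 1, 1)
    t0 <- matrix(stats::runif(3600, 0.4, 0.6), 60, 60)
    t1 <- t0 + 0.1
    res <- mwu_change_test(t0, t1, typ, n_samples = 300,
                           min_separation_cells = 2, seed = 1)
    expect_equal(res$direction, "increase")
    expect_lt(res$p_value, 0.001)
  })
})

test_that("thinned samples honour the minimum pairwise separation", {
  withr::with_seed(43, {
    cells <- as.matrix(expand.grid(r = 1:40, c = 1:40))
    take <- forestcond:::thin_cells(cells, n = 60, min_separation = 5,
                                    dims = c(40, 40))
    pts <- cells[take, , drop = FALSE]
    d <- as.matrix(stats::dist(pts))
    diag(d) <- Inf
    expect_true(all(d >= 5))
    expect_gt(length(take), 30)
  })
})

test_that("no systematic change stays mostly non-significant", {
  hits <- vapply(1:8, function(seed) {
    set.seed(seed + 100)
    typ <- banded_typology(40, 40, 1, 1)
    t0 <- matrix(stats::runif(1600), 40, 40)
    t1 <- matrix(stats::runif(1600), 40, 40)
    res <- mwu_change_test(t0, t1, typ, n_samples = 200,
                           min_separation_cells = 2, seed = seed)
    res$p_value < 0.05
  }, logical(1))
  expect_lte(sum(hits), 2)
})
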