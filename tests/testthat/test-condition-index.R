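test_that("rescaling clamps at the reference levels", {
  expect_equal(rescale_indicator(5, 5, 10), 0)
  expect_equal(rescale_indicator(12, 5, 10), 1)
  expect_equal(rescale_indicator(7.5, 5, 10), 0.5)
  expect_equal(rescale_indicator(3, 5, 10), 0)
  expect_error(rescale_indicator(5, 10, 5), "V_H")
  # degenerate levels flag the indicator as uninformative (0), not perfect
  expect_equal(rescale_indicator(c(1, 2, 3), 2, 2), c(0, 0, 0))
  m <- matrix(c(4, 6, 8, 10), 2, 2)
  expect_equal(rescale_indicator(m, 4, 8),
               matrix(c(0, 0.5, 1, 1), 2, 2))
})

test_that("rank sums convert to normalised weights", {
  single <- matrix(1:7, ncol = 1,
                   dimnames = list(paste0("v", 1:7), NULL))
  w <- weights_from_ranks(single)
  expect_equal(w$weight, (1:7) / 28)
  flat <- matrix(rep(c(1:7, 7:1), 2), ncol = 4,
                 dimnames = list(paste0("v", 1:7), NULL))
  expect_equal(weights_from_ranks(flat)$weight, rep(1 / 7, 7))
  withr::with_seed(2, {
    rm5 <- matrix(replicate(5, sample(7)), ncol = 5,
                  dimnames = list(paste0("v", 1:7), NULL))
    w5 <- weights_from_ranks(rm5)
    expect_equal(w5$weight, unname(rowSums(rm5)) / sum(rm5))
    expect_equal(sum(w5$weight), 1)
  })
  expect_error(weights_from_ranks(matrix(0:6, 7, 1,
                                         dimnames = list(1:7, NULL))),
               "ranks")
})

test_that("missing-indicator weights are redistributed proportionally", {
  w <- default_weights()
  expect_equal(sum(w), 1)
  w2 <- redistribute_missing(w, "soc")
  expect_equal(w2[["birds"]], 0.22 / 0.88)
  expect_equal(sum(w2), 1)
  expect_identical(redistribute_missing(w, character(0)), w)
  expect_error(redistribute_missing(w, names(w)), "all indicators")
})

test_that("aggregation matches the double-loop oracle per type", {
  withr::with_seed(23, {
    typ <- banded_typology(20, 20, n_classes = 2, n_regions = 1)
    vars <- list(a = matrix(stats::runif(400), 20),
                 b = matrix(stats::runif(400), 20),
                 c = matrix(stats::runif(400), 20))
    levels <- purrr::map_dfr(typ$catalogue$type_id, function(t)
      tibble::tibble(type_id = t, variable = c("a", "b", "c"),
                     V_L = 0, V_H = 1, fallback_used = FALSE,
                     missing = FALSE, degenerate = FALSE))
    w <- c(a = 0.5, b = 0.3, c = 0.2)
    ind <- rescale_variables(vars, levels, typ)
    agg <- aggregate_index(ind, w, typ)
    for (t in typ$catalogue$type_id) {
      expect_equal(agg$type_means$index[agg$type_means$type_id == t],
                   bf_type_index(vars, levels, typ, w, t),
                   tolerance = 1e-12)
    }
    # per-type mean equals the mean of per-cell indices (linearity)
    for (t in typ$catalogue$type_id) {
      expect_equal(agg$type_means$index[agg$type_means$type_id == t],
                   mean(agg$index[typ$type_id == t]), tolerance = 1e-12)
    }
  })
})

test_that("consensus cells take the consensus value for any weights", {
  typ <- banded_typology(6, 6, 1, 1)
  ind <- list(a = matrix(0.6, 6, 6), b = matrix(0.6, 6, 6),
              c = matrix(0.6, 6, 6))
  for (w in list(c(a = 1 / 3, b = 1 / 3, c = 1 / 3),
                 c(a = 0.7, b = 0.2, c = 0.1))) {
    agg <- aggregate_index(ind, w, typ)
    expect_equal(unique(as.vector(agg$index[typ$type_id > 0])), 0.6)
  }
})

test_that("the index is bounded and monotone in each indicator", {
  withr::with_seed(29, {
    typ <- banded_typology(10, 10, 1, 1)
    ind <- list(a = matrix(stats::runif(100), 10),
                b = matrix(stats::runif(100), 10))
    w <- c(a = 0.4, b = 0.6)
    agg <- aggregate_index(ind, w, typ)
    expect_true(all(agg$index >= 0 & agg$index <= 1))
    ind2 <- ind
    cell <- sample(100, 1)
    ind2$a[cell] <- min(1, ind2$a[cell] + 0.2)
    agg2 <- aggregate_index(ind2, w, typ)
    expect_true(all(agg2$index - agg$index >= -1e-12))
  })
})

test_that("a type-wide absent indicator triggers redistribution", {
  typ <- banded_typology(8, 8, 1, 2)  # two types (two regions)
  t_ids <- typ$catalogue$type_id
  ind <- list(a = matrix(0.4, 8, 8), b = matrix(0.8, 8, 8))
  ind$b[typ$type_id == t_ids[2]] <- NA  # structurally absent for type 2
  w <- c(a = 0.25, b = 0.75)
  agg <- aggregate_index(ind, w, typ)
  m <- agg$type_means
  expect_equal(m$index[m$type_id == t_ids[1]], 0.25 * 0.4 + 0.75 * 0.8)
  expect_equal(m$index[m$type_id == t_ids[2]], 0.4)  # weight all on a
  expect_equal(agg$weights_by_type[[as.character(t_ids[2])]],
               c(a = 1))
})
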