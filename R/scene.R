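# Synthetic scenes: fully simulated landscapes with the statistical structure
# the accounting pipeline assumes -- four forest land-cover classes crossed
# with biogeographic regions, spatially autocorrelated condition variables
# that are stochastically higher inside designated reference sites, sparse
# tree-cover-loss patches, environmental gradients correlated with
# reference-site placement, and over-dispersed bird counts generated from a
# known log-linear model (kept with the scene for parameter-recovery tests).

LAND_COVER_CODES <- c(
  broadleaved = 1L, coniferous = 2L, mixed = 3L, transitional = 4L,
  agriculture = 5L, natural_open = 6L, developed = 7L
)
FOREST_CLASSES <- LAND_COVER_CODES[1:4]

#' Canonical biogeographic region names
#'
#' The eleven European biogeographic zones used by the forest typology, with
#' the Alpine region split into its Scandinavian and non-Scandinavian parts.
#'
#' @return character vector of length 11.
#' @export
region_names_default <- function() {
  c("Alpine", "Alpine-Scandinavia", "Arctic", "Atlantic", "BlackSea",
    "Boreal", "Continental", "Macaronesian", "Mediterranean", "Pannonian",
    "Steppic")
}

#' Native value ranges of the condition variables
#'
#' @return named list of `c(min, max)` per variable: NDWI and NDVI in
#'   \[-1, 1\], soil organic carbon in \[0, 1\], threatened-bird richness in
#'   \[0, 22\], tree cover density, forest area density and landscape
#'   naturalness in \[0, 100\].
#' @export
variable_ranges <- function() {
  list(
    ndwi  = c(-1, 1),
    soc   = c(0, 1),
    birds = c(0, 22),
    trees = c(0, 100),
    ndvi  = c(-1, 1),
    fad   = c(0, 100),
    lm    = c(0, 100)
  )
}

#' Names of the bird-model predictor variables
#'
#' @param with_coords include longitude and latitude (the raw 17-predictor
#'   set before collinearity pruning)?
#' @return character vector of 15 (or 17) predictor names.
#' @export
bird_predictor_names <- function(with_coords = FALSE) {
  p <- c("temperature_mean", "temperature_seasonality",
         "precipitation_annual", "precipitation_seasonality", "altitude",
         "share_urban", "share_cropland", "share_forest", "share_shrubland",
         "share_rivers", "share_sparse_veg", "share_grassland", "lc_shannon",
         "ndvi_summer_mean", "ndvi_summer_range")
  if (with_coords) c(p, "longitude", "latitude") else p
}

default_variable_params <- function() {
  list(
    ndwi  = list(mean = 0.35, sd = 0.12, range_cells = 4),
    soc   = list(mean = 0.25, sd = 0.10, range_cells = 5),
    birds = list(mean = 5.0,  sd = 2.2,  range_cells = 4),
    trees = list(mean = 55,   sd = 16,   range_cells = 4),
    ndvi  = list(mean = 0.55, sd = 0.12, range_cells = 4)
  )
}

default_reference_uplift <- function() {
  c(ndwi = 0.08, soc = 0.10, birds = 2.0, trees = 12, ndvi = 0.08)
}

default_drift <- function() {
  # mild mean improvement between the two accounting years, plus spatial noise
  list(mean = c(ndwi = 0.01, soc = 0.005, birds = 0.3, trees = 1.5,
                ndvi = 0.015),
       sd = c(ndwi = 0.02, soc = 0.01, birds = 0.6, trees = 3, ndvi = 0.03))
}

#' Configuration for a synthetic scene
#'
#' @param grid_shape integer `(rows, cols)` in cells.
#' @param cell_area hectares per cell (default 1 ha, i.e. 100 m cells).
#' @param n_regions number of biogeographic regions, 1 to 11.
#' @param forest_fraction proportion of the grid covered by forest classes.
#' @param reference_fraction proportion of forest cells designated as
#'   reference-site polygons.
#' @param loss_fraction proportion of forest cells flagged as post-2000
#'   tree-cover loss.
#' @param variable_params per-variable `list(mean, sd, range_cells)` on the
#'   variable's native scale; defaults are realistic for European forests.
#' @param reference_uplift named additive shift applied to each variable
#'   inside reference polygons; a single number is recycled.
#' @param drift `list(mean, sd)` of the named per-variable year0 -> year1
#'   drift field.
#' @param n_bird_cells rows in the simulated bird-observation table.
#' @param bird_truth generating model for bird counts, see
#'   [generate_bird_truth()]; `NULL` uses the default truth.
#' @param seed integer seed controlling all randomness.
#' @return a `fc_scene_config` list.
#' @export
scene_config <- function(grid_shape = c(96, 96), cell_area = 1,
                         n_regions = 11, forest_fraction = 0.6,
                         reference_fraction = 0.08, loss_fraction = 0.03,
                         variable_params = default_variable_params(),
                         reference_uplift = default_reference_uplift(),
                         drift = default_drift(),
                         n_bird_cells = 2000, bird_truth = NULL, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2 || any(grid_shape <= 0)) {
    stop("grid_shape must be two positive integers", call. = FALSE)
  }
  for (f in c(forest_fraction, reference_fraction, loss_fraction)) {
    if (!is.numeric(f) || f < 0 || f > 1) {
      stop("fractions must lie in [0, 1]", call. = FALSE)
    }
  }
  if (n_regions < 1 || n_regions > 11) {
    stop("n_regions must be between 1 and 11", call. = FALSE)
  }
  vars <- names(default_variable_params())
  if (length(reference_uplift) == 1 && is.null(names(reference_uplift))) {
    reference_uplift <- stats::setNames(rep(reference_uplift, length(vars)),
                                        vars)
  }
  stopifnot(all(vars %in% names(variable_params)),
            all(vars %in% names(reference_uplift)))
  structure(list(
    grid_shape = grid_shape, cell_area = cell_area, n_regions = n_regions,
    forest_fraction = forest_fraction,
    reference_fraction = reference_fraction, loss_fraction = loss_fraction,
    variable_params = variable_params, reference_uplift = reference_uplift,
    drift = drift, n_bird_cells = as.integer(n_bird_cells),
    bird_truth = bird_truth, seed = as.integer(seed)
  ), class = "fc_scene_config")
}

# run code under a fixed seed without clobbering the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

unit_field <- function(nr, nc, range_cells) {
  f <- smooth_gaussian(matrix(stats::rnorm(nr * nc), nr, nc), range_cells)
  (f - mean(f)) / stats::sd(f)
}

#' True generating model for the simulated bird counts
#'
#' Returns the log-linear quasi-Poisson truth used by [generate_scene()]:
#' three active predictors (forest share, mean summer NDVI, altitude), one
#' quadratic term (altitude, centred), and over-dispersion 2. Kept alongside
#' each scene so that model-recovery tests can compare fitted terms and
#' coefficients against the truth.
#'
#' @param config optional [scene_config()]; its `bird_truth` field overrides
#'   the default.
#' @return list with `coefficients` (named, including `(Intercept)` and one
#'   `<var>_sq` quadratic), `linear_terms`, `quadratic_terms`, `dispersion`.
#' @export
generate_bird_truth <- function(config = NULL) {
  truth <- list(
    coefficients = c(`(Intercept)` = log(5), share_forest = 0.35,
                     ndvi_summer_mean = 0.25, altitude = 0.30,
                     altitude_sq = -0.15),
    linear_terms = c("share_forest", "ndvi_summer_mean", "altitude"),
    quadratic_terms = "altitude",
    dispersion = 2
  )
  if (!is.null(config) && !is.null(config$bird_truth)) {
    truth <- utils::modifyList(truth, config$bird_truth)
  }
  truth
}

#' Simulate over-dispersed counts from a bird truth model
#'
#' Counts follow a quasi-Poisson scheme: mean `mu = exp(linear predictor)`
#' and variance `dispersion * mu`, realised as negative binomial draws with
#' `size = mu / (dispersion - 1)` (exact Poisson when `dispersion = 1`).
#'
#' @param predictors data frame of predictor columns (quadratic terms are
#'   built internally from the centred square of the named predictor).
#' @param truth list as returned by [generate_bird_truth()].
#' @return integer vector of counts.
#' @export
simulate_bird_counts <- function(predictors, truth) {
  co <- truth$coefficients
  lp <- rep(co[["(Intercept)"]], nrow(predictors))
  for (term in setdiff(names(co), "(Intercept)")) {
    if (grepl("_sq$", term)) {
      base <- sub("_sq$", "", term)
      x <- predictors[[base]]
      lp <- lp + co[[term]] * (x - mean(x))^2
    } else {
      lp <- lp + co[[term]] * predictors[[term]]
    }
  }
  mu <- exp(lp)
  phi <- truth$dispersion
  if (phi <= 1) {
    stats::rpois(length(mu), mu)
  } else {
    stats::rnbinom(length(mu), size = mu / (phi - 1), mu = mu)
  }
}

simulate_bird_table <- function(n, truth) {
  p15 <- bird_predictor_names()
  X <- as.data.frame(matrix(stats::rnorm(n * length(p15)), n,
                            dimnames = list(NULL, p15)))
  # longitude/latitude planted collinear (>0.7) with the two climate terms,
  # mirroring why coordinates get pruned before modelling
  X$longitude <- 0.85 * X$temperature_seasonality +
    sqrt(1 - 0.85^2) * stats::rnorm(n)
  X$latitude <- -0.85 * X$temperature_mean + sqrt(1 - 0.85^2) * stats::rnorm(n)
  threatened <- simulate_bird_counts(X, truth)
  total <- threatened + stats::rpois(n, 5)
  tibble::as_tibble(cbind(
    data.frame(cell_id = seq_len(n), total_richness = total,
               threatened_richness = threatened), X))
}

rect_polygon <- function(r0, r1, c0, c1, nr) {
  # closed ring in map coordinates (y increases northward)
  x0 <- c0 - 1; x1 <- c1; y0 <- nr - r1; y1 <- nr - r0 + 1
  cbind(x = c(x0, x1, x1, x0, x0), y = c(y0, y0, y1, y1, y0))
}

#' Generate a synthetic scene
#'
#' Builds a complete co-registered bundle: land cover (4 forest classes plus
#' agriculture / natural open / developed), contiguous region bands, five
#' condition-variable grids for two accounting years (an additive drift field
#' separates the years), canopy cover, a sparse loss mask, environmental
#' grids (elevation, slope, temperature, rainfall), a potential-natural-
#' vegetation grid, reference polygons (rasterised rectangular blobs,
#' preferentially placed at high elevation so reference sites carry an
#' environmental signature), and a simulated bird-observation table with its
#' generating truth. Deterministic given `config$seed`.
#'
#' @param config a [scene_config()].
#' @return an `fc_scene` list; see the package vignette for the layout.
#' @export
generate_scene <- function(config = scene_config()) {
  if (!inherits(config, "fc_scene_config")) {
    stop("config must be created with scene_config()", call. = FALSE)
  }
  with_seed(config$seed, {
    nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
    n_cells <- nr * nc

    # --- land cover -------------------------------------------------------
    suit <- unit_field(nr, nc, 5)
    forest <- if (config$forest_fraction <= 0) {
      matrix(FALSE, nr, nc)
    } else if (config$forest_fraction >= 1) {
      matrix(TRUE, nr, nc)
    } else {
      suit >= stats::quantile(suit, 1 - config$forest_fraction)
    }
    class_field <- unit_field(nr, nc, 6)
    class_cut <- findInterval(
      class_field, stats::quantile(class_field, c(0.25, 0.5, 0.75))) + 1L
    nonforest_field <- unit_field(nr, nc, 5)
    nf_cut <- findInterval(
      nonforest_field, stats::quantile(nonforest_field, c(0.5, 0.9))) + 1L
    land_cover <- matrix(0L, nr, nc)
    land_cover[forest] <- class_cut[forest]
    land_cover[!forest] <- c(LAND_COVER_CODES[["agriculture"]],
                             LAND_COVER_CODES[["natural_open"]],
                             LAND_COVER_CODES[["developed"]])[nf_cut[!forest]]
    # guarantee every forest class occurs whenever any forest exists
    if (any(forest)) {
      for (k in seq_along(FOREST_CLASSES)) {
        if (!any(land_cover[forest] == k)) {
          cell <- sample(which(forest), 1)
          land_cover[cell] <- k
        }
      }
    }

    # --- regions: contiguous column bands ---------------------------------
    region_of_col <- ceiling(config$n_regions * seq_len(nc) / nc)
    regions <- matrix(rep(region_of_col, each = nr), nr, nc)

    # --- environment ------------------------------------------------------
    elevation <- 800 + 600 * unit_field(nr, nc, 7)
    elevation <- clamp(elevation, 0, 3000)
    slope <- clamp(8 + 6 * unit_field(nr, nc, 4) +
                     4 * abs(unit_field(nr, nc, 2)), 0, 45)
    temperature <- 14 - 0.006 * elevation + 1.5 * unit_field(nr, nc, 6)
    rainfall <- clamp(900 + 0.25 * elevation + 180 * unit_field(nr, nc, 6),
                      200, 2500)

    # --- reference polygons (high-elevation biased blobs) -----------------
    forest_idx <- which(forest)
    target_ref <- round(config$reference_fraction * length(forest_idx))
    in_ref <- matrix(FALSE, nr, nc)
    polys <- list()
    # regions that depend on fallback donors hold no sites of their own,
    # the remaining regions receive polygons in turn (high-elevation biased)
    rg_names <- region_names_default()[seq_len(config$n_regions)]
    eligible_rg <- which(!rg_names %in% names(default_fallback_map()))
    eligible_rg <- eligible_rg[vapply(eligible_rg, function(g)
      any(regions[forest_idx] == g), logical(1))]
    if (length(eligible_rg) == 0 && length(forest_idx) > 0) {
      eligible_rg <- sort(unique(regions[forest_idx]))
    }
    # one candidate pool per occurring (region, class) pair so every type
    # in a site-holding region can receive reference cells
    pools <- list()
    pool_regions <- integer(0)
    for (rg in eligible_rg) {
      for (cls in seq_along(FOREST_CLASSES)) {
        pool <- forest_idx[regions[forest_idx] == rg &
                             land_cover[forest_idx] == cls]
        if (length(pool) > 0) {
          pools[[length(pools) + 1]] <- pool
          pool_regions <- c(pool_regions, rg)
        }
      }
    }
    if (target_ref > 0 && length(pools) > 0) {
      # size polygons so two rounds over the pools roughly meet the target
      # (two per pool keeps types covered when a polygon is later rejected)
      base_half <- clamp(round(sqrt(target_ref / (2 * length(pools))) / 2),
                         1, 5)
      iter <- 0
      while ((sum(in_ref) < target_ref || iter < 2 * length(pools)) &&
             iter < max(300, 3 * length(pools))) {
        iter <- iter + 1
        k <- (iter - 1) %% length(pools) + 1
        pool <- pools[[k]]
        rg <- pool_regions[k]
        band <- range(which(region_of_col == rg))
        w <- rank(elevation[pool])^2
        centre <- pool[sample.int(length(pool), 1, prob = w)]
        rc <- arrayInd(centre, c(nr, nc))
        hr <- clamp(base_half + sample(-1:1, 1), 1, 5)
        hw <- clamp(base_half + sample(-1:1, 1), 1, 5)
        r0 <- max(1, rc[1] - hr); r1 <- min(nr, rc[1] + hr)
        c0 <- max(band[1], rc[2] - hw); c1 <- min(band[2], rc[2] + hw)
        in_ref[r0:r1, c0:c1] <- TRUE
        origin <- if (stats::runif(1) < 0.6) "primary" else "protected"
        iucn <- if (origin == "primary") NA_character_ else
          sample(c("Ia", "Ib", "II", "IV"), 1,
                 prob = c(0.3, 0.2, 0.4, 0.1))
        polys[[length(polys) + 1]] <- list(
          origin = origin, iucn = iucn,
          coords = rect_polygon(r0, r1, c0, c1, nr))
      }
    }
    reference_polygons <- tibble::tibble(
      polygon_id = seq_along(polys),
      origin = vapply(polys, `[[`, character(1), "origin"),
      iucn_category = vapply(polys, `[[`, character(1), "iucn"),
      coords = lapply(polys, `[[`, "coords")
    )

    # --- loss mask: small disturbance patches -----------------------------
    loss_mask <- matrix(FALSE, nr, nc)
    target_loss <- round(config$loss_fraction * length(forest_idx))
    if (target_loss > 0 && length(forest_idx) > 0) {
      while (sum(loss_mask & forest) < target_loss) {
        seed_cell <- forest_idx[sample.int(length(forest_idx), 1)]
        rc <- arrayInd(seed_cell, c(nr, nc))
        h <- sample(0:1, 1)
        loss_mask[max(1, rc[1] - h):min(nr, rc[1] + h),
                  max(1, rc[2] - h):min(nc, rc[2] + h)] <- TRUE
      }
    }

    # --- condition variables, two accounting years ------------------------
    ranges <- variable_ranges()
    year0 <- list(); year1 <- list()
    for (v in names(config$variable_params)) {
      p <- config$variable_params[[v]]
      base <- p$mean + p$sd * unit_field(nr, nc, p$range_cells)
      base <- base + config$reference_uplift[[v]] * in_ref
      driftf <- config$drift$mean[[v]] +
        config$drift$sd[[v]] * unit_field(nr, nc, p$range_cells)
      year0[[v]] <- clamp(base, ranges[[v]][1], ranges[[v]][2])
      year1[[v]] <- clamp(base + driftf, ranges[[v]][1], ranges[[v]][2])
    }

    # canopy cover tracks tree cover density inside forest, sparse outside
    canopy <- matrix(clamp(10 + 6 * stats::rnorm(n_cells), 0, 100), nr, nc)
    canopy[forest] <- clamp(year0$trees[forest] + 5 * stats::rnorm(sum(forest)),
                            0, 100)
    # loss depresses year-1 tree cover where it struck
    year1$trees <- clamp(year1$trees - 25 * (loss_mask & forest),
                         ranges$trees[1], ranges$trees[2])

    # --- potential natural vegetation: mostly matches observed classes ----
    pnv <- matrix(class_cut, nr, nc)
    mismatch <- unit_field(nr, nc, 6)
    flip <- mismatch > stats::quantile(mismatch, 0.75)
    pnv[flip] <- (pnv[flip] %% 4L) + 1L

    # --- birds ------------------------------------------------------------
    truth <- generate_bird_truth(config)
    bird_obs <- simulate_bird_table(config$n_bird_cells, truth)

    structure(list(
      config = config,
      land_cover = land_cover,
      regions = regions,
      region_names = region_names_default()[seq_len(config$n_regions)],
      variables = list(year0 = year0, year1 = year1),
      canopy_cover = canopy,
      loss_mask = loss_mask,
      elevation = elevation, slope = slope,
      temperature = temperature, rainfall = rainfall,
      pnv = pnv,
      designated_reference = in_ref,
      reference_polygons = reference_polygons,
      bird_obs = bird_obs,
      bird_truth = truth
    ), class = "fc_scene")
  })
}

#' @export
print.fc_scene <- function(x, ...) {
  dims <- dim(x$land_cover)
  cat("<fc_scene> ", dims[1], "x", dims[2], " cells, ",
      sum(x$land_cover %in% FOREST_CLASSES), " forest cells, ",
      nrow(x$reference_polygons), " reference polygons, seed ",
      x$config$seed, "\n", sep = "")
  invisible(x)
}
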