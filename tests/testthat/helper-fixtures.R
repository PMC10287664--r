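# Shared fixtures, built in code.

# a small scene that exercises every stage quickly
small_config <- function(seed = 1, n_bird_cells = 400, ...) {
  scene_config(grid_shape = c(48, 48), n_regions = 4,
               n_bird_cells = n_bird_cells, seed = seed, ...)
}

# brute-force moving-window proportion (double loop), the independent oracle
# for window_proportion()
bf_window_proportion <- function(mask, size, edge_rule = "shrink") {
  h <- (size - 1) / 2
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      rs <- max(1, r - h):min(nr, r + h)
      cs <- max(1, c - h):min(nc, c + h)
      den <- if (edge_rule == "shrink") length(rs) * length(cs) else size^2
      out[r, c] <- 100 * sum(mask[rs, cs]) / den
    }
  }
  out
}

# closed rectangle ring in map coordinates covering cells r0..r1 x c0..c1
rect_ring <- function(r0, r1, c0, c1, nr) {
  x0 <- c0 - 1; x1 <- c1; y0 <- nr - r1; y1 <- nr - r0 + 1
  cbind(x = c(x0, x1, x1, x0, x0), y = c(y0, y0, y1, y1, y0))
}

# tiny typology built from explicit class/region bands
banded_typology <- function(nr = 20, nc = 20, n_classes = 2, n_regions = 2,
                            cell_area = 1) {
  land_cover <- matrix(rep(rep(seq_len(n_classes),
                               each = ceiling(nr / n_classes))[seq_len(nr)],
                           nc), nr, nc)
  regions <- matrix(rep(rep(seq_len(n_regions),
                            each = ceiling(nc / n_regions))[seq_len(nc)],
                        each = nr), nr, nc)
  build_typology(land_cover, regions, cell_area)
}

# independent single-type index recomputation: naive per-cell loops over
# Eq. 1 (clamped rescale) and Eq. 3 (weighted mean), used as the oracle for
# aggregate_index() and run_oat()
bf_type_index <- function(variables, levels, typology, weights, type) {
  idx <- which(typology$type_id == type)
  vars <- names(weights)
  lv <- levels[levels$type_id == type, ]
  present <- vars[vapply(vars, function(v) {
    row <- lv[lv$variable == v, ]
    nrow(row) == 1 && !is.na(row$V_H)
  }, logical(1))]
  if (length(present) == 0) return(NA_real_)
  w <- weights[present] / sum(weights[present])
  vals <- vapply(idx, function(i) {
    s <- 0
    for (v in present) {
      row <- lv[lv$variable == v, ]
      x <- variables[[v]][i]
      ind <- if (row$V_H == row$V_L) 0 else
        min(max((x - row$V_L) / (row$V_H - row$V_L), 0), 1)
      s <- s + w[[v]] * ind
    }
    s
  }, numeric(1))
  mean(vals)
}
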