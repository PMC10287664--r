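# Grids are plain base-R matrices. Registration convention used throughout the
# package: row 1 is the northern (top) edge, column 1 the western edge, cells
# are squares of `cell_area` hectares (default 1 ha, i.e. 100 m cells). The
# centre of cell (r, c) sits at map coordinates x = c - 0.5, y = nrow - r + 0.5
# measured in cell units.

#' Check that grids share shape and registration
#'
#' @param ... matrices to compare.
#' @return Invisibly, the common `dim()`.
#' @keywords internal
assert_coregistered <- function(...) {
  grids <- list(...)
  grids <- grids[!vapply(grids, is.null, logical(1))]
  dims <- lapply(grids, dim)
  if (length(dims) == 0) return(invisible(NULL))
  ref <- dims[[1]]
  ok <- vapply(dims, function(d) identical(d, ref), logical(1))
  if (!all(ok)) {
    stop("grids are not co-registered: shapes ",
         paste(vapply(dims, function(d) paste(d, collapse = "x"),
                      character(1)), collapse = ", "),
         call. = FALSE)
  }
  invisible(ref)
}

#' Smooth a grid with a Gaussian kernel
#'
#' Produces spatially autocorrelated fields by separable Gaussian convolution.
#' Edges are renormalised (the kernel mass falling outside the grid is
#' discarded and the remaining weights rescaled), so no artificial darkening
#' occurs at map borders.
#'
#' @param m numeric matrix.
#' @param range_cells kernel standard deviation in cells; `0` returns the
#'   input unchanged.
#' @return A matrix of the same shape.
#' @export
smooth_gaussian <- function(m, range_cells) {
  stopifnot(is.matrix(m), range_cells >= 0)
  if (range_cells == 0) return(m)
  band <- function(n) {
    idx <- seq_len(n)
    k <- stats::dnorm(outer(idx, idx, "-"), sd = range_cells)
    k / rowSums(k)  # row-normalised: handles edges exactly
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

#' Moving-window sums via a summed-area table
#'
#' @param m numeric matrix (logical is coerced).
#' @param size odd window side length in cells.
#' @return list with `sum` (window sums, shrunk at edges) and `count`
#'   (number of in-bounds cells in each window).
#' @keywords internal
window_sums <- function(m, size) {
  if (size %% 2 != 1 || size < 1) {
    stop("window size must be an odd positive integer, got ", size,
         call. = FALSE)
  }
  m <- m * 1
  nr <- nrow(m); nc <- ncol(m)
  h <- (size - 1) / 2
  # integral image with a zero border
  s <- matrix(0, nr + 1, nc + 1)
  s[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  r1 <- pmax(seq_len(nr) - h, 1); r2 <- pmin(seq_len(nr) + h, nr)
  c1 <- pmax(seq_len(nc) - h, 1); c2 <- pmin(seq_len(nc) + h, nc)
  sums <- s[r2 + 1, c2 + 1, drop = FALSE] - s[r1, c2 + 1, drop = FALSE] -
    s[r2 + 1, c1, drop = FALSE] + s[r1, c1, drop = FALSE]
  counts <- outer(r2 - r1 + 1, c2 - c1 + 1)
  list(sum = sums, count = counts)
}

#' Proportion of marked cells in a moving window
#'
#' For every grid cell, the percentage of `mask` cells that are `TRUE` within
#' a square window centred on the cell. This is the primitive behind both the
#' forest area density (connectivity) metric and landscape naturalness, where
#' a 23 x 23 window of 1-ha cells spans the 529 ha neighbourhood.
#'
#' @param mask logical (or 0/1) matrix of marked cells.
#' @param size odd window side length in cells (default 23).
#' @param edge_rule `"shrink"` (default) divides by the number of in-bounds
#'   window cells; `"pad-zero"` always divides by `size^2`, treating
#'   out-of-bounds cells as unmarked.
#' @param domain optional logical matrix; cells outside it are set to `NA`
#'   in the result.
#' @return numeric matrix of percentages in \[0, 100\].
#' @export
window_proportion <- function(mask, size = 23,
                              edge_rule = c("shrink", "pad-zero"),
                              domain = NULL) {
  edge_rule <- match.arg(edge_rule)
  stopifnot(is.matrix(mask))
  assert_coregistered(mask, domain)
  ws <- window_sums(mask, size)
  denom <- if (edge_rule == "shrink") ws$count else size^2
  pct <- 100 * ws$sum / denom
  if (!is.null(domain)) pct[!domain] <- NA_real_
  pct
}

#' Hectares covered by a square window
#'
#' @param size odd window side length in cells.
#' @param cell_area hectares per cell.
#' @return window area in hectares (529 for the default 23-cell window of
#'   1-ha cells).
#' @export
window_area_ha <- function(size = 23, cell_area = 1) {
  if (size %% 2 != 1 || size < 1) stop("window size must be odd and >= 1")
  size^2 * cell_area
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Write a grid as an ESRI ASCII raster
#'
#' Plain-text single-band raster with the standard six-line header. `NA` cells
#' are written as the nodata value.
#'
#' @param m matrix to write (top row = north).
#' @param path output file.
#' @param cellsize cell edge length in map units (default 100, i.e. 1-ha
#'   cells in metres).
#' @param nodata nodata sentinel.
#' @return `path`, invisibly.
#' @export
write_grid_asc <- function(m, path, cellsize = 100, nodata = -9999) {
  stopifnot(is.matrix(m))
  m <- m * 1
  m[is.na(m)] <- nodata
  header <- c(
    paste("ncols", ncol(m)),
    paste("nrows", nrow(m)),
    paste("xllcorner", 0),
    paste("yllcorner", 0),
    paste("cellsize", cellsize),
    paste("NODATA_value", nodata)
  )
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an ESRI ASCII raster written by [write_grid_asc()]
#'
#' @param path file to read.
#' @return numeric matrix with nodata cells as `NA`.
#' @export
read_grid_asc <- function(path) {
  lines <- readLines(path)
  header <- lines[1:6]
  val <- function(key) {
    ln <- header[grepl(paste0("^", key), header, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  nc <- val("ncols"); nr <- val("nrows"); nodata <- val("NODATA_value")
  body <- strsplit(trimws(lines[-(1:6)]), "\\s+")
  m <- matrix(as.numeric(unlist(body)), nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  m
}
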