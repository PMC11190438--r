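#' Hexagonal cell lattice
#'
#' Builds the adjacency structure of a hexagonal grid of cells in
#' "odd-r" offset layout (odd rows shifted right by half a cell).
#' Interior cells have six neighbours; boundary cells keep only their
#' geometric neighbours unless `periodic = TRUE`, in which case the grid
#' wraps in both directions.
#'
#' Cells are indexed row-major: cell `(i, j)` (row `i`, column `j`,
#' 1-based) has linear index `(i - 1) * cols + j`.
#'
#' @param rows,cols Grid extents in cells (each >= 1).
#' @param periodic Wrap neighbour relations around the boundary.
#' @return An object of class `hex_lattice`: a list with `rows`, `cols`,
#'   `periodic`, `n_cells`, `cell_ids` (labels `"rXX_cYY"`) and
#'   `neighbours`, a list of integer vectors of linear cell indices.
#' @examples
#' lat <- hex_lattice(10, 6)
#' lengths(lat$neighbours)[1:6]
#' @export
hex_lattice <- function(rows, cols, periodic = FALSE) {
  stopifnot(rows >= 1, cols >= 1, rows == round(rows), cols == round(cols))
  rows <- as.integer(rows)
  cols <- as.integer(cols)

  idx <- function(i, j) (i - 1L) * cols + j
  neighbours <- vector("list", rows * cols)

  # odd-r offset: neighbour column offsets depend on row parity
  off_even <- cbind(c(-1L, -1L, 0L, 0L, 1L, 1L), c(-1L, 0L, -1L, 1L, -1L, 0L))
  off_odd  <- cbind(c(-1L, -1L, 0L, 0L, 1L, 1L), c(0L, 1L, -1L, 1L, 0L, 1L))

  for (i in seq_len(rows)) {
    off <- if ((i - 1L) %% 2L == 0L) off_even else off_odd
    for (j in seq_len(cols)) {
      ni <- i + off[, 1L]
      nj <- j + off[, 2L]
      if (periodic) {
        ni <- ((ni - 1L) %% rows) + 1L
        nj <- ((nj - 1L) %% cols) + 1L
      }
      ok <- ni >= 1L & ni <= rows & nj >= 1L & nj <= cols
      nb <- sort(unique(idx(ni[ok], nj[ok])))
      neighbours[[idx(i, j)]] <- nb[nb != idx(i, j)]
    }
  }

  ids <- as.vector(t(outer(seq_len(rows), seq_len(cols),
                           function(i, j) sprintf("r%02d_c%02d", i, j))))
  structure(
    list(rows = rows, cols = cols, periodic = periodic,
         n_cells = rows * cols, cell_ids = ids, neighbours = neighbours),
    class = "hex_lattice"
  )
}

#' @export
print.hex_lattice <- function(x, ...) {
  cat(sprintf("<hex_lattice %d x %d (%s), %d cells>\n", x$rows, x$cols,
              if (x$periodic) "periodic" else "bounded", x$n_cells))
  invisible(x)
}

#' Mean protein level over a cell's lattice neighbours
#'
#' @param p Numeric vector of per-cell protein levels, one per lattice cell.
#' @param lattice A [hex_lattice()].
#' @param cell Linear cell index (or vector of indices); defaults to all
#'   cells.
#' @return Mean of `p` over each requested cell's neighbour set.
#' @export
neighbour_average <- function(p, lattice, cell = seq_len(lattice$n_cells)) {
  stopifnot(inherits(lattice, "hex_lattice"), length(p) == lattice$n_cells)
  if (any(cell < 1 | cell > lattice$n_cells)) {
    stop("cell index out of range")
  }
  vapply(cell, function(c) {
    nb <- lattice$neighbours[[c]]
    if (length(nb) == 0L) stop("cell ", c, " has an empty neighbour set")
    mean(p[nb])
  }, numeric(1))
}
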