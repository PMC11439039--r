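# Hexagonal lattice machinery -------------------------------------------------
#
# Benzenoid patches (nanocone flakes, flat nanotube lattices, the benzenoid
# catalogue) are all built as unions of hexagonal cells on the infinite
# honeycomb lattice. Cells are addressed by axial coordinates (q, r); the six
# corners of the cell at (q, r) live at integer points (3q, q + 2r) + offset,
# with offsets (2,0), (1,1), (-1,1), (-2,0), (-1,-1), (1,-1). Adjacent cells
# (axial offsets (1,0), (0,1), (-1,1), (-1,0), (0,-1), (1,-1)) share exactly
# one edge, so the union of cell boundaries is the benzenoid skeleton.

HEX_CORNERS <- rbind(c(2, 0), c(1, 1), c(-1, 1), c(-2, 0), c(-1, -1), c(1, -1))

#' Build a benzenoid patch from hexagon-cell coordinates
#'
#' Low-level generator shared by [make_nanocone()], the flat nanotube lattice
#' of [make_zigzag_nanotube()] and [benzenoid_catalogue()]. Vertices are
#' numbered deterministically (sorted by lattice position), so repeated calls
#' give identical graphs.
#'
#' @param cells Two-column matrix of axial hexagon coordinates (q, r), one
#'   hexagonal ring per row.
#' @return A `molecular_graph`.
#' @export
hexagonal_patch <- function(cells) {
  cells <- as_edge_matrix(cells)  # reuses the 2-column coercion/validation
  if (nrow(cells) == 0L) stop("at least one hexagon cell is required")
  if (anyDuplicated(paste(cells[, 1L], cells[, 2L])))
    stop("duplicate hexagon cell")
  # corner points of every cell, as complex keys x + yi
  cx <- 3 * cells[, 1L]
  cy <- cells[, 1L] + 2 * cells[, 2L]
  pts <- complex(real = rep(cx, each = 6L) + rep(HEX_CORNERS[, 1L], nrow(cells)),
                 imaginary = rep(cy, each = 6L) + rep(HEX_CORNERS[, 2L], nrow(cells)))
  keys <- unique(pts)
  keys <- keys[order(Re(keys), Im(keys))]
  id <- seq_along(keys) - 1L
  names(id) <- as.character(keys)
  v <- matrix(id[as.character(pts)], ncol = 6L, byrow = TRUE)
  e <- rbind(cbind(v[, 1L], v[, 2L]), cbind(v[, 2L], v[, 3L]),
             cbind(v[, 3L], v[, 4L]), cbind(v[, 4L], v[, 5L]),
             cbind(v[, 5L], v[, 6L]), cbind(v[, 6L], v[, 1L]))
  e <- unique(cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L])))
  build_graph(length(keys), e)
}

# Cell coordinates of the flat zigzag polyhex lattice ZC6[m, n]:
# n columns of hexagons, alternating m and m - 1 per column, each odd column
# nestled between its neighbours so the strip stays straight.
zigzag_lattice_cells <- function(m, n) {
  cells <- NULL
  for (j in seq_len(n) - 1L) {
    if (j %% 2L == 0L) {
      s <- -(j %/% 2L); k <- m
    } else {
      s <- -((j - 1L) %/% 2L); k <- m - 1L
    }
    cells <- rbind(cells, cbind(j, s + seq_len(k) - 1L))
  }
  cells
}

#' Generate a zigzag polyhex nanotube graph
#'
#' Two geometries are available. `"lattice"` (default) is the flat 2D polyhex
#' lattice of the tube: `n` columns of hexagons alternating `m` and `m - 1`
#' rings per column — the structure whose descriptor series this package's
#' reference tables validate against. `"cylinder"` closes the lattice into a
#' tube: `n + 1` rings of `2m` atoms (full cycles) joined by `m` axial bonds
#' per gap at alternating positions, giving `2m(n+1)` vertices and `m(3n+2)`
#' edges.
#'
#' @param m Hexagons per row (around the circumference); `m >= 2`.
#' @param n Hexagons per column (along the axis); `n >= 1`.
#' @param geometry `"lattice"` or `"cylinder"`.
#' @param transpose Swap the roles of `m` and `n`.
#' @return A `molecular_graph` (connected, simple, bipartite, max degree 3).
#' @export
make_zigzag_nanotube <- function(m, n, geometry = c("lattice", "cylinder"),
                                 transpose = FALSE) {
  geometry <- match.arg(geometry)
  m <- as.integer(m); n <- as.integer(n)
  if (isTRUE(transpose)) { tmp <- m; m <- n; n <- tmp }
  if (is.na(m) || m < 2L) stop("`m` must be at least 2 (cylinder undefined)")
  if (is.na(n) || n < 1L) stop("`n` must be at least 1")
  if (geometry == "lattice")
    return(hexagonal_patch(zigzag_lattice_cells(m, n)))
  # cylinder: rings j = 0..n of 2m atoms, vertex id = 2m*j + i
  two_m <- 2L * m
  vid <- function(i, j) two_m * j + (i %% two_m)
  ring <- do.call(rbind, lapply(0:n, function(j)
    cbind(vid(0:(two_m - 1L), j), vid(1:two_m, j))))
  vert <- NULL
  for (j in 0:(n - 1L)) {
    i <- seq(j %% 2L, two_m - 1L, by = 2L)
    vert <- rbind(vert, cbind(vid(i, j), vid(i, j + 1L)))
  }
  build_graph(two_m * (n + 1L), rbind(ring, vert))
}

#' Generate an armchair polyhex nanotube graph
#'
#' Cylindrical armchair tessellation: `n + 1` rings of `2m` atoms; within each
#' ring the atoms are bonded in pairs (offset alternating with ring parity),
#' and every atom bonds to its axial neighbour in the next ring. This gives
#' `2m(n+1)` vertices and `m(3n+1)` edges, bipartite with max degree 3.
#'
#' @inheritParams make_zigzag_nanotube
#' @return A `molecular_graph`.
#' @export
make_armchair_nanotube <- function(m, n, transpose = FALSE) {
  m <- as.integer(m); n <- as.integer(n)
  if (isTRUE(transpose)) { tmp <- m; m <- n; n <- tmp }
  if (is.na(m) || m < 2L) stop("`m` must be at least 2 (cylinder undefined)")
  if (is.na(n) || n < 1L) stop("`n` must be at least 1")
  two_m <- 2L * m
  vid <- function(i, j) two_m * j + (i %% two_m)
  inring <- do.call(rbind, lapply(0:n, function(j) {
    i <- seq(j %% 2L, two_m - 1L, by = 2L)
    cbind(vid(i, j), vid(i + 1L, j))
  }))
  vert <- do.call(rbind, lapply(0:(n - 1L), function(j)
    cbind(vid(0:(two_m - 1L), j), vid(0:(two_m - 1L), j + 1L))))
  build_graph(two_m * (n + 1L), rbind(inring, vert))
}

#' Generate a one-hexagonal nanocone graph
#'
#' The hexagonal flake CNC6[n]: a central hexagon wrapped by `n` concentric
#' layers of hexagons (the circumcoronene series; n = 0 is benzene, n = 1 is
#' the coronene skeleton). `6(n+1)^2` vertices, `9n^2 + 15n + 6` edges, planar
#' and bipartite with max degree 3.
#'
#' @param n Number of hexagon layers around the core; `n >= 0`.
#' @return A `molecular_graph`.
#' @export
make_nanocone <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("`n` must be a nonnegative integer")
  qr <- expand.grid(q = -n:n, r = -n:n)
  keep <- pmax(abs(qr$q), abs(qr$r), abs(-qr$q - qr$r)) <= n
  hexagonal_patch(as.matrix(qr[keep, , drop = FALSE]))
}

# Curated catalogue of lower benzenoid hydrocarbons, stored as axial hexagon
# cells. A standard set of 30 lower PHs (hydrogen-suppressed skeletons); users
# reproducing a specific published test set should verify the membership
# against their source and may substitute their own edge lists.
BENZENOID_CELLS <- list(
  "benzene"                 = rbind(c(0, 0)),
  "naphthalene"             = rbind(c(0, 0), c(0, 1)),
  "anthracene"              = cbind(0, 0:2),
  "phenanthrene"            = rbind(c(0, 0), c(0, 1), c(1, 1)),
  "pyrene"                  = rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1)),
  "tetracene"               = cbind(0, 0:3),
  "benz[a]anthracene"       = rbind(c(0, 0), c(0, 1), c(0, 2), c(1, 2)),
  "chrysene"                = rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 2)),
  "benzo[c]phenanthrene"    = rbind(c(0, 0), c(0, 1), c(1, 1), c(2, 0)),
  "triphenylene"            = rbind(c(0, 0), c(1, 0), c(-1, 1), c(0, -1)),
  "pentacene"               = cbind(0, 0:4),
  "pentaphene"              = rbind(c(0, 0), c(0, 1), c(0, 2), c(1, -1), c(1, 2)),
  "dibenz[a,h]anthracene"   = rbind(c(0, 0), c(0, 1), c(0, 2), c(1, -1), c(-1, 3)),
  "dibenz[a,c]anthracene"   = rbind(c(0, 0), c(0, 1), c(0, 2), c(1, -1), c(-1, 0)),
  "picene"                  = rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 2), c(2, 2)),
  "pentahelicene"           = rbind(c(0, 0), c(0, 1), c(1, 1), c(2, 0), c(2, -1)),
  "benzo[b]chrysene"        = rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 2), c(1, 3)),
  "benzo[c]chrysene"        = rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 2), c(0, 3)),
  "benzo[a]tetracene"       = rbind(c(0, 0), c(0, 1), c(0, 2), c(0, 3), c(1, 3)),
  "naphtho[2,3-a]anthracene" = rbind(c(0, 0), c(0, 1), c(0, 2), c(1, 2), c(2, 2)),
  "hexacene"                = cbind(0, 0:5),
  "benzo[a]pentacene"       = rbind(c(0, 0), c(0, 1), c(0, 2), c(0, 3), c(0, 4), c(1, 4)),
  "benzo[a]pyrene"          = rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1), c(2, 1)),
  "benzo[e]pyrene"          = rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1), c(2, -1)),
  "perylene"                = rbind(c(1, 0), c(0, 0), c(0, 1), c(2, -1), c(2, 0)),
  "benzo[ghi]perylene"      = rbind(c(1, 0), c(0, 0), c(0, 1), c(2, -1), c(2, 0), c(1, 1)),
  "anthanthrene"            = rbind(c(0, 0), c(0, 1), c(1, -1), c(1, 0), c(2, -2), c(2, -1)),
  "coronene"                = rbind(c(0, 0), c(1, 0), c(0, 1), c(-1, 1), c(-1, 0), c(0, -1), c(1, -1)),
  "dibenzo[a,h]pyrene"      = rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1), c(2, 1), c(-1, 0)),
  "dibenzo[a,i]pyrene"      = rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1), c(2, 1), c(2, -1))
)

#' Benzenoid catalogue
#'
#' Returns the hydrogen-suppressed skeleton of a catalogued lower benzenoid
#' hydrocarbon, built deterministically from curated hexagon-cell coordinates.
#'
#' @param name Catalogue entry name, e.g. `"benzene"`, `"naphthalene"`,
#'   `"coronene"`. Call [benzenoid_names()] for the full list.
#' @return A `molecular_graph`.
#' @export
benzenoid_catalogue <- function(name) {
  if (length(name) != 1L || !is.character(name) || !name %in% names(BENZENOID_CELLS))
    stop("unknown benzenoid '", paste(name, collapse = ","),
         "'; available: ", paste(names(BENZENOID_CELLS), collapse = ", "))
  hexagonal_patch(BENZENOID_CELLS[[name]])
}

#' Names of the shipped benzenoid catalogue
#' @return Character vector of the 30 entry names.
#' @export
benzenoid_names <- function() names(BENZENOID_CELLS)
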