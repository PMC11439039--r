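#' Matrix kinds
#'
#' The eleven chemical matrices supported by [build_matrix()], in canonical
#' order: `DIST` (distance), `DLAP` (distance Laplacian, `Diag(Tr) - D`),
#' `DSLAP` (distance signless Laplacian, `Diag(Tr) + D`), `HARARY` (reciprocal
#' distance), `SZEGED` (`q_w * q_z` on edges), `PI` (`q_w + q_z` on edges),
#' `DEGDIST` (`(d_w + d_z)/d(w,z)` on all pairs), `SCHULTZ` (`A + D`),
#' `GUTMAN` (`d_w * d_z / d(w,z)` on all pairs), `ABC2`
#' (`sqrt((q_w + q_z - 2)/(q_w q_z))` on edges) and `GA2`
#' (`2 sqrt(q_w q_z)/(q_w + q_z)` on edges).
#'
#' @export
MATRIX_KINDS <- c("DIST", "DLAP", "DSLAP", "HARARY", "SZEGED", "PI",
                  "DEGDIST", "SCHULTZ", "GUTMAN", "ABC2", "GA2")

# kinds whose entries live only on bonds and need edge-cut counts
EDGE_KINDS <- c("SZEGED", "PI", "ABC2", "GA2")

#' Build one of the eleven chemical matrices
#'
#' Constructs the requested symmetric matrix from a graph, its distance data
#' and (for the edge-supported kinds) its Szeged edge-cut counts. Entries are
#' computed in double precision from the exact integer distance/degree/count
#' values; both triangles are filled from a single formula evaluation, so the
#' result is exactly symmetric.
#'
#' @param g A `molecular_graph` with at least 2 vertices.
#' @param d Its `distance_data`.
#' @param q Its `edge_cut_counts`; required for kinds `SZEGED`, `PI`, `ABC2`,
#'   `GA2`, ignored otherwise.
#' @param kind One of [MATRIX_KINDS].
#' @return An object of class `chemical_matrix`: list with `kind`, `values`
#'   (dense n x n numeric), and the centering constants `t` (mean transmission)
#'   and `sigma` (total transmission) carried for the Laplacian-type
#'   energy/Estrada shifts downstream.
#'
#' @details Edge-supported kinds (`SZEGED`, `PI`, `ABC2`, `GA2`) store explicit
#'   zeros off the bond support; distance-supported kinds (`DIST`, `HARARY`,
#'   `DEGDIST`, `GUTMAN`) are formula-valued on every off-diagonal pair. The
#'   diagonal is zero except for `DLAP`/`DSLAP`, whose diagonal is the
#'   transmission vector. For the single edge of K2, `q_w + q_z - 2 = 0` and the
#'   ABC2 entry is 0 by the formula itself; no special case is needed.
#' @examples
#' c6 <- build_graph(6, cbind(0:5, c(1:5, 0)))
#' d <- all_pairs_distances(c6)
#' q <- edge_cut_counts(c6, d)
#' build_matrix(c6, d, q, "GA2")$values  # equals the adjacency matrix of C6
#' @export
build_matrix <- function(g, d, q = NULL, kind = MATRIX_KINDS) {
  kind <- match.arg(kind)
  stopifnot(inherits(g, "molecular_graph"), inherits(d, "distance_data"))
  if (g$n < 2L)
    stop("chemical matrices are undefined for a single-vertex graph (no distances)")
  if (kind %in% EDGE_KINDS && !inherits(q, "edge_cut_counts"))
    stop(sprintf("kind '%s' requires edge-cut counts (see edge_cut_counts())", kind))

  n <- g$n
  D <- d$dist
  deg <- degrees(g)
  off <- D > 0

  vals <- switch(kind,
    DIST  = D,
    DLAP  = diag(d$transmissions, n) - D,
    DSLAP = diag(d$transmissions, n) + D,
    HARARY = {
      m <- matrix(0, n, n); m[off] <- 1 / D[off]; m
    },
    DEGDIST = {
      s <- outer(deg, deg, `+`)
      m <- matrix(0, n, n); m[off] <- s[off] / D[off]; m
    },
    GUTMAN = {
      p <- outer(deg, deg)
      m <- matrix(0, n, n); m[off] <- p[off] / D[off]; m
    },
    SCHULTZ = adjacency_matrix(g) + D,
    SZEGED = edge_supported(n, q, q$q_w * q$q_z),
    PI     = edge_supported(n, q, q$q_w + q$q_z),
    ABC2   = edge_supported(n, q, sqrt((q$q_w + q$q_z - 2) / (q$q_w * q$q_z))),
    GA2    = edge_supported(n, q, 2 * sqrt(q$q_w * q$q_z) / (q$q_w + q$q_z))
  )
  structure(list(kind = kind, values = vals,
                 t = d$mean_transmission, sigma = d$total_transmission),
            class = "chemical_matrix")
}

edge_supported <- function(n, q, entry) {
  m <- matrix(0, n, n)
  i <- q$v1 + 1L; j <- q$v2 + 1L
  m[cbind(i, j)] <- entry
  m[cbind(j, i)] <- entry
  m
}

#' @export
print.chemical_matrix <- function(x, ...) {
  cat(sprintf("<chemical_matrix %s: %d x %d, t = %.4f, sigma = %g>\n",
              x$kind, nrow(x$values), ncol(x$values), x$t, x$sigma))
  invisible(x)
}

#' Export a chemical matrix as dense CSV plus JSON sidecar
#'
#' Writes the full square matrix without header, and a sidecar
#' `<path>.json` with `{kind, n, t, sigma}`.
#'
#' @param m A `chemical_matrix`.
#' @param path Output CSV path.
#' @export
write_matrix_csv <- function(m, path) {
  stopifnot(inherits(m, "chemical_matrix"))
  utils::write.table(m$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(kind = m$kind, n = nrow(m$values), t = m$t, sigma = m$sigma),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
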