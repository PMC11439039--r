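#' Build a molecular graph
#'
#' A molecular graph is the hydrogen-suppressed skeleton of a compound: vertices
#' are (heavy) atoms, edges are bonds, all bonds have unit length. Vertices are
#' indexed 0-based everywhere in this package (files, reports, error messages).
#'
#' @param n_vertices Positive integer, number of atoms.
#' @param edges Two-column matrix (or data.frame, or list of length-2 vectors)
#'   of 0-based vertex indices, one bond per row.
#' @param labels Optional character vector of per-vertex labels.
#'
#' @return An object of class `molecular_graph`: a list with elements
#'   `n` (vertex count), `edges` (normalized two-column integer matrix, smaller
#'   index first, rows sorted) and `labels`.
#'
#' @details Self-loops, duplicate edges and out-of-range indices are rejected
#'   with an error naming the offending edge. Connectivity is *not* required at
#'   construction time (generators assemble graphs incrementally); it is
#'   enforced by [all_pairs_distances()], where disconnection first matters.
#'
#' @examples
#' k2 <- build_graph(2, rbind(c(0, 1)))
#' c6 <- build_graph(6, cbind(0:5, c(1:5, 0)))
#' degrees(c6)
#' @export
build_graph <- function(n_vertices, edges, labels = NULL) {
  n_vertices <- as.integer(n_vertices)
  if (length(n_vertices) != 1L || is.na(n_vertices) || n_vertices < 1L)
    stop("`n_vertices` must be a single positive integer")
  edges <- as_edge_matrix(edges)
  if (nrow(edges) > 0L) {
    if (any(is.na(edges)))
      stop("edge list contains missing values")
    bad <- which(edges[, 1L] < 0L | edges[, 2L] < 0L |
                   edges[, 1L] >= n_vertices | edges[, 2L] >= n_vertices)
    if (length(bad))
      stop(sprintf("edge (%d, %d) references a vertex outside 0..%d",
                   edges[bad[1L], 1L], edges[bad[1L], 2L], n_vertices - 1L))
    loops <- which(edges[, 1L] == edges[, 2L])
    if (length(loops))
      stop(sprintf("self-loop at vertex %d is not allowed", edges[loops[1L], 1L]))
    # normalize: smaller endpoint first, rows sorted
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
    ord <- order(edges[, 1L], edges[, 2L])
    edges <- edges[ord, , drop = FALSE]
    dup <- which(duplicated(edges))
    if (length(dup))
      stop(sprintf("duplicate edge (%d, %d)", edges[dup[1L], 1L], edges[dup[1L], 2L]))
  }
  if (!is.null(labels) && length(labels) != n_vertices)
    stop("`labels` must have one entry per vertex")
  storage.mode(edges) <- "integer"
  colnames(edges) <- c("v1", "v2")
  structure(list(n = n_vertices, edges = edges, labels = labels),
            class = "molecular_graph")
}

as_edge_matrix <- function(edges) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.list(edges)) edges <- do.call(rbind, lapply(edges, function(e) e[1:2]))
  if (is.null(edges) || length(edges) == 0L)
    return(matrix(integer(0), ncol = 2L))
  if (!is.matrix(edges) || ncol(edges) != 2L)
    stop("`edges` must be a two-column matrix of vertex indices")
  storage.mode(edges) <- "integer"
  edges
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph: %d vertices, %d edges>\n", x$n, nrow(x$edges)))
  invisible(x)
}

#' Vertex degrees (valencies) of a molecular graph
#'
#' @param g A `molecular_graph`.
#' @return Integer vector of length `g$n` (vertex i's degree at position i + 1).
#' @export
degrees <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  d <- integer(g$n)
  t1 <- tabulate(g$edges[, 1L] + 1L, nbins = g$n)
  t2 <- tabulate(g$edges[, 2L] + 1L, nbins = g$n)
  d + t1 + t2
}

# igraph handle with the exact vertex count (tolerates isolated vertices)
to_igraph <- function(g) {
  igraph::make_empty_graph(n = g$n, directed = FALSE) +
    igraph::edges(as.vector(t(g$edges + 1L)))
}

#' All-pairs graph distances, transmissions and transmission aggregates
#'
#' Computes the geodesic (shortest-path, unit bond length) distance matrix by
#' breadth-first search, the per-vertex transmissions `Tr(w)` (row sums), the
#' mean transmission `t` and the total transmission `sigma` (half the sum of all
#' transmissions, i.e. the Wiener index).
#'
#' @param g A connected `molecular_graph`.
#' @return An object of class `distance_data`: list with `dist` (n x n integer
#'   matrix), `transmissions`, `mean_transmission`, `total_transmission`.
#' @examples
#' p3 <- build_graph(3, rbind(c(0, 1), c(1, 2)))
#' d <- all_pairs_distances(p3)
#' d$transmissions       # 3 2 3
#' d$total_transmission  # 4
#' @export
all_pairs_distances <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  ig <- to_igraph(g)
  dm <- igraph::distances(ig, algorithm = "unweighted")
  if (any(is.infinite(dm))) {
    ij <- which(is.infinite(dm), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "graph is disconnected: infinite distance between vertices %d and %d",
      ij[1L] - 1L, ij[2L] - 1L))
  }
  dimnames(dm) <- NULL
  tr <- rowSums(dm)
  structure(list(
    dist = dm,
    transmissions = tr,
    mean_transmission = sum(tr) / g$n,
    total_transmission = sum(tr) / 2
  ), class = "distance_data")
}

#' Szeged-type edge-cut counts
#'
#' For every bond e = wz, counts the vertices strictly closer to w than to z
#' (`q_w`), strictly closer to z (`q_z`), and equidistant (`q_0`). The standard
#' Szeged convention compares `d(x, w)` with `d(x, z)`. Each endpoint counts
#' itself, so `q_w >= 1` and `q_z >= 1`; for bipartite graphs `q_0 = 0` for
#' every edge.
#'
#' @param g A `molecular_graph`.
#' @param d The matching `distance_data` from [all_pairs_distances()].
#' @return An object of class `edge_cut_counts`: a data.frame with columns
#'   `v1`, `v2` (0-based endpoints, matching `g$edges` row order), `q_w`,
#'   `q_z`, `q_0`.
#' @export
edge_cut_counts <- function(g, d) {
  stopifnot(inherits(g, "molecular_graph"), inherits(d, "distance_data"))
  if (nrow(d$dist) != g$n)
    stop("distance data does not match graph size")
  m <- nrow(g$edges)
  qw <- integer(m); qz <- integer(m)
  for (k in seq_len(m)) {
    w <- g$edges[k, 1L] + 1L
    z <- g$edges[k, 2L] + 1L
    dw <- d$dist[, w]; dz <- d$dist[, z]
    qw[k] <- sum(dw < dz)
    qz[k] <- sum(dz < dw)
  }
  out <- data.frame(v1 = g$edges[, 1L], v2 = g$edges[, 2L],
                    q_w = qw, q_z = qz, q_0 = g$n - qw - qz)
  class(out) <- c("edge_cut_counts", "data.frame")
  out
}

#' Read a molecular graph from an edge-list TSV
#'
#' One edge per line, two 0-based integer columns separated by whitespace;
#' lines starting with `#` are comments. The vertex count is `max index + 1`
#' unless given.
#'
#' @param path File path.
#' @param n_vertices Optional explicit vertex count.
#' @return A `molecular_graph`.
#' @export
read_edgelist_tsv <- function(path, n_vertices = NULL) {
  raw <- utils::read.table(path, header = FALSE, comment.char = "#",
                           colClasses = "integer")
  if (ncol(raw) < 2L) stop("edge-list file must have two integer columns")
  e <- as.matrix(raw[, 1:2])
  if (is.null(n_vertices)) n_vertices <- max(e) + 1L
  build_graph(n_vertices, e)
}

#' Write a molecular graph as an edge-list TSV
#'
#' @param g A `molecular_graph`.
#' @param path Output file path.
#' @param comment Optional comment line written at the top.
#' @export
write_edgelist_tsv <- function(g, path, comment = NULL) {
  stopifnot(inherits(g, "molecular_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(sprintf("%d\t%d", g$edges[, 1L], g$edges[, 2L]), con)
  invisible(path)
}

#' Read a molecular graph from a dense adjacency CSV
#'
#' Square symmetric 0/1 matrix, comma-separated, no header.
#'
#' @param path File path.
#' @return A `molecular_graph`.
#' @export
read_adjacency_csv <- function(path) {
  a <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(a) <- NULL
  if (nrow(a) != ncol(a)) stop("adjacency matrix must be square")
  if (!all(a %in% c(0, 1))) stop("adjacency matrix entries must be 0 or 1")
  if (!isTRUE(all.equal(a, t(a)))) stop("adjacency matrix must be symmetric")
  if (any(diag(a) != 0)) stop("adjacency matrix has a nonzero diagonal (self-loop)")
  idx <- which(upper.tri(a) & a == 1, arr.ind = TRUE)
  build_graph(nrow(a), cbind(idx[, 1L] - 1L, idx[, 2L] - 1L))
}

#' Is the graph bipartite?
#'
#' @param g A `molecular_graph`.
#' @return Logical.
#' @export
is_bipartite_graph <- function(g) {
  igraph::bipartite_mapping(to_igraph(g))$res
}

#' Is the graph connected?
#'
#' @param g A `molecular_graph`.
#' @return Logical.
#' @export
is_connected_graph <- function(g) {
  igraph::is_connected(to_igraph(g))
}

adjacency_matrix <- function(g) {
  a <- matrix(0, g$n, g$n)
  a[g$edges + 1L] <- 1
  a[g$edges[, 2:1, drop = FALSE] + 1L] <- 1
  a
}
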