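#' Eigenvalue spectrum of a chemical matrix
#'
#' Real symmetric eigendecomposition; eigenvalues are returned sorted
#' descending. The centering constants (mean transmission `t`, total
#' transmission `sigma`) are carried along for the Laplacian-type energy and
#' Estrada shifts.
#'
#' @param m A `chemical_matrix`, or a plain symmetric numeric matrix.
#' @param kind Matrix kind when `m` is a plain matrix.
#' @param t,sigma Centering constants when `m` is a plain matrix.
#' @return An object of class `graph_spectrum`: list with `values` (descending
#'   eigenvalues), `kind`, `t`, `sigma`.
#' @export
eigen_spectrum <- function(m, kind = NULL, t = NA_real_, sigma = NA_real_) {
  if (inherits(m, "chemical_matrix")) {
    kind <- m$kind; t <- m$t; sigma <- m$sigma; m <- m$values
  }
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("`m` must be a square matrix")
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m))))
    stop("matrix is not symmetric within tolerance")
  ev <- sort(eigen(m, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  structure(list(values = ev, kind = kind, t = t, sigma = sigma),
            class = "graph_spectrum")
}

#' @export
print.graph_spectrum <- function(x, ...) {
  cat(sprintf("<graph_spectrum %s: n = %d, range [%.4f, %.4f]>\n",
              if (is.null(x$kind)) "?" else x$kind,
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Spectral radius
#'
#' The largest eigenvalue of the matrix spectrum.
#'
#' @param s A `graph_spectrum`.
#' @return Numeric scalar.
#' @export
spectral_radius <- function(s) {
  stopifnot(inherits(s, "graph_spectrum"), length(s$values) > 0L)
  s$values[1L]
}

#' Graph energy
#'
#' For most matrix kinds the energy is the sum of absolute eigenvalues. For the
#' distance Laplacian and signless Laplacian kinds the eigenvalues are first
#' centered at the mean transmission `t` (their average in exact arithmetic,
#' since the trace is `2 * sigma = n * t`), i.e. `sum(|delta_i - t|)`.
#'
#' @param s A `graph_spectrum`.
#' @return Numeric scalar.
#' @export
energy <- function(s) {
  stopifnot(inherits(s, "graph_spectrum"))
  if (isTRUE(s$kind %in% c("DLAP", "DSLAP"))) {
    if (is.na(s$t)) stop("centered energy needs the mean transmission t")
    sum(abs(s$values - s$t))
  } else {
    sum(abs(s$values))
  }
}

#' Estrada index
#'
#' Sum of exponentials of the eigenvalues. For the distance Laplacian and
#' signless Laplacian kinds the exponents are shifted, by default by the total
#' transmission `sigma` (i.e. `sum(exp(delta_i - sigma))`); the shift can be
#' switched to the mean transmission `t` or disabled via `shift`.
#'
#' When the largest (shifted) exponent exceeds `exponent_cap` the sum would
#' overflow double precision; it is then evaluated in the log domain as
#' `delta_1 + log(sum(exp(delta_i - delta_1)))` and the *logarithm* of the
#' Estrada index is returned, flagged with attribute `log_domain = TRUE`.
#'
#' @param s A `graph_spectrum`.
#' @param shift For `DLAP`/`DSLAP` kinds: `"sigma"` (default), `"t"` or
#'   `"none"`.
#' @param exponent_cap Largest exponent evaluated directly (default 700, just
#'   under the double-precision limit of ~709.78).
#' @return Numeric scalar with attribute `log_domain` (TRUE if the value is the
#'   natural log of the Estrada index).
#' @export
estrada <- function(s, shift = c("sigma", "t", "none"), exponent_cap = 700) {
  stopifnot(inherits(s, "graph_spectrum"))
  shift <- match.arg(shift)
  ev <- s$values
  if (isTRUE(s$kind %in% c("DLAP", "DSLAP"))) {
    sh <- switch(shift,
                 sigma = s$sigma,
                 t = s$t,
                 none = 0)
    if (is.na(sh)) stop("shifted Estrada index needs the centering constants")
    ev <- ev - sh
  }
  top <- max(ev)
  if (top > exponent_cap) {
    val <- top + log(sum(exp(ev - top)))
    return(structure(val, log_domain = TRUE))
  }
  structure(sum(exp(ev)), log_domain = FALSE)
}

#' Count negative eigenvalues
#'
#' Number of eigenvalues below `-tol` (default 1e-9, suited to integer matrices
#' of modest norm).
#'
#' @param s A `graph_spectrum`.
#' @param tol Absolute zero threshold.
#' @return Integer.
#' @export
count_negative_eigenvalues <- function(s, tol = 1e-9) {
  stopifnot(inherits(s, "graph_spectrum"))
  sum(s$values < -tol)
}

descriptor_names <- function() {
  as.vector(t(outer(MATRIX_KINDS, c("rho", "En", "Es"),
                    function(k, p) paste(p, k, sep = "_"))))
}

#' Compute all 33 distance-spectral descriptors of a molecular graph
#'
#' Runs the full pipeline for one molecule: one breadth-first-search distance
#' pass, one edge-cut pass, then for each of the eleven chemical matrices the
#' spectral radius (`rho_*`), graph energy (`En_*`) and Estrada index (`Es_*`).
#' Deterministic: identical input gives identical output.
#'
#' @param g A connected `molecular_graph` with at least 2 vertices.
#' @param molecule Molecule identifier used in reports.
#' @param config A [run_config()] (controls the Laplacian Estrada shift and the
#'   overflow cap).
#' @return A one-row data.frame: column `molecule` followed by the 33 named
#'   descriptors in kind order (`rho_DIST`, `En_DIST`, `Es_DIST`, `rho_DLAP`,
#'   ...). Columns whose Estrada index overflowed and is reported in the log
#'   domain are listed in the `log_estrada` attribute.
#' @examples
#' suite <- descriptor_suite(build_graph(6, cbind(0:5, c(1:5, 0))), "benzene")
#' suite$En_GA2   # 8: the GA2 matrix of C6 is its adjacency matrix
#' @export
descriptor_suite <- function(g, molecule = "molecule", config = run_config()) {
  stopifnot(inherits(g, "molecular_graph"))
  if (g$n < 2L) stop("descriptor suite needs at least 2 vertices")
  d <- all_pairs_distances(g)
  q <- edge_cut_counts(g, d)
  out <- numeric(0)
  logged <- character(0)
  for (kind in MATRIX_KINDS) {
    s <- eigen_spectrum(build_matrix(g, d, q, kind))
    es <- estrada(s, shift = config$estrada_shift,
                  exponent_cap = config$exponent_cap)
    vals <- c(spectral_radius(s), energy(s), as.numeric(es))
    names(vals) <- paste(c("rho", "En", "Es"), kind, sep = "_")
    if (isTRUE(attr(es, "log_domain")))
      logged <- c(logged, paste0("Es_", kind))
    out <- c(out, vals)
  }
  rec <- cbind(data.frame(molecule = molecule, stringsAsFactors = FALSE),
               as.data.frame(as.list(out)))
  attr(rec, "log_estrada") <- logged
  rec
}
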