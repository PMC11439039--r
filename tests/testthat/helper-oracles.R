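# Independent oracles and small graph builders used across the suite.
# These deliberately avoid the package's own BFS/eigen code paths.

path_graph <- function(n) build_graph(n, cbind(0:(n - 2L), 1:(n - 1L)))
cycle_graph <- function(n) build_graph(n, cbind(0:(n - 1L), c(1:(n - 1L), 0L)))
k2 <- function() build_graph(2, rbind(c(0, 1)))

# deterministic random tree by preferential attachment order
random_tree <- function(n, seed) {
  set.seed(seed)
  parents <- vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1))
  build_graph(n, cbind(parents - 1L, 1:(n - 1L)))
}

# all-pairs distances by iterated boolean matrix powers (oracle for BFS)
oracle_distances <- function(g) {
  n <- g$n
  a <- matrix(FALSE, n, n)
  a[g$edges + 1L] <- TRUE
  a[g$edges[, 2:1, drop = FALSE] + 1L] <- TRUE
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  reach <- diag(n) > 0
  step <- 0L
  repeat {
    step <- step + 1L
    # grow reachability by one hop
    nxt <- (reach %*% a) > 0
    new <- nxt & !reach & !(diag(n) > 0)
    if (!any(new)) break
    d[new] <- step
    reach <- reach | nxt
    if (step > n) break
  }
  d
}

# Independent symmetric eigensolver: classic cyclic Jacobi rotations,
# implemented here from first principles (no call into LAPACK's QR-based
# eigen()). Characteristic-polynomial root-finding was tried first but cannot
# resolve eigenvalues of multiplicity three to 1e-6 in double precision;
# Jacobi has no such degeneracy problem and stays fully independent.
oracle_eigenvalues <- function(m) {
  a <- m
  n <- nrow(a)
  if (n == 1L) return(a[1, 1])
  for (sweep in 1:50) {
    off <- sqrt(sum(a[upper.tri(a)]^2))
    if (off < 1e-13 * max(1, max(abs(diag(a))))) break
    for (p in 1:(n - 1L)) for (q in (p + 1L):n) {
      if (abs(a[p, q]) < 1e-300) next
      theta <- (a[q, q] - a[p, p]) / (2 * a[p, q])
      t <- sign(theta) / (abs(theta) + sqrt(theta^2 + 1))
      if (theta == 0) t <- 1
      cs <- 1 / sqrt(t^2 + 1); sn <- t * cs
      rp <- a[p, ]; rq <- a[q, ]
      a[p, ] <- cs * rp - sn * rq
      a[q, ] <- sn * rp + cs * rq
      cp <- a[, p]; cq <- a[, q]
      a[, p] <- cs * cp - sn * cq
      a[, q] <- sn * cp + cs * cq
    }
  }
  sort(diag(a), decreasing = TRUE)
}

# symmetric circulant eigenvalues: first row c (c[1] is the diagonal entry)
circulant_eigenvalues <- function(c0) {
  n <- length(c0)
  j <- 0:(n - 1L)
  ev <- vapply(j, function(jj) sum(c0 * cos(2 * pi * jj * j / n)), numeric(1))
  sort(ev, decreasing = TRUE)
}

# independent re-derivation of all 33 invariants from first principles
oracle_suite <- function(g) {
  d <- oracle_distances(g)
  n <- g$n
  deg <- degrees(g)
  tr <- rowSums(d)
  tmean <- mean(tr); sig <- sum(tr) / 2
  a <- matrix(0, n, n)
  a[g$edges + 1L] <- 1; a[g$edges[, 2:1, drop = FALSE] + 1L] <- 1
  off <- d > 0
  qs <- t(apply(g$edges, 1, function(e) {
    w <- e[1] + 1L; z <- e[2] + 1L
    c(sum(d[, w] < d[, z]), sum(d[, z] < d[, w]))
  }))
  edge_mat <- function(vals) {
    m <- matrix(0, n, n)
    m[cbind(g$edges[, 1] + 1L, g$edges[, 2] + 1L)] <- vals
    m[cbind(g$edges[, 2] + 1L, g$edges[, 1] + 1L)] <- vals
    m
  }
  hollow <- function(num) { m <- matrix(0, n, n); m[off] <- num[off] / d[off]; m }
  mats <- list(
    DIST = d,
    DLAP = diag(tr) - d,
    DSLAP = diag(tr) + d,
    HARARY = hollow(matrix(1, n, n)),
    SZEGED = edge_mat(qs[, 1] * qs[, 2]),
    PI = edge_mat(qs[, 1] + qs[, 2]),
    DEGDIST = hollow(outer(deg, deg, `+`)),
    SCHULTZ = a + d,
    GUTMAN = hollow(outer(deg, deg)),
    ABC2 = edge_mat(sqrt((qs[, 1] + qs[, 2] - 2) / (qs[, 1] * qs[, 2]))),
    GA2 = edge_mat(2 * sqrt(qs[, 1] * qs[, 2]) / (qs[, 1] + qs[, 2]))
  )
  out <- numeric(0)
  for (kind in names(mats)) {
    ev <- oracle_eigenvalues(mats[[kind]])
    rho <- ev[1]
    en <- if (kind %in% c("DLAP", "DSLAP")) sum(abs(ev - tmean)) else sum(abs(ev))
    es <- if (kind %in% c("DLAP", "DSLAP")) sum(exp(ev - sig)) else sum(exp(ev))
    v <- c(rho, en, es)
    names(v) <- paste(c("rho", "En", "Es"), kind, sep = "_")
    out <- c(out, v)
  }
  out
}

ref_csv <- function(name) {
  utils::read.csv(system.file("extdata", name, package = "distspectra"))
}
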