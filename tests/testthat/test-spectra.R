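spec_of <- function(g, kind) {
  d <- all_pairs_distances(g)
  q <- if (kind %in% c("SZEGED", "PI", "ABC2", "GA2")) edge_cut_counts(g, d)
  eigen_spectrum(build_matrix(g, d, q, kind))
}

test_that("C6 spectra match the circulant closed forms", {
  c6 <- cycle_graph(6)
  # distance matrix of C6 is circulant with first row (0,1,2,3,2,1)
  expect_equal(spec_of(c6, "DIST")$values,
               circulant_eigenvalues(c(0, 1, 2, 3, 2, 1)), tolerance = 1e-10)
  expect_equal(spec_of(c6, "DIST")$values, c(9, 0, 0, -1, -4, -4),
               tolerance = 1e-10)
  expect_equal(spec_of(c6, "DLAP")$values, c(13, 13, 10, 9, 9, 0),
               tolerance = 1e-10)
  # Schultz = A + D: circulant first row (0,2,2,3,2,2)
  expect_equal(spec_of(c6, "SCHULTZ")$values,
               circulant_eigenvalues(c(0, 2, 2, 3, 2, 2)), tolerance = 1e-10)
})

test_that("spectral radius, energy and Estrada on reference cases", {
  c6 <- cycle_graph(6)
  sD <- spec_of(c6, "DIST")
  expect_equal(spectral_radius(sD), 9)
  expect_equal(energy(sD), 18)
  expect_equal(count_negative_eigenvalues(sD), 3L)

  expect_equal(energy(spec_of(c6, "DLAP")), 18)       # sum |delta - t|, t = 9
  expect_equal(energy(spec_of(c6, "GA2")), 8)
  expect_equal(energy(spec_of(c6, "ABC2")), 16 / 3)
  expect_equal(energy(spec_of(c6, "SCHULTZ")), 22)
  expect_equal(energy(spec_of(c6, "SZEGED")), 72)     # 9 * adjacency energy
  expect_equal(spectral_radius(spec_of(c6, "PI")), 12)
  expect_equal(spectral_radius(spec_of(c6, "GA2")), 2)

  sH <- spec_of(k2(), "HARARY")
  expect_equal(sH$values, c(1, -1))
  expect_equal(as.numeric(estrada(sH)), exp(1) + exp(-1))
  expect_equal(count_negative_eigenvalues(sH), 1L)

  # GA2(C6) = A(C6), spectrum {2, 1, 1, -1, -1, -2}
  expect_equal(as.numeric(estrada(spec_of(c6, "GA2"))),
               exp(2) + 2 * exp(1) + 2 * exp(-1) + exp(-2))
})

test_that("Laplacian-type Estrada shifts are selectable", {
  c6 <- cycle_graph(6)
  sL <- spec_of(c6, "DLAP")
  # sigma shift (default, as printed): sum exp(delta - 27)
  expect_equal(as.numeric(estrada(sL, "sigma")), sum(exp(sL$values - 27)))
  # t shift: sum exp(delta - 9)
  expect_equal(as.numeric(estrada(sL, "t")), sum(exp(sL$values - 9)))
  expect_equal(as.numeric(estrada(sL, "none")), sum(exp(sL$values)))
  # the two shifts differ by the constant factor exp(sigma - t)
  expect_equal(as.numeric(estrada(sL, "t")) / as.numeric(estrada(sL, "sigma")),
               exp(27 - 9))
})

test_that("Estrada overflow falls back to the log domain with a flag", {
  s <- structure(list(values = c(800, 2, 0), kind = "SZEGED",
                      t = NA_real_, sigma = NA_real_),
                 class = "graph_spectrum")
  es <- estrada(s)
  expect_true(attr(es, "log_domain"))
  expect_equal(as.numeric(es), 800 + log(sum(exp(c(800, 2, 0) - 800))))
  # all-zero spectrum: plain sum e^0 = n
  s0 <- structure(list(values = numeric(5) , kind = "DIST",
                       t = NA_real_, sigma = NA_real_),
                  class = "graph_spectrum")
  expect_equal(as.numeric(estrada(s0)), 5)
  expect_false(attr(estrada(s0), "log_domain"))
  expect_equal(count_negative_eigenvalues(s0), 0L)
})

test_that("spectral invariants: trace conservation, centering, PSD, Frobenius", {
  graphs <- list(path_graph(5), cycle_graph(7), random_tree(9, 11),
                 benzenoid_catalogue("pyrene"), make_nanocone(1))
  for (g in graphs) {
    d <- all_pairs_distances(g)
    q <- edge_cut_counts(g, d)
    for (kind in MATRIX_KINDS) {
      m <- build_matrix(g, d, q, kind)
      s <- eigen_spectrum(m)
      expect_false(is.unsorted(rev(s$values)))
      expect_equal(sum(s$values), sum(diag(m$values)),
                   tolerance = 1e-8 * g$n)
    }
    sL <- eigen_spectrum(build_matrix(g, d, NULL, "DLAP"))
    # centered eigenvalues sum to zero (trace = n * t)
    expect_lt(abs(sum(sL$values - d$mean_transmission)), 1e-6)
    # PSD with exactly one zero eigenvalue on connected graphs
    expect_lt(abs(sL$values[g$n]), 1e-8)
    expect_gt(sL$values[g$n - 1L], 1e-8)
    # Frobenius: distance spectral radius is positive
    expect_gt(spectral_radius(eigen_spectrum(build_matrix(g, d, NULL, "DIST"))), 0)
  }
})

test_that("non-symmetric input is rejected", {
  m <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(eigen_spectrum(m), "not symmetric")
})

test_that("descriptor suite returns the 33 named invariants deterministically", {
  c6 <- cycle_graph(6)
  rec <- descriptor_suite(c6, "benzene")
  expect_equal(ncol(rec), 34L)
  expect_equal(rec$molecule, "benzene")
  expect_equal(rec$En_GA2, 8)
  expect_equal(rec$rho_GA2, 2)
  expect_equal(rec$En_DEGDIST, 4 * rec$En_HARARY)
  rec2 <- descriptor_suite(c6, "benzene")
  expect_identical(rec, rec2)
})
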