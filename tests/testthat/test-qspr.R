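synthetic_props <- function(n = 30, seed = 42) {
  set.seed(seed)
  data.frame(molecule = sprintf("m%02d", seq_len(n)),
             Hc = round(runif(n, 80, 260), 2),
             Ent = round(runif(n, 250, 550), 2))
}

test_that("noiseless coefficients are recovered exactly", {
  props <- synthetic_props(12)
  y <- 2 * props$Hc - 1 * props$Ent + 5
  names(y) <- props$molecule
  m <- suppressWarnings(fit_property_model(y, props, descriptor = "En_H"))
  expect_equal(unname(m$coefficients), c(2, -1, 5), tolerance = 1e-10)
  expect_equal(m$r2, 1, tolerance = 1e-12)
  expect_equal(m$s, 0, tolerance = 1e-8)
  expect_equal(m$rho, sqrt(m$r2))
})

test_that("rho = sqrt(r2) and residual orthogonality hold under noise", {
  props <- synthetic_props(30)
  set.seed(7)
  y <- 0.2 * props$Hc - 0.08 * props$Ent + 13 + rnorm(30, sd = 0.5)
  names(y) <- props$molecule
  m <- fit_property_model(y, props)
  expect_equal(m$rho, sqrt(m$r2), tolerance = 1e-12)
  r <- residuals(m$fit)
  expect_lt(abs(sum(r * props$Hc)) / sum(abs(r * props$Hc) + 1), 1e-8)
  expect_lt(abs(sum(r * props$Ent)) / sum(abs(r * props$Ent) + 1), 1e-8)
  expect_true(all(m$ci95 > 0))
})

test_that("95% confidence intervals achieve nominal Monte-Carlo coverage at n = 30", {
  props <- synthetic_props(30, seed = 9)
  beta <- c(Hc = 2, Ent = -1, intercept = 5)
  set.seed(2024)
  hits <- c(Hc = 0, Ent = 0, intercept = 0)
  reps <- 1000
  for (i in seq_len(reps)) {
    y <- beta["Hc"] * props$Hc + beta["Ent"] * props$Ent + beta["intercept"] +
      rnorm(30, sd = 4)
    names(y) <- props$molecule
    m <- fit_property_model(y, props)
    hits <- hits + as.numeric(abs(m$coefficients - beta) <= m$ci95)
  }
  cover <- hits / reps
  expect_true(all(cover > 0.93 & cover < 0.97))
})

test_that("alignment and degeneracy errors are reported usefully", {
  props <- synthetic_props(6)
  y <- stats::setNames(rnorm(6), c(props$molecule[1:5], "ghost"))
  expect_error(fit_property_model(y, props), "missing from property table: ghost")
  y3 <- stats::setNames(1:3, props$molecule[1:3])
  expect_error(fit_property_model(y3, props), "at least 4")
  colp <- data.frame(molecule = letters[1:6], Hc = 1:6, Ent = 2 * (1:6))
  yc <- stats::setNames(rnorm(6), letters[1:6])
  expect_error(fit_property_model(yc, colp), "collinear")
})

test_that("inverse (prediction) direction fits property on descriptor", {
  props <- synthetic_props(10)
  y <- 0.5 * props$Hc   # descriptor proportional to heat capacity
  names(y) <- props$molecule
  m <- suppressWarnings(fit_property_model(y, props, descriptor = "En_H",
                          response = "property", property = "Hc"))
  expect_equal(unname(m$coefficients[1]), 2, tolerance = 1e-10)
  expect_equal(m$r2, 1, tolerance = 1e-12)
})

test_that("descriptor ranking sorts by multiple rho with alphabetical tie-break", {
  tab <- ref_csv("reference_descriptor_rho.csv")
  ranked <- rank_descriptors(tab, k = 5)
  expect_equal(ranked$descriptor,
               c("En_HARARY", "Es_ABC2", "En_DEGDIST", "En_GA2", "Es_GA2"))
  expect_equal(ranked$rho, c(0.9963, 0.9941, 0.9929, 0.9924, 0.9916))
  expect_equal(ranked$placement, 1:5)

  tie <- data.frame(descriptor = c("b_desc", "a_desc"), rho = c(0.9, 0.9))
  expect_equal(rank_descriptors(tie)$descriptor, c("a_desc", "b_desc"))

  single <- rank_descriptors(data.frame(descriptor = "x", rho = 0.5))
  expect_equal(single$placement, 1L)
})

test_that("series fits recover exact polynomials and report CIs", {
  x <- 1:8
  f <- suppressWarnings(fit_series(x, 2 * x + 1, "linear"))
  expect_equal(unname(f$coefficients), c(2, 1), tolerance = 1e-12)
  expect_equal(f$s, 0, tolerance = 1e-8)

  f2 <- suppressWarnings(fit_series(x, 3 * x^2 - x + 4, "quadratic"))
  expect_equal(unname(f2$coefficients), c(3, -1, 4), tolerance = 1e-10)

  expect_error(fit_series(1:2, 1:2, "linear"), "at least 3 points")
  expect_error(fit_series(1:3, 1:3, "quadratic"), "at least 4 points")
})
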