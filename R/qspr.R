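#' Read a property table
#'
#' CSV with header `molecule,Hc,Ent`: molecule identifier, heat capacity and
#' entropy (both in J mol^-1 K^-1). Experimental values are an external user
#' input (e.g. retrieved from the NIST WebBook); none are bundled.
#'
#' @param path CSV file path.
#' @return data.frame with columns `molecule`, `Hc`, `Ent`.
#' @export
read_property_table <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("molecule", "Hc", "Ent")
  if (!all(need %in% names(p)))
    stop("property table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(p$molecule)) stop("duplicate molecule ids in property table")
  if (!all(is.finite(p$Hc)) || !all(is.finite(p$Ent)))
    stop("property values must be finite")
  p[need]
}

#' Fit the structure-property regression for one descriptor
#'
#' Ordinary least squares of a descriptor on heat capacity and entropy jointly
#' (`descriptor ~ Hc + Ent` with intercept), the regression direction used when
#' screening descriptors: the descriptor is the response, the two measured
#' properties are the predictors. 95% confidence half-widths use the
#' t-distribution with `n - 3` degrees of freedom. The multiple correlation
#' coefficient is `rho = sqrt(r^2)`.
#'
#' For practical property prediction the direction can be inverted with
#' `response = "property"`, which fits `property ~ descriptor` instead
#' (choose which property via `property`).
#'
#' @param descriptor_values Named numeric vector (names = molecule ids), or a
#'   data.frame with columns `molecule` and the descriptor named by
#'   `descriptor`.
#' @param props Property table (see [read_property_table()]).
#' @param descriptor Descriptor name (used for reporting; required when
#'   `descriptor_values` is a data.frame).
#' @param response `"descriptor"` (default, screening direction) or
#'   `"property"` (prediction direction).
#' @param property Which property is the response in the inverted direction.
#' @return An object of class `qspr_model`: list with `response`,
#'   `coefficients`, `ci95` (half-widths), `r2`, `rho`, `s` (residual standard
#'   error), `n` and the underlying `lm` fit.
#' @examples
#' props <- data.frame(molecule = letters[1:6],
#'                     Hc = c(80, 120, 160, 160, 200, 230),
#'                     Ent = c(270, 330, 390, 395, 450, 500))
#' y <- 2 * props$Hc - props$Ent + 5
#' names(y) <- props$molecule
#' m <- fit_property_model(y, props, descriptor = "En_H")
#' m$coefficients  # (Hc, Ent, intercept) = (2, -1, 5); m$r2 == 1
#' @export
fit_property_model <- function(descriptor_values, props,
                               descriptor = "descriptor",
                               response = c("descriptor", "property"),
                               property = c("Hc", "Ent")) {
  response <- match.arg(response)
  property <- match.arg(property)
  if (is.data.frame(descriptor_values)) {
    if (!descriptor %in% names(descriptor_values))
      stop("column '", descriptor, "' not found in descriptor table")
    v <- descriptor_values[[descriptor]]
    names(v) <- descriptor_values$molecule
    descriptor_values <- v
  }
  ids <- names(descriptor_values)
  if (is.null(ids)) stop("descriptor values must be named by molecule id")
  missing_ids <- setdiff(ids, props$molecule)
  if (length(missing_ids))
    stop("molecules missing from property table: ",
         paste(missing_ids, collapse = ", "))
  props <- props[match(ids, props$molecule), ]
  n <- length(ids)
  if (n < 4L) stop("at least 4 molecules are required for a 3-parameter fit")
  dat <- data.frame(y = as.numeric(descriptor_values),
                    Hc = props$Hc, Ent = props$Ent)
  if (response == "descriptor") {
    if (abs(stats::cor(dat$Hc, dat$Ent)) > 1 - 1e-12)
      stop("Hc and Ent are collinear; the joint fit is not identifiable")
    fit <- stats::lm(y ~ Hc + Ent, data = dat)
    cf <- stats::coef(fit)[c("Hc", "Ent", "(Intercept)")]
    names(cf) <- c("Hc", "Ent", "intercept")
  } else {
    dat$p <- dat[[property]]
    fit <- stats::lm(p ~ y, data = dat)
    cf <- stats::coef(fit)[c("y", "(Intercept)")]
    names(cf) <- c(descriptor, "intercept")
  }
  sm <- summary(fit)
  se <- sm$coefficients[, "Std. Error"]
  se <- se[match(c("Hc", "Ent", "(Intercept)", "y"), names(se), nomatch = 0L)]
  dfree <- fit$df.residual
  ci95 <- stats::qt(0.975, dfree) * se
  names(ci95) <- names(cf)
  r2 <- sm$r.squared
  structure(list(
    response = if (response == "descriptor") descriptor else property,
    direction = response,
    coefficients = cf,
    ci95 = ci95,
    r2 = r2,
    rho = sqrt(r2),
    s = sm$sigma,
    n = n,
    fit = fit
  ), class = "qspr_model")
}

#' @export
print.qspr_model <- function(x, ...) {
  cat(sprintf("<qspr_model %s: n = %d, r2 = %.4f, rho = %.4f, s = %.4f>\n",
              x$response, x$n, x$r2, x$rho, x$s))
  co <- sprintf("%.4f (+/-%.4f)", x$coefficients, x$ci95)
  cat(paste(sprintf("  %-10s %s", names(x$coefficients), co), collapse = "\n"), "\n")
  invisible(x)
}

#' Rank descriptors by multiple correlation
#'
#' Sorts descriptors by the multiple correlation coefficient rho, descending;
#' the nearer rho is to one, the more effective the descriptor. Ties are broken
#' alphabetically by descriptor name.
#'
#' @param models Either a list of `qspr_model` objects or a data.frame with
#'   columns `descriptor` and `rho`.
#' @param k Optionally keep only the top k.
#' @return data.frame with columns `descriptor`, `rho`, `placement`.
#' @export
rank_descriptors <- function(models, k = NULL) {
  if (is.data.frame(models)) {
    tab <- models[c("descriptor", "rho")]
  } else {
    if (!length(models)) stop("at least one model is required")
    tab <- data.frame(
      descriptor = vapply(models, function(m) m$response, character(1)),
      rho = vapply(models, function(m) m$rho, numeric(1)))
  }
  tab <- tab[order(-tab$rho, tab$descriptor), ]
  tab$placement <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  if (!is.null(k)) tab <- tab[seq_len(min(k, nrow(tab))), ]
  tab
}

#' Polynomial series fit with 95% confidence intervals
#'
#' Least-squares fit of a descriptor series against a structure size parameter
#' (e.g. the number of hexagon layers), linear or quadratic. Confidence
#' half-widths use the t-distribution as in [fit_property_model()].
#'
#' @param x Integer (or numeric) size sequence.
#' @param y Descriptor values.
#' @param form `"linear"` or `"quadratic"`.
#' @return List with `form`, `coefficients` (highest degree first, intercept
#'   last), `ci95`, `r2`, `s`, `n`, `fit`.
#' @export
fit_series <- function(x, y, form = c("linear", "quadratic")) {
  form <- match.arg(form)
  degree <- if (form == "linear") 1L else 2L
  if (length(x) != length(y)) stop("`x` and `y` lengths differ")
  if (length(x) < degree + 2L)
    stop(sprintf("need at least %d points for a %s fit", degree + 2L, form))
  dat <- data.frame(x = as.numeric(x), y = as.numeric(y))
  fit <- if (degree == 1L) stats::lm(y ~ x, data = dat)
         else stats::lm(y ~ I(x^2) + x, data = dat)
  sm <- summary(fit)
  cf <- stats::coef(fit)
  ord <- if (degree == 1L) c("x", "(Intercept)") else c("I(x^2)", "x", "(Intercept)")
  cf <- cf[ord]
  se <- sm$coefficients[ord, "Std. Error"]
  ci95 <- stats::qt(0.975, fit$df.residual) * se
  names(cf) <- names(ci95) <-
    if (degree == 1L) c("slope", "intercept") else c("quadratic", "slope", "intercept")
  list(form = form, coefficients = cf, ci95 = ci95,
       r2 = sm$r.squared, s = sm$sigma, n = length(x), fit = fit)
}
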