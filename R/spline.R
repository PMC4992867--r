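#' Select knots for a least-squares cubic spline
#'
#' Places `n_interior` interior knots at quantiles of the observation times
#' and adjusts them minimally so that the Schoenberg-Whitney admissibility
#' condition holds: every cubic B-spline basis function's support must
#' contain at least one data point, and a strictly interleaving assignment
#' of data points to basis functions must exist. Knots are taken at data
#' sites with at least one observation strictly between consecutive interior
#' knots, which guarantees admissibility on a strictly increasing grid.
#' Boundary knots are repeated `degree + 1` times at the data extremes.
#'
#' With `n_interior = 0` the fit degenerates to a single global cubic
#' least-squares polynomial.
#'
#' @param time_min Strictly increasing numeric vector of observation times.
#' @param n_interior Number of interior knots (>= 0).
#' @return Full knot vector (numeric) with attribute `"interior"` holding
#'   the interior knots.
#' @export
select_knots <- function(time_min, n_interior) {
  x <- as.numeric(time_min)
  n <- length(x)
  if (any(diff(x) <= 0)) {
    abort("time_min must be strictly increasing")
  }
  if (n_interior < 0) {
    abort("n_interior must be >= 0")
  }
  min_pts <- n_interior + 4
  if (n < min_pts) {
    abort(paste0("Need at least ", min_pts, " data points for a cubic ",
                 "spline with ", n_interior, " interior knots; got ", n))
  }
  degree <- 3L
  boundary <- c(rep(x[1], degree + 1), rep(x[n], degree + 1))
  if (n_interior == 0) {
    knots <- sort(boundary)
  } else {
    # Quantile-indexed data sites, thinned to keep >= 1 observation strictly
    # inside every inter-knot interval (index gap >= 2).
    probs <- seq_len(n_interior) / (n_interior + 1)
    idx <- unique(pmin(pmax(round(quantile(seq_len(n), probs, names = FALSE,
                                           type = 7)), 2L), n - 1L))
    idx <- thin_indices(idx, lo = 2L, hi = n - 1L, gap = 2L)
    interior <- x[idx]
    knots <- sort(c(boundary, interior))
  }
  interior <- knots[knots > x[1] & knots < x[n]]
  if (!sw_admissible(knots, x)) {
    abort("Could not construct an admissible knot vector for these data")
  }
  structure(knots, interior = interior)
}

# Enforce a minimum index gap between knot sites within [lo, hi]; drops
# sites that cannot be shifted without violating the gap.
thin_indices <- function(idx, lo, hi, gap) {
  out <- integer(0)
  prev <- lo - gap
  for (i in sort(unique(idx))) {
    i <- max(i, prev + gap)
    if (i > hi) break
    out <- c(out, i)
    prev <- i
  }
  out
}

#' Schoenberg-Whitney admissibility of a knot vector
#'
#' Tests whether a full knot vector admits a unique least-squares B-spline
#' fit for the given data sites: there must exist strictly increasing data
#' points \eqn{x_{j_1} < \dots < x_{j_m}} with \eqn{x_{j_i}} inside the
#' support of the i-th basis function. Checked greedily; equality with the
#' outermost boundary knots is allowed.
#'
#' @param knots Full knot vector (boundary knots repeated `ord` times).
#' @param x Data sites (need not be sorted).
#' @param ord Spline order (degree + 1); 4 for cubics.
#' @return `TRUE` if admissible.
#' @export
sw_admissible <- function(knots, x, ord = 4L) {
  knots <- sort(as.numeric(knots))
  x <- sort(as.numeric(x))
  n_basis <- length(knots) - ord
  if (n_basis < 1 || length(x) < n_basis) return(FALSE)
  lo_all <- knots[1]
  hi_all <- knots[length(knots)]
  j <- 1L
  for (i in seq_len(n_basis)) {
    lo <- knots[i]
    hi <- knots[i + ord]
    ok <- FALSE
    while (j <= length(x)) {
      inside <- (x[j] > lo && x[j] < hi) ||
        (x[j] == lo_all && lo == lo_all) ||
        (x[j] == hi_all && hi == hi_all)
      if (inside) {
        ok <- TRUE
        j <- j + 1L
        break
      }
      if (x[j] >= hi) break
      j <- j + 1L
    }
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Fit a least-squares cubic B-spline
#'
#' Finds the cubic B-spline over the given knots minimizing the sum of
#' squared residuals. Because cubics lie in the spline space for any
#' admissible knot vector, cubic-polynomial data are reproduced to machine
#' precision.
#'
#' @param x Observation sites (strictly increasing).
#' @param y Observations, same length as `x`.
#' @param knots Full knot vector from [select_knots()], or a number of
#'   interior knots to select automatically.
#' @return An object of class `lsq_spline` with `predict()`, `fitted()`,
#'   `residuals()`, [tidy()] and [glance()] methods.
#' @examples
#' x <- seq(0, 100, by = 2)
#' fit <- fit_lsq_cubic_spline(x, x^3, knots = select_knots(x, 5))
#' max(abs(residuals(fit)))
#' @export
fit_lsq_cubic_spline <- function(x, y, knots) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  stopifnot(length(x) == length(y))
  if (length(knots) == 1 && knots == round(knots) && knots >= 0 &&
      is.null(attr(knots, "interior"))) {
    knots <- select_knots(x, as.integer(knots))
  }
  knots <- sort(as.numeric(knots))
  ord <- 4L
  if (!sw_admissible(knots, x, ord)) {
    abort(paste0("Knot vector violates the Schoenberg-Whitney conditions ",
                 "for these data (singular design)"))
  }
  B <- splines::splineDesign(knots, x, ord = ord)
  qrB <- qr(B)
  if (qrB$rank < ncol(B)) {
    abort("Singular spline design matrix; choose fewer or better-placed knots")
  }
  coef <- qr.coef(qrB, y)
  fit <- drop(B %*% coef)
  structure(
    list(knots = knots, coef = coef, degree = 3L,
         range = range(x), n = length(x),
         fitted = fit, residuals = y - fit),
    class = "lsq_spline")
}

#' Evaluate a fitted least-squares spline
#'
#' @param object `lsq_spline` object.
#' @param x Evaluation sites within the fitted range.
#' @param deriv Derivative order (0, 1 or 2).
#' @param ... Unused.
#' @return Numeric vector of spline (derivative) values.
#' @export
predict.lsq_spline <- function(object, x, deriv = 0L, ...) {
  x <- as.numeric(x)
  if (any(x < object$range[1] | x > object$range[2])) {
    abort("Evaluation sites outside the fitted range")
  }
  B <- splines::splineDesign(object$knots, x, ord = object$degree + 1L,
                             derivs = rep(as.integer(deriv), length(x)))
  drop(B %*% object$coef)
}

#' @export
fitted.lsq_spline <- function(object, ...) object$fitted

#' @export
residuals.lsq_spline <- function(object, ...) object$residuals

#' @export
print.lsq_spline <- function(x, ...) {
  interior <- x$knots[x$knots > x$range[1] & x$knots < x$range[2]]
  cat("Least-squares cubic B-spline\n")
  cat("  data points: ", x$n, "\n", sep = "")
  cat("  interior knots: ", length(interior), "\n", sep = "")
  cat("  residual RMS: ", signif(sqrt(mean(x$residuals^2)), 4), "\n", sep = "")
  invisible(x)
}

#' Tidy a fitted least-squares spline
#'
#' @param x `lsq_spline` object.
#' @param ... Unused.
#' @return Tibble of B-spline coefficients with their knot spans.
#' @export
tidy.lsq_spline <- function(x, ...) {
  ord <- x$degree + 1L
  n_basis <- length(x$coef)
  tibble(term = paste0("b", seq_len(n_basis)),
         estimate = as.numeric(x$coef),
         support_lo = x$knots[seq_len(n_basis)],
         support_hi = x$knots[seq_len(n_basis) + ord])
}

#' One-row summary of a fitted least-squares spline
#'
#' @param x `lsq_spline` object.
#' @param ... Unused.
#' @return Tibble with data size, basis size, knot count and residual RMS.
#' @export
glance.lsq_spline <- function(x, ...) {
  interior <- x$knots[x$knots > x$range[1] & x$knots < x$range[2]]
  tibble(nobs = x$n,
         n_basis = length(x$coef),
         n_interior_knots = length(interior),
         sigma = sqrt(mean(x$residuals^2)),
         rss = sum(x$residuals^2))
}
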