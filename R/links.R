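#' Construct a parametric monotone link specification
#'
#' The latent-process model observes cognition through a strictly increasing
#' transformation `h(y)` that normalizes the raw score to the latent scale.
#' Four families are supported: `"linear"` (affine; used as the identity at
#' estimation time, with the residual standard deviation estimated freely),
#' `"beta"` (rescaled Beta cumulative distribution function with location and
#' scale), and monotone I-spline families with knots placed either
#' equidistantly (`"splines_equidistant"`) or at empirical quantiles of the
#' outcome (`"splines_quantile"`).
#'
#' For the spline families the transform is
#' \deqn{h(y) = \eta_0 + \sum_{k=1}^{K+1} \eta_k^2 I_k(y)}
#' where the `I_k` are monotone I-splines (integrated M-splines) on `n_knots`
#' total knots (boundary knots at the observed outcome range) and the squared
#' parametrization enforces nonnegative basis coefficients, hence a
#' nondecreasing transform. With `n_knots` total knots the basis has
#' `n_knots + 1` members, so the family carries `n_knots + 2` parameters.
#'
#' @param family one of `"linear"`, `"beta"`, `"splines_equidistant"`,
#'   `"splines_quantile"`.
#' @param n_knots total number of knots including the two boundary knots
#'   (ignored for `"linear"` and `"beta"`).
#' @param outcomes numeric vector of observed outcome values; defines the
#'   boundary knots / rescaling range.
#' @return an object of class `link_spec`: list with `family`, `knots`,
#'   `range`, `n_par` (number of link parameters) and, for spline families,
#'   the augmented knot sequence used to build the basis.
#' @export
build_link <- function(family = c("linear", "splines_equidistant",
                                  "splines_quantile", "beta"),
                       n_knots = 5L, outcomes) {
  family <- match.arg(family)
  if (missing(outcomes) || length(outcomes) == 0L || anyNA(outcomes))
    stop("'outcomes' must be a non-missing numeric vector")
  rng <- range(outcomes)
  if (rng[2] <= rng[1]) stop("degenerate outcome range: max(outcomes) must exceed min(outcomes)")

  spec <- list(family = family, range = rng)
  if (family == "linear") {
    spec$knots <- NULL
    spec$n_par <- 2L          # location, scale (fixed to identity at fit time)
  } else if (family == "beta") {
    spec$knots <- NULL
    spec$n_par <- 4L          # two shapes, location, scale
    spec$epsilon <- 1e-4      # open-interval rescaling margin
  } else {
    n_knots <- as.integer(n_knots)
    if (n_knots < 2L) stop("spline links need at least 2 knots (the boundary knots)")
    knots <- if (family == "splines_equidistant") {
      seq(rng[1], rng[2], length.out = n_knots)
    } else {
      if (n_knots > length(unique(outcomes)))
        stop("n_knots exceeds the number of distinct outcome values")
      as.numeric(stats::quantile(outcomes, probs = seq(0, 1, length.out = n_knots),
                                 type = 7, names = FALSE))
    }
    if (anyDuplicated(knots))
      stop("duplicated knots: outcome distribution too coarse for n_knots = ", n_knots)
    spec$knots <- knots
    spec$n_knots <- n_knots
    # cubic B-spline augmented sequence; I-splines arise as right partial sums
    spec$aug_knots <- c(rep(rng[1], 4L), knots[-c(1L, n_knots)], rep(rng[2], 4L))
    spec$n_basis <- n_knots + 1L
    spec$n_par <- n_knots + 2L
  }
  class(spec) <- "link_spec"
  spec
}

#' @export
print.link_spec <- function(x, ...) {
  cat("<link_spec> family:", x$family, "| parameters:", x$n_par, "\n")
  if (!is.null(x$knots)) cat("  knots:", paste(signif(x$knots, 5), collapse = ", "), "\n")
  invisible(x)
}

# I-spline design matrices on the augmented cubic knot sequence.
# I_k(y) = sum_{j > k} B_j(y) over the cubic B-spline basis: each column is
# nondecreasing from 0 to 1. derivs = 1 gives the M-spline (density) basis.
ispline_basis <- function(y, spec, derivs = 0L) {
  stopifnot(inherits(spec, "link_spec"), !is.null(spec$aug_knots))
  n_b4 <- length(spec$aug_knots) - 4L          # cubic B-spline count = n_knots + 2
  B <- splines::splineDesign(spec$aug_knots, y, ord = 4L,
                             derivs = rep(derivs, length(y)))
  # right-to-left cumulative sums, dropping the first B-spline
  out <- matrix(0, nrow = length(y), ncol = spec$n_basis)
  acc <- rep(0, length(y))
  for (j in n_b4:2L) {
    acc <- acc + B[, j]
    out[, j - 1L] <- acc
  }
  out
}

#' Evaluate a monotone link transform and its derivative
#'
#' @param y numeric vector of outcome values.
#' @param spec a [build_link()] specification.
#' @param eta numeric vector of link parameters (length `spec$n_par`). For
#'   spline families `eta[1]` is the intercept and `eta[-1]` are the square
#'   roots of the basis coefficients; for `"beta"`,
#'   `eta = (sqrt(a), sqrt(b), location, sqrt(scale))`; for `"linear"`,
#'   `eta = (location, scale)`.
#' @return list with components `h` (transformed values) and `dh`
#'   (derivative of the transform, strictly positive wherever defined).
#' @export
link_transform <- function(y, spec, eta) {
  stopifnot(inherits(spec, "link_spec"))
  if (length(eta) != spec$n_par)
    stop("eta has length ", length(eta), ", expected ", spec$n_par)
  if (anyNA(y)) stop("missing outcome values passed to link_transform")
  switch(spec$family,
    linear = {
      if (eta[2] <= 0) stop("linear link scale must be positive")
      list(h = (y - eta[1]) / eta[2], dh = rep(1 / eta[2], length(y)))
    },
    beta = {
      eps <- spec$epsilon
      if (any(y < spec$range[1] - 1e-12) || any(y > spec$range[2] + 1e-12))
        stop("outcome value outside the link support [",
             spec$range[1], ", ", spec$range[2], "]")
      u <- eps + (1 - 2 * eps) * (y - spec$range[1]) / diff(spec$range)
      u <- pmin(pmax(u, eps / 2), 1 - eps / 2)
      a <- eta[1]^2 + 1e-6
      b <- eta[2]^2 + 1e-6
      sc <- eta[4]^2 + 1e-8
      h <- (stats::pbeta(u, a, b) - eta[3]) / sc
      dh <- stats::dbeta(u, a, b) * (1 - 2 * eps) / diff(spec$range) / sc
      list(h = h, dh = dh)
    },
    {
      if (any(y < spec$range[1] - 1e-12) || any(y > spec$range[2] + 1e-12))
        stop("outcome value outside the spline support [",
             spec$range[1], ", ", spec$range[2], "]")
      y <- pmin(pmax(y, spec$range[1]), spec$range[2])
      coefs <- eta[-1]^2
      IB <- ispline_basis(y, spec, derivs = 0L)
      MB <- ispline_basis(y, spec, derivs = 1L)
      list(h = eta[1] + drop(IB %*% coefs), dh = drop(MB %*% coefs))
    }
  )
}

# Reasonable starting values for the link parameters: map the observed range
# approximately onto the standardized outcome scale.
link_init <- function(spec, outcomes) {
  m <- mean(outcomes); s <- stats::sd(outcomes)
  switch(spec$family,
    linear = c(0, 1),
    beta = c(1, 1, 0.5, sqrt(0.3)),
    {
      span <- diff(spec$range) / s
      c((spec$range[1] - m) / s, rep(sqrt(span / spec$n_basis), spec$n_basis))
    }
  )
}

# TRUE when the link carries free parameters (latent-process scale fixed by
# sigma_eps = 1 and class-1 intercept = 0); FALSE for the identity-linear case.
link_is_estimated <- function(spec) spec$family != "linear"
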