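#' Specify a latent class mixed model
#'
#' A finite mixture of linear mixed models on a latent cognitive process.
#' Class membership follows an intercept-only multinomial logit; the latent
#' process is
#' \deqn{\Lambda_{ij} = X_{ij}\beta + U_{ij}\delta_g + Z_{ij} b_i + \epsilon_{ij}}
#' with class-common fixed effects \eqn{\beta} over `shared_design`,
#' class-specific coefficients \eqn{\delta_g} over `class_design`
#' (by default intercept and time, i.e. the trajectory itself), subject
#' random effects \eqn{b_i \sim N(0, B)} over `random_design`, and the
#' outcome observed through the monotone link `h` of a [build_link()]
#' specification.
#'
#' @param n_classes number of latent classes G (>= 1).
#' @param link a `link_spec` from [build_link()].
#' @param shared_design character vector of cohort columns with class-common
#'   coefficients (no intercept; the intercept is class-specific).
#' @param class_design columns with class-specific coefficients; must contain
#'   `"intercept"` and may contain `"time"`.
#' @param random_design subject random-effect columns, a subset of
#'   `c("intercept", "time")`.
#' @param class_variance_scaling if `TRUE`, estimate class-specific
#'   proportional scalings \eqn{\omega_g} of the random-effect covariance
#'   (\eqn{\omega_G = 1}).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(n_classes,
                       link,
                       shared_design = c("baseline_age", "sex", "abeta",
                                         "tau_ec", "adj_hv"),
                       class_design = c("intercept", "time"),
                       random_design = c("intercept", "time"),
                       class_variance_scaling = FALSE) {
  n_classes <- as.integer(n_classes)
  stopifnot(n_classes >= 1L, inherits(link, "link_spec"))
  if (length(class_design) == 0L) stop("class_design must be non-empty")
  if (!"intercept" %in% class_design) stop("class_design must contain 'intercept'")
  if (!all(random_design %in% c("intercept", "time")))
    stop("random_design must be a subset of c('intercept', 'time')")
  structure(list(n_classes = n_classes, link = link,
                 shared_design = shared_design, class_design = class_design,
                 random_design = random_design,
                 class_variance_scaling = isTRUE(class_variance_scaling)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> G =", x$n_classes, "| link:", x$link$family, "\n")
  cat("  shared:", paste(x$shared_design, collapse = ", "), "\n")
  cat("  class-specific:", paste(x$class_design, collapse = ", "),
      "| random:", paste(x$random_design, collapse = ", "), "\n")
  invisible(x)
}

# ---- parameter layout -------------------------------------------------------
#
# The free parameter vector theta is laid out as
#   xi      (G-1)                class-membership logits, class G is reference
#   beta    (p)                  shared fixed effects
#   delta   (q_c x G, minus the  class-specific coefficients, column-major;
#            class-1 intercept   with an estimated link the class-1 intercept
#            when link estimated) is fixed at 0 for identifiability
#   chol(B) (q_r (q_r+1) / 2)    row-wise lower triangle of the Cholesky factor
#   s       (1, linear link)     sigma_eps = |s|; omitted (fixed 1) otherwise
#   eta     (link$n_par)         only when the link is estimated
#   omega   (G-1, optional)      sqrt of class variance scalings, omega_G = 1

param_layout <- function(spec) {
  G <- spec$n_classes
  p <- length(spec$shared_design)
  qc <- length(spec$class_design)
  qr <- length(spec$random_design)
  est_link <- link_is_estimated(spec$link)
  n_delta <- qc * G - if (est_link) 1L else 0L
  n_chol <- qr * (qr + 1L) / 2L
  n_sigma <- if (est_link) 0L else 1L
  n_eta <- if (est_link) spec$link$n_par else 0L
  n_omega <- if (spec$class_variance_scaling) G - 1L else 0L
  sizes <- as.integer(c(xi = G - 1L, beta = p, delta = n_delta, chol = n_chol,
                        sigma = n_sigma, eta = n_eta, omega = n_omega))
  names(sizes) <- c("xi", "beta", "delta", "chol", "sigma", "eta", "omega")
  offs <- cumsum(c(0L, sizes))[seq_along(sizes)]
  names(offs) <- names(sizes)
  list(sizes = sizes, offsets = offs, total = as.integer(sum(sizes)),
       G = G, p = p, qc = qc, qr = qr, est_link = est_link)
}

#' Number of free parameters of a model specification
#' @param spec a [model_spec()].
#' @return integer count of free parameters.
#' @export
n_parameters <- function(spec) param_layout(spec)$total

take <- function(theta, layout, what) {
  n <- layout$sizes[[what]]
  if (n == 0L) return(numeric(0))
  off <- layout$offsets[[what]]
  theta[(off + 1L):(off + n)]
}

# Unpack theta into interpretable components.
unpack_params <- function(theta, spec) {
  layout <- param_layout(spec)
  if (length(theta) != layout$total)
    stop("parameter vector has length ", length(theta),
         ", expected ", layout$total)
  G <- layout$G; qc <- layout$qc; qr <- layout$qr
  xi <- take(theta, layout, "xi")
  beta <- take(theta, layout, "beta")
  d <- take(theta, layout, "delta")
  if (layout$est_link) d <- c(0, d)          # class-1 latent intercept fixed
  delta <- matrix(d, nrow = qc, ncol = G)    # delta[, g]; intercept row first
  L <- matrix(0, qr, qr)
  L[lower.tri(L, diag = TRUE)] <- take(theta, layout, "chol")
  sigma <- if (layout$est_link) 1.0 else abs(take(theta, layout, "sigma"))
  eta <- if (layout$est_link) take(theta, layout, "eta") else
    c(0, 1)[seq_len(spec$link$n_par)]
  omega <- if (spec$class_variance_scaling) c(take(theta, layout, "omega"), 1) else
    rep(1, G)
  list(xi = xi, beta = beta, delta = delta, L = L, B = L %*% t(L),
       sigma = sigma, eta = eta, omega = omega, layout = layout)
}

pack_params <- function(xi, beta, delta, L, sigma, eta, spec, omega = NULL) {
  layout <- param_layout(spec)
  d <- as.numeric(delta)
  if (layout$est_link) d <- d[-1L]
  out <- c(xi, beta, d, L[lower.tri(L, diag = TRUE)],
           if (!layout$est_link) sigma,
           if (layout$est_link) eta,
           if (spec$class_variance_scaling) omega[-spec$n_classes])
  stopifnot(length(out) == layout$total)
  out
}

#' Class-membership probabilities from logit intercepts
#'
#' Softmax with the last class as reference: \eqn{\pi_g =
#' \exp(\xi_g) / \sum_h \exp(\xi_h)} with \eqn{\xi_G = 0}.
#'
#' @param xi numeric vector of G-1 logit intercepts (may be empty for G = 1).
#' @return vector of G probabilities summing to 1.
#' @export
class_probabilities <- function(xi) {
  z <- c(xi, 0)
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}
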