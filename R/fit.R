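#' Control settings for LCMM estimation
#'
#' @param max_iter maximum optimizer iterations.
#' @param tol_param convergence tolerance on the largest absolute parameter
#'   change of an accepted step.
#' @param tol_loglik tolerance on the log-likelihood change.
#' @param tol_grad tolerance on the scaled gradient criterion
#'   \eqn{g' H^{-1} g / \mathrm{npar}}.
#' @param refine if `TRUE`, follow the quasi-Newton phase with damped-Newton
#'   (Marquardt) refinement until all three criteria hold; burn-in fits in the
#'   grid search disable this.
#' @param refine_max maximum refinement iterations.
#' @return list of class `lcmm_control`.
#' @export
lcmm_control <- function(max_iter = 500L, tol_param = 1e-4, tol_loglik = 1e-4,
                         tol_grad = 1e-4, refine = TRUE, refine_max = 25L) {
  structure(list(max_iter = as.integer(max_iter), tol_param = tol_param,
                 tol_loglik = tol_loglik, tol_grad = tol_grad,
                 refine = isTRUE(refine), refine_max = as.integer(refine_max)),
            class = "lcmm_control")
}

# Negative log-likelihood on the (scaled-design) parameter vector; large
# finite penalty outside the feasible region so optim can recover.
make_objective <- function(md, spec) {
  bad <- 1e10
  function(theta) {
    up <- try(unpack_params(theta, spec), silent = TRUE)
    if (inherits(up, "try-error")) return(bad)
    sd_ <- tryCatch(subject_logdens(md, spec, up), error = function(e) NULL)
    if (is.null(sd_)) return(bad)
    ll <- sum(log_row_sum_exp(sd_$logdens) + sd_$jacobian)
    if (!is.finite(ll)) return(bad)
    -ll
  }
}

#' Fit a latent class mixed model by maximum likelihood
#'
#' Maximizes the mixture log-likelihood by a quasi-Newton (BFGS) ascent
#' followed by damped-Newton (Marquardt) refinement. Convergence is declared
#' only when three criteria hold simultaneously on an accepted step: the
#' largest parameter change is below `tol_param`, the log-likelihood change
#' is below `tol_loglik`, and \eqn{g' H^{-1} g / \mathrm{npar}} is below
#' `tol_grad`. Continuous shared covariates are z-scored internally for
#' optimizer conditioning; reported estimates are back-transformed.
#'
#' @param cohort a [longitudinal_cohort()].
#' @param spec a [model_spec()].
#' @param init optional initial [parameter_vector()] or packed numeric vector
#'   (on the original covariate scale); defaults to a data-driven start.
#' @param control an [lcmm_control()].
#' @return object of class `lcmm_fit` with elements `spec`, `params`
#'   (back-transformed [parameter_vector()]), `loglik`, `npar`, `converged`,
#'   `convergence` (per-criterion values), `posterior`, `modal_class`,
#'   `class_counts`, `proportions`, `bic`, `sabic`, `relative_entropy`,
#'   `iterations`, and `trace` (accepted log-likelihood values).
#' @export
fit_lcmm <- function(cohort, spec, init = NULL, control = lcmm_control()) {
  if (!inherits(cohort, "longitudinal_cohort"))
    cohort <- longitudinal_cohort(cohort, require_covariates = spec$shared_design)
  md <- build_model_data(cohort, spec, scale_covariates = TRUE)
  layout <- param_layout(spec)
  theta0 <- if (is.null(init)) default_init(md, spec) else
    rescale_theta(as_theta(init, spec), spec, md, to_internal = TRUE)
  fn <- make_objective(md, spec)
  f0 <- fn(theta0)
  if (f0 >= 1e10) stop("initial parameters give a non-finite likelihood")
  gr <- function(theta) pracma::grad(fn, theta, heps = 1e-6)

  opt <- stats::optim(theta0, fn, gr = gr, method = "BFGS",
                      control = list(maxit = control$max_iter, reltol = 1e-12))
  theta <- opt$par
  f <- opt$value
  trace <- c(-f0, -f)
  iterations <- opt$counts[["function"]]

  converged <- FALSE
  crit <- c(param = NA_real_, loglik = NA_real_, grad = NA_real_)
  singular_hessian <- FALSE
  if (control$refine) {
    lambda <- 1e-3
    for (it in seq_len(control$refine_max)) {
      g <- pracma::grad(fn, theta, heps = 1e-6)
      H <- pracma::hessian(fn, theta, h = 1e-4)
      H <- (H + t(H)) / 2
      dH <- pmax(abs(diag(H)), 1e-6)
      step_ok <- FALSE
      for (k in 1:25) {
        Hd <- H + lambda * diag(dH, length(dH))
        d <- tryCatch(solve(Hd, -g), error = function(e) NULL)
        if (!is.null(d) && all(is.finite(d))) {
          f_new <- fn(theta + d)
          if (f_new <= f + 1e-12) { step_ok <- TRUE; break }
        }
        lambda <- lambda * 10
      }
      if (!step_ok) { singular_hessian <- is.null(d); break }
      d_par <- max(abs(d))
      d_ll <- f - f_new
      theta <- theta + d
      f <- f_new
      trace <- c(trace, -f)
      iterations <- iterations + 1L
      lambda <- max(lambda / 10, 1e-10)
      grad_crit <- tryCatch({
        Hp <- H + 1e-8 * diag(dH, length(dH))
        as.numeric(crossprod(g, solve(Hp, g))) / layout$total
      }, error = function(e) NA_real_)
      crit <- c(param = d_par, loglik = d_ll, grad = abs(grad_crit))
      if (isTRUE(d_par < control$tol_param) &&
          isTRUE(d_ll < control$tol_loglik) &&
          isTRUE(is.finite(grad_crit) && abs(grad_crit) < control$tol_grad)) {
        converged <- TRUE
        break
      }
    }
  }

  build_fit(theta, spec, md, loglik = -f, converged = converged,
            crit = crit, iterations = iterations, trace = trace,
            singular_hessian = singular_hessian)
}

# Assemble the fitted-model object from an internal-scale parameter vector.
build_fit <- function(theta, spec, md, loglik, converged, crit, iterations,
                      trace, singular_hessian = FALSE) {
  layout <- param_layout(spec)
  up <- unpack_params(theta, spec)
  sd_ <- subject_logdens(md, spec, up)
  G <- spec$n_classes
  if (is.null(sd_)) {
    post <- matrix(NA_real_, md$n_subj, G)
    modal <- rep(NA_integer_, md$n_subj)
  } else {
    lse <- log_row_sum_exp(sd_$logdens)
    post <- exp(sd_$logdens - lse)
    modal <- max.col(post, ties.method = "first")
  }
  counts <- tabulate(modal, nbins = G)
  N <- md$n_subj
  ent <- if (G >= 2 && !anyNA(post)) relative_entropy(post) else NA_real_
  theta_orig <- rescale_theta(theta, spec, md, to_internal = FALSE)
  upo <- unpack_params(theta_orig, spec)
  params <- parameter_vector(xi = upo$xi, beta = upo$beta, delta = upo$delta,
                             B_chol = upo$L, sigma_eps = upo$sigma,
                             eta = upo$eta, omega = upo$omega)
  structure(list(
    spec = spec, theta = theta, theta_scaling = list(centers = md$centers,
                                                     scales = md$scales),
    params = params, loglik = loglik, npar = layout$total,
    converged = converged,
    convergence = list(criteria = crit, iterations = iterations,
                       singular_hessian = singular_hessian),
    posterior = post, modal_class = modal,
    subject_ids = md$subject_ids,
    class_counts = counts, proportions = counts / N,
    n_subjects = N, n_obs = md$n_obs,
    bic = bic(loglik, layout$total, N),
    sabic = sabic(loglik, layout$total, N),
    relative_entropy = ent, trace = trace), class = "lcmm_fit")
}

#' @export
print.lcmm_fit <- function(x, ...) {
  cat("<lcmm_fit> G =", x$spec$n_classes, "| link:", x$spec$link$family, "\n")
  cat("  N =", x$n_subjects, "subjects,", x$n_obs, "observations\n")
  cat("  loglik:", format(x$loglik), "| npar:", x$npar,
      "| converged:", x$converged, "\n")
  cat("  SABIC:", format(x$sabic), "| BIC:", format(x$bic),
      "| relative entropy:", format(x$relative_entropy), "\n")
  cat("  class proportions:", paste(signif(x$proportions, 4), collapse = " / "), "\n")
  invisible(x)
}

# Map a parameter vector between the original covariate scale and the
# internal z-scored design scale. beta_int = beta_orig * s; class intercepts
# absorb sum(beta_orig * c).
rescale_theta <- function(theta, spec, md, to_internal = TRUE) {
  if (!length(md$centers) || all(md$scales == 1 & md$centers == 0)) return(theta)
  up <- unpack_params(theta, spec)
  c_ <- md$centers; s_ <- md$scales
  if (to_internal) {
    beta2 <- up$beta * s_
    shift <- sum(up$beta * c_)
    up$delta[1, ] <- up$delta[1, ] + shift
  } else {
    beta2 <- up$beta / s_
    shift <- sum((up$beta / s_) * c_)
    up$delta[1, ] <- up$delta[1, ] - shift
  }
  if (param_layout(spec)$est_link && abs(up$delta[1, 1]) > 1e-12) {
    # keep the class-1 intercept pinned at 0 by pushing the shift into the
    # link intercept (h and the latent process share location freely)
    adj <- up$delta[1, 1]
    up$delta[1, ] <- up$delta[1, ] - adj
    up$eta[1] <- up$eta[1] - adj
  }
  pack_params(up$xi, beta2, up$delta, up$L, up$sigma, up$eta, spec, up$omega)
}

# Data-driven one-class-style start: pooled least squares for the trajectory,
# residual spread for variance components, link_init for the link.
default_init <- function(md, spec) {
  G <- spec$n_classes
  est_link <- link_is_estimated(spec$link)
  y0 <- if (est_link) {
    eta0 <- link_init(spec$link, md$y)
    link_transform(md$y, spec$link, eta0)$h
  } else {
    eta0 <- c(0, 1)
    md$y
  }
  D <- cbind(md$U, md$X)
  cf <- tryCatch(stats::coef(stats::lm.fit(D, y0)), error = function(e) rep(0, ncol(D)))
  cf[is.na(cf)] <- 0
  qc <- ncol(md$U)
  delta1 <- cf[seq_len(qc)]
  beta <- if (ncol(md$X)) cf[qc + seq_len(ncol(md$X))] else numeric(0)
  res_sd <- stats::sd(y0 - drop(D %*% cf))
  if (!is.finite(res_sd) || res_sd <= 0) res_sd <- 1
  qr_ <- length(spec$random_design)
  L <- diag(rep(res_sd * 0.5, qr_), qr_, qr_)
  if (qr_ >= 2) L[qr_, qr_] <- res_sd * 0.1     # slope variability starts small
  # spread class intercepts/slopes around the pooled trajectory
  delta <- matrix(rep(delta1, G), ncol = G)
  if (G > 1) {
    spread <- res_sd * seq(-1, 1, length.out = G)
    delta[1, ] <- delta[1, ] + spread
  }
  if (est_link) {
    adj <- delta[1, 1]
    delta[1, ] <- delta[1, ] - adj
    eta0[1] <- eta0[1] - adj
  }
  sigma <- res_sd * if (est_link) 1 else 0.7
  if (est_link) sigma <- 1
  pack_params(rep(0, G - 1), beta, delta, L, sigma, eta0, spec,
              rep(1, G))
}

#' Posterior class-membership probabilities
#'
#' Bayes-rule posteriors \eqn{p_{ig} = \pi_g f_{ig} / \sum_h \pi_h f_{ih}},
#' computed in log space. Modal assignments break ties toward the lower class
#' index.
#'
#' @param fit an `lcmm_fit`.
#' @param cohort optionally, a cohort to classify (defaults to the fitting
#'   cohort's stored posteriors).
#' @return N x G matrix with unit row sums; attribute `modal` holds the modal
#'   assignment.
#' @export
posterior_matrix <- function(fit, cohort = NULL) {
  stopifnot(inherits(fit, "lcmm_fit"))
  if (is.null(cohort)) {
    post <- fit$posterior
    attr(post, "modal") <- fit$modal_class
    return(post)
  }
  spec <- fit$spec
  md <- build_model_data(cohort, spec, scale_covariates = FALSE)
  up <- unpack_params(rescale_theta(fit$theta, spec,
                                    list(centers = fit$theta_scaling$centers,
                                         scales = fit$theta_scaling$scales),
                                    to_internal = FALSE), spec)
  sd_ <- subject_logdens(md, spec, up)
  if (is.null(sd_)) stop("numerical failure computing posteriors")
  post <- exp(sd_$logdens - log_row_sum_exp(sd_$logdens))
  attr(post, "modal") <- max.col(post, ties.method = "first")
  rownames(post) <- md$subject_ids
  post
}

#' Posterior class probabilities at explicit parameter values
#'
#' Bayes-rule posteriors for a given cohort, model specification and
#' parameter vector, without fitting.
#'
#' @inheritParams total_loglik
#' @return N x G matrix with unit row sums and a `modal` attribute (ties
#'   toward the lower class index).
#' @export
posterior_from_params <- function(cohort, spec, params) {
  md <- build_model_data(cohort, spec, scale_covariates = FALSE)
  up <- unpack_params(as_theta(params, spec), spec)
  sd_ <- subject_logdens(md, spec, up)
  if (is.null(sd_)) stop("numerical failure computing posteriors")
  post <- exp(sd_$logdens - log_row_sum_exp(sd_$logdens))
  attr(post, "modal") <- max.col(post, ties.method = "first")
  rownames(post) <- md$subject_ids
  post
}

#' Relative entropy of a posterior classification
#'
#' \eqn{E = 1 - \frac{-\sum_i \sum_g p_{ig} \ln p_{ig}}{N \ln G}}; values near
#' 1 indicate crisp classification, 0 an uninformative one.
#'
#' @param posterior N x G matrix of posterior probabilities (G >= 2, unit row
#'   sums).
#' @return scalar between 0 and 1.
#' @export
relative_entropy <- function(posterior) {
  posterior <- as.matrix(posterior)
  G <- ncol(posterior)
  if (G < 2L) stop("relative entropy is undefined for G = 1")
  pl <- posterior * log(posterior)
  pl[posterior == 0] <- 0
  ent <- -sum(pl)
  1 - ent / (nrow(posterior) * log(G))
}

#' Bayesian information criterion
#' @param loglik maximized log-likelihood.
#' @param npar number of free parameters.
#' @param N number of subjects.
#' @return `-2 loglik + npar * log(N)`.
#' @export
bic <- function(loglik, npar, N) -2 * loglik + npar * log(N)

#' Sample-size-adjusted BIC
#'
#' Uses the adjusted sample size `(N + 2) / 24`; lower values indicate better
#' fit. Preferred over BIC for cohorts below ~1000 subjects.
#'
#' @inheritParams bic
#' @return `-2 loglik + npar * log((N + 2) / 24)`.
#' @export
sabic <- function(loglik, npar, N) -2 * loglik + npar * log((N + 2) / 24)
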