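#' Assemble a longitudinal analysis cohort
#'
#' Validates and orders the long-format table the latent class mixed model
#' consumes: one row per cognitive visit, with the subject's baseline
#' covariates repeated on each row.
#'
#' @param data data.frame with columns `subject_id`, `time` (years from the
#'   subject's cognitive baseline), `outcome` (cognitive score), and the
#'   baseline covariates `baseline_age`, `sex` (1 = female), `abeta`,
#'   `tau_ec`, `adj_hv` (or whatever a [model_spec()] names in its
#'   `shared_design`).
#' @param require_covariates character vector of covariate columns that must
#'   be present and complete.
#' @return `data` ordered by subject and time, classed `longitudinal_cohort`.
#' @details Invariants enforced: every subject has at least 2 visits, visit
#'   times are strictly increasing within subject with the first equal to 0,
#'   and no retained visit has a missing outcome. Covariates must be constant
#'   within subject (complete-case).
#' @export
longitudinal_cohort <- function(data,
                                require_covariates = c("baseline_age", "sex",
                                                       "abeta", "tau_ec",
                                                       "adj_hv")) {
  need <- c("subject_id", "time", "outcome", require_covariates)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("cohort table is missing columns: ", paste(miss, collapse = ", "))
  data <- as.data.frame(data)
  data <- data[order(data$subject_id, data$time), , drop = FALSE]
  rownames(data) <- NULL
  if (anyNA(data$outcome)) stop("missing outcome at retained visits")
  if (anyNA(data[require_covariates])) stop("incomplete covariates: cohort must be complete-case")
  sp <- split(seq_len(nrow(data)), data$subject_id)
  for (idx in sp) {
    tt <- data$time[idx]
    if (length(tt) < 2L)
      stop("subject ", data$subject_id[idx[1]], " has fewer than 2 visits")
    if (abs(tt[1]) > 1e-9)
      stop("subject ", data$subject_id[idx[1]], " first visit time is not 0")
    if (any(diff(tt) <= 0))
      stop("subject ", data$subject_id[idx[1]], " visit times are not strictly increasing")
    for (v in require_covariates)
      if (length(unique(data[[v]][idx])) != 1L)
        stop("covariate '", v, "' varies within subject ", data$subject_id[idx[1]])
  }
  class(data) <- c("longitudinal_cohort", "data.frame")
  data
}

# Stack the model's design pieces for the likelihood core. Ordering follows
# the cohort (already subject/time sorted). When scale_covariates = TRUE,
# continuous shared covariates are z-scored and centers/scales recorded so
# estimates can be reported on the original scale.
build_model_data <- function(cohort, spec, scale_covariates = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  if (!inherits(cohort, "longitudinal_cohort"))
    cohort <- longitudinal_cohort(cohort, require_covariates = spec$shared_design)
  ids <- unique(cohort$subject_id)
  len <- as.integer(table(factor(cohort$subject_id, levels = ids)))
  start0 <- cumsum(c(0L, len[-length(len)]))
  design_col <- function(nm) {
    if (nm == "intercept") rep(1, nrow(cohort)) else cohort[[nm]]
  }
  X <- if (length(spec$shared_design))
    do.call(cbind, lapply(spec$shared_design, design_col)) else
    matrix(0, nrow(cohort), 0L)
  colnames(X) <- spec$shared_design
  centers <- rep(0, ncol(X)); scales <- rep(1, ncol(X))
  names(centers) <- names(scales) <- spec$shared_design
  if (scale_covariates && ncol(X)) {
    for (j in seq_len(ncol(X))) {
      xj <- X[, j]
      binary <- all(xj %in% c(0, 1))
      if (!binary && stats::sd(xj) > 0) {
        centers[j] <- mean(xj); scales[j] <- stats::sd(xj)
        X[, j] <- (xj - centers[j]) / scales[j]
      }
    }
  }
  U <- do.call(cbind, lapply(spec$class_design, design_col))
  colnames(U) <- spec$class_design
  Z <- if (length(spec$random_design))
    do.call(cbind, lapply(spec$random_design, design_col)) else
    matrix(0, nrow(cohort), 0L)
  md <- list(y = cohort$outcome, X = X, U = U, Z = Z,
             start0 = start0, len = len, subject_ids = ids,
             centers = centers, scales = scales,
             n_subj = length(ids), n_obs = nrow(cohort))
  if (!is.null(spec$link$aug_knots)) {
    # knots are fixed, so the I-spline design of the outcomes can be cached
    yy <- pmin(pmax(md$y, spec$link$range[1]), spec$link$range[2])
    md$IB <- ispline_basis(yy, spec$link, derivs = 0L)
    md$MB <- ispline_basis(yy, spec$link, derivs = 1L)
  }
  md
}

log_row_sum_exp <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  mx + log(rowSums(exp(m - mx)))
}

# Per-subject log contributions: n_subj x G matrix of log pi_g + log density,
# plus the per-subject Jacobian sums of the link transform.
subject_logdens <- function(md, spec, up) {
  lt <- if (!is.null(md$IB)) {
    coefs <- up$eta[-1]^2
    list(h = up$eta[1] + drop(md$IB %*% coefs), dh = drop(md$MB %*% coefs))
  } else {
    link_transform(md$y, spec$link, up$eta)
  }
  if (any(!is.finite(lt$h)) || any(lt$dh <= 0))
    return(NULL)
  r <- if (ncol(md$X)) lt$h - drop(md$X %*% up$beta) else lt$h
  logpi <- log(class_probabilities(up$xi))
  ld <- class_logdens_cpp(r, md$U, md$Z,
                          as.integer(md$start0), as.integer(md$len),
                          up$delta, up$L, up$sigma^2, logpi, up$omega^2)
  if (anyNA(ld)) return(NULL)
  jac <- as.numeric(rowsum(log(lt$dh),
                           group = rep(seq_len(md$n_subj), md$len)))
  list(logdens = ld, jacobian = jac)
}

as_theta <- function(params, spec) {
  if (is.numeric(params)) return(params)
  if (inherits(params, "lcmm_params") || is.list(params)) {
    L <- params$B_chol
    if (is.null(L)) L <- t(chol(params$B))
    eta <- params$eta
    if (is.null(eta)) {
      if (link_is_estimated(spec$link))
        stop("'eta' must be supplied for an estimated (non-linear) link")
      eta <- c(0, 1)
    }
    return(pack_params(params$xi, params$beta, params$delta, L,
                       params$sigma_eps %||% 1, eta,
                       spec, params$omega %||% rep(1, spec$n_classes)))
  }
  stop("cannot interpret 'params'")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mixture log-likelihood contribution of one subject
#'
#' Computes \eqn{\log \sum_g \pi_g \phi(h(y_i); X_i\beta + U_i\delta_g,
#' \omega_g^2 Z_i B Z_i' + \sigma_\epsilon^2 I) + \sum_j \log h'(y_{ij})},
#' the random effects having been integrated out in closed form.
#'
#' @param subject_data rows of a cohort for a single subject.
#' @param spec a [model_spec()].
#' @param params a [parameter_vector()] (or packed numeric vector).
#' @return scalar log-likelihood contribution.
#' @export
subject_loglik <- function(subject_data, spec, params) {
  if (length(unique(subject_data$subject_id)) != 1L)
    stop("subject_data must contain exactly one subject")
  md <- build_model_data_single(subject_data, spec)
  up <- unpack_params(as_theta(params, spec), spec)
  sd_ <- subject_logdens(md, spec, up)
  if (is.null(sd_))
    stop("numerical failure (non-positive-definite covariance or invalid link) for subject ",
         subject_data$subject_id[1])
  as.numeric(log_row_sum_exp(sd_$logdens) + sd_$jacobian)
}

# Relax the >= 2 visit invariant for single-subject likelihood evaluation.
build_model_data_single <- function(subject_data, spec) {
  ids <- unique(subject_data$subject_id)
  dc <- function(nm) if (nm == "intercept") rep(1, nrow(subject_data)) else subject_data[[nm]]
  X <- if (length(spec$shared_design))
    do.call(cbind, lapply(spec$shared_design, dc)) else matrix(0, nrow(subject_data), 0L)
  U <- do.call(cbind, lapply(spec$class_design, dc))
  Z <- if (length(spec$random_design))
    do.call(cbind, lapply(spec$random_design, dc)) else matrix(0, nrow(subject_data), 0L)
  list(y = subject_data$outcome, X = X, U = U, Z = Z,
       start0 = 0L, len = nrow(subject_data), subject_ids = ids,
       centers = NULL, scales = NULL, n_subj = 1L, n_obs = nrow(subject_data))
}

#' Total mixture log-likelihood of a cohort
#'
#' Sum of [subject_loglik()] contributions over independent subjects.
#'
#' @inheritParams subject_loglik
#' @param cohort a [longitudinal_cohort()].
#' @return scalar log-likelihood.
#' @export
total_loglik <- function(cohort, spec, params) {
  md <- build_model_data(cohort, spec, scale_covariates = FALSE)
  up <- unpack_params(as_theta(params, spec), spec)
  sd_ <- subject_logdens(md, spec, up)
  if (is.null(sd_)) {
    per <- vapply(split(seq_len(nrow(cohort)), cohort$subject_id), function(idx) {
      tryCatch(subject_loglik(cohort[idx, , drop = FALSE], spec, params),
               error = function(e) NA_real_)
    }, numeric(1))
    bad <- names(per)[is.na(per)]
    stop("numerical failure in subjects: ", paste(bad, collapse = ", "))
  }
  sum(log_row_sum_exp(sd_$logdens) + sd_$jacobian)
}

#' Construct an explicit parameter vector
#'
#' @param xi G-1 class-membership logit intercepts (reference class last,
#'   fixed at 0).
#' @param beta shared fixed effects, in `shared_design` order.
#' @param delta `length(class_design)` x G matrix of class-specific
#'   coefficients (intercept row first). With an estimated link the class-1
#'   intercept must be 0.
#' @param B_chol lower-triangular Cholesky factor of the random-effect
#'   covariance (alternatively supply `B`).
#' @param sigma_eps residual standard deviation (fixed at 1 when the link is
#'   estimated).
#' @param eta link parameters (see [link_transform()]).
#' @param omega optional class variance scalings (length G, last = 1).
#' @param B random-effect covariance matrix, used if `B_chol` is missing.
#' @return list of class `lcmm_params`.
#' @export
parameter_vector <- function(xi, beta, delta, B_chol = NULL, sigma_eps = 1,
                             eta = NULL, omega = NULL, B = NULL) {
  if (is.null(B_chol)) {
    if (is.null(B)) stop("supply B_chol or B")
    B_chol <- if (all(B == 0)) B * 0 else t(chol(B))
  }
  structure(list(xi = xi, beta = beta, delta = as.matrix(delta),
                 B_chol = B_chol, B = B_chol %*% t(B_chol),
                 sigma_eps = sigma_eps, eta = eta, omega = omega),
            class = "lcmm_params")
}
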