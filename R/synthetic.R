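#' Configuration for the synthetic aging-cohort generator
#'
#' Defaults emulate the observational aging cohort the trajectory analysis
#' was designed for: three latent trajectory classes (normal: lower baseline
#' and stable; resilient: higher baseline and stable; declining: steep
#' negative slope) mixed 71 / 22.5 / 6.5 percent, 2-10 irregular visits per
#' subject about 1.05 years apart, baseline covariates matching the cohort's
#' published distributions (age 71.9 (9.4) years, 59% women, amyloid 1.17
#' (0.19) DVR truncated above 0.9, entorhinal tau 1.33 (0.28) SUVR truncated
#' above 1, hippocampal volume regressing on intracranial volume so
#' head-size adjustment is non-trivial), and class-patterned
#' resilience-related factors (verbal IQ means 120.8 / 126.1 / 124.0, past
#' cognitive activity means 2.97 / 2.83 / 2.44).
#'
#' @param n_subjects number of subjects.
#' @param proportions class mixing proportions (sum to 1).
#' @param intercepts,slopes per-class latent trajectory parameters
#'   (composite units; units/year).
#' @param beta shared covariate effects on the latent process, named for the
#'   design columns.
#' @param random_sd standard deviations of the subject random intercept and
#'   slope.
#' @param random_corr correlation between random intercept and slope.
#' @param residual_sd measurement noise.
#' @param visit_lambda Poisson mean of the visit-count distribution
#'   (truncated to `visit_range`).
#' @param visit_range minimum/maximum visits per subject.
#' @param visit_spacing,visit_jitter mean and SD of the visit interval
#'   (years); follow-up is capped at `max_followup`.
#' @param max_followup maximum follow-up (years).
#' @param distortion strength of the monotone cubic warp applied to the
#'   observed outcome (0 = none), exercising the spline links.
#' @param covariate_class_effects if `TRUE`, covariate distributions differ
#'   by class (confounded stress-test mode); by default the subgroups do not
#'   differ on age, sex or pathology, mirroring the modelled cohort.
#' @param cr_effects `"default"` for class-patterned resilience factors,
#'   `"null"` for identical distributions across classes.
#' @param amnart_means,past_activity_means per-class means of the two
#'   factors with published group differences.
#' @param progression_hazards per-class constant yearly hazards of clinical
#'   progression.
#' @param seed mandatory integer seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 200L,
                             proportions = c(0.71, 0.225, 0.065),
                             intercepts = c(0.0, 0.7, 0.9),
                             slopes = c(-0.02, -0.02, -0.30),
                             beta = c(baseline_age = -0.015, sex = 0.10,
                                      abeta = -0.40, tau_ec = -0.40,
                                      adj_hv = 2e-4),
                             random_sd = c(0.22, 0.05),
                             random_corr = 0,
                             residual_sd = 0.18,
                             visit_lambda = 6,
                             visit_range = c(2L, 10L),
                             visit_spacing = 1.05,
                             visit_jitter = 0.15,
                             max_followup = 10,
                             distortion = 0,
                             covariate_class_effects = FALSE,
                             cr_effects = c("default", "null"),
                             amnart_means = c(120.77, 126.09, 124.00),
                             past_activity_means = c(2.97, 2.83, 2.44),
                             progression_hazards = c(0.030, 0.046, 0.067),
                             seed) {
  if (missing(seed)) stop("a seed is mandatory for synthetic generation")
  cr_effects <- match.arg(cr_effects)
  stopifnot(abs(sum(proportions) - 1) < 1e-8, all(proportions > 0),
            all(random_sd > 0), residual_sd > 0,
            visit_range[1] >= 2L, visit_range[1] <= visit_range[2],
            length(intercepts) == length(proportions),
            length(slopes) == length(proportions))
  structure(as.list(environment()), class = "synthetic_config")
}

rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lower | x > upper))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

# monotone cubic warp centred at the latent mean; derivative >= 1 everywhere
apply_distortion <- function(lambda, strength, center = 0, scale = 1) {
  z <- (lambda - center) / scale
  lambda + strength * scale * z^3
}

#' Generate a synthetic longitudinal cohort with known truth
#'
#' Draws true class memberships, baseline covariates, irregular visit
#' schedules, subject random effects, and observed outcomes
#' \eqn{y = D(\Lambda + \varepsilon)} where \eqn{\Lambda} follows the
#' class-specific linear mixed model of [synthetic_config()] and `D` is an
#' optional monotone distortion. Deterministic under a fixed seed.
#'
#' @param config a [synthetic_config()].
#' @return list with `cohort` (a [longitudinal_cohort()]) and `truth`
#'   (per-subject class, random effects, and the generating parameters).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  N <- config$n_subjects
  G <- length(config$proportions)
  cls <- sample.int(G, N, replace = TRUE, prob = config$proportions)

  baseline_age <- stats::rnorm(N, 71.89, 9.41)
  sex <- stats::rbinom(N, 1, 0.59)
  abeta <- rtrunc_norm(N, 1.17, 0.19, lower = 0.9)
  tau_ec <- rtrunc_norm(N, 1.33, 0.28, lower = 1.0)
  etiv <- stats::rnorm(N, 1.45e6, 1.4e5)
  hv_slope <- 0.003
  raw_hv <- 7490 + hv_slope * (etiv - 1.45e6) + stats::rnorm(N, 0, 780)
  if (config$covariate_class_effects) {
    abeta <- abeta + c(0, -0.02, 0.10)[cls]
    baseline_age <- baseline_age + c(0, 0, 3.5)[cls]
  }
  adj_hv <- adjust_hippocampal_volume(raw_hv, etiv)

  sds <- config$random_sd
  Brand <- diag(sds) %*% matrix(c(1, config$random_corr,
                                  config$random_corr, 1), 2) %*% diag(sds)
  Lr <- t(chol(Brand))
  n_vis <- pmin(pmax(stats::rpois(N, config$visit_lambda),
                     config$visit_range[1]), config$visit_range[2])
  bmat <- t(Lr %*% matrix(stats::rnorm(2 * N), 2))

  X <- cbind(baseline_age, sex, abeta, tau_ec, adj_hv)
  bnames <- names(config$beta)
  xb <- drop(X[, bnames, drop = FALSE] %*% config$beta)
  lam_center <- mean(config$intercepts[cls] + xb)
  lam_scale <- stats::sd(config$intercepts[cls] + xb) + 0.5

  rows <- vector("list", N)
  for (i in seq_len(N)) {
    gaps <- abs(stats::rnorm(n_vis[i] - 1L, config$visit_spacing,
                             config$visit_jitter))
    gaps <- pmax(gaps, 0.2)
    t <- c(0, cumsum(gaps))
    t <- t[t <= config$max_followup]
    if (length(t) < 2L) t <- c(0, config$max_followup)
    lam <- config$intercepts[cls[i]] + config$slopes[cls[i]] * t + xb[i] +
      bmat[i, 1] + bmat[i, 2] * t +
      stats::rnorm(length(t), 0, config$residual_sd)
    y <- if (config$distortion > 0)
      apply_distortion(lam, config$distortion, lam_center, lam_scale) else lam
    rows[[i]] <- data.frame(subject_id = sprintf("S%04d", i), time = t,
                            outcome = y, baseline_age = baseline_age[i],
                            sex = sex[i], abeta = abeta[i],
                            tau_ec = tau_ec[i], adj_hv = as.numeric(adj_hv)[i],
                            raw_hv = raw_hv[i], etiv = etiv[i])
  }
  cohort <- longitudinal_cohort(do.call(rbind, rows))
  truth <- list(subject_id = sprintf("S%04d", seq_len(N)),
                class = cls, random_effects = bmat,
                config = config,
                generating = list(proportions = config$proportions,
                                  intercepts = config$intercepts,
                                  slopes = config$slopes,
                                  beta = config$beta,
                                  B = Brand,
                                  residual_sd = config$residual_sd))
  list(cohort = cohort, truth = truth)
}

#' Generate class-patterned cognitive-resilience factors
#'
#' Draws per-subject resilience-related factors conditional on true class:
#' education years, verbal IQ, occupational Data-People-Things ratings,
#' national deprivation percentile, 25 past and 11 current activity items on
#' the 1-5 scale, cardiovascular risk, and APOE-e4 carriage. In `"null"`
#' mode all classes share one distribution.
#'
#' @param truth the `truth` component of [generate_cohort()].
#' @param config the same [synthetic_config()].
#' @return data.frame, one row per subject, including item-level activity
#'   responses (`past_item_1..25`, `current_item_1..11`).
#' @export
generate_cr_factors <- function(truth, config) {
  set.seed(config$seed + 1L)
  cls <- truth$class
  N <- length(cls)
  null_mode <- config$cr_effects == "null"
  pick <- function(means, sds) {
    m <- if (null_mode) rep(mean(means), length(means)) else means
    stats::rnorm(N, m[cls], sds[cls])
  }
  edu <- round(pmin(pmax(pick(c(15.96, 16.91, 17.54), c(2.93, 2.48, 2.73)), 8), 22))
  amnart <- pick(config$amnart_means, c(8.94, 5.38, 6.39))
  past_m <- if (null_mode) rep(mean(config$past_activity_means), 3) else
    config$past_activity_means
  cur_m <- if (null_mode) rep(mean(c(2.78, 2.77, 2.60)), 3) else
    c(2.78, 2.77, 2.60)
  item_draw <- function(mu, k) {
    m <- matrix(stats::rnorm(N * k, mu[cls], 1.0), N, k)
    matrix(pmin(pmax(round(m), 1), 5), N, k)
  }
  past_items <- item_draw(past_m, 25L)
  colnames(past_items) <- paste0("past_item_", 1:25)
  cur_items <- item_draw(cur_m, 11L)
  colnames(cur_items) <- paste0("current_item_", 1:11)
  out <- data.frame(subject_id = truth$subject_id,
                    education_years = edu,
                    amnart_viq = amnart,
                    dot_data = sample(0:6, N, TRUE),
                    dot_people = sample(0:8, N, TRUE),
                    dot_things = sample(0:7, N, TRUE),
                    national_adi = sample(1:100, N, TRUE),
                    cvd_risk = rtrunc_norm(N, 26.8, 18.0, lower = 1),
                    apoe_e4 = stats::rbinom(N, 1,
                                            if (null_mode) 0.28 else
                                              c(0.25, 0.36, 0.31)[cls]))
  cbind(out, past_items, cur_items)
}

#' Generate clinical-progression visit series
#'
#' Draws exponential progression times with class-specific hazards and
#' encodes them as global Clinical Dementia Rating visit sequences on an
#' annual schedule over each subject's follow-up: scores are 0 before
#' progression and 0.5 from the first post-progression visit onward (so the
#' two-consecutive-nonzero rule recovers the event), censored at the last
#' visit otherwise.
#'
#' @param truth the `truth` component of [generate_cohort()].
#' @param config the same [synthetic_config()].
#' @param followup per-subject follow-up years (default: the generator's
#'   maximum).
#' @return data.frame with `subject_id`, `time`, `cdr_global`.
#' @export
generate_progression <- function(truth, config, followup = NULL) {
  set.seed(config$seed + 2L)
  cls <- truth$class
  N <- length(cls)
  hz <- config$progression_hazards[cls]
  t_event <- ifelse(hz > 0, stats::rexp(N, pmax(hz, 1e-12)), Inf)
  fu <- if (is.null(followup)) rep(config$max_followup, N) else followup
  rows <- lapply(seq_len(N), function(i) {
    t <- seq(0, fu[i], by = 1)
    score <- ifelse(t >= t_event[i], 0.5, 0)
    data.frame(subject_id = truth$subject_id[i], time = t, cdr_global = score)
  })
  do.call(rbind, rows)
}
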