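#' Enumerate the candidate model grid
#'
#' The search space crosses link families with class counts; the default
#' grid (4 families, 2-7 classes) yields 24 candidate models, alongside the
#' 4 one-class initializer specifications.
#'
#' @param outcomes observed outcome vector (defines knots/ranges of the
#'   links).
#' @param families link family names (see [build_link()]).
#' @param class_range integer vector of class counts.
#' @param n_knots total knots for spline families.
#' @param ... passed to [model_spec()] (design choices).
#' @return object of class `candidate_grid`: list with `specs` (one
#'   [model_spec()] per family x class count, in deterministic family-major
#'   order) and `init_specs` (the one-class models per family).
#' @export
enumerate_candidates <- function(outcomes,
                                 families = c("linear", "beta",
                                              "splines_equidistant",
                                              "splines_quantile"),
                                 class_range = 2:7, n_knots = 5L, ...) {
  if (!length(families) || !length(class_range))
    stop("families and class_range must be non-empty")
  links <- lapply(families, function(f) build_link(f, n_knots, outcomes))
  names(links) <- families
  specs <- list()
  for (f in families) for (G in class_range)
    specs[[paste0(f, "_G", G)]] <- model_spec(G, links[[f]], ...)
  init_specs <- lapply(links, function(l) model_spec(1L, l, ...))
  names(init_specs) <- families
  structure(list(specs = specs, init_specs = init_specs,
                 families = families, class_range = class_range),
            class = "candidate_grid")
}

#' Build multi-class starting values from a one-class fit
#'
#' Copies the shared effects, variance components and link parameters of a
#' converged one-class model and seeds the class-specific trajectory
#' coefficients by jittering the one-class intercept/slope with Gaussian
#' noise scaled to the outcome standard deviation (on the latent scale).
#' Class-membership logits start at 0.
#'
#' @param fitted_1class a converged one-class `lcmm_fit`.
#' @param G target number of classes.
#' @param seed integer seed controlling the jitter (deterministic).
#' @param jitter_scale jitter standard deviation as a multiple of the
#'   latent-outcome standard deviation; 0 reproduces the degenerate mixture
#'   of identical classes.
#' @return packed numeric parameter vector for the G-class model (original
#'   covariate scale).
#' @export
init_from_one_class <- function(fitted_1class, G, seed = 1L,
                                jitter_scale = 0.5) {
  stopifnot(inherits(fitted_1class, "lcmm_fit"),
            fitted_1class$spec$n_classes == 1L)
  if (!fitted_1class$converged)
    stop("one-class initializer did not converge; aborting this link family")
  p1 <- fitted_1class$params
  spec1 <- fitted_1class$spec
  if (G == 1L) return(as_theta(p1, spec1))
  specG <- model_spec(G, spec1$link, shared_design = spec1$shared_design,
                      class_design = spec1$class_design,
                      random_design = spec1$random_design,
                      class_variance_scaling = spec1$class_variance_scaling)
  est_link <- link_is_estimated(spec1$link)
  latent_sd <- if (est_link) 1 else p1$sigma_eps + sqrt(max(p1$B[1, 1], 0))
  qc <- nrow(p1$delta)
  delta <- matrix(rep(p1$delta[, 1], G), ncol = G)
  old <- if (exists(".Random.seed", .GlobalEnv, inherits = FALSE))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(as.integer(seed))
  delta <- delta + matrix(stats::rnorm(qc * G, 0, jitter_scale * latent_sd),
                          qc, G) * c(1, rep(0.25, qc - 1L))
  if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
  if (est_link) {
    adj <- delta[1, 1]
    delta[1, ] <- delta[1, ] - adj
    eta <- p1$eta; eta[1] <- eta[1] - adj
  } else eta <- p1$eta
  pack_params(rep(0, G - 1L), p1$beta, delta, p1$B_chol, p1$sigma_eps,
              eta, specG, rep(1, G))
}

#' Grid-search estimation from multiple random departures
#'
#' Implements the automatic grid search used for multi-class estimation:
#' short burn-in optimizations (capped iteration count) are run from
#' `n_departures` random departures around the one-class solution, and the
#' departure with the highest interim log-likelihood is then optimized to
#' full convergence.
#'
#' @param cohort a [longitudinal_cohort()].
#' @param spec the multi-class [model_spec()] to estimate.
#' @param fit_1class optional converged one-class fit for the same link
#'   family (computed on the fly if missing).
#' @param n_departures number of random departures.
#' @param burn_iters optimizer iterations allotted to each departure.
#' @param seed integer seed; departure d uses seed `seed * 1000 + d`.
#' @param control an [lcmm_control()] for the final full fit.
#' @param jitter_scale passed to [init_from_one_class()].
#' @return the fully optimized `lcmm_fit`, with a `grid_search` element
#'   recording each departure's seed and interim log-likelihood.
#' @export
grid_search_fit <- function(cohort, spec, fit_1class = NULL,
                            n_departures = 15L, burn_iters = 30L,
                            seed = 1L, control = lcmm_control(),
                            jitter_scale = 0.5) {
  if (!inherits(cohort, "longitudinal_cohort"))
    cohort <- longitudinal_cohort(cohort, require_covariates = spec$shared_design)
  if (is.null(fit_1class)) {
    spec1 <- model_spec(1L, spec$link, shared_design = spec$shared_design,
                        class_design = spec$class_design,
                        random_design = spec$random_design)
    fit_1class <- fit_lcmm(cohort, spec1, control = control)
  }
  if (spec$n_classes == 1L) return(fit_1class)
  burn_control <- lcmm_control(max_iter = burn_iters,
                               tol_param = control$tol_param,
                               tol_loglik = control$tol_loglik,
                               tol_grad = control$tol_grad, refine = FALSE)
  departures <- data.frame(departure = seq_len(n_departures),
                           seed = as.integer(seed) * 1000L + seq_len(n_departures),
                           loglik = NA_real_)
  best <- NULL
  for (d in seq_len(n_departures)) {
    init_d <- init_from_one_class(fit_1class, spec$n_classes,
                                  seed = departures$seed[d],
                                  jitter_scale = jitter_scale)
    fit_d <- tryCatch(fit_lcmm(cohort, spec, init = init_d,
                               control = burn_control),
                      error = function(e) NULL)
    if (!is.null(fit_d)) {
      departures$loglik[d] <- fit_d$loglik
      if (is.null(best) || fit_d$loglik > best$loglik) best <- fit_d
    }
  }
  if (is.null(best)) {
    out <- fit_1class
    out$converged <- FALSE
    out$grid_search <- list(departures = departures, note = "all departures failed")
    return(out)
  }
  final <- fit_lcmm(cohort, spec, init = best$params, control = control)
  final$grid_search <- list(departures = departures,
                            best_departure = which.max(departures$loglik))
  final
}

#' Filter candidate fits on convergence and class size
#'
#' Keeps fits that converged and whose smallest modal-class proportion is at
#' least `min_prop` (default: every class holds at least 5% of the sample).
#'
#' @param fits list of `lcmm_fit` objects.
#' @param min_prop minimum admissible class proportion.
#' @return the admissible sublist (possibly empty), with an
#'   `admissible` logical attribute aligned with the input.
#' @export
filter_candidates <- function(fits, min_prop = 0.05) {
  ok <- vapply(fits, function(f) {
    isTRUE(f$converged) && min(f$proportions) >= min_prop
  }, logical(1))
  out <- fits[ok]
  attr(out, "admissible") <- unname(ok)
  out
}

#' Select the favored model among admissible candidates
#'
#' Ranks admissible fits by SABIC (ascending) and favors the lowest-SABIC
#' candidate whose relative entropy exceeds `entropy_gate`. The full ranking
#' is retained so the theoretical plausibility of the favored trajectories
#' can be reviewed by the analyst; that third criterion is advisory and is
#' not automated.
#'
#' @param admissible list of admissible `lcmm_fit`s (see
#'   [filter_candidates()]).
#' @param entropy_gate minimum relative entropy (exclusive).
#' @return list of class `selection_report`: `favored` (an `lcmm_fit` or
#'   `NULL`), `table` (per-candidate summary in SABIC order) and `decision`.
#' @export
select_favored <- function(admissible, entropy_gate = 0.5) {
  if (!length(admissible)) {
    return(structure(list(favored = NULL,
                          table = data.frame(),
                          decision = "no admissible candidate models"),
                     class = "selection_report"))
  }
  tab <- candidate_table(admissible)
  tab <- tab[order(tab$sabic), , drop = FALSE]
  tab$entropy_pass <- !is.na(tab$relative_entropy) &
    tab$relative_entropy > entropy_gate
  pick <- which(tab$entropy_pass)[1]
  if (is.na(pick)) {
    return(structure(list(favored = NULL, table = tab,
                          decision = sprintf(
                            "all candidates at or below the entropy gate (%.2f)",
                            entropy_gate)),
                     class = "selection_report"))
  }
  structure(list(favored = admissible[[tab$candidate[pick]]],
                 table = tab,
                 decision = sprintf(
                   "favored: %s (lowest SABIC with relative entropy > %.2f)",
                   tab$label[pick], entropy_gate)),
            class = "selection_report")
}

candidate_table <- function(fits) {
  data.frame(
    candidate = seq_along(fits),
    label = vapply(fits, function(f)
      paste0(f$spec$link$family, "_G", f$spec$n_classes), character(1)),
    family = vapply(fits, function(f) f$spec$link$family, character(1)),
    n_classes = vapply(fits, function(f) as.integer(f$spec$n_classes), integer(1)),
    converged = vapply(fits, function(f) isTRUE(f$converged), logical(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    npar = vapply(fits, function(f) f$npar, numeric(1)),
    sabic = vapply(fits, function(f) f$sabic, numeric(1)),
    bic = vapply(fits, function(f) f$bic, numeric(1)),
    relative_entropy = vapply(fits, function(f)
      ifelse(is.null(f$relative_entropy), NA_real_, f$relative_entropy), numeric(1)),
    min_proportion = vapply(fits, function(f) min(f$proportions), numeric(1)),
    row.names = NULL)
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report>", x$decision, "\n")
  if (nrow(x$table)) print(x$table[, c("label", "converged", "sabic",
                                       "relative_entropy", "min_proportion")])
  invisible(x)
}

#' Label trajectory classes by predicted level and slope
#'
#' For a 3-class model, computes each class's predicted latent intercept and
#' slope at the covariate means and labels the class whose slope falls below
#' the others by more than `decline_margin` as `"Declining"`; of the
#' remaining classes, the higher intercept is `"Resilient"` and the lower
#' `"Normal"`. Labelling keys on the slope first, so a declining class with
#' the lowest baseline level (as seen in transfer cohorts) is still labelled
#' `"Declining"`. Other class counts, or slope/intercept ties within
#' tolerance, yield generic labels `C1..CG` ordered by baseline level, with a
#' warning in the tie case.
#'
#' @param fit an `lcmm_fit`.
#' @param decline_margin minimum slope separation (latent units/year) for a
#'   distinct declining class.
#' @param tol tie tolerance.
#' @return character vector of length G mapping class index to label.
#' @export
label_classes <- function(fit, decline_margin = 0.05, tol = 1e-8) {
  stopifnot(inherits(fit, "lcmm_fit"))
  G <- fit$spec$n_classes
  delta <- fit$params$delta
  has_time <- "time" %in% fit$spec$class_design
  intercepts <- delta[1, ]
  slopes <- if (has_time) delta[match("time", fit$spec$class_design), ] else rep(0, G)
  generic <- paste0("C", rank(-intercepts, ties.method = "first"))
  if (G != 3L) {
    names(generic) <- NULL
    return(generic)
  }
  o <- order(slopes)
  if (abs(slopes[o[1]] - slopes[o[2]]) < max(tol, decline_margin)) {
    if (max(slopes) - min(slopes) < tol)
      warning("class slopes are tied; returning generic labels")
    else
      warning("no class separates as distinctly declining; returning generic labels")
    return(generic)
  }
  labels <- character(3)
  labels[o[1]] <- "Declining"
  rest <- o[2:3]
  if (abs(diff(intercepts[rest])) < tol) {
    warning("remaining class intercepts are tied; returning generic labels")
    return(generic)
  }
  labels[rest[which.max(intercepts[rest])]] <- "Resilient"
  labels[rest[which.min(intercepts[rest])]] <- "Normal"
  labels
}

#' Report modal-class proportions as percentages
#'
#' @param assignments vector of modal class assignments (or a vector of
#'   per-class counts when `counts = TRUE`).
#' @param N sample size.
#' @param digits maximum decimals (trailing zeros trimmed).
#' @param counts interpret `assignments` as per-class counts.
#' @return numeric vector of percentages (names = class).
#' @export
class_proportion_report <- function(assignments, N = length(assignments),
                                    digits = 2, counts = FALSE) {
  n_g <- if (counts) as.numeric(assignments) else
    as.numeric(table(assignments))
  pct <- round(n_g / N * 100, digits)
  names(pct) <- if (counts) names(assignments) %||% seq_along(n_g) else
    names(table(assignments))
  pct
}

#' Replicated grid-search fit with modal-model selection
#'
#' Repeats [grid_search_fit()] with distinct seeds and groups the solutions
#' by modal-partition equivalence up to label permutation (pairwise adjusted
#' Rand index of 1 within `ari_tol`). The best-likelihood member of the most
#' frequent group is returned; frequency ties resolve toward the higher
#' log-likelihood (noted in the report).
#'
#' @inheritParams grid_search_fit
#' @param n_repeats number of replicated grid searches.
#' @param seeds optional explicit integer seeds (length `n_repeats`).
#' @param ari_tol tolerance on `1 - ARI` for partition identity.
#' @param ... passed to [grid_search_fit()].
#' @return list of class `modal_fit_report`: `fit` (the selected
#'   `lcmm_fit`), `frequency` (per-group counts), `groups` (repeat-to-group
#'   map), `tie` flag.
#' @export
replicate_modal_fit <- function(cohort, spec, n_repeats = 10L, seeds = NULL,
                                ari_tol = 1e-8, ...) {
  if (is.null(seeds)) seeds <- seq_len(n_repeats)
  stopifnot(length(seeds) == n_repeats)
  fits <- vector("list", n_repeats)
  for (r in seq_len(n_repeats))
    fits[[r]] <- grid_search_fit(cohort, spec, seed = seeds[r], ...)
  group <- integer(n_repeats)
  reps <- list()
  for (r in seq_len(n_repeats)) {
    assigned <- FALSE
    for (g in seq_along(reps)) {
      ari <- mclust::adjustedRandIndex(fits[[r]]$modal_class,
                                       reps[[g]]$modal_class)
      if (is.finite(ari) && (1 - ari) <= ari_tol) {
        group[r] <- g; assigned <- TRUE; break
      }
    }
    if (!assigned) { reps[[length(reps) + 1L]] <- fits[[r]]; group[r] <- length(reps) }
  }
  freq <- tabulate(group, nbins = length(reps))
  top <- which(freq == max(freq))
  tie <- length(top) > 1L
  if (tie) {
    best_ll <- vapply(top, function(g)
      max(vapply(fits[group == g], function(f) f$loglik, numeric(1))), numeric(1))
    top <- top[which.max(best_ll)]
  } else top <- top[1]
  members <- fits[group == top]
  pick <- members[[which.max(vapply(members, function(f) f$loglik, numeric(1)))]]
  structure(list(fit = pick, frequency = freq, groups = group,
                 seeds = seeds, tie = tie), class = "modal_fit_report")
}

#' @export
print.modal_fit_report <- function(x, ...) {
  cat("<modal_fit_report> groups:", length(x$frequency),
      "| frequencies:", paste(x$frequency, collapse = "/"),
      if (x$tie) "(frequency tie resolved by log-likelihood)", "\n")
  print(x$fit)
  invisible(x)
}

#' Sensitivity refits of the favored configuration
#'
#' Refits the favored link/class configuration under standard sensitivity
#' variants: without shared covariates; with a named covariate column
#' replaced by an alternative measurement; and restricted to subjects with a
#' minimum number of visits. Reports SABIC, entropy, class proportions, and
#' assignment agreement (adjusted Rand) against the reference fit.
#'
#' @param cohort a [longitudinal_cohort()].
#' @param favored_fit the reference `lcmm_fit`.
#' @param swap named list mapping a shared covariate to a replacement column
#'   present in `cohort` (e.g. `list(tau_ec = "tau_it")`); variants whose
#'   replacement column is missing are skipped with a message.
#' @param min_visits visit-count restrictions to try (default 3).
#' @param ... passed to [grid_search_fit()].
#' @return data.frame, one row per variant.
#' @export
sensitivity_suite <- function(cohort, favored_fit, swap = list(),
                              min_visits = 3L, ...) {
  spec <- favored_fit$spec
  rows <- list()
  run_variant <- function(name, co, sd_override = NULL) {
    sp <- model_spec(spec$n_classes, spec$link,
                     shared_design = sd_override %||% spec$shared_design,
                     class_design = spec$class_design,
                     random_design = spec$random_design)
    f <- tryCatch(grid_search_fit(co, sp, ...), error = function(e) NULL)
    if (is.null(f)) return(NULL)
    common <- intersect(f$subject_ids, favored_fit$subject_ids)
    ari <- mclust::adjustedRandIndex(
      f$modal_class[match(common, f$subject_ids)],
      favored_fit$modal_class[match(common, favored_fit$subject_ids)])
    data.frame(variant = name, converged = f$converged, sabic = f$sabic,
               relative_entropy = f$relative_entropy,
               min_proportion = min(f$proportions),
               agreement_ari = ari)
  }
  rows$reference <- data.frame(variant = "reference",
                               converged = favored_fit$converged,
                               sabic = favored_fit$sabic,
                               relative_entropy = favored_fit$relative_entropy,
                               min_proportion = min(favored_fit$proportions),
                               agreement_ari = 1)
  rows$unconditioned <- run_variant("unconditioned", cohort,
                                    sd_override = character(0))
  for (nm in names(swap)) {
    repl <- swap[[nm]]
    if (!repl %in% names(cohort)) {
      message("sensitivity variant '", nm, " -> ", repl,
              "' skipped: column not present")
      next
    }
    co2 <- cohort
    co2[[nm]] <- co2[[repl]]
    rows[[paste0("swap_", nm)]] <-
      run_variant(paste0(nm, " replaced by ", repl),
                  longitudinal_cohort(co2, require_covariates = spec$shared_design))
  }
  for (mv in min_visits) {
    keep <- names(which(table(cohort$subject_id) >= mv))
    co3 <- cohort[cohort$subject_id %in% keep, , drop = FALSE]
    rows[[paste0("minvisits_", mv)]] <-
      run_variant(sprintf("at least %d visits", mv),
                  longitudinal_cohort(co3, require_covariates = spec$shared_design))
  }
  do.call(rbind, Filter(Negate(is.null), rows))
}
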