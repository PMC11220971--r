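#' Kruskal-Wallis omnibus test
#'
#' Tie-corrected Kruskal-Wallis rank-sum test across subgroups (thin wrapper
#' over [stats::kruskal.test()] returning the pieces the reporting layer
#' uses).
#'
#' @param values numeric vector.
#' @param groups grouping factor.
#' @return list with `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) == 0L)) stop("empty group")
  ok <- !is.na(values) & !is.na(groups)
  kt <- stats::kruskal.test(values[ok], droplevels(groups[ok]))
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = if (is.nan(kt$p.value)) 1 else kt$p.value)
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Pairwise z statistics from mean-rank differences on the joint ranking,
#' with tie-corrected pooled variance
#' \eqn{\left(\frac{N(N+1)}{12} - \frac{\sum_t (t^3 - t)}{12(N-1)}\right)
#' \left(\frac{1}{n_a} + \frac{1}{n_b}\right)} and two-sided p-values.
#' Adjusted p-values use the Hochberg step-up method within the family of
#' pairwise comparisons.
#'
#' @param values numeric vector.
#' @param groups grouping factor.
#' @param adjust p-adjustment method for the pairwise family (default
#'   `"hochberg"`).
#' @return data.frame: `group1`, `group2`, `z`, `p_raw`, `p_adjusted`.
#' @export
dunn_posthoc <- function(values, groups, adjust = "hochberg") {
  groups <- factor(groups)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  k <- nlevels(groups)
  if (k < 2L) stop("need at least 2 groups")
  N <- length(values)
  r <- rank(values)
  mean_rank <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  base_var <- N * (N + 1) / 12 - tie_term
  combs <- utils::combn(levels(groups), 2)
  z <- p <- numeric(ncol(combs))
  for (j in seq_len(ncol(combs))) {
    a <- combs[1, j]; b <- combs[2, j]
    se <- sqrt(base_var * (1 / n_g[[a]] + 1 / n_g[[b]]))
    z[j] <- if (se == 0) 0 else (mean_rank[[a]] - mean_rank[[b]]) / se
    p[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  data.frame(group1 = combs[1, ], group2 = combs[2, ], z = z, p_raw = p,
             p_adjusted = hochberg_adjust(p))
}

#' Hochberg step-up adjustment
#'
#' Step-up multiple-comparison correction: with ascending
#' \eqn{p_{(1..m)}}, \eqn{\tilde p_{(m)} = p_{(m)}} and
#' \eqn{\tilde p_{(i)} = \min(\tilde p_{(i+1)}, (m - i + 1) p_{(i)})},
#' capped at 1 and returned in input order. The largest p-value is always
#' left unchanged.
#'
#' @param p raw p-values.
#' @return adjusted p-values.
#' @export
hochberg_adjust <- function(p) stats::p.adjust(p, method = "hochberg")

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR-adjusted p-values (\eqn{\tilde p_{(i)} =
#' \min_{j \ge i} \frac{m}{j} p_{(j)}}), capped at 1, input order preserved.
#'
#' @param p raw p-values.
#' @return adjusted p-values.
#' @export
bh_fdr_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Region-of-interest tau regressions across subgroups
#'
#' Regresses each region's tau tracer uptake (SUVR) on subgroup membership
#' in an ordinary linear regression and controls the false discovery rate
#' across regions by Benjamini-Hochberg. By default the subgroup enters as a
#' single Resilient-versus-rest indicator contrast (one estimate per
#' region); `coding = "factor"` instead codes the subgroup as a factor and
#' tests its overall effect by F-test.
#'
#' @param roi_suvr data.frame/matrix of per-subject SUVR values, one column
#'   per region.
#' @param class_labels per-subject subgroup labels.
#' @param resilient_label label defining the indicator contrast.
#' @param coding `"resilient_indicator"` or `"factor"`.
#' @return data.frame: `roi`, `estimate`, `p_raw`, `p_fdr`.
#' @export
roi_tau_analysis <- function(roi_suvr, class_labels,
                             resilient_label = "Resilient",
                             coding = c("resilient_indicator", "factor")) {
  coding <- match.arg(coding)
  roi_suvr <- as.data.frame(roi_suvr)
  drop <- vapply(roi_suvr, function(x) all(is.na(x)), logical(1))
  if (any(drop)) {
    warning("ROI column(s) omitted (all missing): ",
            paste(names(roi_suvr)[drop], collapse = ", "))
    roi_suvr <- roi_suvr[!drop]
  }
  res <- lapply(names(roi_suvr), function(nm) {
    y <- roi_suvr[[nm]]
    if (stats::sd(y, na.rm = TRUE) == 0)
      return(data.frame(roi = nm, estimate = 0, p_raw = 1))
    if (coding == "resilient_indicator") {
      x <- as.integer(class_labels == resilient_label)
      sm <- summary(stats::lm(y ~ x))
      if (nrow(sm$coefficients) < 2L)
        return(data.frame(roi = nm, estimate = 0, p_raw = 1))
      data.frame(roi = nm, estimate = sm$coefficients[2, 1],
                 p_raw = sm$coefficients[2, 4])
    } else {
      fit <- stats::lm(y ~ factor(class_labels))
      an <- stats::anova(fit)
      data.frame(roi = nm, estimate = NA_real_, p_raw = an$`Pr(>F)`[1])
    }
  })
  out <- do.call(rbind, res)
  out$p_fdr <- bh_fdr_adjust(out$p_raw)
  rownames(out) <- NULL
  out
}

#' Categorical group-difference test
#'
#' Pearson's chi-squared test of independence by default; switches to
#' Fisher's exact test when any expected cell count is below
#' `fisher_threshold` (with a simulated p-value for tables beyond 2x2 whose
#' exact computation is infeasible).
#'
#' @param table a contingency table (matrix) or the result of [table()].
#' @param fisher_threshold expected-count threshold for the exact test.
#' @param simulate_B replicates for simulated Fisher p-values on large
#'   tables.
#' @return list with `method`, `statistic` (chi-squared branch), `p_value`,
#'   `expected`.
#' @export
categorical_tests <- function(table, fisher_threshold = 5, simulate_B = 1e4) {
  table <- as.matrix(table)
  cs <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  expected <- cs$expected
  if (any(expected < fisher_threshold)) {
    ft <- if (all(dim(table) == 2L)) stats::fisher.test(table)
    else tryCatch(stats::fisher.test(table),
                  error = function(e)
                    stats::fisher.test(table, simulate.p.value = TRUE,
                                       B = simulate_B))
    list(method = "fisher", statistic = NA_real_, p_value = ft$p.value,
         expected = expected)
  } else {
    list(method = "chisq", statistic = unname(cs$statistic),
         p_value = if (is.nan(cs$p.value)) 1 else cs$p.value,
         expected = expected)
  }
}

#' Kaplan-Meier curves and log-rank comparison of progression
#'
#' Product-limit survival estimates per subgroup with the k-group log-rank
#' test and per-group percentages progressed.
#'
#' @param time time to event or censoring (years).
#' @param event 1 = progressed, 0 = censored.
#' @param group subgroup labels.
#' @return list with `survfit` (a [survival::survfit()] object), `chisq`,
#'   `df`, `p_value`, `progressed_pct` (per group).
#' @export
km_logrank <- function(time, event, group) {
  if (all(event == 0)) stop("no progression events observed; log-rank undefined")
  group <- factor(group)
  sf <- survival::survfit(survival::Surv(time, event) ~ group)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd_$n) - 1L
  pct_arr <- tapply(event, group, function(e) 100 * mean(e))
  pct <- stats::setNames(as.numeric(pct_arr), names(pct_arr))
  list(survfit = sf, chisq = unname(sd_$chisq), df = df,
       p_value = stats::pchisq(sd_$chisq, df, lower.tail = FALSE),
       progressed_pct = pct)
}

#' Mixed-model contrasts of subgroup intercepts and slopes
#'
#' Confirms that identified subgroups differ on trajectory level and slope:
#' a one-class linear mixed model (the G = 1 identity-link reduction of the
#' latent class machinery) with subgroup dummies and subgroup-by-time
#' interactions as fixed effects, Wald-tested against zero using standard
#' errors from the numerical Hessian at the optimum.
#'
#' @param cohort a [longitudinal_cohort()].
#' @param class_labels per-subject subgroup labels (reference = first
#'   level).
#' @param control an [lcmm_control()].
#' @return data.frame of contrast estimates, standard errors, z and p
#'   values; rows `<level>_intercept` and `<level>_slope` are differences
#'   from the reference level.
#' @export
trajectory_contrast <- function(cohort, class_labels, control = lcmm_control()) {
  lab <- factor(class_labels)
  ids <- unique(cohort$subject_id)
  stopifnot(length(lab) == length(ids))
  ref <- levels(lab)[1]
  co <- as.data.frame(cohort)
  dummy_names <- character(0)
  for (lv in levels(lab)[-1]) {
    dnm <- paste0("grp_", make.names(lv))
    inm <- paste0(dnm, "_x_time")
    co[[dnm]] <- as.integer(lab[match(co$subject_id, ids)] == lv)
    co[[inm]] <- co[[dnm]] * co$time
    dummy_names <- c(dummy_names, dnm, inm)
  }
  lk <- build_link("linear", outcomes = co$outcome)
  sp <- model_spec(1L, lk, shared_design = dummy_names)
  constant_cols <- dummy_names[!grepl("_x_time$", dummy_names)]
  co <- longitudinal_cohort(co, require_covariates = constant_cols)
  ft <- fit_lcmm(co, sp, control = control)
  md <- build_model_data(co, sp, scale_covariates = TRUE)
  fn <- make_objective(md, sp)
  H <- pracma::hessian(fn, ft$theta, h = 1e-4)
  V <- tryCatch(solve((H + t(H)) / 2), error = function(e) {
    warning("singular Hessian; using pseudo-inverse for Wald standard errors")
    pracma::pinv((H + t(H)) / 2)
  })
  layout <- param_layout(sp)
  idx <- layout$offsets[["beta"]] + seq_len(layout$sizes[["beta"]])
  est_int <- unpack_params(ft$theta, sp)$beta   # internal (scaled) scale
  se_int <- sqrt(pmax(diag(V)[idx], 0))
  scales <- md$scales
  est <- est_int / scales
  se <- se_int / scales
  z <- est / se
  lv <- rep(levels(lab)[-1], each = 2)
  what <- rep(c("intercept", "slope"), times = nlevels(lab) - 1L)
  data.frame(contrast = paste0(lv, "_vs_", ref, "_", what),
             estimate = unname(est), se = unname(se), z = unname(z),
             p_value = 2 * stats::pnorm(-abs(z)))
}

#' Subgroup comparison of final-visit scores
#'
#' Regression-to-the-mean check: extracts each subject's last observed
#' outcome and compares subgroups by Kruskal-Wallis with Dunn post-hoc
#' tests.
#'
#' @param cohort a [longitudinal_cohort()].
#' @param class_labels per-subject subgroup labels (order of
#'   `unique(cohort$subject_id)`).
#' @return list with `omnibus` ([kruskal_wallis()] result), `pairwise`
#'   ([dunn_posthoc()] table), `final_scores`.
#' @export
final_visit_comparison <- function(cohort, class_labels) {
  ids <- unique(cohort$subject_id)
  stopifnot(length(class_labels) == length(ids))
  last_idx <- vapply(split(seq_len(nrow(cohort)), cohort$subject_id),
                     function(i) i[length(i)], integer(1))
  last_idx <- last_idx[match(ids, names(last_idx))]
  y <- cohort$outcome[last_idx]
  list(omnibus = kruskal_wallis(y, class_labels),
       pairwise = dunn_posthoc(y, class_labels),
       final_scores = data.frame(subject_id = ids, final_outcome = y,
                                 class = class_labels))
}
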