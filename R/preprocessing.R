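#' Head-size adjustment of hippocampal volume
#'
#' Regresses raw (left + right summed) hippocampal volume on estimated total
#' intracranial volume within the cohort being processed and removes the
#' head-size effect:
#' \deqn{\mathrm{adj\_hv} = \mathrm{raw\_hv} - b\,(\mathrm{eTIV} -
#'   \overline{\mathrm{eTIV}})}
#' where `b` is the ordinary-least-squares slope. A subject at the mean eTIV
#' keeps their raw volume. Reference coefficients can be injected to
#' replicate an adjustment estimated on a wider cohort.
#'
#' @param raw_hv raw bilateral hippocampal volume (mm^3).
#' @param etiv estimated total intracranial volume (mm^3).
#' @param b,mean_etiv optional externally estimated slope and reference mean.
#' @return numeric vector of adjusted volumes with attributes `b` and
#'   `mean_etiv`.
#' @export
adjust_hippocampal_volume <- function(raw_hv, etiv, b = NULL, mean_etiv = NULL) {
  stopifnot(length(raw_hv) == length(etiv))
  ok <- !(is.na(raw_hv) | is.na(etiv))
  if (any(!ok)) warning(sum(!ok), " subject(s) with missing volume data excluded pairwise")
  if (is.null(b)) {
    if (sum(ok) < 3L) stop("need at least 3 complete volume pairs to estimate b")
    if (stats::sd(etiv[ok]) == 0) stop("eTIV has zero variance; cannot estimate b")
    fit <- stats::lm(raw_hv[ok] ~ etiv[ok])
    b <- unname(stats::coef(fit)[2])
    mean_etiv <- mean(etiv[ok])
  } else if (is.null(mean_etiv)) stop("mean_etiv must accompany an external b")
  adj <- raw_hv - b * (etiv - mean_etiv)
  attr(adj, "b") <- b
  attr(adj, "mean_etiv") <- mean_etiv
  adj
}

#' Cognitive composite as a mean of referenced z-scores
#'
#' Averages z-scores of component neuropsychological tests referenced to
#' cohort baseline means and standard deviations (the five-test preclinical
#' composite). Components flagged lower-is-better (e.g. a timed trail-making
#' score) are sign-flipped after standardization.
#'
#' @param component_scores data.frame or matrix, one column per component.
#' @param reference_stats optional list with `mean` and `sd` vectors (one
#'   entry per component); defaults to the supplied rows (i.e. the reference
#'   cohort at baseline).
#' @param direction_flags logical vector, `TRUE` where lower raw scores mean
#'   better performance.
#' @param min_components minimum non-missing components per row (default:
#'   all of them); rows below the minimum return `NA` and are counted in a
#'   message.
#' @return numeric composite vector with attribute `reference_stats`.
#' @export
compute_pacc5 <- function(component_scores, reference_stats = NULL,
                          direction_flags = rep(FALSE, ncol(component_scores)),
                          min_components = ncol(component_scores)) {
  component_scores <- as.matrix(component_scores)
  k <- ncol(component_scores)
  stopifnot(length(direction_flags) == k)
  if (is.null(reference_stats)) {
    reference_stats <- list(mean = colMeans(component_scores, na.rm = TRUE),
                            sd = apply(component_scores, 2, stats::sd, na.rm = TRUE))
  }
  if (any(!is.finite(reference_stats$sd)) || any(reference_stats$sd <= 0))
    stop("reference SDs must be positive")
  z <- sweep(sweep(component_scores, 2, reference_stats$mean, "-"),
             2, reference_stats$sd, "/")
  z[, direction_flags] <- -z[, direction_flags, drop = FALSE]
  n_ok <- rowSums(!is.na(z))
  comp <- rowMeans(z, na.rm = TRUE)
  comp[n_ok < min_components] <- NA_real_
  comp[n_ok == 0] <- NA_real_
  if (any(n_ok < min_components))
    message(sum(n_ok < min_components),
            " row(s) below the minimum of ", min_components,
            " non-missing components set to NA")
  attr(comp, "reference_stats") <- reference_stats
  comp
}

#' Apply the longitudinal inclusion criteria
#'
#' Anchors each subject's analysis baseline at the first cognitive visit
#' within `window_days` of their first tau-PET scan, drops earlier
#' (retrospective) visits, and retains subjects with at least `min_visits`
#' remaining assessments and complete covariates. Duplicated visit dates are
#' deduplicated keeping the first. Visit times are re-expressed in years
#' from the subject's analysis baseline.
#'
#' @param visits data.frame with `subject_id`, `visit_date` (Date or
#'   ISO-8601 string), `outcome`.
#' @param baselines data.frame with `subject_id`, `scan_date`, and the
#'   baseline covariates to carry forward.
#' @param window_days inclusion window between baseline visit and tau scan
#'   (inclusive).
#' @param min_visits minimum retained visits.
#' @param covariates covariate columns of `baselines` required complete.
#' @return list with `cohort` (a [longitudinal_cohort()]) and `exclusions`
#'   (data.frame of subject, reason).
#' @export
apply_inclusion_criteria <- function(visits, baselines, window_days = 365,
                                     min_visits = 2L,
                                     covariates = c("baseline_age", "sex",
                                                    "abeta", "tau_ec",
                                                    "adj_hv")) {
  visits$visit_date <- as.Date(visits$visit_date)
  baselines$scan_date <- as.Date(baselines$scan_date)
  if (anyNA(visits$visit_date) || anyNA(baselines$scan_date))
    stop("unparseable dates in visit or scan tables")
  excl <- list()
  rows <- list()
  for (sid in as.character(unique(baselines$subject_id))) {
    b <- baselines[baselines$subject_id == sid, , drop = FALSE][1, ]
    v <- visits[visits$subject_id == sid, , drop = FALSE]
    v <- v[order(v$visit_date), , drop = FALSE]
    dup <- duplicated(v$visit_date)
    if (any(dup)) {
      message("subject ", sid, ": ", sum(dup), " duplicated visit date(s) dropped")
      v <- v[!dup, , drop = FALSE]
    }
    if (anyNA(b[covariates])) {
      excl[[sid]] <- "incomplete covariates"; next
    }
    win <- abs(as.numeric(v$visit_date - b$scan_date)) <= window_days
    if (!any(win)) {
      excl[[sid]] <- "no cognitive baseline within window of tau scan"; next
    }
    base_date <- v$visit_date[which(win)[1]]
    v <- v[v$visit_date >= base_date, , drop = FALSE]  # no retrospective visits
    v <- v[!is.na(v$outcome), , drop = FALSE]
    if (nrow(v) < min_visits) {
      excl[[sid]] <- "insufficient timepoints"; next
    }
    out <- data.frame(subject_id = sid,
                      time = as.numeric(v$visit_date - base_date) / 365.25,
                      outcome = v$outcome)
    for (cv in covariates) out[[cv]] <- b[[cv]]
    rows[[sid]] <- out
  }
  exclusions <- if (length(excl))
    data.frame(subject_id = names(excl),
               reason = unlist(excl, use.names = FALSE))
  else data.frame(subject_id = character(0), reason = character(0))
  if (!length(rows))
    return(list(cohort = NULL, exclusions = exclusions))
  cohort <- longitudinal_cohort(do.call(rbind, rows),
                                require_covariates = covariates)
  rownames(cohort) <- NULL
  list(cohort = cohort, exclusions = exclusions)
}

#' Cognitive-resilience residual
#'
#' Standardized residual of baseline cognition regressed on age, sex,
#' amyloid, entorhinal tau, and adjusted hippocampal volume: the part of
#' baseline performance not explained by demographics and pathology. The
#' residual is `observed - predicted`, divided by the residual standard
#' deviation (denominator `n - p - 1`), so higher values reflect higher
#' resilience.
#'
#' @param baseline data.frame with one row per subject.
#' @param outcome column name of baseline cognition.
#' @param predictors predictor column names.
#' @return numeric vector of standardized residuals.
#' @export
cr_residual <- function(baseline,
                        outcome = "pacc5",
                        predictors = c("baseline_age", "sex", "abeta",
                                       "tau_ec", "adj_hv")) {
  f <- stats::reformulate(predictors, response = outcome)
  n <- nrow(baseline)
  if (n <= length(predictors) + 1L) stop("too few subjects for the residual regression")
  fit <- stats::lm(f, data = baseline)
  if (fit$rank < length(predictors) + 1L) stop("rank-deficient residual regression design")
  r <- stats::residuals(fit)
  s <- sqrt(sum(r^2) / stats::df.residual(fit))
  if (s < 1e-12)
    stop("degenerate residual regression: outcome is an exact linear function of the predictors")
  as.numeric(r / s)
}

#' Biomarker positivity flags
#'
#' Strict-threshold flags: amyloid positivity above `abeta_cut` (DVR) and
#' hippocampal atrophy below `hv_cut` (mm^3). Boundary values are negative
#' for both.
#'
#' @param abeta neocortical amyloid burden.
#' @param adj_hv adjusted hippocampal volume.
#' @param abeta_cut,hv_cut published thresholds.
#' @return data.frame with logical `abeta_positive`, `hc_atrophy`.
#' @export
threshold_flags <- function(abeta, adj_hv, abeta_cut = 1.185, hv_cut = 6723) {
  data.frame(abeta_positive = abeta > abeta_cut,
             hc_atrophy = adj_hv < hv_cut)
}

#' Cognitive-activity scores
#'
#' Past activity is the mean of 25 lifetime items, current activity the mean
#' of 11 current items, each on a 1-5 frequency scale. A score is computed
#' from the answered items when at least `min_frac` of them are answered,
#' otherwise it is missing.
#'
#' @param past matrix/data.frame of the 25 past items (rows = subjects).
#' @param current matrix/data.frame of the 11 current items.
#' @param min_frac minimum answered fraction.
#' @return data.frame with `past_activity`, `current_activity`.
#' @export
activity_scores <- function(past, current, min_frac = 0.8) {
  score <- function(m, label) {
    m <- as.matrix(m)
    if (!all(m %in% c(1:5, NA)))
      stop(label, " activity responses must be integers 1-5 or missing")
    frac <- rowMeans(!is.na(m))
    s <- rowMeans(m, na.rm = TRUE)
    low <- frac < min_frac
    s[low | frac == 0] <- NA_real_
    if (any(low)) message(sum(low), " ", label,
                          "-activity score(s) set missing (<", min_frac * 100,
                          "% items answered)")
    s
  }
  data.frame(past_activity = score(past, "past"),
             current_activity = score(current, "current"))
}

#' Occupational complexity from Data-People-Things ratings
#'
#' Reverses each Dictionary of Occupational Titles rating on its own scale
#' (data 0-6, people 0-8, things 0-7; low raw ratings denote high
#' complexity) and sums, giving a score from 0 (minimal complexity) to 21
#' (maximal complexity).
#'
#' @param data,people,things integer ratings.
#' @return numeric complexity score.
#' @export
occupational_complexity <- function(data, people, things) {
  chk <- function(x, hi, nm) {
    if (any(!is.na(x) & (x < 0 | x > hi)))
      stop("'", nm, "' ratings must lie in 0-", hi)
    x
  }
  (6 - chk(data, 6, "data")) + (8 - chk(people, 8, "people")) +
    (7 - chk(things, 7, "things"))
}

#' Neighborhood-disadvantage tertiles
#'
#' Categorizes national area-deprivation percentiles into tertiles (lowest /
#' intermediate / highest deprivation) using cut points from a reference
#' distribution, by default the values being categorized (a wider-cohort
#' distribution can be supplied to replicate external cuts).
#'
#' @param national_adi values to categorize (1-100).
#' @param reference distribution supplying the tertile cut points.
#' @return factor with levels `Lowest`, `Intermediate`, `Highest`; attribute
#'   `cuts` holds the two cut points.
#' @export
adi_tertiles <- function(national_adi, reference = national_adi) {
  if (any(!is.na(national_adi) & (national_adi < 1 | national_adi > 100)))
    stop("national ADI values must lie in 1-100")
  cuts <- stats::quantile(reference, c(1/3, 2/3), na.rm = TRUE, names = FALSE)
  if (diff(range(reference, na.rm = TRUE)) == 0) {
    warning("degenerate reference distribution; single category returned")
    out <- factor(rep("Lowest", length(national_adi)),
                  levels = c("Lowest", "Intermediate", "Highest"))
    out[is.na(national_adi)] <- NA
    attr(out, "cuts") <- cuts
    return(out)
  }
  out <- cut(national_adi, breaks = c(-Inf, cuts, Inf),
             labels = c("Lowest", "Intermediate", "Highest"), right = TRUE)
  attr(out, "cuts") <- cuts
  out
}

#' Clinical-progression events from CDR visit series
#'
#' Progression is the first of two consecutive visits with a nonzero global
#' Clinical Dementia Rating (0.5, 1, or 2), or a final visit with a nonzero
#' score; the event time is the first visit of the qualifying pair (or that
#' final visit). Non-progressors are censored at their last CDR assessment.
#'
#' @param cdr data.frame with `subject_id`, `time`, `cdr_global`
#'   (values in 0/0.5/1/2).
#' @return data.frame with one row per subject: `subject_id`,
#'   `time_to_event`, `event` (1 = progressed). Subjects with an empty
#'   series are dropped with a message.
#' @export
progression_events <- function(cdr) {
  bad <- !cdr$cdr_global %in% c(0, 0.5, 1, 2)
  if (any(bad)) stop("invalid CDR global scores: ",
                     paste(unique(cdr$cdr_global[bad]), collapse = ", "))
  out <- lapply(split(cdr, cdr$subject_id), function(d) {
    d <- d[order(d$time), , drop = FALSE]
    nz <- d$cdr_global > 0
    n <- nrow(d)
    ev_idx <- NA_integer_
    pair <- which(nz[-n] & nz[-1])
    if (length(pair)) ev_idx <- pair[1]
    else if (nz[n]) ev_idx <- n
    if (is.na(ev_idx))
      data.frame(subject_id = d$subject_id[1], time_to_event = d$time[n],
                 event = 0L)
    else
      data.frame(subject_id = d$subject_id[1], time_to_event = d$time[ev_idx],
                 event = 1L)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  dropped <- setdiff(unique(cdr$subject_id), res$subject_id)
  if (length(dropped)) message(length(dropped), " subject(s) with empty CDR series dropped")
  res
}
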