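test_that("hippocampal-volume adjustment removes the head-size effect", {
  raw <- c(7000, 7500, 8000)
  etiv <- c(1.4e6, 1.5e6, 1.6e6)
  adj <- adjust_hippocampal_volume(raw, etiv)
  expect_equal(attr(adj, "b"), 0.005)
  expect_equal(as.numeric(adj), c(7500, 7500, 7500))

  # subject exactly at the mean eTIV keeps the raw volume
  set.seed(8)
  etiv2 <- rnorm(20, 1.5e6, 1e5)
  etiv2 <- c(etiv2, mean(etiv2))   # last subject sits exactly at the mean eTIV
  raw2 <- 7500 + 0.004 * (etiv2 - 1.5e6) + rnorm(21, 0, 300)
  adj2 <- adjust_hippocampal_volume(raw2, etiv2)
  expect_equal(attr(adj2, "mean_etiv"), etiv2[21])
  expect_equal(as.numeric(adj2[21]), raw2[21])
  # adjusted volume is empirically uncorrelated with eTIV
  expect_lt(abs(cor(as.numeric(adj2), etiv2)), 1e-8)

  # constant raw volume: b = 0, adjustment is the identity
  adj3 <- adjust_hippocampal_volume(rep(7000, 5), c(1.3e6, 1.4e6, 1.5e6, 1.6e6, 1.7e6))
  expect_equal(as.numeric(adj3), rep(7000, 5))
  expect_error(adjust_hippocampal_volume(raw, rep(1.5e6, 3)), "variance")
})

test_that("the cognitive composite averages referenced z-scores with sign flips", {
  ref <- list(mean = rep(10, 5), sd = rep(2, 5))
  at_mean <- matrix(10, 1, 5)
  expect_equal(compute_pacc5(at_mean, ref), 0, ignore_attr = TRUE)
  one_up <- at_mean; one_up[1] <- 12
  expect_equal(compute_pacc5(one_up, ref), 0.2, ignore_attr = TRUE)
  flags <- c(TRUE, rep(FALSE, 4))
  expect_equal(compute_pacc5(one_up, ref, direction_flags = flags), -0.2,
               ignore_attr = TRUE)
  # reference defaults to the supplied cohort: composite mean is 0
  set.seed(2)
  m <- matrix(rnorm(250, 10, 2), 50, 5)
  expect_lt(abs(mean(compute_pacc5(m))), 1e-10)
  expect_error(compute_pacc5(at_mean, list(mean = rep(10, 5), sd = rep(0, 5))),
               "positive")
  # missing-component policy
  some_na <- at_mean; some_na[1] <- NA
  expect_message(out <- compute_pacc5(some_na, ref), "minimum")
  expect_true(is.na(out))
  expect_equal(compute_pacc5(some_na, ref, min_components = 4), 0,
               ignore_attr = TRUE)
})

test_that("inclusion filtering anchors baselines at the tau scan and is idempotent", {
  visits <- data.frame(
    subject_id = c(rep("keep17wk", 3), rep("scanlate", 4), rep("onevisit", 1),
                   rep("window_miss", 3), rep("dupdate", 3)),
    visit_date = c("2015-01-01", "2016-01-05", "2017-02-01",      # scan 17wk after baseline
                   "2013-01-01", "2015-06-01", "2016-06-01", "2017-06-01",  # retrospective dropped
                   "2015-01-01",                                   # single visit
                   "2010-01-01", "2011-01-01", "2011-12-01",      # all visits >1y from scan
                   "2015-01-01", "2015-01-01", "2016-03-01"),     # duplicated date
    outcome = c(0.5, 0.4, 0.3,  0.2, 0.3, 0.2, 0.1,  0.9,  1, 1, 1,  0.2, 0.25, 0.1))
  baselines <- data.frame(
    subject_id = c("keep17wk", "scanlate", "onevisit", "window_miss", "dupdate"),
    scan_date = c("2015-05-01", "2015-03-01", "2015-01-15", "2013-06-01",
                  "2015-02-01"),
    baseline_age = 70, sex = 1, abeta = 1.1, tau_ec = 1.3, adj_hv = 7400)
  expect_message(res <- apply_inclusion_criteria(visits, baselines),
                 "duplicated")
  ids <- unique(res$cohort$subject_id)
  expect_setequal(ids, c("keep17wk", "scanlate", "dupdate"))
  expect_setequal(res$exclusions$reason[res$exclusions$subject_id == "onevisit"],
                  "insufficient timepoints")
  expect_true("window_miss" %in% res$exclusions$subject_id)
  # retrospective visit before the anchored baseline was dropped
  expect_equal(sum(res$cohort$subject_id == "scanlate"), 3L)
  expect_equal(res$cohort$time[res$cohort$subject_id == "scanlate"][1], 0)

  # idempotence: feeding the retained cohort back through changes nothing
  visits2 <- data.frame(subject_id = res$cohort$subject_id,
                        visit_date = as.Date("2020-01-01") +
                          round(res$cohort$time * 365.25),
                        outcome = res$cohort$outcome)
  base2 <- data.frame(subject_id = ids, scan_date = "2020-01-01",
                      baseline_age = 70, sex = 1, abeta = 1.1, tau_ec = 1.3,
                      adj_hv = 7400)
  res2 <- apply_inclusion_criteria(visits2, base2)
  expect_equal(nrow(res2$cohort), nrow(res$cohort))
  expect_equal(res2$cohort$outcome, res$cohort$outcome)
})

test_that("the resilience residual matches a normal-equations oracle", {
  set.seed(13)
  n <- 10
  base <- data.frame(pacc5 = rnorm(n), baseline_age = rnorm(n, 72, 8),
                     sex = rbinom(n, 1, 0.5), abeta = rnorm(n, 1.2, 0.2),
                     tau_ec = rnorm(n, 1.3, 0.2), adj_hv = rnorm(n, 7400, 800))
  r <- cr_residual(base)
  X <- cbind(1, base$baseline_age, base$sex, base$abeta, base$tau_ec, base$adj_hv)
  res_or <- base$pacc5 - X %*% solve(t(X) %*% X, t(X) %*% base$pacc5)
  s <- sqrt(sum(res_or^2) / (n - 6))
  expect_equal(r, as.numeric(res_or / s), tolerance = 1e-10)
  expect_lt(abs(mean(r)), 1e-10)
  # standardized residuals have (residual-denominator) SD 1 by construction
  expect_equal(sqrt(sum(r^2) / (n - 6)), 1, tolerance = 1e-8)

  exact <- base
  exact$pacc5 <- 0.3 * base$baseline_age - base$abeta
  expect_error(cr_residual(exact), "degenerate")
})

test_that("biomarker thresholds are strict inequalities", {
  fl <- threshold_flags(c(1.185, 1.27, 1.0), c(6723, 7141, 6722.9))
  expect_identical(fl$abeta_positive, c(FALSE, TRUE, FALSE))
  expect_identical(fl$hc_atrophy, c(FALSE, FALSE, TRUE))
})

test_that("activity scores average the item sets with the answered-fraction rule", {
  past <- matrix(3, 2, 25)
  cur <- matrix(2, 2, 11)
  sc <- activity_scores(past, cur)
  expect_equal(sc$past_activity, c(3, 3))
  expect_equal(sc$current_activity, c(2, 2))

  alt <- matrix(rep(c(1, 5), length.out = 25), 1, 25)   # 13 ones, 12 fives
  expect_equal(activity_scores(alt, matrix(3, 1, 11))$past_activity,
               (13 * 1 + 12 * 5) / 25)

  cur_na <- matrix(4, 1, 11); cur_na[1, 1:6] <- NA      # 6 of 11 missing
  expect_message(sc2 <- activity_scores(matrix(3, 1, 25), cur_na), "missing")
  expect_true(is.na(sc2$current_activity))
  expect_error(activity_scores(matrix(7, 1, 25), matrix(3, 1, 11)), "1-5")
})

test_that("occupational complexity reverses each scale and sums to 0-21", {
  expect_equal(occupational_complexity(0, 0, 0), 21)
  expect_equal(occupational_complexity(6, 8, 7), 0)
  expect_equal(occupational_complexity(3, 4, 3), 11)
  expect_error(occupational_complexity(7, 0, 0), "0-6")
})

test_that("deprivation tertiles come from the reference distribution", {
  ref <- 1:99
  tert <- adi_tertiles(c(2, 40, 90), reference = ref)
  expect_identical(as.character(tert), c("Lowest", "Intermediate", "Highest"))
  expect_equal(attr(tert, "cuts"), quantile(ref, c(1/3, 2/3), names = FALSE))
  expect_warning(one <- adi_tertiles(rep(50, 4)), "degenerate")
  expect_true(all(one == "Lowest"))
  expect_error(adi_tertiles(c(0, 5)), "1-100")
})

test_that("progression events follow the two-consecutive-or-final rule", {
  cdr <- rbind(
    data.frame(subject_id = "pair", time = c(0, 2, 3), cdr_global = c(0, 0.5, 0.5)),
    data.frame(subject_id = "blip", time = c(0, 2, 3), cdr_global = c(0, 0.5, 0)),
    data.frame(subject_id = "final", time = c(0, 1, 2), cdr_global = c(0, 0, 0.5)),
    data.frame(subject_id = "never", time = c(0, 1, 4), cdr_global = c(0, 0, 0)))
  ev <- progression_events(cdr)
  ev <- ev[match(c("pair", "blip", "final", "never"), ev$subject_id), ]
  expect_equal(ev$event, c(1L, 0L, 1L, 0L))
  expect_equal(ev$time_to_event, c(2, 3, 2, 4))
  expect_error(progression_events(
    data.frame(subject_id = "x", time = 0, cdr_global = 3)), "invalid")
})
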