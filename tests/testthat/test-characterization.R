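test_that("Kruskal-Wallis reduces to zero on exchangeable groups and matches ranks", {
  kw0 <- kruskal_wallis(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p_value, 1)

  # no-ties rank-formula oracle: H = 12/(N(N+1)) sum n_i (Rbar_i - Rbar)^2
  v <- c(1, 2, 3, 4, 5, 6)
  g <- rep(c("a", "b"), each = 3)
  r <- rank(v)
  H_or <- 12 / (6 * 7) * sum(3 * (tapply(r, g, mean) - 3.5)^2)
  kw <- kruskal_wallis(v, g)
  expect_equal(kw$statistic, H_or)
  expect_equal(kw$df, 1)

  kw3 <- kruskal_wallis(c(1, 2, 3), c("a", "b", "c"))
  expect_equal(kw3$statistic, 12 / (3 * 4) * sum((1:3 - 2)^2))
  expect_error(kruskal_wallis(1:3, rep("a", 3)), "2 groups")
})

test_that("Dunn post-hoc z matches the mean-rank closed form", {
  same <- dunn_posthoc(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$z, 0)
  expect_equal(same$p_raw, 1)

  v <- c(1, 2, 3, 4, 5, 6); g <- rep(c("a", "b"), each = 3)
  d <- dunn_posthoc(v, g)
  se <- sqrt((6 * 7 / 12) * (1 / 3 + 1 / 3))
  expect_equal(abs(d$z), abs(2 - 5) / se)
  expect_equal(d$p_raw, 2 * pnorm(-abs(d$z)))

  # the clearly shifted group carries the largest |z|
  set.seed(6)
  v3 <- c(rnorm(15), rnorm(15), rnorm(15, 5))
  g3 <- rep(c("a", "b", "c"), each = 15)
  d3 <- dunn_posthoc(v3, g3)
  far <- d3$group1 != d3$group2 & (d3$group1 == "c" | d3$group2 == "c")
  expect_gt(min(abs(d3$z[far])), abs(d3$z[!far]))
  expect_true(all(d3$p_adjusted >= d3$p_raw))
})

test_that("step-up adjustments follow their published arithmetic", {
  expect_equal(hochberg_adjust(0.03), 0.03)
  expect_equal(hochberg_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  set.seed(1)
  p <- runif(10)
  expect_equal(max(hochberg_adjust(p)), max(p))
  expect_equal(bh_fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr_adjust(p), bh_fdr_adjust(p))  # rerun reproduces itself
  expect_true(all(bh_fdr_adjust(p) >= p))
})

test_that("FDR adjustment reproduces the published regional tau table", {
  tab <- tau_roi_reference()
  expect_equal(nrow(tab), 33L)
  adj <- bh_fdr_adjust(tab$p_raw)
  expect_equal(adj[which.max(tab$p_raw)], 0.980)
  stable <- !(tab$roi %in% c("paracentral", "rostral middle frontal"))
  expect_equal(round(adj[stable], 3), rep(0.976, sum(stable)))
  # paracentral computes from rounded raw p to 0.495 vs printed 0.490
  expect_lt(abs(adj[tab$roi == "paracentral"] - tab$p_fdr_published[
    tab$roi == "paracentral"]), 0.01)
})

test_that("ROI regressions flag shifted regions and respect the null", {
  set.seed(17)
  n <- 120
  cls <- sample(c("Normal", "Resilient", "Declining"), n, TRUE,
                c(0.7, 0.22, 0.08))
  rois <- as.data.frame(matrix(rnorm(n * 8, 1.3, 0.2), n, 8))
  names(rois) <- paste0("roi_", 1:8)
  rois$roi_3 <- rois$roi_3 + 0.4 * (cls == "Resilient")   # true signal
  res <- roi_tau_analysis(rois, cls)
  expect_equal(res$roi[which.min(res$p_fdr)], "roi_3")
  expect_true(all(res$p_fdr >= res$p_raw))
  # constant column path
  rois$roi_9 <- 1.5
  res2 <- roi_tau_analysis(rois, cls)
  expect_equal(res2$p_raw[res2$roi == "roi_9"], 1)
  expect_equal(res2$estimate[res2$roi == "roi_9"], 0)
  # factor coding gives an omnibus p
  res3 <- roi_tau_analysis(rois[1:8], cls, coding = "factor")
  expect_true(all(is.na(res3$estimate)))
  expect_true(all(res3$p_raw >= 0 & res3$p_raw <= 1))
})

test_that("categorical testing switches to Fisher below expected-count 5", {
  flat <- matrix(c(10, 10, 10, 10), 2)
  r1 <- categorical_tests(flat)
  expect_identical(r1$method, "chisq")
  expect_equal(r1$statistic, 0)
  expect_equal(r1$p_value, 1)

  small <- matrix(c(8, 1, 2, 9), 2)   # expected counts < 5
  r2 <- categorical_tests(small)
  expect_identical(r2$method, "fisher")
  # hypergeometric enumeration oracle for the 2x2 exact test
  m <- 10; nn <- 10; k <- 9
  probs <- dhyper(0:9, m, nn, k)
  p_or <- sum(probs[probs <= dhyper(8, m, nn, k) * (1 + 1e-7)])
  expect_equal(r2$p_value, p_or, tolerance = 1e-10)

  big <- matrix(c(50, 30, 40, 60), 2)
  expect_identical(categorical_tests(big)$method, "chisq")
})

test_that("log-rank matches an observed-minus-expected oracle", {
  # two groups, four distinct event times, no censoring before the last event
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 1, 1, 0, 0)
  group <- c("a", "b", "a", "b", "a", "b")
  km <- km_logrank(time, event, group)
  # hand computation over the four event times
  at_risk <- function(t) list(a = sum(time >= t & group == "a"),
                              b = sum(time >= t & group == "b"))
  O_a <- E_a <- V <- 0
  for (t in c(1, 2, 3, 4)) {
    r <- at_risk(t); n <- r$a + r$b
    d <- 1
    O_a <- O_a + (group[time == t] == "a") * 1
    E_a <- E_a + d * r$a / n
    V <- V + d * (r$a / n) * (1 - r$a / n) * (n - d) / (n - 1)
  }
  chisq_or <- (sum(O_a) - E_a)^2 / V
  expect_equal(km$chisq, chisq_or, tolerance = 1e-10)
  expect_equal(km$df, 1L)
  expect_equal(unname(km$progressed_pct), c(2/3, 2/3) * 100)

  same <- km_logrank(rep(c(1, 2, 3), 2), rep(1, 6), rep(c("a", "b"), each = 3))
  expect_equal(same$chisq, 0, tolerance = 1e-12)
  expect_error(km_logrank(1:4, rep(0, 4), rep(c("a", "b"), 2)), "no progression")
})

test_that("trajectory contrasts recover engineered subgroup differences", {
  set.seed(23)
  N <- 90
  cls <- rep(c("Normal", "Declining"), times = c(60, 30))
  dat <- do.call(rbind, lapply(seq_len(N), function(i) {
    t <- 0:3
    slope <- if (cls[i] == "Declining") -0.3 else 0
    data.frame(subject_id = sprintf("c%03d", i), time = t,
               outcome = 0.2 + slope * t + rnorm(1, 0, 0.2) +
                 rnorm(4, 0, 0.15))
  }))
  co <- longitudinal_cohort(dat, require_covariates = character(0))
  tc <- trajectory_contrast(co, cls)
  slope_row <- grepl("slope", tc$contrast)
  expect_lt(abs(abs(tc$estimate[slope_row]) - 0.3),
            2 * tc$se[slope_row] + 0.02)
  expect_lt(tc$p_value[slope_row], 0.001)
  expect_gt(tc$p_value[grepl("intercept", tc$contrast)], 0.001)

  # permuting which level is reference flips signs, not magnitudes
  tc2 <- trajectory_contrast(co, factor(cls, levels = c("Declining", "Normal")))
  expect_equal(abs(tc2$estimate), abs(tc$estimate), tolerance = 1e-3)
})

test_that("final-visit comparison detects a shifted group and handles single visits", {
  set.seed(29)
  ids <- sprintf("f%02d", 1:45)
  cls <- rep(c("a", "b", "c"), each = 15)
  dat <- do.call(rbind, lapply(seq_along(ids), function(i) {
    last <- if (cls[i] == "c") -2 else 0
    data.frame(subject_id = ids[i], time = 0:2,
               outcome = c(rnorm(2, 0, 0.3), rnorm(1, last, 0.3)))
  }))
  co <- longitudinal_cohort(dat, require_covariates = character(0))
  fv <- final_visit_comparison(co, cls)
  expect_lt(fv$omnibus$p_value, 0.01)
  worst <- fv$pairwise[fv$pairwise$group1 == "c" | fv$pairwise$group2 == "c", ]
  expect_true(all(worst$p_adjusted < 0.05))
  expect_equal(fv$final_scores$final_outcome,
               dat$outcome[seq(3, nrow(dat), by = 3)])
})
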