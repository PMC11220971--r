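test_that("candidate enumeration is the family-by-class Cartesian product", {
  y <- rnorm(200)
  grid <- enumerate_candidates(y)
  expect_length(grid$specs, 24L)
  expect_length(grid$init_specs, 4L)
  expect_identical(names(grid$specs)[1], "linear_G2")

  small <- enumerate_candidates(y, families = "linear", class_range = 2:3)
  expect_length(small$specs, 2L)
  init_only <- enumerate_candidates(y, families = "linear", class_range = 1L)
  expect_length(init_only$specs, 1L)
  expect_identical(init_only$specs[[1]]$n_classes, 1L)
  expect_error(enumerate_candidates(y, families = character(0)), "non-empty")
})

make_two_class_cohort <- function(N = 60, seed = 11) {
  set.seed(seed)
  cls <- rep(1:2, times = c(round(0.6 * N), N - round(0.6 * N)))
  do.call(rbind, lapply(seq_len(N), function(i) {
    t <- 0:3
    mu <- if (cls[i] == 1) 0 - 0.02 * t else 1.4 - 0.35 * t
    data.frame(subject_id = sprintf("t%03d", i), time = t,
               outcome = mu + rnorm(1, 0, 0.25) + rnorm(4, 0, 0.2),
               true_class = cls[i])
  }))
}

test_that("one-class initialization seeds multi-class starts deterministically", {
  dat <- make_two_class_cohort()
  co <- longitudinal_cohort(dat, require_covariates = character(0))
  sp1 <- model_spec(1, build_link("linear", outcomes = co$outcome),
                    shared_design = character(0))
  f1 <- fit_lcmm(co, sp1)
  expect_true(f1$converged)

  expect_equal(init_from_one_class(f1, 1L),
               resiltraj:::as_theta(f1$params, sp1))

  i_a <- init_from_one_class(f1, 3L, seed = 42)
  i_b <- init_from_one_class(f1, 3L, seed = 42)
  expect_identical(i_a, i_b)
  expect_false(identical(i_a, init_from_one_class(f1, 3L, seed = 43)))

  # zero jitter: degenerate mixture reproduces the one-class likelihood
  sp3 <- model_spec(3, sp1$link, shared_design = character(0))
  i0 <- init_from_one_class(f1, 3L, seed = 1, jitter_scale = 0)
  expect_equal(total_loglik(co, sp3, i0), f1$loglik, tolerance = 1e-6)
})

test_that("grid search returns the best departure, deterministically", {
  dat <- make_two_class_cohort(N = 50, seed = 12)
  co <- longitudinal_cohort(dat, require_covariates = character(0))
  sp <- model_spec(2, build_link("linear", outcomes = co$outcome),
                   shared_design = character(0))
  g1 <- grid_search_fit(co, sp, n_departures = 4, burn_iters = 25, seed = 3)
  g2 <- grid_search_fit(co, sp, n_departures = 4, burn_iters = 25, seed = 3)
  expect_identical(g1$theta, g2$theta)
  expect_identical(g1$grid_search$departures, g2$grid_search$departures)
  expect_gte(g1$loglik, max(g1$grid_search$departures$loglik, na.rm = TRUE) - 1e-8)
  expect_true(g1$converged)
  # the 60/40 split should be recovered
  truth <- dat$true_class[!duplicated(dat$subject_id)]
  expect_gt(mclust::adjustedRandIndex(truth, g1$modal_class), 0.8)
})

test_that("admissibility requires convergence and a 5% smallest class", {
  stub <- function(converged, props) {
    structure(list(converged = converged, proportions = props),
              class = "lcmm_fit")
  }
  fits <- list(a = stub(TRUE, c(0.71, 0.225, 0.065)),
               b = stub(TRUE, c(0.97, 0.03)),
               c = stub(FALSE, c(0.5, 0.5)))
  keep <- filter_candidates(fits)
  expect_identical(names(keep), "a")
  expect_identical(attr(keep, "admissible"), c(TRUE, FALSE, FALSE))
  expect_length(filter_candidates(fits, min_prop = 0.01), 2L)
})

test_that("favored-model selection ranks by SABIC behind the entropy gate", {
  stub <- function(sabic, entropy, label_G) {
    structure(list(converged = TRUE, sabic = sabic, bic = sabic + 5,
                   loglik = -sabic / 2, npar = 10,
                   relative_entropy = entropy, proportions = c(0.6, 0.4),
                   spec = list(n_classes = label_G,
                               link = list(family = "linear"))),
              class = "lcmm_fit")
  }
  cands <- list(stub(900, 0.8, 2), stub(850, 0.4, 3), stub(860, 0.7, 4))
  rep1 <- select_favored(cands)
  expect_identical(rep1$favored$sabic, 860)
  expect_false(rep1$table$entropy_pass[1])   # lowest SABIC fails the gate

  single <- select_favored(cands[1])
  expect_identical(single$favored$sabic, 900)

  none <- select_favored(list(stub(800, 0.4, 2), stub(820, 0.5, 3)))
  expect_null(none$favored)
  expect_match(none$decision, "entropy gate")
  empty <- select_favored(list())
  expect_null(empty$favored)
})

test_that("class labelling keys on slope first, then baseline level", {
  stub_fit <- function(intercepts, slopes) {
    lk <- build_link("linear", outcomes = c(-2, 2))
    structure(list(spec = model_spec(length(intercepts), lk),
                   params = list(delta = rbind(intercepts, slopes))),
              class = "lcmm_fit")
  }
  expect_identical(label_classes(stub_fit(c(0.0, 0.7, 0.9),
                                          c(-0.02, -0.02, -0.30))),
                   c("Normal", "Resilient", "Declining"))
  # transfer-cohort pattern: the declining class has the lowest baseline
  expect_identical(label_classes(stub_fit(c(-0.5, 0.6, -1.0),
                                          c(-0.01, -0.01, -0.4))),
                   c("Normal", "Resilient", "Declining"))
  expect_warning(lab <- label_classes(stub_fit(c(0, 0.5, 1),
                                               c(-0.1, -0.1, -0.1))),
                 "tie|generic")
  expect_setequal(lab, c("C1", "C2", "C3"))
  # non-3-class models get generic level-ordered labels
  expect_identical(label_classes(stub_fit(c(0.2, -0.4), c(0, 0))),
                   c("C1", "C2"))
})

test_that("proportion reporting matches printed rounding conventions", {
  expect_equal(unname(class_proportion_report(c(142, 45, 13), N = 200,
                                              counts = TRUE)),
               c(71, 22.5, 6.5))
  expect_equal(unname(class_proportion_report(c(141, 10, 9), N = 160,
                                              counts = TRUE)),
               c(88.12, 6.25, 5.62))
  expect_equal(unname(class_proportion_report(c(200), N = 200, counts = TRUE)),
               100)
  expect_equal(unname(class_proportion_report(rep(c("a", "b"), c(3, 1)))),
               c(75, 25))
})

test_that("replicated fits group by partition up to label permutation", {
  dat <- make_two_class_cohort(N = 40, seed = 14)
  co <- longitudinal_cohort(dat, require_covariates = character(0))
  sp <- model_spec(2, build_link("linear", outcomes = co$outcome),
                   shared_design = character(0))
  rep_fit <- replicate_modal_fit(co, sp, n_repeats = 3, seeds = c(5, 6, 7),
                                 n_departures = 3, burn_iters = 20)
  expect_identical(sum(rep_fit$frequency), 3L)
  expect_s3_class(rep_fit$fit, "lcmm_fit")
  # permuted labellings of one partition count as a single group
  expect_identical(length(rep_fit$frequency), max(rep_fit$groups))
})

test_that("sensitivity variants behave as designed on engineered data", {
  set.seed(31)
  N <- 60
  dat <- do.call(rbind, lapply(seq_len(N), function(i) {
    x <- rnorm(1)
    g <- 1 + (i > 0.6 * N)
    t <- 0:3
    mu <- if (g == 1) 0 - 0.02 * t else 1.3 - 0.3 * t
    data.frame(subject_id = sprintf("v%03d", i), time = t,
               outcome = mu + 0.8 * x + rnorm(1, 0, 0.2) + rnorm(4, 0, 0.2),
               covar = x, covar_copy = x)
  }))
  co <- longitudinal_cohort(dat, require_covariates = c("covar", "covar_copy"))
  sp <- model_spec(2, build_link("linear", outcomes = co$outcome),
                   shared_design = "covar")
  ft <- grid_search_fit(co, sp, n_departures = 3, burn_iters = 20, seed = 2)
  out <- sensitivity_suite(co, ft, swap = list(covar = "covar_copy"),
                           min_visits = 3L,
                           n_departures = 3, burn_iters = 20, seed = 2)
  expect_true(all(c("reference", "unconditioned") %in%
                    c("reference", out$variant)))
  # strong covariate signal: the unconditioned model fits worse
  expect_gt(out$sabic[out$variant == "unconditioned"],
            out$sabic[out$variant == "reference"])
  # swapping in an identical copy reproduces the reference SABIC
  expect_equal(out$sabic[grepl("replaced", out$variant)],
               out$sabic[out$variant == "reference"], tolerance = 1e-6)
  # every subject already has 4 visits: the restriction changes nothing
  expect_equal(out$sabic[grepl("at least 3", out$variant)],
               out$sabic[out$variant == "reference"], tolerance = 1e-6)
  # a missing replacement column is skipped, not fatal
  expect_message(
    out2 <- sensitivity_suite(co, ft, swap = list(covar = "nope"),
                              min_visits = integer(0)),
    "skipped")
})
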