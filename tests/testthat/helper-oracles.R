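# Independent oracles used across the suite. These deliberately avoid the
# package's own likelihood code paths.

# log multivariate-normal density from first principles
ldmvn <- function(y, mu, V) {
  k <- length(y)
  ch <- chol(V)
  w <- backsolve(ch, y - mu, transpose = TRUE)
  -0.5 * (k * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(w^2))
}

# brute-force mixture log-likelihood by Gauss-Hermite integration over the
# subject random effects (identity link), for small instances
gh_mixture_loglik <- function(cohort, pi_g, beta, delta, B, sigma,
                              shared_cols, n_nodes = 50) {
  gh <- pracma::gaussHermite(n_nodes)
  nodes <- gh$x * sqrt(2)
  w <- gh$w / sqrt(pi)
  L <- if (all(B == 0)) B * 0 else t(chol(B))
  q <- nrow(B)
  G <- length(pi_g)
  total <- 0
  for (idx in split(seq_len(nrow(cohort)), cohort$subject_id)) {
    y <- cohort$outcome[idx]
    t <- cohort$time[idx]
    Zi <- cbind(1, t)[, seq_len(q), drop = FALSE]
    xb <- if (length(shared_cols))
      drop(as.matrix(cohort[idx, shared_cols, drop = FALSE]) %*% beta) else 0
    f <- 0
    for (g in seq_len(G)) {
      mu0 <- xb + delta[1, g] + if (nrow(delta) > 1) delta[2, g] * t else 0
      if (q == 2) {
        val <- 0
        for (a in seq_len(n_nodes)) for (b in seq_len(n_nodes)) {
          u <- L %*% c(nodes[a], nodes[b])
          val <- val + w[a] * w[b] * prod(dnorm(y, mu0 + Zi %*% u, sigma))
        }
      } else if (q == 1) {
        val <- sum(vapply(seq_len(n_nodes), function(a)
          w[a] * prod(dnorm(y, mu0 + Zi %*% (L * nodes[a]), sigma)),
          numeric(1)))
      } else val <- prod(dnorm(y, mu0, sigma))
      f <- f + pi_g[g] * val
    }
    total <- total + log(f)
  }
  total
}

# balanced single-class mixed-model data for the G = 1 reduction tests
make_balanced_cohort <- function(N = 50, n_visits = 5, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(N), function(i) {
    t <- seq(0, n_visits - 1)
    age <- rnorm(1, 72, 9)
    sex <- rbinom(1, 1, 0.5)
    b0 <- rnorm(1, 0, 0.4); b1 <- rnorm(1, 0, 0.1)
    y <- 0.5 - 0.1 * t + 0.02 * (age - 72) + 0.3 * sex + b0 + b1 * t +
      rnorm(n_visits, 0, 0.3)
    data.frame(subject_id = sprintf("B%03d", i), time = t, outcome = y,
               baseline_age = age, sex = sex)
  }))
}

# align estimated classes to true classes by confusion-matrix maximum overlap
align_classes <- function(true, est, G = max(true)) {
  perms <- if (G == 3) list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1),
                            c(3,1,2), c(3,2,1))
  else combinat_perms(G)
  tab <- table(factor(true, levels = 1:G), factor(est, levels = 1:G))
  best <- perms[[which.max(vapply(perms, function(p)
    sum(diag(tab[, p, drop = FALSE])), numeric(1)))]]
  best   # est class best[g] corresponds to true class g
}

combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in combinat_perms(n - 1L)) {
      q <- integer(n); q[1] <- i; q[-1] <- setdiff(seq_len(n), i)[p]
      out[[length(out) + 1L]] <- q
    }
  }
  out
}
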