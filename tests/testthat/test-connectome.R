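# Monte-Carlo oracle for the replication Bayes factor: self-normalized
# importance sampling of the discovery posterior for delta with a uniform
# proposal, averaging the replication noncentral-t likelihood.
mc_repbf <- function(t_o, n_o, t_r, n_r, df_o, df_r, ndraws = 2e5) {
  c1 <- t_o / sqrt(n_o); c2 <- t_r / sqrt(n_r)
  s <- 1 / sqrt(min(n_o, n_r))
  delta <- runif(ndraws, min(c1, c2) - 12 * s, max(c1, c2) + 12 * s)
  w <- suppressWarnings(dt(t_o, df_o, ncp = delta * sqrt(n_o)))
  num <- mean(w * suppressWarnings(dt(t_r, df_r, ncp = delta * sqrt(n_r))))
  num / (mean(w) * dt(t_r, df_r))
}

test_that("ridge partial correlation reduces to Pearson correlation for K = 2, rho = 0", {
  set.seed(31)
  x <- matrix(rnorm(400), ncol = 2)
  x[, 2] <- x[, 2] + 0.6 * x[, 1]
  r <- ridge_partial_correlation(x, rho = 0)
  expect_equal(r[1, 2], cor(x)[1, 2], tolerance = 1e-10)
  expect_equal(diag(r), c(1, 1), ignore_attr = TRUE)
})

test_that("unregularized partial correlations recover the generating precision matrix", {
  theta <- matrix(c(1, -0.4, 0.2,
                    -0.4, 1, -0.3,
                    0.2, -0.3, 1), 3, 3)
  sim <- simulate_component_timeseries(1, K = 3, T_len = 1e5,
                                       partial = data.frame(
                                         i = c(2, 3, 3), j = c(1, 1, 2),
                                         r = c(0.4, -0.2, 0.3)),
                                       seed = 77)
  expect_equal(sim$theta, theta)
  r <- ridge_partial_correlation(sim$ts[[1]], rho = 0)
  target <- -theta / sqrt(tcrossprod(diag(theta)))
  diag(target) <- 1
  expect_equal(r, target, tolerance = 0.02, ignore_attr = TRUE)
})

test_that("heavy regularization shrinks off-diagonal partial correlations to zero", {
  set.seed(5)
  x <- matrix(rnorm(500 * 4), ncol = 4)
  x[, 2] <- x[, 2] + x[, 1]
  r <- ridge_partial_correlation(x, rho = 1e6)
  expect_true(all(abs(r[upper.tri(r)]) < 1e-4))
  expect_error(ridge_partial_correlation(cbind(x, 1), rho = 1),
               "constant")
})

test_that("partial correlation matrices are symmetric, bounded, unit-diagonal", {
  set.seed(6)
  for (k in c(3, 10, 19)) {
    x <- matrix(rnorm(300 * k), ncol = k)
    r <- ridge_partial_correlation(x, rho = 1)
    expect_equal(r, t(r))
    expect_equal(diag(r), rep(1, k), ignore_attr = TRUE)
    expect_true(all(abs(r) <= 1 + 1e-12))
  }
})

test_that("Fisher transform is atanh with a working inverse and domain guard", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_equal(fisher_z(0.5), 0.5493061, tolerance = 1e-6)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z_inv(fisher_z(r)), r, tolerance = 1e-12)
  expect_error(fisher_z(1), "< 1")
})

test_that("edge vectorization yields K(K-1)/2 stable lower-triangle entries", {
  expect_length(vectorize_edges(diag(19)), 171)
  expect_length(vectorize_edges(diag(3)), 3)
  m <- matrix(1:9, 3, 3)
  v <- vectorize_edges(m)
  expect_equal(unname(v), c(m[2, 1], m[3, 1], m[3, 2]))
  expect_equal(names(v), c("IC02-IC01", "IC03-IC01", "IC03-IC02"))
  expect_identical(vectorize_edges(m), vectorize_edges(m))
})

test_that("the group model reduces to the pooled-variance t-test for one site", {
  set.seed(41)
  a <- rnorm(40); b <- rnorm(35, 0.4)
  fit <- fit_edge_model(c(a, b), factor(rep(c("TD", "ASD"), c(40, 35)),
                                        levels = c("TD", "ASD")))
  tt <- t.test(b, a, var.equal = TRUE)
  expect_equal(fit$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(fit$p, tt$p.value, tolerance = 1e-10)
  expect_equal(fit$model, "lm")

  # aliased covariates are an error naming the column
  g <- rep(c("TD", "ASD"), c(40, 35))
  expect_error(fit_edge_model(c(a, b), g, age = as.numeric(g == "ASD")),
               "rank-deficient")
})

test_that("the mixed model absorbs site intercepts", {
  set.seed(43)
  n <- 240
  site <- sample(paste0("site", 1:4), n, TRUE)
  group <- factor(rep(c("TD", "ASD"), each = n / 2), levels = c("TD", "ASD"))
  site_eff <- setNames(rnorm(4, 0, 2), paste0("site", 1:4))
  y <- site_eff[site] + 0.5 * (group == "ASD") + rnorm(n)
  fit <- fit_edge_model(y, group, site = site)
  expect_equal(fit$model, "lme")
  expect_equal(fit$estimate, 0.5, tolerance = 0.35)
  expect_lt(fit$p, 0.05)
})

test_that("edge-model false positives stay at the nominal 0.05 rate under the null", {
  set.seed(47)
  group <- rep(c("TD", "ASD"), c(40, 40))
  p <- replicate(1000, fit_edge_model(rnorm(80), group)$p)
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 3.5 * sqrt(0.05 * 0.95 / 1000))
})

test_that("Cohen's d is the pooled-SD standardized mean difference", {
  set.seed(51)
  x <- rnorm(50)
  expect_equal(cohens_d(x, x), 0)
  a <- rnorm(2000, 1, 1); b <- rnorm(2000, 0, 1)
  expect_equal(cohens_d(a, b), 1, tolerance = 0.08)
  # planted 0.51 at the replication-half group sizes is recovered on average
  d_hat <- replicate(400, cohens_d(rnorm(83, 0.51), rnorm(122, 0)))
  expect_equal(mean(d_hat), 0.51, tolerance = 0.03)
})

test_that("repBF moves in the right direction and matches the MC oracle within 2%", {
  strong_fail <- replication_bayes_factor(4, 50, 0, 50)
  expect_lt(strong_fail, 1)
  strong_rep <- replication_bayes_factor(4, 50, 4, 50)
  expect_gt(strong_rep, 1)

  set.seed(61)
  grid <- expand.grid(t_o = c(0, 1, 2.5, 4), t_r = c(-1, 0.5, 2, 3.5, 5),
                      n = c(40, 90))
  grid <- grid[seq(1, nrow(grid), by = 2), ]  # 20 points
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    bf <- replication_bayes_factor(g$t_o, g$n, g$t_r, g$n,
                                   df_orig = 2 * g$n - 2, df_rep = 2 * g$n - 2)
    oracle <- mc_repbf(g$t_o, g$n, g$t_r, g$n, 2 * g$n - 2, 2 * g$n - 2)
    expect_equal(bf, oracle, tolerance = 0.02)
  }
})

test_that("replication analysis recovers exactly the planted consensus edges", {
  planted <- data.frame(i = c(13L, 12L, 17L), j = c(7L, 3L, 12L),
                        group = "SC=RRB", d = 0.6)
  sim <- simulate_connectome_dataset(
    group_sizes = list(discovery = c("SC=RRB" = 77L, TD = 121L),
                       replication = c("SC=RRB" = 83L, TD = 122L)),
    planted = planted, n_sites = 1L, site_sd = 0, seed = 72)
  half <- function(h) list(edges = h$edges,
                           group = factor(h$pheno$group, levels = c("TD", "SC=RRB")))
  res <- edge_replication_analysis(half(sim$discovery), half(sim$replication))
  results_by_thr <- setNames(rep(list(res), 3), c("0.5", "0.8", "1.0"))
  cons <- consensus_edges(results_by_thr)
  expect_setequal(cons$edge, c("IC13-IC07", "IC12-IC03", "IC17-IC12"))

  # consensus is the intersection of the per-threshold replicable sets
  manual <- Reduce(intersect, lapply(results_by_thr, function(r) r$edge[r$replicable]))
  expect_setequal(cons$edge, manual)

  # an edge failing at one threshold is excluded
  res2 <- res
  res2$replicable[res2$edge == "IC13-IC07"] <- FALSE
  cons2 <- consensus_edges(c(results_by_thr, list("0.9" = res2)))
  expect_false("IC13-IC07" %in% cons2$edge)
  expect_true("IC12-IC03" %in% cons2$edge)
})

test_that("the dimensional model reports slope statistics with the replication criterion inputs", {
  set.seed(81)
  n <- 150
  x <- rnorm(n)
  y <- 0.3 * x + rnorm(n)
  sex <- sample(c("M", "F"), n, TRUE)
  age <- runif(n, 6, 30)
  fit <- dimensional_edge_model(y, x, sex = sex, age = age)
  oracle <- summary(lm(y ~ x + factor(sex) + age))$coefficients
  expect_equal(fit$estimate, oracle["x", "Estimate"], tolerance = 1e-10)
  expect_equal(fit$t, oracle["x", "t value"], tolerance = 1e-10)
  expect_lt(fit$p, 0.01)
  expect_equal(fit$n_eff, n - 4L)
  lmfit <- summary(lm(y ~ x))$coefficients
  plain <- dimensional_edge_model(y, x)
  expect_equal(plain$t, lmfit["x", "t value"], tolerance = 1e-10)
})
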