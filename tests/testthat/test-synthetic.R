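test_that("every generator is bit-reproducible under a fixed seed", {
  expect_identical(simulate_adir_cohort(40, seed = 5),
                   simulate_adir_cohort(40, seed = 5))
  expect_identical(simulate_cohort_pair(50, 50, seed = 5),
                   simulate_cohort_pair(50, 50, seed = 5))
  gs <- list(discovery = c(ASD = 15L, TD = 20L),
             replication = c(ASD = 15L, TD = 20L))
  expect_identical(
    simulate_connectome_dataset(gs, K = 5, planted = data.frame(), seed = 5),
    simulate_connectome_dataset(gs, K = 5, planted = data.frame(), seed = 5))
  expect_identical(
    simulate_expression_atlas(n_genes = 50, n_coupled = 5, n_samples = 40, seed = 5),
    simulate_expression_atlas(n_genes = 50, n_coupled = 5, n_samples = 40, seed = 5))
  expect_identical(simulate_gene_lists(c("A", "B", "C"), 100, 10, 2, seed = 5),
                   simulate_gene_lists(c("A", "B", "C"), 100, 10, 2, seed = 5))
  # different seeds give different draws
  expect_false(identical(simulate_adir_cohort(40, seed = 5),
                         simulate_adir_cohort(40, seed = 6)))
})

test_that("item codes are pinned at the severity extremes", {
  sev0 <- data.frame(subject_id = "a", sc = 0, rrb = 0)
  sim0 <- simulate_adir_cohort(1, dummy_rate = 0, seed = 1, severities = sev0)
  expect_true(all(sim0$records[, -1] == 0))

  sev1 <- data.frame(subject_id = "a", sc = 1, rrb = 1)
  sim1 <- simulate_adir_cohort(1, dummy_rate = 0, seed = 1, severities = sev1)
  expect_true(all(sim1$records[, -1] == 3))
})

test_that("recovered domain scores are unbiased for the latent severity", {
  n <- 4000
  sev <- data.frame(subject_id = sprintf("s%04d", 1:n), sc = 0.5, rrb = 0.5)
  sim <- simulate_adir_cohort(n, dummy_rate = 0.05, seed = 9, severities = sev)
  scores <- score_adir(sim$records)
  expect_equal(mean(scores$sc_pct), 0.5, tolerance = 0.01)
  expect_equal(mean(scores$rrb_pct), 0.5, tolerance = 0.01)
})

test_that("the severity generator hits the reference difference-score distribution", {
  sev <- simulate_severities(20000, seed = 13)
  d <- sev$sc - sev$rrb
  ref <- ndar_combined_norms()
  expect_lt(abs(mean(d) - ref$mean), 0.005)
  expect_lt(abs(sd(d) - ref$sd), 0.005)
  expect_true(all(sev$sc >= 0 & sev$sc <= 1 & sev$rrb >= 0 & sev$rrb <= 1))
})

test_that("connectome truth tables drive the downstream effect sizes", {
  # no planted effects: edge-wise d centred at zero
  gs <- list(discovery = c(ASD = 60L, TD = 60L),
             replication = c(ASD = 60L, TD = 60L))
  null_sim <- simulate_connectome_dataset(gs, K = 10, planted = data.frame(),
                                          n_sites = 1, site_sd = 0, seed = 17)
  g <- null_sim$discovery$pheno$group
  ds <- apply(null_sim$discovery$edges, 2, function(v) {
    cohens_d(v[g == "ASD"], v[g == "TD"])
  })
  expect_equal(mean(ds), 0, tolerance = 0.06)
  expect_equal(nrow(null_sim$truth), 0)

  # planted d = 0.51 on IC13-IC07 recovered over replicates
  planted <- data.frame(i = 13L, j = 7L, group = "ASD", d = 0.51)
  gs2 <- list(discovery = c(ASD = 83L, TD = 122L),
              replication = c(ASD = 83L, TD = 122L))
  d_hat <- vapply(1:60, function(s) {
    sim <- simulate_connectome_dataset(gs2, K = 19, planted = planted,
                                       n_sites = 1, site_sd = 0, seed = 1000 + s)
    g <- sim$discovery$pheno$group
    v <- sim$discovery$edges[, "IC13-IC07"]
    cohens_d(v[g == "ASD"], v[g == "TD"])
  }, numeric(1))
  expect_equal(mean(d_hat), 0.51, tolerance = 0.06)
})

test_that("time-series mode round-trips through the ridge estimator", {
  partial <- data.frame(i = c(2, 4), j = c(1, 3), r = c(0.3, -0.25))
  sim <- simulate_component_timeseries(1, K = 5, T_len = 1e4,
                                       partial = partial, seed = 23)
  r <- ridge_partial_correlation(sim$ts[[1]], rho = 0)
  expect_lt(abs(r[2, 1] - 0.3), 0.03)
  expect_lt(abs(r[4, 3] + 0.25), 0.03)
  expect_lt(abs(r[5, 1]), 0.03)
  expect_error(
    simulate_component_timeseries(1, K = 3, T_len = 10,
                                  partial = data.frame(i = c(2, 3, 3),
                                                       j = c(1, 1, 2),
                                                       r = c(0.8, 0.8, 0.8))),
    "non-PD")
})

test_that("planted enrichment multipliers shift the sampled overlap", {
  network <- sprintf("NET%03d", 1:200)
  flat_overlap <- vapply(1:50, function(s) {
    length(intersect(simulate_gene_lists(network, 2000, 100, 1,
                                         seed = s)$annotation, network))
  }, numeric(1))
  rich_overlap <- vapply(1:50, function(s) {
    length(intersect(simulate_gene_lists(network, 2000, 100, 8,
                                         seed = s)$annotation, network))
  }, numeric(1))
  expect_equal(mean(flat_overlap), 100 * 200 / 2000, tolerance = 1)
  expect_gt(mean(rich_overlap), 2.5 * mean(flat_overlap))
})

test_that("child seeds are deterministic, distinct, and 32-bit safe", {
  s1 <- child_seeds(17, 5)
  expect_identical(s1, child_seeds(17, 5))
  expect_false(anyDuplicated(s1) > 0)
  expect_true(all(s1 >= 1 & s1 < 2^31))
  # deriving child seeds does not disturb the caller's RNG stream
  set.seed(1); a <- rnorm(1)
  set.seed(1); invisible(child_seeds(99, 3)); b <- rnorm(1)
  expect_identical(a, b)
})
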