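#' Simulate latent SC/RRB severities for a cohort
#'
#' Draws (SC, RRB) severity pairs from a bivariate normal truncated to the
#' unit square, calibrated so that the SC-RRB difference score matches the
#' reference distribution of the pooled NDAR sample (mean 0.01045243,
#' SD 0.19482749). The between-domain correlation is solved from
#' \code{var(diff) = 2 sd^2 (1 - rho)}; because truncation to [0, 1]
#' slightly shrinks the realized moments, the working parameters are then
#' adjusted by a few seeded moment-matching iterations against a large
#' calibration draw before the final sample is taken.
#'
#' @param n Number of subjects.
#' @param sc_mean,rrb_mean Marginal means (defaults 0.3305, 0.3200).
#' @param marginal_sd Common marginal SD (default 0.15).
#' @param diff_mean,diff_sd Target difference-score mean/SD, defaulting to
#'   the shipped combined reference norms.
#' @param seed Integer seed.
#' @return Data.frame \code{subject_id}, \code{sc}, \code{rrb}.
#' @export
simulate_severities <- function(n, sc_mean = NULL, rrb_mean = 0.32,
                                marginal_sd = 0.15,
                                diff_mean = ndar_combined_norms()$mean,
                                diff_sd = ndar_combined_norms()$sd,
                                seed = 1L) {
  sc_mean <- sc_mean %||% (rrb_mean + diff_mean)
  draw <- function(m, mu_d, sd_d, seed_k) {
    rho <- 1 - sd_d^2 / (2 * marginal_sd^2)
    if (abs(rho) > 1) stop("diff_sd incompatible with marginal_sd")
    with_seed(seed_k, {
      out <- matrix(NA_real_, 0, 2)
      while (nrow(out) < m) {
        k <- 2 * (m - nrow(out)) + 10
        z1 <- stats::rnorm(k); z2 <- stats::rnorm(k)
        sc <- (rrb_mean + mu_d) + marginal_sd * z1
        rrb <- rrb_mean + marginal_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
        ok <- sc >= 0 & sc <= 1 & rrb >= 0 & rrb <= 1
        out <- rbind(out, cbind(sc, rrb)[ok, , drop = FALSE])
      }
      out[seq_len(m), , drop = FALSE]
    })
  }
  seeds <- child_seeds(seed, 4)
  # moment-match the post-truncation difference score to the targets
  mu_d <- sc_mean - rrb_mean; sd_d <- diff_sd
  for (it in 1:3) {
    cal <- draw(20000, mu_d, sd_d, seeds[it])
    d <- cal[, 1] - cal[, 2]
    mu_d <- mu_d + (diff_mean - mean(d))
    sd_d <- sd_d * diff_sd / stats::sd(d)
  }
  out <- draw(n, mu_d, sd_d, seeds[4])
  data.frame(subject_id = sprintf("sub%05d", seq_len(n)),
             sc = out[, 1], rrb = out[, 2], stringsAsFactors = FALSE)
}

#' Simulate an ADI-R item-level cohort with known latent severities
#'
#' Item codes are drawn as Binomial(3, severity) per item, so the expected
#' subscale percentage equals the latent domain severity; a configurable
#' fraction of items is replaced by dummy codes (7/8), which the scoring
#' stage must ignore.
#'
#' @param n Number of subjects.
#' @param mapping Item mapping (default the bundled schematic mapping).
#' @param dummy_rate Fraction of item entries set to dummy codes (default
#'   0.05).
#' @param seed Integer seed.
#' @param severities Optional data.frame with \code{subject_id}, \code{sc},
#'   \code{rrb} to use as the latent truth instead of drawing it.
#' @param ... Passed to \code{\link{simulate_severities}}.
#' @return List with \code{records} (wide item-code data.frame ready for
#'   \code{\link{score_adir}}) and \code{truth} (latent \code{sc},
#'   \code{rrb}, \code{diff} per subject).
#' @export
simulate_adir_cohort <- function(n, mapping = default_item_mapping(),
                                 dummy_rate = 0.05, seed = 1L,
                                 severities = NULL, ...) {
  seeds <- child_seeds(seed, 2)
  truth <- if (is.null(severities)) {
    simulate_severities(n, seed = seeds[1], ...)
  } else {
    stopifnot(all(c("subject_id", "sc", "rrb") %in% names(severities)),
              nrow(severities) == n)
    severities
  }
  with_seed(seeds[2], {
    records <- data.frame(subject_id = truth$subject_id,
                          stringsAsFactors = FALSE)
    for (k in seq_len(nrow(mapping))) {
      sev <- if (mapping$domain[k] == "SC") truth$sc else truth$rrb
      code <- stats::rbinom(n, 3, sev)
      if (dummy_rate > 0) {
        dummy <- stats::runif(n) < dummy_rate
        code[dummy] <- sample(c(7L, 8L), sum(dummy), replace = TRUE)
      }
      records[[mapping$item_id[k]]] <- code
    }
    truth$diff <- truth$sc - truth$rrb
    list(records = records, truth = truth)
  })
}

#' Simulate a pair of i.i.d. cohorts from one generating distribution
#'
#' Both cohorts are drawn from the same difference-score distribution
#' (default: the pooled reference norms), emulating a Discovery/Replication
#' partition of one population. In \code{"scores"} mode the cohorts carry
#' difference scores directly; in \code{"items"} mode full item-level
#' cohorts are generated.
#'
#' @param n1,n2 Cohort sizes (defaults 889 and 890).
#' @param mode \code{"scores"} or \code{"items"}.
#' @param diff_mean,diff_sd Generating difference-score mean and SD.
#' @param seed Integer seed.
#' @return List of two elements; in scores mode each is a data.frame with
#'   \code{subject_id} and \code{diff}, in items mode each is the value of
#'   \code{\link{simulate_adir_cohort}}.
#' @export
simulate_cohort_pair <- function(n1 = 889, n2 = 890, mode = c("scores", "items"),
                                 diff_mean = ndar_combined_norms()$mean,
                                 diff_sd = ndar_combined_norms()$sd,
                                 seed = 1L) {
  mode <- match.arg(mode)
  seeds <- child_seeds(seed, 2)
  if (mode == "scores") {
    gen <- function(n, s) with_seed(s, data.frame(
      subject_id = sprintf("sub%05d", seq_len(n)),
      diff = stats::rnorm(n, diff_mean, diff_sd),
      stringsAsFactors = FALSE))
    list(discovery = gen(n1, seeds[1]), replication = gen(n2, seeds[2]))
  } else {
    list(discovery = simulate_adir_cohort(n1, seed = seeds[1],
                                          diff_mean = diff_mean, diff_sd = diff_sd),
         replication = simulate_adir_cohort(n2, seed = seeds[2],
                                            diff_mean = diff_mean, diff_sd = diff_sd))
  }
}

#' Default planted edge effects for the connectome generator
#'
#' The three consensus edges reported for the subtype-vs-TD contrasts, with
#' the Replication-set standardized effect sizes: IC07-IC13 hyperconnectivity
#' in SC=RRB (d = 0.51), IC03-IC12 hypoconnectivity in SC=RRB (d = -0.36),
#' IC12-IC17 hypoconnectivity in SC>RRB (d = -0.41).
#'
#' @return Data.frame with columns \code{i}, \code{j}, \code{group},
#'   \code{d}.
#' @export
default_planted_edges <- function() {
  data.frame(i = c(13L, 12L, 17L), j = c(7L, 3L, 12L),
             group = c("SC=RRB", "SC=RRB", "SC>RRB"),
             d = c(0.51, -0.36, -0.41),
             stringsAsFactors = FALSE)
}

#' Default LEAP-style group sizes
#'
#' Discovery and Replication cohort sizes per group at the z = 1 subtype
#' threshold (SC=RRB 77/83, SC>RRB 50/49, TD 121/122).
#'
#' @return Named list of named integer vectors.
#' @export
default_group_sizes <- function() {
  list(discovery = c("SC=RRB" = 77L, "SC>RRB" = 50L, "TD" = 121L),
       replication = c("SC=RRB" = 83L, "SC>RRB" = 49L, "TD" = 122L))
}

#' Simulate a Discovery/Replication connectome dataset with planted effects
#'
#' Edge mode: each subject's Fisher-z edge value is Normal(mu, sigma^2)
#' where mu is 0 for TD plus the planted standardized difference on the
#' planted (edge, group) combinations, plus a site intercept drawn per
#' (site, edge). The same planted truth is applied in both halves so that
#' the replication machinery has true consensus edges to find.
#'
#' @param group_sizes As \code{\link{default_group_sizes}}.
#' @param K Number of components (default 19 giving 171 edges).
#' @param planted Data.frame of planted effects (\code{i}, \code{j} 1-based
#'   component indices with \code{i > j}, \code{group}, \code{d}); default
#'   \code{\link{default_planted_edges}}.
#' @param n_sites Number of acquisition sites (default 3).
#' @param site_sd SD of the per-(site, edge) intercepts (default 0.1).
#' @param sigma Residual SD of edge values (default 1).
#' @param seed Integer seed.
#' @return List with \code{discovery} and \code{replication}, each a list
#'   of \code{edges} (subjects x edges matrix), \code{pheno} (subject_id,
#'   group, sex, age, site), and a \code{truth} data.frame with planted
#'   effects keyed by edge name.
#' @export
simulate_connectome_dataset <- function(group_sizes = default_group_sizes(),
                                        K = 19L,
                                        planted = default_planted_edges(),
                                        n_sites = 3L, site_sd = 0.1,
                                        sigma = 1, seed = 1L) {
  enames <- edge_names(K)
  truth <- data.frame(edge = character(0), group = character(0), d = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(planted)) {
    stopifnot(all(planted$i > planted$j), all(planted$i <= K), all(planted$j >= 1))
    truth <- data.frame(edge = sprintf("IC%02d-IC%02d", planted$i, planted$j),
                        group = planted$group, d = planted$d,
                        stringsAsFactors = FALSE)
    stopifnot(all(truth$edge %in% enames))
  }
  seeds <- child_seeds(seed, length(group_sizes))
  halves <- lapply(seq_along(group_sizes), function(h) {
    sizes <- group_sizes[[h]]
    n <- sum(sizes)
    with_seed(seeds[h], {
      group <- rep(names(sizes), sizes)
      site <- sample(paste0("site", seq_len(n_sites)), n, replace = TRUE)
      sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.75, 0.25))
      age <- stats::rnorm(n, 16.5, 5.5)
      site_eff <- matrix(stats::rnorm(n_sites * length(enames), 0, site_sd),
                         nrow = n_sites,
                         dimnames = list(paste0("site", seq_len(n_sites)), enames))
      mu <- matrix(0, nrow = n, ncol = length(enames),
                   dimnames = list(NULL, enames))
      for (k in seq_len(nrow(truth))) {
        mu[group == truth$group[k], truth$edge[k]] <-
          mu[group == truth$group[k], truth$edge[k]] + truth$d[k] * sigma
      }
      edges <- mu + site_eff[site, , drop = FALSE] +
        matrix(stats::rnorm(n * length(enames), 0, sigma), nrow = n)
      rownames(edges) <- sprintf("%s_sub%04d", names(group_sizes)[h], seq_len(n))
      pheno <- data.frame(subject_id = rownames(edges), group = group,
                          sex = sex, age = age, site = site,
                          stringsAsFactors = FALSE)
      list(edges = edges, pheno = pheno)
    })
  })
  names(halves) <- names(group_sizes)
  c(halves, list(truth = truth))
}

#' Simulate component time series from group-specific precision matrices
#'
#' Draws T x K multivariate-normal time series whose generating precision
#' matrix has unit diagonal and off-diagonal entries chosen so the implied
#' partial correlations equal the planted values (with unit diagonal,
#' partial correlation r_ij = -Theta_ij). Used to round-trip the ridge
#' partial-correlation estimator against its generating truth.
#'
#' @param n_subjects Number of subjects.
#' @param K Components; \code{T_len} timepoints each.
#' @param T_len Timepoints per subject.
#' @param partial Data.frame (\code{i}, \code{j}, \code{r}) of nonzero
#'   generating partial correlations (i > j); all others are 0.
#' @param seed Integer seed.
#' @return List with \code{ts} (named list of T x K matrices) and
#'   \code{theta} (the generating precision matrix).
#' @export
simulate_component_timeseries <- function(n_subjects, K = 19L, T_len = 200L,
                                          partial = NULL, seed = 1L) {
  theta <- diag(K)
  if (!is.null(partial) && nrow(partial)) {
    for (k in seq_len(nrow(partial))) {
      theta[partial$i[k], partial$j[k]] <- -partial$r[k]
      theta[partial$j[k], partial$i[k]] <- -partial$r[k]
    }
  }
  ev <- eigen(theta, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8) stop("planted partial correlations make the precision matrix non-PD")
  sigma <- solve(theta)
  L <- chol(sigma)
  with_seed(seed, {
    ts <- lapply(seq_len(n_subjects), function(s) {
      z <- matrix(stats::rnorm(T_len * K), nrow = T_len)
      m <- z %*% L
      colnames(m) <- sprintf("IC%02d", seq_len(K))
      m
    })
    names(ts) <- sprintf("sub%04d", seq_len(n_subjects))
    list(ts = ts, theta = theta)
  })
}

#' Simulate a multi-donor expression atlas with planted gene-map couplings
#'
#' Network maps are smooth random fields over an ordered set of shared
#' sample locations (low-order Fourier basis with random coefficients).
#' "Coupled" genes follow \code{beta * map + donor intercept + noise} in
#' every donor (with the planted sign); "null" genes are pure noise. A
#' fraction of samples is flagged non-cortical to exercise the cortex
#' restriction.
#'
#' @param networks Character vector of network ids (one map each).
#' @param n_genes Total genes in the atlas.
#' @param n_coupled Planted positively-coupled genes per network.
#' @param n_negative Planted negatively-coupled genes per network.
#' @param n_samples Shared sample locations per donor.
#' @param n_donors Donors (default 6).
#' @param beta Coupling strength (slope SNR; default 1).
#' @param frac_subcortical Fraction of samples flagged non-cortical
#'   (default 0.1).
#' @param seed Integer seed.
#' @return List with \code{atlas} (\code{expression} per donor +
#'   \code{samples} table), \code{maps} (named list of sample_id/value
#'   data.frames), and \code{truth} (gene, network, beta).
#' @export
simulate_expression_atlas <- function(networks = "IC17", n_genes = 1000L,
                                      n_coupled = 50L, n_negative = 0L,
                                      n_samples = 200L, n_donors = 6L,
                                      beta = 1, frac_subcortical = 0.1,
                                      seed = 1L) {
  genes <- sprintf("G%05d", seq_len(n_genes))
  sample_ids <- sprintf("s%04d", seq_len(n_samples))
  donors <- sprintf("donor%d", seq_len(n_donors))
  need <- length(networks) * (n_coupled + n_negative)
  if (need > n_genes) stop("more planted genes than genes in the atlas")
  seeds <- child_seeds(seed, 3)

  maps <- with_seed(seeds[1], {
    x <- seq_len(n_samples) / n_samples
    out <- lapply(networks, function(nw) {
      v <- rep(0, n_samples)
      for (k in 1:4) {
        v <- v + stats::rnorm(1) * sin(2 * pi * k * x) +
          stats::rnorm(1) * cos(2 * pi * k * x)
      }
      data.frame(sample_id = sample_ids, value = as.numeric(scale(v)),
                 stringsAsFactors = FALSE)
    })
    names(out) <- networks
    out
  })

  truth <- with_seed(seeds[2], {
    pool <- sample(genes, need)
    if (need) {
      split_idx <- rep(seq_along(networks), each = n_coupled + n_negative)
      data.frame(
        gene = pool,
        network = networks[split_idx],
        beta = rep(c(rep(beta, n_coupled), rep(-beta, n_negative)),
                   times = length(networks)),
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(gene = character(0), network = character(0), beta = numeric(0))
    }
  })

  samples <- do.call(rbind, lapply(donors, function(d) {
    data.frame(sample_id = sample_ids, donor = d,
               cortical = c(rep(TRUE, round(n_samples * (1 - frac_subcortical))),
                            rep(FALSE, n_samples - round(n_samples * (1 - frac_subcortical)))),
               stringsAsFactors = FALSE)
  }))

  expression <- with_seed(seeds[3], {
    out <- lapply(donors, function(d) {
      e <- matrix(stats::rnorm(n_genes * n_samples), nrow = n_genes,
                  dimnames = list(genes, sample_ids))
      e <- e + stats::rnorm(n_genes, 0, 0.5)  # gene-by-donor intercepts
      for (k in seq_len(nrow(truth))) {
        e[truth$gene[k], ] <- e[truth$gene[k], ] +
          truth$beta[k] * maps[[truth$network[k]]]$value
      }
      e
    })
    names(out) <- donors
    out
  })

  list(atlas = list(expression = expression, samples = samples),
       maps = maps, truth = truth)
}

#' Simulate annotation gene lists with a planted enrichment odds multiplier
#'
#' Samples an annotation list from a gene universe where members of a
#' designated network set have their sampling weight multiplied by
#' \code{odds_multiplier} (biased urn sampling without replacement), so the
#' expected enrichment odds against the network set is controlled.
#'
#' @param network_set Character vector of network-set genes.
#' @param background_n Universe size; the universe is the network set plus
#'   filler symbols up to \code{background_n}.
#' @param list_size Annotation list size.
#' @param odds_multiplier Planted weight multiplier (1 = no enrichment).
#' @param seed Integer seed.
#' @return List with \code{annotation} (character vector), \code{universe},
#'   and \code{truth} (the multiplier).
#' @export
simulate_gene_lists <- function(network_set, background_n = 20787,
                                list_size = 100L, odds_multiplier = 1,
                                seed = 1L) {
  network_set <- unique(toupper(network_set))
  n_fill <- background_n - length(network_set)
  if (n_fill < 0) stop("network set larger than background")
  universe <- c(network_set, sprintf("BG%05d", seq_len(n_fill)))
  w <- c(rep(odds_multiplier, length(network_set)), rep(1, n_fill))
  annotation <- with_seed(seed, sample(universe, list_size, prob = w))
  list(annotation = annotation, universe = universe,
       truth = list(odds_multiplier = odds_multiplier))
}
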