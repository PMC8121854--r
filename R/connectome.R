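#' Ridge-regularized partial correlation matrix
#'
#' Estimates direct between-component connectivity from a T x K component
#' time-series matrix via the Tikhonov-regularized precision matrix, using
#' the netmats convention: columns are demeaned and variance-normalized, the
#' covariance C is rescaled by \code{1/sqrt(mean(diag(C)^2))}, \code{rho} is
#' added to the diagonal, and the partial correlation is read off the
#' inverse as \code{r_ij = -P_ij / sqrt(P_ii P_jj)}.
#'
#' @param ts Numeric matrix, T timepoints x K components, no missing values,
#'   non-constant columns, T > K.
#' @param rho Non-negative ridge penalty (the study convention is 1).
#' @return Symmetric K x K matrix with unit diagonal, entries in [-1, 1].
#' @export
ridge_partial_correlation <- function(ts, rho = 1) {
  ts <- as.matrix(ts)
  stopifnot(is.numeric(ts), !anyNA(ts), rho >= 0)
  if (nrow(ts) <= ncol(ts)) stop("need more timepoints than components")
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) stop("constant component time series: ",
                          paste(which(sds == 0), collapse = ", "))
  x <- scale(ts)
  C <- stats::cov(x)
  C <- C / sqrt(mean(diag(C)^2))
  P <- tryCatch(solve(C + rho * diag(ncol(C))), error = function(e) {
    stop("precision matrix is singular; set rho > 0 to regularize (",
         conditionMessage(e), ")")
  })
  d <- sqrt(diag(P))
  r <- -P / tcrossprod(d)
  diag(r) <- 1
  dimnames(r) <- list(colnames(ts), colnames(ts))
  (r + t(r)) / 2
}

#' Fisher r-to-z transformation
#'
#' @param r Correlations with \code{|r| < 1}.
#' @return \code{atanh(r)}.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) stop("|r| must be < 1 for Fisher's z")
  atanh(r)
}

#' Inverse Fisher transformation
#' @param z Fisher z values.
#' @return \code{tanh(z)}.
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Component-pair names for the lower-triangle edge ordering
#'
#' Components are reported 1-based as IC01..IC19; edges are lower-triangle
#' pairs (i > j) in row-major order, matching \code{\link{vectorize_edges}}.
#'
#' @param K Number of components.
#' @return Character vector of length \code{K(K-1)/2}, e.g. "IC02-IC01".
#' @export
edge_names <- function(K) {
  idx <- which(lower.tri(matrix(0, K, K)), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  sprintf("IC%02d-IC%02d", idx[, "row"], idx[, "col"])
}

#' Extract the lower triangle of a connectivity matrix as an edge vector
#'
#' @param m Square K x K matrix.
#' @return Named numeric vector of the \code{K(K-1)/2} lower-triangle
#'   entries (i > j), row-major, named as in \code{\link{edge_names}}.
#' @export
vectorize_edges <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == ncol(m))
  K <- nrow(m)
  idx <- which(lower.tri(m), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  stats::setNames(m[idx], edge_names(K))
}

#' Per-subject Fisher-z edge vectors from component time series
#'
#' @param ts_list Named list of T x K time-series matrices, one per subject.
#' @param rho Ridge penalty passed to \code{\link{ridge_partial_correlation}}.
#' @return Subjects x edges matrix of Fisher-z partial correlations.
#' @export
edge_matrix <- function(ts_list, rho = 1) {
  rows <- lapply(ts_list, function(ts) {
    fisher_z(pmin(pmax(vectorize_edges(ridge_partial_correlation(ts, rho)),
                       -1 + 1e-12), 1 - 1e-12))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(ts_list)
  out
}

#' Pooled-SD Cohen's d
#'
#' @param a,b Numeric vectors for the two groups.
#' @return \code{(mean(a) - mean(b)) / pooled SD}.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 2, nb >= 2)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2))
  (mean(a) - mean(b)) / sp
}

#' Edge-wise group model with site random intercepts
#'
#' Fits connectivity ~ group + sex + age with a random intercept per site
#' and returns the group-contrast estimate, t and two-sided p. With fewer
#' than three sites, or if the mixed fit fails, the model falls back to
#' fixed site dummies (plain least squares); the fallback is recorded. With
#' a single site and no covariates the model reduces to the two-sample
#' pooled-variance t-test. p-values use the t distribution with residual
#' degrees of freedom (n minus the fixed-effect rank).
#'
#' @param values Numeric vector of edge values (one per subject).
#' @param group Factor with the contrast's reference level LAST, i.e. the
#'   reported contrast is level 2 minus level 1 of \code{factor(group)}
#'   as coded by treatment contrasts; pass a two-level factor.
#' @param sex,age Optional covariate vectors (NULL to omit).
#' @param site Optional site vector for random intercepts (NULL = one site).
#' @return List with \code{estimate}, \code{t}, \code{p}, \code{df},
#'   \code{n}, \code{model} ("lme", "fixed-site" or "lm").
#' @export
fit_edge_model <- function(values, group, sex = NULL, age = NULL, site = NULL) {
  group <- factor(group)
  if (nlevels(group) != 2) stop("group must have exactly 2 levels")
  dat <- data.frame(y = values, group = group)
  terms <- "group"
  if (!is.null(sex)) { dat$sex <- factor(sex); if (nlevels(dat$sex) > 1) terms <- c(terms, "sex") }
  if (!is.null(age)) { dat$age <- as.numeric(age); terms <- c(terms, "age") }
  fixed <- stats::reformulate(terms, response = "y")
  n_sites <- if (is.null(site)) 1L else length(unique(site))

  X <- stats::model.matrix(fixed, dat)
  if (qr(X)$rank < ncol(X)) {
    aliased <- colnames(X)[-seq_len(qr(X)$rank)]
    stop("rank-deficient design; aliased columns: ", paste(aliased, collapse = ", "))
  }

  fit_fixed_site <- function() {
    if (n_sites > 1) {
      dat$site <- factor(site)
      fml <- stats::update(fixed, . ~ . + site)
    } else fml <- fixed
    m <- stats::lm(fml, dat)
    co <- summary(m)$coefficients
    k <- grep("^group", rownames(co))[1]
    list(estimate = co[k, 1], t = co[k, 3],
         df = m$df.residual,
         p = 2 * stats::pt(-abs(co[k, 3]), m$df.residual),
         model = if (n_sites > 1) "fixed-site" else "lm")
  }

  res <- if (n_sites >= 3) {
    dat$site <- factor(site)
    tryCatch({
      m <- nlme::lme(fixed, random = ~ 1 | site, data = dat, method = "REML")
      co <- summary(m)$tTable
      k <- grep("^group", rownames(co))[1]
      df <- length(values) - qr(X)$rank
      list(estimate = co[k, "Value"], t = co[k, "t-value"], df = df,
           p = 2 * stats::pt(-abs(co[k, "t-value"]), df), model = "lme")
    }, error = function(e) fit_fixed_site())
  } else fit_fixed_site()

  c(res[c("estimate", "t", "p", "df")], list(n = length(values), model = res$model))
}

#' Edge-wise dimensional model with a continuous predictor
#'
#' Same covariate and site structure as \code{\link{fit_edge_model}} but the
#' predictor of interest is continuous (e.g. SC severity, RRB severity, or
#' the z-normalized SC-RRB difference); the reported statistics are for its
#' slope.
#'
#' @param values Edge values.
#' @param predictor Continuous predictor vector.
#' @param sex,age,site As in \code{\link{fit_edge_model}}.
#' @return List with \code{estimate}, \code{t}, \code{p}, \code{df},
#'   \code{n}, \code{n_eff} (n minus fixed-effect rank), \code{model}.
#' @export
dimensional_edge_model <- function(values, predictor, sex = NULL, age = NULL,
                                   site = NULL) {
  dat <- data.frame(y = values, x = as.numeric(predictor))
  terms <- "x"
  if (!is.null(sex)) { dat$sex <- factor(sex); if (nlevels(dat$sex) > 1) terms <- c(terms, "sex") }
  if (!is.null(age)) { dat$age <- as.numeric(age); terms <- c(terms, "age") }
  fixed <- stats::reformulate(terms, response = "y")
  n_sites <- if (is.null(site)) 1L else length(unique(site))
  X <- stats::model.matrix(fixed, dat)
  rank <- qr(X)$rank

  res <- if (n_sites >= 3) {
    dat$site <- factor(site)
    tryCatch({
      m <- nlme::lme(fixed, random = ~ 1 | site, data = dat, method = "REML")
      co <- summary(m)$tTable
      df <- nrow(dat) - rank
      list(estimate = co["x", "Value"], t = co["x", "t-value"], df = df,
           p = 2 * stats::pt(-abs(co["x", "t-value"]), df), model = "lme")
    }, error = function(e) NULL)
  } else NULL
  if (is.null(res)) {
    if (n_sites > 1) { dat$site <- factor(site); fixed <- stats::update(fixed, . ~ . + site) }
    m <- stats::lm(fixed, dat)
    co <- summary(m)$coefficients
    res <- list(estimate = co["x", 1], t = co["x", 3], df = m$df.residual,
                p = 2 * stats::pt(-abs(co["x", 3]), m$df.residual),
                model = if (n_sites > 1) "fixed-site" else "lm")
  }
  c(res[c("estimate", "t", "p", "df")],
    list(n = nrow(dat), n_eff = nrow(dat) - rank, model = res$model))
}

#' Edge-wise Discovery/Replication analysis for one contrast
#'
#' Fits the group model on every edge in both halves, computes Cohen's d per
#' half and the replication Bayes factor from the two t-statistics, and
#' flags edges meeting the replication rule: Discovery p < 0.05, repBF > 10,
#' and same-sign effects in the two halves.
#'
#' @param disc,repl Lists with elements \code{edges} (subjects x edges
#'   matrix), \code{group} (two-level factor), and optional \code{sex},
#'   \code{age}, \code{site}.
#' @param repbf_threshold Replication Bayes factor criterion (default 10).
#' @param alpha Discovery significance criterion (default 0.05).
#' @return Data.frame, one row per edge: statistics per half, \code{d_disc},
#'   \code{d_repl}, \code{repbf}, \code{replicable}.
#' @export
edge_replication_analysis <- function(disc, repl, repbf_threshold = 10,
                                      alpha = 0.05) {
  stopifnot(ncol(disc$edges) == ncol(repl$edges))
  edges <- colnames(disc$edges) %||% as.character(seq_len(ncol(disc$edges)))
  half_stats <- function(h) {
    g <- factor(h$group)
    lev <- levels(g)
    t(vapply(seq_len(ncol(h$edges)), function(j) {
      fit <- fit_edge_model(h$edges[, j], g, sex = h$sex, age = h$age,
                            site = h$site)
      d <- cohens_d(h$edges[g == lev[2], j], h$edges[g == lev[1], j])
      c(estimate = fit$estimate, t = fit$t, p = fit$p, d = d)
    }, numeric(4)))
  }
  sd_ <- half_stats(disc)
  sr_ <- half_stats(repl)
  n_eff <- function(h) {
    tab <- table(h$group)
    as.numeric(tab[1]) * as.numeric(tab[2]) / sum(tab)
  }
  df_half <- function(h) sum(table(h$group)) - 2
  repbf <- vapply(seq_along(edges), function(j) {
    replication_bayes_factor(sd_[j, "t"], n_eff(disc), sr_[j, "t"], n_eff(repl),
                             df_orig = df_half(disc), df_rep = df_half(repl))
  }, numeric(1))
  out <- data.frame(
    edge = edges,
    estimate_disc = sd_[, "estimate"], t_disc = sd_[, "t"], p_disc = sd_[, "p"],
    d_disc = sd_[, "d"],
    estimate_repl = sr_[, "estimate"], t_repl = sr_[, "t"], p_repl = sr_[, "p"],
    d_repl = sr_[, "d"],
    repbf = repbf,
    stringsAsFactors = FALSE
  )
  out$replicable <- out$p_disc < alpha & out$repbf > repbf_threshold &
    sign(out$t_disc) == sign(out$t_repl) & out$t_disc != 0
  rownames(out) <- NULL
  out
}

#' Consensus edges across subtype-threshold analyses
#'
#' An edge is a consensus edge when it meets the replication rule
#' (Discovery p < 0.05, repBF above the criterion, same-sign effects) at
#' EVERY subtype-defining z-threshold in the sweep, i.e. the consensus set
#' is the intersection of the per-threshold replicable sets.
#'
#' @param results_by_threshold Named list of tables from
#'   \code{\link{edge_replication_analysis}}, one per z-threshold.
#' @return Data.frame of consensus edges with per-threshold evidence
#'   (\code{replicable_<threshold>} logical columns).
#' @export
consensus_edges <- function(results_by_threshold) {
  stopifnot(length(results_by_threshold) >= 1)
  edges <- results_by_threshold[[1]]$edge
  flags <- vapply(results_by_threshold, function(r) {
    r$replicable[match(edges, r$edge)]
  }, logical(length(edges)))
  flags <- matrix(flags, nrow = length(edges),
                  dimnames = list(NULL, names(results_by_threshold)))
  flags[is.na(flags)] <- FALSE
  consensus <- rowSums(!flags) == 0
  out <- data.frame(edge = edges, consensus = consensus,
                    stringsAsFactors = FALSE)
  for (nm in colnames(flags)) out[[paste0("replicable_", nm)]] <- flags[, nm]
  out[out$consensus, , drop = FALSE]
}
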