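#' Decode a network map against a multi-donor expression atlas
#'
#' For each gene and each donor, the gene's expression profile across
#' cortical samples is standardized and regressed on the standardized
#' network map values at the same samples; the slope (equal to the Pearson
#' correlation after standardization) measures spatial similarity between
#' gene expression and the network. The six donor slopes are then combined
#' with a one-sample t-test against zero, p-values are BH-FDR corrected
#' across genes, and a gene is retained when q < 0.05 with a positive
#' t-statistic (consistently positive coupling across donors).
#'
#' @param map Data.frame with columns \code{sample_id}, \code{value}
#'   (unthresholded map statistic per sample location).
#' @param atlas List with \code{expression} (named list, one genes x samples
#'   matrix per donor with sample ids as column names) and \code{samples}
#'   (data.frame with \code{sample_id}, \code{donor}, \code{cortical}).
#' @param q_threshold FDR retention threshold (default 0.05).
#' @return Data.frame, one row per gene: per-donor slopes
#'   (\code{slope_<donor>}), \code{t}, \code{p}, \code{q}, \code{retained}.
#'   Genes with fewer than 2 donors with estimable slopes are dropped and
#'   counted in attribute \code{"n_dropped"}.
#' @export
decode_network <- function(map, atlas, q_threshold = 0.05) {
  stopifnot(all(c("sample_id", "value") %in% names(map)))
  donors <- names(atlas$expression)
  genes <- rownames(atlas$expression[[1]])
  slopes <- matrix(NA_real_, nrow = length(genes), ncol = length(donors),
                   dimnames = list(genes, donors))
  for (d in donors) {
    expr <- atlas$expression[[d]]
    info <- atlas$samples[atlas$samples$donor == d, , drop = FALSE]
    ctx <- info$sample_id[info$cortical]
    ctx <- intersect(intersect(ctx, colnames(expr)), map$sample_id)
    if (length(ctx) < 3) next
    mv <- map$value[match(ctx, map$sample_id)]
    if (stats::sd(mv) == 0) next
    mz <- (mv - mean(mv)) / stats::sd(mv)
    e <- expr[, ctx, drop = FALSE]
    es <- apply(e, 1, stats::sd)
    ez <- (e - rowMeans(e)) / es
    # slope of z-expression on z-map = Pearson correlation
    slopes[, d] <- as.numeric(ez %*% mz) / (length(ctx) - 1)
    slopes[es == 0, d] <- NA_real_
  }
  n_ok <- rowSums(!is.na(slopes))
  keep <- n_ok >= 2
  n_dropped <- sum(!keep)
  slopes <- slopes[keep, , drop = FALSE]

  tt <- apply(slopes, 1, function(s) {
    s <- s[!is.na(s)]
    m <- mean(s); se <- stats::sd(s) / sqrt(length(s))
    if (se == 0) {
      t <- sign(m) * Inf
      p <- if (m == 0) 1 else 0
    } else {
      t <- m / se
      p <- 2 * stats::pt(-abs(t), df = length(s) - 1)
    }
    c(t = t, p = p)
  })
  out <- data.frame(gene = rownames(slopes), stringsAsFactors = FALSE)
  for (d in donors) out[[paste0("slope_", d)]] <- slopes[, d]
  out$t <- tt["t", ]
  out$p <- tt["p", ]
  out$q <- fdr_bh(out$p)
  out$retained <- out$q < q_threshold & out$t > 0
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Genes retained by a decoded-gene table
#'
#' @param decoded Table from \code{\link{decode_network}}.
#' @return Character vector of retained gene ids.
#' @export
retained_genes <- function(decoded) decoded$gene[decoded$retained]

#' Subtype-specific gene sets by set algebra over network gene lists
#'
#' Builds the gene set specific to the networks affected in one subtype:
#' the union of the target networks' retained genes minus the union of the
#' exclusion networks' retained genes. E.g. the SC>RRB set is genes unique
#' to the perisylvian network (IC17) excluding the networks implicated in
#' the other subtype, and the SC=RRB set is the union over IC03/IC07/IC13
#' excluding IC12 and IC17.
#'
#' @param gene_lists Named list of character vectors (retained genes per
#'   network, e.g. \code{list(IC17 = ..., IC12 = ...)}).
#' @param targets Names of the networks defining the subtype.
#' @param exclude Names of networks whose genes are removed.
#' @return Data.frame with \code{gene} and logical membership columns, one
#'   per input network, for the genes in the subtype-specific set.
#' @export
subtype_specific_genes <- function(gene_lists, targets, exclude = character(0)) {
  stopifnot(all(targets %in% names(gene_lists)),
            all(exclude %in% names(gene_lists)))
  target_union <- unique(unlist(gene_lists[targets], use.names = FALSE))
  excl_union <- unique(unlist(gene_lists[exclude], use.names = FALSE))
  genes <- sort(setdiff(target_union, excl_union))
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (nm in names(gene_lists)) out[[nm]] <- genes %in% gene_lists[[nm]]
  out
}
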