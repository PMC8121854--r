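#' Read a one-symbol-per-line gene list
#'
#' Symbols are upper-cased and de-duplicated; matching downstream is exact
#' on the upper-cased symbol (no alias resolution).
#'
#' @param path Path to a plain-text file, one gene symbol per line.
#' @return Character vector of unique upper-case symbols.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- toupper(trimws(x))
  unique(x[nzchar(x)])
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT file (set name, description, then members,
#'   tab-separated).
#' @return Named list of character vectors of unique upper-case symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(strsplit(lines, "\t"), function(f) {
    unique(toupper(trimws(f[-(1:2)])))
  })
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, character(1), 1)
  sets
}

#' Hypergeometric over-representation test between two gene lists
#'
#' Tests whether the overlap between a network gene set and an annotation
#' list is larger than expected when both are drawn from a fixed background
#' universe of \code{background_n} genes. The p-value is the upper
#' hypergeometric tail P(X >= a); the odds ratio comes from the 2x2 overlap
#' table with a declared zero-cell convention: OR = 0 when the overlap is
#' empty, Inf when a margin cell is empty with a > 0, optionally the
#' Haldane-Anscombe +0.5 correction.
#'
#' @param set_a Character vector, the network gene set.
#' @param set_b Character vector, the annotation list.
#' @param background_n Background universe size (the decoding service
#'   considers 20,787 genes).
#' @param haldane Apply the +0.5 zero-cell correction to the OR
#'   (default FALSE).
#' @return One-row data.frame: counts \code{a} (overlap), \code{b}
#'   (network only), \code{c} (annotation only), \code{d} (neither),
#'   \code{odds_ratio}, \code{p}.
#' @export
hypergeometric_enrichment <- function(set_a, set_b, background_n = 20787,
                                      haldane = FALSE) {
  set_a <- unique(toupper(set_a)); set_b <- unique(toupper(set_b))
  if (!length(set_a) || !length(set_b)) stop("empty gene list")
  if (length(set_a) > background_n || length(set_b) > background_n) {
    stop("gene list larger than the background universe")
  }
  a <- length(intersect(set_a, set_b))
  b <- length(set_a) - a
  cc <- length(set_b) - a
  d <- background_n - a - b - cc
  if (d < 0) stop("background_n smaller than the union of the lists")
  p <- stats::phyper(a - 1, length(set_b), background_n - length(set_b),
                     length(set_a), lower.tail = FALSE)
  odds_ratio <- if (haldane) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  } else if (a == 0) {
    0
  } else if (b == 0 || cc == 0) {
    Inf
  } else {
    (a * d) / (b * cc)
  }
  data.frame(a = a, b = b, c = cc, d = d,
             odds_ratio = odds_ratio, p = p)
}

#' Enrichment grid over network sets and annotation lists
#'
#' Runs \code{\link{hypergeometric_enrichment}} for every (network set,
#' annotation) pair and applies a single BH-FDR family spanning ALL tests in
#' the grid; only tests with q < 0.05 are flagged significant.
#'
#' @param network_sets Named list of character vectors.
#' @param annotation_sets Named list of character vectors.
#' @param background_n Background universe size.
#' @param q_threshold Significance threshold on the FDR q (default 0.05).
#' @param haldane Passed through to the OR computation.
#' @return Long-format data.frame: \code{network}, \code{annotation},
#'   counts, \code{odds_ratio}, \code{p}, \code{q}, \code{significant}.
#' @export
enrichment_grid <- function(network_sets, annotation_sets,
                            background_n = 20787, q_threshold = 0.05,
                            haldane = FALSE) {
  combos <- expand.grid(network = names(network_sets),
                        annotation = names(annotation_sets),
                        stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    res <- hypergeometric_enrichment(network_sets[[combos$network[i]]],
                                     annotation_sets[[combos$annotation[i]]],
                                     background_n, haldane = haldane)
    cbind(combos[i, , drop = FALSE], res)
  })
  out <- do.call(rbind, rows)
  out$q <- fdr_bh(out$p)
  out$significant <- out$q < q_threshold
  rownames(out) <- NULL
  out
}
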