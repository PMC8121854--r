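#' Derive deterministic child seeds from one master seed
#'
#' All stochastic stages of the pipeline draw their own seed from a single
#' master seed through this function, so that any stage can be regenerated
#' independently of the others while the whole run stays reproducible.
#'
#' @param seed Integer master seed.
#' @param n Number of child seeds to derive.
#' @return Integer vector of length \code{n}, each in \code{[1, 2^31 - 2]}.
#' @export
child_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Run an expression under a local RNG seed
#'
#' Evaluates \code{expr} with the RNG seeded at \code{seed}, restoring the
#' caller's RNG state afterwards.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of \code{expr}.
#' @export
with_seed <- function(seed, expr) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Thin wrapper over \code{\link[stats]{p.adjust}} with \code{method = "BH"},
#' exposed as the single FDR entry point used by the decoding and enrichment
#' stages.
#'
#' @param p Numeric vector of p-values.
#' @return Numeric vector of BH-adjusted q-values, same order as \code{p}.
#' @export
fdr_bh <- function(p) {
  stopifnot(is.numeric(p), all(is.na(p) | (p >= 0 & p <= 1)))
  stats::p.adjust(p, method = "BH")
}
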