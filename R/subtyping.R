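#' Reference norms for SC-RRB difference scores
#'
#' Constructs the mean/SD reference used to z-normalize SC-RRB difference
#' scores. Norms estimated on one cohort can be applied to another for
#' out-of-sample subtype prediction.
#'
#' @param mean Mean of the difference score.
#' @param sd Standard deviation (must be > 0).
#' @param n Sample size the norms were estimated on (NA for external norms).
#' @return An object of class \code{"scrrb_norms"}.
#' @export
norm_params <- function(mean, sd, n = NA_integer_) {
  stopifnot(is.finite(mean), is.finite(sd))
  if (sd <= 0) stop("norms require sd > 0")
  structure(list(mean = mean, sd = sd, n = n), class = "scrrb_norms")
}

#' @export
print.scrrb_norms <- function(x, ...) {
  cat(sprintf("SC-RRB difference-score norms: mean = %.8f, sd = %.8f (n = %s)\n",
              x$mean, x$sd, ifelse(is.na(x$n), "external", x$n)))
  invisible(x)
}

#' Combined reference norms for applying the subtyping model to new cohorts
#'
#' The difference-score mean and standard deviation estimated on the pooled
#' NDAR reference sample (n = 1779), shipped as named constants so the
#' subtyping model can be applied to any new ADI-R cohort without refitting.
#'
#' @return \code{scrrb_norms} with mean 0.01045243 and SD 0.19482749.
#' @export
ndar_combined_norms <- function() {
  norm_params(mean = 0.01045243, sd = 0.19482749, n = 1779L)
}

#' Estimate difference-score norms from a cohort
#'
#' @param diffs Numeric vector of SC-RRB difference scores.
#' @return \code{scrrb_norms} with the sample mean and sample SD
#'   (\code{n - 1} denominator).
#' @export
compute_norms <- function(diffs) {
  diffs <- diffs[!is.na(diffs)]
  if (length(diffs) < 2) stop("need at least 2 difference scores")
  s <- stats::sd(diffs)
  if (!is.finite(s) || s == 0) {
    stop("degenerate norms: difference scores are constant")
  }
  norm_params(mean = mean(diffs), sd = s, n = length(diffs))
}

.subtype_levels <- c("RRB>SC", "SC=RRB", "SC>RRB")

#' Assign SC-RRB balance subtype labels
#'
#' z-normalizes the SC-RRB difference score against the supplied norms and
#' thresholds it: z strictly above the cutoff is SC>RRB, z strictly below
#' the negative cutoff is RRB>SC, everything in between (boundary included)
#' is SC=RRB.
#'
#' @param scores Data.frame with a \code{diff} column (or \code{sc_pct} and
#'   \code{rrb_pct} from which \code{diff} is computed) and, if present,
#'   \code{subject_id}.
#' @param norms \code{scrrb_norms}; use \code{\link{compute_norms}} on the
#'   cohort itself for in-sample labels or foreign norms for prediction.
#' @param threshold Positive z cutoff (default 1).
#' @return Data.frame with \code{subject_id}, \code{diff}, \code{z},
#'   \code{threshold} and factor \code{label} in
#'   \code{RRB>SC / SC=RRB / SC>RRB}.
#' @export
assign_subtypes <- function(scores, norms, threshold = 1) {
  stopifnot(inherits(norms, "scrrb_norms"), threshold > 0)
  if (!"diff" %in% names(scores)) {
    if (!all(c("sc_pct", "rrb_pct") %in% names(scores))) {
      stop("scores must contain 'diff' or both 'sc_pct' and 'rrb_pct'")
    }
    scores$diff <- scores$sc_pct - scores$rrb_pct
  }
  z <- (scores$diff - norms$mean) / norms$sd
  label <- ifelse(z > threshold, "SC>RRB", ifelse(z < -threshold, "RRB>SC", "SC=RRB"))
  data.frame(
    subject_id = if ("subject_id" %in% names(scores)) as.character(scores$subject_id)
                 else as.character(seq_along(z)),
    diff = scores$diff,
    z = z,
    threshold = threshold,
    label = factor(label, levels = .subtype_levels),
    stringsAsFactors = FALSE
  )
}

#' Predict subtype labels out-of-sample with foreign norms
#'
#' Identical mechanics to \code{\link{assign_subtypes}} but using norms
#' estimated on a reference cohort (e.g. a Discovery set, or the shipped
#' combined reference norms) to label a new cohort; the result is tagged as
#' predicted.
#'
#' @inheritParams assign_subtypes
#' @param reference_norms \code{scrrb_norms} from the reference cohort.
#' @return As \code{\link{assign_subtypes}}, with attribute
#'   \code{"predicted"} set to \code{TRUE}.
#' @export
predict_out_of_sample <- function(scores, reference_norms, threshold = 1) {
  out <- assign_subtypes(scores, reference_norms, threshold)
  attr(out, "predicted") <- TRUE
  out
}

#' Agreement between predicted and actual subtype labels
#'
#' @param predicted,actual Label vectors or assignment tables from
#'   \code{\link{assign_subtypes}}.
#' @return List with \code{confusion} (rows = predicted, columns = actual),
#'   \code{accuracy} (trace / total) and \code{per_class} (recall per actual
#'   class).
#' @export
subtype_accuracy <- function(predicted, actual) {
  p <- if (is.data.frame(predicted)) predicted$label else predicted
  a <- if (is.data.frame(actual)) actual$label else actual
  p <- factor(as.character(p), levels = .subtype_levels)
  a <- factor(as.character(a), levels = .subtype_levels)
  stopifnot(length(p) == length(a), length(p) > 0)
  confusion <- table(predicted = p, actual = a)
  per_class <- diag(confusion) / colSums(confusion)
  list(confusion = confusion,
       accuracy = sum(diag(confusion)) / length(p),
       per_class = per_class)
}

#' Subtype labels across a grid of z thresholds
#'
#' The subtype boundary is a free parameter, so labels are produced across
#' a sweep of z cutoffs (default 0.5 to 1.0 in steps of 0.1) and downstream
#' analyses report effects that are robust to the cutoff.
#'
#' @inheritParams assign_subtypes
#' @param thresholds Numeric vector of positive cutoffs.
#' @return Named list of assignment tables, one per threshold.
#' @export
threshold_sweep <- function(scores, norms, thresholds = seq(0.5, 1.0, by = 0.1)) {
  stopifnot(all(thresholds > 0))
  out <- lapply(thresholds, function(th) assign_subtypes(scores, norms, th))
  names(out) <- formatC(thresholds, format = "f", digits = 1)
  out
}

#' Split a cohort into balanced Discovery and Replication halves
#'
#' Randomly halves the cohort within each stratum (by default site x sex),
#' so the halves are balanced on the stratifying variables; singleton strata
#' are assigned by a seeded coin flip and recorded. Optionally age-matches a
#' comparison group to a target group within each half by greedy nearest
#' neighbour matching without replacement.
#'
#' @param pheno Data.frame with \code{subject_id} plus the stratum columns.
#' @param strata Character vector of column names to stratify on.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @param age_match Optional list \code{list(group_col=, target=, comparison=,
#'   age_col=)}; when supplied, comparison-group members in each half are
#'   pruned to the nearest-age matches of the target group in that half.
#' @return List with integer row-index vectors \code{discovery} and
#'   \code{replication} (disjoint) and a data.frame \code{log} of singleton
#'   strata.
#' @export
split_discovery_replication <- function(pheno, strata = c("site", "sex"),
                                        seed = 1L, age_match = NULL) {
  stopifnot(all(strata %in% names(pheno)))
  with_seed(seed, {
    key <- interaction(pheno[strata], drop = TRUE)
    disc <- integer(0); repl <- integer(0)
    log <- data.frame(stratum = character(0), note = character(0),
                      stringsAsFactors = FALSE)
    for (s in levels(key)) {
      idx <- which(key == s)
      idx <- idx[sample.int(length(idx))]
      if (length(idx) == 1) {
        to_disc <- stats::runif(1) < 0.5
        if (to_disc) disc <- c(disc, idx) else repl <- c(repl, idx)
        log <- rbind(log, data.frame(stratum = s, note = "singleton coin flip",
                                     stringsAsFactors = FALSE))
      } else {
        half <- floor(length(idx) / 2)
        extra <- length(idx) - 2 * half
        disc <- c(disc, idx[seq_len(half + (extra && stats::runif(1) < 0.5))])
        repl <- c(repl, setdiff(idx, disc))
      }
    }
    disc <- sort(disc); repl <- sort(repl)
    if (!is.null(age_match)) {
      disc <- .age_match_half(pheno, disc, age_match)
      repl <- .age_match_half(pheno, repl, age_match)
    }
    list(discovery = disc, replication = repl, log = log)
  })
}

# greedy nearest-neighbour age matching without replacement: each target
# subject claims the closest unclaimed comparison subject; unmatched
# comparison subjects are dropped from the half
.age_match_half <- function(pheno, idx, am) {
  g <- pheno[[am$group_col]][idx]
  age <- pheno[[am$age_col]][idx]
  tgt <- which(g %in% am$target)
  cmp <- which(g == am$comparison)
  other <- setdiff(seq_along(idx), c(tgt, cmp))
  if (!length(tgt) || !length(cmp)) return(idx)
  available <- cmp
  kept <- integer(0)
  for (t in tgt[order(age[tgt])]) {
    if (!length(available)) break
    j <- available[which.min(abs(age[available] - age[t]))]
    kept <- c(kept, j)
    available <- setdiff(available, j)
  }
  sort(idx[sort(c(tgt, other, kept))])
}
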