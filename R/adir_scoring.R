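#' Read an ADI-R item-to-subscale mapping
#'
#' The mapping assigns every ADI-R item to one DSM-5 subscale: A1--A3 for the
#' social-communication (SC) domain and B1--B4 for the restricted repetitive
#' behavior (RRB) domain. The mapping is data, not code: the instrument's
#' item sets depend on interview version and age band, so the mapping ships
#' as an editable CSV with columns \code{item_id}, \code{domain},
#' \code{subscale}, \code{applicable}.
#'
#' @param path Path to a mapping CSV. Defaults to the schematic mapping
#'   bundled with the package (see \code{\link{default_item_mapping}}).
#' @return A data.frame with columns \code{item_id}, \code{domain},
#'   \code{subscale}, \code{applicable}.
#' @export
read_item_mapping <- function(path) {
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("item_id", "domain", "subscale")
  missing_cols <- setdiff(required, names(map))
  if (length(missing_cols)) {
    stop("item mapping is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"applicable" %in% names(map)) map$applicable <- "all"
  if (anyDuplicated(map$item_id)) {
    stop("item mapping assigns an item to more than one subscale: ",
         paste(unique(map$item_id[duplicated(map$item_id)]), collapse = ", "))
  }
  sc <- map$subscale[map$domain == "SC"]
  rrb <- map$subscale[map$domain == "RRB"]
  if (!all(sc %in% c("A1", "A2", "A3")) || !all(rrb %in% c("B1", "B2", "B3", "B4"))) {
    stop("SC subscales must be A1-A3 and RRB subscales B1-B4")
  }
  map
}

#' Schematic default ADI-R item mapping
#'
#' A schematic DSM-5 grouping of ADI-R-style items into A1--A3 (SC) and
#' B1--B4 (RRB) subscales, bundled with the package. It carries the correct
#' structure (every item in exactly one subscale, realistic item counts per
#' subscale) but is NOT the instrument's age-dependent item table; analyses
#' of real ADI-R data must supply a mapping configured from the instrument.
#'
#' @return A mapping data.frame as from \code{\link{read_item_mapping}}.
#' @export
default_item_mapping <- function() {
  read_item_mapping(system.file("extdata", "adir_item_mapping.csv",
                                package = "scrrb", mustWork = TRUE))
}

.valid_codes <- c(0L, 1L, 2L, 3L, 6L, 7L, 8L, 9L)

#' Recode raw ADI-R item codes into a scoreable long table
#'
#' Raw ADI-R codes 0--3 indicate increasing symptom severity and are kept
#' unchanged -- in particular a code of 3 is NOT truncated to 2, preserving
#' the severity information in the 2-vs-3 distinction. Codes 6--9 are dummy
#' codes carrying no severity information and are marked unusable, as are
#' missing entries. Any other code is rejected at load.
#'
#' @param records Data.frame with a \code{subject_id} column and one column
#'   per item, values in \code{{0,1,2,3,6,7,8,9}} or \code{NA}.
#' @param mapping Item mapping (see \code{\link{read_item_mapping}}); must
#'   cover every item column present in \code{records}.
#' @return Long data.frame with columns \code{subject_id}, \code{item_id},
#'   \code{domain}, \code{subscale}, \code{score}, \code{usable}.
#' @export
recode_item_scores <- function(records, mapping) {
  if (!"subject_id" %in% names(records)) stop("records must have a subject_id column")
  item_cols <- setdiff(names(records), "subject_id")
  unknown <- setdiff(item_cols, mapping$item_id)
  if (length(unknown)) {
    stop("items not covered by the mapping: ", paste(unknown, collapse = ", "))
  }
  long <- data.frame(
    subject_id = rep(as.character(records$subject_id), times = length(item_cols)),
    item_id = rep(item_cols, each = nrow(records)),
    score = as.integer(unlist(records[item_cols], use.names = FALSE)),
    stringsAsFactors = FALSE
  )
  bad <- !is.na(long$score) & !(long$score %in% .valid_codes)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("invalid item code %d for subject '%s', item '%s'",
                 long$score[i], long$subject_id[i], long$item_id[i]))
  }
  idx <- match(long$item_id, mapping$item_id)
  long$domain <- mapping$domain[idx]
  long$subscale <- mapping$subscale[idx]
  long$usable <- !is.na(long$score) & long$score <= 3L
  long[c("subject_id", "item_id", "domain", "subscale", "score", "usable")]
}

#' Percentage severity for one subscale
#'
#' Severity as a fraction of the maximum attainable: \code{sum(scores) /
#' (3 * n)} over the usable (code 0--3) items. The denominator counts only
#' usable items, so subjects with different numbers of scoreable items are
#' placed on a comparable 0--1 scale.
#'
#' @param scores Integer vector of usable item scores (each in 0--3).
#' @return Fraction in \code{[0, 1]}, or \code{NA_real_} if no usable items.
#' @export
subscale_percentage <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (!length(scores)) return(NA_real_)
  stopifnot(all(scores >= 0 & scores <= 3))
  sum(scores) / (3 * length(scores))
}

#' Domain severity from subscale percentages
#'
#' The domain score is the arithmetic mean of its subscale percentages
#' (summed and scaled by the number of contributing subscales), keeping the
#' domain score in \code{[0, 1]}. Missing subscales are dropped from the
#' mean under the default "available-mean" policy.
#'
#' @param subscale_pcts Numeric vector of subscale fractions, \code{NA} for
#'   subscales with no usable items.
#' @return Fraction in \code{[0, 1]}, or \code{NA_real_} if every subscale
#'   is missing.
#' @export
domain_percentage <- function(subscale_pcts) {
  ok <- !is.na(subscale_pcts)
  if (!any(ok)) return(NA_real_)
  mean(subscale_pcts[ok])
}

#' Score an ADI-R cohort into SC and RRB percentage severities
#'
#' Runs the full item-to-domain chain: recode raw codes, compute per-subscale
#' percentage severities over usable items, and average subscales into the
#' SC (A1--A3) and RRB (B1--B4) domain scores. Subjects for whom a whole
#' domain has no usable item are dropped; their ids are recorded in the
#' \code{"dropped"} attribute of the result.
#'
#' @param records Wide item-code data.frame (see
#'   \code{\link{recode_item_scores}}).
#' @param mapping Item mapping; defaults to the bundled schematic mapping.
#' @param min_items Minimum usable items for a subscale to count (default 1).
#' @return Data.frame with one row per retained subject: \code{subject_id},
#'   one column per subscale (A1..B4), \code{sc_pct}, \code{rrb_pct},
#'   \code{diff} (= sc_pct - rrb_pct) and \code{n_scoreable}. Attribute
#'   \code{"dropped"} lists dropped subject ids with reasons.
#' @export
score_adir <- function(records, mapping = default_item_mapping(), min_items = 1L) {
  long <- recode_item_scores(records, mapping)
  subjects <- unique(long$subject_id)
  subscales <- sort(unique(mapping$subscale))
  usable <- long[long$usable, , drop = FALSE]

  pct <- matrix(NA_real_, nrow = length(subjects), ncol = length(subscales),
                dimnames = list(subjects, subscales))
  n_usable <- matrix(0L, nrow = length(subjects), ncol = length(subscales),
                     dimnames = list(subjects, subscales))
  for (ssc in subscales) {
    u <- usable[usable$subscale == ssc, , drop = FALSE]
    if (!nrow(u)) next
    sums <- tapply(u$score, u$subject_id, sum)
    cnts <- tapply(u$score, u$subject_id, length)
    n_usable[names(cnts), ssc] <- as.integer(cnts)
    keep <- cnts >= min_items
    pct[names(sums)[keep], ssc] <- sums[keep] / (3 * cnts[keep])
  }

  sc_cols <- intersect(c("A1", "A2", "A3"), subscales)
  rrb_cols <- intersect(c("B1", "B2", "B3", "B4"), subscales)
  sc_pct <- apply(pct[, sc_cols, drop = FALSE], 1, domain_percentage)
  rrb_pct <- apply(pct[, rrb_cols, drop = FALSE], 1, domain_percentage)

  out <- data.frame(subject_id = subjects, stringsAsFactors = FALSE)
  for (s in subscales) out[[s]] <- pct[, s]
  out$sc_pct <- sc_pct
  out$rrb_pct <- rrb_pct
  out$diff <- sc_pct - rrb_pct
  out$n_scoreable <- rowSums(n_usable)

  drop <- is.na(out$sc_pct) | is.na(out$rrb_pct)
  dropped <- data.frame(
    subject_id = out$subject_id[drop],
    reason = ifelse(is.na(out$sc_pct[drop]),
                    "no usable SC items", "no usable RRB items"),
    stringsAsFactors = FALSE
  )
  out <- out[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}
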