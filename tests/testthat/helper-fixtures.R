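# small hand-built fixtures shared across test files

# a 3-subscale / 6-item mapping small enough to reason about by hand
tiny_mapping <- function() {
  data.frame(
    item_id = c("s1", "s2", "s3", "s4", "r1", "r2"),
    domain = c("SC", "SC", "SC", "SC", "RRB", "RRB"),
    subscale = c("A1", "A1", "A2", "A2", "B1", "B2"),
    applicable = "all",
    stringsAsFactors = FALSE
  )
}

tiny_records <- function() {
  data.frame(
    subject_id = c("p1", "p2", "p3"),
    s1 = c(3L, 0L, 7L), s2 = c(3L, 0L, 8L),
    s3 = c(2L, 0L, 1L), s4 = c(1L, 0L, NA),
    r1 = c(0L, 0L, 2L), r2 = c(3L, 0L, 9L),
    stringsAsFactors = FALSE
  )
}

# brute-force DSM-5 percentage scoring used as the independent oracle
brute_force_scores <- function(records, mapping) {
  t(vapply(seq_len(nrow(records)), function(i) {
    pct <- sapply(unique(mapping$subscale), function(ssc) {
      items <- mapping$item_id[mapping$subscale == ssc]
      v <- unlist(records[i, items])
      v <- v[!is.na(v) & v <= 3]
      if (!length(v)) NA_real_ else sum(v) / (3 * length(v))
    })
    sc <- pct[unique(mapping$subscale[mapping$domain == "SC"])]
    rrb <- pct[unique(mapping$subscale[mapping$domain == "RRB"])]
    c(sc_pct = mean(sc[!is.na(sc)]), rrb_pct = mean(rrb[!is.na(rrb)]))
  }, numeric(2)))
}
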