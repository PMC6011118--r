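# shared fixtures: toy genomes, published-arm outcome tables, oracles

toy_genome <- function(bin_width = NULL) {
  genome_table(c("chr1", "chr18", "chr21"),
               c(1e6, 5e5, 4e5),
               c(0.42, 0.40, 0.41),
               bin_width = bin_width)
}

# assemble a calls/truth pair from per-class outcome vectors
outcome_cohort <- function(outcomes) {
  # outcomes: list of c(truth, called, n)
  rows <- do.call(rbind, lapply(outcomes, function(o) {
    n <- as.integer(o[[3]])
    data.frame(truth_label = rep(o[[1]], n), status = rep(o[[2]], n),
               stringsAsFactors = FALSE)
  }))
  rows$sample_id <- sprintf("s%03d", seq_len(nrow(rows)))
  list(calls = rows[, c("sample_id", "status")],
       truth = rows[, c("sample_id", "truth_label")])
}

# the two published validation arms (34 T21, 18 T18, 6 T13, 159 euploid),
# encoded from their reported per-class outcomes
tmap_arm <- function() {
  outcome_cohort(list(
    list("trisomy21", "trisomy21", 33),
    list("trisomy21", "trisomy18", 1),    # wrong-chromosome call
    list("trisomy18", "trisomy18", 16),
    list("trisomy18", "euploid", 1),      # false negative
    list("trisomy18", "trisomy21", 1),    # wrong-chromosome call
    list("trisomy13", "trisomy13", 6),
    list("euploid", "euploid", 148),
    list("euploid", "trisomy18", 11)))    # false positives
}

hpg_arm <- function() {
  outcome_cohort(list(
    list("trisomy21", "trisomy21", 34),
    list("trisomy18", "trisomy18", 18),
    list("trisomy13", "trisomy13", 6),
    list("euploid", "euploid", 154),
    list("euploid", "trisomy21", 2),
    list("euploid", "trisomy18", 2),
    list("euploid", "trisomy13", 1)))
}

# independent ROC oracle: evaluate Youden's J at every threshold
# candidate by direct counting and return the maximum
brute_force_max_j <- function(scores, labels) {
  u <- sort(unique(scores))
  m <- length(u)
  cand <- c(-Inf, if (m > 1) (u[-m] + u[-1]) / 2, Inf)
  cases <- scores[labels]
  ctrls <- scores[!labels]
  max(vapply(cand, function(t) {
    mean(cases > t) + mean(ctrls <= t) - 1
  }, 0))
}

# hand-written SAM text for parser fixtures
write_sam_text <- function(path, body,
                           sq = c("@SQ\tSN:chr1\tLN:1000000",
                                  "@SQ\tSN:chr18\tLN:500000",
                                  "@SQ\tSN:chr21\tLN:400000")) {
  writeLines(c("@HD\tVN:1.6\tSO:unknown", sq, body), path)
}

sam_line <- function(qname, flag, chrom, pos, mapq, len) {
  if (bitwAnd(flag, 4L) != 0L) {
    sprintf("%s\t%d\t*\t0\t0\t*\t*\t0\t0\t*\t*", qname, flag)
  } else {
    sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*",
            qname, flag, chrom, pos, mapq, len)
  }
}

# chromosome_counts built directly from a named vector
cc <- function(...) chromosome_counts(c(...))
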