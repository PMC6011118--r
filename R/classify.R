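#' Combination rules for the three aneuploidy scores
#'
#' A sample is called positive for a chromosome when the rule's
#' constituent scores all exceed (strictly) their cut-offs. `TR_AND_FGR`
#' — both GC-corrected statistics above cut-off at the same time — is
#' the default: no single score is accurate enough alone, and this
#' conjunction yields the fewest combined false positives and
#' negatives.
#'
#' @format Character vector of recognized rule identifiers.
#' @export
SCORE_RULES <- c("TR_AND_FGR", "ALL_THREE", "ANY_TWO", "Z_AND_TR",
                 "Z_AND_FGR", "Z", "TR", "FGR")

# does `rule` fire for one chromosome's scores? strict > throughout
rule_fires <- function(z, tr, fgr, cz, ctr, cfgr, rule) {
  pz <- z > cz
  ptr <- tr > ctr
  pfgr <- fgr > cfgr
  switch(rule,
         Z = pz, TR = ptr, FGR = pfgr,
         TR_AND_FGR = ptr & pfgr,
         Z_AND_TR = pz & ptr,
         Z_AND_FGR = pz & pfgr,
         ANY_TWO = (pz + ptr + pfgr) >= 2,
         ALL_THREE = pz & ptr & pfgr,
         stop("unrecognized rule: ", rule))
}

#' ROC-optimal cut-off by Youden's J
#'
#' Sweeps every threshold candidate — the midpoints between adjacent
#' sorted unique score values, plus minus and plus infinity — and
#' returns the cut-off maximizing Youden's J = sensitivity +
#' specificity - 1, where a sample is positive when its score is
#' strictly greater than the cut-off. Ties on J are broken toward
#' higher specificity, then toward the higher cut-off.
#'
#' @param scores numeric score values.
#' @param labels logical, `TRUE` for cases (trisomic), `FALSE` for
#'   controls; both classes must be present.
#' @return List: `cutoff`, `sensitivity`, `specificity`, `j`.
#' @export
roc_cutoff <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), is.logical(labels))
  n_case <- sum(labels)
  n_ctrl <- sum(!labels)
  if (n_case == 0 || n_ctrl == 0) {
    stop("both classes must be present for ROC calibration")
  }
  u <- sort(unique(scores))
  m <- length(u)
  # candidate k (k = 0..m) sits between u[k] and u[k+1]:
  # positives are the scores strictly above u[k]
  cum_case <- c(0, cumsum(tabulate(findInterval(scores[labels], u),
                                   nbins = m)))
  cum_ctrl <- c(0, cumsum(tabulate(findInterval(scores[!labels], u),
                                   nbins = m)))
  sens <- (n_case - cum_case) / n_case
  spec <- cum_ctrl / n_ctrl
  j <- sens + spec - 1
  cand <- c(-Inf, if (m > 1) (u[-m] + u[-1]) / 2, Inf)
  best <- which(j == max(j))
  if (length(best) > 1) best <- best[spec[best] == max(spec[best])]
  best <- best[length(best)]   # highest cut-off among remaining ties
  list(cutoff = cand[best], sensitivity = sens[best],
       specificity = spec[best], j = j[best])
}

#' Collect per-sample scores into a cohort table
#'
#' @param score_sets list of [score_sample()] results.
#' @return Long data frame: `sample_id`, `chrom`, `z`, `tr`, `fgr`,
#'   `size_ratio`, `total_unique`.
#' @export
cohort_scores <- function(score_sets) {
  do.call(rbind, lapply(score_sets, function(s) {
    cbind(data.frame(sample_id = s$sample_id, stringsAsFactors = FALSE),
          s$scores,
          data.frame(size_ratio = s$size_ratio,
                     total_unique = s$total_unique))
  }))
}

#' Calibrate score cut-offs on a labelled cohort
#'
#' For each target chromosome and each score, derives the ROC-optimal
#' cut-off ([roc_cutoff()]) using that chromosome's trisomic samples as
#' cases and the euploid samples as controls. All combination rules are
#' then evaluated on the calibration cohort itself and the rule with
#' the fewest misclassified samples (false positives plus false
#' negatives) is recorded, ties resolving to `TR_AND_FGR`.
#'
#' @param scores cohort score table from [cohort_scores()].
#' @param truth data frame `sample_id`, `truth_label` with labels in
#'   `euploid`, `trisomy13`, `trisomy18`, `trisomy21`; at least one
#'   case per target chromosome and two euploid controls.
#' @param rule force a specific combination rule instead of selecting
#'   one.
#' @param target_chroms chromosomes to calibrate.
#' @return An object of class `cutoff_set`: `cutoffs` (data frame:
#'   chrom, score, cutoff, sensitivity, specificity), `rule`,
#'   `provenance`.
#' @export
calibrate <- function(scores, truth, rule = NULL,
                      target_chroms = TARGET_CHROMS) {
  stopifnot(all(c("sample_id", "chrom", "z", "tr", "fgr") %in%
                  names(scores)),
            all(c("sample_id", "truth_label") %in% names(truth)))
  lab <- stats::setNames(truth$truth_label, truth$sample_id)
  if (sum(lab == "euploid") < 2) stop("need at least 2 euploid controls")
  rows <- list()
  for (ch in target_chroms) {
    sub <- scores[scores$chrom == ch, , drop = FALSE]
    is_case <- lab[sub$sample_id] == chrom_to_label(ch)
    is_ctrl <- lab[sub$sample_id] == "euploid"
    if (!any(is_case)) stop("no calibration cases for ", ch)
    keep <- is_case | is_ctrl
    for (sc in c("z", "tr", "fgr")) {
      r <- roc_cutoff(sub[[sc]][keep], is_case[keep])
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, score = sc, cutoff = r$cutoff,
        sensitivity = r$sensitivity, specificity = r$specificity,
        stringsAsFactors = FALSE)
    }
  }
  cutoffs <- do.call(rbind, rows)
  selection <- NULL
  if (is.null(rule)) {
    errs <- vapply(SCORE_RULES, function(rl) {
      cs <- structure(list(cutoffs = cutoffs, rule = rl),
                      class = "cutoff_set")
      calls <- classify_cohort_scores(scores, cs)
      truth_here <- lab[calls$sample_id]
      sum(calls$status != truth_here)
    }, 0)
    rule <- SCORE_RULES[which.min(errs)]  # SCORE_RULES puts TR_AND_FGR first
    selection <- errs
  } else {
    rule <- match.arg(rule, SCORE_RULES)
  }
  structure(list(cutoffs = cutoffs, rule = rule,
                 provenance = list(
                   n_samples = length(unique(scores$sample_id)),
                   n_cases = vapply(target_chroms, function(ch)
                     sum(lab == chrom_to_label(ch)), 0),
                   n_controls = sum(lab == "euploid"),
                   criterion = "youden_j",
                   rule_errors = selection)),
            class = "cutoff_set")
}

#' @export
print.cutoff_set <- function(x, ...) {
  cat(sprintf("cutoff_set: rule %s (calibrated on %d samples)\n",
              x$rule, x$provenance$n_samples %||% NA))
  print(x$cutoffs, row.names = FALSE)
  invisible(x)
}

#' Serialize / load cut-offs as JSON
#'
#' @param cutoffs a [calibrate()] result.
#' @param path JSON path.
#' @export
write_cutoffs_json <- function(cutoffs, path) {
  stopifnot(inherits(cutoffs, "cutoff_set"))
  jsonlite::write_json(unclass(cutoffs), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_cutoffs_json
#' @export
read_cutoffs_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(cutoffs = as.data.frame(raw$cutoffs),
                 rule = raw$rule, provenance = raw$provenance),
            class = "cutoff_set")
}

# classify every sample in a cohort score table; gates assumed passed
classify_cohort_scores <- function(scores, cutoffs) {
  ids <- unique(scores$sample_id)
  do.call(rbind, lapply(ids, function(id) {
    sub <- scores[scores$sample_id == id, , drop = FALSE]
    ss <- structure(list(sample_id = id,
                         scores = sub[, c("chrom", "z", "tr", "fgr")],
                         size_ratio = sub$size_ratio[1],
                         total_unique = sub$total_unique[1]),
                    class = "score_set")
    call <- classify(ss, cutoffs)
    data.frame(sample_id = id, status = call$status,
               positives = paste(call$positives, collapse = ","),
               stringsAsFactors = FALSE)
  }))
}

#' Classify one sample
#'
#' Applies the cut-off set's combination rule to each target
#' chromosome, with every constituent comparison strict (`score >
#' cutoff`). Gate failures short-circuit: a sample that failed the
#' read-count or size-ratio gate is `noninformative`; a sample whose
#' size ratio could not be computed is `non_evaluable`. Otherwise zero
#' firing chromosomes yield `euploid`, exactly one yields that trisomy,
#' and with several the chromosome with the largest TR is called while
#' the full set of firing chromosomes is preserved in `positives` for
#' audit.
#'
#' @param score_set a [score_sample()] result.
#' @param cutoffs a [calibrate()] result (cut-offs for every target
#'   chromosome must be present).
#' @param informative read-count gate outcome (see [informative()]).
#' @param size_gate size-ratio gate outcome (see [size_gate()]); `NA`
#'   marks a non-evaluable ratio.
#' @return An object of class `sample_call`: `sample_id`, `status` in
#'   `euploid`/`trisomy13`/`trisomy18`/`trisomy21`/`noninformative`/
#'   `non_evaluable`, `positives` (chromosomes whose rule fired),
#'   `scores`.
#' @export
classify <- function(score_set, cutoffs, informative = TRUE,
                     size_gate = TRUE) {
  stopifnot(inherits(cutoffs, "cutoff_set"))
  mk <- function(status, positives = character()) {
    structure(list(sample_id = score_set$sample_id, status = status,
                   positives = positives, scores = score_set),
              class = "sample_call")
  }
  if (is.na(size_gate)) return(mk("non_evaluable"))
  if (!informative || !size_gate) return(mk("noninformative"))
  sc <- score_set$scores
  ct <- cutoffs$cutoffs
  fired <- vapply(sc$chrom, function(ch) {
    cc <- ct[ct$chrom == ch, , drop = FALSE]
    get_cut <- function(s) {
      v <- cc$cutoff[cc$score == s]
      if (length(v) != 1) stop("missing cutoff for ", ch, " score ", s)
      v
    }
    i <- which(sc$chrom == ch)
    rule_fires(sc$z[i], sc$tr[i], sc$fgr[i], get_cut("z"),
               get_cut("tr"), get_cut("fgr"), cutoffs$rule)
  }, TRUE)
  positives <- sc$chrom[fired]
  if (length(positives) == 0) return(mk("euploid"))
  called <- if (length(positives) == 1) positives else {
    positives[which.max(sc$tr[match(positives, sc$chrom)])]
  }
  mk(chrom_to_label(called), positives)
}

#' @export
print.sample_call <- function(x, ...) {
  cat(sprintf("sample_call '%s': %s%s\n", x$sample_id, x$status,
              if (length(x$positives) > 0)
                sprintf(" (positives: %s)",
                        paste(x$positives, collapse = ", ")) else ""))
  invisible(x)
}
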