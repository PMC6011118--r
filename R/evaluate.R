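#' Evaluate cohort calls against truth
#'
#' Scores a cohort of classification calls with the error taxonomy
#' standard in NIPT validation studies. Overall sensitivity counts a
#' pathological sample as detected when it is called trisomic for *any*
#' chromosome — a trisomic sample called for the wrong chromosome
#' ("incorrectly identified") is detected overall, yet counts as a
#' per-chromosome false negative for its true chromosome and a false
#' positive for the called one. Per-chromosome specificity uses as
#' denominator all samples whose truth is not that trisomy (euploid and
#' other trisomies alike). Overall specificity is the fraction of
#' euploid samples not called trisomic. Percentages are reported
#' rounded half-up to two decimals.
#'
#' Samples whose call is `noninformative` or `non_evaluable` are
#' excluded from every metric; their number is reported.
#'
#' @param calls data frame with `sample_id` and `status`, or a list of
#'   [classify()] results.
#' @param truth data frame `sample_id`, `truth_label`; the ID sets must
#'   match.
#' @param target_chroms chromosomes evaluated per-chromosome.
#' @return An object of class `confusion_summary`: `per_chromosome`
#'   (data frame: chrom, tp, fn, fp, tn, sensitivity, specificity),
#'   `overall` (n_pathological, n_detected, n_false_negative,
#'   n_false_positive, n_incorrectly_identified, n_euploid,
#'   sensitivity, specificity), `n_excluded`, `n_evaluated`.
#' @export
evaluate <- function(calls, truth, target_chroms = TARGET_CHROMS) {
  if (is.list(calls) && !is.data.frame(calls)) {
    calls <- do.call(rbind, lapply(calls, function(x)
      data.frame(sample_id = x$sample_id, status = x$status,
                 stringsAsFactors = FALSE)))
  }
  stopifnot(all(c("sample_id", "status") %in% names(calls)),
            all(c("sample_id", "truth_label") %in% names(truth)))
  if (nrow(calls) == 0) stop("empty cohort")
  if (!setequal(calls$sample_id, truth$sample_id) ||
      anyDuplicated(calls$sample_id) || anyDuplicated(truth$sample_id)) {
    stop("sample_id sets of calls and truth do not match")
  }
  lab <- stats::setNames(truth$truth_label, truth$sample_id)[calls$sample_id]
  excluded <- calls$status %in% c("noninformative", "non_evaluable")
  status <- calls$status[!excluded]
  lab <- lab[!excluded]
  if (length(status) == 0) stop("no evaluable samples")

  per <- do.call(rbind, lapply(target_chroms, function(ch) {
    tl <- chrom_to_label(ch)
    truth_n <- lab == tl
    called_n <- status == tl
    tp <- sum(truth_n & called_n)
    fn <- sum(truth_n & !called_n)
    fp <- sum(!truth_n & called_n)
    tn <- sum(!truth_n & !called_n)
    data.frame(chrom = ch, tp = tp, fn = fn, fp = fp, tn = tn,
               sensitivity = if (tp + fn > 0)
                 round_half_up(100 * tp / (tp + fn)) else NA_real_,
               specificity = if (fp + tn > 0)
                 round_half_up(100 * tn / (fp + tn)) else NA_real_,
               stringsAsFactors = FALSE)
  }))

  is_path <- lab %in% TRISOMY_LABELS
  is_called_tri <- status %in% TRISOMY_LABELS
  n_path <- sum(is_path)
  n_eu <- sum(!is_path)
  n_detected <- sum(is_path & is_called_tri)
  n_fn <- sum(is_path & !is_called_tri)
  n_fp <- sum(!is_path & is_called_tri)
  n_wrong <- sum(is_path & is_called_tri & status != lab)
  overall <- list(
    n_pathological = n_path, n_detected = n_detected,
    n_false_negative = n_fn, n_false_positive = n_fp,
    n_incorrectly_identified = n_wrong, n_euploid = n_eu,
    sensitivity = if (n_path > 0)
      round_half_up(100 * n_detected / n_path) else NA_real_,
    specificity = if (n_eu > 0)
      round_half_up(100 * (n_eu - n_fp) / n_eu) else NA_real_)
  structure(list(per_chromosome = per, overall = overall,
                 n_excluded = sum(excluded),
                 n_evaluated = length(status)),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  o <- x$overall
  cat(sprintf("confusion_summary: %d evaluated (%d excluded)\n",
              x$n_evaluated, x$n_excluded))
  cat(sprintf("  overall: sensitivity %.2f%%, specificity %.2f%% (%d/%d detected, %d FP, %d FN, %d wrong-chromosome)\n",
              o$sensitivity, o$specificity, o$n_detected,
              o$n_pathological, o$n_false_positive, o$n_false_negative,
              o$n_incorrectly_identified))
  print(x$per_chromosome, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation summary as JSON
#'
#' @param summary a [evaluate()] result.
#' @param path JSON path.
#' @export
write_summary_json <- function(summary, path) {
  stopifnot(inherits(summary, "confusion_summary"))
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Run the full screening pipeline on a cohort
#'
#' End-to-end driver: build the euploid reference panel, score every
#' sample, apply the read-count and size-ratio gates, calibrate the
#' cut-offs on the informative samples (resubstitution, as in
#' two-reference clinical validation designs) or reuse supplied
#' cut-offs, classify, and evaluate against truth. Deterministic given
#' its inputs.
#'
#' @param cohort list of samples as produced by [simulate_cohort()]
#'   (each with `sample_id`, `counts`, optional `lengths`, `truth`), or
#'   the same structure assembled from real count data.
#' @param truth optional data frame `sample_id`, `truth_label`; derived
#'   from the cohort's attached ground truth when omitted.
#' @param reference_ids sample IDs to build the reference panel from;
#'   default the first two euploid samples (the minimal panel used in
#'   small clinical series).
#' @param cutoffs a [calibrate()] result to reuse; when `NULL`,
#'   cut-offs are calibrated on this cohort.
#' @param rule force a combination rule during calibration.
#' @param gc_model GC-correction model for panel and samples.
#' @param min_reads read-count gate (strict `>`).
#' @param gate_cutoff size-ratio gate (strict `>`); samples without
#'   fragment lengths skip the size gate.
#' @param out_dir optional directory; when given, calls TSV and summary
#'   JSON are written there.
#' @return List: `panel`, `cutoffs`, `scores`, `calls` (data frame),
#'   `summary` ([evaluate()] result), `n_noninformative`.
#' @export
run_pipeline <- function(cohort, truth = NULL, reference_ids = NULL,
                         cutoffs = NULL, rule = NULL,
                         gc_model = c("none", "strata", "loess", "linear"),
                         min_reads = 1e6, gate_cutoff = 0.84,
                         out_dir = NULL) {
  gc_model <- match.arg(gc_model)
  stopifnot(length(cohort) > 0)
  ids <- vapply(cohort, `[[`, "", "sample_id")
  if (is.null(truth)) {
    truth <- data.frame(
      sample_id = ids,
      truth_label = vapply(cohort, function(s) {
        if (s$truth$trisomy == "none") "euploid"
        else chrom_to_label(s$truth$trisomy)
      }, ""),
      stringsAsFactors = FALSE)
  }
  if (is.null(reference_ids)) {
    eu <- truth$sample_id[truth$truth_label == "euploid"]
    if (length(eu) < 2) stop("need at least two euploid samples for the reference panel")
    reference_ids <- eu[1:2]
  }
  ref_samples <- lapply(cohort[match(reference_ids, ids)], `[[`, "counts")
  panel <- suppressWarnings(build_reference(ref_samples,
                                            gc_model = gc_model))

  gates <- lapply(cohort, function(s) {
    sg <- TRUE
    if (!is.null(s$lengths)) {
      sg <- tryCatch(size_gate(size_ratio(s$lengths, gate = gate_cutoff),
                               cutoff = gate_cutoff),
                     niptscreen_non_evaluable = function(e) NA)
    }
    list(informative = informative(s$counts, min_reads = min_reads),
         size_gate = sg)
  })
  score_sets <- lapply(cohort, function(s) {
    score_sample(s$counts, panel, lengths = s$lengths)
  })
  scores <- cohort_scores(score_sets)

  usable <- vapply(gates, function(g)
    isTRUE(g$informative) && isTRUE(g$size_gate), TRUE)
  if (is.null(cutoffs)) {
    cutoffs <- calibrate(scores[scores$sample_id %in% ids[usable], ,
                                drop = FALSE],
                         truth[truth$sample_id %in% ids[usable], ,
                               drop = FALSE],
                         rule = rule)
  }
  calls <- do.call(rbind, lapply(seq_along(cohort), function(i) {
    call <- classify(score_sets[[i]], cutoffs,
                     informative = gates[[i]]$informative,
                     size_gate = gates[[i]]$size_gate)
    data.frame(sample_id = call$sample_id, status = call$status,
               positives = paste(call$positives, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  summary <- evaluate(calls, truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(calls, file.path(out_dir, "calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_summary_json(summary, file.path(out_dir, "summary.json"))
    write_cutoffs_json(cutoffs, file.path(out_dir, "cutoffs.json"))
  }
  list(panel = panel, cutoffs = cutoffs, scores = scores, calls = calls,
       summary = summary, n_noninformative = sum(!usable))
}
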