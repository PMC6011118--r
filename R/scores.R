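#' Percent genomic representation of a chromosome
#'
#' The share, in percent, of a sample's unique reads that map to one
#' chromosome, out of all reads on the included chromosomes
#' (chr1-chr22, chrX). This is the quantity all three aneuploidy
#' statistics are built on; summed over the included chromosomes it is
#' exactly 100.
#'
#' @param counts a [chromosome_counts()] with `total_unique > 0`.
#' @param chrom chromosome name; must be present in the counts.
#' @return `100 * counts[chrom] / total_unique`.
#' @export
percent_representation <- function(counts, chrom) {
  stopifnot(inherits(counts, "chromosome_counts"))
  if (counts$total_unique <= 0) stop("zero total unique reads")
  if (!chrom %in% names(counts$counts)) {
    stop("chromosome not in the included set: ", chrom)
  }
  100 * unname(counts$counts[chrom]) / counts$total_unique
}

# %GR for every included chromosome at once
percent_representation_all <- function(counts) {
  if (counts$total_unique <= 0) stop("zero total unique reads")
  100 * counts$counts / counts$total_unique
}

#' GC-correct binned read counts
#'
#' Read yield varies systematically with local GC content; left
#' uncorrected this inflates the variance of chromosome representation
#' and biases GC-extreme chromosomes. Each bin's count is rescaled by
#' `m_bar / m(gc_bin)` where `m(.)` is the fitted count-versus-GC trend
#' and `m_bar` the global mean bin count, so that after correction the
#' expected bin count no longer depends on GC. Corrected chromosome
#' counts are the corrected bin sums.
#'
#' Three trend estimators are available: `"strata"` (default) pools
#' bins into GC strata of width `strata_width` and uses the stratum
#' mean — parameter-light and exactly the identity when counts carry no
#' GC trend; `"loess"` and `"linear"` fit smooth or straight-line
#' trends. The trend is fitted on full-width bins only (short terminal
#' bins are corrected but do not inform the fit); strata without fit
#' bins borrow the nearest nonempty stratum's factor.
#'
#' @param counts a [chromosome_counts()] with `bin_counts`; at least 20
#'   bins with nonzero counts are required.
#' @param model trend estimator.
#' @param strata_width GC stratum width (default 0.005, i.e. 0.5% GC).
#' @param span loess span.
#' @return A corrected [chromosome_counts()] (counts need not be
#'   integer); `bin_counts` holds the corrected bin values.
#' @export
gc_correct <- function(counts, model = c("strata", "loess", "linear"),
                       strata_width = 0.005, span = 0.75) {
  model <- match.arg(model)
  stopifnot(inherits(counts, "chromosome_counts"))
  bc <- counts$bin_counts
  if (is.null(bc)) stop("bin_counts required for GC correction")
  if (sum(bc$count > 0) < 20) {
    stop("insufficient data: fewer than 20 bins with nonzero counts")
  }
  fit_mask <- if (!is.null(bc$full_width)) bc$full_width else {
    w <- bc$bin_end - bc$bin_start
    w == max(w)
  }
  fit <- bc[fit_mask, , drop = FALSE]
  m_bar <- mean(fit$count)
  m_hat <- switch(model,
    strata = {
      stratum <- floor(bc$gc_fraction / strata_width)
      fit_stratum <- stratum[fit_mask]
      means <- tapply(fit$count, fit_stratum, mean)
      lev <- as.numeric(names(means))
      ok <- means > 0
      if (!any(ok)) stop("all GC strata empty")
      # nearest nonempty stratum for bins whose stratum has no usable fit
      nearest <- vapply(stratum, function(s) {
        cand <- lev[ok]
        cand[which.min(abs(cand - s))]
      }, 0)
      use <- ifelse(stratum %in% lev[ok], stratum, nearest)
      unname(means[as.character(use)])
    },
    linear = {
      lmfit <- stats::lm(count ~ gc_fraction, data = fit)
      pred <- stats::predict(lmfit, newdata = bc)
      pmax(pred, m_bar * 1e-3)
    },
    loess = {
      lofit <- stats::loess(count ~ gc_fraction, data = fit, span = span,
                            degree = 1,
                            control = stats::loess.control(surface = "direct"))
      pred <- stats::predict(lofit, newdata = bc)
      pmax(pred, m_bar * 1e-3)
    })
  factor <- m_bar / m_hat
  corrected <- bc
  corrected$count <- bc$count * factor
  new_counts <- tapply(corrected$count,
                       factor(corrected$chrom, levels = names(counts$counts)),
                       sum)
  new_counts[is.na(new_counts)] <- 0
  chromosome_counts(stats::setNames(as.numeric(new_counts),
                                    names(counts$counts)),
                    sample_id = counts$sample_id, bin_counts = corrected)
}

#' Build a euploid reference panel
#'
#' Summarizes reference (euploid-pregnancy) samples into the normal
#' range every score is compared against: per-chromosome mean and SD of
#' percent genomic representation, both raw and GC-corrected. SDs use
#' the n-1 denominator. Panels built from very few samples (fewer than
#' 10) are statistically fragile — the SD is then poorly estimated — and
#' trigger a warning, but remain usable.
#'
#' @param samples list of [chromosome_counts()] (>= 2 euploid samples).
#' @param gc_model GC-correction trend passed to [gc_correct()], or
#'   `"none"` to skip correction (corrected moments then equal the raw
#'   ones). Samples without bin counts force `"none"`.
#' @return An object of class `reference_panel`: `chromosomes`,
#'   `raw_mean`, `raw_sd`, `corr_mean`, `corr_sd` (named vectors),
#'   `n_reference`, `gc_model`.
#' @export
build_reference <- function(samples,
                            gc_model = c("strata", "loess", "linear",
                                         "none")) {
  gc_model <- match.arg(gc_model)
  stopifnot(length(samples) >= 2,
            all(vapply(samples, inherits, TRUE, "chromosome_counts")))
  if (length(samples) < 10) {
    warning(sprintf("reference panel has only %d samples; the normal-range SD is fragile",
                    length(samples)))
  }
  if (gc_model != "none" &&
      any(vapply(samples, function(s) is.null(s$bin_counts), TRUE))) {
    gc_model <- "none"
  }
  chroms <- names(samples[[1]]$counts)
  raw <- t(vapply(samples, percent_representation_all,
                  numeric(length(chroms))))
  corr <- if (gc_model == "none") raw else {
    t(vapply(samples, function(s) {
      percent_representation_all(gc_correct(s, model = gc_model))
    }, numeric(length(chroms))))
  }
  structure(list(chromosomes = chroms,
                 raw_mean = apply(raw, 2, mean),
                 raw_sd = apply(raw, 2, stats::sd),
                 corr_mean = apply(corr, 2, mean),
                 corr_sd = apply(corr, 2, stats::sd),
                 n_reference = length(samples), gc_model = gc_model),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("reference_panel: %d euploid samples, GC model '%s'\n",
              x$n_reference, x$gc_model))
  tgt <- intersect(TARGET_CHROMS, x$chromosomes)
  for (ch in tgt) {
    cat(sprintf("  %s: raw %%GR %.4f (SD %.4f), corrected %.4f (SD %.4f)\n",
                ch, x$raw_mean[ch], x$raw_sd[ch], x$corr_mean[ch],
                x$corr_sd[ch]))
  }
  invisible(x)
}

#' Serialize / load a reference panel as JSON
#'
#' @param panel a [build_reference()] panel.
#' @param path JSON path.
#' @return `path` (write) or a `reference_panel` (read).
#' @export
write_panel_json <- function(panel, path) {
  stopifnot(inherits(panel, "reference_panel"))
  jsonlite::write_json(unclass(panel), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_panel_json
#' @export
read_panel_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("raw_mean", "raw_sd", "corr_mean", "corr_sd")) {
    raw[[f]] <- stats::setNames(unlist(raw[[f]]), raw$chromosomes)
  }
  structure(raw[c("chromosomes", "raw_mean", "raw_sd", "corr_mean",
                  "corr_sd", "n_reference", "gc_model")],
            class = "reference_panel")
}

#' Z-score of chromosome representation
#'
#' Standardized deviation of the sample's raw percent genomic
#' representation from the euploid reference: `(%GR - mean_ref) /
#' sd_ref`. Deliberately computed on raw (non-GC-corrected)
#' representation — it is the GC-blind statistic the two corrected
#' scores are contrasted with.
#'
#' @param pgr sample raw %GR for `chrom` (or a [chromosome_counts()]).
#' @param panel a [build_reference()] panel with `raw_sd[chrom] > 0`.
#' @param chrom target chromosome.
#' @return The z value.
#' @export
z_score <- function(pgr, panel, chrom) {
  stopifnot(inherits(panel, "reference_panel"))
  if (inherits(pgr, "chromosome_counts")) {
    pgr <- percent_representation(pgr, chrom)
  }
  s <- panel$raw_sd[chrom]
  if (is.na(s) || s <= 0) {
    stop("reference SD is zero for ", chrom, "; z-score undefined")
  }
  unname((pgr - panel$raw_mean[chrom]) / s)
}

#' Trisomy Ratio (TR)
#'
#' GC-corrected percent representation of the target chromosome divided
#' by the reference panel's GC-corrected mean. Expectation 1 for a
#' euploid sample and `1 + ff/2` under trisomy at fetal fraction ff, so
#' `2 * (TR - 1)` doubles as a chromosome-dosage estimate of the fetal
#' fraction.
#'
#' @param corr_pgr sample GC-corrected %GR for `chrom` (or a corrected
#'   [chromosome_counts()]).
#' @param panel reference panel with `corr_mean[chrom] > 0`.
#' @param chrom target chromosome.
#' @return The TR value.
#' @export
trisomy_ratio <- function(corr_pgr, panel, chrom) {
  stopifnot(inherits(panel, "reference_panel"))
  if (inherits(corr_pgr, "chromosome_counts")) {
    corr_pgr <- percent_representation(corr_pgr, chrom)
  }
  m <- panel$corr_mean[chrom]
  if (is.na(m) || m <= 0) stop("reference corrected mean is zero for ", chrom)
  unname(corr_pgr / m)
}

#' Fractional Genomic Representation (FGR)
#'
#' The GC-corrected percent representation of the target chromosome
#' itself, on the percent scale. Unlike TR it is not normalized to the
#' panel mean; it is compared downstream against its own ROC-derived
#' cut-off.
#'
#' @param counts a GC-corrected [chromosome_counts()] (or a corrected
#'   %GR value, returned unchanged).
#' @param panel reference panel (carried for interface symmetry; the
#'   statistic itself is panel-free).
#' @param chrom target chromosome.
#' @return The FGR value (percent).
#' @export
fgr <- function(counts, panel, chrom) {
  if (inherits(counts, "chromosome_counts")) {
    return(percent_representation(counts, chrom))
  }
  counts
}

#' Score one sample against a reference panel
#'
#' Computes Z, TR and FGR for chromosomes 13, 18 and 21, applying the
#' panel's GC-correction model to the sample when it carries bin counts.
#' Deterministic given counts and panel.
#'
#' @param counts a [chromosome_counts()] for an informative sample.
#' @param panel a [build_reference()] panel.
#' @param lengths optional fragment lengths; when given, the size ratio
#'   is computed and carried in the result.
#' @param target_chroms chromosomes to score.
#' @param ... passed to [size_ratio()].
#' @return An object of class `score_set`: `sample_id`, `scores` (data
#'   frame: chrom, z, tr, fgr), `size_ratio` (or `NA`), `total_unique`.
#' @export
score_sample <- function(counts, panel, lengths = NULL,
                         target_chroms = TARGET_CHROMS, ...) {
  stopifnot(inherits(counts, "chromosome_counts"),
            inherits(panel, "reference_panel"))
  corrected <- if (panel$gc_model != "none" && !is.null(counts$bin_counts)) {
    gc_correct(counts, model = panel$gc_model)
  } else counts
  scores <- data.frame(
    chrom = target_chroms,
    z = vapply(target_chroms, function(ch) z_score(counts, panel, ch), 0),
    tr = vapply(target_chroms, function(ch)
      trisomy_ratio(corrected, panel, ch), 0),
    fgr = vapply(target_chroms, function(ch) fgr(corrected, panel, ch), 0),
    stringsAsFactors = FALSE, row.names = NULL)
  sr <- if (is.null(lengths)) NA_real_ else
    size_ratio(lengths, ...)$size_ratio
  structure(list(sample_id = counts$sample_id, scores = scores,
                 size_ratio = sr, total_unique = counts$total_unique),
            class = "score_set")
}

#' @export
print.score_set <- function(x, ...) {
  cat(sprintf("score_set '%s' (%s unique reads, size ratio %s)\n",
              x$sample_id, format(round(x$total_unique), big.mark = ","),
              if (is.na(x$size_ratio)) "-" else sprintf("%.3f", x$size_ratio)))
  print(x$scores, row.names = FALSE)
  invisible(x)
}
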