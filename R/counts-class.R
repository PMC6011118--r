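#' Per-chromosome unique-read counts for one sample
#'
#' The central per-sample container: unique-read counts per chromosome,
#' their total, and optionally per-bin counts carrying each bin's GC
#' fraction (the input to GC correction). Counts may be non-integer
#' after GC rescaling.
#'
#' @param counts named numeric vector, chromosome -> count (all >= 0).
#' @param sample_id sample identifier.
#' @param bin_counts optional data frame with columns `chrom`,
#'   `bin_start`, `bin_end`, `gc_fraction`, `count` (0-based half-open
#'   bins). Per-chromosome sums must match `counts`.
#' @return An object of class `chromosome_counts`: list with elements
#'   `sample_id`, `counts`, `total_unique`, `bin_counts`.
#' @export
chromosome_counts <- function(counts, sample_id = "sample",
                              bin_counts = NULL) {
  stopifnot(is.numeric(counts), !is.null(names(counts)),
            all(counts >= 0))
  if (!is.null(bin_counts)) {
    stopifnot(all(c("chrom", "bin_start", "bin_end", "gc_fraction",
                    "count") %in% names(bin_counts)),
              all(bin_counts$count >= 0))
    bysum <- tapply(bin_counts$count, bin_counts$chrom, sum)
    common <- intersect(names(counts), names(bysum))
    if (any(abs(counts[common] - bysum[common]) > 1e-6)) {
      stop("bin_counts do not sum to the per-chromosome counts")
    }
  }
  structure(list(sample_id = sample_id, counts = counts,
                 total_unique = sum(counts), bin_counts = bin_counts),
            class = "chromosome_counts")
}

#' @export
print.chromosome_counts <- function(x, ...) {
  cat(sprintf("chromosome_counts '%s': %s unique reads on %d chromosomes%s\n",
              x$sample_id, format(round(x$total_unique), big.mark = ","),
              sum(x$counts > 0),
              if (is.null(x$bin_counts)) "" else
                sprintf(" (%d bins)", nrow(x$bin_counts))))
  invisible(x)
}

#' Write counts to TSV
#'
#' @param x a [chromosome_counts()] object.
#' @param path output path; columns `chrom`, `count`.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(x, path) {
  stopifnot(inherits(x, "chromosome_counts"))
  utils::write.table(
    data.frame(chrom = names(x$counts), count = unname(x$counts)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
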