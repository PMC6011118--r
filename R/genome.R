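#' Genome tables for chromosome-representation analysis
#'
#' A genome table holds, for each chromosome, its name, length in bp and
#' GC fraction, and optionally a fixed-width binning of each chromosome
#' with a per-bin GC fraction. It is the coordinate and GC reference used
#' by read counting, GC correction and the synthetic-data generator.
#'
#' @param chrom character vector of chromosome names.
#' @param length integer vector of chromosome lengths (bp).
#' @param gc_fraction numeric vector of per-chromosome GC fractions in
#'   `[0, 1]`.
#' @param bin_width bin width in bp, or `NULL` for no binning. Terminal
#'   bins shorter than `bin_width` are kept and flagged
#'   (`full_width = FALSE`).
#' @param bin_gc optional data frame of per-bin GC
#'   (`chrom, bin_start, bin_end, gc_fraction`); when `NULL` and
#'   `bin_width` is given, per-bin GC is synthesized deterministically
#'   around each chromosome's GC fraction (see Details).
#'
#' @details Real per-bin GC tracks require the reference sequence itself;
#' when none is supplied the table carries a synthetic but deterministic
#' per-bin GC covariate: chromosome GC plus a bounded sinusoidal
#' modulation (amplitude 0.04). This preserves the property the GC
#' correction depends on — bins of like GC behave alike — without
#' shipping genome sequence. Coordinates are 0-based half-open
#' internally.
#'
#' @return An object of class `genome_table`: a list with elements
#'   `chromosomes` (data frame: chrom, length, gc_fraction) and `bins`
#'   (data frame: chrom, bin_start, bin_end, gc_fraction, full_width; or
#'   `NULL`).
#' @export
genome_table <- function(chrom, length, gc_fraction, bin_width = NULL,
                         bin_gc = NULL) {
  stopifnot(is.character(chrom), !anyDuplicated(chrom),
            length(chrom) == length(length),
            length(chrom) == length(gc_fraction))
  if (any(length <= 0)) stop("chromosome lengths must be positive")
  if (any(gc_fraction < 0 | gc_fraction > 1)) {
    stop("gc_fraction must lie in [0, 1]")
  }
  chromosomes <- data.frame(chrom = chrom, length = as.numeric(length),
                            gc_fraction = as.numeric(gc_fraction),
                            stringsAsFactors = FALSE)
  bins <- NULL
  if (!is.null(bin_gc)) {
    stopifnot(all(c("chrom", "bin_start", "bin_end", "gc_fraction") %in%
                    names(bin_gc)))
    bins <- bin_gc
    if (is.null(bins$full_width)) {
      w <- bins$bin_end - bins$bin_start
      bins$full_width <- w == max(w)
    }
  } else if (!is.null(bin_width)) {
    stopifnot(bin_width > 0)
    bins <- do.call(rbind, lapply(seq_len(nrow(chromosomes)), function(i) {
      len <- chromosomes$length[i]
      starts <- seq(0, len - 1, by = bin_width)
      ends <- pmin(starts + bin_width, len)
      idx <- seq_along(starts)
      gc <- chromosomes$gc_fraction[i] + 0.04 * sin(idx * 0.7)
      data.frame(chrom = chromosomes$chrom[i], bin_start = starts,
                 bin_end = ends,
                 gc_fraction = pmin(pmax(gc, 0), 1),
                 full_width = (ends - starts) == bin_width,
                 stringsAsFactors = FALSE)
    }))
    rownames(bins) <- NULL
  }
  structure(list(chromosomes = chromosomes, bins = bins,
                 bin_width = bin_width),
            class = "genome_table")
}

#' Bundled hg19 genome table (chr1-chr22, chrX)
#'
#' Chromosome lengths for the GRCh37/hg19 assembly with approximate
#' per-chromosome GC fractions. chrY is excluded: maternal plasma cfDNA
#' is overwhelmingly maternal (female) in origin and the autosomal
#' trisomy statistics never target it.
#'
#' @param bin_width bin width in bp (default 50 kb), or `NULL` to skip
#'   binning.
#' @return A [genome_table()].
#' @export
default_genome <- function(bin_width = 50000L) {
  path <- system.file("extdata", "hg19_chromosomes.tsv",
                      package = "niptscreen", mustWork = TRUE)
  read_genome_table(path, bin_width = bin_width)
}

#' Read a genome table from TSV
#'
#' @param path TSV with columns `chrom`, `length`, `gc_fraction`.
#' @inheritParams genome_table
#' @return A [genome_table()].
#' @export
read_genome_table <- function(path, bin_width = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "length", "gc_fraction") %in% names(tab)))
  genome_table(tab$chrom, tab$length, tab$gc_fraction,
               bin_width = bin_width)
}

#' @export
print.genome_table <- function(x, ...) {
  cat(sprintf("genome_table: %d chromosomes, %.2f Gb total\n",
              nrow(x$chromosomes), sum(x$chromosomes$length) / 1e9))
  if (!is.null(x$bins)) {
    cat(sprintf("  %d bins of width %s bp\n", nrow(x$bins),
                format(x$bin_width, big.mark = ",")))
  }
  invisible(x)
}

#' Default per-chromosome base proportions
#'
#' Base multinomial weights proportional to chromosome length, the
#' euploid expectation for uniformly sampled unique reads.
#'
#' @param genome a [genome_table()].
#' @return Named numeric vector summing to 1.
#' @export
chromosome_weights <- function(genome) {
  w <- genome$chromosomes$length / sum(genome$chromosomes$length)
  names(w) <- genome$chromosomes$chrom
  w
}

# internal: chromosome GC as a named vector
genome_gc <- function(genome) {
  gc <- genome$chromosomes$gc_fraction
  names(gc) <- genome$chromosomes$chrom
  gc
}
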