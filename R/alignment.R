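#' Read alignments from SAM or BAM
#'
#' Loads one record per alignment line and flags the uniquely mapped
#' ones. Most NIPT pipelines keep only reads reported at a single
#' confident location; since mappers encode that differently, uniqueness
#' is operationalized here as: primary (not secondary 0x100, not
#' supplementary 0x800), mapped, and MAPQ >= `min_mapq`. The fragment
#' length is the aligned query length — single-end cfDNA reads span the
#' whole plasma molecule — except for paired records, where the absolute
#' template length is used instead.
#'
#' @param path SAM or BAM file (`.sam` input is converted on the fly).
#' @param genome a [genome_table()]; records on chromosomes absent from
#'   it are dropped with a warning reporting the number skipped.
#' @param min_mapq minimum MAPQ for a read to count as uniquely mapped
#'   (default 1: MAPQ 0 conventionally marks multi-mapping reads).
#' @return A data frame of records: `chrom`, `pos` (1-based leftmost),
#'   `length` (bp), `mapq`, `flag`, `is_unique`.
#' @export
read_alignments <- function(path, genome, min_mapq = 1L) {
  stopifnot(file.exists(path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("flag", "rname", "pos", "mapq", "qwidth", "isize")))[[1]]
  flag <- res$flag
  unmapped <- bitwAnd(flag, 4L) != 0L
  secondary <- bitwAnd(flag, 256L) != 0L
  supplementary <- bitwAnd(flag, 2048L) != 0L
  paired <- bitwAnd(flag, 1L) != 0L
  len <- ifelse(paired & !is.na(res$isize) & res$isize != 0L,
                abs(res$isize), res$qwidth)
  rec <- data.frame(chrom = as.character(res$rname),
                    pos = res$pos, length = len,
                    mapq = res$mapq, flag = flag,
                    is_unique = !unmapped & !secondary & !supplementary &
                      !is.na(res$mapq) & res$mapq >= min_mapq,
                    stringsAsFactors = FALSE)
  mapped_unknown <- !unmapped & !(rec$chrom %in% genome$chromosomes$chrom)
  if (any(mapped_unknown)) {
    warning(sprintf("skipped %d records on chromosomes absent from the genome table",
                    sum(mapped_unknown)))
    rec <- rec[!mapped_unknown, , drop = FALSE]
  }
  rec
}

#' Count uniquely mapped reads per chromosome
#'
#' Tallies `is_unique` records over the genome table's chromosomes
#' (by convention chr1-chr22 and chrX; chrY never enters the totals the
#' representation statistics are computed on). With `with_bins = TRUE`
#' each unique read increments exactly one bin, chosen by its leftmost
#' position.
#'
#' @param records data frame from [read_alignments()] (one sample).
#' @param genome a [genome_table()] (binned if `with_bins`).
#' @param with_bins also produce per-bin counts.
#' @param sample_id sample identifier carried into the result.
#' @return A [chromosome_counts()].
#' @export
count_unique <- function(records, genome, with_bins = FALSE,
                         sample_id = "sample") {
  chroms <- genome$chromosomes$chrom
  u <- records[records$is_unique & records$chrom %in% chroms, ,
               drop = FALSE]
  counts <- table(factor(u$chrom, levels = chroms))
  counts <- stats::setNames(as.numeric(counts), chroms)
  bc <- NULL
  if (with_bins) {
    bins <- genome$bins
    if (is.null(bins)) stop("genome has no bins; rebuild with bin_width set")
    bc <- bins[, c("chrom", "bin_start", "bin_end", "gc_fraction")]
    bc$count <- 0
    if (nrow(u) > 0) {
      # 0-based position within chromosome -> bin index
      pos0 <- u$pos - 1L
      key <- paste0(u$chrom, ":", pos0 %/% genome$bin_width)
      bkey <- paste0(bins$chrom, ":", bins$bin_start %/% genome$bin_width)
      tab <- table(key)
      idx <- match(names(tab), bkey)
      if (anyNA(idx)) stop("read position beyond chromosome end")
      bc$count[idx] <- as.numeric(tab)
    }
  }
  chromosome_counts(counts, sample_id = sample_id, bin_counts = bc)
}

#' Is a sample informative?
#'
#' A specimen is informative when strictly more than `min_reads` unique
#' reads survive alignment and filtering; at or below the threshold it
#' is reported noninformative and excluded from classification. The
#' default of one million reflects the depth at which trisomy 13/18/21
#' sensitivity and specificity plateau in shallow-sequencing NIPT.
#'
#' @param counts a [chromosome_counts()].
#' @param min_reads threshold (strict `>`), default 1e6.
#' @return `TRUE` or `FALSE`.
#' @export
informative <- function(counts, min_reads = 1e6) {
  stopifnot(inherits(counts, "chromosome_counts"))
  counts$total_unique > min_reads
}

#' Fragment lengths of uniquely mapped reads
#'
#' @param records data frame from [read_alignments()].
#' @return Integer vector of lengths, in record order; empty when no
#'   record is unique.
#' @export
fragment_lengths <- function(records) {
  records$length[records$is_unique]
}
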