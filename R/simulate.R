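#' Simulation configuration for synthetic maternal-plasma data
#'
#' Bundles everything the generator needs to emit one sample: sequencing
#' depth, trisomy status, fetal fraction, GC-bias strength, the
#' fragment-length mixture model and per-chromosome base proportions.
#'
#' The dosage model: a fetus trisomic for chromosome c contributes three
#' copies of c instead of two, so at fetal fraction ff the expected
#' relative overrepresentation of c in plasma is `1 + ff/2`.
#'
#' @param seed integer RNG seed; identical configs give identical draws.
#' @param n_reads number of unique reads to emit (>= 0).
#' @param trisomy one of `"none"`, `"chr13"`, `"chr18"`, `"chr21"`.
#' @param fetal_fraction fetal cfDNA fraction in `[0, 1]`.
#' @param gc_bias_slope per-unit-GC multiplicative count bias; the
#'   expected count factor for chromosome (or bin) GC g is
#'   `1 + gc_bias_slope * (g - mean GC)`. Default 0.3.
#' @param fragment_model list with `maternal_mean`, `maternal_sd`,
#'   `fetal_mean`, `fetal_sd` in bp. Defaults 166/20 (maternal) and
#'   143/20 (fetal), the canonical cfDNA size shift: fetal fragments run
#'   shorter than maternal ones.
#' @param chromosome_weights named base proportions over the genome's
#'   chromosomes, summing to 1; default proportional to hg19 chromosome
#'   lengths (chr1-chr22, chrX).
#' @param genome a [genome_table()]; supplies chromosome names, GC and
#'   bins.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_reads = 5e6,
                              trisomy = c("none", "chr13", "chr18", "chr21"),
                              fetal_fraction = 0.1,
                              gc_bias_slope = 0.3,
                              fragment_model = list(maternal_mean = 166,
                                                    maternal_sd = 20,
                                                    fetal_mean = 143,
                                                    fetal_sd = 20),
                              chromosome_weights = NULL,
                              genome = default_genome(bin_width = NULL)) {
  trisomy <- match.arg(trisomy)
  if (is.null(chromosome_weights)) {
    chromosome_weights <- chromosome_weights(genome)
  }
  stopifnot(is.numeric(n_reads), n_reads >= 0,
            fetal_fraction >= 0, fetal_fraction <= 1,
            !is.null(names(chromosome_weights)),
            setequal(names(chromosome_weights), genome$chromosomes$chrom))
  if (abs(sum(chromosome_weights) - 1) > 1e-9) {
    stop("chromosome_weights must sum to 1")
  }
  fm <- fragment_model
  stopifnot(all(c("maternal_mean", "maternal_sd", "fetal_mean",
                  "fetal_sd") %in% names(fm)))
  if (fm$maternal_sd <= 0 || fm$fetal_sd <= 0) {
    stop("fragment model SDs must be positive")
  }
  structure(list(seed = as.integer(seed), n_reads = n_reads,
                 trisomy = trisomy, fetal_fraction = fetal_fraction,
                 gc_bias_slope = gc_bias_slope, fragment_model = fm,
                 chromosome_weights = chromosome_weights,
                 genome = genome),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "simulation_config: %s reads, trisomy=%s, ff=%.3f, gc slope=%.2f, seed=%d\n",
    format(x$n_reads, big.mark = ","), x$trisomy, x$fetal_fraction,
    x$gc_bias_slope, x$seed))
  invisible(x)
}

# ground truth attached to every simulated sample
ground_truth <- function(trisomy, fetal_fraction) {
  structure(list(
    trisomy = trisomy, fetal_fraction = fetal_fraction,
    expected_overrepresentation =
      if (trisomy == "none") 1 else 1 + fetal_fraction / 2),
    class = "ground_truth")
}

# per-chromosome (or per-bin) expected sampling probabilities under the
# generator's law, renormalized
simulation_probs <- function(config, with_bins = FALSE) {
  genome <- config$genome
  gc <- genome_gc(genome)
  gc_bar <- mean(gc)
  tri_factor <- function(chrom) {
    ifelse(chrom == config$trisomy & config$trisomy != "none",
           1 + config$fetal_fraction / 2, 1)
  }
  if (!with_bins) {
    w <- config$chromosome_weights[genome$chromosomes$chrom]
    p <- w * (1 + config$gc_bias_slope * (gc - gc_bar)) *
      tri_factor(names(w))
    if (any(p < 0) || sum(p) <= 0) stop("weights not normalizable")
    return(p / sum(p))
  }
  bins <- genome$bins
  if (is.null(bins)) stop("genome has no bins; rebuild with bin_width set")
  # base weight split across a chromosome's bins by bp
  chrlen <- stats::setNames(genome$chromosomes$length,
                            genome$chromosomes$chrom)
  w <- config$chromosome_weights[bins$chrom] *
    (bins$bin_end - bins$bin_start) / chrlen[bins$chrom]
  p <- w * (1 + config$gc_bias_slope * (bins$gc_fraction - gc_bar)) *
    tri_factor(bins$chrom)
  if (any(p < 0) || sum(p) <= 0) stop("weights not normalizable")
  p / sum(p)
}

#' Simulate per-chromosome unique-read counts
#'
#' Draws `n_reads` reads from a multinomial whose per-chromosome
#' probability is proportional to
#' `weight[c] * (1 + gc_bias_slope * (GC(c) - mean GC)) * d(c)`, where
#' the dosage factor `d(c)` is `1 + fetal_fraction/2` for the trisomic
#' chromosome and 1 otherwise, renormalized. With `with_bins = TRUE` the
#' draw is made at bin level (the same law evaluated on per-bin GC) and
#' chromosome counts are the bin sums, giving downstream GC correction
#' something to correct.
#'
#' @param config a [simulation_config()].
#' @param with_bins simulate at bin resolution (requires a binned
#'   genome).
#' @return A list with `counts` (a [chromosome_counts()]) and `truth`
#'   (trisomy label, fetal fraction, expected overrepresentation).
#' @export
simulate_counts <- function(config, with_bins = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  genome <- config$genome
  p <- simulation_probs(config, with_bins = with_bins)
  draw <- with_seed(config$seed, {
    if (config$n_reads == 0) rep(0L, length(p))
    else as.vector(stats::rmultinom(1, size = config$n_reads, prob = p))
  })
  if (!with_bins) {
    counts <- stats::setNames(as.numeric(draw), names(p))
    cc <- chromosome_counts(counts, sample_id = sprintf("sim%d", config$seed))
  } else {
    bins <- genome$bins
    bc <- data.frame(chrom = bins$chrom, bin_start = bins$bin_start,
                     bin_end = bins$bin_end,
                     gc_fraction = bins$gc_fraction,
                     count = as.numeric(draw),
                     stringsAsFactors = FALSE)
    counts <- tapply(bc$count, factor(bc$chrom,
                                      levels = genome$chromosomes$chrom),
                     sum)
    counts <- stats::setNames(as.numeric(counts), genome$chromosomes$chrom)
    cc <- chromosome_counts(counts, sample_id = sprintf("sim%d", config$seed),
                            bin_counts = bc)
  }
  list(counts = cc,
       truth = ground_truth(config$trisomy, config$fetal_fraction))
}

#' Simulate cfDNA fragment lengths
#'
#' Draws `n` fragment lengths from a two-component normal mixture: with
#' probability `fetal_fraction` from the (shorter) fetal component,
#' otherwise from the maternal component. Lengths are truncated to
#' `[50, 400]` bp by rejection and rounded to integer bp.
#'
#' @param config a [simulation_config()].
#' @param n number of fragments (>= 0).
#' @return Integer vector of `n` fragment lengths in bp.
#' @export
simulate_fragments <- function(config, n) {
  stopifnot(inherits(config, "simulation_config"), n >= 0)
  fm <- config$fragment_model
  with_seed(config$seed + 1L, {
    fetal <- stats::runif(n) < config$fetal_fraction
    mu <- ifelse(fetal, fm$fetal_mean, fm$maternal_mean)
    sd <- ifelse(fetal, fm$fetal_sd, fm$maternal_sd)
    len <- stats::rnorm(n, mu, sd)
    bad <- which(len < 50 | len > 400)
    while (length(bad) > 0) {
      len[bad] <- stats::rnorm(length(bad), mu[bad], sd[bad])
      bad <- bad[len[bad] < 50 | len[bad] > 400]
    }
    as.integer(round(len))
  })
}

#' Simulate a labelled cohort of maternal-plasma samples
#'
#' Emits euploid and trisomic samples with per-sample fetal fraction and
#' sequencing depth drawn uniformly from the given ranges, returned in
#' randomized order with ground truth attached. Fully reproducible from
#' `seed`.
#'
#' @param n_euploid,n_t21,n_t18,n_t13 sample counts per class (>= 0).
#' @param ff_range fetal-fraction range, `c(lo, hi)` in `[0, 1]`.
#' @param depth_range unique-read depth range, `c(lo, hi)`.
#' @param seed cohort seed.
#' @param genome a [genome_table()].
#' @param n_fragments fragment lengths sampled per specimen for the
#'   size-ratio statistic (a subsample stands in for the full read set).
#' @param with_bins simulate bin-level counts.
#' @param gc_bias_slope passed to each sample's [simulation_config()].
#' @return List of samples; each has `sample_id`, `counts`
#'   ([chromosome_counts()]), `lengths` and `truth`.
#' @export
simulate_cohort <- function(n_euploid, n_t21, n_t18, n_t13,
                            ff_range = c(0.04, 0.3),
                            depth_range = c(1.5e6, 9e6),
                            seed = 1L,
                            genome = default_genome(bin_width = NULL),
                            n_fragments = 20000L,
                            with_bins = FALSE,
                            gc_bias_slope = 0.3) {
  ns <- c(n_euploid, n_t21, n_t18, n_t13)
  stopifnot(all(ns >= 0), length(ff_range) == 2, length(depth_range) == 2)
  if (ff_range[1] > ff_range[2] || depth_range[1] > depth_range[2]) {
    stop("empty or inverted range")
  }
  total <- sum(ns)
  if (total == 0) return(list())
  labels <- rep(c("none", "chr21", "chr18", "chr13"), times = ns)
  plan <- with_seed(seed, {
    ord <- sample.int(total)
    data.frame(trisomy = labels[ord],
               ff = stats::runif(total, ff_range[1], ff_range[2]),
               depth = round(stats::runif(total, depth_range[1],
                                          depth_range[2])),
               seed = sample.int(2^30, total),
               stringsAsFactors = FALSE)
  })
  lapply(seq_len(total), function(i) {
    cfg <- simulation_config(seed = plan$seed[i], n_reads = plan$depth[i],
                             trisomy = plan$trisomy[i],
                             fetal_fraction = plan$ff[i],
                             gc_bias_slope = gc_bias_slope,
                             genome = genome)
    sim <- simulate_counts(cfg, with_bins = with_bins)
    sim$counts$sample_id <- sprintf("s%03d", i)
    list(sample_id = sprintf("s%03d", i), counts = sim$counts,
         lengths = simulate_fragments(cfg, n_fragments),
         truth = sim$truth)
  })
}

#' Write a cohort manifest TSV
#'
#' @param cohort output of [simulate_cohort()].
#' @param path output TSV (`sample_id`, `truth_label`, `fetal_fraction`).
#' @return `path`, invisibly.
#' @export
write_cohort_manifest <- function(cohort, path) {
  man <- data.frame(
    sample_id = vapply(cohort, `[[`, "", "sample_id"),
    truth_label = vapply(cohort, function(s) {
      if (s$truth$trisomy == "none") "euploid"
      else chrom_to_label(s$truth$trisomy)
    }, ""),
    fetal_fraction = vapply(cohort, function(s) s$truth$fetal_fraction,
                            0),
    stringsAsFactors = FALSE)
  utils::write.table(man, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write aligned reads as a SAM file
#'
#' Emits a syntactically valid single-end SAM (v1.6) with `@HD`/`@SQ`
#' headers from the genome table. Sequence and quality fields are `*`
#' placeholders; the CIGAR is `<length>M` so parsers recover the
#' fragment length from the alignment. Secondary records get flag 0x100.
#'
#' @param chrom,pos,length,mapq parallel vectors describing each read
#'   (1-based leftmost position, fragment length in bp, MAPQ).
#' @param secondary logical vector; `TRUE` marks a secondary alignment.
#' @param path output SAM path.
#' @param genome a [genome_table()]; chromosomes must come from it.
#' @return `path`, invisibly.
#' @export
write_sam <- function(chrom, pos, length, mapq, path, genome,
                      secondary = FALSE) {
  n <- base::length(chrom)
  secondary <- rep_len(secondary, n)
  mapq <- rep_len(mapq, n)
  known <- genome$chromosomes$chrom
  if (!all(chrom %in% known)) {
    stop("unknown chromosome: ",
         paste(unique(setdiff(chrom, known)), collapse = ", "))
  }
  stopifnot(all(pos >= 1), all(length >= 1))
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", known,
                      as.integer(genome$chromosomes$length)))
  flag <- ifelse(secondary, 256L, 0L)
  body <- sprintf("r%06d\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*",
                  seq_len(n), flag, chrom, as.integer(pos),
                  as.integer(mapq), as.integer(length))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Simulate one sample straight to SAM
#'
#' Convenience wrapper: draws per-chromosome counts and fragment lengths
#' from `config`, places reads uniformly at random along each
#' chromosome, optionally contaminates the file with secondary
#' alignments and low-MAPQ records (for unique-read filter testing), and
#' writes the SAM. Returns the generator's own bookkeeping so round-trip
#' tests have an exact oracle.
#'
#' @param config a [simulation_config()] (use modest `n_reads`; one SAM
#'   line per read).
#' @param path output SAM path.
#' @param secondary_fraction fraction of reads duplicated as secondary
#'   alignments (flag 0x100, MAPQ 0).
#' @param low_mapq_fraction fraction of primary reads demoted to MAPQ 0
#'   (ambiguous placement; excluded by the default uniqueness filter).
#' @param mapq MAPQ assigned to uniquely mapped reads.
#' @return List: `path`, `unique_counts` (named per-chromosome tally of
#'   reads that pass the uniqueness filter), `unique_lengths`, `truth`.
#' @export
simulate_sam <- function(config, path, secondary_fraction = 0,
                         low_mapq_fraction = 0, mapq = 40L) {
  sim <- simulate_counts(config)
  counts <- sim$counts$counts
  n <- sum(counts)
  chrom <- rep(names(counts), times = counts)
  lens <- simulate_fragments(config, n)
  chrlen <- stats::setNames(config$genome$chromosomes$length,
                            config$genome$chromosomes$chrom)
  extra <- with_seed(config$seed + 2L, {
    pos <- 1L + floor(stats::runif(n) * pmax(chrlen[chrom] - lens, 1))
    low <- stats::runif(n) < low_mapq_fraction
    sec <- stats::runif(n) < secondary_fraction
    list(pos = pos, low = low, sec = sec)
  })
  read_mapq <- ifelse(extra$low, 0L, as.integer(mapq))
  # secondary copies re-report the same read at its own position
  sec_idx <- which(extra$sec)
  all_chrom <- c(chrom, chrom[sec_idx])
  all_pos <- c(extra$pos, extra$pos[sec_idx])
  all_len <- c(lens, lens[sec_idx])
  all_mapq <- c(read_mapq, rep(0L, length(sec_idx)))
  all_sec <- c(rep(FALSE, n), rep(TRUE, length(sec_idx)))
  write_sam(all_chrom, all_pos, all_len, all_mapq, path, config$genome,
            secondary = all_sec)
  keep <- !extra$low
  uc <- tapply(rep(1, sum(keep)),
               factor(chrom[keep], levels = names(counts)), sum)
  uc[is.na(uc)] <- 0
  list(path = path,
       unique_counts = stats::setNames(as.numeric(uc), names(counts)),
       unique_lengths = lens[keep],
       truth = sim$truth)
}
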