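make_panel <- function(chroms, mean, sd, corr_mean = mean,
                       corr_sd = sd, gc_model = "none", n = 2) {
  structure(list(chromosomes = chroms,
                 raw_mean = stats::setNames(mean, chroms),
                 raw_sd = stats::setNames(sd, chroms),
                 corr_mean = stats::setNames(corr_mean, chroms),
                 corr_sd = stats::setNames(corr_sd, chroms),
                 n_reference = n, gc_model = gc_model),
            class = "reference_panel")
}

test_that("percent representation is count share on the percent scale", {
  x <- cc(chr21 = 13, chr1 = 987)
  expect_equal(percent_representation(x, "chr21"), 1.3)
  expect_error(percent_representation(x, "chr7"), "not in the included set")
  expect_error(percent_representation(cc(chr1 = 0), "chr1"), "zero total")
  # shares sum to exactly 100
  sim <- simulate_counts(simulation_config(seed = 2, n_reads = 1e5))$counts
  expect_equal(sum(vapply(names(sim$counts), percent_representation,
                          0, counts = sim)), 100)
})

test_that("GC correction is the identity when there is nothing to correct", {
  # all bins share one GC value -> single stratum -> identity
  g <- toy_genome(bin_width = 5e4)
  bins <- g$bins
  bins$gc_fraction <- 0.41
  set.seed(6)
  bins$count <- rpois(nrow(bins), 50)
  counts <- tapply(bins$count, factor(bins$chrom,
                                      levels = g$chromosomes$chrom), sum)
  x <- chromosome_counts(stats::setNames(as.numeric(counts),
                                         g$chromosomes$chrom),
                         bin_counts = bins)
  corr <- gc_correct(x, model = "strata")
  expect_equal(corr$counts, x$counts)

  # unbiased simulation: per-chromosome relative change < 1%
  cfg <- simulation_config(seed = 12, n_reads = 5e5, gc_bias_slope = 0,
                           genome = default_genome(bin_width = 1e6))
  sim <- simulate_counts(cfg, with_bins = TRUE)$counts
  corr2 <- gc_correct(sim)
  rel <- abs(corr2$counts - sim$counts) / pmax(sim$counts, 1)
  expect_true(all(rel < 0.01))
})

test_that("GC correction pulls biased representation toward base weights", {
  g <- default_genome(bin_width = 1e6)
  w <- chromosome_weights(g)
  # chr19 is the most GC-extreme chromosome in the table
  devs <- vapply(1:20, function(i) {
    cfg <- simulation_config(seed = 3000 + i, n_reads = 1e6,
                             gc_bias_slope = 0.8, genome = g)
    sim <- simulate_counts(cfg, with_bins = TRUE)$counts
    corr <- gc_correct(sim)
    c(raw = abs(100 * sim$counts[["chr19"]] / sim$total_unique -
                  100 * w[["chr19"]]),
      corr = abs(100 * corr$counts[["chr19"]] / corr$total_unique -
                   100 * w[["chr19"]]))
  }, c(raw = 0, corr = 0))
  expect_lt(mean(devs["corr", ]), mean(devs["raw", ]))
})

test_that("loess and linear trend models also remove a linear GC bias", {
  cfg <- simulation_config(seed = 44, n_reads = 1e6, gc_bias_slope = 0.8,
                           genome = default_genome(bin_width = 1e6))
  sim <- simulate_counts(cfg, with_bins = TRUE)$counts
  w19 <- 100 * chromosome_weights(cfg$genome)[["chr19"]]
  raw_dev <- abs(100 * sim$counts[["chr19"]] / sim$total_unique - w19)
  for (m in c("loess", "linear")) {
    corr <- gc_correct(sim, model = m)
    expect_lt(abs(100 * corr$counts[["chr19"]] / corr$total_unique - w19),
              raw_dev)
  }
  expect_error(gc_correct(cc(chr1 = 100)), "bin_counts required")
  few <- chromosome_counts(
    c(chr1 = 5),
    bin_counts = data.frame(chrom = "chr1", bin_start = 0, bin_end = 10,
                            gc_fraction = 0.4, count = 5))
  expect_error(gc_correct(few), "insufficient")
})

test_that("the reference panel summarizes %GR with n-1 SDs and warns when tiny", {
  a <- cc(chr21 = 12, chr1 = 988)   # %GR 1.2
  b <- cc(chr21 = 14, chr1 = 986)   # %GR 1.4
  expect_warning(panel <- build_reference(list(a, b)), "fragile")
  expect_equal(unname(panel$raw_mean["chr21"]), 1.3)
  expect_equal(unname(panel$raw_sd["chr21"]), sd(c(1.2, 1.4)))
  expect_equal(unname(panel$raw_sd["chr21"]), abs(1.2 - 1.4) / sqrt(2))

  # identical samples: SD 0, z undefined downstream
  expect_warning(degen <- build_reference(list(a, a)))
  expect_equal(unname(degen$raw_sd["chr21"]), 0)
  expect_error(z_score(1.3, degen, "chr21"), "undefined")
  expect_error(build_reference(list(a)))
})

test_that("panel moments match the generator expectation on simulated euploids", {
  g <- default_genome(bin_width = NULL)
  refs <- lapply(1:50, function(i)
    simulate_counts(simulation_config(seed = 4000 + i, n_reads = 1e6,
                                      gc_bias_slope = 0))$counts)
  panel <- build_reference(refs, gc_model = "none")
  w21 <- 100 * chromosome_weights(g)[["chr21"]]
  se <- 100 * sqrt(w21 / 100 * (1 - w21 / 100) / 1e6) / sqrt(50)
  expect_lt(abs(panel$raw_mean[["chr21"]] - w21), 3 * se)
})

test_that("z, TR and FGR implement their defining arithmetic", {
  panel <- make_panel(c("chr13", "chr18", "chr21"),
                      mean = c(3.8, 2.5, 1.30), sd = c(0.02, 0.02, 0.01))
  expect_equal(z_score(1.30, panel, "chr21"), 0)
  expect_equal(z_score(1.33, panel, "chr21"), 3.0)
  expect_equal(trisomy_ratio(1.30, panel, "chr21"), 1.0)
  expect_equal(trisomy_ratio(1.43, panel, "chr21"), 1.1)
  expect_equal(fgr(cc(chr21 = 13, chr1 = 987), panel, "chr21"), 1.3)
  # affine invariance of z
  shifted <- make_panel(c("chr13", "chr18", "chr21"),
                        mean = c(3.8, 2.5, 1.30) + 5,
                        sd = c(0.02, 0.02, 0.01))
  expect_equal(z_score(1.33 + 5, shifted, "chr21"),
               z_score(1.33, panel, "chr21"))
})

test_that("a reference sample scored against its own panel sits at the null", {
  a <- cc(chr13 = 38, chr18 = 24, chr21 = 12, chr1 = 926)
  b <- cc(chr13 = 40, chr18 = 26, chr21 = 14, chr1 = 920)
  mid <- cc(chr13 = 39, chr18 = 25, chr21 = 13, chr1 = 923)
  expect_warning(panel <- build_reference(list(a, b)))
  ss <- score_sample(mid, panel)
  expect_equal(ss$scores$z, rep(0, 3), tolerance = 1e-10)
  expect_equal(ss$scores$tr, rep(1, 3), tolerance = 1e-10)
  # deterministic
  expect_identical(ss, score_sample(mid, panel))
})

test_that("the affected chromosome dominates the z-scores under trisomy", {
  refs <- lapply(1:20, function(i)
    simulate_counts(simulation_config(seed = 5000 + i, n_reads = 1e6,
                                      gc_bias_slope = 0))$counts)
  panel <- build_reference(refs, gc_model = "none")
  wins <- vapply(1:100, function(i) {
    cfg <- simulation_config(seed = 6000 + i, n_reads = 1e6,
                             trisomy = "chr18", fetal_fraction = 0.15,
                             gc_bias_slope = 0)
    ss <- score_sample(simulate_counts(cfg)$counts, panel)
    z <- stats::setNames(ss$scores$z, ss$scores$chrom)
    z["chr18"] > z["chr13"] && z["chr18"] > z["chr21"]
  }, TRUE)
  expect_gte(sum(wins), 95)
})

test_that("TR dosage recovery: 2(TR-1) estimates the fetal fraction", {
  refs <- lapply(1:20, function(i)
    simulate_counts(simulation_config(seed = 7000 + i, n_reads = 2e6,
                                      gc_bias_slope = 0))$counts)
  panel <- build_reference(refs, gc_model = "none")
  tr <- vapply(1:40, function(i) {
    cfg <- simulation_config(seed = 7100 + i, n_reads = 2e6,
                             trisomy = "chr21", fetal_fraction = 0.2,
                             gc_bias_slope = 0)
    ss <- score_sample(simulate_counts(cfg)$counts, panel)
    ss$scores$tr[ss$scores$chrom == "chr21"]
  }, 0)
  expect_lt(abs(2 * (mean(tr) - 1) - 0.2), 0.01)
})

test_that("panels survive a JSON round trip", {
  a <- cc(chr21 = 12, chr1 = 988)
  b <- cc(chr21 = 14, chr1 = 986)
  expect_warning(panel <- build_reference(list(a, b)))
  tf <- withr::local_tempfile(fileext = ".json")
  write_panel_json(panel, tf)
  back <- read_panel_json(tf)
  expect_equal(back$raw_mean, panel$raw_mean)
  expect_equal(back$raw_sd, panel$raw_sd)
  expect_equal(back$n_reference, panel$n_reference)
})
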