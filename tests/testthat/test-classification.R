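test_that("perfectly separated scores give J = 1 with an interior cutoff", {
  scores <- c(0.1, 0.2, 0.3, 1.1, 1.2)
  labels <- c(FALSE, FALSE, FALSE, TRUE, TRUE)
  r <- roc_cutoff(scores, labels)
  expect_equal(r$j, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_gt(r$cutoff, 0.3)
  expect_lt(r$cutoff, 1.1)
})

test_that("the midpoint rule lands between adjacent classes", {
  r <- roc_cutoff(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r$cutoff, 2.5)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_error(roc_cutoff(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("ties on J resolve toward higher specificity, then higher cutoff", {
  # inverted data: every candidate has J <= 0, maximum J = 0 is tied at
  # the extremes; the rule must choose the highest cutoff (call nothing)
  r <- roc_cutoff(c(1, 2), c(TRUE, FALSE))
  expect_equal(r$j, 0)
  expect_equal(r$specificity, 1)
  expect_equal(r$cutoff, Inf)
})

test_that("the sweep matches exhaustive enumeration on random instances", {
  set.seed(17)
  for (i in 1:200) {
    n <- sample(5:80, 1)
    scores <- round(rnorm(n), sample(0:2, 1))  # rounding induces ties
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    expect_equal(roc_cutoff(scores, labels)$j,
                 brute_force_max_j(scores, labels))
  }
})

test_that("the sweep agrees with pROC's empirical Youden optimum", {
  skip_if_not_installed("pROC")
  set.seed(23)
  for (i in 1:20) {
    n <- 60
    labels <- c(rep(TRUE, 20), rep(FALSE, 40))
    scores <- rnorm(n, mean = ifelse(labels, 1, 0))
    r <- roc_cutoff(scores, labels)
    pr <- pROC::roc(labels, scores, direction = "<", quiet = TRUE)
    best <- pROC::coords(pr, "best", best.method = "youden",
                         transpose = FALSE)
    expect_equal(r$j, max(best$sensitivity + best$specificity - 1),
                 tolerance = 1e-12)
  }
})

# a synthetic score table with controllable separation per score;
# n_tri cases of each trisomy so all three chromosomes calibrate
fake_scores <- function(n_eu, n_tri, sep = c(z = 3, tr = 3, fgr = 3),
                        seed = 1) {
  set.seed(seed)
  lab <- c(rep("euploid", n_eu),
           rep(c("trisomy13", "trisomy18", "trisomy21"), each = n_tri))
  ids <- sprintf("s%03d", seq_along(lab))
  chroms <- c("chr13", "chr18", "chr21")
  rows <- do.call(rbind, lapply(seq_along(ids), function(i) {
    bump <- as.numeric(chroms == sub("^trisomy", "chr", lab[i]))
    data.frame(sample_id = ids[i], chrom = chroms,
               z = rnorm(3) + bump * sep["z"],
               tr = 1 + 0.02 * rnorm(3) + bump * 0.02 * sep["tr"],
               fgr = 1.3 + 0.013 * rnorm(3) + bump * 0.013 * sep["fgr"],
               size_ratio = 1.5, total_unique = 5e6,
               stringsAsFactors = FALSE)
  }))
  list(scores = rows,
       truth = data.frame(sample_id = ids, truth_label = lab,
                          stringsAsFactors = FALSE))
}

test_that("calibration is deterministic and prefers informative scores", {
  fx <- fake_scores(40, 10, sep = c(z = 0, tr = 4, fgr = 4), seed = 2)
  cs1 <- calibrate(fx$scores, fx$truth)
  cs2 <- calibrate(fx$scores, fx$truth)
  expect_identical(cs1, cs2)
  # z carries no signal here: the z-only rule can never beat TR alone
  errs <- cs1$provenance$rule_errors
  expect_gte(errs[["Z"]], errs[["TR"]])
  expect_false(cs1$rule == "Z")
})

test_that("on well-separated cohorts the conjunction rule wins or ties", {
  fx <- fake_scores(60, 15, sep = c(z = 5, tr = 5, fgr = 5), seed = 3)
  cs <- calibrate(fx$scores, fx$truth)
  errs <- cs$provenance$rule_errors
  expect_lte(errs[["TR_AND_FGR"]], min(errs[c("Z", "TR", "FGR")]))
  expect_equal(cs$rule, "TR_AND_FGR")
})

mini_cutoffs <- function(rule = "TR_AND_FGR") {
  structure(list(
    cutoffs = do.call(rbind, lapply(c("chr13", "chr18", "chr21"),
      function(ch) data.frame(chrom = ch, score = c("z", "tr", "fgr"),
                              cutoff = c(3, 1.05, 1.35),
                              sensitivity = 1, specificity = 1,
                              stringsAsFactors = FALSE))),
    rule = rule, provenance = list()), class = "cutoff_set")
}

mini_score_set <- function(z, tr, fgr, id = "s") {
  structure(list(sample_id = id,
                 scores = data.frame(chrom = c("chr13", "chr18", "chr21"),
                                     z = z, tr = tr, fgr = fgr,
                                     stringsAsFactors = FALSE),
                 size_ratio = 1.5, total_unique = 5e6),
            class = "score_set")
}

test_that("classification implements the conjunction rule with strict cuts", {
  ct <- mini_cutoffs()
  # everything below the cut-offs
  expect_equal(classify(mini_score_set(c(0, 0, 0), c(1, 1, 1),
                                       c(1.3, 1.3, 1.3)), ct)$status,
               "euploid")
  # TR and FGR above for chr21 only
  call <- classify(mini_score_set(c(0, 0, 1), c(1, 1, 1.10),
                                  c(1.3, 1.3, 1.43)), ct)
  expect_equal(call$status, "trisomy21")
  expect_equal(call$positives, "chr21")
  # conjunction unsatisfied: TR above, FGR below
  expect_equal(classify(mini_score_set(c(0, 4, 0), c(1, 1.10, 1),
                                       c(1.3, 1.30, 1.3)), ct)$status,
               "euploid")
  # scores exactly at the cut-off do not fire (strict >)
  expect_equal(classify(mini_score_set(c(3, 3, 3), c(1.05, 1.05, 1.05),
                                       c(1.35, 1.35, 1.35)), ct)$status,
               "euploid")
})

test_that("gate failures pre-empt scoring", {
  ct <- mini_cutoffs()
  ss <- mini_score_set(c(0, 0, 9), c(1, 1, 1.2), c(1.3, 1.3, 1.5))
  expect_equal(classify(ss, ct, informative = FALSE)$status,
               "noninformative")
  expect_equal(classify(ss, ct, size_gate = FALSE)$status,
               "noninformative")
  expect_equal(classify(ss, ct, size_gate = NA)$status, "non_evaluable")
})

test_that("multiple positives arbitrate to the largest TR, keeping the set", {
  ct <- mini_cutoffs()
  call <- classify(mini_score_set(c(5, 5, 5), c(1.08, 1.12, 1.10),
                                  c(1.45, 1.45, 1.45)), ct)
  expect_equal(call$status, "trisomy18")
  expect_setequal(call$positives, c("chr13", "chr18", "chr21"))
})

test_that("raising any cutoff never converts a negative into a positive", {
  set.seed(41)
  ct <- mini_cutoffs()
  for (i in 1:50) {
    ss <- mini_score_set(rnorm(3, 2, 2), 1 + rnorm(3, 0.03, 0.05),
                         1.3 + rnorm(3, 0.04, 0.06))
    before <- classify(ss, ct)
    raised <- ct
    k <- sample(nrow(raised$cutoffs), 1)
    raised$cutoffs$cutoff[k] <- raised$cutoffs$cutoff[k] + runif(1, 0, 1)
    after <- classify(ss, raised)
    expect_true(all(after$positives %in% before$positives))
    if (before$status == "euploid") expect_equal(after$status, "euploid")
  }
})

test_that("cut-off sets survive a JSON round trip", {
  fx <- fake_scores(30, 8, seed = 5)
  cs <- calibrate(fx$scores, fx$truth)
  tf <- withr::local_tempfile(fileext = ".json")
  write_cutoffs_json(cs, tf)
  back <- read_cutoffs_json(tf)
  expect_equal(back$rule, cs$rule)
  expect_equal(back$cutoffs$cutoff, cs$cutoffs$cutoff)
})

test_that("calibrate-then-classify recovers favorable synthetic cohorts", {
  # 200-sample cohorts at ff >= 0.1 and depth >= 5M: the regime where
  # the screen should be essentially perfect
  tot <- matrix(0, 2, 3, dimnames = list(c("tp", "truth"),
                                         c("chr13", "chr18", "chr21")))
  fp <- 0; n_eu <- 0
  for (s in 1:10) {
    coh <- simulate_cohort(130, 30, 22, 18, ff_range = c(0.1, 0.25),
                           depth_range = c(5e6, 9e6), seed = 100 + s,
                           n_fragments = 2000, gc_bias_slope = 0)
    res <- run_pipeline(coh)
    per <- res$summary$per_chromosome
    tot["tp", per$chrom] <- tot["tp", per$chrom] + per$tp
    tot["truth", per$chrom] <- tot["truth", per$chrom] + per$tp + per$fn
    fp <- fp + res$summary$overall$n_false_positive
    n_eu <- n_eu + res$summary$overall$n_euploid
  }
  sens <- tot["tp", ] / tot["truth", ]
  expect_true(all(sens >= 0.95))
  expect_gte((n_eu - fp) / n_eu, 0.95)
})
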