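# niptscreen

Noninvasive prenatal screening for fetal trisomies 13, 18 and 21 from
shallow whole-genome sequencing of maternal plasma cell-free DNA
(cfDNA), for bioinformaticians building or validating counting-based
NIPT pipelines.

Maternal plasma cfDNA is a mixture of maternal and placental DNA. A
fetal trisomy of chromosome *c* adds half an extra copy of *c* to the
placental compartment, so at fetal fraction *f* the expected share of
reads from *c* rises by the dosage factor **1 + f/2**. `niptscreen`
turns that signal into calls:

1. **Counting** — read SAM/BAM, keep uniquely mapped reads (primary,
   mapped, MAPQ ≥ threshold), tally per chromosome and per 50 kb bin.
2. **Gating** — a sample needs strictly more than 1 M unique reads, and
   a short/long fragment-size ratio strictly above 0.84 (the
   sequencing-only proxy for adequate fetal fraction: fetal fragments
   are shorter).
3. **Scoring** — per target chromosome, against a euploid reference
   panel: the **Z-score** `z = (%GR − μ_ref)/σ_ref` on raw percent
   genomic representation; the **Trisomy Ratio**
   `TR = %GR_corrected / μ_ref,corrected` (≈ 1 euploid, 1 + f/2
   trisomic); and the **FGR**, the GC-corrected %GR itself. GC
   correction rescales binned counts by the fitted count-versus-GC
   trend.
4. **Calibration & classification** — per-score cut-offs maximizing
   Youden's J on a labelled cohort ROC; the default combination rule
   calls a chromosome when **TR and FGR both** exceed their cut-offs
   (strictly).
5. **Evaluation** — NIPT confusion bookkeeping in which a trisomic
   sample called for the wrong chromosome counts as detected overall
   but as a per-chromosome false negative and false positive.

Because no public dataset accompanies this design, the package includes
a seeded synthetic generator (multinomial chromosome counts with linear
GC bias and the dosage factor; mixture fragment lengths 143/166 bp;
SAM output with secondary/low-MAPQ contamination) with ground truth
attached, so every stage is testable end to end.

## Worked example

Simulate a favorable 200-sample cohort (fetal fraction 0.10–0.25,
5–9 M unique reads) and run the whole screen:

```r
library(niptscreen)
cohort <- simulate_cohort(n_euploid = 130, n_t21 = 30, n_t18 = 22,
                          n_t13 = 18, ff_range = c(0.1, 0.25),
                          depth_range = c(5e6, 9e6), seed = 7,
                          gc_bias_slope = 0)
res <- run_pipeline(cohort)
res$cutoffs$rule
#> [1] "TR_AND_FGR"
res$summary
#> confusion_summary: 200 evaluated (0 excluded)
#>   overall: sensitivity 100.00%, specificity 100.00% (70/70 detected, 0 FP, 0 FN, 0 wrong-chromosome)
#>  chrom tp fn fp  tn sensitivity specificity
#>  chr13 18  0  0 182         100         100
#>  chr18 22  0  0 178         100         100
#>  chr21 30  0  0 170         100         100
```

The rule that wins calibration is the TR-and-FGR conjunction, and in
this easy regime (ample fetal fraction and depth) the screen is
perfect: all 70 trisomic samples are called for the right chromosome
and no euploid sample is flagged. Scoring a single euploid sample shows
the statistics at their null values:

```r
score_sample(cohort[[1]]$counts, res$panel, lengths = cohort[[1]]$lengths)
#> score_set 's001' (6,848,861 unique reads, size ratio 2.392)
#>  chrom          z        tr      fgr
#>  chr13 -0.7071068 0.9977902 3.793843
#>  chr18  0.7071068 1.0006050 2.567478
#>  chr21  0.7071068 1.0022596 1.587446
```

TR sits within a few tenths of a percent of 1 (euploid expectation),
and FGR equals each chromosome's percent share of reads — chr21 carries
about 1.59% of the genome's sequence, hence of the unique reads. A
trisomy 21 sample at fetal fraction 0.2 would instead show
TR(chr21) ≈ 1.10, i.e. `2 × (TR − 1)` recovers the fetal fraction.

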