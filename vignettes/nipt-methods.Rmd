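---
title: "Statistical methods for cfDNA aneuploidy screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for cfDNA aneuploidy screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(niptscreen)
```

## The screening problem

Maternal plasma carries cell-free DNA (cfDNA) from both the mother and
the placenta. The placental ("fetal") component — typically 3–20% of
plasma cfDNA, rising with gestational age — reflects the fetal
karyotype. If the fetus is trisomic for chromosome $c$, the placental
compartment contributes three copies of $c$ rather than two, so at
fetal fraction $f$ the relative abundance of reads from $c$ rises by a
factor of

$$ 1 + \frac{f}{2}, $$

the basic dosage identity the whole screen rests on. At $f = 0.10$ this
is a 5% excess — detectable only because shallow whole-genome
sequencing counts hundreds of thousands of reads per chromosome, making
the binomial noise on a chromosome's share of reads far smaller than
the dosage signal.

`niptscreen` implements the full decision pipeline used by clinical
validation studies of this design: count uniquely mapped reads per
chromosome from SAM/BAM, gate samples on read depth and on a
fragment-size proxy for fetal fraction, compute three
chromosome-representation statistics against a euploid reference panel,
calibrate per-score cut-offs by ROC analysis, classify, and score the
cohort-level confusion bookkeeping. Because no clinical data accompany
the design it emulates, the package also ships a seeded synthetic
generator that reproduces the statistical structure every downstream
stage assumes, with known ground truth.

## Chromosome representation and the three scores

For one sample, let $n_c$ be its unique-read count on chromosome $c$
and $N = \sum_c n_c$ the total over the included chromosomes
(chr1–chr22 and chrX; chrY is excluded because plasma is overwhelmingly
maternal in origin). The percent genomic representation is

$$ \%GR_c = 100 \, \frac{n_c}{N}, $$

which sums to exactly 100 over the included set. All three statistics
compare a sample's $\%GR_c$ for $c \in \{13, 18, 21\}$ against a panel
of euploid pregnancies:

* **Z-score** — $z_c = (\%GR_c - \mu_c) / \sigma_c$, with $\mu_c,
  \sigma_c$ the panel mean and SD ($n-1$ denominator) of *raw* %GR.
  Deliberately GC-blind: it is the baseline the two corrected scores
  are contrasted with.
* **Trisomy Ratio (TR)** — GC-corrected $\%GR_c$ divided by the panel's
  GC-corrected mean. Euploid expectation 1; trisomy expectation
  $1 + f/2$, so $2(TR - 1)$ doubles as a chromosome-dosage estimate of
  the fetal fraction.
* **Fractional Genomic Representation (FGR)** — the GC-corrected
  $\%GR_c$ itself, on the percent scale, compared downstream to its own
  ROC cut-off rather than normalized to the panel.

A degenerate panel (SD of zero, as happens with two identical reference
samples) makes the Z-score undefined; the package raises an error
rather than returning $\pm\infty$. Panels of fewer than ten samples
trigger a fragility warning but remain usable, since minimal
two-reference panels are a real (if statistically brittle) clinical
design.

## GC correction

Sequencing yield varies smoothly with local GC content, inflating the
variance of %GR and biasing GC-extreme chromosomes (chr19 and chr22 at
the high end, chr4 and chr13 at the low end). `gc_correct()` works on
fixed-width bins (default 50 kb, configurable): each bin's count is
rescaled by $\bar m / m(g)$, where $m(g)$ is the fitted count-versus-GC
trend and $\bar m$ the global mean bin count, then corrected chromosome
counts are the corrected bin sums.

The default trend estimator stratifies bins into GC strata of width
0.005 (0.5% GC) and uses stratum means — parameter-light, and exactly
the identity when counts carry no GC trend (all bins in one stratum
share one factor of 1). LOESS and straight-line alternatives are
selectable; all three remove a linear bias in simulation. The trend is
fitted on full-width bins only, so short terminal bins are corrected
but never distort the fit; strata with no usable bins borrow the
nearest nonempty stratum's factor. At least 20 nonzero bins are
required — below that the trend is unidentifiable and the function
refuses rather than guessing.

## Fetal fraction from fragment size

Placental cfDNA fragments run shorter than maternal ones (modal lengths
near 143 bp versus 166 bp), so the ratio of short-window to long-window
fragment counts rises monotonically with fetal fraction.
`size_ratio()` counts fragments in an inclusive short window (default
100–150 bp) and long window (default 163–169 bp, bracketing the
maternal mode); both windows are configuration, not constants. A sample
whose ratio is not strictly greater than 0.84 fails the fetal-fraction
gate and is reported noninformative; a sample with an empty long window
is *non-evaluable*, a distinct state, so downstream reporting can
distinguish "too little fetal DNA" from "no measurement". The positive
linear ratio-to-fraction calibration (`fit_size_calibration()`) is
provided for interpretation, but only the gate feeds the classifier.

The second gate is depth: a sample is informative only with strictly
more than one million unique reads (configurable; some published
pipelines require 3.5 M). Both gates are strict inequalities — a sample
exactly at either boundary fails.

## Calibration and classification

Per chromosome and per score, `roc_cutoff()` sweeps every threshold
candidate — midpoints between adjacent sorted unique score values plus
$\pm\infty$ — and picks the cut-off maximizing Youden's
$J = \text{sensitivity} + \text{specificity} - 1$, with a sample
positive when its score is strictly greater than the cut-off. Ties on
$J$ resolve toward higher specificity, then the higher cut-off: in a
screening test, indifference should default to calling fewer positives.
The sweep is checked in the test suite against exhaustive enumeration
and against an independent ROC implementation (pROC).

Cases for each chromosome's ROC are that chromosome's trisomic samples;
controls are the euploid samples. `calibrate()` then evaluates all
eight score-combination rules on the calibration cohort and records the
one minimizing misclassified samples (false positives plus false
negatives), with ties resolving to **TR AND FGR** — both GC-corrected
scores above cut-off at the same time — since no single score is
accurate enough alone. Calibrating and evaluating on the same cohort
(resubstitution) mirrors small clinical validation series;
`run_pipeline()` also accepts externally supplied cut-offs, which is
the statistically sound held-out design.

`classify()` applies the rule per chromosome. Zero firing chromosomes
give `euploid`; exactly one gives that trisomy; when several fire the
chromosome with the largest TR is called — TR is the score with a
direct dosage interpretation, so the largest TR marks the strongest
chromosome-specific signal — and the full positives set is retained for
audit. Gate failures pre-empt scoring entirely.

## Cohort evaluation semantics

`evaluate()` implements the error taxonomy of NIPT validation studies,
where one sample can count differently at the overall and
per-chromosome levels:

* **Overall sensitivity** counts a trisomic sample as detected when it
  is called trisomic for *any* chromosome. A trisomy 18 sample called
  trisomy 21 ("incorrectly identified") is detected overall.
* **Per-chromosome metrics** count only exact matches: that same sample
  is a chr18 false negative *and* a chr21 false positive.
* **Per-chromosome specificity** uses as denominator every sample whose
  truth is not that trisomy — euploid and other trisomies alike.
* **Overall specificity** is the fraction of euploid samples not called
  trisomic for anything.

Noninformative and non-evaluable samples are excluded from all metrics
and reported as an exclusion count. Percentages are rounded half-up to
two decimals, the reporting convention of the studies this bookkeeping
reproduces. The test suite verifies that the published two-mapper
validation arms' complete metric sets (overall 98.28%/93.08% and
100%/96.86%, with all per-trisomy values) follow exactly from their
enumerated outcome tables under these conventions — which is also the
only convention set consistent with every printed value.

## The synthetic generator

No public dataset accompanies the clinical design, so the generator is
a first-class module with ground truth, emulating exactly the
statistical structure the pipeline consumes:

* **Counts** — a multinomial over chromosomes (or bins) with
  probability proportional to
  $w_c \,(1 + s\,(g_c - \bar g))\,d_c$: length-proportional base
  weights $w_c$ (hg19), a linear GC bias with slope $s$ (default 0.3,
  a moderate single-digit-percent distortion) around the unweighted
  mean chromosome GC $\bar g$, and the dosage factor
  $d_c = 1 + f/2$ on the trisomic chromosome.
* **Fragment lengths** — a two-component normal mixture, fetal
  143 ± 20 bp with probability $f$, maternal 166 ± 20 bp otherwise,
  truncated to [50, 400] bp by rejection and rounded to integer bp.
  The SDs are chosen so a cohort's overall mean read length sits in the
  mid-140s to low-160s, matching shallow single-end cfDNA sequencing.
* **Cohorts** — per-sample fetal fraction and depth drawn uniformly
  from configurable ranges (defaults 0.04–0.30 and 1.5–9 M unique
  reads, a realistic clinical spread around a multi-million-read mean),
  returned in randomized order, fully reproducible from one seed. Each
  specimen carries a 20,000-fragment length subsample: the size-ratio
  statistic is a ratio of window counts and needs only a sample, not
  one length per read.
* **SAM output** — syntactically valid single-end SAM v1.6 with
  placeholder bases, uniform read placement, and configurable fractions
  of secondary and MAPQ-0 records, so the uniqueness filter can be
  tested end-to-end against the generator's own bookkeeping.

Per-bin GC in the bundled genome table is synthesized deterministically
(chromosome GC plus a bounded sinusoidal modulation of amplitude 0.04)
because real binned GC tracks require the reference sequence itself;
what GC correction needs — a reproducible covariate under which bins of
like GC behave alike — is preserved.

What the generator does **not** emulate: mappability structure, PCR
duplicates, base-call errors, within-genome coverage waves beyond the
linear GC law, maternal copy-number variants, or confined placental
mosaicism. Passing tests therefore demonstrate that the statistical
machinery is correct under the stated model, not that clinical
performance on real plasma would match; the published clinical
sensitivities and specificities enter the package only as evaluation
semantics (worked examples for `evaluate()`), never as pipeline
outputs.

## Numerical and design choices

* "Uniquely mapped" is operationalized as primary, mapped, MAPQ ≥ 1;
  the MAPQ threshold is exposed so tag- or flag-based conventions can
  be emulated. Template length is used for paired records.
* Internal coordinates are 0-based half-open; SAM's 1-based positions
  are converted on read. Bin width defaults to 50 kb.
* The dosage factor enters a renormalized multinomial, so the exact
  expected count ratio for the trisomic chromosome is
  $(1 + f/2)/(1 + w_c f/2)$ — about 1.0983 rather than 1.10 for chr21
  at $f = 0.2$; tests assert the renormalized form where precision
  matters.
* Strict inequalities everywhere a threshold is compared: both gates
  and every score-versus-cutoff comparison.
* All randomness flows through per-call seeds; identical configurations
  give byte-identical outputs, including SAM files.

Simulation-backed tests run at deliberately modest problem sizes —
cohorts of ~200 samples, depths of 1–10 M reads drawn as multinomial
counts rather than per-read records, 10–100 replicates per property —
chosen so the whole suite exercises every closed-form expectation
(dosage recovery to ±0.005 on TR, z null calibration, GC-bias removal)
at comfortable statistical margins while staying quick to run.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
cohort <- simulate_cohort(n_euploid = 130, n_t21 = 30, n_t18 = 22,
                          n_t13 = 18, ff_range = c(0.1, 0.25),
                          depth_range = c(5e6, 9e6), seed = 7,
                          gc_bias_slope = 0)
res <- run_pipeline(cohort)
res$cutoffs$rule      # which combination rule won the calibration
res$summary           # per-chromosome and overall confusion summary
```

## Known limitations

* The reference panel's "normal range" is global, not per-flow-cell;
  batch effects are out of scope.
* Resubstitution calibration overstates accuracy; use external cut-offs
  for honest error estimates.
* No sex-chromosome aneuploidy scoring, no subchromosomal CNV calling,
  no posterior probabilities or confidence intervals.
* The ratio-to-fetal-fraction calibration is linear and unvalidated
  outside the generator's mixture model.
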