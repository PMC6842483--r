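---
title: "Methods: copy-number dosage and differential expression concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number dosage and differential expression concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question and the model

Somatic copy-number variation (CNV) is pervasive in tumors and cancer cell
lines. The working model of this package is a gene-wise dosage effect: for
most genes, mRNA abundance responds approximately linearly to the underlying
DNA copy number, so high-level amplification tends to produce upregulation
and homozygous deletion tends to produce downregulation. The analysis
quantifies that concordance per gene and per cohort, classifies the genes
where it is strongest, and asks whether carrying a concordant event is
associated with overall survival.

The pipeline works on two standard input dialects:

* **GISTIC-style discrete calls**: per (gene, sample) integers on the
  five-level scale -2 (homozygous deletion), -1 (hemizygous deletion),
  0 (neutral), +1 (gain), +2 (high-level amplification).
* **PICNIC-style absolute copy number** plus a per-sample average genome
  ploidy, as produced for cell-line panels. Amplification is called when
  (ploidy <= 2.7 and total copy number >= 5) or (ploidy > 2.7 and total
  copy number >= 9); deletion when (ploidy <= 2.7 and total copy number
  = 0) or (ploidy > 2.7 and total copy number < ploidy - 2.7). These
  thresholds define only amplification and deletion, so the intermediate
  +-1 levels exist only on the GISTIC path.

Only the extreme levels (+-2) count as *variant events* in the tendency
classification; gains and hemizygous losses are retained as regression
abscissae but are deliberately not treated as amplification/deletion
events.

# Diploid-referenced Z-scores

Expression is standardized per gene against the samples that are
copy-number neutral (call 0) *for that gene*:

$$ z_{gs} = \frac{x_{gs} - u_g}{o_g}, $$

where \(u_g\) and \(o_g\) are the mean and standard deviation of the gene's
expression over its diploid reference set. This is the cBioPortal-style
convention: each gene's variant samples are measured in units of that
gene's natural diploid variability. Choices worth stating:

* \(o_g\) uses the sample (n-1) denominator; reference sets can be small
  and the unbiased scale is the convention for this style of Z-score.
* A gene needs at least `min_diploid` (default 3) diploid samples and
  strictly positive reference variance; otherwise all its Z-scores stay
  undefined and the gene is excluded downstream with a recorded reason.
  Imputation is never attempted — a 1-2 sample reference makes \(o_g\)
  meaningless, and imputing call 0 for missing calls would contaminate
  the reference sets.
* Expression values are used as-is (RSEM-like non-negative values). A
  `log2_offset` argument exists for users who prefer log space, but it is
  off by default so the standardization matches the convention above.

A sample is called upregulated when \(z > 2\) and downregulated when
\(z < -2\); both comparisons are strict, so \(z = 2\) exactly is not an
event. The four variation tendencies are the cross of variant status and
DEG status: A&U, A&D, D&U, D&D.

# Concordance statistics

* **Per-gene Spearman rho** between the discrete calls and the Z-scores,
  computed literally as the Pearson correlation of the two midrank vectors
  (average ranks for ties). Undefined below 3 complete pairs or when a rank
  vector is constant.
* **Median-Z linear fit**: for each observed call level, the median Z at
  that level; an unweighted ordinary least-squares line through those
  points (one point per level, regardless of how many samples sit at each
  level), reported with its Pearson r. At least 3 distinct levels are
  required. The same construction pooled over all valid genes gives the
  cohort-level dosage-response fit.
* **Welch's t** compares the pooled Z-scores of amplified versus deleted
  (gene, sample) pairs, with Welch-Satterthwaite degrees of freedom.
  Degenerate inputs are handled explicitly: zero variance in both groups
  yields t = 0, p = 1 when the means agree and a flagged infinite t
  otherwise.

# AUG / DDG identification

Per gene, the concordant events are counted: \(n_{AU}\) and \(n_{DD}\).
The concordance ratio \(n_{AU} / (n_{AU} + n_{DD})\) (and its complement)
measures which direction dominates. A gene is an **AUG**
(amplified-and-upregulated gene) when its AU ratio strictly exceeds 0.5,
its rho strictly exceeds a threshold, and \(n_{AU}\) strictly exceeds a
count threshold; **DDGs** are symmetric. Since the two ratios cannot both
exceed 0.5, no gene can be both.

Thresholds come in two modes:

* **calibrated** (default): the count and rho thresholds are the medians of
  the reference oncogene list (for AUGs) and the reference tumor-suppressor
  list (for DDGs). Medians of even-length lists are means of the two
  central order statistics, which is how half-integer count thresholds
  arise. The package ships generic curated reference lists under
  `inst/extdata/` as configurable stand-ins for real-data use; synthetic
  cohorts carry their own planted reference panels.
* **fixed**: verbatim thresholds (defaults rho > 0.4 and count > 146.5 for
  AUGs, rho > 0.41 and count > 18.5 for DDGs) appropriate for cohorts of
  roughly ten thousand samples; for other cohort sizes the calibrated mode
  is the sensible choice because the count criterion scales with cohort
  size.

Rho enters as the *signed* call-versus-Z correlation for both classes: a
true DDG has positive rho, because deletion accompanied by downregulation
is a positive dosage relationship. Top genes are ranked by their concordant
event count, with ties broken by rho and then gene symbol so the order is
deterministic. The chromosome summary reports, for the union of identified
AUGs and DDGs, the fraction located on each chromosome.

# Survival analysis

For a chosen gene and tendency, samples split into carriers (labelled with
that tendency) and non-carriers; overall survival is compared with the
Kaplan-Meier product-limit estimator and the two-group log-rank test. Both
are implemented directly in the package — the product over event times of
\(1 - d_i/n_i\), and the chi-square with hypergeometric variance — so the
computation is fully inspectable; the test suite cross-checks both against
the survival package on random cohorts. Events precede censorings at tied
times (the standard convention). The gene screen reports raw log-rank
p-values together with Benjamini-Hochberg adjusted ones, labelled
separately.

# What the synthetic cohorts emulate

The generator produces paired call/expression/clinical cohorts with the
structure the analysis assumes:

* Calls are i.i.d. per (gene, sample) from per-gene rates. Background
  defaults: amp 0.02, del 0.005 (amplification events more frequent than
  deletions, emulating selection against deletions), gain 0.05, hemizygous
  loss 0.03. There is deliberately no chromosomal segment correlation:
  every downstream procedure is gene-wise, so segmental structure would add
  nothing the tests could detect.
* Expression of a dosage-sensitive gene is baseline + slope x call + noise,
  floored at 0; insensitive genes (fraction `1 - dosage_fraction`, default
  15%) draw expression independent of their calls. Background slopes are
  N(0.5, 0.15) against noise sd 1, which leaves only a minority of variant
  events crossing the |z| > 2 line — matching the observation that
  concordant events are a modest fraction (roughly 10-30%) of all variant
  copy-number events, while discordant events stay below 1-2%.
* With probability `discord_rate` a variant event's slope contribution is
  sign-flipped, modelling biological discordance of unknown mechanism;
  the rate is a free parameter, not an estimate.
* Planted gene classes: strongly concordant AUG analogues (default 50,
  amp rate 0.2) and DDG analogues (30, del rate 0.15) with strong slopes
  (N(2, 0.25)), plus moderately concordant reference panels (30 oncogene
  analogues at amp rate 0.06, 10 TSG analogues at del rate 0.05). The
  reference genes are truth-labelled AUG/DDG — they genuinely are
  concordant by construction — but they are tracked separately from the
  strongly planted sets, because calibrating on the median of a reference
  list necessarily leaves about half of that list below threshold; the
  recovery benchmarks therefore measure sensitivity on the strongly
  planted sets and count only truth-"neither" genes as false discoveries.
* Absolute copy number and ploidy are generated by inverting the PICNIC
  rules (e.g. an amplification in a near-diploid sample draws total copy
  number >= 5), so a single cohort exercises both input dialects and the
  +-2 calls round-trip exactly.
* Survival times are exponential with the hazard multiplied by
  `survival_hazard_ratio` (default 2) for carriers of the planted survival
  gene's concordant amplification, with independent exponential censoring
  (means 50 and 80 time units) — the simplest model with a known log-rank
  alternative.

What the generator does **not** emulate: genome coordinates and
segment-level CNV, cohort batch structure, expression normalization
artefacts, mixed tumor purity, and any realistic correlation between genes.
Passing tests therefore demonstrate that the statistical machinery is
correct and calibrated under the assumed dosage model, not that real TCGA
or cell-line cohorts would reproduce any particular published value.

# Numerical and design choices

* All DEG/threshold comparisons are strict inequalities, following the
  "more than"/"less than" definitions.
* The ploidy boundary 2.7 belongs to the near-diploid branch; the
  high-ploidy deletion cutoff `ploidy - 2.7` is applied unrounded, exactly
  as specified, including when it exceeds 1.
* Missing calls are "not evaluable", never imputed to neutral.
* Median-level fits are unweighted across levels; duplicating samples
  within a level leaves the fit unchanged (a tested invariant).
* Deterministic tie-breaks everywhere a ranking is produced; the pipeline
  writes an MD5 manifest and reruns reproduce identical checksums.
* Problem sizes used in the shipped studies: the default cohort is 2,000
  genes x 500 samples (recovery and pattern checks), 500 genes x 60
  samples for the Z-score contract, and 1,000 replicates of n = 200 for
  the log-rank null calibration. These sizes give the binomial/Monte-Carlo
  error margins the assertions need while keeping each study in the
  seconds-to-minutes range.

# Known limitations

* The PICNIC path cannot distinguish gains and hemizygous losses, so
  per-gene rho values computed from it use a three-level abscissa.
* Fixed-mode thresholds do not scale with cohort size; calibrated mode
  requires reference genes present in the cohort.
* The log-rank test uses the asymptotic chi-square reference; very small
  carrier groups (a handful of samples) are better served by permutation,
  which is out of scope here.
* Survival screening tests one gene at a time without covariate
  adjustment; no Cox modelling is provided.
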