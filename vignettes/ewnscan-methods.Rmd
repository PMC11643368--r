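---
title: "Scoring non-coding variants for enhancer gain and loss: methods and design"
author: "ewnscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring non-coding variants for enhancer gain and loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ewnscan)
```

## The problem

A large fraction of disease-associated genetic variation is non-coding and is
thought to act by creating or destroying tissue-specific enhancers. Given
two populations with different disease incidence — here, men of African
ancestry (AA), who face substantially higher prostate-cancer risk than men of
European ancestry (EA) — one mechanism-first strategy is:

1. restrict to common non-coding SNPs that are strongly differentiated
   between the populations (top tail of F~ST~),
2. ask a sequence model of tissue-specific enhancer activity whether the
   alternate allele of each SNP would create (*gained*) or destroy (*lost*)
   an enhancer,
3. validate the calls orthogonally (allelic read imbalance at heterozygous
   sites, transcription-factor motif disruption), and
4. aggregate the risk alleles into a polygenic risk score (PRS).

ewnscan implements this pipeline end to end, together with seeded synthetic
generators for every input, so the whole chain is testable without any
external data.

## The enhancer sequence model

The scorer is a 1-D convolutional network over one-hot encoded DNA
(A, C, G, T columns; any other letter becomes the zero vector). Each
convolution block is valid-padding convolution, ReLU, and non-overlapping
max-pooling; the blocks feed a fully connected ReLU layer with dropout and a
single sigmoid unit, so scores live in [0, 1] and larger means more
enhancer-like. Training minimises binary cross-entropy with Adam
(`learning_rate`, default 2e-3 for the reduced preset) and stops early when
validation loss fails to improve for `patience` epochs. All randomness
(initialisation, shuffling, dropout) derives from one integer seed, and the
trainer is single-threaded, so a fit is exactly reproducible.

Two presets are provided:

* `cnn_spec_full()` — five convolution layers with 320, 320, 240, 240 and
  480 kernels and a 180-unit dense layer. This is the geometry appropriate
  for corpora of tens of thousands of real enhancers with a 10:1 negative
  ratio.
* `cnn_spec_reduced()` — one layer of 32 width-12 kernels with *global* max
  pooling and a 32-unit dense layer. This is the desk-scale default used in
  the examples, tests and the bundled evaluation script.

The reduced preset is deliberately not a shrunken copy of the full stack.
With a few thousand training sequences, a positional dense readout over
pooled feature maps has enough freedom to memorise the training set without
learning the motif at all (we observed held-out auROC near chance while
training loss collapsed). Global max pooling makes the readout
translation-invariant — the network can only report *whether and how
strongly* its kernels fire somewhere in the window — which is exactly the
right inductive bias for motif-driven enhancer activity at this data scale.
On planted-motif data the reduced model comes within about 0.01–0.02 auROC
of the optimal detector that scans with the true generative PWM, so little
is left on the table. Max pooling was retained over alternatives after
ablation: coarse positional pooling (4–8 regions) reintroduces the
overfitting, and global *average* pooling — attractive in principle because
it preserves motif multiplicity as a soft count — dilutes the gradient so
much that optimisation never escapes its initial plateau; it remains
available via `pool_type = "avg"`. Early stopping is guarded by a
`min_epochs` floor (15 for the reduced preset) because on small data the
loss sits on a plateau for several epochs before motif discovery, and
patience alone would quit during it.

Strand handling follows the training convention for enhancers, whose
activity is strand-symmetric: reverse complements of the positive training
sequences can be appended (`augment_rc = TRUE`; requires an explicit
validation set so a sequence and its mirror never straddle the split), and
at inference `score_sequences()` averages the forward and
reverse-complement scores by default.

### Activation threshold

Downstream logic needs a binary notion of "active enhancer".
`calibrate_threshold()` scores a negative (background) set and returns the
smallest τ whose empirical false-positive rate is at most the target
(default FPR 0.01), ties broken upward; a sequence is called active when its
score is ≥ τ. The empirical FPR at τ on the calibration set is therefore
≤ the target by construction, which the tests assert exactly. When even the
largest observed score is too permissive, τ is placed just above it (FPR 0).

## The essential window number

A SNP's regulatory effect depends on where it sits inside a putative
enhancer, so the SNP is evaluated under every plausible placement: windows
of the model's input length (default 1000 bp) are centred at offsets
−200, −180, …, +200 bp from the SNP (stride 20), giving 21 windows, each
containing the SNP. For each window both allele versions are scored; the
per-window *delta* is alt − ref.

* an **activation** window has ref score < τ ≤ alt score;
* a **deactivation** window has alt score < τ ≤ ref score;
* the SNP is **gained** if more than 85% of windows have positive delta
  *and* at least 5 windows are activated; **lost** mirrors this; anything
  else is **none**.
* the **essential window number (EWN)** is the activation count for gained
  calls and the deactivation count for lost calls (0–21 at the defaults);
  for `none` the larger of the two counts is reported for diagnostics.

Numerical conventions, chosen once and asserted in tests: zero deltas count
as sign-inconsistent for both directions; the consistency comparison is a
strict inequality (with 21 windows, > 0.85 means at least 18 same-sign
deltas); a score exactly at τ counts as active; windows that would run off
a chromosome end are dropped and the EWN gate stays at an absolute ≥ 5
(conservative — a truncated profile cannot compensate with a lower bar).
SNP positions are 1-based; window arithmetic is 0-based half-open
internally. Only single-nucleotide variants are accepted, and the reference
allele is validated against the genome base, a mismatch being a per-SNP
error that `scan_panel()` collects without aborting the scan.

The window length follows the model input (1 kb). The EWN rule itself is
scorer-agnostic: the test suite drives it both with the trained network and
with a deterministic toy scorer (a logistic function of exact motif-string
counts), and checks exact agreement with an independently coded brute-force
implementation of the rule on random profiles.

## Population prefilter

`fst_hudson()` is the population-level Hudson estimator
\((p_1-p_2)^2 / (p_1(1-p_2) + p_2(1-p_1))\), clamped to [0, 1] and defined
as 0 when both populations are fixed for the same allele. No sample-size
correction is applied because only population frequencies, not genotype
counts, flow through the pipeline. The prefilter keeps SNPs with minor
allele frequency ≥ 5% in either population ("common"), drops SNPs inside
annotated CDS ("non-coding" is read minimally as CDS-exclusion; UTRs,
introns and intergenic sequence are retained), keeps the top 5% of F~ST~
(ties at the cutoff all retained), and assigns *dominance* — which
population has the higher alternate-allele frequency; exact ties are
excluded from both dominance-stratified sets. Alleles follow the EA-major
convention: the EA major allele is the reference, so the alternate allele is
the EA-minor one. GWAS association of called SNP sets is summarised with
`enrichment_ratio_curve()` — the fraction of foreground scores above a
cutoff over the same fraction in the background, with optional foreground
bootstrap CIs; cutoffs where the background fraction is zero are reported
as missing rather than infinite.

## Allelic-imbalance validation

At a heterozygous site of a true gained eSNP the alternate allele should
attract more active-mark reads than the reference allele. With merged read
counts per site, `call_imbalance()` excludes sites with fewer than 6 total
reads, then requires both a directional read-ratio above 1.5 (alt/ref for
gained, ref/alt for lost; a zero denominator with a non-zero numerator
counts as infinite) and a one-sided exact binomial p ≤ 0.01 at null
probability 0.5. The one-sided test matches the directional hypothesis the
model supplies; the null of 0.5 is used as stated, with no mapping-bias
correction (reference-bias corrections and beta-binomial overdispersion are
out of scope — counts are assumed to come from an upstream allele-aware
pileup). Group comparisons use the sample odds ratio and a two-sided Fisher
exact p-value on the 2×2 imbalanced/not table.

## Motif disruption

PWMs are probability matrices with a 0.01 pseudocount log-odds transform
against a uniform background (configurable). Scanning is a plain log-odds
sum at every start position on both strands; positions containing non-ACGT
letters can never be hits. Per-motif hit thresholds are calibrated on
background sequence — dinucleotide-shuffled input via the Altschul–Erickson
algorithm is provided as a seedable generator — as the smallest score whose
background hit density is at most 5 per 10 kb (a budget of 0 places the
threshold strictly above the best background score). SNP-level scanning
uses the 100-bp window centred on the SNP, builds both allele versions, and
counts the SNP as carrying the motif if *either* version has a hit on
either strand, avoiding allelic bias. Enrichment of motif-carrying eSNPs
over non-eSNPs is a one-sided Fisher test per motif (presence/absence per
SNP), Benjamini–Hochberg corrected across motifs at q = 0.05 for reporting.
Per-TF summaries attach the mean EWN of the motif-carrying eSNPs and the
number of distinct target genes under the two-nearest-genes rule
(strand-aware TSS distance, ties broken by genomic order), with the
reporting flag requiring ≥ 15 targets and mean EWN ≥ 7.

## Polygenic risk score

Following the reference procedure exactly, the PRS is fitted by
*multivariate linear regression* of the binary case label on the dosage
matrix (OLS; a logistic fit is available behind `method = "logistic"` for
comparison, but linear is the default for fidelity). The score of an
individual is the intercept plus the weighted count of alternate alleles.
A rank-deficient design falls back to a ridge solve with λ = 1e-6. SNPs
missing from a scored cohort are imputed at their mean training dosage
(2 × allele frequency) and flagged.

Accuracy is summarised by control-quantile enrichment: the control scores
define quintile edges, and the report gives the percentage of *cases*
strictly above the top edge and strictly below the bottom edge (ties fall
to the lower bin; under exchangeability both percentages sit near 20%).
The percentages are taken over all cases, matching the phrase "percentage
of cases in top and bottom 20 percentile PRS among controls".
`prs_cv()` runs stratified 10-fold cross-validation and reports the fold
mean ± s.d.; `prs_transfer()` evaluates a model trained on one cohort on
another by resampling 90% of it 10 times.

## What the synthetic data emulates — and what it does not

Every generator is a pure function of a `synth_config()` and its seed, with
per-generator sub-streams so regenerating one input never shifts another.

* **Enhancer sequences** — i.i.d. background at GC 0.41 (human-like) with
  1–3 planted instances of a 12-bp forkhead-like PWM (about 14 bits at the
  default column concentration 0.85), on either strand, at recorded
  positions; negatives are motif-free background of the same composition.
  No repeat structure, no GC isochores, no chromatin context.
* **SNP panels** — Balding–Nichols draws: ancestral frequency uniform on
  [0.05, 0.95], population frequencies Beta-distributed around it with
  drift c~AA~ = 0.05 and c~EA~ = 0.10 (the out-of-Africa bottleneck left
  non-African populations with more drift from the ancestral pool), giving
  a realistic F~ST~ continuum. No linkage disequilibrium between SNPs.
* **Read counts** — negative-binomial depths (mean 30, size 5; the merged
  ChIP depth distribution is not observable from the outside, so it is
  configurable with this default) and binomial allele counts at
  `plogis(effect)`, effect ±2 log-odds at true eSNPs.
* **Genotypes** — Hardy–Weinberg dosages at the panel frequencies and a
  logistic liability with N(0, 0.5²) weights on 10 causal SNPs; the
  intercept is found by bisection so the expected case fraction hits its
  target exactly.

Passing tests on these data demonstrate that the *statistics and machinery*
are correct and calibrated; they do not demonstrate biological validity of
any particular trained model, since real enhancers are not single planted
motifs and real cohorts have LD and population structure that the
generators deliberately omit.

## Problem sizes used by the bundled checks

The test suite trains the reduced model at 150–1000 bp with hundreds to a
couple of thousand sequences per class; the bundled evaluation script
(`scripts/acceptance.R`) uses the full desk-scale design — 4,000 positives
and 4,000 negatives at 1 kb, 70/15/15 split, reverse-complement-augmented
training — and reports held-out auROC on the 15% test split. These sizes
are the package's own desk-scale choices: large enough for the reduced
architecture to sit near the generative-model optimum, small enough to run
on a laptop CPU in minutes.

## Known limitations

* Indels, multi-allelic sites and combinatorial multi-SNP effects are out
  of scope; so are LD pruning, imputation and >2-population F~ST~.
* The binomial imbalance test ignores reference-mapping bias and
  overdispersion.
* The linear-regression PRS is used as specified; it is not a calibrated
  probability model.
* The full 5-layer architecture is provided but is not exercised by the
  bundled checks — at desk scale it is both unnecessary and data-starved.
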