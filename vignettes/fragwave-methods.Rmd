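---
title: "Classifying cancer from cfDNA fragment-size profiles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying cancer from cfDNA fragment-size profiles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragwave)
```

## The signal: fragment-size probability mass functions

Cell-free DNA (cfDNA) circulates in plasma as fragments whose size
distribution carries a nucleosomal footprint: a dominant mode near
166 bp (mono-nucleosomal protection), a shoulder near 145 bp, and an
oscillation with roughly 10-bp period below 150 bp attributed to
histone–DNA contact spacing. Tumor-derived fragments are on average
shorter, so a cancer patient's profile carries excess mass below
150 bp. fragwave classifies patients from this signal alone.

The unit object is the fragment-size PMF over an inclusive range
$[k, m]$, by default $[51, 250]$ bp (200 values):

$$\mathrm{PMF}(l) = \frac{N_l}{\sum_{j=k}^{m} N_j},$$

where $N_l$ counts fragments of size $l$ whose (0-based, leftmost)
start coordinate falls in the genomic region under consideration.
Both endpoints are inclusive — only the inclusive reading of
$[51, 250]$ yields a length-200 vector, which is the convention used
throughout. Profiles are never smoothed; smoothness is enforced
upstream by the per-subsample fragment floor instead.

## From alignments to binned histograms

`build_bins()` tiles autosomes into fixed 1-Mb half-open bins
(0-based), with a possibly shorter terminal bin per chromosome.
`ingest_bam()` keeps properly paired, primary, non-duplicate
alignments with MAPQ ≥ 20 on the leftmost read, takes the fragment
size as `|TLEN|`, counts each pair once (positive-TLEN record), and
assigns the fragment to the bin containing its leftmost coordinate.
Read-level filters are not part of the method definition; these are
standard cfDNA practice and are configurable. Sizes are stored over a
wide window (1–1000 bp, the range paired-end WGS can resolve);
windowing to the analysis range happens only when PMFs are computed.

## Bin-subsampling augmentation

Deep models need more training examples than a cohort has patients.
The augmentation exploits the genome itself: fragments from different
1-Mb bins are (to a good approximation) independent draws from the
same patient-level size distribution, so disjoint sets of bins yield
multiple statistically independent PMFs — "subsamples" — that share
the patient's label.

`make_subsamples()` draws bins uniformly at random without
replacement from the patient's not-yet-used pool and accumulates
whole bins until the in-range fragment count reaches
`min_fragments`. Consequences of this design:

* **No fragment reuse.** Subsamples of a patient use pairwise
  disjoint bin sets, by construction rather than by bookkeeping over
  individual fragments. The phrase "sampling fragments from bins"
  admits a per-fragment reading; the whole-bin reading is adopted
  because it guarantees disjointness with simple provenance. An
  optional flag (`trim`) for exact per-fragment trimming was
  considered and rejected: whole bins keep the count slightly above
  the floor, which only helps smoothness.
* **No over-accumulation.** Bins are added only while the count is
  below the floor, so removing the last-added bin always violates the
  minimum.
* **Coverage errors are informative.** If the pool cannot support the
  requested number of subsamples, the error names the achievable
  maximum (`floor(total / min_fragments)` before sampling, or the
  number completed if the pool runs dry mid-way).

With real WGS data the floor is 1,000,000 fragments per subsample
(the package default). Synthetic runs scale the floor together with
the generated coverage (see below) — the structure of the sampler
(bins-until-floor, disjointness) is what the tests exercise, and it
is scale-free.

Per-patient subsample counts are odd so majority votes cannot tie:
cancer patients get 5 (3 when coverage permits only 3), and healthy
patients get a mix of 3s and 5s chosen so the augmented class totals
are near balance. The balance target is stated by the method; the
assignment rule is not, so the package uses a deterministic rule —
the first $k$ healthy patients in sorted id order get 5, with
$k = \mathrm{round}((C - 3n_H)/2)$ for cancer total $C$ — which is
reproducible and reaches balance within the arithmetic's resolution
(for an 80/73 cohort: healthy average 4.55 subsamples).

## Wavelet features

The discrete wavelet transform decomposes a PMF into approximation
and detail coefficients localized in both fragment size and
frequency, which suits a signal that mixes a sharp 166-bp mode, a
broad slope, and a narrow-band 10-bp oscillation. No R wavelet
package is declared as a dependency: the multi-level Mallat pyramid
is implemented in the package itself (`wavedec()`/`waverec()`), with
hardcoded Daubechies/symlet filter banks, half-sample symmetric
boundary extension, per-level coefficient lengths
$n_{k} = \lfloor (n_{k-1} + L - 1)/2 \rfloor$, and perfect
reconstruction. The conventions mirror those of the mainstream DWT
libraries, and the test suite pins the implementation to reference
coefficient vectors computed once with PyWavelets and frozen.

Defaults: Daubechies-4, full decomposition depth
($\lfloor \log_2(n/(L-1)) \rfloor = 4$ for $n = 200$), symmetric
boundary. The method description does not name a wavelet family,
level, or boundary mode, and no standard combination reproduces the
printed DWT feature length of 224 exactly (db4/symmetric at full
depth gives $19+19+31+55+103 = 227$). The feature length is therefore
treated as a consequence of the configuration, not a constant;
wavelet and level are configuration options.

The ablation analysis (`ablate_region()`, `ablation_experiment()`)
zeroes one of five named profile regions before the transform —
left oscillatory, right oscillatory, mode, slope, tail — with
default boundaries [51,100], [101,150], [151,180], [181,220],
[221,250] bp. The region names are conventional; the boundaries are
package defaults (the source analysis names the regions without
printing boundaries) and configurable. The ablated signal is
deliberately not renormalized: the importance probe is "what does the
model lose when this part of the raw signal is blanked", and
renormalizing would leak the removed mass into the remaining values.

## Benchmark features

The three engineered baseline features are: the short/long mass
ratio $\sum_{100}^{150} \mathrm{PMF} / \sum_{151}^{220} \mathrm{PMF}$;
the mean fragment size over sizes whose PMF value exceeds the 80th
percentile of PMF values; and the mass strictly right of 166 bp.
"Average FS corresponding to the part of the PMF curve above the 80th
percentile" is ambiguous; the unweighted mean over qualifying sizes
is the default and a PMF-weighted variant sits behind the
`weighted` flag. "Right of 166" excludes 166 itself.

## Classifiers

* **Logistic regression** (`stats::glm`, binomial) and **random
  forest** (`randomForest`, 500 trees, seeded) on any feature kind.
* **Feed-forward network**: three hidden layers of 64/32/16 neurons,
  leaky-ReLU (slope 0.01), dropout 0.2 per hidden layer, Adam at
  learning rate $10^{-3}$, binary cross-entropy from logits
  (numerically stabilized), at most 400 epochs, full-batch by
  default. Dropout rate, learning rate, batch size and
  initialization (He-scaled normal) are not fixed by the method
  description; they are common defaults surfaced in `dnn_spec()`.
  The network is implemented directly in R with matrix operations —
  at these input sizes (a few hundred rows, ≤ 230 features) a
  full-batch epoch is a handful of BLAS calls and training takes
  seconds.

Features are z-scored with statistics fitted on training rows only
and applied unchanged to test rows, making standardization
leakage-safe by construction; constant columns pass through with unit
scale.

Two stopping rules are implemented exactly as stated:

1. **Rule 1 (convergence):** stop when the mean training loss over
   the last 5 epochs drops below 0.1 *and* the range of those 5
   losses relative to their mean is at most 15%. Never fires before
   epoch 5; training always halts at 400 epochs regardless.
2. **Rule 2 (validation):** split 10% off the training set
   (patient-grouped when patient ids are supplied), stop after 5
   consecutive strict increases of the validation loss, and restore
   the checkpoint from 5 epochs before the stop (a 6-deep checkpoint
   ring buffer).

Rule 1 is the default for experiments, consistent with its greater
stability and independence from a validation split.

## Patient-level aggregation and metrics

Subsample probabilities are thresholded at 0.5; an exact 0.5 counts
as cancer (sensitivity-favoring tie rule, fixed and documented).
Three assessments are reported side by side:

* **Subsample**: every subsample scored independently.
* **Consensus**: a patient is called only if all its votes agree;
  otherwise the decision is *undefined*, which is counted as an error
  of the patient's true class (false positive if healthy, false
  negative if cancer). The number of undefined patients always equals
  the number of non-unanimous patients.
* **Majority**: strict majority of an odd number of votes; with 5
  votes the minimum support for a call is 3/5 = 60%.

AUROC/AUPRC need a patient-level score, which the method description
does not define for the patient-level assessments. The package's
choices: majority uses the fraction of cancer votes (a `mean_prob`
variant is available); consensus uses the mean subsample probability;
the subsample method uses raw probabilities. These are design
decisions, not reconstructions. AUROC is the midrank Mann–Whitney
statistic (cross-checked against pROC in the tests); AUPRC is average
precision with tied scores processed as blocks.

## Evaluation design

`patient_split()` assigns whole patients to train or test (default
test fraction 0.25), stratified by class × flowcell; no patient ever
appears on both sides, which the tests assert across a 20-split grid.
`run_experiment()` runs `n_splits` splits × `n_retrains`
re-trainings; each split re-augments the cohort with its own seed, so
splits differ both in patient composition and in the bins their
subsamples use. Reports carry medians plus two IQR summaries: the
median across splits of the within-split IQR (model stochasticity)
and the IQR of split medians (data-composition variability).
`cross_validate()` runs patient-grouped stratified k-fold CV (default
k = 10) on one fixed augmented dataset.

Seeds form a deterministic grid: split $i$ uses `base + i` for
splitting and `base + 1000 + i` for augmentation; retrain $j$ in
split $i$ uses `base + 2000 + 100 i + j`. Every run is bit-replayable
from the base seed; baseline models retrain once per split by default
since their fit variance is negligible next to the DNN's (this
interpretation of "re-runs" is a package decision).

## The synthetic cohort generator

`generate_cohort()` exists so that every downstream stage is testable
without sequencing data. The class PMF (`make_class_pmf()`) is a
mixture of non-negative components, each normalized to unit mass:

* a Gaussian mode at 166 bp (width 9 bp, weight 0.60);
* a Gaussian shoulder at 145 bp (width 7 bp, weight 0.15);
* a damped raised-cosine oscillation with 10-bp period on
  [51, 150] bp (weight 0.25, exponential envelope rising toward
  150 bp).

The cancer signal is convex contamination: with
$\delta = \text{tumor fraction} \times \text{short-shift mass}$, the
class PMF is $(1-\delta)\,h + \delta\,s$ where $s$ is the healthy PMF
restricted below 150 bp and renormalized. Hence tumor fraction 0
reproduces the healthy model exactly, any positive fraction strictly
increases sub-150-bp mass, and the short/long benchmark ratio is
strictly increasing in tumor fraction — properties the tests assert.
All numeric values above are fixtures chosen to resemble published
healthy profiles qualitatively; no quantitative class-PMF parameters
are published for the cohorts the method was developed on, so the
defaults are explicitly not estimates of any real cohort.

Per-bin fragment totals are negative-binomial (mean
`fragments_per_bin`, size `dispersion` = 8) to mimic the
flowcell-to-flowcell coverage variation of real data (0.1×–30×
across flowcells), and per-bin size histograms are multinomial draws
from the class PMF. One sample per patient (pre-treatment samples
only); flowcell labels cycle round-robin within class so strata stay
balanced.

What the generator does **not** emulate: GC and mappability bias,
regional (chromatin-state) differences between bins, within-patient
longitudinal structure, real inter-patient heterogeneity of the
healthy profile, and batch effects on the *shape* of the profile
(flowcell is a label only). Passing tests therefore demonstrate that
the pipeline recovers a class signal of the assumed form under
multinomial sampling noise and coverage dispersion — not that it
attains any particular accuracy on real cohorts.

## Problem sizes and numerical choices

Synthetic experiments in the tests and the acceptance script use
40+40-patient cohorts, 50 bins per sample with ~4000 fragments per
bin (~200k fragments per sample), a 25,000-fragment subsample floor
(about 7 bins per subsample, 35 of 50 bins at 5 subsamples — the
same headroom regime as 1M-fragment subsamples over ~2900 autosomal
bins), 5 splits × 3 re-trainings, and 10 CV folds. These sizes are
the package's chosen desk-scale study conditions; the structure of
every computation is identical at full scale.

Other numerical decisions: PMF validity tolerance 1e-9 at
construction; DWT reconstruction verified to 1e-8; probabilities are
compared to the 0.5 threshold with `>=`; quantiles use R's default
type 7; `round()` (banker's rounding) decides per-stratum test counts
and the healthy 3/5 balance count; empty strata and single-patient
strata degrade with warnings rather than errors.

## Known limitations

* The DWT feature length (227) intentionally differs from the
  printed 224, which no standard convention reproduces; results are
  insensitive to this at the model level but coefficient-position
  feature names are not comparable across conventions.
* The patient-level AUROC definitions under consensus/majority are
  package choices (see above).
* `ingest_bam()` reads whole files sequentially and does not require
  a BAM index; region-restricted ingest is not implemented.
* Baseline models retrain once per split by default.
* No GC correction, duplicate marking, or non-autosomal contigs.
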