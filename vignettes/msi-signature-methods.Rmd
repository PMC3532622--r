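---
title: "Methods: an MSI expression signature and its validation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an MSI expression signature and its validation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msisig)
library(dplyr)
```

## Scope and model

`msisig` builds and applies a nearest-centroid gene-expression classifier
for the microsatellite-instability (MSI) phenotype of colorectal tumours,
plus the analyses used to validate such a classifier: mutation load over a
fixed capture panel, survival of classifier strata, TYMS expression, and
technical reproducibility. The data model is log-ratio expression from a
common-reference two-channel design: each sample is hybridised against a
pooled reference and summarised per gene as a Lowess-corrected log2 ratio.

The classifier itself is deliberately simple. Two centroids — the mean
signature-gene profile of the MSI-labelled and of the MSS-labelled training
samples — are frozen, and a new sample $x$ is scored by

$$\mathrm{index}(x) = \cos(x, c_{\mathrm{MSI}}) - \cos(x, c_{\mathrm{MSS}}),$$

the difference of its cosine correlations to the two centroids, a number in
$[-2, 2]$. Two thresholds turn the index into a three-way call: below the
primary threshold MSS, at or above the secondary threshold MSI, in between
MSI-like. "MSI-like" is the clinically interesting middle stratum: samples
the hospital assay calls MSS but whose expression program, mutation load
and survival resemble MSI.

### Reading of "cosine correlation"

We read cosine correlation as uncentred cosine similarity on the log-ratio
vectors. Log-ratios are already ratio-to-reference measurements, so the
zero point is meaningful and centring would discard it. Because the phrase
is genuinely ambiguous, `msi_index(..., centered = TRUE)` computes the
Pearson (centred) variant instead; nothing else in the pipeline changes.

### Boundary convention

An index "exceeding" a threshold is implemented inclusively (`>=`) at both
thresholds. The convention is stated here, in the function documentation,
and is frozen with the model in the signature file, so a frozen classifier
cannot drift in boundary behaviour between environments.

## Gene selection

Candidate genes are ranked by a two-sided two-sample Student's *t*-test
(equal variance; Welch by flag) of MSI- vs MSS-labelled samples, ascending
in p-value, ties broken by descending $|t|$ then lexicographically — a
deterministic permutation, invariant to input gene order. A gene with zero
pooled variance carries no usable evidence and is assigned $t = 0$,
$p = 1$, flagged `degenerate`.

Selection runs a stratified 10-fold cross-validation, repeated (1000 times
at study scale), ranking genes on each training portion only and counting
how often each gene lands in the top `top_k`. The signature is the 64 genes
with the highest appearance count. Choices worth making explicit:

* **`top_k` defaults to the signature size (64).** "Top-ranking genes" has
  no stated size; counting exactly as many genes per loop as will be
  selected is the natural reading, and `top_k` is exposed for any other.
* **Folds are stratified by class.** At 11% prevalence, unstratified
  10-fold CV would regularly produce training folds with almost no MSI
  samples; stratification (shuffle within class, deal fold ids cyclically)
  keeps both classes in every fold and is required before fold counts
  approach the minority class size.
* **Loops are counted per fold-within-repeat** (so 10 x repeats loops in
  total). Counting per repeat instead would only rescale all counts by 10
  in expectation and leaves the selected set essentially unchanged.
* **Tie-break for equal counts** is the lower mean p-value across loops,
  then gene id; with the count conservation invariant
  (`sum(counts) = repeats x folds x top_k`) this makes the whole selection
  deterministic given the seed.

On all-null data the appearance frequencies do *not* hover at the binomial
chance level per loop: with the dataset fixed, whichever genes look best by
sampling accident look best in nearly every training fold, so their counts
approach the number of loops. What chance behaviour actually looks like is
instability *across* datasets — independent null cohorts share selected
genes only at chance overlap — and that is the property the test suite
asserts.

## Threshold optimisation and performance

Candidate thresholds are the midpoints between adjacent sorted unique index
values plus $\pm\infty$; midpoints make the inclusive boundary unambiguous.
Every candidate is scored and the maximiser of sensitivity + specificity
returned, ties to the lowest threshold (favouring sensitivity). The
external-platform variant restricts candidates to sensitivity $\ge 0.9$
first. The optimisation criterion is the Youden-style sum; plain overall
accuracy (fraction correct) is reported separately by
`performance_report()`, never optimised — the two differ materially at 11%
prevalence, where a trivial all-MSS classifier is 89% accurate.

The secondary threshold is chosen among signature-positive samples only, by
the same sum-maximising rule for hospital-MSI vs hospital-MSS positives. No
published criterion exists for this cut; ours is a stated choice. At the
operation level, positives containing a single hospital class are an error
(the threshold is undefined); the `optimize_thresholds()` pipeline wrapper
documents two degenerate fallbacks — no hospital-MSS positives collapses
the secondary threshold onto the primary (every positive is MSI), no
hospital-MSI positives pushes it to $+\infty$ (every positive stays
MSI-like).

AUC is the Mann–Whitney statistic over positive x negative pairs with ties
counted one half; the 95% CI is a stratified bootstrap (2000 resamples,
seeded) by default, or DeLong. The bootstrap is the default because it makes
no variance approximation at the small positive-class sizes typical here.

Platform reduction (`reduce_to_platform()`) restricts a frozen model to the
genes another platform measures (the study's FFPE platform retained 58 of
64 genes). Index distributions shift with dimension, so reduced models are
flagged `thresholds_stale` and refuse to classify until thresholds are
re-optimised on a calibration set; the dropped genes are recorded in
provenance.

## Mutation frequency

Variant records pass the inclusion filters if coverage $\ge 10$, variant
reads $\ge 5$, at least one variant read on *each* strand (no per-strand
minimum is stated anywhere, so $\ge 1$ is the weakest faithful reading),
the consequence is protein-coding, and the variant is absent from the
normal-sample panel. Germline subtraction itself is upstream sequencing
work; the pipeline consumes its result as the `in_normal_panel` flag.
Per-sample mutation frequency is the fraction of *distinct* panel genes
(615 in the study's cancer-kinome capture) with at least one surviving
variant — multiple variants in a gene count once — and groups are compared
with a two-sided Student's *t*-test on these per-sample fractions.

## Survival and TYMS

Follow-up is administratively censored at a 10-year horizon (events beyond
it become censorings at the horizon). Kaplan–Meier curves and the log-rank
test summarise strata; the headline effect estimate is a univariable Cox
model for binary signature-positive (MSI and MSI-like combined) vs MSS,
with Efron tie handling. The binary contrast is primary because the
concordant-MSI stratum can be event-free, which makes per-stratum hazard
ratios degenerate; when one group has no events the function still reports
the estimate but warns that the CI is unbounded. Stage filtering (e.g.
restricting prognosis to stage II) is a data-preparation step
(`dplyr::filter` on the clinical table), not hard-coded. TYMS expression is
compared between classes with two-sided *t*-tests (MSI vs MSS and MSI-like
vs MSS).

## The synthetic-study generator

`sim_config()` fixes the study conditions; `simulate_cohort()`,
`simulate_variants()`, `simulate_survival()` and `simulate_replicates()`
draw from them deterministically per seed. Defaults, with the reasoning:

| parameter | default | why |
|---|---|---|
| `n_samples` | 276 | development-cohort size |
| `prevalence_msi` | 0.11 | observed hospital-MSI fraction |
| `n_genes` / `n_informative` | 1000 / 64 | genome-scale array reduced to desk scale; planted program equals the signature size |
| `effect_size_msi` | 2 (SD units) | a dominant expression program: strong but overlapping single-gene effects |
| `prevalence_msi_like_among_mss` | 0.10 | MSI-like fraction among hospital-MSS, matching the scale of the reported MSI-like group |
| `effect_attenuation_msi_like` | 0.6 | MSI-like shares the program at reduced strength — the phenotype without asserting its cause |
| `hospital_error_rate` | 0.02 | small assay error, so hospital labels are imperfect ground truth |
| `mut_rate_msi/msi_like/mss` | 0.082 / 0.064 / 0.016 | reported per-class mean mutation frequencies |
| `hazard_ratio_positive` | 0.25 | reported prognostic effect |
| `event_rate_mss` | 0.2 at 10y | plausible stage-II distant-metastasis rate; sets the baseline exponential hazard |
| `censor_range` | 5–15 y | uniform administrative censoring, accrual-style follow-up |
| `tech_noise_sd` | 0.05 | technical noise well below biological spread, the regime of the replicate experiments |
| `tyms_sd` | 0.15 | TYMS class shifts of 0.4 / 0.3 with within-class SD 0.15 reproduce the extreme reported separation (p far below 1e-10 at cohort scale); SD 1 would not |

Two seeds govern a cohort. `program_seed` fixes the *biology* — which genes
carry the MSI program and each gene's direction — and is shared across
cohorts by default, because development and validation cohorts of the same
disease express the same program; without this, a model frozen on one
cohort would be meaningless on another. `seed` governs everything
sample-level: class draws, expression noise, label errors, outcomes.
Variant simulation gives genuine mutations coverage and read counts that
always pass the inclusion filters (coverage $\ge 10$ by construction,
variant reads $\ge 5$, binomial strand split), and injects a configurable
fraction of decoy records each violating exactly one filter, marked in a
bookkeeping column so tests can verify the filters remove exactly the
decoys.

What the generator does **not** emulate: gene–gene correlation (genes are
independent given class, so selection faces no collinearity), array spatial
artefacts, batch effects beyond scalar day/operator offsets, non-exponential
hazards, and cohort-specific platform differences. Passing tests therefore
demonstrate correctness of the machinery under the stated statistical
structure, not performance on real tumours.

One consequence worth stating because the pipeline computes it: with the
default generator and a threshold optimised against (error-prone) hospital
labels, roughly 10–15% of latent-MSS samples land above the primary
threshold. In survival analysis by *signature call*, these false positives
carry full MSS hazard into the positive group, so the calls-based hazard
ratio attenuates toward 1 (median near 0.65 across replicate validation
cohorts) even though the latent-strata analysis recovers the generated 0.25.
The acceptance script reports both numbers; the gap is misclassification
dilution, not an estimation bias.

## Numerical choices

* Lowess normalisation: span 0.3, 3 robustness iterations — common
  two-channel MA-correction practice; both configurable. Normalisation is
  per array, matching the common-reference design; the fit is interpolated
  back to input order and subtracted from $M$.
* Internal log scale is log2 for $M$/$A$; a log10 display (as used for
  TYMS) is a plotting-layer conversion, not a data-model change.
* Missing expression values are imputed by per-gene means, capped at 20%
  missingness per gene; imputed cells are recorded in an attribute.
* Signature files are versioned JSON with doubles at 17 significant digits,
  so a frozen model round-trips bit-exactly and diffs cleanly.
* All stochastic steps (fold shuffling, bootstrap, generator) take explicit
  seeds; `withr::local_seed` keeps them from disturbing the caller's RNG
  state.

## Problem sizes in the test suite

The suite exercises the study-scale design at reduced repetition counts
chosen as the package's own test scale: CV selection at 50 repeats (vs 1000
at study scale, which changes only the resolution of the frequency table),
recovery and AUC summarised over 10 generator seeds, mutation and survival
recovery over 100 seeds, and oracle comparisons on instances up to 500
elements, where brute-force enumeration is exact and fast.

## Known limitations

* Equal-variance *t*-ranking is the faithful default; strongly
  heteroscedastic genes would rank differently under Welch (available by
  flag).
* The secondary-threshold criterion is a package choice; published results
  fixed theirs on the development cohort without stating the rule.
* Cross-platform read-out supports both re-deriving centroids on the new
  platform and reusing mapped centroids; which the original study used is
  not determinable from its description, so neither mode is privileged.
* The generator's independence assumptions make gene selection easier than
  on correlated real data; recovery rates here are upper bounds.
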