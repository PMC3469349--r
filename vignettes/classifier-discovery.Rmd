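---
title: "Discovering and validating exposure classifiers in expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and validating exposure classifiers in expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A chemical exposure leaves a transcriptional trace. Given log2-intensity
expression profiles of treated and control animals for several
chemical-tissue conditions, we want, per condition, a compact *gene
classifier*: a small set of features whose expression separates treated from
control samples, unique to that condition, and validated on data the
discovery never saw. `gaclassify` implements that full procedure — wrapper
feature selection by a genetic algorithm, data-complexity characterisation,
candidate qualification and prioritisation, gene-set-enrichment validation,
and probe cross-mapping between array designs — together with a synthetic
data generator that plants known signal so every stage can be tested against
ground truth.

# The model and procedure

## Data complexity: Fisher's discriminant ratio

For feature $i$ with class means $\mu_1, \mu_2$ and unbiased class variances
$\sigma_1^2, \sigma_2^2$,

$$ f_i = \frac{(\mu_1 - \mu_2)^2}{\sigma_1^2 + \sigma_2^2}. $$

The condition-level summary is $\max_i f_i$ (the classic F1 complexity
measure); a small maximum means no single feature separates the classes
well — a "harder" condition. The estimator choice (unbiased, $n-1$) and the
max-versus-mean summary are options (`condition_complexity(summary =)`),
with max the default. Features constant in both classes get $f_i = 0$ when
the means agree and are flagged and excluded from the maximum otherwise, so
a degenerate probe cannot dominate the summary.

## GA-wrapped feature search

Chromosomes are fixed-size sets of distinct feature indices (default 5).
Fitness is the mean test-set accuracy of a classifier (linear soft-margin
SVM via `e1071`, or a deterministic k-nearest-neighbour vote, default
$k=3$, on features z-scored with training statistics) over stratified
random train/test splits (default 10 splits at 2/3 training fraction). The
population (default 50) evolves by tournament selection (size 2), uniform
crossover, point mutation (resampling an index from the search space) and
elitism (1).

Two numerical choices deserve emphasis:

* **Fresh splits, evaluated once.** Each chromosome is scored once, on
  splits drawn freshly at its first evaluation, and cached. A fixed split
  set shared across a whole search can be *hill-climbed*: the GA finds
  chromosomes that fit that particular split set, and on pure-noise data
  this manufactures "models" passing the fitness goal. With
  evaluate-once-on-fresh-splits, split luck is not heritable, the estimate
  is unbiased, and the cached value keeps the best recorded fitness
  non-decreasing under elitism.
* **Confirmation before collection.** When the best chromosome reaches the
  fitness goal (default 0.90) it is re-evaluated on an independent set of
  splits; only a confirmed hit is collected (achieved fitness = mean of the
  two evaluations), and the population restarts either way. The restart
  implements "multiple models per search" with controlled redundancy and
  stops a cycle from climbing ever deeper into dataset-specific overfit
  after a goal-hit.

A limitation worth stating plainly: with 10 vs 10 samples and thousands of
candidate features there *exist* small feature subsets whose honest
cross-validated accuracy exceeds 0.90 on label-free noise — we measured
subsets at 0.91–0.92 true accuracy (100 independent splits) in a
2,000-feature null condition. A sufficiently thorough search will find
them; no split scheme can prevent it, because it is a property of the
dataset geometry, not of evaluation noise. This is the familiar
feature-selection overfitting problem at small sample size, and it is why
the downstream qualification, deduplication and independent validation
stages exist. Searches restricted to networks of 20–50 genes are far less
exposed (the subset space is orders of magnitude smaller); in our null
controls, network-restricted searches collect nothing.

## Qualification, deduplication, ranking

The union of a search's models is screened by an algorithmic version of
two-way heat-map inspection: average-linkage hierarchical clustering of the
condition's samples restricted to the candidate features, cut into exactly
two clusters, must reproduce the treated/control partition exactly.
Euclidean sample distance is the default. We initially used
1 − Pearson-correlation distance, but between-sample correlations estimated
over classifier-sized feature sets (5–100 features) carry sampling noise of
order $1/\sqrt{m}$, which made the exact-partition criterion erratic on
data with realistic between-gene baseline variation (qualification became
close to a coin flip on clearly separated conditions). Euclidean distance
aggregates the class separation directly; the correlation option remains
available (`qualify_by_bifurcation(distance = "correlation")`).

In the network path, each (condition, network) model union is screened
first; qualified networks are merged per condition. Features appearing in
two or more conditions' sets are then removed *from all of them* — a
feature responsive to several chemicals makes every classifier containing
it less condition-specific in the field. Remaining features are ranked by
the number of networks that selected them (ties: model-count, then feature
id — a deterministic, documented chain) and capped at 100.

## Validation by gene set enrichment

Classifiers become GMT gene sets (one per condition; members are gene
symbols where a mapping is supplied, probe ids otherwise; the set
description carries the tissue so validation pairs sets and profiles within
a tissue only). For a validation profile, features are ranked by
signal-to-noise $(\mu_t - \mu_c)/(\sigma_t + \sigma_c)$ with each SD
floored at $\max(\sigma, 0.2|\mu|, 0.2)$; the weighted running-sum
enrichment score (weight $p = 1$; increments $\propto |metric|^p$ at set
members normalised to sum 1, decrements $1/(N - |S|)$ elsewhere; ES is the
signed maximum deviation, preferring the positive extreme when the two
extremes tie exactly in magnitude, which happens routinely at $p = 0$ where
the steps are rational) is assessed against phenotype permutations
(default 1,000; all distinct label assignments are enumerated exactly when
fewer exist). Nominal p is conditional on the observed sign with an
add-one guard, `(1 + k)/(1 + m)` where `k` counts same-sign permutation
scores at least as extreme and `m` all same-sign permutation scores —
dividing a same-sign count by the total permutation count would be
anti-conservative by roughly the opposite-sign fraction (we verified the
conditional form holds the 5 % type-I rate over 1,000 null simulations).
NES divides by the mean same-sign permutation score; the FDR q compares
the observed NES with the pooled permutation NES distribution across
sets. A classifier is declared enriched at q < 0.25.
In validation reports the flag additionally requires ES > 0: the diagnostic
claim is that the classifier's signature is coordinately *elevated* in the
treated class, as in training; a signature significantly depleted from a
ranking is not a diagnostic match (we observed exactly this false positive
on a signal-free profile before fixing the direction).

## Probe cross-mapping

Two designs are matched per probe pair by any of three evidence classes:
identical sequence; Smith–Waterman local alignment (`Biostrings`), with the
E-value cutoffs converted to minimum scores via the ungapped
Karlin–Altschul relation $S = \ln(K m n / E)/\lambda$ (for +1/−1 scoring
and uniform base composition, $\lambda = \ln 3$ exactly, $K \approx
0.333$); or same-chromosome start positions within a tolerance. The relaxed
level uses E-10 and ±50 bp; the elevated level E-25 and ±20 bp, so elevated
mappings are a subset of relaxed ones by construction. For 60-mer probes
the E-25 score threshold (≈ 59) sits just below a perfect match — elevated
alignment evidence effectively demands near-identity, which is the intended
behaviour of an elevated stringency at this probe length. Many-to-many
matches are preserved; translation policy (all partners, or first) handles
fan-out, and unmapped members are dropped with a per-set loss report.
Coordinates are 0-based half-open (BED convention); strand is ignored by
default, with a strand-aware flag.

# The synthetic data generator

`simulation_params()` defines a multi-condition two-class study: Gaussian
within-class noise on the log2 scale (SD 1), per-feature baseline
intensities N(8, 1.5²) — between-gene baseline variation is what gives real
samples their shared correlation structure, and without it
correlation-based clustering is meaningless — and planted features whose
treated-class mean is shifted by `delta` × SD. Planted features take
baselines at or above the grand mean: a detectable shift presupposes an
expressed gene, so truth features survive the intensity filter
(floor log2(64), ≥ 75 % of samples). Treated/control samples are paired two
to an array with channel labels, so the ≥ 9-array condition gate and
channel bookkeeping are exercised. Networks (default 20–50 genes) cover a
controlled fraction of each condition's planted features; at fraction 0 the
network path has provably no recoverable signal. Probe-design pairs share
targets by sequence (optionally degraded by point mutations) and/or
jittered coordinates, with truth recorded.

What the generator does **not** emulate: dye and spatial artifacts,
heavy-tailed noise, gene-gene correlation beyond the shared baseline,
batch effects, and real annotation structure. Passing tests therefore show
that the machinery is correct and calibrated on its stated model, not that
classifiers from any particular real dataset will validate.

# Problem sizes and defaults used in tests and analyses

The package-scale study conditions (chosen once, as the package's own
desk-scale miniature of a multi-chemical exposure design):

* Conditions: 3 per study (two with signal, one null), 10 treated vs 10
  control each (10 arrays — above the 9-array gate).
* Planted signal: delta = 3 within-class SDs. The transcriptome-recovery
  check plants 5 features in 2,000; the end-to-end study plants 12 per
  signal condition in 400 features — an exposure perturbs a signature of
  genes, not a handful, and network-level screening needs a few planted
  members per covering network.
* Search configs in analyses: KNN fitness for both scopes (the network
  batch is dozens of searches; KNN is an order of magnitude cheaper per
  evaluation, the same reason the original network-scale searches use it),
  population 20–30, budgets 30–60 generations, 3–8 models collected.
  Package defaults remain population 50 / 200 generations / 50 models.
* GSEA: 1,000 phenotype permutations at FDR 0.25; the null-calibration
  check uses 199 permutations per instance over 1,000 instances — after
  sign conditioning roughly half the permutations count, so ~100 same-sign
  draws are needed for the attainable p-values to step finely enough to
  resolve a 5 % rejection rate.

# Known limitations

* Transcriptome-wide searches at n = 20 can collect a handful of confirmed
  models on truly null data (see above); the qualification and validation
  stages, not the search, are the guard. Network-restricted searches do not
  show this at the sizes used here.
* Exact-partition bifurcation is a strict, somewhat brittle criterion: one
  borderline sample disqualifies a candidate. That is faithful to its
  purpose (it is the formalisation of conservative visual screening, and
  most candidates are *expected* to fail it), but it makes per-seed
  qualification of weakly separated conditions variable.
* The FDR scheme pools permutation NES across the sets under test; with
  very few sets the q estimates are coarse.
* The built-in aligner scores synthetic probe pairs; real cross-design
  mapping should feed precomputed alignment tables through the
  `alignment_table` hook rather than re-deriving E-value calibrations.
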