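---
title: "Methods: quantifying song differentiation across isolated populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying song differentiation across isolated populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(songdiff)
```

This vignette documents the models, rules and numerical choices behind
`songdiff`: what each stage computes, which parameters matter and why
their defaults are what they are, what the synthetic-data generator does
and does not emulate, and where the design was genuinely open.

## Data model

The atomic unit is a **note**: one continuous trace on a spectrogram,
described by four numbers (start time, end time, low frequency, high
frequency; seconds and Hz throughout) plus population / individual / song
labels. A **song** is a labelled group of notes; a **bout** is an
individual's ordered song sequence. Notes within a song may overlap in
time — overlapping traces are exactly what the two-voice phenomenon
produces — so validation requires only `end > start`, `high > low`, and
finite non-negative values. Song membership comes from the labels; field
protocols delimit songs manually and no silence threshold is stated
anywhere we could adopt, so automatic gap segmentation
(`segment_songs_by_gap`, default 1.0 s) is provided but never applied
implicitly.

## The 14 spectral variables

`extract_features` computes, per song: mean and SD of note length, of
high frequency, of low frequency, and of note bandwidth (8); song
bandwidth (max high − min low over notes); song duration (max end − min
start); number of notes; delivery rate (notes / song duration); and the
two complex-vocal-mechanism (CVM) rates (14 total). The authoritative
per-variable table for the study this reconstructs is in unpublished
supplementary material, so the set was reconstructed from the variables
named in the reported principal-component loadings (mean and SD of high
frequency, of note bandwidth, song bandwidth, SD of low frequency; mean
and SD of note length and delivery rate; the two syrinx variables) plus
the standard complements needed to reach fourteen. "Mean and variance"
summaries are implemented as mean and SD, matching the loading
descriptions. The SD of a single observation is defined as 0 so one-note
songs remain analyzable.

**CVM indicators.** Songbirds normally take a minibreath between notes;
its minimum duration is about 2 ms. An internote interval (start of note
*i+1* minus end of note *i*) below 2 ms, or outright temporal overlap,
implies either both syrinx halves sounding at once or nonlinear dynamics
of a single syrinx — the two cannot be distinguished from annotations, and
no attempt is made to. The counters are exclusive: an interval in
[0, 2 ms) is a *short interval*, a negative interval is an *overlap*; each
is scaled by the song's note count to remove bias from population
differences in notes per song. Both rates are invariant to time
translation and frequency shifts of a song. The 2 ms threshold is held in
seconds internally (0.002) and is configurable (`cvm_threshold_ms`).

**Frequency shifts.** For each consecutive pair, the shift is the later
note's high frequency minus the earlier note's low frequency. Pairs are
classed by the same interval against the same threshold; the boundary
case (exactly 2 ms) falls in the at-or-above class, a choice the source
material leaves open. The two shift distributions are compared with a
two-sample Kolmogorov–Smirnov test (asymptotic p). Shifts are pooled over
all songs by default — the reported statistic in the motivating study is a
single global D — with per-song tables available from
`frequency_shifts`.

## Song types, SVI and versatility

The motivating protocol identified song types *visually*. Reproducibility
demands an explicit rule, so `song_signatures` operationalizes it:

* two notes are the same **note class** when their relative differences
  in duration and in bandwidth are both ≤ `tolerance` (default 0.20;
  relative difference = |a−b| / max(a,b));
* absolute frequency position is excluded, so a uniform transposition of
  a song is the same type;
* a **trill** is a maximal run of ≥ 2 consecutive same-class notes and
  collapses to a single run marker, so trill elongation or shortening
  does not create a new type;
* a song's **signature** is its collapsed sequence of class ids; two
  songs are the same type iff their signatures are equal.

Classing is greedy and deterministic: all of an individual's notes are
clustered first (within an individual, renditions of a class are tight,
so repeated songs resolve to identical signatures), and each
individual-level class is then mapped once onto a global class list in
canonical dataset order. Doing the global match per song instead would
let a class sitting near the tolerance boundary of another individual's
exemplar flip identity between renditions; the two-stage order removes
that instability by construction.

On a bout of N consecutive songs (default 11, the minimum available per
individual in the motivating study; individuals with fewer are excluded
with a warning), `classify_bouts` walks the sequence: a song is **same**
if its signature equals the previous song's, **old** if it equals an
earlier non-adjacent song's, **mod** if it is novel but shares a
contiguous note-class subsequence of length ≥ 2 (a copied combination of
notes) with an earlier song of the bout, else **new**. The first song is
"new" by convention. Requiring length ≥ 2 for "mod" is deliberate:
sharing a single note class would make nearly every song "modified". The
Song Variety Index is SVI = distinct signatures / N ∈ [1/N, 1]. Bout
selection defaults to the first N songs; `start = "random"` gives seeded
random windows for robustness checks.

Per-population summaries use a percentile bootstrap (default 1000
replications) resampling **individuals** within populations — the
individual is the unit of replication for SVI and the category
proportions — with single-individual populations reported as point
estimates with the interval flagged unavailable.

## Multivariate battery

* **PCA** on the correlation matrix (the variables mix Hz, s, counts and
  proportions), retaining eigenvalues > 1. Signs are fixed by making the
  largest-magnitude loading of each component positive, so results are
  reproducible across platforms. Constant columns are dropped with a
  warning.
* **Nested MANOVA** respects the sampling hierarchy: songs within
  individuals within populations, all effects fixed. The SSCP
  decomposition is hierarchical (population deviations from the grand
  mean; individual deviations from their population mean; song residuals)
  and the population effect is tested against the individual-within-
  population stratum — using the song-level residual would badly
  overstate population differences when individuals are the replicates.
  Wilks' Λ with Rao's F approximation is reported; the univariate
  per-component version reduces exactly to the classical nested F ratios.
* **Canonical discriminant analysis** solves the symmetric whitened
  eigenproblem of between- against pooled within-population SSCP;
  canonical correlation of axis i is √(λᵢ/(1+λᵢ)). Classification is by
  linear discriminant analysis with the resubstitution rate reported by
  default — matching the convention of the motivating study — and
  leave-one-individual-out cross-validation available as the honest
  alternative (`cv = "individual"`). A ridge is added to a singular
  within-group matrix, with a message.
* **NMDS** runs on Euclidean distances between z-scored feature vectors
  (the dissimilarity is not specified in the source material; Euclidean
  on standardized variables is the least-assumptive choice), 2
  dimensions, monotone-regression stress minimization, best of 20 seeded
  random starts. An all-equal distance matrix yields a flagged trivial
  zero-stress solution.
* **Kruskal–Wallis** (tie-corrected) across populations, with Dunn's
  rank-sum z tests and Bonferroni correction over all pairs as the post
  hoc.

## Isolation analysis

Population × population distance matrices: great-circle km from
coordinates; barrier counts from ordered zones along the mountain chain
(count encoding by default, binary available — the source is ambiguous);
song-spectral distance as Euclidean distance between population centroids
in retained-PC space; song-syntax distance as Euclidean distance over
(mean SVI, mean category proportions); genetic F_ST always as an input
matrix, never estimated. `mantel` correlates upper triangles with
significance by joint row/column permutation, one-tailed positive by
default (the isolation hypotheses are directional), add-one correction
for sampled permutations, and exact enumeration whenever n! fits in the
permutation budget — with six populations, all 720 relabelings are always
enumerated, so p-values are exact and seed-free. `partial_mantel`
correlates residuals after regressing both triangles on the control
matrix, permuting the first matrix with residual recomputation.

## The synthetic-data generator

`simulate_dataset` generates note tables with the hierarchical structure
the analysis assumes, plus a ground-truth ledger, so every stage is
testable by parameter recovery. Per individual:

* a pool of 10 note classes on a 4 × 4 duration × bandwidth grid with
  ratio-1.5 spacing (33% relative steps, beyond the 20% matching
  tolerance) scaled by population means and a lognormal individual factor
  (σ capped at 0.08 so the grid stays separated);
* song types are class sequences (length 4–9, no immediate repeats, an
  optional trill position whose run length is redrawn at each rendition);
  a global registry rejects any type whose realized class sequence could
  match another individual's, so repertoires are disjoint by
  construction — emulating the observation that wild individuals share no
  song types;
* bouts follow a 4-state Markov choice among new / mod / old / same with
  probabilities (0.8t, 0.2t, 0.6(1−t), 0.4(1−t)) from the repertoire
  turnover t, under availability constraints (first song new; "old" needs
  an earlier type other than the previous one). "Mod" copies a contiguous
  ≥ 2-class block from an earlier bout song and adds or deletes notes,
  matching the classifier's rule by construction; planted "new" types
  avoid bigram overlap with earlier bout songs so the classifier can
  recover the planted category. `expected_svi` computes the implied SVI
  expectation for any t by Monte Carlo of the same chain;
* notes are realized with 2% lognormal rendition jitter; with probability
  `cvm_prob` an internote interval is drawn uniformly from [−10, 2) ms,
  otherwise uniformly from a silent-gap window — [10, 300] ms generically,
  or [0.5, 1.5] × (1/delivery_rate − mean note length) when a
  delivery-rate target is set, so tempo differences are realized without
  contaminating the CVM window;
* the synthetic F_ST matrix is α·(barrier count) + β·(km) + Gaussian
  noise, clipped to [0, 0.5] (α = 0.06, β = 2·10⁻⁴, σ = 0.015).

The default configuration is study-shaped: six populations (BRAH, OOTY,
GRHL, KODI, HWS, PEP) in four barrier zones separated by three barriers,
38 individuals (range 2–10 per population, the small northern BRAH
population contributing two), 11–30 songs per individual drawn uniformly
(matching the reported 22 ± 7, range 11–30 sampling effort at the moment
level). Coordinates are plausible Western Ghats placements spanning
roughly 600 km, not the true site coordinates, which are unpublished.
Three spectral clusters are planted — slow, narrow-band, low-frequency
northern songs (BRAH, OOTY, spread along the geographic gradient); fast
broadband central songs (GRHL, KODI, HWS); and a distinct high-frequency
southern population (PEP) positioned mid-gradient on the tempo axes.
That last choice is deliberate: geography and barrier counts are strongly
collinear in a linear sky-island chain, and a population spectrally
extreme in frequency but intermediate in tempo breaks the monotone
alignment of spectral distance with barrier count, so the design plants
"spectral traits follow geographic distance" and, through barrier-zone-
linked turnover values (0.20 / 0.45 / 0.70 / 0.95), "syntax follows
barriers" as recoverable, distinct signals. CVM prevalence differs
between every pair of populations (0.02–0.55), including within the
central cluster, mirroring the idea that CVM usage separates even
recently fragmented, genetically similar populations.

What the generator does **not** emulate: realistic note shapes or
frequency contours (only interval-level statistics), within-bout temporal
autocorrelation of CVM usage, observer error in note annotation, and
recording noise. Passing tests therefore demonstrate that the estimators
recover their targets under the assumed hierarchical model, not that the
pipeline is robust to annotation error in field data.

## Numerical choices and problem sizes

Deterministic tie-breaks everywhere: note sorting by start then end time;
greedy class matching in canonical dataset order; PCA/DFA sign fixing by
largest loading. All stochastic steps (bout selection, bootstrap, NMDS
restarts, Mantel sampling, simulation) take explicit seeds; the pipeline
fans a single master seed out to fixed per-stage offsets so stages can be
rerun in isolation. Mantel p-values with six populations are exact
(720-term enumeration). The test suite sizes its simulations to run on a
single CPU in minutes: type-I calibrations use 2000 replicates of
five-population matrices at 199 permutations (where the achievable
rejection level of the add-one estimator at α = 0.05 is 0.045);
bootstrap-coverage experiments use 200 replicates of a 20-individual
population with 400 bootstrap draws; qualitative study reconstruction
aggregates three replicate simulations, because single draws of
population-level distance matrices built from 2–10 individuals are
noisy.

## Known limitations

* The note-matching tolerance (20%) stands in for a visual judgement; the
  SVI level (though not its ordering across populations) shifts with it.
* The "mod" rule is an explicit proxy for "contains a combination of
  notes exactly copied from a previous song"; other operationalizations
  are defensible.
* Nested effects are fixed, not random; with very few individuals per
  population the population F is anti-conservative in the random-effects
  reading.
* Resubstitution classification rates are optimistic; use
  `cv = "individual"` for honest rates.
* F_ST is consumed, never estimated; the synthetic F_ST is a toy
  landscape model for exercising the Mantel battery.
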