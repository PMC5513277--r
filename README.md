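# songdiff

Quantifying population-level differentiation in birdsong from note-level
spectrogram annotations.

Songbird populations isolated on mountaintop "sky islands" diverge not only
genetically but also culturally: their learned songs drift apart. Because
song is transmitted by learning, different song traits can respond to
different mechanisms of isolation — gradual change with geographic distance
versus sharp breaks across dispersal barriers (ancient valleys, rivers,
deforestation gaps). `songdiff` implements a complete analysis pipeline for
testing these patterns from Raven-style selection tables (one row per
annotated note: start/end time in seconds, low/high frequency in Hz, plus
population / individual / song labels), with no audio processing required.

The pipeline has five analysis stages plus a first-class synthetic-data
generator:

1. **Ingest** (`read_selection_table`, `assemble_songs`,
   `summarize_dataset`) — validate note tables and organize them into
   songs, bouts, individuals and populations.
2. **Spectral traits** (`song_features`) — 14 song-level variables: mean
   and SD of note length, high frequency, low frequency and note
   bandwidth; song bandwidth; song duration; number of notes; delivery
   rate; and two complex-vocal-mechanism (CVM) indicators. A CVM —
   two-voice use of both syrinx halves, or nonlinear dynamics of one — is
   indexed by internote intervals shorter than a minibreath (< 2 ms) and
   by temporal overlap of consecutive notes, each scaled by the number of
   notes in the song. `frequency_shifts` / `ks_compare_shifts` test
   whether frequency jumps between notes are larger across sub-minibreath
   intervals (two-sample Kolmogorov–Smirnov).
3. **Syntax complexity** (`song_signatures`, `select_bout`,
   `classify_bouts`, `build_library`) — song types are equivalence classes
   of note-composition signatures (notes matched on duration and
   bandwidth within a relative tolerance; trills collapsed; absolute
   frequency ignored). On a fixed bout of N = 11 consecutive songs per
   individual the Song Variety Index is SVI = distinct types / N, and each
   song is classed as new / modified / old / same. A cross-population
   song-type library and individual-by-individual sharing matrix follow,
   with grouped percentile-bootstrap confidence intervals
   (`bootstrap_summary`, 1000 replications).
4. **Multivariate differentiation** (`pca_reduce`, `nested_manova`,
   `nested_anova_per_pc`, `discriminant_analysis`, `nmds`,
   `kruskal_dunn`) — PCA of the 14 traits on the correlation matrix
   (retain eigenvalues > 1), nested MANOVA/ANOVA (songs within individuals
   within populations; the population effect is tested against the
   individual stratum, Wilks' Λ with Rao's F), canonical discriminant
   analysis with resubstitution classification, NMDS ordination, and
   Kruskal–Wallis with Dunn–Bonferroni post hoc tests of CVM usage.
5. **Isolation analysis** (`geographic_distances`, `barrier_distances`,
   `song_distance_matrices`, `mantel`, `partial_mantel`) — population ×
   population distance matrices (great-circle km, ordered barrier counts,
   song-spectral, song-syntax, and a genetic F_ST matrix consumed as
   input) compared by Mantel and partial Mantel permutation tests
   (one-tailed positive by default; exact enumeration when the number of
   populations is small).
6. **Simulation** (`simulate_dataset`, `default_study_config`,
   `recover_parameters`, `reconstruct_study`) — a hierarchical generator
   of note tables with planted population differences in note length,
   bandwidth, delivery rate, CVM prevalence and repertoire turnover, a
   ground-truth ledger, and recovery checks for every stage.

## Worked example

Simulate the default study-shaped dataset — six populations on four sky
islands (~600 km span, three barriers), 38 individuals, 11–30 songs each —
and run the full pipeline:

```r
library(songdiff)
sim <- simulate_dataset(seed = 1)
report <- run_pipeline(sim, seed = 1)
print(report)
```

```
== Song differentiation report ==
Dataset manifest
  populations: 6 (BRAH, GRHL, HWS, KODI, OOTY, PEP)
  individuals: 38   songs: 778   notes: 5231
  songs per individual: 20.5 +/- 5.6 (range 11-30)
Syntax stage: 418 songs in 38 bouts of 11; 293 unique song types
Cross-individual shared song types: 0
PCA: retained 3 component(s) (eigenvalue > cutoff), 71.6% of variation
Nested MANOVA: population F = 55.14 (p = 9.96e-37), individual F = 4.99 (p = 5.74e-46)
Canonical discriminant analysis: 3 axes, correct classification 67.1% (resubstitution)
  canonical correlations: 0.94, 0.82, 0.22
NMDS: 778 points in 2 dimensions, stress = 0.1507
CVM short-interval rate by population: Kruskal-Wallis chi-square = 98.69, df = 5, p = 9.96e-20
Frequency shifts across minibreath boundary: KS D = 0.125, p = 9.24e-12
Mantel battery:
                      test partial      r      p
1      spectral~geographic   FALSE  0.733 0.0042
2         spectral~barrier   FALSE  0.842 0.0083
6        syntax~geographic   FALSE  0.964 0.0042
7           syntax~barrier   FALSE  0.977 0.0083
...
```

Reading the output: the syntax stage analyzes exactly 11 songs from each
of the 38 individuals (418 songs); no song type is shared between
individuals; population-level spectral differences dwarf
individual-within-population differences (F = 55.1 vs 5.0); songs classify
back to their population well above the 1/6 chance rate; and syntax
distances track barrier counts more strongly than spectral distances do —
the pattern the simulated landscape plants.

`recover_parameters(sim, report)` compares every measured quantity with
the generating parameters (CVM rates against `cvm_prob · (n−1)/n`, SVI
against the bout-chain expectation, discriminant confusion against the
planted clusters, sharing against the disjoint-repertoire construction).

A thin command-line front end is included at `inst/exec/songdiff`
(subcommands `simulate` and `run`).

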