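---
title: "Methods: feature prioritization and genotoxicity prediction for HPTLC-based EDA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feature prioritization and genotoxicity prediction for HPTLC-based EDA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edatox)
```

## Scope and data model

`edatox` operates downstream of vendor peak picking and retention-time
alignment. Its unit of analysis is the *feature*: a retention time, an
exact ion m/z (here positive-mode [M+H]⁺ with a neutral monoisotopic
mass), per-sample injection-replicate areas, and optionally MS2 spectra.
Samples play one of four roles: the unfractionated *parent* extract,
*zone fractions* eluted from bioactive HPTLC zones (by TLC-interface
elution or manual silica scraping with methanol or ethyl acetate),
*blank fractions* cut from unused plate regions, and off-zone fractions.
Areas keep a per-replicate `gap_filled` flag: gap filling imputes values
below the picking threshold during alignment, and an imputed value is
never treated as a detection. This single flag drives most of the
filter semantics, which is why areas are stored per replicate rather
than pre-averaged — each rule chooses its own aggregation.

Mass arithmetic uses hard-coded most-abundant-isotope masses (IUPAC, nine
decimal places) for {C, H, N, O, S, Cl, Br, F, P, Na, K} and a proton mass
of 1.007276 Da (electron accounted). Isotope patterns, multiple charging,
and negative-mode adducts are out of scope: the workflow's decisions rest
entirely on monoisotopic exact masses.

## The filter cascade

A feature survives zone *z* when four conditions hold jointly.

| rule | condition | default |
|---|---|---|
| parent abundance | mean non-gap-filled parent area, strictly above threshold | 10⁶ area units |
| fraction/parent ratio | `ratio_low` ≤ Ā_frac/Ā_parent ≤ `ratio_high`, inclusive | 0.10–0.75 |
| blank exclusion | Ā_frac strictly above `blank_factor` × max blank peak | 10× |
| zone exclusivity | no genuine off-zone replicate above the abundance threshold | — |

Rationale for the ratio window: fractionation recovers only part of a
compound (observed recoveries are ≈10% for interface elution and ≈38% for
manual scraping), so a fraction/parent ratio near 1 marks ubiquitous
background rather than a zone-resident compound, and a very low ratio is
indistinguishable from carry-over. For low-recovery elution methods,
`ratio_low` can be relaxed (e.g. to 0.05), which by construction can only
grow the surviving set — the cascade is monotone in each threshold, and
being a pure conjunction it is invariant to rule order. Both properties
are exercised by the test suite against a brute-force loop oracle.

Three points were genuinely open and are package decisions:

* **Inclusivity of the ratio bounds.** "Between 10 and 75%" is read
  inclusively; the boundary cases are configuration-sensitive and tested
  at exactly 0.10 and 0.75.
* **Strictness.** "Above the threshold" and "above 10 times greater" are
  strict comparisons; a parent mean of exactly 10⁶ fails.
* **What "detected" means off-zone.** In blank fractions any genuine peak
  counts (no abundance floor). In off-zone fractions the default requires
  a genuine peak above the abundance threshold, because threshold-free
  exclusion would be dominated by gap-filling noise; a config switch
  (`off_zone_any_peak`) restores the stricter reading.

Replicate aggregation is the arithmetic mean over non-gap-filled
replicates that are present; a group with no genuine replicates
contributes 0. Fractions stamped directly above/below a zone's centre
share the zone's label; "off-zone" means a different zone letter.

## Merging and suspect screening

Feature tables from separate runs are merged by connected components
under |Δmass| ≤ 2 ppm (of the larger mass) *and* |Δrt| ≤ 0.2 min. The 2 ppm
matches the alignment tolerance of Orbitrap non-target workflows; the rt
tolerance is a package choice, narrow relative to a ~27-min gradient,
since vendor alignment internals are opaque. Cluster representatives take
area-weighted mean mass/rt — stable under replicate noise — and the
lexicographically smallest member id, making the merge order-invariant
and idempotent on the feature set.

Suspect screening annotates a feature with every list entry whose neutral
monoisotopic mass lies within 2 ppm, sorted by absolute error. Suspect
masses are recomputed from formulas when absent, and a supplied mass must
agree with its formula within 2 ppm — a guard against transcription
errors in curated lists.

## In-source fragment grouping

In-source ionization artifacts appear as extra MS1 features at the intact
compound's retention time. Two co-eluting features (|Δrt| ≤ 0.05 min) are
linked when (a) their MS2 spectra share at least `min_shared = 2` fragment
ions, matched one-to-one closest-first within 0.005 Da, or (b) one
feature's intact ion m/z occurs among the other's MS2 fragments. Groups
are connected components (transitive closure is intended: a fragment
series of one chemical should collapse even if the extreme members share
nothing directly); the highest-mass member is flagged as the plausible
intact compound. No numeric tolerances for "shared fragment" are given in
published workflows that rely on manual inspection, so the defaults were
fixed once: tight enough to tolerate only small synthetic jitter
(rt_tol = 0.05 min, mz_tol = 0.005 Da), loose enough that the packaged
13-feature example reproduces its documented collapse into 8 chemicals.
Downstream ranking still treats features independently; groups annotate
the report. Adduct/isotopologue networking and cross-sample correlation
evidence are out of scope.

## Genotoxicity models

Endpoint datasets pair binary molecular fingerprints (default length
2048) with activity calls. Two curated endpoint families are emulated:
p53 pathway activation (prior ≈ 723/5953 active) and DNA damage in
repair-deficient DT40 lines (prior ≈ 257/3057). DT40 activity is defined
through sensitivity ratios: a chemical is active when wild-type AC50 /
mutant AC50 ≥ 2 in at least one mutant line. The 2-fold default is a
package decision — the ratio construction is standard but no numeric
cutoff is published — as is the conservative treatment of missing data:
chemicals untested in all mutant lines, or lacking a wild-type AC50, are
inactive. Ratios are invariant under common rescaling of concentrations,
so units cancel.

Classifiers are gradient-boosted trees (xgboost) with fixed shallow
settings: depth 4, learning rate 0.3, 80 rounds, no subsampling, one
thread, positive-class weight `n_inactive/n_active`. There is no
hyperparameter search: fixed settings keep runs desk-scale and exactly
seed-deterministic, which the suite asserts. The split is stratified
0.85/0.15; held-out balanced accuracy, sensitivity and specificity are
attached to the model, and model artifacts serialize to a self-describing
JSON (schema version, fingerprint length, seed, metrics, booster) from
which predictions reproduce exactly.

A feature is called *potentially genotoxic* when P > 0.5 (strictly) in at
least one endpoint — the "more likely than not, anywhere" rule. It is
monotone in every probability and deliberately asymmetric: one confident
endpoint suffices.

Fingerprints are consumed as input (or simulated); predicting
fingerprints from MS2 spectra is an upstream tool's job, and reproducing
published model weights is explicitly not attempted — the package
validates the *procedure* by parameter recovery on synthetic data
(below), not the published numbers.

## Candidate ranking and priority

Candidate structures are ranked against a feature's fingerprint by
Jaccard (Tanimoto) similarity over bits. This is a documented stand-in
for proprietary spectral-ranking scores; every downstream statistic
depends only on the rank order, so any strictly monotone transform of
the score yields identical reports (tested). Ties break
lexicographically by structure id, making ranking total and
deterministic.

The top decile of *n* candidates contains round-half-up(*n*/10) members,
minimum 1. Round-half-up is the only rule consistent with all the
documented count pairs (1085→109, 311→31, 356→36, 1283→128); reported
percentages are likewise rounded half-up to one decimal, with raw ratios
retained in machine output, since printed roundings in the source
tables are not internally consistent at the second decimal.

The final priority key is: any-endpoint activity (desc), top-decile
percent active (desc), overall percent active (desc), parent abundance
(desc), feature id. It encodes the evidence hierarchy — MS2-level
activity first, then agreement among top-ranked structures — and leaves
no ties.

## The synthetic-study generator

`simulate_study()` emulates, at the aligned-feature-table level, the data
an EDA study produces: log10-normal parent areas (mu 6.8, sigma 0.6, so a
realistic minority falls below the 10⁶ threshold, matching observed
parent areas of 10⁶–10⁸); four zones with per-method recoveries
(interface 0.10, manual 0.38, optionally Beta-distributed); blank-origin
features and low-level blank contamination of matrix features;
injection triplicates with multiplicative log-normal noise (CV 10% —
no replicate-variance figures are published, so this is a package
choice); gap-filled rows emitted for absent feature/sample pairs with
probability 0.5 to exercise the "no filled gaps" logic; in-source clone
clusters sharing retention time and planted fragment ions (85.0283,
99.0440, 127.0389 by default, for recognizability); spiked chemicals
that obey their specification exactly; suspect lists with decoys; and
fingerprints whose true activity is the OR of planted rule bits. The
per-bit probability of the rule bits is set so the *post-noise* label
prior matches the requested active fraction in expectation. Everything
is reproducible from one integer seed.

What the generator does **not** emulate — and what green tests therefore
do not show about real data: chromatographic peak shapes and integration
error, mass-accuracy drift, retention-time warping across runs,
structured (non-random) fingerprint correlations between related
chemicals, assay dose–response, and matrix-dependent ionization
suppression. The generator validates the *logic* of the pipeline
(filters, grouping, ranking, learning), not instrument physics.

Degenerate inputs are defined behaviour: an empty configuration yields an
empty table; a feature absent from blanks has blank maximum 0; an
all-gap-filled replicate group aggregates to 0; a single-class endpoint
dataset refuses to train.

## Validation strategy and problem sizes

The test suite pairs every non-trivial operation with an independent
oracle: the filter cascade against a plain-loop enumeration (1000 random
tables of 12 features, two zones); in-source grouping against
breadth-first-search components on 1000 random graphs of ≤ 15 nodes
realized as planted fragment sets; greedy fragment matching against
exhaustive optimal assignment on ≤ 8-peak spectra; Jaccard ranking and
candidate statistics against brute-force recounts. End-to-end, a spiked
chemical at 38% recovery is recovered by the default cascade in 100 of
100 seeded studies and a 5%-recovery spike in none, reflecting the ratio
window's design. Classifier checks train on 2000 planted-rule
fingerprints of length 256 across five seeds (balanced accuracy ≥ 0.9;
the padding-bit count does not affect learnability of a 3-bit rule) with
a permuted-label null near 0.5, and feature importance concentrates on
the planted bits. These sizes are the package's chosen desk-scale
defaults; the generator itself defaults to parent-extract scale
(2693 matrix features).

## Known limitations

* The fraction-to-zone mapping arrives as labels; plate-image analysis
  and zone-coordinate detection are out of scope.
* Similarity ranking is a stand-in; with real spectral-ranking scores
  the candidate statistics are computed identically from the supplied
  order.
* Classifiers share the fate of their training data: the synthetic
  planted-rule datasets demonstrate procedure correctness, not
  real-endpoint accuracy; applicability-domain estimation is not
  implemented.
* Only [M+H]⁺ is supported; chemicals ionizing otherwise are invisible
  to the suspect matcher and the m/z consistency checks.
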