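---
title: "Methods: ligand-based target deconvolution of phenotypic screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ligand-based target deconvolution of phenotypic screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depickr)
library(tibble)
```

## The problem

Phenotypic suppression screens score compounds by whether they rescue a
disease phenotype in a whole organism or cell model, and therefore say
nothing directly about mechanism. depickr implements the computational route
from such screens to candidate protein targets: compounds are fingerprinted
and deduplicated across libraries, each screened compound receives known and
ligand-based predicted targets, and each target is tested for statistical
over-representation among the screen's active compounds. Two companion
analyses quantify cross-screen agreement (a permutation test on the number
of shared actives) and the biology of the resulting target sets (GO
biological-process enrichment with is_a propagation). A set of small
summary-statistic routines reproduces the auxiliary numbers such studies
print: hit rates, pooled t-tests and one-way ANOVA with Tukey comparisons
recomputed from published group summaries, comparative-Ct fold changes,
network summaries, and MeSH D27 category tallies.

## Fingerprints and deduplication

Compounds are represented as circular (Morgan/ECFP-style) fingerprints: sets
of hashed atom-environment identifiers. The initial identifier of an atom
hashes its element, degree and formal charge; each iteration up to the
radius re-hashes the previous identifier together with the sorted
(bond order, neighbour identifier) pairs. Radius 2 (the ECFP-4 convention)
is the default everywhere. A degree-0 atom's environment cannot grow, so its
identifier is constant across iterations and contributes a single feature.

Two numerical choices matter:

* **Hash function.** Feature identifiers come from a seedless, platform-
  stable 31-bit polynomial string hash (base 131 modulo the Mersenne prime
  2^31 − 1). All intermediate products stay below 2^38, so the arithmetic is
  exact in doubles on any platform and features stay within R's native
  integer range. A wider hash would reduce the (already negligible at
  library scale) collision probability but cannot be computed exactly in
  base R doubles; externally computed fingerprints (e.g. RDKit ECFP) can be
  supplied via `read_fingerprints()` and flow through every downstream step
  unchanged.
* **Desalting tie-break.** `desalt()` keeps the largest connected component;
  equal-sized components are ordered by their sorted radius-2 feature
  multiset and the lexicographically smallest wins, which makes the choice
  deterministic by construction.

The native SMILES reader covers the minimal subset needed for library
ingestion (organic-subset and bracket atoms, charges, branches, rings,
single/double/triple bonds, dot-disconnection). Aromaticity is *not*
perceived: lowercase aromatic atoms are read as their element with single
ring bonds. Structures beyond the subset should be fingerprinted with a
chemistry toolkit and loaded through the pass-through path.

Duplicate collapsing uses Tanimoto similarity `|A∩B|/|A∪B|` with a default
threshold of 1.0 — "duplicate" means identical feature sets, not close
analogy — and transitive closure at lower thresholds. Canonical ids are the
lexicographically smallest member id (radix order, locale-independent).

## Ligand-based target prediction

Prediction against a reference association database follows the
k-nearest-neighbour / naive Bayes design of ligand-based target prediction
servers. For a query fingerprint:

1. **Neighbour space.** Database compounds are sorted by descending Tanimoto
   similarity (ties by ascending id) and the shortest prefix covering 10
   distinct annotated targets is retained. Compounds with zero similarity
   share no substructure with the query and are excluded from the space; a
   query with no structural overlap to the database receives no predictions
   rather than arbitrary ones.
2. **Scoring.** Each candidate target t is scored with a Laplacian-corrected
   naive Bayes sum over query features f:
   `score = Σ_f ln[(A_ft + 1) / (A_f·P(t) + 1)]`, where `A_ft` counts
   annotated compounds of t containing f, `A_f` counts all compounds
   containing f, and `P(t)` is t's annotation prior. Features unseen in the
   database contribute `ln 1 = 0`, so the score is additive over disjoint
   feature sets and insensitive to vocabulary mismatch.
3. **Ranking and precision.** Targets are ranked by descending score (ties
   by descending occurrence in the space, then id), capped at 10, and each
   prediction receives an empirical precision from cross-validation:
   leave-one-out by default, each held-out compound fully removed from the
   counts and the neighbour search. Predictions are binned over occurrence
   (1/2/3/≥4) × rank (1/2/3/4–10) × maximum Tanimoto
   ([0,0.4), [0.4,0.7), [0.7,1]); per-bin precision is the fraction of
   cross-validated predictions whose target was truly annotated. Bins with
   fewer than 20 predictions fall back to the marginal rank-bin precision,
   then to the overall precision — coarse, monotone-friendly bins that do
   not overfit small reference databases.

Ranking by score (not occurrence) and binned empirical precision (not a
parametric model) were genuinely open design choices; both are the simplest
readings consistent with the published server description, and the
calibration artifact is a plain JSON table so an alternative calibration can
be dropped in.

## Target enrichment (DePick)

Per screened compound, the target set is the union of known annotations
(precision 1.0 by definition) and predictions with precision strictly above
0.5. Compounds exceeding 100 known-or-predicted targets are discarded as
promiscuous; compounds with no targets leave the analysis universe. The
universe for the hypergeometric test is therefore *all screened,
non-promiscuous compounds with at least one target — actives and inactives
alike*; alternative universes were considered (inactives-only backgrounds,
annotated-actives conditioning) but the symmetric definition matches how
active and inactive sets are described in this analysis tradition and keeps
the universe stable under relabelling. The test is one-sided (enrichment
only), `k = 0` targets are retained at `p = 1` so the
Benjamini–Hochberg family does not shift, and BH adjustment is applied
within one screen's target family at FDR 10%.

The identical kernel (`hyper_enrichment()`) backs GO enrichment, so both
paths are exercised by a single set of kernel tests, including exhaustive
enumeration of all `C(N, n)` active assignments for `N ≤ 12` and a
hand-computed BH step-up oracle.

## Cross-screen overlap significance

The shared-active statistic shuffles the first screen's active labels
uniformly over its compounds, keeping the second screen's actives fixed, and
counts how often the number of shared actives reaches the observed count.
Because only one label vector moves, the per-permutation count is exactly a
hypergeometric draw (population = screen A, marked = B-active shared
compounds, draws = A-actives); the implementation samples it directly with
`rhyper()`, which makes one million permutations a sub-second computation
while remaining a genuine Monte-Carlo permutation test. The analytic
upper-tail hypergeometric probability is always returned alongside as an
exact oracle, and `shuffle_both = TRUE` switches to literal permutation of
both label vectors. An empirical p of exactly zero is printed as
`< 1/n_perm` in text output while the numeric field stores 0.

When only screen dimensions are published, `dual_screen_from_counts()`
materialises id sets matching them; the number of B-actives inside the
shared subset defaults to the proportional assumption
`round(n_shared · n_active_B / n_B)` — an assumption, not data, and
overridable with real membership lists.

## GO enrichment

The OBO reader consumes `[Term]` stanzas (id, name, namespace, is_a),
skips obsolete terms and rejects cyclic is_a graphs naming a cycle member.
Annotations (GAF or GPAD, auto-detected by column count; NOT-qualified rows
dropped) are closed upward along is_a edges only — part_of is deliberately
ignored, as propagation along is_a is what the analysis this package
implements used. The background universe counts only ids carrying at least
one propagated annotation (configurable), since unannotated ids are
uninformative for term enrichment and silently inflate `N`.

## Summary statistics

The group-summary routines exist because published tables often print only
(mean, SD, n). `pooled_t_test_summary()` is the pooled-variance Student
test — the printed p-values of the motivating study reproduce under the
pooled form, not Welch. `anova_tukey_summary()` pools within-group variance
into the MSE, uses the equal-n studentized-range statistic with the
Tukey–Kramer standard error for unequal n, and takes adjusted p-values from
`ptukey()` (accurate to well below 1e-4). Reproducing a Tukey p-value from
*rounded* printed summaries rather than raw data shifts results at the
±0.002 level, which is why the round-trip tests compare against `aov()` +
`TukeyHSD()` on raw samples and the printed-value checks carry a small
absolute tolerance. `ddct_fold_change()` normalises against the arithmetic
mean of reference-gene Cts (the geometric mean of reference quantities),
the standard multi-reference convention. Degenerate inputs are handled
explicitly: two identical groups with zero SD give `p = 1` with a flag,
zero error variance with unequal means is an error, and the SEM of a single
value is 0 by convention with a warning.

## What the synthetic generators emulate

`sim_config()` freezes the study conditions all generators draw from. The
defaults mirror the motivating study's printed dimensions at roughly one
tenth scale: screens of 160 and 475 compounds sharing 108, expected hit
rates 8.4% and 7.4%, a reference database of 560 compounds annotated to 16
targets (two per compound), and one designated disease target whose carriers
are active with five-fold elevated probability in both screens — which
plants, at once, within-screen target enrichment and a cross-screen excess
of shared actives. Structural signal is planted as disjoint 8-feature blocks
per target carried at probability 0.9 by annotated compounds against a 2%
background rate, in a 512-feature universe. Baseline rates are solved so the
expected hit rate matches the configured one. The seeded power and
type-I-error properties in the test suite run at these defaults: the planted
target is tested on the larger screen (recovery in ≥ 80% of 200 seeded
simulations at FDR 10%) because ~13 actives in a 160-compound screen simply
do not carry enough information for reliable recovery at any realistic
target-family structure, while the ~35 actives of the larger screen do; the
null configuration (`active_excess = 1`) bounds the fraction of datasets
with any significant target near the nominal 10%.

Random feature sets are not chemistry: they preserve the statistical
structure the predictor exploits (shared substructure ⇒ shared targets) but
none of the property distributions, scaffold clustering or activity cliffs
of real libraries. Passing tests on synthetic data therefore validate the
algorithms and their calibration, not predictive performance on real
compounds — that depends entirely on the reference association database
supplied by the user.

## Problem sizes and runtime

The test suite computes everything it asserts: 200 recovery and 500 null
screen simulations against one 560-compound database, 200 planted-block
prediction queries, 20-seed ontology simulations, and one million
permutations for the study-scale overlap test (seconds, via the
hypergeometric draw). The whole suite runs in a few minutes on one CPU;
the acceptance script in under a minute.

## Known limitations

* No aromaticity, stereochemistry, tautomer or valence handling in the
  native SMILES path; the pass-through fingerprint path is the route for
  real chemistry.
* The 31-bit feature hash admits collisions in principle; at library scale
  (≤ 10^5 distinct environments) the expected collision count is small, and
  collisions only ever merge features (slightly blurring similarity), never
  crash the pipeline.
* Precision calibration on small synthetic databases occupies few bins; the
  fallback rule then dominates, which is intended but means calibrated
  precisions on toy databases are coarse.
* The proportional assignment of screen-B actives to the shared subset in
  `dual_screen_from_counts()` is an assumption to be replaced with real
  membership lists whenever they exist.
* Multi-screen (> 2) overlap statistics and part_of propagation are out of
  scope.
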