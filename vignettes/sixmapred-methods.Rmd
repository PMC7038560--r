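---
title: "Methods: sequence features and evaluation protocol for 6mA prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence features and evaluation protocol for 6mA prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sixmapred)
```

This vignette documents the model behind `sixmapred`, the choices that were
genuinely open when it was built, and what its tests do and do not
establish.

## The prediction problem and its assumptions

The unit of prediction is a 41-nt DNA window with a candidate adenine at
position 21. The central assumption is that adenine methyltransferase and
demethylase activity is guided by the local sequence context, so the
neighbourhood carries enough signal to discriminate methylated from
unmethylated adenines. Everything downstream — features, selection,
classifier — operates on that window only; chromatin state, replication
timing and any other cell-state information are outside the model.

Windows must be pure A/C/G/T. Ambiguous bases are rejected at validation
rather than imputed, because every encoder below assumes a 4-letter
alphabet; silently imputing an N would manufacture features from data that
is not there.

## Feature families

**EIIP trinucleotide features (64).** Each trinucleotide *xyz* contributes
the mean electron–ion interaction pseudopotential of its three bases
multiplied by its frequency in the window. "Frequency" is taken as
overlapping count divided by the number of trinucleotide start positions
(L − 2 = 39), so frequencies sum to 1 and every feature is bounded by the
largest per-base value (0.1340). Other normalizations (e.g. by count of the
most frequent trinucleotide) would not give a probability simplex, which is
why the per-position normalization was chosen.

**PSTNP (39 + 39).** The propensity matrices are positional frequency
differences between classes, so each entry lies in [−1, 1], zero means "no
information at this position", and swapping the classes negates the matrix
exactly — properties the test suite asserts. Rows are indexed
lexicographically (A < C < G < T; A < C for the double-stranded reduction)
so serialized models are portable. PSTNP is the only encoder fitted from
labeled data, which has a protocol consequence discussed under
*Evaluation* below.

**Physicochemical Type-II features (30).** Lagged products of standardized
dinucleotide step properties, lags m = 1..5 over Λ = 6 properties, ordered
lag-major. Two numerical choices deserve note:

- *Standardization is a z-score.* Each property is centered and scaled to
  mean 0, SD 1 across its 16 dinucleotide values before use. Any affine
  transformation of the raw property values therefore leaves the features
  unchanged; only the relative pattern across dinucleotides matters.
- *The normalizer is fixed at 1/(L − k − 1) for every lag* (k = 2), while
  the lag-m sum has L − k − m terms. The last dinucleotide of the window
  is also excluded as the left partner of a pair. This makes longer lags
  carry slightly smaller magnitudes by construction. A
  `normalize_per_lag` switch divides each lag by its own term count
  instead, for users who prefer an unbiased per-lag mean; it is off by
  default so that the default output matches the fixed-normalizer
  definition the encoder documents.

The bundled property table (`inst/extdata/dinuc_bdna_properties_synthetic.tsv`)
is a synthetic, complementary-symmetric compilation of typical B-DNA step
parameters (Rise, Roll, Shift, Slide, Tilt, Twist), not a snapshot of any
external database; it satisfies the double-strand symmetry
value(XY) = value(revcomp(XY)) that physical step parameters must. Because
of the z-score invariance above, the tests validate the physicochemical
encoder against an in-repo brute-force oracle rather than against any
published feature values, and users with a preferred property source can
supply their own table via `dinuc_properties(path = ...)`.

## Entropy profiling

`positional_entropy()` summarises positional conservation as the Shannon
entropy (bits) of the trinucleotide distribution at each start position:
0 for a perfectly conserved position, 6 bits for uniform use of all 64
trinucleotides. Positions whose trinucleotide overlaps a fixed base (the
central adenine) can reach at most 4 bits, since only 16 combinations
remain — visible as a dip in any profile of valid windows, independent of
methylation signal.

## Dataset construction

For genome + site-table input the package applies, in order: a Qv
confidence filter (keep Qv ≥ 30, the boundary kept, matching a p < 0.001
detection confidence); ±20-nt window extraction (1-based inclusive
coordinates; minus-strand sites yield the reverse complement so the
methylated adenine always reads A at position 21 — the only convention
consistent with the center-A contract); negative sampling of plus-strand
adenines more than 500 bp from every positive on the same chromosome,
without replacement and seeded; and greedy redundancy reduction. The
redundancy filter is an order-dependent greedy pass using plain
column-wise (Hamming) identity — windows are equal-length, so no alignment
is needed — keeping a window only if its identity with every previously
kept window is below 0.6. It guarantees a maximum pairwise identity below
the threshold but, like any greedy filter, is not a clustering method: the
kept set depends on input order.

## Feature selection

The ranking score is relevance plus diversity:
|Pearson(x, y)| + mean standardized-column distance to the other features,
normalized by the maximum pairwise distance so the term is scale-free and
in [0, 1]. Euclidean distance is the default; cosine is available. This
decomposition is one reasonable reading of the maximum-relevance
maximum-distance family — the family fixes the structure (relevance term
plus inter-feature distance term) but not the weights or metric, so the
package defines and documents a concrete, testable instance. Constant
features get relevance 0 rather than an error. Ties are broken by original
column order, and every tie-break in the package (including the IFS prefix
and grid argmax) goes to the smallest index, for determinism.

Incremental feature selection evaluates prefixes of the ranking by
stratified k-fold CV accuracy with one shared fold assignment, selecting
the smallest prefix attaining the maximum. The sweep cost is linear in the
prefix cap `max_k`; desk-scale runs in the tests cap it at 5–40 features,
a size chosen to exercise the curve shape while keeping a full pipeline
run in seconds.

## Classifier and tuning

Gradient-boosted trees with logistic output. `n_rounds` defaults to 100
(the library-conventional value), `nthread = 1` and a fixed seed so that
training is bit-reproducible — a property the suite asserts through
repeated runs and serialization round-trips. Grid search explores
gamma ∈ {0, 0.1, 0.2}, eta ∈ {0.1, ..., 0.5} and max_depth ∈ {2, 4, 6, 8,
10} (75 points) by default, with a much denser `fine_grid()` preset
(gamma step 0.002, eta step 0.05, depth step 1) for production-scale
tuning; all points share one fold assignment, so the comparison is paired
and invariant to enumeration order. The decision threshold is 0.5 with the
boundary classified positive — a convention, exposed as a predictor field.

## Evaluation

Metrics are computed in their error-rate form (Sn = 1 − FN/N⁺, etc.); the
suite property-tests their exact agreement with the textbook TP/TN forms
over a thousand random confusion tables, and reports metrics as `NA` when
a denominator class is empty instead of erroring. auROC is the midrank
Mann–Whitney statistic (exact under ties) with curve points at every
distinct threshold; trapezoidal integration of the curve reproduces the
area to 1e-10.

Because PSTNP is fitted from labeled data, fitting it on the full dataset
before cross-validation would leak held-out labels into the encoding.
`evaluate_cv()` therefore refits the propensity matrices inside every
fold by default (`refit_pstnp = FALSE` mimics whole-dataset fitting for
comparison). The leak-free protocol has a visible small-sample cost:
training rows contribute to their own propensity estimates (one part in
n per class), so at very small n the training features are slightly
inflated relative to held-out features and CV accuracy dips below what a
larger sample gives. This is a property of the protocol, not a bug; at the
synthetic benchmark scale (400 + 400) the effect is negligible.

The jackknife test is exact leave-one-out: n models, each trained
(propensity refit included) on n − 1 samples. k-fold CV is the documented
fast mode; `folds = n` reproduces the jackknife exactly, which the suite
asserts.

## The synthetic generator

The generator emulates the two sequence signals that motivate the feature
design: a GAGG motif enriched over the central adenine (planted at offset
20, so the motif's A is the central A) and adenine enrichment four
positions downstream of the center. Defaults — 400 windows per class,
uniform background composition, `plant_prob = 1`,
`plus_four_A_prob = 0.8` — were fixed once as the package's study
conditions: class sizes large enough for stable fold estimates at desk
scale, a fully planted motif as the "signal present" condition, and a +4
enrichment well above the 0.25 background. A null configuration
(`plant_prob = 0`, `plus_four_A_prob = 0`) makes the classes exactly
exchangeable, which the suite uses to check that the pipeline finds
nothing where nothing was planted (CV accuracy within 3 binomial σ of
0.5).

What the generator does *not* emulate: realistic genome composition
(GC skew, repeats, CpG structure), species-specific 6mA motif spectra,
positional jitter of the motif, or label noise from imperfect site calls.
Passing the synthetic end-to-end tests therefore demonstrates that the
machinery recovers a planted positional signal under controlled
conditions — it does not certify accuracy on any real genome, which
depends on data quality and on how representative the training windows
are.

## Degenerate inputs and edge conventions

- Identical positive and negative training sets give exactly zero
  propensity matrices; identical samples give zero entropy.
- Empty FASTA input yields an empty, warned-about sample set; malformed
  FASTA is an error naming the offending line.
- Invalid prediction records are flagged (`status = "invalid"`) and kept
  in the output, never silently dropped.
- Scores exactly at the threshold are called positive.
- `sample_negatives()` errors with the eligible count when asked for more
  negatives than exist — never silently undersamples.

## Problem sizes in the shipped tests

The suite runs encoder oracles on single windows, selection and model
tests on tens of samples, and the end-to-end signal-recovery checks on
100–400 windows per class with 5-fold CV — sizes chosen so the whole suite
completes in well under a minute on one core while every contract is still
exercised at a non-trivial scale. The same code paths scale to
thousands-of-windows datasets unchanged.

## Known limitations

- The greedy identity filter is order-dependent and not equivalent to
  word-based clustering tools; on heavily redundant inputs the kept set
  differs from a cluster-representative selection.
- The MRMD instance here is one defensible member of its family; rankings
  from other weightings or metrics will differ, and the IFS optimum with
  them too.
- Negative sampling draws plus-strand adenines only; minus-strand
  negatives can be constructed by the caller via strand-aware extraction
  if needed.
- The predictor is only as transferable as its training windows;
  cross-species application should be validated on held-out data from the
  target species.
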