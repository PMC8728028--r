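---
title: "Methods: quantifying and predicting 3' UTR element activity from MPRA counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and predicting 3' UTR element activity from MPRA counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utrmpra)
library(dplyr)
```

## The measurement model

The package analyses massively parallel reporter assays (MPRAs) in which a
library of 160-nt 3' UTR fragments is cloned behind a reporter, integrated
into cells via lentivirus, and read out by sequencing DNA and RNA before
(`t0`) and 4 h after (`t4`) transcription shut-off. Each independent
integrant ("clone") is tagged by a random 8-mer barcode, so clone-to-clone
spread for the same fragment measures technical noise.

Two ratio statistics summarise a clone:

* **steady-state expression** = RNA / (RNA + DNA) at `t0`;
* **stability** = r4 / (r4 + r0), where r_t is the RNA/(RNA + DNA) ratio at
  timepoint t.

Stability is 0.5 exactly when the two ratios agree (no decay over the
chase); values below 0.5 indicate decay. Both statistics are bounded in
[0, 1] and do not diverge when counts are small, which is why they are used
instead of a fitted decay rate. A designed mutation's effect is
`delta = mutant − reference` on these statistics.

**Normalization.** Counts are scaled per column to counts-per-million
(`normalize_counts()`) before ratios are formed, making results invariant
to per-sample sequencing depth. Because CPM rescales RNA and DNA columns by
different totals, the CPM-based ratio is a monotone recalibration of the
raw within-clone proportion (a library whose average RNA share is p maps to
about 0.5 at p); comparative analyses (deltas, variance decomposition,
prediction) are unaffected, but simulation checks that compare estimates
with planted absolute proportions use the raw within-clone ratios
(`clone_activity(use = "raw")`), which are exactly unbiased for a binomial
read split.

**Aggregation and QC.** Ratios are computed per clone and then averaged
across clones per segment (`summarize_segments()`); the clone-level values
also feed the variance decomposition. Segments are kept only if at least 5
clones have more than 5 raw DNA counts each (strictly greater) and at least
one clone has at least one RNA count — zero RNA across all clones is
treated as a technical dropout. The DNA/RNA conditions gate each analysis
timepoint separately: `t0` for expression, `t0` and `t4` for stability.
Clones with undefined ratios (zero denominators) are dropped, not imputed.
The timepoint is a column-name convention (`*_t4`), so 2-h or 6-h chase
tables run through the same code path.

## ARE scanning: length and registration

An AU-rich element (ARE) is a maximal perfect match to the infinite repeat
`AUUUAUUUAUUU...` (an `A` every 4 nt). Matches of length >= 6 count at any
phase, plus exact `AUUUA` pentamers at length 5. The *starting
registration* g in {0, 1, 2, 3} is the phase of the first nucleotide
(`AUUU* = 0`, `UUUA* = 1`, `UUAU* = 2`, `UAUU* = 3`): `UUAUUU` is an ARE of
length 6 and registration 2 even though it contains no `AUUUA`, while
`UAUUU` is too short at its phase. The *effective length* is
`length + g` — the length the element would have if extended leftward to
phase 0 — and is the package's univariate ARE activity predictor. The
*naive pentamer count* `floor((length + g − 2) / 4)` coarsens effective
length to pentamer units.

```{r}
scan_ares(c("UUUAUUU", "UUAUUU", "GAUUUAUUUAG"))
```

Coordinates are 0-based half-open throughout, sequences are stored in the
RNA alphabet (FASTA readers map T to U), and the scanner is verified
against an exhaustive brute-force oracle in the test suite.

**Cluster labels.** The five-cluster categorical taxonomy counts AUUUA
repeats: clusters 3–5 are 3/4/5 exact overlapping repeats (13/17/21 nt).
The published shapes of clusters 1–2 are 13-nt motifs with AU-rich flanks
around one or two core pentamers; the package instantiates them as
`WWWWAUUUAWWWW` and `WWAUUUAUUUAWW` (W = A/U), the minimal motifs matching
those shapes. A segment takes the highest matching cluster; segments with a
bare `AUUUA` but no cluster motif are `AUUUA_only`. When one ARE must
represent a segment, the longest wins, ties broken leftmost.

## CDE scanning

A constitutive decay element (CDE) is a stem-loop with degenerate core
`UUCYRYGAA` (Y = C/U, R = A/G) and a lower stem of reverse-complementary
flanks. The scanner reports every core occurrence with its maximal stem
length n <= 5: the n nt upstream must be the strict Watson–Crick reverse
complement (A–U, G–C; no G·U wobble) of the n nt downstream. Wobble pairs
are excluded as the simplest reading of the motif definition; the "unpaired
nucleotide" outside the stem is a consequence of maximality (the next pair
fails or the sequence ends) rather than an extra requirement.

```{r}
scan_cdes("CCUUCCACGAAGG") # lower stem of 2
```

## Designed mutations

ARE disruption replaces the central U of each AUUUA pentamer with C or G,
alternating along the sequence (`AUUUAUUUA` to `AUCUAUGUA`). Pentamers tile
the matched run from its first phase-0 position at 4-nt steps; every tiled
pentamer whose centre lies inside the run is mutated, including a trailing
partial pentamer, so no residual ARE of length >= 5 survives across the
original run. For runs whose registration leaves no complete pentamer
(e.g. `UUAUUU`) this rule reduces to mutating the centre of the
phase-aligned UUU triple. CDE disruption either mutates the first two core
positions (`UUCYRYGAA` to `UAGYRYGAA`) or shuffles the stem + core + stem
span with a seeded permutation that preserves nucleotide composition.

## UTR windowing

`segment_utr()` tiles a UTR with 160-nt windows shifted by 80 nt, starting
at 0, 80, 160, ...; terminal windows of at least 20 nt are right-padded to
full length from a neutral padding sequence and shorter tails are dropped.
The bundled pad is a synthetic AU/GC-balanced 160-mer free of ARE and CDE
motifs; assay-specific pads can be supplied. Padded length is recorded per
segment so padding can be masked downstream.

## GC residualization

GC-rich fragments express less for reasons unrelated to the motifs under
study, so a polynomial trend in GC fraction is fitted to each outcome and
subtracted (`residualize()`). The fit uses an orthogonal basis internally
and reports monomial coefficients. The order (default 5) can be selected by
leave-one-out cross-validation computed in closed form from the hat-matrix
diagonal: the smallest order whose LOO Pearson r is within 0.002 of the
best over orders 1–7 is chosen. The 0.002 tolerance operationalises "no
significant improvement" at the dataset sizes this package targets
(thousands of segments); it is configurable. The curve is fitted on
reference segments only and applied to all segments, so designed-mutation
effects cannot leak into the GC trend. Residualization is idempotent and
leaves residuals numerically orthogonal to all fitted GC powers.

## Explainability (b-squared)

How much of the segment-to-segment variance is sequence-driven rather than
technical? The sampling variance of each segment mean is estimated from its
clones (within-segment variance / number of clones); averaging these gives
the dataset's technical variance, and

```
b2 = (total variance − technical variance) / total variance
```

Near 0, clone noise explains everything; near 1, sequence differences
dominate. For mutation outcomes the unit is the pair delta, whose sampling
variance is the sum of the two members' sampling variances (independence
assumed). Standard errors are leave-one-segment-out jackknives — the
underlying resampling method of the published tables is not specified, and
the jackknife is the standard choice for smooth ratio statistics. Slightly
negative estimates are possible in small samples and are reported with a
warning rather than clipped.

The fraction of sequence-driven variance explained by a candidate grouping
(e.g. cluster labels, effective-length categories) is
`(b2_total − b2_groups) / b2_total`, where `b2_groups` is computed on
within-group deviations (pooled, degrees of freedom corrected for the
number of groups) with the same technical variance. Singleton groups give
fraction 1; uninformative groupings give 0.

The plain b2 ratio estimator carries an O(1/n) small-sample bias (the
expectation of 1/variance exceeds 1/expectation). The package reports the
ratio as defined; validation simulations therefore use 1,000 segments per
replicate, where the bias is an order of magnitude below the Monte-Carlo
resolution of the check.

## Prediction benchmarking (leave-one-chromosome-out)

Predictors are compared by out-of-chromosome correlation: for each
chromosome, models are trained on the segments of all other chromosomes and
the held-out segments are predicted; pooled out-of-fold predictions are
correlated with the measurements (pooling, rather than per-fold averaging,
is recorded in the report metadata). Splitting by chromosome keeps
overlapping 80-nt-shifted windows on the same side of the split. Evaluation
is restricted to ARE-bearing segments.

* Categorical predictors (cluster label, naive pentamer count, effective
  length) predict the training-set category mean; a category unseen in
  training falls back to the global training mean.
* A user-supplied continuous score (e.g. an external ARE-scoring
  algorithm, which this package does not reimplement) is used via linear
  regression.
* The lasso k-mer regression solves y = Xb + c with L1 penalty, where X
  counts overlapping 5-mers (a 160-nt segment has 156). Counts rather than
  per-position frequencies are used — with fixed-length segments the two
  differ only by a constant factor, and counts keep integer sparsity; a
  fixed-length assumption is documented rather than enforced. The penalty
  is chosen by inner 5-fold cross-validation on the training fold with the
  one-standard-error rule, deterministically given the seed. Training uses
  all segments (including motif-free ones); mutation effects are predicted
  as predicted(mutant) − predicted(reference), never by training on deltas.
* For mutation outcomes, categorical predictors train on training-fold
  deltas grouped by the reference segment's category, restricted to
  mutations that disrupt ARE pentamers.

Two methods are compared by a two-sided Mann–Whitney U test on their
squared out-of-fold residuals over the common test set.

## The simulator

`simulate_library()` and `simulate_counts()` generate data with known
ground truth so every stage is testable without downloads. The generator
emulates: 160-nt segments with background composition at a target GC
fraction (default 0.45); planted AREs spanning lengths 5–21 and all four
registrations and planted CDEs with stems 0–5, flanked by guards that make
the planted element maximal and recoverable by the scanners; designed
mutant partners built with the package's own mutators; about 22 clones per
segment (Poisson) — the t0 clone depth of the motivating assay — at a mean
read depth of 100 per clone and timepoint; a baseline stability of 0.56
for motif-free segments with a mild negative linear GC trend; motif
effects monotone in effective length and stem length; segment-level
residual noise (SD 0.02) and clone-level jitter (SD 0.02) on the latent
ratio. Reads are split binomially (RNA ~ Binomial(T, r), DNA = T − RNA)
because the expression statistic is a proportion; the t4 latent ratio is
derived from the planted stability via r4 = s·r0/(1 − s), clamped inside
(0, 1).

It does **not** emulate: lentiviral integration-site biases, PCR
jackpotting, barcode collisions, batch or cell-type effects, secondary
structure, or position effects of elements within the segment. Passing
tests on simulated data therefore demonstrate correctness of the
estimators under the stated noise model, not robustness to those real-data
artefacts.

```{r}
cfg <- sim_config(n_segments = 120, seed = 7)
sim <- simulate_dataset(cfg)
act <- summarize_segments(sim$counts)
act <- residualize(act, segments = sim$segments, order = 2)
glance(attr(act, "gc_fits")$stability)
```

## Numerical and design choices

* 0-based half-open coordinates everywhere; RNA alphabet internally.
* TSV artifacts use UTF-8, `NA` for missing, floats at 6 decimals;
  identical inputs and seeds give byte-identical outputs.
* All randomness (shuffles, simulations, CV folds) is seeded explicitly;
  there is no hidden global-seed dependence.
* Ties among equal-length AREs: leftmost wins.
* One-mismatch ARE variants are deliberately out of scope (they were
  evaluated and rejected in the motivating analyses); the scanner is
  strict.
* Degenerate cases error loudly: empty sequences, rank-deficient GC fits,
  all-single-clone segments, zero-variance outcomes (except the lasso,
  which returns the all-zero model by contract).

Problem sizes used by the validation suite (chosen to keep estimator bias
below Monte-Carlo resolution while remaining quick on one CPU): 200
replicates of 1,000 x 10 clone values for b2 recovery; 1,500 segments for
LOO order selection; 100 simulations of 240 segments across 12 chromosomes
for the predictor-ordering property.

## Known limitations

* The b2 machinery implements exactly the clone-derived technical variance,
  the ratio, and the group fraction described above; refinements of the
  companion variance-audit methodology (alternative resampling schemes,
  bias corrections) are not reproduced.
* The CPM recalibration of ratio scale (above) means absolute expression
  values are comparable within a dataset, not across datasets.
* Per-cell-line analyses are independent runs; the package offers no batch
  integration.
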