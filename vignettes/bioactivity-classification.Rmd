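---
title: "Bioactivity-based target classification and its diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bioactivity-based target classification and its diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioactree)
```

## The model

`bioactree` analyzes full-matrix percent-inhibition screens: a library of
compounds, each assayed at a low and a high concentration, against a panel
of targets.  The package treats each *compound instance* — one compound at
one concentration — as a distinct entity throughout.  This is deliberate:
a strong inhibitor (active at both concentrations) contributes its
substructure features twice to a target's active set, a weak one only
once, so profiles weight chemical evidence by potency without ever using
the raw percentage values beyond the activity call.

### Activity calls

An instance is active on a target when it inhibits ≥ 50 % of native
activity (inclusive boundary; both the threshold and the boundary
convention are explicit arguments).  Raw values outside [0, 100] occur in
real assay data and are accepted with a warning; they binarize by the same
rule.  The 40–60 % mid-band, where a binary call is least reliable, is
reported as a panel statistic (half-open interval [40, 60) by default —
the closed/open choice is configurable because conventions differ).

### Enrichment profiles

For target *t* and feature *i*, with `f_A`/`f_I` the number of
active/inactive instances whose compound contains the feature,

* `E_i = f_A / f_I` when both counts are positive,
* `E_i = (f_A + 1) / (f_I + 2)` when either is zero (Laplacian
  correction).

The correction is applied *only* at zero counts; an always-corrected
variant is available (`always_correct = TRUE`) for sensitivity analysis.
Two interpretation decisions were genuinely open and are resolved as
follows: frequencies are raw instance *counts*, not proportions of the
active/inactive set sizes (with proportions, E would change whenever set
sizes differ — worth knowing when comparing panels of different density);
and a feature counts once per compound however often it occurs within the
molecule, because enrichment compares presence across compounds rather
than multiplicity within one.

All profiles live on the panel-wide vocabulary (lexicographically ordered
union of feature sets), so features absent from a target's compounds
contribute the constant E = 1/2 rather than dropping out of the vector.

### Distances, trees, embedding

Three inter-target metrics are provided: normalized Manhattan distance
between enrichment profiles (sum of absolute differences divided by the
vocabulary size), and Tanimoto (`D = 1 - c/(n_a + n_b - c)`) or Hamming
distance between binary bioactivity fingerprints.  Two all-empty
fingerprints get Tanimoto distance 0 with a warning; in the pipeline the
case cannot occur because zero-active targets are excluded before series
construction.  Hamming distances are raw counts by default — every
consumer here (neighbor joining, MDS) is invariant to the scale — with a
length-normalized option.

Neighbor joining is the classic Saitou–Nei agglomeration.  Exact ties in
the Q-criterion are broken by the lowest (row, column) index pair so that
identical input always yields an identical Newick string.  Negative branch
lengths are retained by default, matching the behavior of the standard
distance-tree programs; an optional clamp mode zeroes them and transfers
the deficit to the sibling branch.  Patristic matrices can be normalized
by their maximum entry, the usual 0–1 scale of sequence-based target
trees.

The MDS diagnostic is SMACOF majorization of raw stress from a seeded
Gaussian start.  The reported trace is the normalized stress
`sqrt(sum (d_hat - d)^2 / sum d^2)`; since the majorization step never
increases raw stress and the normalizer is constant, the trace is
monotonically non-increasing — this is asserted in the test suite.
Stopping conditions are a minimum stress change of 0.00005 or 5000 steps.
The stress functional of the historical GUI tools ("signed relative
stress") is not recoverable from their documentation; this package
minimizes raw stress and reports the normalized form, and makes no claim
of numerical agreement with those tools.

### SAC score series and the neighborhood verdict

For a *common* target, every other (*variable*) target contributes one
point: the percentage of shared active instances under one of three
normalizations (by the common target's actives, by the variable target's —
the default, and the one least biased by promiscuity differences — or by
the union of both active sets), against their bioactivity distance.  The
union, rather than the sum of totals, is used for the "both" mode because
a compound active on both targets should count once in the denominator;
the sum variant remains available.

"Mean centering" of a series is implemented as *multiplicative* rescaling
to mean distance 0.5 and mean percentage 50: an additive shift could never
produce SAC scores above 200 from percentages bounded by 100, while
observed series do exceed 200 at small distances — a point at five times
its series mean scores exactly 250.  Rescaling an already-scaled series is
the identity, and verdicts are invariant under any common positive
rescaling of the raw axes.

Each scaled series is fitted with an unweighted OLS quadratic; the series
shows *neighborhood behavior* iff the fitted slope is negative at scaled
distance 0.40 **and** 0.67 and R² > 0.2.  Degenerate series (fewer than 3
points, all-identical distances, or unscalable all-zero percentages — the
signature of a target whose actives are disjoint from the rest of the
panel) are classified outlier with an explicit reason.  The R² gate is
calibrated: 200-point pure-noise series are rejected in well over 90 % of
repetitions.

### Data-density exclusion

`shared_total` counts a target's active instances that are active on at
least one other target.  Targets with `shared_total ≤ 16` (roughly 10 % of
the maximum shared-activity count in a dense panel) are excluded in a
single pass computed on the unfiltered panel, and profiles, distances,
trees and SAC series are rebuilt from the kept panel.  The filter is
monotone in its threshold, and a zero-active target is always excluded and
never receives a series.

## The synthetic study conditions

`generate_panel()` emulates the structure of a dense kinase-panel screen;
its defaults are the package's reference conditions and the ones the
acceptance analysis runs under:

* 6 target clusters × 8 targets, 150 compounds × 2 concentrations (1 and
  10 µM), 3 sparse targets, 1 zero-active target — 52 targets × 300
  instances.
* Cluster chemotypes are disjoint signature-feature blocks of *unequal*
  size (12–60 features).  Equal-size signatures make all clusters pairwise
  equidistant, which real panels are not; the spread keeps the
  inter-cluster distance distribution right-skewed, with most scaled
  distances between 0.2 and 0.6 and a small tail beyond 1.0, as observed
  in dense kinase panels.
* Each target carries a sensitivity multiplier (U(0.35, 1.25) on the
  within-cluster activity probability 0.8, capped at 1, also scaling the
  low-concentration response) and a promiscuity multiplier (U(0.5, 6) on
  the background probability 0.02).  Homogeneous targets would produce a
  bimodal distance cliff; the multipliers reproduce the realistic spread
  of per-target inhibitor counts (roughly 10–70 of 300 instances).
* Pan-inhibitors (2 compounds) are active nearly everywhere and carry no
  cluster signature — the staurosporine analog.
* Sparse targets have no matched chemotype in the library: their few
  actives (≤ 10 instances) are pan-inhibitor and background hits, so what
  little activity they have is shared with many targets at arbitrary
  distances.  This reproduces the mechanism by which data-poor targets
  contaminate other targets' SAC series and their own.
* Low-concentration actives are nested within high-concentration actives
  per (compound, target); percent values are drawn from [60, 100] for
  actives and [0, 40) for inactives, with 2 % mid-band contamination drawn
  from [50, 60) and [40, 50) respectively so planted calls survive
  binarization.

What the generator does *not* emulate: real molecular structures (features
are abstract ids; the RDKit featurization path is tested separately on
real SMILES), correlated assay noise, dose–response inconsistencies, and
the long-range hierarchical relatedness of a 200+-target panel.  Passing
tests on synthetic panels therefore demonstrate correctness of the
computations and qualitative reproduction of the analysis phenomena, not
quantitative agreement with any particular experimental dataset.

## Problem sizes and numerical choices

The reference conditions (52 × 300, ~2000 features) run the full two-stage
pipeline in a few seconds; test-suite fixtures are smaller still, and the
neighbor-joining consistency check uses 200 random trees of 5–20 leaves.
Tolerances: enrichment values are exact small-integer ratios and are
compared exactly; NJ recovery of additive matrices is asserted to 1e-8;
SAC rescaling means to 1e-9; Newick round-trips to 12 significant digits
(15 digits are written).  Quadratic fits use `stats::lm` without
robustification, matching the plain least-squares convention of the
original analysis style.

## Known limitations

* The neighborhood rule evaluates slopes at scaled distances 0.40 and
  0.67, constants inherited from panels whose scaled distances extend to
  about 1.9.  On small panels (a few dozen targets), especially *after*
  density filtering, the attainable scaled-distance range shrinks toward
  ~1.0, and 0.67 falls near the edge of the data where a convex quadratic
  often turns upward even for cleanly decreasing series.  Consequently the
  enrichment-metric neighborhood fraction is conservative (and can
  *decrease* from stage 1 to stage 2) at this scale, while the
  fingerprint-Tanimoto fraction — whose distances relate almost
  functionally to shared-activity percentages — shows the expected
  stage-2 improvement robustly.  On panels of a few hundred targets the
  distinction disappears.
* SAC distances are read from the distance matrix, not from tree path
  lengths (an option exists), since the series are defined on distances
  directly; patristic series inherit NJ reconstruction error.
* Sequence-based distances are never computed from sequences; they are
  ingested as Newick trees or distance matrices, and gatekeeper residues
  as an annotation table.
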