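---
title: "3D-SDAR modeling of TdP risk: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{3D-SDAR modeling of TdP risk: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdar3d)
```

## The model

`sdar3d` classifies compounds as torsadogenic (TdP-positive, activity 1)
or not (activity 0) from a spectral data-activity relationship built on
atom pairs. For a molecule with 3D coordinates and per-atom ¹³C/¹⁵N
chemical shifts, every unordered pair of carbon/nitrogen atoms yields the
triplet (δ₁, δ₂, d): the two isotropic shifts in PPM and the Euclidean
interatomic distance in Å. Triplets are counted into a fixed tessellation
of (shift × shift × distance) boxes; the resulting sparse occupancy
vector is the compound's fingerprint. Because only shifts and pairwise
distances enter, the fingerprint is exactly invariant under rotation,
translation and atom reordering — no alignment to a hypothetical receptor
pose is ever needed, which is the method's main structural advantage over
alignment-based pharmacophore searches.

The underlying assumptions are that (i) shifts summarize the local
electronic environment of an atom well enough to act as an "electrostatic
coordinate", (ii) the geometric relationship between two such
environments carries the activity-relevant steric information, and
(iii) activity can be expressed as the presence of a modest number of
recurring (environment, environment, distance) motifs — the toxicophores
the model ultimately reports.

## Binning

Default windows and widths:

| axis | window | bin width | bins |
|------|--------|-----------|------|
| ¹³C shift | −4 .. +204 PPM (width 208, midpoint 100) | 8 PPM | 26 |
| ¹⁵N shift | −356 .. −11 PPM (width 345, midpoint −183.5) | 20 PPM (2.5 × w_C) | 18 (last truncated) |
| distance | 1 .. 20 Å | 1 Å | 19 |

Nitrogen shifts use the negative-PPM convention; a provider emitting
positive ¹⁵N values must be converted upstream. The carbon:nitrogen
width ratio of 2.5 is fixed by the method; the carbon width itself is a
tunable for which 8 PPM is this package's default — it divides the carbon
window into exactly 26 bins and keeps the grid at desk scale. The 1-Å
distance bins match the precision at which toxicophore features are
conventionally described ("7–8 Å"). Bins are left-closed/right-open, the
upper window edge belongs to the last bin, and out-of-window values cause
the pair to be skipped (and counted in a skip log, so occupancy plus
skips always equals the number of C/N pairs).

The CC, CN and NN pair classes occupy disjoint bin-id blocks because the
two axes have element-specific windows; a mixed grid would create
meaningless boxes. Canonical axis assignment (CC/NN: smaller shift on
axis 1; CN: carbon on axis 1) makes bin ids independent of atom
enumeration order. Bonded pairs are *not* excluded — no topological
filter is applied — and occupancies are counts by default (binary is
available), preserving the multiplicity of symmetric environments such as
the equivalent carbons of a benzene ring.

Atom indices are 1-based throughout, matching the MOL V2000 atom block
and the `id,atom_index,element,shift_ppm` shift-table interface, so no
boundary translation exists anywhere (R itself is 1-based).

The feature matrix retains the bins that are nonzero in at least one
*modeling* compound and z-scores each retained column with
modeling-compound statistics (constant columns map to zero); external
compounds are transformed with the frozen statistics and may fall outside
the training range. "Scaling" is interpreted as this standardization of
the occupancy matrix before the network — min–max and no-op modes are
available behind `binning_config(scaling=)` for sensitivity checks.

## The MLP ensemble

The classifier is an ensemble of 200 multilayer perceptrons. "Two
layers" means two *weight* layers: one hidden layer plus the output unit
(a two-hidden-layer variant sits behind `mlp_config(hidden_layers = 2)`).
Per member, the hidden-unit count is drawn from 3..16 and the hidden and
output activations independently from {identity, tanh}, emulating an
automated network search; each member draws an independent uniform-random
holdout of 25% of the modeling compounds (redrawn if fewer than two
compounds of either class would remain for training).

Training is full-batch gradient descent on the sum-of-squares error
E = Σᵢ (yᵢ − tᵢ)² plus a weight-decay penalty λ Σ w² over connection
weights (biases are not decayed). Numerical choices that matter:

* **Step size.** The configured learning rate (default 0.1) is the
  *initial* step. A fixed step of 0.1 on a sum-of-squares loss diverges
  for any realistically wide standardized feature matrix, so each epoch
  uses backtracking: the step is halved while it would increase the
  penalized loss, and grows back (×1.2, capped at the configured rate)
  after accepted steps. Descent is therefore monotone by construction.
  A non-finite loss still triggers one restart at η/10, then a training
  failure.
* **Early stopping.** The holdout error — computed on outputs clamped to
  [0, 1], the scale classification uses — is tracked every epoch; the
  best-so-far weights are kept and training stops after 20 epochs without
  improvement (or at 500 epochs).
* **Weight decay.** Default λ = 0.3. The retained-bin count (hundreds)
  far exceeds the modeling-set size (tens), and with a token λ every
  member memorizes noise bins and generalizes at chance; λ in 0.1..0.7
  behaves near-identically on planted-rule data, and 0.3 is the center of
  that plateau. λ is deliberately large compared to textbook defaults
  because the penalty competes with an unnormalized (summed, not
  averaged) error term.
* **Output clamping.** Identity-output members can emit values outside
  [0, 1]; outputs are clamped only for prediction, aggregation and ROC,
  never inside the training gradient.

The compound score is the **median** of the 200 clamped member outputs;
class 1 is called at score ≥ 0.5, with the tie going to the TdP-positive
class because recall of actives is what toxicophore construction depends
on. Evaluation reports both conventions used for subsampled ensembles:
the mean over members of each member's accuracy on its own training and
holdout partition, and the ensemble-median accuracy on the modeling set,
on out-of-bag (per-compound median over the members that held it out) and
on the external set, plus ROC curves/AUC (via pROC) and per-class gain
curves. Single-class sets get their ROC marked undefined while accuracy
is still reported. Class imbalance is not reweighted.

## Sensitivity analysis and toxicophores

Per member, the importance of bin b is the mean-substitution error ratio
E_b/E₀: the member's sum-of-squares error on its own training partition
after replacing column b with its training-partition mean, over the
unperturbed error (machine epsilon is substituted when E₀ = 0, and the
member flagged). A column the weights ignore — or one that is constant in
the partition — yields exactly 1. For one hidden layer the substitution
is evaluated through an exact rank-1 update of the hidden pre-activation
(O(n·H) per column instead of a full forward pass); tests verify equality
with the brute-force recomputation to 1e-10. A permutation-based
importance is available for comparison (`method = "permutation"`).

Aggregate sensitivity is the mean ratio over members; bins are ranked
descending and the significant set is the top 5% (minimum 3 bins) or,
optionally, all bins above a ratio threshold — the cutoff is a documented
package choice, as no canonical value exists. Significant bins are then
back-projected: for every active modeling compound, all atom pairs whose
triplet falls inside the decoded box are listed. When a matched atom
belongs to an aromatic ring, the reported anchor becomes the ring
centroid and the distance is recomputed to it, so features read like
"benzene ring to nitrogen, 7–8 Å"; non-ring atoms keep atom-anchored
distances. Display distances are rounded to 0.1 Å, machine output keeps
full precision. Features are reported per bin (no merging of adjacent
significant bins — no principled merge rule exists, so none is applied
by default), sorted by sensitivity then support (the number of distinct
active compounds matched). Aromatic rings are those whose bonds all carry
the aromatic flag (MOL bond type 4); for Kekulé-form inputs without
flags, even rings with strictly alternating single/double orders are
accepted.

## The synthetic generator

Real 3D-SDAR studies hinge on commercial shift predictions and curated
clinical labels, neither of which can ship with a package, so `sdar3d`
includes a generator whose datasets exercise every stage — structures,
shifts, manifests, the real file formats — with a known ground truth.
Its defaults are the package's study conditions:

* 60 compounds, half active, split 55:38-style into modeling and
  external roles (external fraction 38/93); label noise 0 by default.
* Each compound is a small abstract atom cloud: a planted hexagonal
  "aromatic ring" of six carbons (circumradius 1.39 Å, aromatic-flagged
  bonds) plus 2–4 further atoms placed uniformly in a 4-Å sphere with a
  1.2-Å minimum separation; bonds beyond the ring are a nearest-neighbor
  spanning tree. These are deliberately *not* chemically valid
  geometries — fingerprinting consumes only elements, shifts,
  coordinates and ring flags.
* Shifts come from a small class palette (aliphatic/midrange/carbonyl
  carbons, amine/amide/aromatic nitrogens) of truncated normals with
  narrow spreads, emulating how substructure-based predictors assign
  recurring environments nearly identical values. The six ring carbons
  are symmetry-equivalent and share one shift.
* Activity is planted as a spatial rule mirroring the classic
  aromatic-ring/basic-nitrogen toxicophore motif: an aromatic-class
  carbon (116–124 PPM) and an amine-class nitrogen (−336..−316 PPM) at
  7–8 Å. The rule box is aligned to a single tessellation cell so "the
  planted bin" is well defined. Crucially the design is
  matched-control: *every* compound carries the rule-band ring and an
  amine nitrogen; only in actives is the nitrogen placed at a rule
  distance from a ring carbon, and inactives are rejection-sampled
  (brute-force pair scan) to contain no rule-satisfying pair. Neither
  "has an aromatic ring" nor "has an amine" alone separates the classes —
  only the 7–8 Å relationship does.

What passing the recovery harness shows, and what it does not: with the
defaults (n = 60, no label noise, 200 members) the ensemble reaches
≥ 90% external accuracy, ranks the planted bin within the top 5% of
retained bins by sensitivity, and reports a top toxicophore whose
distance range contains 7–8 Å, across seeds. This demonstrates that the
pipeline — binning, training, aggregation, sensitivity, back-projection —
recovers a clean planted signal end to end. It does *not* calibrate
expected performance on real drugs, where shifts are noisier, the
activity rule is neither single-bin nor noise-free, and class structure
is confounded; on such data the method's characteristic signature is a
large train/holdout generalization gap, which the member-level metrics
expose honestly.

Problem sizes throughout the tests (60 × ~130–250 bins, 200 members;
smaller for unit tests) were chosen so the full suite and the acceptance
script each run in minutes on a single core while keeping the ensemble at
its full 200 members wherever the ensemble contract is asserted.

## Degenerate inputs and edge rules

* 2D-flagged structure records with all-zero z are rejected (fingerprints
  need geometry); multi-conformer input is out of scope — one geometry
  per compound.
* A molecule with fewer than two C/N atoms has an empty fingerprint; a
  modeling set whose fingerprints are all empty is a degenerate-input
  error.
* Shift tables must cover every C/N atom of a molecule (missing indices
  are listed); shifts outside wide sanity windows (C −50..250,
  N −500..100 PPM) warn but pass through.
* External-compound bins absent from the retained set are dropped
  silently and counted.
* Exact ties at the 0.5 decision threshold predict class 1.
* `bin_axis_index` treats the upper window edge as belonging to the last
  bin, so the windows are closed overall.

## The packaged manifest fixture

`inst/extdata/tdp_manifest_synthetic.csv` is a synthetic stand-in (as its
name states) for a TdP study roster: 55 modeling compounds (32 active,
23 inactive) and 38 external compounds with post-marketing report counts
≥ 25. The external activity split (37 active, 1 inactive) is an inference
from typical published external-set accuracy/recall figures, not a
transcription; only the counts are meaningful. Ids are synthetic labels,
not drug names.

## Known limitations

* The package does not predict NMR shifts; real use requires an external
  predictor, and prediction quality bounds model quality.
* Structure preparation (protonation, tautomers, geometry optimization)
  is upstream and out of scope; coordinates are taken as given.
* With tens of compounds and hundreds of bins the ensemble *will* overfit
  its training partitions; conclusions should rest on holdout/external
  metrics and on sensitivity ranks, never on training accuracy.
* Sensitivity ratios from members with near-zero training error are
  unstable (flagged); the aggregate over 200 members is the quantity to
  interpret.
* Ring perception is intentionally minimal (aromatic flags, or Kekulé
  alternation); exotic aromatic systems in unflagged inputs may be
  missed, affecting only the centroid presentation of toxicophores, not
  the model itself.
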