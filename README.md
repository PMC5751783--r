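# sdar3d

Three-dimensional spectral data-activity relationship (3D-SDAR) modeling of
drug-induced Torsade-de-Pointes (TdP) risk.

Blockade of the hERG cardiac potassium channel delays ventricular
repolarization and can trigger Torsade de Pointes, a potentially fatal
arrhythmia; recognizing torsadogenic liability early is a core drug-safety
screen. `sdar3d` implements a structure-activity method whose descriptors
are *pairs of atomic NMR chemical shifts plus the distance between the two
atoms*:

* every unordered pair of C/N atoms in a molecule contributes a triplet
  (δ₁ PPM, δ₂ PPM, d Å), where δ are the ¹³C/¹⁵N isotropic chemical shifts
  (carbon positive, nitrogen negative convention) and d the interatomic
  distance from the 3D geometry;
* triplets are tessellated into a binned abstract space — carbon window
  −4..+204 PPM (default 8-PPM bins), nitrogen window −356..−11 PPM (bin
  width 2.5× the carbon width), distance window 1..20 Å (1-Å bins), with
  CC, CN and NN pair classes in disjoint bin blocks — giving a sparse
  compound × bin fingerprint that is invariant under rotation and
  translation of the coordinates;
* the z-scored fingerprint matrix is classified by an ensemble of 200
  multilayer perceptrons (one hidden layer, identity/tanh activations,
  full-batch gradient descent on Σ(yᵢ−tᵢ)² with weight decay and early
  stopping, each member trained with an independent random 25% holdout),
  aggregated as the **median** of the member outputs with a 0.5 decision
  threshold;
* per-bin importance is measured by mean-substitution sensitivity
  analysis (error ratio E_b/E₀ after replacing a bin column with its
  training mean, averaged over members), and the most sensitive bins are
  decoded and back-projected onto the active compounds as 3D
  **toxicophores** — element pair, shift windows and distance range, with
  distances re-expressed relative to aromatic-ring centroids.

Because the shifts of the original study came from a commercial predictor,
shifts are a pluggable input here: supply a `id,atom_index,element,shift_ppm`
table, or use the built-in deterministic rule-based fallback for testing.

## Worked example

A fully synthetic end-to-end run: 60 compounds with a planted rule
(aromatic-class carbon 116–124 PPM and amine-class nitrogen −336..−316 PPM
at 7–8 Å ⇔ active), 200-member ensemble, sensitivity ranking and
toxicophore back-projection:

```r
library(sdar3d)
rec <- recovery_harness(synthetic_spec(), n_members = 200, seed = 1)
rec
#> <sdar_recovery> model n=35, external n=25, 122 retained bins
#>   external accuracy 96.0%, sensitivity 93.3%; member mean train 96.7% / holdout 84.4%
#>   planted bin best rank 1 of 122 (top 0.8%)
#> <sdar_toxicophore> bin 18000 [CN]: shifts 116..124 / -336..-316 PPM, distance 7.0-8.0 A; support 15 compound(s), sensitivity 46.133
```

Reading: of the 25 external (blind) compounds, 96% are classified
correctly and 93.3% of the true TdP-positives are recovered; the single
bin carrying the planted rule is ranked most sensitive of all 122 retained
bins; and the top toxicophore feature decodes exactly to the planted
aromatic-C/amine-N pair at 7–8 Å, supported by 15 of the active modeling
compounds.

On real data the workflow is the same with files instead of the
generator:

```r
mols  <- read_structures("structures.sdf")
man   <- read_manifest("manifest.csv")          # id,activity,role
prov  <- shift_provider_table("shifts.csv")     # id,atom_index,element,shift_ppm
fps   <- lapply(man$id, function(id)
           compute_fingerprint(mols[[id]], assign_shifts(mols[[id]], prov)))
feats <- build_feature_matrix(fps, man$id[man$role == "model"])
ens   <- train_ensemble(feats, setNames(man$activity, man$id),
                        n_members = 200, master_seed = 1)
evaluate_ensemble(ens)
sens  <- aggregate_sensitivity(ens)
```

A command-line wrapper with subcommands (`synth`, `fingerprint`, `train`,
`predict`, `evaluate`, `importance`, `toxicophore`) is installed at
`inst/cli/sdar3d.R`:

```sh
Rscript inst/cli/sdar3d.R synth --seed 1 --out run/
Rscript inst/cli/sdar3d.R train --structures run/structures.sdf \
    --shifts run/shifts.csv --manifest run/manifest.csv --seed 1 --out run/
```

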