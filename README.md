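# rnassess

Automated assessment of predicted RNA three-dimensional structures against
a reference, with the metric suite used in blind RNA structure prediction
assessments — plus a synthetic decoy generator so every metric can be
exercised with known ground truth, no downloads required.

Blind prediction exercises compare dozens of submitted models of large RNAs
(ribozymes, riboswitches, RNA–protein-free complexes) against subsequently
released crystal structures. A single number cannot capture model quality:
a model can have the right global fold but wrong base-pairing chemistry, or
locally perfect helices that are misassembled, or good coordinates that are
sterically impossible. `rnassess` computes the complementary panel used for
such rankings:

- **RMSD** — root mean square deviation over paired atoms after optimal
  (Kabsch) rigid superposition, in Å:
  `RMSD = sqrt( (1/N) Σᵢ |pᵢ − (R qᵢ + t)|² )`, minimised over rotations
  `R` (det +1) and translations `t`.
- **INF** (Interaction Network Fidelity) — geometric mean of precision and
  sensitivity of the predicted contact network,
  `INF = sqrt(PPV × STY)` with `PPV = TP/(TP+FP)`, `STY = TP/(TP+FN)`,
  computed separately for canonical Watson–Crick pairs, non-Watson–Crick
  pairs, and base stacking, and pooled. Base pairs and stacking contacts
  are detected geometrically and classified by Leontis–Westhof edge
  (Watson–Crick / Hoogsteen / Sugar) and cis/trans orientation.
- **DI** (Deformation Index) — `DI = RMSD / INF`: RMSD inflated by failure
  to reproduce the reference interaction network.
- **DP** (Deformation Profile) — an N×N matrix whose entry (i, j) is the
  mean distance over residue j's atoms when the model is superposed on the
  reference using *only* residue i's atoms; separates local from global
  deformation, with per-domain min/mean/max summaries.
- **MCQ** (Mean of Circular Quantities) — mean circular dissimilarity, in
  degrees in [0°, 180°], over the per-residue torsion angles α, β, γ, δ,
  ε, ζ, χ and the sugar pseudorotation phase P; independent of any
  superposition. Global values below ~15° indicate high similarity, above
  ~45° overall dissimilarity. MCQ-local reports the raw per-angle
  differences.
- **Clash Score** — steric overlaps ≥ 0.4 Å per 1000 atoms, a physical
  plausibility control.

## Worked example

```r
library(rnassess)

ref <- build_helix("GGCGCAAUCC")          # ideal A-form duplex, 20 nt
decoys <- list(
  gentle = perturb(ref, perturb_noise(0.2, seed = 1)),   # 0.2 Å coordinate noise
  rough  = perturb(ref, perturb_noise(1.0, seed = 1)),   # 1.0 Å coordinate noise
  swung  = perturb(ref, perturb_rigid("A", 6, 10, angle = 40))  # domain swing
)
assess(ref, decoys, mode = "by-index")
#> <rna_report> 3 model(s) vs 'helix-GGCGCAAUCC', ranked by rmsd
#> # A tibble: 3 × 10
#>    rank model   rmsd    di inf_all inf_wc inf_nwc inf_stack   mcq clash
#>   <int> <chr>  <dbl> <dbl>   <dbl>  <dbl>   <dbl>     <dbl> <dbl> <dbl>
#> 1     1 gentle 0.357 0.364   0.982  1          NA     0.972 18.9   30.4
#> 2     2 rough  1.79  4.63    0.386  0.548      NA     0.333 76.5  738.
#> 3     3 swung  1.84  1.95    0.946  0.9        NA     0.972  1.09  51.5
```

Reading the table: the gentle decoy keeps every canonical pair
(`inf_wc = 1`) at RMSD 0.36 Å; heavy noise destroys half the pairing
network (`inf_wc = 0.55`) so its DI (4.6 Å) is far worse than its RMSD
(1.8 Å) alone; the rigid domain swing has RMSD comparable to heavy noise
but near-perfect internal geometry (`mcq = 1.1°`) — exactly the
distinction this metric panel is designed to expose. `inf_nwc` is `NA`
because an ideal duplex has no non-Watson–Crick pairs to predict —
"nothing to predict" is reported as NA, never as 0. The noise decoys pick
up nonzero clash scores because random displacement creates overlaps.

Real structures come in through `read_pdb()` (models and reference as PDB
files), `build_correspondence()` handles engineered sequence variants via
alignment-based residue pairing, and `deformation_profile()` /
`dp_export()` produce per-residue matrices with `autoplot()` heatmaps.
A command-line front end lives at `inst/cli/rnassess.R`
(`assess`, `dp`, `forge` subcommands).

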