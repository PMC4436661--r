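---
title: "Assessing RNA 3D models: metrics, geometry and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing RNA 3D models: metrics, geometry and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnassess)
```

# The assessment problem

Given a reference RNA structure and one or more predicted models of the
same molecule, `rnassess` produces a scorecard per model and a ranking.
No single metric suffices: coordinate-space measures (RMSD) reward global
fold accuracy, interaction-space measures (INF) reward base-pairing and
stacking chemistry, torsion-space measures (MCQ) reward local backbone
geometry independently of any superposition, and the Clash Score controls
for physically impossible geometry. The package computes all of them over
one explicit residue correspondence, so coverage differences between
models are visible rather than silently absorbed.

# The metrics

## Residue correspondence

Every metric operates on an explicit 1:1 nucleotide pairing.  Three modes:
by-index (positional), by-number (PDB numbering + insertion code), and the
default by-alignment: per-chain global alignment (match +2, mismatch -1,
gap open -5, gap extend -1) that pairs aligned columns *including*
mismatched letters, with a warning.  The default is alignment because
deposited references are sometimes engineered variants of the predicted
sequence (e.g. a re-designed tRNA acceptor stem): number-based matching
can silently misalign such chains, while alignment pairs the engineered
positions explicitly and reports them.  Unmatched residues are listed,
never dropped; metrics use paired residues only.

## Superposition and RMSD

`kabsch_superpose()` computes the least-squares rigid motion via SVD of
the 3x3 cross-covariance, forcing determinant +1 so reflections can never
masquerade as fits.  The default atom selection is all heavy atoms of
paired residues (`backbone`, `c1-prime` and `phosphate` subsets are
available, since published table values depend on this unstated
convention).  There is no outlier rejection: the global RMSD is reported
as is, and local quality is the Deformation Profile's job.  Collinear or
sub-3-point inputs are rejected as degenerate rather than silently
producing an arbitrary rotation.

## Interaction annotation

Base pairs and stacking are detected geometrically, per residue pair:

* pair: >= 2 N/O edge-atom contacts within 3.5 Å (or one within 3.2 Å),
  base-plane angle <= 65°, mutual plane offset <= 2.5 Å, origin distance
  <= 12 Å;
* edge classification (Watson-Crick / Hoogsteen / Sugar) by the edge-atom
  set contributing the most contacts, ties resolved W > H > S;
* orientation cis/trans by the sign of the C1'-N-N-C1' pseudo-dihedral
  (|angle| <= 90° is cis);
* stacking: origin distance <= 5.5 Å, normals within 30° of (anti)parallel,
  center-center vector within 40° of either normal; pairs already emitted
  as base pairs are excluded, and chain neighbours (i, i+1) are eligible
  as stacking only.

These thresholds follow common annotation practice; they live in one
config block (`.annot_params`) so they can be calibrated against any
reference annotator.  Published INF values depend on the annotator used,
so exact reproduction of third-party tables is a calibration exercise,
not a correctness criterion.  The GU cis-WW wobble counts as canonical
Watson-Crick by default (`wobble_as_wc = FALSE` gives the alternative),
matching the usual convention in prediction assessment.

## INF, DI, DP

`INF = sqrt(PPV * STY)` per category (canonical WC / non-WC / stacking)
and pooled.  An empty reference category yields `NA`, never 0 — "nothing
to predict" and "all predictions wrong" must not be conflated.  Matching
is at the residue-pair level by default (a model pair that finds the right
partners but the wrong edge still matches); `strict = TRUE` additionally
requires edge and orientation identity.  `DI = RMSD / INF` uses the pooled
INF as denominator (per-category DIs are also reported), so
`DI >= RMSD` always, with equality only at INF = 1.

The Deformation Profile anchors a superposition on each residue in turn
(its paired atoms only, minimum 3) and measures every other residue under
that motion.  Anchoring on single residues rather than windows keeps rows
interpretable ("what does the structure look like from here?"); the
multi-scale view comes from domain aggregation (min/mean/max over
user-supplied named residue ranges).  Windowed anchoring was considered
and rejected as a default because it blurs the local/global distinction
the matrix exists to expose.

## Torsions and MCQ

Seven backbone/glycosidic dihedrals (alpha through zeta, chi) plus the
sugar pseudorotation phase P (from the five endocyclic nu torsions, with
the quadrant fixed by the sign of nu2) make 8 slots per residue.  Chain
termini leave alpha (5') and epsilon/zeta (3') undefined; any missing atom
undefines exactly the angles it participates in, recorded in `defined`
flags rather than imputed.  P enters as one slot alongside the seven
dihedrals — treating pucker via a single phase rather than five separate
nu slots keeps the eight slots comparably weighted.

MCQ-global aggregates the per-slot circular differences (each in
[0°, 180°]) by the circular mean `atan2(mean sin, mean cos)`; because the
prose description of "mean dissimilarity" is ambiguous, an arithmetic-mean
mode is provided (`method = "arithmetic"`).  For constant offsets the two
agree exactly, which is the identity used in the tests.  Slots defined on
only one side are excluded from the mean and counted as a completeness
penalty, never filled in.  Reports surface the interpretation guide:
global MCQ < 15° high similarity, > 45° overall dissimilarity (for large
RNAs).

## Clash Score

Non-bonded atom pairs whose van der Waals spheres (C 1.70, N 1.55, O 1.52,
P 1.80, H 1.20 Å) overlap by >= 0.4 Å, per 1000 atoms.  Exclusions: pairs
within 3 covalent bonds (intra-residue bond table plus the O3'-P backbone
bridge), and N/O-N/O pairs at >= 2.6 Å, which are treated as hydrogen
bonds (`hbond_exempt = FALSE` disables this).  Candidate pairs come from a
spatial grid whose cell size provably does not affect the output (tested
against an all-pairs oracle).  This is the overlap-threshold definition
applied to the atoms present: probe-based scorers add hydrogens first and
score contact dots, so agreement with such published values is approximate
(about +/-15%) on hydrogen-free models; hydrogen presence is recorded in
every report.

# The synthetic decoy generator

`build_helix()` produces ideal A-form duplexes from four template
nucleotides placed by helical symmetry: twist 32.7° and rise 2.81 Å per
step (standard A-form fiber values), x-displacement -4.59 Å and
inclination 25.97° from the helix axis.  The templates were constructed
once and are versioned as a plain-text PDB
(`inst/extdata/aform-templates.pdb`, labelled synthetic): bases in
standard reference-frame coordinates (so the Watson-Crick partner is a
180° rotation about the pair dyad), an analytically built C3'-endo ribose
(pseudorotation phase 18°, amplitude 38°, ideal bond lengths/angles), and
a sugar-phosphate pose fixed by a one-time geometry optimization so that
consecutive residues connect covalently (O3'-P about 1.6 Å) without a
single steric clash.  The resulting torsions are textbook A-RNA (alpha
-70°, beta -177°, gamma 50°, delta 86°, epsilon -164°, zeta -71°, chi
-151°, P about 18°), and the construction guarantees: one canonical cis-WC
pair per position, stacking between all chain neighbours, Clash Score 0.

`perturb()` applies three decoy transformations with exact ground truth:

* `perturb_noise(sigma, seed)` — i.i.d. Gaussian displacement per
  coordinate; for N atoms the expected RMSD is `sigma * sqrt(3)` (the
  6-parameter rigid fit removes a negligible fraction of the variance at
  N ~ 2000); bit-stable under a fixed seed without disturbing the
  caller's RNG state;
* `perturb_rigid(...)` — rotation/translation of a residue range,
  emulating a mis-placed domain: RMSD grows, torsions inside both bodies
  are untouched, and DP rows anchored in the fixed domain light up exactly
  at the moved columns;
* `perturb_bond(key, bond, delta)` — rotation of everything distal to one
  rotatable bond, changing exactly that torsion by delta (ring bonds are
  refused); the surgical instrument for MCQ-local tests.

`decoy_suite()` packages graded series of these with their analytic
expectations attached.

What the generator deliberately does **not** emulate: loops, junctions,
non-canonical motifs, tertiary contacts, crystallographic artefacts
(alternate conformations, missing residues, modified bases beyond the
mapping table) and experimental coordinate error.  Green tests on decoys
therefore validate the *metrics* — their algebra, invariances and
sensitivities — not the package's ability to rank real blind predictions,
which additionally depends on annotation-threshold calibration against
curated references.

# Numerical choices and degenerate inputs

* Dihedrals use the atan2 formulation with the IUPAC sign convention
  (verified against an independent implementation); degenerate geometry
  (collinear triples) yields NA, propagated via defined flags.
* Kabsch rejects < 3 points or collinear sets ("degenerate point set")
  instead of returning an ill-defined rotation.
* The clash overlap test uses a 1e-9 tolerance so that exact-boundary
  overlaps (e.g. two oxygens at precisely 2.64 Å) count as clashes on all
  platforms.
* Alternate locations resolve to highest occupancy, ties to the first
  encountered — deterministic and independent of label order.
* Multi-MODEL files read the first block by default (submissions are
  single-model); an index selects others.
* Unknown residue codes that look like nucleotides (sugar atoms plus a
  glycosidic nitrogen) raise an error rather than being dropped, because
  silently losing residues corrupts every downstream count; true ligands
  and waters are dropped under the default RNA-only policy (ligands can
  be retained, flagged, with `keep_ligands = TRUE` — they are excluded
  from all metrics either way, which mirrors how RNA-only comparisons
  are published).
* CSV/JSON outputs round to 4 decimals, contain no timestamps, and
  serialise NA as `NA`/`null`; re-running on identical input is
  byte-identical.

# Problem sizes

The test suite and the acceptance script run on duplexes of 10-104
residues (up to ~2200 atoms), ten noise seeds per sigma; the full suite
completes in well under a minute on a single core.  These sizes were
chosen because every assertion is already sharp at this scale: the noise
RMSD estimator's relative error scales like 1/sqrt(N_atoms), and at 2210
atoms the sigma*sqrt(3) check is tested at 5%.

# Known limitations

* The geometric annotator is deliberately simple (no bifurcated pairs, no
  base-phosphate or ribose H-bond classes, no A-minor typing); INF values
  against references annotated by other tools will differ near decision
  boundaries.
* Clash Score approximates probe-based scorers only coarsely on
  hydrogen-free models (see above).
* Sequence-independent (structure-based) residue mapping is out of scope;
  correspondence is index-, number- or sequence-alignment-based.
* The helix builder makes ideal duplexes only; it is a test substrate,
  not a modelling tool.
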