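---
title: "Modelling anion recognition by the CaNN backbone motif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling anion recognition by the CaNN backbone motif}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cannmotif)
```

## The system

The CaNN motif is a backbone-only anion binding site formed by three
consecutive residues: the Calpha–H of residue −1 and the amide N–H of
residues 0 and +1, typically in the loop immediately N-terminal to an
alpha-helix (the "anchoring helix"). Tetrahedral oxyanions (sulfate,
hydrogen phosphate) dock against it in a characteristic pattern: one
oxygen bridges Calpha(−1)–H and N(0)–H simultaneously while a second
oxygen accepts only from N(+1)–H. Binding is coupled to conformation —
the motif holds helical torsions at the N0/N+1 positions while the
anion is present and relaxes towards polyproline II (PPII) when it
leaves, so the anchoring helix is effectively extended by one
N-terminal turn during residence.

This package models that system end to end for a family of designed
18-residue chimeric peptides (four motif residues followed by a
designed Ala/Aib/Lys anchor helix) and their 5-residue truncations. It
does not dock or simulate: docking-pose ensembles and binding/unbinding
trajectories are *emulated* by seeded generators with known ground
truth, so every analysis stage can be validated quantitatively.

## Backbone construction

Chains are extended atom by atom from internal coordinates (the
standard NeRF scheme): each atom is placed from a bond length, a bond
angle and a torsion relative to three previously placed atoms. Bond
lengths and angles are fixed at Engh–Huber-style ideal values (N–CA
1.458 Å, CA–C 1.525 Å, C–N 1.329 Å, C=O 1.231 Å, N–H 1.01 Å, CA–HA
1.09 Å; N–CA–C 111.2°, CA–C–N 116.2°, C–N–CA 121.7°), so the only free
parameters are the user's (phi, psi) per residue; omega is fixed at
180° (trans) throughout, including the caps. Construction is exact:
re-measuring torsions from the coordinates reproduces the inputs to
numerical precision, far inside the 0.5° acceptance band used by the
tests.

Choices worth knowing about:

* **Caps.** The N-acetyl cap is built as CH3–C(=O)– preceding residue
  1 and defines phi(1); the C-amide –NH2 cap defines psi(n). Without
  them the terminal torsions would be undefined, but the tabulated
  designs print torsions for residue 1, so the caps are structural,
  not cosmetic.
* **Chirality.** Calpha substituents are placed at torsion offsets of
  −120° (CB) and +120° (HA) from the backbone C about the N–CA axis.
  The sign was fixed against an independently embedded L-alanine
  reference geometry (improper N–C–CA–CB = +120° for L-residues) and is
  guarded by a test that also checks the handedness of built helices
  via the sign of consecutive Calpha-triad torsions. During development
  the dual-oracle comparison (an independent torsion implementation
  plus bio3d's) caught a sign inversion that had silently produced
  mirror-image chains — the reason the suite pins the convention at
  three independent points.
* **Side chains** are built only to CB (Gly: HA2/HA3; Aib: CB1/CB2, no
  Halpha). Every interaction analysed here uses backbone atoms only,
  so rotamers would add cost and no information.
* **Gly's two Halpha.** The contact evaluation uses whichever Halpha is
  nearer the candidate acceptor; the pro-R/pro-S distinction is not
  meaningful for this analysis.

## Contact detection and energetics

Geometric acceptance is donor-kind specific — d(H···O) ≤ 3.0 Å for
Calpha donors, ≤ 2.7 Å for amide donors, angle ≥ 90°, all inclusive.
The amide cutoff is exposed as a configuration value
(`hbond_cutoffs()`) because the crystal-structure convention uses 3 Å
for all donors; 2.7 Å is the default here. Energies come from the
four-term point-charge Coulomb sum (factor 332 kcal·Å/mol·e²) with the
charge set fixed at q_S = 1.6, q_O = −0.9, amide (q_H, q_N) =
(0.3, −0.5), Calpha (q_H, q_C) = (0.06, −0.1); E ≤ −1.0 kcal/mol
classifies as strong, (−1.0, −0.5] as weak. The canonical-pattern
predicate is purely geometric (energies are reported but do not gate
it): exactly two interacting oxygens, one of whose donor sets contains
both Calpha(−1) and N(0), the other exactly {N(+1)}.

## Conformational states and trajectories

`classify_state()` is total over (phi, psi): the strict helical window
[−85, −55] × [−69, −45] is carved out first, then PPII
[−85, −55] × [130, 170], then a broad right-handed box
[−110, −40] × [−80, −5] labelled *non-canonical helical* (the region a
residue stabilised by a neighbouring Aib occupies after unbinding,
between helical and PPII), then *other*. Boundaries are inclusive and
ties go to the more specific region. The broad-box bounds are a package
definition — the term is used loosely in the literature — and are
exposed via `rama_windows()`.

Anion residence in a trajectory is the initial maximal run of frames
with ≥ 1 motif contact, tolerating gaps shorter than `gap_tol = 10`
frames so that contact flicker does not split one residence episode;
the transition report gives per-motif-residue helical fractions before
and after residence ends. NH–NH(i, i+1) < 4 Å is used as the helicity
criterion for consecutive amide protons.

## Synthetic generators: what they emulate, and what not

`generate_canonical_pose()` places an ideal rigid anion (S–O 1.49 Å,
P–O 1.54 Å, tetrahedral) against the motif by minimising the maximum of
six tolerance-scaled geometry errors (three distances, three angles;
smooth p = 8 approximation) over the six rigid degrees of freedom, with
deterministic multi-start and a soft clearance hinge that keeps the two
spare oxygens out of contact range. The default targets (d = 1.9 Å /
160° at the amide donors, 2.6 Å / 120° at the weaker Calpha donor) sit
in the middle of the ranges reported for docked conformers. A solution
is accepted only when every constraint is within 0.15 Å / 10°;
otherwise the call errors with the achieved residual. Feasibility
depends on the motif conformation: the defaults are feasible on the
native (beta–alphaR–alphaR) motif — the conformation the bound state
actually adopts — and not on an artificially all-helical one, which is
why the trajectory generator keeps the Calpha(−1) residue at its native
beta torsions.

`generate_pose_ensemble()` (default n = 250, the conventional docking
run size) applies Gaussian rigid-body jitter to the anion:
sigma_trans = 0.03 Å, sigma_rot = 2°. These defaults were chosen once
to reproduce the scale of variation reported for docked-conformer
ensembles (distance ranges of roughly 0.1 Å, sigma/mu of order 10⁻²)
and are not tuned per test.

`generate_switch_trajectory()` (defaults n_frames = 1000,
unbind_frame = 400, relax_frames = 100, at 1 frame per ps — a
desk-scale analogue of a trajectory saved every 1 ps whose bound phase
lasts ~400 ps) jitters backbone torsions around state-dependent
centres: bound frames hold N0/N+1 in the strict helical window
(truncated normal, s.d. 4°), after unbinding N0 resamples in the PPII
window immediately while N+1 lags `relax_frames` frames in the broad
helical box (emulating the stabilising effect of the neighbouring Aib)
before following. The anion is re-anchored each frame by least-squares
superposition of the six donor atoms, jittered, and after unbinding
retreats along a fixed escape direction at 0.5 Å/frame. Gap-tolerant
residence detection therefore recovers unbind_frame within the
documented ±10-frame band.

What the generators deliberately do **not** model: force-field
energetics, solvent, anion internal flexibility, side-chain contacts,
or any kinetics beyond the prescribed switch. Passing tests demonstrate
that the analysis stack recovers known ground truth from data with the
right geometry and noise structure — not that real docking or MD output
would look like this in detail.

## Ensemble statistics

Per donor and metric the ensemble summary reports n/min/max/mean of the
closest-contact values plus a least-squares Gaussian fit to the
density-normalised histogram (Sturges binning — the bin count is a
configuration option since the choice is not standardised), with
adjusted R² = 1 − (1 − R²)(n_bins − 1)/(n_bins − 3) for the
three-parameter fit, and sigma/mu as the dispersion diagnostic. The fit
is intentionally diagnostic: unimodal tight ensembles give adj. R² ≥
0.9 while bimodal ones degrade below 0.7, and the tests assert both
directions. The histogram estimator carries sampling variance of its
own (single draws at n = 250 recover sigma to ~5% on average but can
stray to ~15%), so parameter-recovery guarantees are asserted on
replicate averages. Models in which a donor has no contact are excluded
per donor, not dropped, mirroring how ranges over interacting
conformers are reported. Degenerate (zero-spread) samples skip the fit
and report the range fields only.

## Restraint translation

NOE classes map to upper distance limits 4.25/3.5/3.0 Å. The Karplus
curve ³J = 6.4 cos²θ − 1.4 cos θ + 1.9 Hz uses θ = |phi − 60°| taken as
the *wrapped* circular difference so phi near −180° behaves correctly.
Inversion solves the quadratic in cos θ analytically rather than by
grid search: the analytic route is exact, cheaper, and — decisive for
correctness — keeps tangency solutions, e.g. J exactly at the curve's
interior minimum (1.823 Hz), which a sign-change grid scan silently
drops. Near-zero discriminants are treated as zero; each root is
widened to ±10° (the conventional restraint width) and overlapping
intervals are merged across the ±180° wrap.

## Mass computation

Monoisotopic and average masses are summed from CODATA/IUPAC atomic
masses with cap deltas (acetyl +C2H2O; amide −O+N+H), Aib as C4H7NO.
Adducts are modelled as the neutral peptide plus the intact dianion,
[M + anion]²⁻, with the electron mass included (negligible at one
decimal but kept for correctness): this reproduces the sulfate
assignment at m/z 926.5 with isotopic spacing 0.5. The same computation
for hydrogen phosphate also gives ≈ 926.50, one last-digit unit above
the instrument-observed 926.4; the package reports the computed value
and leaves the discrepancy to calibration, rather than forcing the
observed number.

## Problem sizes and limitations

The test suite and the acceptance script run ensembles of 250 poses and
trajectories of 1000 frames (5 seeds), the package's standard working
scale; model building itself is milliseconds. Known limitations: PDB
support is deliberately minimal (fixed columns, first altLoc kept with
a warning, no mmCIF/symmetry/B-factor semantics); the builder does not
model cis-proline or non-ideal bond geometry; the canonical-pose solver
is a geometric construction, not an energy minimiser, and its
feasibility check is in terms of the stated tolerances only; and the
docking binding-free-energy column of ensemble reports is rendered
"n/a" — reproducing it would require the docking engine's scoring
function, which is out of scope.
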