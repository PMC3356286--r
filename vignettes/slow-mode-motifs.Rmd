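---
title: "Slow-mode essential dynamics and regulatory motif detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slow-mode essential dynamics and regulatory motif detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modemotif)
```

## The model

Multi-domain chaperone dimers such as the Hsp90 family work by large
collective motions: the N-terminal (NTD), middle (M) and C-terminal (CTD)
domains of each protomer open, close and twist against each other, and a
small set of residues — hinges at domain interfaces, mobile recognition
loops, catalytic clusters — appears to regulate those motions.  `modemotif`
implements the analysis layer that extracts this architecture from a
conformational ensemble:

1. **Flexibility profiling.**  After Kabsch least-squares superposition of
   every frame, per-frame RMSD and per-residue RMSF over the C-alpha trace.

2. **Salt-bridge occupancy networks.**  A candidate acidic–basic pair is
   *formed* in a frame when the minimum distance over its charged-site
   pairs (carboxylate O, basic N) is at most a cutoff (default 4 Å);
   occupancy is the fraction of frames formed.  Bridges are filtered at the
   0.90 ("high occupancy") and 0.95 ("most stabilizing") tiers and
   classified intra-domain / inter-domain / inter-monomer.

3. **Essential dynamics.**  The 3N Cartesian covariance of the superposed
   ensemble, `C = <dx dx'>` (population average over frames), is
   diagonalized.  Eigenvectors are the collective modes, eigenvalues their
   mean-square amplitudes in Å²; the residue cross-correlation map (DCCM)
   is the 3-vector normalization
   `c_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2> <|dr_j|^2>)`.

4. **Mode-filtered correlation.**  The coupling carried by a subset S of
   slow modes alone is

   `c_ij(S) = sum_{k in S} lambda_k (v_k,i . v_k,j) / sqrt(msf_i(S) msf_j(S))`,

   with `msf_i(S) = sum_{k in S} lambda_k |v_k,i|^2`.  This equals the time
   correlation of the trajectory reconstructed from those modes (a tested
   identity), and for a single mode it reduces to the cosine between
   eigenvector residue blocks, independent of the eigenvalue.

5. **NMSF profiles.**  `msf_i(S)` normalized so each monomer's maximum is
   1, letting both protomers share one axis.  The default subset is the two
   slowest modes.

6. **Motif calling.**  On the smoothed NMSF profile, local minima are
   called **anchors** (hinge-like, globally rigid), local maxima
   **recognition sites** (conformationally mobile), and curvature
   sign-changes **turning points** marking sharp rigid-to-flexible
   transitions.  Each motif spans ±5 residues around its seed, clipped at
   domain boundaries, and is flagged *inter-domain coupled* when any span
   residue has an other-domain partner with `|c| >= 0.5` in the
   mode-filtered map.

The working assumption throughout is the one that underlies essential
dynamics itself: the functionally relevant motions are the large-amplitude,
low-index modes of an approximately Gaussian fluctuation ensemble around a
single reference basin.  Multi-basin kinetics, anharmonicity and
solvent-mediated effects are outside the model.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `cutoff` | 4.0 | Å | salt-bridge N–O distance criterion (the conventional value; exposed because scoring conventions differ between studies) |
| `min_occupancy` | 0.90 | – | "high occupancy" tier; 0.95 marks the most stabilizing bridges |
| `modes` | 1:2 | – | slow-mode subset for DCCM/NMSF/motifs |
| `window` | 5 | residues | centered moving-average smoothing, per monomer |
| `min_prominence` | 0.05 | fraction of profile range | persistence floor for extrema; relative, so detection is affine-invariant |
| `min_run` | 2 | residues | curvature sign must persist this long on both sides of an inflection |
| `corr_threshold` | 0.5 | – | coupling support threshold on the absolute mode-filtered correlation |
| `span_radius` | 5 | residues | motif half-width, matching the ~11-residue scale of known regulatory linkers and loops |
| `superpose_reference` | frame 1 | – | fitting reference; a `structure_model` may be supplied instead |

## The synthetic generator and its ground truth

No reference trajectories ship with the package; instead `synthetic_spec()`
defines a seeded generative model whose every downstream answer is known in
closed form (`planted_truth()`):

* frame *t* = reference + Σ_k √λ_k η_kt v_k + ε_t, with η i.i.d. standard
  normal, ε isotropic Gaussian noise, followed by a small random rigid-body
  jitter per frame so that, like raw MD frames, the ensemble must be
  superposed before analysis;
* the reference is two 60-residue helical-arc protomers at exact 3.8 Å
  C-alpha spacing, split NTD/M/CTD = 0.35/0.40/0.25;
* the default modes have amplitudes λ = (10, 3, 1) Å² and noise σ = 0.3 Å
  over T = 1000 frames.  The λ₁/λ₂ ratio above 3 keeps mode recovery
  stable at this trajectory length.

The default mode geometry was designed around three constraints, and the
design is deliberate rather than incidental:

* **Internal motions only.**  Mode fields are projected out of the
  6-dimensional rigid-body subspace and orthonormalized; a recovered mode
  of a superposed ensemble is internal by construction, so a planted mode
  must be too, or recovery comparisons are ill-posed.  Fields are further
  designed with near-zero net force per monomer (mode 2 is a full sine
  period across the CTD) and tapered to zero at chain termini, so the
  rigid-body projection barely perturbs the designed shapes.
* **A planted inter-domain architecture.**  Mode 1 peaks inside the NTD,
  declines across the M-domain, crosses zero at the M/CTD boundary and
  moves the CTD in anti-phase — planting a positive NTD–M and negative
  NTD–CTD block correlation, the signature of an open chaperone dimer, plus
  an inter-domain hinge.
* **Well-posed extrema.**  Domain weights are tapered across boundaries and
  the two slow modes load on complementary regions, so every extremum of
  the planted NMSF profile is comfortably above the 5% prominence floor and
  no feature sits at the detection threshold.

Planted salt bridges are pseudo-site pairs whose separation per frame is
`bound_distance` (3 Å) or `unbound_distance` (7 Å) by a seeded Bernoulli
draw — not rotamer physics, but exactly the two-state statistic the
occupancy estimator must recover, testable on a C-alpha-only ensemble.

What passing on this generator does **not** show: robustness to
anharmonic or multi-basin dynamics, to sparse sampling of slow transitions,
to real side-chain geometry, or to disordered segments.  The generator is a
correctness oracle, not a realism benchmark.

## Numerical choices

* Covariance uses the population convention (divide by T), so the
  projection identity var(q_k) = λ_k holds exactly on the same ensemble.
* Eigenvector signs are fixed by making each vector's largest-magnitude
  component positive; eigenvalues below zero by round-off are clipped.
* Extremum prominence is persistence-style: the least prominent extremum
  (contrast against adjacent anchors) is removed iteratively until all
  survivors clear the floor, which keeps minima and maxima alternating.
  Plateaus collapse to their leftmost index; the first and last
  ⌈window/2⌉ residues of each monomer are excluded as smoothing edge
  artefacts.  The same machinery defines both the detector and the
  synthetic truth scan, so "a planted extremum at prominence q" means one
  thing.
* Inflections are curvature (second-difference) sign changes holding for
  `min_run` residues on both sides; the leftmost index of the crossing is
  reported.  Zero-variance residues are flagged undefined rather than
  imputed.
* RMSD and all covariance analysis are C-alpha-only (one consistent
  selection throughout; a backbone-atom RMSD variant is not implemented).
  RMSF is taken about the time-mean structure, the standard choice.
* Whole-dimer PCA in one 3N space, profiles split per monomer afterwards.
  Per-monomer NMSF normalization (max = 1) was chosen over global
  normalization so both protomers are readable on one axis even when their
  sampled amplitudes differ.
* The snapshot interval (default 200 ps) is metadata only; every stored
  frame enters the analysis.

## Problem sizes

The validation suite runs the default spec (120 residues, T = 1000) across
50-seed replicate studies for mode, NMSF and extremum recovery, T = 2000
for occupancy recovery, and T = 5000 for the generator's own
mean-square-fluctuation self-consistency check.  At these sizes the whole
suite completes in a few minutes on one core; they were chosen as the
smallest sizes at which the stochastic recovery criteria have comfortable
statistical margins.

## Known limitations

* Salt-bridge detection on real input requires side-chain coordinates per
  frame (multi-model PDB); a C-alpha-only DCD carries no sites and the
  bridge stage is skipped.
* Occupancy is a distance criterion only — no angular term, no protonation
  states, no water-mediated bridges.
* Missing residues are handled by analyzing what is present (contiguous
  internal indexing alongside author numbering); no gap imputation.
* The motif caller parameterizes choices the field usually makes by eye
  (smoothing, prominence, coupling support); defaults are tuned on the
  synthetic suite and should be revisited for ensembles with very
  different length scales.
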