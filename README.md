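# modemotif

Trajectory analysis for multi-domain protein dimers: essential-dynamics
PCA, dynamic cross-correlation maps, salt-bridge occupancy networks, and
detection of the regulatory motifs — anchors (hinges), recognition sites
and turning points — that organize slow collective motions.

## Who this is for

Structural bioinformaticians studying allosteric machines of the Hsp90
chaperone type: homodimers whose N-terminal (NTD), middle (M) and
C-terminal (CTD) domains move collectively, where the interesting biology
sits in a handful of residues that anchor, transmit or receive those
motions.  Given a reference structure (PDB), an ensemble (DCD or
multi-model PDB) and a domain annotation, the package produces the full
analysis layer; a seeded synthetic generator with closed-form ground truth
stands in for trajectories so that every stage is testable.

## The method

For a superposed C-alpha ensemble, the 3N covariance `C = <dx dx'>` is
diagonalized into modes `(lambda_k, v_k)`.  The analysis then works with
quantities restricted to a subset S of slow modes (default the two
largest):

* **mode-filtered cross-correlation**
  `c_ij(S) = sum_{k in S} lambda_k (v_k,i . v_k,j) / sqrt(msf_i(S) msf_j(S))`
  — equal to the time correlation of the trajectory reconstructed from S;
* **NMSF profile** `msf_i(S) = sum_{k in S} lambda_k |v_k,i|^2`, normalized
  to max 1 per monomer;
* **motif calls**: NMSF minima → anchors, maxima → recognition sites,
  curvature sign changes → turning points, each requiring (or flagged for)
  cross-domain coupling support at `|c| >= 0.5`;
* **salt-bridge occupancy**: fraction of frames in which an acidic–basic
  pair sits within 4 Å (minimum over charged-site pairs), with the 0.90 /
  0.95 occupancy tiers and domain classification.

See `vignettes/slow-mode-motifs.Rmd` for the model, its assumptions and all
numerical choices.

## Worked example

The `analysis/` scripts run the whole study on the default synthetic dimer
(two 60-residue protomers, planted modes with amplitudes 10/3/1 Å², three
planted salt bridges):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_flexibility.R
Rscript analysis/03_saltbridges.R
Rscript analysis/04_essential_dynamics.R
Rscript analysis/05_motifs.R
```

Stage 4 prints the recovered spectrum and coupling signs:

```
top eigenvalues (A^2): 10.11, 2.989, 1.184, 0.2254, 0.2223
two slowest modes carry 29% of the total fluctuation
  NTD-M block mean correlation +0.90 (positive)
  NTD-CTD block mean correlation -0.34 (negative)
```

— the planted amplitudes (10, 3, 1 Å²) come back on top of the noise
floor, and the block means recover the planted architecture: the NTD moves
with the M-domain and against the CTD, the anti-correlated inter-domain
signature of an open chaperone dimer.  Stage 5 calls the motifs:

```
4 anchor, 6 recognition, 15 turning-point motif(s)
  recognition A:NTD 9-19 (seed 14) [inter-domain coupled]
  anchor A:M 38-45 (seed 43) [inter-domain coupled]
  recognition A:CTD 46-54 (seed 49) [inter-domain coupled]
  ...
planted extremum recall within +-2 residues: 100% (10/10)
NMSF Pearson correlation with planted profile: 0.996
```

The NTD recognition peak, the hinge anchor at the M/CTD boundary and the
mobile CTD lobes are exactly where the generator planted them.  Stage 3
recovers the planted bridge occupancies (0.99 → 0.994, 0.93 → 0.935,
0.42 → 0.428) and their domain classes.

The same pipeline runs on real input through a YAML config
(`pipeline_config()` / `run_full_pipeline()`), pointing `input:` at a
reference PDB and a DCD or multi-model PDB trajectory with a domain map.

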