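# ringalign

Quantitative analysis of **intramolecular aromatic side-chain dynamics** in
minimal peptoids and peptides. Sequences built on the diphenylalanine motif
carry two phenyl rings per molecule; how those rings align and reorient —
and whether that depends on the backbone's fixed *cis*/*trans* amide state
(cc, ct, tc, tt) — correlates with whether the sequence self-assembles into
well-defined nanostructures. This package is for simulators who already
have (or want to emulate) multi-molecule trajectory ensembles, one per
amide state, and need the descriptor statistics.

## The descriptors

With ipso the ring carbon bonded to the side-chain linker and para the
carbon opposite it, for the two consecutive rings of one molecule:

- **ρ = r_ipso / r_para** — the ratio of ipso–ipso to para–para carbon
  distances. ρ = 1.0 is exact face-to-face stacking; ρ > 1 means the ring
  tips are buried (r_para < r_ipso).
- **λ** — the para1–ipso1–ipso2–para2 dihedral (IUPAC sign), wrapped to
  [0, 360) by adding 360° to negative values. λ = ±180° is coplanar anti.
- **Δλ switching** — a frame-to-frame change of λ of at least 20° counts
  as one ring-reorientation event. Per-molecule counts average to the
  population mean **x̄_λ**, bootstrapped (n = 1000) for uncertainty.
- **η = x̄_λmax / x̄_λmin** across a sequence's amide states. η ≈ 1 means
  side-chain torsional exploration is backbone-independent
  (homogeneous); η ≫ 1 flags backbone-dependent dynamics.
- **ρ–λ occupancy surfaces** — raw 60 × 60 histograms of every (ρ, λ)
  point of every molecule and frame, with a histogram-intersection
  overlap score between surfaces.

A synthetic trajectory generator produces 25-molecule × 2500-frame
ensembles whose λ(t) follows a seeded jump process realised in actual 3D
coordinates with *exact* descriptor-level ground truth, so the entire
pipeline is testable without an MD engine. A grid-search partial-charge
fitting protocol (0.05 e grid, symmetry groups, 1.2–1.5× dipole
overestimation filter, ±0.2 kcal/mol water-probe tolerance) is included
for force-field side-chain parametrization.

## Worked example

Four synthetic amide-state ensembles with switch probabilities in ratio
7 : 4 : 5 : 4 (so the ground-truth η is 1.75), analysed end to end:

```r
library(ringalign)
report <- run_analysis(list(
  synthetic = list(
    spec = synthetic_spec(n_molecules = 25, n_frames = 2500, seed = 11),
    p_by_state = c(cc = 0.028, ct = 0.016, tc = 0.020, tt = 0.016)),
  convention = "circular", seed = 11))
report
#> <analysis report> states: cc, ct, tc, tt
#>   cc: x_bar = 70.440 (bootstrap 70.406 +/- 1.722)
#>   ct: x_bar = 38.520 (bootstrap 38.539 +/- 1.391)
#>   tc: x_bar = 49.920 (bootstrap 49.925 +/- 1.249)
#>   tt: x_bar = 40.200 (bootstrap 40.188 +/- 1.267)
#>   eta = 1.8287 [1.6589, 2.0449] (99% bootstrap interval)
```

Each state's x̄_λ sits near its binomial expectation (2499 × p: 70.0,
40.0, 50.0, 40.0), and the 99% bootstrap interval for η covers the
generating ratio 1.75. Surfaces come along for free:

```r
surface_overlap(report$surfaces$cc, report$surfaces$tc)
#> [1] 0.902208
```

For real trajectories, replace `synthetic` with
`ensembles = list(cc = "cc.pdb", ct = "ct.pdb", ...)`; ring atoms are
resolved by residue templates (`ring_template()`: ipso = CG, para = CZ
for benzyl-bearing residues) and `write_report()` emits the TSV/JSON
bundle with a reproducibility manifest.

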