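---
title: "Quantifying intramolecular aromatic ring dynamics with rho, lambda and eta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intramolecular aromatic ring dynamics with rho, lambda and eta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringalign)
```

## The problem

Minimal peptoids (poly-N-substituted glycines) and their peptide analogues
carrying two phenyl side chains — sequences built around the
diphenylalanine self-assembly motif — organise into nanostructures whose
formation depends on how the two aromatic rings of each molecule present
themselves to the environment. Because the peptoid backbone amide can
occupy either the *cis* (c) or *trans* (t) conformation and isomerises far
too slowly for a conventional simulation to average over, ensembles are
simulated separately in each fixed amide state (cc, ct, tc, tt for a
two-bond sequence). The question this package answers quantitatively is:
how do the two rings of one molecule align and reorient over a trajectory,
and does that behaviour depend on the backbone amide state?

## Descriptors

For two consecutive phenyl rings, with ipso the ring carbon bonded to the
side-chain linker and para the carbon directly opposite:

* **rho** — the ratio of the ipso–ipso to para–para carbon distances,
  `rho = r_ipso / r_para`. Exactly face-to-face stacked rings give
  rho = 1; rho > 1 means the para "tips" of the rings are buried closer
  together than their bases.
* **lambda** — the para1–ipso1–ipso2–para2 dihedral, computed with the
  IUPAC sign convention and wrapped to [0, 360) by adding 360 to negative
  values. Lambda = 180 (equivalently −180) is the coplanar anti
  arrangement, lambda = 0 the eclipsed one.

Ring 1 is always the ring nearer the N-terminus. A proper dihedral is
invariant under reversing the traversal order, so this rule exists for
bookkeeping consistency rather than because the value depends on it; the
wrap convention, however, does make the reported number depend on the sign
convention, which is why both are fixed and documented. Internally all
indices are 1-based, the natural R convention, and coordinates are
Angstrom throughout.

```{r descriptors}
ring <- benzene_ring_template()
stacked <- ring + matrix(c(0, 0, 3.5), 6, 3, byrow = TRUE)
compute_rho(ring["CG", ], stacked["CG", ], ring["CZ", ], stacked["CZ", ])
compute_lambda(c(-1.39, 1.2, 0), c(0, 0, 0), c(4.6, 0, 0), c(5.99, -1.2, 0))
```

Degenerate geometries (coincident para carbons, collinear torsion atoms)
raise errors rather than returning sentinels: they indicate corrupt input,
never legitimate chemistry.

## Switching statistics

The frame-to-frame change `delta-lambda` is compared between each frame
and the next; a step of at least 20 degrees (inclusive) counts as one
switching event of the intramolecular ring organisation. Counts are summed
per molecule and averaged over the population to give `x_bar`. Two
delta-lambda conventions are provided:

* `"literal"` (default): `|lam[i+1] − lam[i]|` on the wrapped values,
  matching the stated procedure verbatim. It counts a spurious switch
  whenever the torsion drifts across the 0/360 boundary.
* `"circular"`: `min(d, 360 − d)`, the shortest angular distance, which is
  boundary-safe.

Every summary records the convention used. For ground-truth validation
work (below) the circular convention is the right comparator, since jump
events are defined on the circle; with uniformly distributed lambda the
literal convention inflates each molecule's count by roughly
`(n_frames − 1) * E[step] / 360` boundary artifacts, which is why the two
conventions are kept strictly apart in reports.

Uncertainty on `x_bar` comes from bootstrap resampling (n = 1000 by
default). The default resampling unit is the per-molecule switch count,
because `x_bar` is defined as a mean over molecules; resampling frame-level
delta-lambda values (`unit = "steps"`) is available for series-level
uncertainty, as the choice of unit is genuinely open. All bootstraps are
seeded and record their seed.

Homogeneity across amide states is summarised by
`eta = x_bar_max / x_bar_min` over a sequence's states: eta near 1 means
side-chain torsional exploration is independent of the backbone amide
configuration, the regime associated with well-defined assembly; eta well
above 1 flags backbone-dependent dynamics. A zero minimum yields +Inf with
a warning — degenerate but representable. `bootstrap_eta()` resamples
molecules within each state independently to give a percentile interval
for eta.

## Occupancy surfaces

`build_surface()` histograms every (rho, lambda) point of every molecule
and frame on a 60 x 60 grid — 60 bins per axis, consistent with the
resolution such surfaces are displayed at. Lambda is binned on [0, 360);
rho on [0, 2] by default, covering the sampling observed in aqueous runs
(up to about 1.8), with out-of-range points tallied rather than silently
dropped so points are always conserved. Raw counts are kept: no kernel
smoothing, no free-energy transform. `surface_overlap()` scores two
surfaces by histogram intersection of the count-normalised grids, turning
qualitative "these states are dynamically similar" statements into a
symmetric [0, 1] number. Display remapping of lambda to (−180, 180] is
cosmetic only (`lambda_display()`).

## The synthetic generator

`generate_ensemble()` produces trajectory ensembles with the statistical
structure the analysis assumes and nothing else — no force field, no
solvent, no realistic amide isomerisation kinetics. Defaults emulate the
layout of the reference simulations: 25 molecules, 2500 frames (a 50 ns
run sampled every 20 ps), two ideal benzene rings (C–C 1.39 Angstrom) per
molecule. Per frame-step and molecule, lambda jumps with probability `p`
by a magnitude drawn uniformly from [25, 120] degrees and otherwise
jitters by under 5 degrees. The supports are validated against the
threshold: jumps at or above it, jitter strictly below, so the
ground-truth switch count equals the number of jump events *exactly* under
the circular convention, and the generator reports where the literal
convention disagrees (wrap crossings).

Geometrically, each frame is constructed in closed form. With ipso1 at the
origin, para1 on the y-axis and ipso2 at distance `d` on the x-axis, the
direction of the ipso2-to-para2 vector has polar angle mu and azimuth
equal to lambda, and the para–para distance satisfies

    r_para^2 = d^2 + 2 a^2 + 2 a (d cos(mu) − a cos(lambda) sin(mu)),

with `a` the ring diameter. Solving this for mu at the programmed
(rho, lambda) realises both descriptors simultaneously to machine
precision. An earlier design idea — rotating ring 2 rigidly about the
ipso–ipso axis to change lambda "without changing rho" — does not survive
the algebra: that rotation moves para2 on a circle whose distance to para1
depends on the rotation angle, so rho and lambda cannot be decoupled that
way. The closed-form solve is what actually keeps them independently
controllable. Programs outside the reachable band (roughly rho in
[0.6, 1.4] at `d = 5` across all lambda) raise a generation error rather
than silently clipping.

Each molecule is then placed by its own random rigid transform (the
descriptors are rigid-invariant) on a 25-Angstrom grid, and
`generate_state_family()` derives one independent, deterministically
seed-split ensemble per amide state.

```{r generator}
fam <- generate_state_family(
  synthetic_spec(n_molecules = 10, n_frames = 400, seed = 42),
  c(cc = 0.04, ct = 0.02, tc = 0.03, tt = 0.02))
counts <- lapply(fam$ensembles, function(e)
  mean_switches(lambda_matrix(compute_series(e$ensemble)),
                convention = "circular")$per_molecule_switches)
compute_eta(lapply(counts, mean))
fam$eta_truth
```

What passing these tests shows — and what it does not: recovering the
programmed switch rates and eta from synthetic coordinates validates the
geometry, wrap, counting and resampling machinery end to end. It says
nothing about force-field accuracy, solvent effects, or whether 2500
frames suffice to converge a real sequence's switching statistics; those
are properties of the simulations being ingested, not of this analysis.

## Charge fitting

`run_charge_fit()` implements the additive force-field side-chain
protocol: every combination of per-atom partial charges on a 0.05 e grid
(chemically equivalent atoms tied into symmetry groups) that sums to the
molecular charge is enumerated exhaustively — in integer grid units with
remaining-sum pruning and a 1e7-point refusal cap, since the search is
exponential in free groups. Candidates must overestimate the quantum
reference dipole by a factor of 1.2–1.5 (inclusive at both ends, the
standard compensation for missing polarisation) and reproduce reference
water-probe interaction energies within ±0.2 kcal/mol, evaluated as
Coulomb (332.0636 kcal Å mol⁻¹ e⁻²) plus Lennard-Jones
`eps[(rmin/r)^12 − 2(rmin/r)^6]` with geometric-mean eps and summed
rmin/2. Survivors are ranked by RMS deviation with deterministic
tie-breaking, replacing a by-hand final adjustment with a reproducible
criterion. Quantum references (dipole, probe energies) are inputs, never
computed. Well depths are stored positive even though force-field tables
print them negated.

## Numerical choices and problem sizes

* Torsion: `atan2` formulation; agreement with an independent
  plane-normal construction is asserted to 1e-9 degrees over 1000 random
  quadruples, and rho/lambda rigid-transform invariance to 1e-9 over 1000
  random transforms.
* Switch threshold comparison is inclusive (>= 20 degrees); the dipole
  band is inclusive at 1.2 and 1.5 — interval endpoints belong to the
  accepted set wherever the defining rule is stated as a closed bound.
* Charge enumeration runs in exact integer grid units, so sum constraints
  are met to 1e-9 in e without floating-point drift.
* Validation sizes: property suites use 400–800-frame ensembles; the
  full-scale eta-recovery study uses the default 25 x 2500 layout across
  four states and ten seeds, chosen to mirror the reference population
  layout while keeping the whole suite in tens of seconds on one CPU.
* Frame spacing is carried as metadata only; no statistic in the package
  depends on it.

## Interfaces

The package is a library: `run_analysis()` and `run_charge_fit()` are the
orchestration entry points (ingest-or-synthesize, then descriptors,
surfaces, switching, eta, TSV/JSON bundle with a manifest), and this
vignette plus the exported functions are the intended user surface —
rather than a shell executable, since every use we anticipate starts from
R objects or files already on disk. Multi-model PDB I/O goes through
bio3d; the multi-frame XYZ reader/writer is the package's own, as no
installed R package handles frame-block XYZ. Binary trajectory formats
are deliberately not parsed here; convert upstream, or read frames with an
external tool and hand coordinates to `trajectory_ensemble()` directly.

## Known limitations

* Exactly two rings per molecule; sequences with more aromatic side
  chains are out of scope, as are ring-plane/centroid descriptors.
* No kinetic modelling of switching (no rates, no autocorrelation), and
  no significance testing between sequences.
* Ingested trajectories must be pre-wrapped molecule-whole; the validator
  flags broken rings (intra-ring C–C distance over 3 Angstrom) but does
  not unwrap periodic images.
* The literal delta-lambda convention, kept as the default for fidelity
  to the defining procedure, overcounts at the 0/360 boundary; use the
  circular convention when comparing against generator ground truth.
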