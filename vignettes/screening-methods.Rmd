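---
title: "Coarse-grained screening of cholesterol-peptide self-assembly: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained screening of cholesterol-peptide self-assembly: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pepscreen` ranks cholesterol-modified 12-mer peptides by self-assembly
propensity using coarse-grained implicit-solvent dynamics and four
structural/energetic observables. This vignette is the package's account
of the model: what is simulated, which knobs matter, what the
synthetic-data generator does and does not emulate, and where the design
was genuinely open.

## The coarse-grained model

Each conjugate is a chain of 13 beads: one cholesterol terminal-domain
(CTD) bead followed by one bead per residue. The potential is

* harmonic bonds along the chain, `E = k/2 (r - r0)^2`, with
  `k = 10 kcal/(mol A^2)` and `r0 = 4 A` (a typical residue-residue
  spacing at this resolution);
* between beads of **different** molecules only: a 12-6 Lennard-Jones
  term under Lorentz-Berthelot mixing, and a screened Coulomb term
  `E = k_C q_i q_j / (eps_r r)` with `k_C = 332.0636 kcal A/(mol e^2)`;
* no intramolecular nonbonded terms at all.

Bead parameters (shipped in `inst/extdata/bead_params.csv`, model
defaults rather than literature values): residues have
`sigma = 4.5 A`, `epsilon = 0.2 kcal/mol`, radius 2.25 A; the CTD bead
is larger and deeper (`sigma = 6 A`, radius 3 A,
`epsilon = 0.5-3.0 kcal/mol`). Charges are formal side-chain charges:
K/R +1, D/E -1, H neutral by default. Because the histidine of these
delivery peptides is functionally relevant at endosomal pH, an `acidic`
mode makes H +1; it plays no role in the default screen. Cholesterol
blocks the N-terminus, so modified entries carry pure side-chain charge;
unmodified entries add +1/-1 termini.

The CTD well depth is the hydrophobic driver. Aromatic side chains (W,
F, Y) pack against the cholesterol domain and strengthen aggregation, so
the screen derives `epsilon_CTD = 0.5 + 0.5 x (number of W/F/Y)`, capped
at 3.0 kcal/mol. The cap keeps the deepest well near 5 k_B T at 300 K -
strongly aggregating but numerically tame.

Masses are reduced coarse-grained masses (10 amu per residue bead, 40
amu for the CTD), not chemical masses: with energies in kcal/mol and
lengths in Angstrom the reduced time unit is ~49 fs, and light beads
compress the diffusive encounter times that dominate aggregation
kinetics. Only ratios of time scales matter for the screen's readouts.

## Dynamics

The integrator is the BAOAB splitting of Langevin dynamics. With zero
friction it reduces exactly to velocity Verlet (the NVE tests exploit
this); for a non-interacting particle the O-step is an exact
Ornstein-Uhlenbeck update, so equipartition holds at any stable `dt`.
Thermostat noise comes from a counter-based generator (splitmix64 mixing
of seed, step, bead and axis, then Box-Muller), so trajectories are
bit-reproducible for a fixed seed regardless of threading or R's RNG
state. Divergence (potential energy above 1e6 kcal/mol) aborts with the
offending step.

Defaults: `dt = 0.05`, `friction = 0.01` per reduced time, 300 K, 20 000
steps saved every 500 (41 frames). The friction is deliberately low -
high-friction Brownian motion would make 16 molecules in a ~50 A box
take far longer than the simulated window to find each other. A
steepest-descent minimization (displacement-capped, adaptive step)
precedes dynamics, mirroring the standard minimize-then-heat protocol:
packed starting configurations can place a bead pair deep inside the
CTD's repulsive wall, and without relaxation the first few steps can
catapult the system into divergence.

The simulation is constant-volume. The reference protocol equilibrated
pressure with a barostat before production, but at this resolution a
barostat adds nothing to the screening observables, so NVT was chosen
deliberately. Likewise there is no explicit water: the dielectric
constant (`eps_r = 10` by default) is the implicit-solvent knob standing
in for aqueous screening; the value is a compromise that leaves a +8
library member strongly repulsive while letting +1 to +3 members
interact.

## Geometry conventions

Coordinates are stored unwrapped per molecule and molecules are never
split across the periodic boundary; all pairwise interactions, the
saturation number and the contact clustering use the minimum-image
convention, so absolute wrapping is immaterial to them. SASA, R_g and
the cluster anisotropy are computed in open space on the unwrapped
coordinates: an aggregated cluster stays geometrically contiguous this
way, while dispersed molecules drift apart and read as isolated - which
is the intended signal. `wrap_molecules()` exists for writing
visualizable frames. The one caveat is that open-space SASA ignores
occlusion by periodic images; at the screen's densities molecules of
interest are either in one compact cluster or far apart, where the
effect is negligible.

## Observables

* **SASA** (Shrake-Rupley): every bead sphere is inflated by the probe
  radius (1.4 A, water; the source text never states its probe or units,
  and this package reports A^2 without claiming to match the printed
  scale) and sampled with a deterministic Fibonacci lattice (default 960
  points; no RNG, so SASA is exactly reproducible). Doubling the point
  count moves a typical frame total by well under 0.5%.
* **R_g**: mass-weighted RMS distance from the centre of mass of the
  full bead set.
* **VDW / ELE**: the intermolecular Lennard-Jones and Coulomb sums, full
  pairwise (no cutoff) by default, reported system-total. These are
  computed by a vectorised R implementation that is independent of the
  simulator's C++ force loop; the two agree to 1e-8 relative on every
  frame, which is one of the package's invariant tests.
* **Saturation number**: for each molecule's CTD group, the count of
  other molecules whose CTD group lies within 3 A *surface* distance
  (centre distance minus both radii, minimum image). "Approximately 3 A"
  admitted several distance semantics; surface-surface was chosen
  because it is radius-independent and the cutoff is exposed as a
  parameter. Per-frame maxima and minima are reported and then
  summarised over time - whether the original extremes were per-frame or
  per-run is not stated, and this choice is documented rather than
  resolved.
* **Largest-cluster fraction and kappa^2**: molecules are clustered by
  connected components of the contact graph (any intermolecular bead
  pair within 4.5 A surface distance; components via igraph, with a BFS
  oracle in the tests). The largest cluster's gyration-tensor
  anisotropy kappa^2 distinguishes sphere-like (kappa^2 near 0) from
  stringy (near 1) assemblies.

Metric summaries are means and sample SDs over the frames after a
burn-in fraction (default 0.5; the averaging window of the source
analysis is unstated, and half-trajectory averaging is a conventional
conservative choice).

## Kinetic classification

Timelines are classified into the three observed behaviours:
`fast_stable` (assembled in the early window, still assembled and
sphere-like at the end), `transient` (assembled at the end but not
early+stable+spherical), `non_aggregator` (final-window mean
largest-cluster fraction below the assembly threshold). The early window
is the first 5% of frames - the 10-of-200 ratio of the source
narrative - excluding the time-0 frame, which is contact-percolated by
construction (16 chains packed at 3 A separation are mostly "in
contact" at a 4.5 A cutoff) and carries no kinetic information.
Thresholds: assembled = 0.4 (a plurality cluster of a 16-molecule
system), stable = 0.5, sphere-like kappa^2 <= 0.2. "Sphere-like" had
only visual evidence in the source; kappa^2 <= 0.2 is this package's
operationalisation.

## Ranking

Each of the five summary metrics is converted to a within-library rank
(ascending for SASA, R_g, VDW, ELE; descending for max saturation
number) and combined as an equal-weight rank-sum; the source presents
dot scores without a formula, so rank-sum was chosen for scale-freeness
(multiplying any metric by a positive constant cannot change the
ordering) and the weights are exposed. Systems with net charge above +6
(a cap chosen for a 12-mer from the named offenders being +7/+8-class
sequences; no numeric cap is stated in the source) are flagged
"excess cationic charge" but stay ranked, so reports remain complete;
the top five non-excluded systems are marked selected, matching the five
synthesized candidates of the original workflow.

## The synthetic library and what the tests do (and do not) show

The original ten sequences exist only as a figure and are not
transcribed anywhere machine-readable, so the package ships a synthetic
panel with the same design logic (`synthetic_library()`): SP01 is a
dominant aggregator (five aromatics, +1), SP02/SP03 are weak aggregators
(two aromatics, +2), SP04-SP07 are transients (+3), and SP08-SP10 are
+7/+8 non-aggregators that also trip the charge cap. The screen's
validation is therefore *structural*: planted aggregators must out-rank
planted non-aggregators in essentially every replicate, the extreme
presets must separate directionally in SASA/VDW/saturation in every
seed, and the seed-averaged best candidate must be concordant across all
three readouts (smallest SASA, most negative VDW, largest saturation) -
the pattern the original screen reported for its lead candidate.

Screen conditions: 16 copies per system in a 48 A box. The reference
atomistic protocol used a 110 A box with explicit water;
`pack_system()` defaults to that geometry, but the screening runs use a
smaller box because at coarse-grained reduced length the encounter rate
in a 110 A box is far too low for desk-scale runs - 48 A was fixed, once,
as the smallest box at which the non-aggregating preset stays genuinely
dispersed (time-mean cluster size ~1.5 molecules) while aggregating
presets assemble within the window. Five seed replicates of the
10-system screen take roughly five minutes on one core.

Known limitations, stated plainly:

* With intramolecular nonbonded terms excluded (the model contract),
  chains have no self-excluded volume: strongly charged systems stretch
  and can show *larger* SASA than dispersed neutral ones. The
  directional SASA claims therefore attach to the extreme presets, and
  the composite ranking - where VDW, ELE and saturation dominate the
  separation of weak aggregators from non-aggregators - carries the
  recovery result.
* Aggregation here is percolation-and-freeze: deep CTD wells make
  cluster fusion rare on the simulated window, so final cluster sizes
  retain packing noise. Averaging over seed replicates is part of the
  method, not an optional extra.
* Nothing at this resolution speaks to transfection efficiency,
  toxicity, or any in vitro/in vivo property; the screen reproduces the
  *structure* of the computational triage stage only, and passing its
  tests shows internal consistency on synthetic data, not agreement
  with atomistic or experimental values.

## Numerical choices

Tolerances and tie-breaks that matter: forces must match
central-difference gradients to 1e-4 kcal/(mol A) and energies the
brute-force sums to 1e-10 relative; beads closer than 1e-6 A raise a
singularity error rather than returning infinities; cluster labels are
canonicalised by lowest molecule id, and the largest-cluster tie goes to
the cluster containing the lowest id; ranking ties break
lexicographically by system name; `summarize_metrics()` uses the sample
(n-1) SD and refuses windows with fewer than two frames. Packing retries
are bounded (1e5 attempts per molecule) and failure names the remedy (a
larger box). The run length maps the source's "10 ns / 200 ns"
vocabulary onto frame fractions rather than attempting a physical time
correspondence; the source itself reports both 100 ns and 200 ns runs,
and this package treats run length as a free parameter.
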