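---
title: "Methods: coarse-grained bilayer variants and raft phase analysis"
author: "cgraft"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coarse-grained bilayer variants and raft phase analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgraft)
```

## Scope and model

`cgraft` addresses raft formation in ternary lipid bilayers: mixtures of a
saturated phospholipid (DPPC), a doubly unsaturated phospholipid (DUPC) and
cholesterol (CHOL) that can demix into coexisting liquid-ordered (Lo) and
liquid-disordered (Ld) phases, and under some force-field modifications
into an arrested gel phase.  The package works at MARTINI coarse-grained
resolution, where each bead stands for roughly four heavy atoms and bead
types (C1, C4, SCx, SP1, Q0, ...) encode polarity and ring character.

The package has four computational layers:

1. **Molecule family** (`buildStandardSpecies()`, `applyDupcVariant()`,
   `makeDppcSoft()`, `makeDppc3b()`, `makeCholVariant()`): the three
   standard species plus every systematically modified molecule used to
   probe which molecular properties drive demixing.  The defining
   parameters are the chain-bead types (C1 vs the more apolar C4 on DUPC
   beads 6, 7, 10, 11), the chain equilibrium angles (180° for DPPC; 100°
   and 120° for DUPC) and the chain angle force constants (25 kJ/mol for
   DPPC; 10 and 45 kJ/mol for DUPC).  Variants assimilate one or more of
   these features (`DUa`, `DUs`, `DUas`, `DUb2`, `DUb3`, `DUb23`), soften
   DPPC (10 kJ/mol), shorten and stiffen it into a sterol mimic
   (`DPPC_3b`: three SC1 chain beads, 300 kJ/mol angles, a tip-tying
   bond), stiffen the cholesterol tail (`CHOL_300`) or enlarge its head
   (`CHOL_+1HB`).
2. **Synthetic bilayer generator** (`buildBilayer()`,
   `simulateLateralDynamics()`, `generateTimecourse()`): desk-scale
   configurations and trajectories carrying the statistical structure the
   observables consume.
3. **Observables**: P2 chain order parameters, grid densities and
   interleaflet correlation, local bilayer-center maps, z-profiles, tail
   interdigitation, umbrella coverage, shifted-potential pair energies,
   MSD and RMSD.
4. **Phase pipeline** (`runTimecourse()`, `energyGainSeries()`,
   `classifyPhase()`, `detectDomains()`): time-series assembly, replicate
   aggregation and Ld/Lo/gel calls.

## Nonbonded registry

Only part of the interaction matrix is fixed by the model this package
implements: the chain-bead block (C1-C1 = C4-C4 = 3.5 kJ/mol, C1-C4 =
3.1 kJ/mol), the ring rules (SCx-SCy = 0.75 x Cx-Cy, SCx against a regular
type keeps the full parent strength) and the single sigma of 0.47 nm.
All remaining entries — the charged/polar head and linker types Q0, Qa,
Na, P1 and their pairings — are registry defaults in the style of the
published MARTINI 2.0 interaction levels.  They are **not** values of this
model; `buildNonbondedMatrix(epsilonTable = ...)` accepts a replacement
table, and analyses that depend on head-group energetics should supply
one.  The same caveat applies to bond lengths and linker angles of the
standard species, which the model leaves untouched in every variant.

## Order parameter

For a bond between consecutive chain beads the order parameter is

$$S = \frac{3\langle\cos^2\theta_z\rangle - 1}{2},$$

with $\theta_z$ the angle between the bond and the bilayer normal.  A
lipid's value is the mean over the bonds of both chains; glycerol-linker
bonds are excluded (this is switchable only by editing the chain
definition in the species registry, which is deliberate: the chain list is
the single source of truth).  For sterols the axis through ring beads 3
and 5 replaces the chain bonds.  The range is $[-0.5, 1]$: 1 for bonds
parallel to the normal, 0 at the magic angle, $-0.5$ for in-plane bonds.
Gel-like states sit near 0.9, fluid disordered chains near 0.2–0.35.

## Synthetic bilayer generator

The generator is phenomenological.  It does **not** integrate a force
field; it constructs configurations whose statistics match a requested
state, which is exactly what the observables need and what keeps every
test independent of MD.

* **Composition.** The default is the reference system: 510 DPPC, 810
  DUPC, 238 CHOL (mole fractions 0.34:0.51:0.15) in a 20 nm box at a
  nominal 295 K, half per leaflet.  Each leaflet is a square lattice with
  one molecule per site; the per-site area follows from box and counts
  (0.51 nm² for the default, matching the reference density).  The
  construction refuses packings below 0.32 nm² per molecule.  Nominal
  areas per molecule (0.64 nm² lipid, 0.32 nm² sterol) are used to match
  leaflet areas when one leaflet is replaced by pure DUPC
  (`asymmetric = TRUE`).
* **Layouts.** `mixed` assigns species to sites at random; `separated`
  and `gel` place the saturated lipid and sterols in one contiguous
  stripe (default; a stripe minimises interface length in a periodic
  square) or disc per leaflet.  Within the ordered domain the species are
  interleaved deterministically so that congruent stripes in the two
  leaflets carry identical per-cell densities.  The registration target
  r in [-1, 1] maps to a lower-leaflet stripe offset of
  (1 - r)/4 of the box: 0 offset for registered domains, a quarter box
  for r = 0, half a box (anti-registered) for r = -1.
* **Order realisation.** Chain bond vectors use the deterministic polar
  angle with $\cos^2\theta^* = (2S+1)/3$ and random azimuth, so the
  measured order parameter equals the target exactly, not just in
  expectation.  Within a chain the azimuths alternate by $\pi$, which
  keeps the chain laterally within half a bond length of its site and
  avoids spurious hard-core contacts between neighbours.
* **z placement.** Heads sit at 2.0 nm (lipids) / 1.4 nm (sterols) above
  the midplane by default; terminal tail beads at half the requested
  interdigitation gap (default +0.4 nm gap for separated states, -0.1 nm
  — interdigitated — for mixed, +0.7 nm for gel, following the reported
  tail separations; the `DPPC_3b` mimic's short tails sit 0.4 nm further
  out).  The gap convention is signed: negative means the leaflets'
  tails overlap in z.
* **Dynamics.** Rigid per-molecule 2D Brownian displacements with
  per-species/per-phase D, accumulated in unwrapped coordinates and
  wrapped into the box.  Defaults (0.1 nm²/ns, 1 ns frame spacing) are
  free parameters of the generator — frame rates and per-phase diffusion
  constants are not reported quantities, so these values are package
  conventions, not literature values.  `gelArrest` freezes ordered-domain
  molecules, reproducing the MSD plateau signature of a gel.
* **Scenarios.** `generateTimecourse()` interpolates linearly between a
  start and end state (mixed→separated, separated→mixed, mixed→gel) with
  chains resampled each frame at the interpolated order target, making
  the pipeline's order, correlation and energy trends monotone by
  construction.

What the generator does **not** emulate: energetic relaxation (lattice
frames at the full reference density contain hard-core contacts, so pair
*energies* are only meaningful at per-molecule areas of about 0.64 nm² or
more — use a larger box or fewer molecules when the energy observable is
the target), chain torsion dynamics, flip-flop, thermostats, or any
force-driven demixing.  Passing tests therefore validate the analysis
chain and its bookkeeping, not MD thermodynamics.

## Observables: numerical choices

* **Grids.** The cell count per axis is `round(box/cellSize)` (nominal
  1.5 nm for correlation grids, 3.0 nm for center maps) and the actual
  cell edge is rescaled to tile the periodic box exactly.  Density counts
  one head bead per molecule, wrapped before binning, so cells sum to the
  leaflet count identically.
* **Interleaflet correlation** is Pearson's r on raw per-cell counts, no
  smoothing, empty cells included; constant fields return a flagged `NA`
  rather than a crash.
* **Bilayer-center maps** average tail-bead z of both leaflets per cell;
  the short-tailed `DPPC_3b` is excluded by default because its tails
  would drag the center toward its own domain.  Cells without tail beads
  are filled by iterative periodic neighbour averaging and flagged.
* **Umbrella coverage.** Squares are axis-aligned and *centered* on the
  sterol head's x/y (the centered reading of the coverage criterion;
  side 0.25 nm for one lipid, 0.47 nm for two), "above" means strictly
  toward the water phase of the sterol's own leaflet with no upper
  z-limit, and lateral offsets are minimum-image.  Centering versus
  cornering of the square is an open convention; the centered choice is
  symmetric and is the one implemented and tested.
* **Pair energies.** Shifted Lennard-Jones (shift onset 0.9 nm) and
  shifted Coulomb (onset 0, relative permittivity 15) with a 1.2 nm
  cutoff; the shift polynomial coefficients solve the smoothness
  conditions F(rc) = 0, F'(rc) = 0 per inverse-power term, and the unit
  tests verify the closed form against numerical integration of the
  shifted force.  Interactions are intermolecular only, minimum-image in
  x/y, open in z; bookkeeping is per unordered species pair, normalised
  by the molecule count of the pair's first species.  The cell-list
  search is bit-equivalent to the brute-force double loop (tested to
  1e-10 on 200-molecule frames).  Permittivity and shift radii are CG
  conventions taken as external defaults.
* **MSD** uses multiple evenly spaced time origins, lateral (x/y)
  displacements from unwrapped coordinates, a log-log slope fit over lags
  up to 20 ns (the onset of the diffusive regime) and D from a
  through-origin linear fit of MSD = 4Dt.  Re-wrapped coordinates are
  detected (jumps above half a box) and rejected with an instruction to
  unwrap.  A terminal log-log slope below 0.2 — or an identically zero
  MSD — flags arrest.
* **RMSD** uses no rotational superposition (the bilayer normal fixes the
  frame); optional removal of the lateral center-of-mass drift only.
* **Energy gains** are differences to the energy at 1 ns (nearest frame
  if off-grid, recorded in an attribute), the time by which construction
  transients are taken to have decayed.

## Phase classification

No numeric thresholds for the phase boundaries exist as measured
constants: gel order is "around 0.9" and the Lo/Ld boundary is not
quantified.  `classifyPhase()` therefore uses configurable conventions,
defaulting to S >= 0.8 *plus* an MSD plateau for gel, S >= 0.45 for Lo,
Ld otherwise, and a largest-domain fraction of 0.5 for calling a field
separated; the thresholds used are echoed in the output.  Only a single
gel label is exposed — the sub-gel/gel distinction is not operationalised
anywhere and is deliberately out of scope.  Classification is monotone in
S: raising order with fixed mobility evidence never demotes a call.

## Problem sizes and determinism

Unit and acceptance tests run on reduced systems — typically 60–200
molecules in 6–11 nm boxes, trajectories of 50–1000 frames — chosen so
the full suite completes in well under ten minutes on one CPU while
keeping every statistical check comfortably powered (the diffusion
recovery test, for instance, uses 1000 frames where the 10 % tolerance
has a wide margin).  Every stochastic element takes an explicit seed:
identical seeds give bit-identical frames and trajectories, and the seeds
used by tests are fixed in the test sources.

## Known limitations

* The generator's energies are structural, not thermal: absolute energy
  scales (and therefore the reference enthalpy gains of the original MD
  study) are outside what a lattice construction can reproduce; only
  signs and trends of energy differences are meaningful here.
* Head/linker nonbonded entries and sterol ring bond geometry are
  registry defaults (see above), adequate for bookkeeping and geometry
  but not authoritative.
* GRO files store species names truncated to five characters; the long
  variant names (`DPPC_soft`, `DPPC_3b_plus1`) survive a round trip only
  through the registry mapping, and two species whose first five
  alphanumeric characters collide cannot share a file.
* Leaflet assignment is static per frame; molecules crossing the midplane
  (flip-flop) are not tracked, matching the generator, which never moves
  molecules between leaflets.
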