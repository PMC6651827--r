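---
title: "Energy-based hydrogen-bond and water-bridge analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-based hydrogen-bond and water-bridge analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wbridge)
```

## Scope

`wbridge` post-processes molecular-dynamics trajectories of systems with two
named solute species in explicit water — typically a glycosaminoglycan
chain and a set of phospholipid headgroups. It answers four questions per
trajectory: which donor–acceptor hydrogen bonds form between the solutes,
which waters bridge both solutes simultaneously, how long each unique pair
persists, and how the solvent-accessible surface of each solute evolves.
Running the simulations themselves is out of scope; the package consumes
their output frames as multi-model PDB, one `MODEL` block per snapshot.

## The hydrogen-bond energy model

A candidate contact is a donor heavy atom D with a covalently bound
hydrogen H, and an acceptor heavy atom A. Its energy is

$$E = E_\mathrm{opt}\,
      \frac{d_0 - \max(d_\mathrm{HA}, d_c)}{d_0 - d_c}\,
      S_\mathrm{DHA}\, S_\mathrm{HAX},$$

with defaults $E_\mathrm{opt} = 25$ kJ/mol, clamp $d_c = 2.1$ Å and zero
distance $d_0 = 2.6$ Å. The clamp means any hydrogen–acceptor approach at
or below 2.1 Å scores the full distance term — closer is not better — and
the term falls linearly to zero at 2.6 Å, which doubles as the spatial
prefilter radius for candidate enumeration.

Both angular factors are piecewise linear, 0 below their lower breakpoint,
1 above the upper:

* $S_\mathrm{DHA}$, on the donor–hydrogen–acceptor angle, ramps over
  100°–165°.
* $S_\mathrm{HAX}$, on the hydrogen–acceptor–X angle, where X is an atom
  covalently bound to the acceptor, ramps over 85°–95° when X is heavy and
  75°–85° when X is a hydrogen (slightly smaller angles are allowed for a
  hydrogen X).

A bond is reported when $E$ strictly exceeds the threshold, 6.25 kJ/mol —
one quarter of the optimum. Equality is not reported; the criterion is a
strict inequality.

### The X rule

When an acceptor has several covalent partners, the partner giving the
*smallest* $S_\mathrm{HAX}$ is used and recorded as `chosen_X`. We read the
one-bond-per-acceptor phrasing found in some H-bond definitions as this
per-partner minimization rather than as discarding all but one bond per
acceptor: contact maps of real systems routinely show one acceptor engaged
by several donors, which a literal single-bond rule could not produce. For
users who want the literal reading, `detect_hbonds(one_per_acceptor = TRUE)`
keeps, per acceptor, only the contact with the smallest scaling factor. An
acceptor with no covalent partner at all (a bare ion) scores
$S_\mathrm{HAX} = 1$; ions are excluded from the analysis groups by default
anyway.

Intramolecular bonds are computed like any others; the headline statistics
restrict to intergroup pairs through the group filter, in either direction
by default.

## Molecular model

The atom table, covalent adjacency and group partition
(`solute_A` / `solute_B` / `water` / `other`) are frame-invariant. Indices
are 1-based throughout, the natural R convention; PDB serial numbers are
preserved for reporting. Waters are recognized by residue name
(`HOH`/`WAT`/`SOL`/`TIP3` plus configurable aliases) and must be three-atom
O/H/H residues; a matching name with any other composition is left outside
the water group with a warning. Water is treated as a 3-site model — three
atoms per residue — regardless of how the generating force field counted
interaction sites. Monatomic ions land in `other` and take no part in
bond detection.

Covalent bonds come from `CONECT` records when present; otherwise they are
inferred from frame-1 geometry: a pair is bonded when its distance is at
most the sum of covalent radii times 1.15. Each hydrogen keeps exactly one
partner (the nearest); a stranded hydrogen triggers a warning and never
acts as a donor. Donors are (polar heavy, H) covalent pairs and acceptors
are polar heavy atoms, with the polar-element set defaulting to
{N, O, S} — sulfur included because sulfate-bearing glycosaminoglycans
carry acceptor-capable SO₄ groups.

Angles are computed in the `atan2(|u × v|, u·v)` form rather than via
`acos`: near 0° and 180° the `acos` form loses about a microdegree, which
matters when probe geometries must be recovered to 1e-6.

## Water bridges, maps, durations

A water residue is a *bridge* in a frame when it holds at least one
above-threshold bond to `solute_A` and at least one to `solute_B` in that
frame, in either role — the water may donate or accept on each side; a
per-role breakdown is reported for transparency. Bridges through chains of
two or more waters are out of scope. For mapping, each bridge contributes
the (A atom, B atom) heavy-atom pairs it joins; two waters spanning the
same pair in one frame are two bridges but one mapped pair.

Contact maps count, per unique (A-side heavy atom, B-side heavy atom) pair,
the frames in which the pair is present — a pair seen twice in one frame
counts once — and report percentages of the total pair–frame incidences,
which sum to 100 when any bond exists. Pair identity uses heavy atoms
(donor heavy, acceptor), matching how interaction-map figures number
oxygens and nitrogens rather than hydrogens.

Durations use the occupancy estimator: presence-frame count × snapshot
interval. This is the primary statistic; the longest contiguous run is
reported alongside as a labeled extra and never substituted. The snapshot
interval is a required configuration value — the PDB dialect carries no
time stamps, and silently assuming one would scale every duration — and
frames must be uniformly spaced (non-uniform times produce an error asking
for resampling). No kinetic (autocorrelation-based) lifetime model is
attempted.

## Solvent-accessible surface

The solvent-accessible surface is the area traced by the center of a
spherical probe — the water oxygen, radius 1.4 Å — rolling over the van der
Waals surface of the selection. We use the Shrake–Rupley construction:
each atom's expanded sphere (Bondi radius + probe) is sampled at
`n_sphere_points` (default 960) points of a deterministic golden-angle
spiral, a point is accessible when outside every other selected atom's
expanded sphere, and the area is the accessible fraction times the expanded
sphere area, summed over atoms. The spiral is a fixed point set, not a
random sample: results are reproducible without seeds, and two runs of the
same input are bit-identical.

Resolution governs two error terms. Against the closed-form sphere area a
single atom is within 1% at 960 points and halving error further under
point doubling (< 0.5%). Orientation of the spiral relative to the
molecule introduces a lattice effect under rigid rotation of roughly 0.5%
at 960 points for a ~10-atom selection, dropping to below 0.1% at 1920
points; users comparing SAS across differently oriented frames at the
sub-percent level should raise `n_sphere_points`. The Bondi radius table
ships as plain text (`inst/extdata/bondi_radii.txt`) and can be replaced
wholesale through `sas_params(radii = ...)`. The default selection for the
reported time series is each solute group alone — waters and ions excluded,
as the probe is the water. Analytic (LCPO/power-diagram) surfaces and
per-residue decompositions are not implemented; per-atom accessible
fractions are exposed for inspection.

## The synthetic-fixture generator

The generator stands in for production trajectories (hundreds of thousands
of atoms, tens of ns) with desk-scale systems whose ground truth is planted
and recorded in a manifest. Scenarios compose small chemical mimics:
hydroxyl donors and carbonyl-type acceptors on the GAG-like chain A,
phosphoryl acceptors and either ethanolamine-like (N–H donors) or
choline-like (no polar hydrogen) headgroups on the lipid-like chain B,
waters placed to realize bridges, and always-present decoys — nonpolar
carbons, isolated waters, an Na/Cl ion pair — that must not register in any
statistic. The ethanolamine/choline twin scenarios share identical
placement, so the count of distinct bonded sites isolates the presence of
N–H donors; at fixture scale the donor-bearing mimic binds strictly more
sites than the donor-free one.

Planted contacts are constructed at exact requested geometry
(`make_geometry_probe_system()` does the same for a lone 4-atom probe and
verifies realization to 1e-6 by recomputation). Coordinates are snapped to
the 0.001 Å grid of the PDB coordinate field, and frames differ by seeded
whole-system translations on that grid: translations preserve every
internal distance and angle exactly, so planted energies hold to 1e-6
kJ/mol through file round trips, frame by frame. Manifests record both the
analytic energy of the requested geometry and the energy realized on the
coordinate grid (they differ by at most a few hundredths of kJ/mol).
Rotation invariance of the scoring function is a property of the detector
and is exercised separately on in-memory geometry, where no print precision
intervenes. Kinetic fixtures toggle pairs off by displacing the acceptor
unit 10 Å before the frame translation, so the off geometry is identical
for every seed.

What the fixtures deliberately do not emulate: force-field energetics,
realistic conformational sampling, solvent crowding, periodic boundaries,
or production concentrations and box sizes. Passing the fixture suite
therefore demonstrates correctness of the detection and aggregation
machinery — not that any particular biological system behaves as the
fixtures do.

## Numerical and design choices

* Threshold comparison is strict (`>`); the 2.6 Å prefilter is purely an
  optimization, and detection on any small system is verified against an
  exhaustive no-prefilter scorer in the test-suite.
* Ties in the X choice (equal scaling factors) resolve to the
  lowest-index partner; detection output is sorted by donor, hydrogen,
  acceptor, so tables are deterministic.
* Covalent-inference tolerance is 0.15 (15% over the radius sum);
  `CONECT` records, when present, override inference entirely, since
  shipped fixtures carry none.
* CSVs are comma-separated, "." decimal, header row, LF endings, written
  atomically (temp file + rename); reruns of the same config and input are
  byte-identical. `run_metadata.json` echoes the full effective
  configuration — there are no unrecorded hidden defaults — plus versions,
  frame count and wall time.
* Degraded mode: water aliases matching nothing disable bridge analysis
  with a warning while direct-bond outputs are produced unchanged; empty
  selections fail before any computation.

## Problem sizes

The shipped validation uses fixture systems of roughly 20–30 atoms over
3–5 frames, randomized oracle-equivalence systems of up to 50 atoms
(200 of them), a 0.01° grid for the scaling-factor properties, and
960–3840 sphere points for the SAS checks. These sizes were chosen so the
entire suite exercises every code path in under a minute per module while
leaving the statistics exact rather than sampled.

## Known limitations

* Only single-water bridges are identified; water-chain bridging of order
  two or more is not.
* The PDB dialect is the only trajectory format; 3-decimal coordinate
  precision bounds how faithfully external geometry survives a round trip.
* SAS absolute values depend on the radius set and probe radius; comparing
  against surfaces computed elsewhere requires matching both.
* The duration estimator is occupancy-based and does not distinguish one
  long residence from many short recurrences except through the separately
  reported longest run.
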