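---
title: "Actin–cofilactin boundary models: construction, observables and the synthetic ensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Actin–cofilactin boundary models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cofilactin)
```

## The problem

Cofilin severs actin filaments at the boundaries between bare and
cofilin-decorated (cofilactin) segments, and the two boundaries of a bound
cluster are asymmetric: severing is fast on the pointed-end side and slow
on the barbed-end side. Structurally, decoration shortens the helical
repeat by roughly 5° per subunit and tilts ("untwists") the outer domain of
each actin subunit. Characterising a boundary therefore means building a
joined bare/decorated filament model and tracking, subunit by subunit, how
twist, internal conformation and inter-subunit contacts cross over from one
state to the other.

This package implements that pipeline at the C-alpha level: the
construction operations (superposition, splicing, replication, ablation),
the per-subunit observables, the sigmoid crossover model, and a synthetic
filament generator that stands in for molecular-dynamics ensembles so that
every estimator can be validated against known ground truth.

## Conventions

* **Indexing.** Subunit positions follow the genetic helix and increase
  toward the pointed end; consecutive indices alternate protofilaments, so
  longitudinal (same-strand) neighbors are n ± 2 and lateral neighbors
  n ± 1. Boundary models are labelled −8..9 with interfacial index i = 0.
  "Barbed side" always means lower indices.
* **Units.** Ångström internally; the 1 nm contact criterion is stored as
  10 Å. Angles in degrees.
* **Occupancy.** A cofilin bridges the longitudinal pair (k, k+2) and is
  keyed by its barbed-side actin k. In a periodic repeat the pointed-most
  cofilin may bridge into the next periodic image ("dangling"); strict
  pair existence is enforced for non-periodic systems. This bookkeeping is
  what makes an 11-subunit fully decorated repeat carry 10 cofilins and
  yield exactly 20 of them in the 22-subunit filament produced by one
  longitudinal replication.

## Construction operations

**Superposition** is the standard Kabsch/SVD least-squares fit returning a
proper rotation, translation and post-fit RMSD. It is cross-checked in the
test suite against an independently implemented quaternion (Horn) solution
to 1e-8 Å.

**Slow-boundary splicing** aligns decorated subunit i onto bare subunit i
by full-subunit C-alpha superposition and keeps bare i−8..i−1 plus
decorated i..i+9; the interfacial actin therefore starts in the decorated
conformation. **Fast-boundary splicing** pools the inner-subdomain
(SD3+SD4) C-alpha of four subunits spanning i..i+3 from each input into a
single rigid fit, then keeps decorated i−8..i+1 and bare i+2..i+9. Pooling
the four subunits into one superposition (rather than averaging
per-subunit transforms) is the simplest single rigid fit and is the
package's own choice. In both modes a cofilin is retained only when both
of its bridged actins lie inside the kept decorated segment, which yields
8 cofilins for a 10-subunit decorated span and leaves each interfacial
subunit touching exactly one cofilin. Fast-mode output is flagged
`requires_relaxation`: by construction it starts with essentially no
D-loop contact across the new interface, and restoring those contacts is a
simulation-time operation outside this package's scope. The discarded
alternative fast construction (interfacial subunit starting actin-like) is
kept available as `mode = "fast_alt"` for completeness.

**Replication** derives the subunit-to-subunit step transform from the
filament itself, verifies every adjacent pair is related by that same
transform (junction periodicity tolerance 0.5 Å RMSD, configurable), and
appends transformed copies at the pointed end, shifting occupancy keys by
the repeat length. Because the appended copy is generated by the composed
step transform, the cross-junction twist equals the interior twist exactly
for ideal inputs.

**Ablation** deletes cofilin records while leaving actin coordinates
bitwise untouched. Cluster layouts are expressed as keep-sets: {k, k+2} is
a longitudinal pair, {k, k+1} a lateral pair; `cofilin_clusters()` groups
keys whose spacing is ≤ 2 into contiguous clusters.

## Observables

* **Twist.** For each adjacent pair (n, n+1) the SD3+SD4 C-alpha sets are
  superposed and the rotation angle of the relative screw transform,
  θ = arccos((tr R − 1)/2) ∈ (0, 180], is stored at position n. The inner
  subdomains are used as the rigid core because they form the
  longitudinally contacting column and are the alignment set used in
  fast-boundary construction. Angles are reported as magnitudes; an
  azimuthal-projection alternative (`method = "azimuth"`) is provided for
  sensitivity checks but is approximate, since it must fit the filament
  axis from the finite set of subunit centers.
* **Flatness and cleft.** φ is the signed IUPAC dihedral of the four
  subdomain centers of mass ordered (SD2, SD1, SD3, SD4) — a torsion of
  the outer domain (SD1+SD2) about the SD1–SD3 axis relative to the inner
  domain — and d = |COM(SD2) − COM(SD4)|, the nucleotide-cleft span. The
  COM ordering and the cleft pair are package conventions (the observable
  definitions leave them open); both the generator and the analyzer share
  them, so round-trip tests are convention-independent. Mirror imaging
  negates φ and preserves d.
* **Contacts.** Counts of C-alpha pairs strictly closer than the cutoff
  (ties at exactly 10 Å are excluded). The D-loop profile counts D-loop
  (44–52) atoms of subunit n against the *entire* C-alpha set of subunit
  n+2; a restricted target-cleft variant is available through
  `contact_spec()`. Subdomain residue ranges default to the canonical
  four-subdomain partition (SD1 = 1–32, 70–137, 338–375; SD2 = 33–69;
  SD3 = 138–180, 270–337; SD4 = 181–269) and are fully configurable,
  because published subdomain definitions differ at boundary residues.
* **Interface integrity.** All-versus-all contacts per longitudinal pair
  (n, n+2); zero contacts flags a ruptured protofilament interface.
* **RMSD.** Pooled selection C-alpha, superposed per frame onto the
  reference before measuring.
* **Statistics.** Per-position means and *population* SDs over a trailing
  frame window (`last_k`, default half the frames), mirroring how
  equilibrium-window statistics are quoted for trajectory observables.

## The transition model

Angle profiles across a boundary are summarised by

θ(n) = A₂ − (A₂ − A₁) / (1 + exp((n − n₀)/N)),

where A₁ and A₂ are the barbed- and pointed-side asymptotes, n₀ the
crossover center and N the crossover length in subunits. The printed form
of this model is typeset ambiguously in the literature; this reading is
the unique one for which A₁ and A₂ are the two limits of the function.
Fitting uses bounded Levenberg–Marquardt (`minpack.lm::nlsLM`) on
per-position means — profiles are summarised before fitting because the
crossover is a property of the mean profile — with initial values taken
from the three outermost positions on each side and the interpolated
midpoint crossing, and N bounded below at 0.05 subunits to keep the model
identifiable on integer position grids. A profile whose initial asymptote
estimates differ by less than 0.5° is rejected as "no transition
detected" rather than fitted. Inverse-variance weighting by the
per-position frame scatter is optional and off by default.

## The synthetic generator

The generator replaces MD trajectories for all testing. A subunit template
is four compact Gaussian subdomain clusters whose centers of mass realise
prescribed (φ, d) exactly: SD1, SD3 and SD4 anchors are fixed, SD2 is
placed in the half-plane rotated by φ about the SD1–SD3 axis, and its
radial offset is solved in closed form so that |COM(SD2) − COM(SD4)| = d
(geometrically unreachable combinations raise a generation error). D-loop
residues ride on SD2 either *extended* toward the pointed end — producing
strictly positive, position-uniform longitudinal D-loop contacts in an
ideal filament — or *retracted* into the SD2 body, producing zero. A
filament applies per-step rotations (possibly position-dependent, e.g. a
sigmoid twist profile) plus a 27.5 Å rise about the +z axis; cofilin
placeholders (compact ~150-point balls of radius 12 Å) are centered
between SD2 of the barbed-side and SD1 of the pointed-side bridged actin.
Frames add i.i.d. Gaussian coordinate noise from a seeded stream, so
identical inputs and seed reproduce outputs bitwise.

Default study conditions: bare filaments use twist 167°, φ = −9°,
d = 25 Å, extended D-loops; decorated filaments use twist 162°,
φ = −28.9°, d = 24 Å, retracted D-loops. Twist values are the cryo-EM
helical symmetries of the two states; the φ defaults are the two
asymptotes of the slow-boundary flatness transition; the rise is the
canonical actin value. Cleft distances are not constrained by published
numbers at this coarse level; 25/24 Å are representative subdomain-COM
separations chosen once and kept configurable.

What the generator does *not* emulate: real protein shapes and sequence,
force fields, hinge-like bending, rupture kinetics, or correlated thermal
motion (noise is i.i.d. per coordinate). Passing round-trip tests
therefore demonstrates estimator correctness — that prescribed geometry is
recovered exactly and that statistics behave as designed — not that the
estimators have been validated against experimental filament ensembles.

## Numerical choices and degenerate inputs

* Superposition requires ≥ 3 non-collinear points; degenerate sets raise a
  numerical error rather than returning an arbitrary frame.
* Twist angles are magnitudes in (0, 180]; the arccos argument is clamped
  to [−1, 1] against rounding.
* Contact counting uses strict inequality at the cutoff.
* Replication tolerance 0.5 Å RMSD; splicing requires ≥ 10 subunits per
  input (≥ 12 decorated for fast mode).
* PDB output is fixed-width, C-alpha only, occupancy 1.00, B-factor 0.00,
  one chain per subunit (A–Z, a–z, 0–9; > 62 chains is an error
  instructing split output), frames as MODEL/ENDMDL. Reading accepts an
  explicit chain map or classifies chains automatically (≥ 300 residues
  actin, < 200 cofilin) with positions assigned by axis projection and
  cofilin keys by nearest bridging midpoint.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic
filaments of 2–22 subunits, profiles of 18 positions, and ensembles of up
to 200 frames for noisy-recovery checks (2000 frames for the scalar
noise-calibration check), sizes chosen so the full suite completes in
seconds while still exercising every code path at the fidelity the
round-trip tolerances (1e-6° on ideal geometry, 1e-8 Å against the
superposition oracle) require.

## Known limitations

* C-alpha only; no side chains, nucleotide or sequence identity.
* The twist estimator reports unsigned magnitudes, so it cannot
  distinguish over- from under-twisting relative to the helical hand.
* The splice junction joins two independently generated template
  instances, so the junction pair's twist reflects the conformational
  discontinuity rather than a calibrated intermediate; boundary-shaped
  profiles for fitter validation should be generated directly with a
  position-dependent twist vector.
* Fast-mode models are returned un-relaxed; downstream refinement is out
  of scope.
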