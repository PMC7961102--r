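# cofilactin

Tools for building and analysing coarse structural models of
**actin–cofilactin severing boundaries**.

Cofilin binds actin filaments between longitudinally adjacent subunits,
shortens the helical repeat (per-subunit twist ~167° bare → ~162°
decorated), tilts the outer domain of each subunit, and severs filaments at
the boundaries between bare and decorated segments. The two boundaries of a
cofilin cluster are not equivalent: the pointed-end side severs fast, the
barbed-end side slowly. `cofilactin` implements, at the C-alpha level, the
model-construction and geometry-analysis pipeline used to study these
boundaries:

- **Construction** — rigid-body (Kabsch) superposition; splicing a bare and
  a decorated filament into an 18-subunit slow- or fast-severing boundary
  model carrying 8 cofilins; longitudinal replication of a periodic repeat
  (an 11-subunit, 10-cofilin cofilactin repeat becomes a 22-subunit,
  20-cofilin filament); computational cofilin *ablation* to carve out
  clusters of n = 1, 2, 3 bound cofilins.
- **Geometry** — per-subunit-pair helical twist (rotation angle of the
  relative screw transform over the inner SD3+SD4 core,
  θ = arccos((tr R − 1)/2)); subunit *flatness*
  φ = dihedral(COM SD2, COM SD1, COM SD3, COM SD4) and cleft distance
  d = |COM SD2 − COM SD4|; C-alpha contact counts below 1 nm (D-loop,
  residues 44–52, against the pointed-end longitudinal neighbor);
  interface-integrity rupture flags; RMSD series against a reference.
- **Transition model** — the sigmoid crossover
  θ(n) = A₂ − (A₂ − A₁) / (1 + exp((n − n₀)/N)),
  with barbed-side asymptote A₁, pointed-side asymptote A₂, crossover
  center n₀ and crossover length N (subunits), fitted to per-position
  profiles by bounded Levenberg–Marquardt.
- **Synthetic data** — a seeded generator producing ideal or noisy
  filaments with prescribed twist/rise, per-subunit φ and d, D-loop
  extension state and cofilin occupancy, emulating the statistical
  structure of an MD ensemble so every estimator can be validated by round
  trip.

Filaments are read and written as standard (multi-model) PDB files, one
chain per subunit.

It is intended for structural biophysicists who want a lightweight,
scriptable way to build boundary geometries, prototype severing-related
observables, or generate calibrated synthetic ensembles for testing
analysis code.

## Worked example

```r
library(cofilactin)

bare <- make_bare_filament(18)            # 167 deg/subunit, extended D-loops
cof  <- make_cofilactin_filament(12)      # 162 deg/subunit, 11 cofilins
b <- splice_boundary(bare, cof, mode = "slow")
b
#> <filament_system> 18 actin subunits (positions -8..9), 8 cofilins, 1 frame(s)
#>   interfacial index i = 0

tw <- twist_profile(b)
per_position_stats(tw, last_k = 1)[c(1:3, 8:11), ]
#>    position_n     mean sd
#> 1          -8 167.0000  0
#> 2          -7 167.0000  0
#> 3          -6 167.0000  0
#> 8          -1 102.2373  0
#> 9           0 162.0000  0
#> 10          1 162.0000  0
#> 11          2 162.0000  0
```

The bare segment (positions −8..−2) sits at its generating twist of 167°,
the decorated segment (0..8) at 162°; the pair spanning the splice junction
(−1) joins two template instances with different internal conformations and
reflects the structural discontinuity at the boundary. Fitting the
transition model to a profile generated from known parameters recovers them
to optimizer precision:

```r
fit <- fit_transition(make_angle_profile(
  transition_params(165.1, 155.1, 1.4, 1.1), -8:9))
fit
#> <transition_params> A1 = 165.100, A2 = 155.100, n0 = 1.400, N = 1.100
#>   rss = 1.616e-27, converged = TRUE
```

A command-line front end over the same functions lives at
`inst/cli/cofilactin-tools.R`:

```sh
Rscript inst/cli/cofilactin-tools.R synth --out out/ --kind boundary --seed 7
Rscript inst/cli/cofilactin-tools.R analyze --input out/filament.pdb --out out/an
Rscript inst/cli/cofilactin-tools.R fit --input out/an/twist.csv --out out/fit
```

See `vignettes/boundary-models.Rmd` for the full account of the model,
estimator conventions and generator design.

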