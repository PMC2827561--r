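---
title: "Building paracrystalline actin bundle models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building paracrystalline actin bundle models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paracryst)
```

## The model

The core bundle of an intestinal microvillus is a paracrystal: ~19 actin
filaments with 13/6 helical symmetry (rise 27.57 Å, twist −166.154° per
monomer; 13 monomers complete 6 turns of the short-pitch helix) packed on a
hexagonal lattice with 12.0 nm center-to-center spacing, all filaments
unipolar and in axial register. Because every filament is generated by the
same screw operator and the filaments are related by pure in-plane
translations, the pose of any bound protein needs to be defined only once,
against a canonical monomer at the origin; symmetry propagation
(`propagate_pose()`) then positions every copy. That single idea — bundle
building as group action — is what this package implements, together with
the selection rules that make the decoration unique and the arithmetic
self-checks that the resulting model must satisfy.

### Why the cross-linker geometry is constrained

An axially registered 13/6 filament presents 13 azimuthal site
orientations per repeat, uniformly spaced 180°/13 = 13.85° apart when axes
are reduced modulo 180° (cross-link axes are undirected). A hexagonal
lattice demands bonds at 0°, 60° and 120°. Two consequences, both computed
by `hexagonal_mismatch()`:

* **Required flexibility (~±7°).** The azimuthal phase between a
  cross-linker's binding orientation and the lattice bond axes is fixed by
  binding chemistry, not adjustable, so the honest bound is the worst case
  over that phase: half the widest gap between achievable axes, 6.92° for
  13/6. At zero phase the three bond classes need only {0, 4.62, 4.62}°
  (reported as `class_deviation`). We deliberately report the phase-free
  worst case as `max_deviation`: a flexibility budget must cover the
  geometry wherever the binding site happens to point. Note this
  definition gives 30° for an ideal 6/1 helix — the per-class deviations
  are the quantity that vanishes there.
* **Maximum flexibility (<±14°).** Adjacent achievable axes are 13.85°
  apart. A cross-linker more flexible than that could bind the
  neighbouring orientation — in particular the reciprocal conformation in
  which its two actin-binding domains swap filaments — and the bundle
  would lose its single, unique cross-linking site per 13-monomer repeat.

### Placement rules

Cross-linkers (`place_all_crosslinkers()`) are placed one per species per
lattice edge per complete repeat. Candidates are enumerated over every
domain-to-filament assignment and monomer pair in the repeat window and
filtered by three criteria: each domain must face its partner filament
within the flexibility bound; the two domains must satisfy the spec's
linker separation limit; and every bead must project between the two
filament axes. Selection then applies the polarity rule — the rank-1
domain (fimbrin ABD1, villin V1–6) sits toward the pointed end relative to
the rank-2 domain — which eliminates the 180°-swapped reciprocal, and
breaks residual ties deterministically (lowest monomer index, then
filament index).

Myosin (`place_myosin()`) decorates only outer-ring filaments, facing
radially outward so its tail can reach the membrane. Per repeat per outer
filament the two clash-free sites of highest radial extension are kept;
their facing deviations are δ and 27.69° − δ, so a lever tolerance of
~±28° admits exactly two. Because the site lattice advances 27.69° per
long-pitch monomer while adjacent outer filaments are 30° apart, the
motors trace helical strands that climb one long-pitch monomer (55.1 Å)
per filament step — with one compulsory double step per circuit, since 13
long-pitch steps, not 12, span 360°. That residue is exactly the "third
myosin per turn"; we assign it, by convention, to the outer filament at
the turn's starting azimuth (the lowest-azimuth outer filament), on every
even-numbered repeat (one turn = two repeats for 13/6). The decoration's
strand count, pitch and handedness are recovered from the placed anchors
by `barber_pole_parameters()`: a right-handed double helix with the
long-pitch period of 26 monomers (717 Å).

## Surrogate component geometry

The EM-derived cross-link coordinates this class of model was originally
fitted against are not publicly deposited, so the package ships
parameterized surrogate components (`surrogate_spec()`, `make_fixture()`)
that encode only placement-relevant topology: fimbrin as two actin-binding
domain beads 40 Å off their filament axes plus a two-bead core; villin as
a six-bead V1–6 arc and a single headpiece bead joined by a ≤40 Å linker;
myosin as a motor bead with a three-segment neck at the 80° rigor lever
angle reaching 175 Å radially, carrying three calmodulin frames. Binding
azimuths are phased so that each bond direction class is served by one
unique monomer per repeat and the two cross-linker species land on
different monomers of every edge (fimbrin ABD1 on repeat levels 1/5/9 for
classes d/e/f, villin V1–6 on 10/1/5) — the vertical staggering that keeps
the saturated model clash-free. All of this is tunable through
`component_spec()` and YAML/JSON spec files; nothing in the placement
logic depends on the surrogate numbers.

What the surrogates do *not* emulate: atomic contact surfaces, linker
conformational ensembles, the villin headpiece–V6 secondary contact (noted
in proximity reports only), or any energetics. Tests passing on surrogate
geometry therefore validate the symmetry, selection and bookkeeping
machinery, not atomic-scale plausibility.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| rise / twist | 27.57 / −166.154 | Å, ° | 13/6 actin operator |
| lattice rings / spacing | 2 / 120 | –, Å | 19-filament bundle, 12.0 nm |
| bundle length | 1000 | nm | microvillus length (362 monomers) |
| closure tolerance | 0.01 | ° | see numerical choices |
| flexibility bound | 6.92 (derived) | ° | worst-case hexagonal mismatch |
| overlap factor | 0.9 | – | soft-core beads overestimate envelopes |
| min radial extension | 150 | Å | motor must span bundle → membrane |
| lever angle | 80 | ° | near-perpendicular rigor orientation |
| effective filament radius | 30 | Å | bundle diameter reporting |

Internally every length is Å and angles are degrees (trigonometry in
radians); scene-level reporting uses nm.

## Numerical choices

* **Closure tolerance 0.01°.** The exact 13/6 twist is −2160/13 =
  −166.153846…°; the conventional printed value −166.154° accumulates a
  0.002° residual over 13 monomers. A 10⁻⁶-degree tolerance would
  therefore classify the standard operator as non-closing. 0.01° accepts
  twists printed to three decimals while still rejecting the genuine
  0.25°/monomer symmetry departure of the isolated filament (closest
  approach 3.25° within 13 monomers), which the package represents as a
  closure-free symmetry via the twist override.
* **Repeats anchored at monomer 0.** Cross-linkers occupy complete
  13-monomer windows only; partial top/bottom repeats stay bare
  (`floor(monomers / 13)` repeats).
* **Ties.** Candidate selection orders by rank-1 monomer index then
  filament index; myosin site ranking orders by radial extension then
  monomer index. Both make rebuilds bit-identical.
* **Degenerate inputs.** Zero twist, non-positive rise, overlapping
  microvilli, sub-repeat bundles and empty models raise typed errors (or
  return empty placement sets where the spec calls for graceful skips).
* **Packing-density conventions.** The bundle is not a crystal, so the
  enclosed volume is convention-dependent. Three conventions are always
  reported side by side: per-filament hexagonal cell (closed form, upper),
  bare hexagonal hull (lower), and hull grown by a probe margin equal to
  the filament radius (default headline). The model's literature value of
  3.9 Å³/Da falls inside this bracket; we do not claim a single
  convention reproduces it, because the original convention is unstated.
* **Masses.** Actin 41.8, fimbrin 70, villin 92.5 kDa — literature values,
  echoed in every density report and configurable.

## Problem sizes

Unit tests run on a 19-filament bundle of 3 repeats (39 monomers); the
clash oracle uses a 7-filament, 2-repeat bundle where all-pairs scanning
is exact and cheap; the census check builds the full 19 × 362 default
bundle once (~9 s, ~25 000 beads). The Monte-Carlo hull oracle uses 2×10⁵
samples; the dense-grid mismatch oracle scans 0.001° steps. These sizes
make every advertised quantity recomputable on a laptop in seconds.

## Known limitations

Filaments are rigid and ideally symmetric — no thermal twist, bending or
the 0.25°/monomer relaxation inside bundles; the coarse clash model uses
a single soft-core factor rather than residue-level contacts; villin's
Ca²⁺-switchable severing, espin/ezrin, and membrane mechanics are out of
scope; scenes are exported coarse-grained only. The "third myosin per
turn" placement is a documented convention, as the source data do not
identify which filament carries it.

## A worked example

```{r example, eval = FALSE}
sym <- make_symmetry(27.57, -166.154)     # 13/6
bundle <- build_bundle(sym, hex_points(2, 120), 1000)
xl <- place_all_crosslinkers(bundle)      # 1134 fimbrin + 1134 villin
motors <- place_myosin(bundle, crosslinkers = xl)   # 661 = 648 + 13
lc <- attach_light_chains(motors)         # 1983 calmodulins
detect_clashes(list(bundle, xl, motors, lc))        # empty
barber_pole_parameters(motors)            # 2 strands, 717 Å, right-handed
stoichiometry_report(list(xl, motors, lc), bundle)
write_assembly(c(list(bundle), list(xl, motors, lc)), "assembly.cif")
```
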