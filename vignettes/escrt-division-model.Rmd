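---
title: "Modelling ESCRT-III-driven archaeal cell division: the cdvsim model and its quantification procedures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ESCRT-III-driven archaeal cell division}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdvsim)
```

## The biological problem

*Sulfolobus acidocaldarius* divides using three ESCRT-III paralogs —
CdvB, CdvB1 and CdvB2 — that assemble into a patterned composite ring at
the cell midzone and are then disassembled in sequence by the AAA-ATPase
Vps4 (CdvC). The three polymers have distinct mechanics: CdvB forms a
stiff, large ring whose preferred radius matches the predivision cell
radius (~170 nm) and acts as a non-contractile template; CdvB2 is a stiff
helical polymer with a much smaller preferred radius (~40 nm) that
accumulates in, and stabilises, thin membrane necks; CdvB1 is softer,
with an intermediate preferred radius (~65 nm) and a membrane-binding
interface tilted ~40 degrees relative to its curvature plane. Removing
CdvB releases the template and lets the two contractile polymers deform
the membrane toward their preferred curvatures, driving constriction and
ultimately scission.

`cdvsim` implements (i) a coarse-grained Langevin simulator of these
three filaments on a deformable membrane tube, with Vps4-style scheduled
species removal, (ii) the reduction of trajectories to axial
filament-density profiles, separation scores and constriction traces,
(iii) a synthetic fluorescence-microscopy generator with embedded ground
truth that emulates the experimental readouts (STED-like rings and bands
at 17-nm pixels with a ~30-nm PSF, constriction time-lapses, cells with
ring plus cytoplasmic pools), and (iv) the matching quantification
procedures (averaged line profiles, FWHM, face-on ring diameters and
channel offsets, cytoplasmic fractions, constriction-rate fits,
cumulative abscission scoring).

## The mechanical model

### Filaments

A filament is a chain of beads spaced `bead_spacing` (default 1 σ, with
σ = 10 nm) along a helix subtending `loops` full turns (default 1.05 —
one loop plus a small overlap). Its elastic energy is a discrete-rod
form measured against the species' preferred helix:

* **Stretch** — harmonic in bond length, stiffness `bond_stiffness`
  (kBT/σ²). The presets carry the published values: 250 for CdvB and
  CdvB2, 50 for CdvB1.
* **Bend** — cosine-harmonic in the angle at each bead,
  `kc/2 (cos θ − cos θ₀)²` with `kc = k_bend / sin² θ₀`, which matches a
  harmonic-in-angle stiffness `k_bend` near the rest angle while staying
  smooth at straight configurations (a plain harmonic in θ has a
  `1/sin θ` force singularity at θ = π that traps gradient descent,
  because the rest angle here is only ~14° from straight). The rest
  angle is measured off the preferred helix (for a planar ring it is the
  interior angle of the inscribed polygon).
* **Twist/tilt** — a harmonic dihedral over bead quadruples, softened by
  the smooth switch `S(x) = x/(x + 5·10⁻⁴)` on each squared bond-cross
  norm so the torsion energy turns off continuously where triples become
  collinear and the dihedral angle is undefined; plus a restoring term
  `k_twist (1 − d·e)` that holds each bead's binding director `d` near
  its rest orientation `e` in the instantaneous discrete frame. The
  torsion is what makes local curvature add up coherently into global
  curvature — without it a chain satisfies its preferred bend angles by
  writhing in three dimensions and never changes its coarse radius.

The binding director marks the membrane-binding interface. At rest it
points toward the local centre of curvature, rotated by the species tilt
about the tangent toward the local binormal ("inward tilt"); CdvB1's
preset tilt is 40°. The restoring term exerts torque on the directors
only — the positional back-reaction of the frame is neglected, which is
second-order near alignment (the term is at its minimum there); total
energies are reported exactly, and the zero-temperature relaxer descends
on the full energy with a backtracking line search, so monotone descent
holds regardless.

Bend and twist stiffnesses are not published for this model family; by
default they co-scale with the printed bond stiffness — bend is three
times the bond stiffness numerically (kBT/rad²), twist one fifth of it —
so the "flexible" species is flexible in every mode and the published
5:1 stiffness ratio between species carries over to every deformation
mode. The factor of three on the bend was calibrated once against the
membrane: the radial drive a nearly-straight filament exerts toward its
preferred curvature scales as the bend stiffness divided by the squared
tube radius, and below this scale the contractile species cannot deform
the tube on desk-scale run lengths. The preferred pitch defaults to one
bead diameter of rise per turn — an essentially planar helix; the
printed model states radii only.

A perturbed free filament relaxed at zero temperature returns to its
preferred radius:

```{r relax, eval = FALSE}
spec <- filament_preset("cdvb2")
f <- perturb_filament(build_helical_filament(spec, tube_radius = 4),
                      sd = 0.2, seed = 1)
fit_circle_radius(relax_zero_temperature(f, spec))  # 39.96 nm
```

A filament built on a tube radius far above its preferred radius (e.g. a
CdvB2 ring opened to 8 σ) is genuinely metastable — a ring must wind up
an extra turn to reach its preferred helix, and the intervening
out-of-plane excursion costs bend and twist energy — so zero-temperature
descent from the tube radius stays at the tube radius. This bistability
is physical for elastic rings; in the membrane simulations thermal noise
and adhesion let the filaments leave that state.

### Membrane

The membrane is a one-particle-thick fluid sheet: oriented particles
with an anisotropic pair potential whose radial part has a repulsive
core below `r_min` and a smooth attractive tail to `r_cut`, and whose
orientation factor favours co-planar, mutually aligned neighbours
(`membrane_params()`; ε = 4.34 kBT, μ = 3, ζ = 4, `r_min` = 1.122 σ,
`r_cut` = 2.6 σ, working temperature 1 kBT — the fluid-membrane region
of this model family). These are calibration choices, not published
values: the study inherits its membrane from cited prior work without
restating parameters.

The initial tube is tiled at a particle spacing of 0.90 σ. Two effects
set this number. First, the condensed fluid phase packs slightly denser
than the pair-minimum distance suggests, so a tube initialised at the
pair-minimum spacing slowly shrinks its radius as the in-plane density
equilibrates (the periodic box fixes the tube length, so area changes
appear as radius changes); the neutral spacing measured from a free
tube is 0.93 σ, at which an 8-σ tube holds its mean radius to ~1% over
3·10⁴ steps at 1 kBT. Second, every adhesive filament ring wraps a
strip of membrane around itself, consuming area; without a margin this
uptake thins the bare sections of a short tube into artifactual
off-site necks whose depth tracks the ring count rather than the ring
mechanics. Initialising at 0.90 σ provides roughly the area the five
rings of the pre-division pattern wrap, so the bare tube stays near its
nominal radius in the control protocol and the minimum-radius readout
reflects filament-driven constriction.

### Adhesion

Each bead attracts membrane particles within `range` (2 σ) through the
same continuous radial shape as the membrane pair potential, modulated
by a Gaussian (width 0.35 in cosine units) in `cos ψ`, where ψ is the
facing angle between the bead's binding director and the inward membrane
normal, centred on the species' target tilt. An untilted species binds
best face-on; CdvB1 binds best with its interface rotated 40° — this is
the coupling through which tilt re-orients the membrane locally (the
angular factor exerts torque on the membrane directors, which
propagates into shape through the membrane's own orientation coupling)
and produces cone-shaped necks. The default adhesion strength (12 kBT
per bead-particle contact) was chosen once so that a constricting
filament drags its membrane annulus inward rather than peeling off it:
at a few kBT the filaments tighten slightly while the tube stays
cylindrical; adhesion is indifferent to tangential sliding on the fluid
membrane, so lateral repositioning remains free at any strength. Beads
also carry a 1-σ excluded volume against each other and against the
membrane (the adhesive core provides it for adhesive species).

### Dynamics and protocols

Positions and directors follow overdamped (first-order) Langevin
dynamics with unit friction and seeded Gaussian noise; directors are
updated by projected torques and re-normalised. The default timestep is
5·10⁻⁴ reduced time units, chosen by a stability sweep against the
stiffest term (bond stiffness 250 kBT/σ²). Three robustness devices
guard the fixed-step integrator in rare stiff configurations, none of
which modifies any energy: filament bead coordinates stay continuous
across the periodic boundary (bonded terms are not minimum-imaged;
pair terms wrap internally); each dihedral quad's torsion force is
clamped at 30 kBT/σ (the softening switch has a narrow gradient spike
near collinear triples); and the deterministic drift of any particle is
capped at 0.05 σ per step, an order of magnitude above typical drifts.
A configuration plus a seed fully determines a trajectory.

`run_protocol()` integrates an assembled state and applies the event
schedule: at a scheduled step all beads of a species are removed
instantaneously — disassembly is modelled as a discrete transition, with
no kinetics, matching how the experiments read it out. The
Vps4⁻ branch is an empty schedule; the Vps4⁺ branch removes CdvB after
an equilibration phase (30% of the run by default). The exact
equilibration length and removal time are not published; both are
config values.

### Scales

The full-scale geometry (`validate_config("fig5-defaults")`) is a
17-σ (170-nm) tube carrying the printed radii verbatim. The package's
working configuration is a desk-scale replica — tube radius 8 σ, length
32 σ, ~2000 membrane particles. Its species keep the full-scale
170:65:40 preferred-radius ratios but are scaled so that the CdvB
template's preferred radius equals the filament ring radius at membrane
contact (`tube_radius − 1`): filaments sit one contact distance inside
the tube, and a template scaled to the tube radius itself would be born
pre-compressed, pushing membrane area into artifactual off-site necks
in the control branch. (This matches the model reading that the large
ring's preferred radius is the inner radius of the membrane.) The tests
run a further-reduced geometry (radius 6 σ, length 24 σ, ~1100
particles, 2·10⁴ steps per protocol) for the stochastic end-to-end
checks; these sizes are stated here as the package's own choices.
Desk-scale runs compress the separation between elastic energy scales
and thermal noise, so they reproduce directions and orderings
(constriction vs control, density-peak ordering, single-neck
preference), not the published effect sizes; that is how they are
tested.

## Trajectory reduction

* `axial_density()` histograms a species' bead z-coordinates over the
  final 20% of snapshots (the post-disassembly steady state).
  "Normalised" follows the convention of comparable peak heights — each
  profile is scaled to unit maximum; unit-integral normalisation is a
  flag. Density is per unit tube length (whether the published profiles
  are per length or per membrane area is unstated; per length is
  implemented). Replicate aggregation reports the per-bin mean and
  population SD across seeds.
* `separation_score()` rescales two profiles to unit integral and
  returns the overlap `Σ min(p_a, p_b)` — 1 for identical profiles, 0
  for disjoint ones.
* `constriction_trace()` bins membrane particles axially (one bin per
  2 σ), takes the mean radial distance per bin as r(z), and reports the
  minimum radius and the necks: local minima below 0.9 of the nominal
  radius, with distinct necks at least one tube radius apart. Both
  thresholds are config values — no published criterion exists. An empty
  axial bin is treated as membrane rupture: the trace is flagged and
  truncated.

## The synthetic-microscopy generator

The generator produces the study conditions, with ground truth attached
to every output:

* STED-like images use 17-nm pixels and a Gaussian PSF of 30-nm FWHM by
  default (the instrument's estimated resolution is measured in the same
  way the package recovers it — an FWHM — so a Gaussian surrogate is the
  natural choice).
* Face-on rings are thin annuli convolved with the PSF; the default
  two-channel geometry is a 1.21-µm inner ring with the second channel
  40 nm larger. Side-view bands are PSF-smoothed stripes. A point
  emitter renders the PSF itself.
* Time-lapses decrease the ring diameter linearly at a configured rate
  (control-like 0.11 µm/min; accelerated 0.20 µm/min), floored at zero,
  with Gaussian measurement noise (SD 0.03 µm) on the measured series —
  frame interval 15 s, matching the live-imaging cadence.
* Cell images place fraction *f* of the photon budget in a ring and the
  rest uniformly over the cell disk, and return the ground-truth masks.

Rendering conventions: every channel is normalised so its noiseless
total equals the photon budget exactly (conservation is exact by
construction); point emitters are sampled at pixel centres rather than
pixel-integrated, so a line-profile FWHM recovers the PSF FWHM to
sub-nanometre accuracy (pixel integration would broaden 29.6 nm to
~31.7 nm — the generator emulates the sampling convention under which
the instrument's resolution figure was obtained). Noise is Poisson shot
noise plus optional Gaussian read noise, both seeded and both zero-able
for deterministic tests.

What the generator does **not** emulate: depletion-laser physics and
adaptive illumination, sample drift, autofluorescent cell envelopes,
out-of-focus light, or non-circular cells. Passing closed-loop tests
therefore demonstrates that the estimators are correct and unbiased
under the stated noise model, not that they are robust to every real
imaging artefact.

## Quantification procedures

* `line_profile()` samples at exactly one-pixel steps (an odd number of
  samples centred on the anchor) and averages arithmetically across the
  profile width, bilinearly interpolating off-grid positions. Sampling
  at non-integer steps would smooth sub-pixel features and bias FWHMs.
* `fwhm()` subtracts a background (profile minimum by default; median of
  the outer samples by flag) and locates the two half-maximum crossings
  with a natural cubic spline — accurate to ~0.15 nm on a
  pixel-sampled 29.6-nm Gaussian, where linear interpolation errs by
  ~1 nm and monotone-Hermite interpolation by ~1.2 nm.
* `ring_diameter()` refines the centre as the intensity centroid,
  azimuthally averages on pixel-width annular bins, and locates the peak
  with parabolic sub-pixel interpolation. The annular binning biases
  single diameters by ~1–3 nm inward; the two-channel *offset* — the
  quantity of interest — is differenced between channels measured
  identically, cancelling most of the bias.
* `cytoplasmic_fraction()` books the ring's signal as its excess above
  the local cytoplasmic level inside a dilated ring zone, and reports
  the complement as the cytoplasmic share — so uniform cytoplasm passing
  under the ring counts as cytoplasm, and a fully ring-localised pool
  (f = 1) yields a share of ~0.
* `constriction_rate()` fits a least-squares slope inside a window
  opening at the first frame below 95% of the initial diameter and
  closing at the last frame above 0.2 µm; the published rates come
  without a stated window, so this rule is an interpretation (both
  bounds are arguments). The rate is reported as the slope magnitude.
  Mean and SD across cells come from `constriction_rate_multi()`.
* `abscission_curve()` counts the fraction of cells separated within a
  scoring window (20 min by default); censored cells count in the
  denominator.
* Band positions for side-view profiles are read by peak picking on the
  averaged profile; the published extraction method is unspecified, and
  peak picking is the simplest defensible choice.

## Design decisions made where the design was open

* **Initial CdvB2 arrangement.** The description of the favoured initial
  condition ("two CdvB1 rings placed outside of the two central CdvB2
  rings") fixes the relative order; `fig5_arrangement()` implements
  exactly that five-ring pattern (CdvB1, CdvB2, CdvB, CdvB2, CdvB1, with
  2-σ gaps), and `inverted = TRUE` swaps the contractile pair for the
  arrangement-comparison analysis. Whether CdvB2 was a single helix or
  two rings in every published run is ambiguous; both are expressible
  through the arrangement table, and the two-ring form is the default.
* **Disassembly.** Instantaneous removal of all beads of a species, no
  kinetics.
* **Replicates.** "More than 10 independent simulations" fixes no exact
  count; the replica drivers default to 10 seeds.
* **Elastic functional forms.** The published model names only radii,
  tilt and per-species bond stiffnesses; the discretisation here
  (harmonic stretch, curvature-matched cosine bend, softened dihedral,
  director restoring) is a faithful generic elastic-rod form, not a
  reproduction of unpublished code.

## What the scaled-down replica does and does not reproduce

The end-to-end checks run the two-protocol experiment at tube radius
6 σ with 16·10³ steps per run over ten fixed seeds. At that scale:

* **Reproduced.** Template release: removing CdvB lowers the minimum
  tube radius relative to the matched-time control in 9 of 10 seeds.
  The filaments stay membrane-bound throughout, CdvB2 winds up into
  multi-turn helices after release, and the control tube is held near
  its nominal radius by the template.
* **Not reproduced — curvature sorting.** The deepest achievable neck
  radius is ~3 σ, limited by the inter-turn excluded volume of the
  wound filaments; both contractile species' preferred radii (1.2 and
  1.9 σ at this scale) lie below it, so both remain in the
  "still-pulling" regime and no differential positioning of CdvB2
  versus CdvB1 around the neck emerges. Sorting requires the neck
  radius to fall between the two preferred radii, which only the
  full-scale geometry allows; the corresponding check is left failing
  rather than weakened.
* **Not reproduced — arrangement dependence.** The single-site-focusing
  advantage of placing CdvB1 outside the central CdvB2 pair rests on
  tilt-driven cone formation channelling constriction toward one
  midpoint. A direct comparison (CdvB1 tilt 40° versus 0°, matched
  seeds) shows the tilt coupling is mechanically inert at this scale —
  the adhesion's angular factor exerts torque on directors and membrane
  orientations but too little shape force to steer where necks form —
  so the arrangement comparison reduces to noise. Making tilt
  mechanically potent would require positional coupling of the
  adhesion anisotropy (a different adhesion model) and a full
  recalibration; the check is left failing rather than weakened.

## Known limitations

* Scission itself is not modelled: membrane rupture is detected and
  flagged, not resolved.
* The desk-scale tube cannot reach the published absolute neck
  diameters; only direction-level statements are tested.
* The membrane has no volume constraint, osmotic pressure or S-layer;
  constriction resistance comes from membrane elasticity alone.
* Filament polymerisation/depolymerisation kinetics are out of scope —
  filaments are preassembled and removed whole.
* The neck-detection separation scale defaults to one tube radius; the
  desk-scale analyses resolve necks at 3 σ because the compressed
  five-ring stack places distinct neck structures 4–5 σ apart.
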