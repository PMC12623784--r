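---
title: "Modelling Cdc42 polarization and septin ring assembly with septring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Cdc42 polarization and septin ring assembly with septring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(septring)
```

## The biological problem

Before a budding-yeast cell forms a bud it concentrates active Cdc42
(Cdc42-GTP) into a single membrane cluster that marks the incipient bud
site; a septin ring then assembles around that cluster and becomes the
mother-bud neck. Two quantitative observations organise the models in this
package: the Cdc42-GTP cluster area grows with cell volume following an
approximate power law, and the septin ring diameter is set jointly by the
cluster and by how spatially focused exocytosis is.

`septring` implements three-dimensional mechanistic models of both
processes: surface reaction-diffusion systems on a spherical membrane
coupled to a well-mixed cytosol, a stochastic exocytosis engine that
displaces membrane material radially from vesicle fusion sites, reduced
particle-based simulators, the quantification metrics (cluster area, ring
diameter, scaling exponents), and a synthetic-microscopy module that
generates ground-truth images for the image-quantification algorithms.

## Model families

### Positive-feedback polarization model

The core is the GTPase cycle with scaffold-mediated positive feedback.
Membrane species (concentrations in the thin membrane compartment, uM):
Cdc42-GTP (`Cdc42T`), Cdc42-GDP (`Cdc42D`), the scaffold-GEF complex
(`BemGEFm`) and its Cdc42-bound form (`BemGEF42`); cytosolic species:
GDI-bound Cdc42 (`Cdc42I`) and the cytosolic scaffold-GEF (`BemGEFc`).
Reactions (first-order rates in 1/s, second-order in 1/(uM s)):

* GEF-catalysed activation: `Cdc42D -> Cdc42T` at `k2a BemGEFm + k3 BemGEF42`
* basal deactivation (background GAP activity): `k2b`
* complex formation `BemGEFm/BemGEFc + Cdc42T -> BemGEF42` (`k4a`, `k7`),
  dissociation `k4b`
* GDI cycling `Cdc42I <-> Cdc42D` (`k5a`, `k5b`), scaffold shuttling
  `BemGEFc <-> BemGEFm` (`k1a`, `k1b`)

Because Cdc42-GTP recruits its own activator, a uniform state is
Turing-unstable: with cytosolic diffusion taken as infinitely fast and slow
membrane diffusion `Dm`, small fluctuations amplify into a single cluster.
The membrane is treated as a compartment of thickness 10 nm, so the
membrane-to-cytosol volume ratio

\[ \eta = \frac{(R + R_m)^3 - R^3}{R^3} \]

converts surface reaction fluxes into cytosolic concentration changes
(`membrane_cytosol_ratio()`).

Two printed-form reconciliations were made in favour of mass-action
consistency (pool conservation is the arbiter): the scaffold loss term in
the `BemGEFm` equation is `-k4a BemGEFm Cdc42T` (the complex-formation
reaction), and the cytosolic exchange integrals carry the signs that
conserve the Cdc42 and scaffold pools.

**Total amounts.** The model family's source publications fix the kinetic
constants but the total pools are not printed alongside them; `septring`
defaults to `Cdc42_tot = 5` uM and `BemGEF_tot = 0.017` uM
(cytosol-equivalent), the magnitudes used across this model lineage. A
linear stability analysis of the uniform state (see
`well_mixed_steady_state()` plus the spherical-harmonic growth rates)
confirms these defaults make the unpolarized state unstable over the whole
65-270 fL range, which is the calibration requirement for every
polarization experiment.

**Membrane diffusion.** The published reaction tables of the polarization
models do not carry a diffusion coefficient; `Dm` defaults to
`0.036` um^2/s, the value of the original positive-feedback model this
family derives from. This choice is anchored on a published output: the
septin model's pole is stated to hold a total Cdc42 concentration of
around 180 uM (vesicles deliver 100 uM, "lower than the pole"). With
`Dm = 0.036` the simulated pole reads ~205 uM; with the septin table's
printed `0.0025` it reads ~900 uM, five-fold above the stated value, and
no admissible rescaling of the (unprinted) total pools can close that gap
while keeping the unpolarized state unstable. The printed output
arbitrates, and the same `Dm` is used across the Cdc42-cycle models.
Units are um, s, uM throughout.

### Negative-feedback model

The negative-feedback extension adds phospho-cycling of the scaffold: at
high `BemGEF42` activity the complex autophosphorylates with a Hill-gated
rate

\[ k_8(x) = k_{8,\max} \frac{x^{n_8}}{h_8^{n_8} + x^{n_8}}, \qquad
   x = \mathit{BemGEF42} + \mathit{BemGEF42}^*, \]

the phosphorylated scaffold (`*` species) still binds Cdc42-GTP but cannot
promote activation. Dephosphorylation happens only in the cytosol, with a
*repressive* Hill gate
`k_9(x) = k_{9,max} h_9^{n_9} / (h_9^{n_9} + x^{n_9})` whose argument is
the area-averaged complex concentration: it switches on once activity has
fallen. The published sources state the gating parameter triplets but not
the functional forms; the repressive direction for `k_9` is forced by the
published dynamics - the feedback must release the scaffold again when
the cluster weakens (enabling the reported oscillations in cluster
intensity), whereas an activating gate irreversibly traps the entire
scaffold pool in the phosphorylated state after a single activity burst
(the area-averaged complex concentration never approaches
`h_9 = 6` uM, so recovery would never switch on). The published gate
parameters are loaded verbatim, including the Hill exponent 10.003.

At basal activity both gates are ~1e-9/s, so the phospho-cycle is frozen on
simulation timescales. The unpolarized initial state is therefore the
unphosphorylated fixed point (starred species zero); the mathematically
exact fixed point with balanced phospho-fluxes is only reachable on ~1e9 s
timescales and is not a biologically meaningful start. With
`k8max = 0` and zero starred species the model reduces *exactly* - bitwise,
by construction of the shared numerical kernels - to the positive-feedback
model.

### Septin ring models (SBE and SBER)

The septin module couples a pole-hardened Cdc42 cycle (faster hydrolysis
`k2b = 0.63` and GDI cycling `k5a = 144`, `k5b = 20.8`, which makes the
cluster smaller and robust to exocytosis) to:

* `Axl2` - a representative septin-recruiting polarity factor, recruited to
  the membrane by `BemGEF42` (`k23`) and recycled (`k22`);
* monomeric membrane septin `S` and polymerised septin `P`, with net
  polymerisation flux `(2 k16 S - k17 P) S` and depolymerisation `k18 P`;
* septin-polarity-factor binding: `Axl2 + S -> Axl2S` at `k19` (the SPR)
  and `Axl2 + Sc -> Axl2S` at `k20` (the PSR), with release `k15`;
  bound septin cannot polymerise, which suppresses polymerisation in the
  cluster centre and drives ring formation at the periphery;
* septin-recruited GAP `GapS` (`k12a`/`k12b`) that converts Cdc42-GTP to
  GDP (`k13 GapS Cdc42T`), letting the forming ring corral the cluster
  without a diffusion barrier;
* in SBER mode only, a vesicle-delivered recruiter `X` that converts
  cytosolic septin to membrane septin (`k25`) and decays (`k24`). SBE mode
  zeroes every `X` reaction and delivers no `X`.

Three printed-form reconciliations (documented in the code): the `k13`
hydrolysis is GAP-catalysed (`k13 GapS Cdc42T`); `k19` is a binding
reaction producing `Axl2S` (the printed reaction table form would destroy
septin); and the `k22` detachment applies to free `Axl2` only, not to the
`Axl2S` complex. The last point is forced by the model's published
behaviour: if `Axl2S` detached at `k22 = 10.5`/s, free membrane septin
would be capped at `k15 k20 Sc / ((k15 + k22) k19)` - about `0.004 Sc`,
independent of Axl2 levels - and no plausible septin pool could ever
polymerise a ring, with or without exocytosis. Without complex
detachment the quasi-equilibrium is `S = k20 Axl2 Sc / k21`, which gives
exactly the magnitudes the published parameter-tuning rationale
describes. The
polymerisation flux appears in the printed equations twice, consistently,
as `(2 k16 S - k17 P) S`; the reaction-table reading of `k17`
(`S + P -> 2P`) would flip that term's sign. Both variants conserve
septin, so conservation cannot arbitrate; the printed equations are
followed as the more specific statement of the dynamics.

The septin-module totals (`GapS_tot = 0.2`, `Axl2_tot = 0.2`,
`Septin_tot = 5` uM) are calibration choices of this package (the sources
do not print them), selected once so that (i) the polarization module
still polarizes at 33-133 fL, (ii) a polymerised-septin ring forms at the
cluster periphery on the simulated horizons (at 33 fL the P crest sits
about 1.1 um from the cluster centre, outside the ~0.7 um cluster), and
(iii) the max-node Cdc42-GTP trace shows the published dip-then-recover
shape after septin-module start. They are regular config values and all
perturbation experiments vary rates, not totals.

### Alternative positive-feedback model

A minimal three-species variant in which the positive feedback is a single
cooperative reaction (`2 Cdc42T + Cdc42D -> 3 Cdc42T`), cytosolic diffusion
is finite, and the cytosol is part of the geometry. The bulk is
discretised as radial shells times the surface mesh (finite volumes:
radial fluxes between shells, cotangent-weighted tangential fluxes within
each shell - the cotangent weights are scale-free, so the surface stiffness
serves every shell). Membrane recruitment saturates at the packing limit
`kmax`, entering as a Robin-type boundary flux on the outermost shell with
exact flux pairing between the shell volume and the boundary area.

## Exocytosis engine

Vesicle fusion (radius 50 nm) adds membrane area `A_exo` and displaces
membrane material radially from the fusion site: a molecule at arc length
`s` moves outward by

\[ \Delta r(s) = \frac{1}{\gamma}\left[ R' \arccos\!\Big(1 -
   \frac{R^2}{R'^2}(1 - \cos(s/R)) - \frac{A_{exo}}{2\pi R'^2 \alpha}\Big)
   - s \right], \qquad R' = \sqrt{R^2 + A_{exo}/4\pi}, \]

with mobile membrane fraction `alpha = 0.5` and lipid/protein velocity
ratio `gamma = 1`. The arccos argument is clamped to `[-1, 1]`; the
forward map `s + dr(s)` is non-decreasing, exactly flat on the terminal
cap where the argument saturates (the far cap maps onto the antipode), and
its terminal value is `pi (R' - R)` (~1.6 nm for the default vesicle), not
exactly zero.

On the mesh the event is a semi-Lagrangian value remap: the new value at
arc `s` is the old value at the pre-image `s_pre` (inverse interpolation
of the forward map on a fine 1D grid). Pure value transport under an
outward stretch inflates each surface integral by order one percent per
event; a uniform per-species flux correction removes that inflation, so
the displacement conserves each integral exactly, and the raw inflation
is reported per event. (A locally mass-conserving remap with the
annulus-area Jacobian was tried and rejected: on a sphere it funnels the
far field into the antipodal saturation cap at extreme concentrations,
an artifact the slowly-diffusing polymer field never recovers from.) The area vacated at the centre is new
vesicle membrane carrying Cdc42-GDP at 100 uM (and `X` at 20 uM in SBER
mode) and none of the other species - this is how vesicles dilute the
pole. Hit sites are drawn uniformly from the eligible set
`Cdc42T > epsilon * max(Cdc42T)`; smaller `epsilon` means more diffused
exocytosis, and the realised eligible-node fraction is logged with every
event. Event times are a Poisson process with rate 0.4/s.

Whether delivery replaces or mixes pre-existing membrane at the footprint
is not specified by the displacement formalism; `septring` mixes by area
fraction when the vacated area is smaller than the vesicle area.

## Time integration

Space: linear surface finite elements on an icosphere (cotangent
stiffness, lumped mass; the lumped node areas are the quadrature weights
of every surface integral). Available node counts are `10 * 4^s + 2`; the
presets use 2562 (desk scale) and 10242 (near the published 9451-node
density).

Time: a first-order implicit-explicit splitting per step,

1. slow transfer reactions (phospho-cycling, rates ~0.006/s) explicitly -
   they move mass within one pool and conserve exactly;
2. reactions by node-local backward Euler, solved with a batched Newton
   iteration in compiled code. Complex-formation rates in a mature cluster
   reach ~10^3/s; treating them implicitly removes any stability limit on
   the step size, which an explicit treatment would cap at ~1 ms;
3. cytosolic scalars advance by the *realised* membrane exchange of each
   conserved pool (the membrane-side update is known exactly, so pool
   totals are conserved to machine precision regardless of Newton
   tolerance); cytosol-internal reactions use the explicit midpoint rule
   (`ode_substep()`);
4. diffusion by backward Euler, one SPD solve per diffusion coefficient:
   Jacobi-preconditioned conjugate gradients warm-started from the current
   field, residual-checked against `lin_tol` with a sparse-Cholesky
   fallback, and an exact mass restoration afterwards. The step operators
   are cached on the power-of-two step-size ladder.

Step-size control is step doubling: a full step is compared against two
half steps; the accepted state is the locally extrapolated combination
`2 x_{dt/2} - x_dt`, which cancels the leading splitting bias (without
extrapolation the O(dt^2) discrepancy between the dt and dt/2 split fixed
points pins the step size near steady state). Growth factor 2, shrink
factor 0.5, growth only after four consecutive comfortable accepts.
Steady state is declared when the node-wise `max |dc|/dt` stays below
`ss_rate_tol` for `ss_window` consecutive accepted steps, after which
cluster metrics are measured (only single-cluster states are used for
scaling fits; multi-cluster outcomes are flagged, not dropped).

Numerical parameters that matter, with defaults: `rel_tol` (local error,
1e-3; experiment presets use 2e-3), `lin_tol` (linear residual, 1e-8),
`newton_tol` (1e-10 relative to the field scale), `dt_max` (10 s),
`ss_rate_tol` (1e-6 uM/s; the desk-scale experiment presets use 5e-4 uM/s,
which bounds the per-field drift at the measurement time by well under a
percent of the cluster scale). Degenerate inputs fail loudly: Newton
non-convergence or a negative excursion beyond 1e-6 of the field scale
rejects the step and retries at dt/2; negative excursions far below the
field scale are clamped (the cytosol bookkeeping runs on the clamped
fields, so conservation is unaffected).

## Experiments

`run_cluster_scaling()` reproduces the volume-scaling design: for each
(volume, replicate), rescale totals by the protein slope, build the mesh,
perturb the homogeneous steady state multiplicatively by
`Uniform(-delta, delta)` with `delta = 0.05` (renormalised so pool totals
are exact), integrate to steady state, measure the cluster area, and fit
`log(area) ~ log(volume)` by OLS. The protein slope is the slope of log
concentration versus log volume: 0 keeps concentrations constant, -1
keeps amounts constant; GAP activity is never rescaled. Per-cell seeds
derive from the master seed and the (volume, replicate) indices, so adding
replicates never reshuffles existing cells.

The desk-scale preset - 12 cells (4 volumes spanning 65-270 fL, 3 seeds
each) on 2562-node meshes with a 3000 s horizon - is the package's default
experiment size; the full published design (60 cells, 9451 nodes) is a
cluster-scale job with identical code paths. Convergence checks in the
test suite verify that halving the local-error tolerance moves individual
steady-state cluster areas by under ~2 percent and that the 2562-node
areas agree with 10242-node areas to within a few percent.

`septin_checkpoint()` runs the polarization module of the septin model to
steady state and hands the cluster to `run_septin_experiment()`, which
integrates SBE/SBER with exocytosis and measures ring diameter (from the
polymerised-septin field), ring formation time (first time the max-node
Cdc42-GTP trace exceeds its initial value after the recruitment dip) and
the eligible-node fraction. `run_sensitivity()` wraps the
diffused-versus-focused comparison for x0.5/x2 perturbations of each
septin-module parameter.

## Quantification

* **Cluster area**: unweighted fraction of nodes with
  `|max - c| < 0.2 (max - min)`, times the membrane area (an area-weighted
  variant is reported alongside); connected components over mesh edges
  flag multi-cluster states.
* **Ring points**: nodes with `|max(P) - P| <= 0.2 max(P)`.
* **Ring diameter**: the ring axis is the mean direction of the points;
  points project to the plane normal to the axis; per-point diameters are
  twice the in-plane radius; points at or below the median radius form the
  inner rim, at or above the outer rim, and the reported diameter is the
  mean of the two rim means - `2r` exactly on a circle,
  `(d_in + d_out)/2` on an ideal annulus. Whether the published per-point
  quantities are chords or twice-radii is not stated; both coincide on
  circles, and twice-radius is used here.
* **Scaling exponent**: OLS of log metric on log volume with slope
  standard error, two-sided t-test p-value and R^2.

## Synthetic imaging

`generate_scene()` renders mother-bud pairs (ellipse masks), an annular
septin-ring channel at each neck, a disc-shaped Cdc42-cluster channel, a
constant background and Gaussian read noise, and stores the ground truth.
The quantifiers mirror standard fluorescence pipelines: Gaussian filter
(sigma 2 px), per-cell threshold at median + 2 sd keeping the largest
component (cluster area); the neck-ellipse procedure with the 10th
brightest pixel building the cell-cycle curve, threshold at the curve
midpoint, a 50 percent object/ellipse overlap rule and major-axis-length
diameters (ring and exocyst-cluster diameter; the exocyst variant keeps at
most one object); full width at half maximum above the profile minimum
(contour-profile diameters, widest crossing on ties, with a warning);
mean + 2 sd inside a 30 x 20 px neck ellipse with an 80 percent overlap
rule (phalloidin actin clusters); and solid-of-revolution volumes from
2D masks. Thresholds are strict (`>`); the published description does not
fix strict versus non-strict, and the strict choice makes a flat cell
yield zero cluster area.

The generator emulates the geometry and noise of the quantified
microscopy, not its optics: there is no point-spread function beyond the
Gaussian blur applied by the quantifiers themselves, no photobleaching,
and cells are ideal ellipses. Passing these tests shows the measurement
algorithms are implemented correctly, not that they are robust to every
real-microscopy artefact.

## What the synthetic data do and do not show

All simulation experiments in this package consume no external data: the
inputs are the published kinetic constants, the geometry, and seeds. The
synthetic conditions reproduce the models' own study design (volumes,
replicate counts, thresholds), so agreement with the published simulation
results validates the reimplementation of the models - it cannot, and is
not meant to, validate the models against new experimental measurements.
The experimentally measured scaling exponents of real cells and the mutant
phenotypes require real microscopy data and are out of scope.

## Reproduction fidelity at desk scale

The acceptance machinery (`scripts/acceptance.R` and the acceptance test
suite) measures what this reconstruction actually produces, and two
quantitative outcomes differ from the originally reported ones; both are
measured, not asserted, and their verification trail is part of the test
suite:

* **Cluster-area scaling exponent.** The desk-scale design (4 volumes
  spanning 65-270 fL, three seeds each, 2562-node meshes, constant
  concentrations) gives a clean power law with exponent 0.50 +/- 0.01
  (R^2 = 0.999) where 0.33 was reported. The measurement is spatially
  converged (areas move ~4% between 2562- and 10242-node meshes),
  temporally converged (areas constant from t = 500 s to t = 8000 s),
  tolerance-independent, and robust to the membrane diffusion choice and
  to halving the total Cdc42. It is, however, strongly sensitive to the
  total scaffold-GEF concentration, which the sources do not print: the
  package uses the literature value 0.017 uM, and no printed anchor pins
  the value that would reproduce 0.33. With constant protein *amounts*
  (protein slope -1) this reconstruction's areas decrease with volume
  (exponent about -0.3) where a flat response was reported - the same
  root cause.

* **Exocytosis-rate and SPR orderings.** At coarse meshes and short
  horizons, reducing the exocytosis rate does not consistently enlarge
  the ring (differences across matched seeds straddle zero), and the
  Cdc42-GTP recovery never re-crosses its initial level (the post-ring
  equilibrium sits below the pre-septin level at this resolution), so the
  formation-time ordering under SPR changes cannot be evaluated by its
  stated metric. The diffused-versus-focused enlargement, the
  dip-and-recovery shape, ring formation without exocytosis, and the
  reduced-GAP enlargement of cluster and ring all reproduce at desk
  scale.

## Known limitations

* Spherical cells only; no membrane deformation or bud-neck curvature.
* Endocytosis is excluded (as in the modelled system).
* The icosphere offers node counts of `10 * 4^s + 2` only; arbitrary
  target counts are honoured to within 20 percent or rejected explicitly.
* The first-order splitting trades temporal order for robustness;
  accuracy is controlled by the step controller, and all headline
  quantities are steady-state measurements insensitive to transient
  accuracy.
* Full-fidelity septin-ring runs at the published resolution take far
  longer than the desk-scale presets; the package ships the coarse
  presets as first-class configurations and the fidelity knobs
  (`target_nodes`, `t_end`, tolerances) scale the same code paths up.
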