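---
title: "A compartmental model of ion and water transport in a salt-stressed root"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A compartmental model of ion and water transport in a salt-stressed root}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(saltroot)
```

## The model

`saltroot` simulates the coupled transport of Na^+^, K^+^, Cl^-^, H^+^ and
water through a discretized Arabidopsis primary root under salt stress, and
uses the simulator to ask where plasma-membrane Na^+^/H^+^ antiporters
(the SOS1 family) must be operating to reproduce whole-root observables.

The root is an annular cylinder of five concentric tissues — epidermis,
cortex, endodermis, xylem parenchyma and xylem — cut into `n_axial`
single-cell layers (30 by default, 6 in the fast `toy` preset). Layers near
the tip form the *apex*; the rest is the *mature* zone. Every living cell
contributes three well-mixed compartments (apoplast, cytosol, vacuole);
mature xylem is an open apoplastic conduit. The mature endodermis carries
the two developmental barriers: the Casparian strip blocks its radial
apoplastic walls, and suberin lamellae block its plasma membranes except in
a configurable fraction of passage-cell layers (placed deterministically,
every `round(1/fraction)`-th mature layer, so rebuilds are reproducible).
Plasmodesmata connect every radially and axially adjacent pair of cytosols,
making the symplast a single connected network spanning both zones.

### Transport laws

* **Channels** (NSCC, inward- and outward-rectifying K^+^ channels, a
  stelar Na^+^-selective uniporter of the HKT1;1 type, background anion
  and H^+^ permeabilities) follow the Goldman–Hodgkin–Katz constant-field
  flux, multiplied by a two-state Boltzmann open probability where the
  channel is voltage gated. Two regulatory couplings are built in: the
  outward rectifier's half-activation voltage tracks the apoplastic K^+^
  Nernst potential (`kor_gating_midpoint()`), and the NSCC permeability is
  blocked hyperbolically by external Ca^2+^ (`nscc_permeability()`).
* **Pumps and symporters** (plasma-membrane and vacuolar H^+^-ATPases,
  K^+^/H^+^ and Cl^-^/2H^+^ symporters) are four-state carrier cycles
  evaluated with the King–Altman closed form
  (`carrier_cycle_flux()`); substrate binding concentration-scales the
  cis/trans binding rates, and the charge-translocating step carries
  symmetric Eyring voltage factors. The cycle rate constants encode the
  thermodynamic drive: the H^+^ pump's cycle equilibrium constant is set
  to stall at a protonmotive force near 500 mV, the scale of ATP
  hydrolysis.
* **Antiporters** (SOS1 on plasma membranes; NHX-type Na^+^/H^+^ and
  K^+^/H^+^ exchangers on tonoplasts; a CHX-type K^+^/H^+^ exchanger on
  plasma membranes) follow the mass-action law
  `J = k_ap (c_in H_out - c_out H_in)` with 1:1 stoichiometry, so they are
  exactly electroneutral.
* **Apoplastic and symplastic ion movement** is an extended Nernst–Planck
  law on each edge of the connectivity graph: Fickian diffusion, electric
  drift on the arithmetic interface mean, and convection with the local
  water flow using smoothed first-order upwinding (see *Numerical
  choices*).
* **Water** follows nonequilibrium thermodynamics: plasma membranes and
  plasmodesmata respond to hydraulic and osmotic gradients
  (`Jv = Lp [ΔP - σ Δπ]`), tonoplasts to osmotic gradients only, and the
  apoplast to hydraulic gradients only. Osmotic pressure is ideal van 't
  Hoff over the four mobile ions plus the fixed charges and buffer where
  present. The transpiration stream is driven by a fixed hydraulic
  pressure of -0.3 MPa at the top of the xylem conduit.

### Electroneutrality, buffering and the DAE

Electric potentials are determined by local electroneutrality. The system
is integrated as an index-1 differential-algebraic system with
`deSolve::radau`: concentrations and volumes are differential states, and
each compartment's potential is an algebraic unknown whose row enforces
zero net charge flux (the once-differentiated electroneutrality
constraint, equivalent to a per-compartment Kirchhoff current law).
Initial states are constructed *exactly* electroneutral — the impermeant
organic-anion pool of every living compartment and the cell-wall fixed
charges are chosen to zero the charge census — so the algebraic rows
preserve electroneutrality along the trajectory; the test-suite verifies
the residual stays within solver tolerance at accepted steps.

Cytosols and vacuoles carry a single equilibrium H^+^ buffer; the state
variable is the total proton pool and the free concentration is recovered
as the positive root of the binding quadratic
(`proton_buffer_partition()`). Charge bookkeeping is unaffected by
buffering because protonating the buffer anion consumes one positive and
one negative charge.

Cell water relations close with a linear elastic law: turgor is
proportional to the relative expansion of the protoplast (cytosol +
vacuole) against the wall. Apoplast compartments use the same law with a
much stiffer modulus (`eps_wall = 1e8` Pa), which keeps walls effectively
rigid while making every volume an ordinary differential state — this is
both physically reasonable (walls are not perfectly rigid) and numerically
essential (a formulation with apoplastic pressures as extra algebraic
unknowns is singular wherever barriers isolate an apoplast compartment).

### A closure the transporter inventory needs

With only the H^+^ pump exporting protons, the cytosolic pH has no steady
state: the pump alkalinizes the cytosol without bound and the resting
potential collapses. Real cells return protons through H^+^-coupled
nutrient transport and the biochemical pH-stat. The model closes the loop
with two minimal components: a small background H^+^ permeability of the
plasma membrane and tonoplast, and a plasma-membrane K^+^/H^+^ exchanger
(the CHX family) that returns H^+^ electroneutrally. Their defaults place
the resting epidermal potential near -120 to -155 mV in low-K^+^ media and
near -60 mV in the 10 mM K^+^ comparison media, with cytosolic pH between
7.5 and 8.5 and vacuolar pH near 5.5.

## Parameters

All parameters live in `default_params()` (SI units; concentrations in
mol m^-3^ = mM). The geometry (radii 60/45/30/20/10 µm, 100 µm cell
height) is an Arabidopsis-plausible default; it scales absolute
observables but not the qualitative behavior. Kinetic defaults are the
package's own fitted values: they were calibrated with the package's
two-stage procedure against the same target structure used for the
original model optimization — root Na^+^/K^+^ contents and epidermal
potentials for the outer root (stage 1), xylem concentrations and the
Na^+^ flux to the shoot (about 50 nmol min^-1^ g^-1^ FW at 50 mM NaCl)
for the stele (stage 2). The wild-type plasma-membrane antiporter
coefficient is 2e-7 m^4^ mol^-1^ s^-1^ in the outer tissues and 1e-6 in
the stele; the `sos1` genotype multiplies all of these by a residual
fraction (default 0.1) because a low — as opposed to absent — antiporter
activity is required to approach the mutant measurements.

The scenario machinery exposes the interesting knobs directly:
`set_scenario()` places antiporters by zone and tissue
(`enumerate_scenarios()` lists the 17 canonical spatial patterns in six
groups), `strength_grid()` is the four-decade strength ladder
1e-8…1e-5 m^4^ mol^-1^ s^-1^, and `classify_reasonable()` applies the
inclusive "within 50% of the wild-type reference" rule to sweep rows.

## Numerical choices

* **Stiff DAE integration**: Radau IIA (`deSolve::radau`) with the
  diagonal mass matrix of the DAE and a banded, internally
  finite-differenced Jacobian. States are ordered layer-major so all
  couplings are local; the bandwidth is measured from the realized edge
  list plus one compartment block (an edge flux can depend on the partner
  cell's vacuole volume through its turgor).
* **Nondimensionalization**: the integrator works on scaled states
  (volumes by their reference values, concentrations and potentials by
  typical magnitudes). Without this the iteration matrix mixes scales of
  1e-15 and 1e2 and the inner Newton iteration stagnates.
* **Smoothed upwinding**: the convective term uses
  `c_up = cbar + tanh(v/1e-13) (c_a - c_b)/2`, i.e. full first-order
  upwinding for any appreciable velocity but differentiable at `v = 0`,
  which prevents Newton chattering on sign changes of near-zero wall
  flows.
* **Consistent initialization**: the algebraic subsystem (potentials,
  plus apoplast volumes so the stiff wall-compliance water balance starts
  equilibrated) is solved by a short pseudo-transient relaxation — the
  artificial capacitance has the physical sign of a membrane capacitance —
  followed by a damped, row-scaled Newton polish that only accepts
  strict-descent steps. Structurally inert unknowns (a potential with no
  charge-carrying pathway) are frozen.
* **Steady states** are declared when the scaled rate of change of every
  differential state falls below `rate_tol` (default 1e-9 s^-1^) along a
  single long relaxation; the salt step is an instantaneous medium switch
  with the algebraic variables re-solved at the discontinuity.
* **Degenerate inputs**: a model with every permeability zero returns its
  initial guess unchanged; a sweep row whose simulation fails is flagged
  in the output table rather than aborting the sweep.

## Synthetic targets and the two-stage fit

`generate_targets()` forward-simulates a truth configuration under the
four printed comparison media (see `medium_preset()`) and emits the seven
optimization observables with multiplicative lognormal noise (chosen
because all targets are positive quantities spanning decades; a relative
sd and a seed fully specify the noise). `two_stage_fit()` then fits outer
parameters against outer-stage targets and, with those frozen, stelar
parameters against stele-stage targets — the separation is justified
because stelar transport barely influences root contents and epidermal
potentials, which the test-suite asserts. Fits are bounded weighted
relative least squares in log10 parameter space, multi-started from a
seeded Latin hypercube, with local identifiability reported as the
condition number of the Fisher information. Because root contents are not
perfectly stele-independent at finite exposure times, the staged result is
refined by a short joint polish over all free parameters against the full
target table (the joint objective has the generating truth as its exact
optimum on noiseless targets); inside an optimization, successive forward
simulations warm-start their pre-salt relaxation from the previous
iterate's steady state. "Spread" in the noisy
recovery check means the union of the per-seed fitted values ± two
standard errors from the local Fisher information — a principled reading
that accounts for each fit's own uncertainty.

The generator's defaults *are* the study conditions: the printed media,
daily exposure scales (1, 10, 15 days map to multiples of 86 400 s from
the salt step) and the toy/default geometries. Tests use the 6-layer toy
root with shortened exposures (hours) and relaxed-but-adequate tolerances;
the scientific checks in the acceptance suite run the full 30-layer root
for 1–15 simulated days. These sizes are the package's own choices for a
self-contained test-suite; nothing about the model changes with size
except the axial resolution (a refinement test bounds that effect at a
few percent).

## What the synthetic data do and do not show

Passing the recovery tests shows the pipeline is self-consistent: the
optimizer can find parameters that the forward model itself generated,
under the model's own noise assumptions. It does not show that the model
family is correct for real roots — inter-laboratory scatter, growth,
root hairs, NO~3~^-^ as a second mobile anion, and the regulatory layer
(SOS2–SOS3 activation of SOS1) are all outside the model.

## Known limitations

* The measured epidermal potential transient depolarizes and then
  partially recovers; the fitted defaults reproduce the fast
  depolarization and the stressed level, but the relaxation is monotone
  (no overshoot-recovery).
* Cl^-^ is the only mobile anion, so its xylem concentration plays the
  role of all free anions and overshoots measured Cl^-^ + NO~3~^-^, as
  expected for this model family.
* Cytosolic pH rides ~0.5–1 unit alkaline of 7.2 in the high-K^+^ media;
  the electroneutral K^+^/H^+^ return path ties cytosolic pH to the
  apoplastic K^+^ ratio.
* Geometry is a single unbranched cylinder; growth, root hairs and
  lateral roots are not represented.
* Under the shipped defaults, apex-only antiporter placements lower the
  15-day mature mean cytosolic Na^+^ by ~20% relative to the
  no-antiporter case: the apex acts as a symplastic sink whose reach
  scales with the plasmodesmal ionic conductance and the root length,
  both poorly constrained. The corresponding test documents this as a
  deviation from the expected near-invariance.
* `zone_surface_efflux()` is a *net* flux. At low external NaCl the apex
  is a net Na^+^ importer while the mature zone turns weakly positive, so
  the expected ordering "apex efflux exceeds mature efflux" — which
  descends from unidirectional tracer measurements — does not hold for
  the net observable; the corresponding test documents this.

## Reproducing the analyses

```{r pipeline}
cfg <- make_truth_config("default")
model <- build_model(cfg)
medium <- medium_preset("flux_content")       # 50 NaCl / 11.9 KCl, pH 5.5
pre <- presalt_medium(medium)
ss <- solve_presalt_steady_state(model, pre)
traj <- run_protocol(attr(ss, "model"), ss,
                     make_protocol(pre_medium = pre, salt_medium = medium,
                                   duration = 86400))
mol_s_kg_to_nmol_min_g(flux_to_shoot(traj, 86400, "Na", per_fw = TRUE))
```

`scripts/acceptance.R` chains these calls into the full set of headline
quantities (flux to shoot, antiporter flux ratios, xylem-loading signs,
genotype contrasts, parameter recovery) and writes them as JSON.
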