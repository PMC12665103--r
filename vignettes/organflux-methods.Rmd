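---
title: "Modeling transport and glucose-insulin dynamics in a convective multi-organoid device"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling transport and glucose-insulin dynamics in a convective multi-organoid device}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organflux)
library(dplyr)
```

## The device and the modeling problem

organflux is a reduced-order model of a recirculating two-chamber
multi-organoid culture device for the liver–pancreas axis. Pancreatic and
liver organoid chambers (POC, LOC; 300 µL each by default) sit above a
1.0 µm-pore PTFE membrane (porosity 0.8, Darcy permeability
2.5 × 10⁻¹⁴ m²). Below the membrane a 0.7 × 0.3 cm connecting channel (CC)
is perfused by a peristaltic pump at 600 µL/min, so the 600 µL circulating
working volume (CC plus pump tubing, the `LOOP` compartment) turns over
about once per minute — the circulation time of human blood. Metabolites
injected into the circulation (glucose) or secreted in a chamber (insulin,
Fetuin-A — represented in transport experiments by 4 kDa and 70 kDa
FITC-dextran tracers) are exchanged between chambers through the membrane
and the channel.

The package answers three questions at desk scale:

1. what convective recirculation contributes to inter-chamber transport,
   relative to pure diffusion (`simulate_transport()`,
   `percent_transferred()`, `fold_enhancement()`);
2. what the membrane's apparent permeability is, as a donor/receiver assay
   would measure it (`estimate_permeability()`);
3. whether a minimal glucose–insulin feedback loop on top of the transport
   network can reproduce the in-vitro glucose tolerance test (GTT) and
   glucose-stimulated insulin secretion (GSIS) read-outs under control,
   palmitate (PA, 0.3 mM) and palmitate + metformin (20 µM) conditions
   (`simulate_gtt()`, `fit_gtt_params()`, `gsis_protocol()`).

## Transport model

Each compartment is well mixed. For species concentration $C_i$ in
compartment $i$ of volume $V_i$:

$$V_i \frac{dC_i}{dt} = \sum_{\text{conv}} Q\,(C_{\text{up}} - C_i)
 + \sum_{\text{membrane}} G_{ij}\,(C_j - C_i)$$

Convective edges form the closed CC ⇄ LOOP ring with volumetric rate $Q$.
A membrane interface contributes the lumped diffusive conductance

$$G = \frac{D\,\varepsilon\,A}{L\,\tau}$$

with free-solution diffusivity $D$ (9.58 × 10⁻¹⁰ m²/s for glucose,
1.35 × 10⁻¹⁰ for the 4 kDa tracer, 2.30 × 10⁻¹¹ for the 70 kDa tracer),
porosity $\varepsilon = 0.8$, exchange area $A$, thickness $L$ (default
50 µm, a typical 1.0 µm-pore PTFE filter; never reported for the actual
device and therefore configurable and surfaced in result provenance), and
tortuosity $\tau$ (default 1: the membrane is described by porosity and
permeability only). Pressure-driven transmembrane flow is available as a
diagnostic (`darcy_velocity()`) but is off by default: at the ~0.01
dyne/cm² wall shear of this device the transmembrane pressure is tiny and
tracer flux is diffusion-dominated.

**No-flow topology.** Without flow the convective terms vanish, but the
chambers stay connected: tracer still crosses the membrane and diffuses
through the stagnant channel. We lump that stagnant layer into a diffusive
path conductance $D\,A_{cc}/L_{path}$ ($A_{cc} = w h$ is the channel
cross-section) placed in series with each membrane conductance. The
calibrated $L_{path}$ comes out near 0.3 mm — an effective unstirred-layer
length, not the geometric channel length: quasi-steady diffusion across a
centimetre-scale channel would transfer orders of magnitude less than the
no-flow assays actually report. The tubing loop exchanges only by
convection; with the pump off it is stranded (diffusion along metres of
narrow tubing is negligible on assay timescales).

**What makes flow matter.** Two mechanisms, both emergent from the
topology: (i) with flow, a chamber-loaded tracer equilibrates against the
full 600 µL circulating volume instead of the ~200 µL channel, and a
channel-loaded solute (glucose) is delivered from the full loop instead of
only the channel fraction; (ii) without flow, the unstirred-path
resistance throttles every membrane exchange. Transfer percentages are
non-decreasing in flow rate and rank with diffusivity under no-flow —
both are asserted as randomized property tests.

## Device geometry defaults and calibration

Only the channel cross-section, membrane pore/porosity/permeability, media
volume and flow rate are reported for the device. The remaining geometry is
handled in two tiers:

* **Fixed defaults, chosen once from standard practice:** chamber media
  volumes of 300 µL (the volume the GSIS protocol uses per well), a CC
  length of 1.0 cm (the scale of the chamber separation, giving
  0.7 × 0.3 × 1.0 cm = 210 µL), and a LOOP of 390 µL so the circulating
  loop totals the stated 600 µL (typical peristaltic tubing holds several
  hundred µL).
* **Calibrated free parameters:** the membrane exchange areas per chamber
  (`exchange_area_POC`, `exchange_area_LOC`) and the no-flow path length
  (`channel_path_length`), fitted by bounded Levenberg–Marquardt
  (`calibrate_transport_metrics()`) to the three reported 4 kDa dextran
  read-outs — 58.4 % accumulated downstream at 180 min under flow, 20.4 %
  without flow, and the 2.1× LOC concentration fold at 3 h. Three
  informative observations determine the three parameters essentially
  exactly (residual norm ~10⁻¹³). All three observations are 4 kDa data,
  so the glucose and 70 kDa metrics remain genuine predictions of the
  calibrated model. `calibrate_geometry()` applies the same machinery to
  raw concentration time series (e.g. synthetic assays), and reports
  flat-sensitivity parameters as non-identifiable instead of silently
  pinning them — the no-flow path, for instance, is unidentifiable from
  flow-only data.

```{r calibrate, eval = FALSE}
dev <- mod_device_default()
cal <- calibrate_transport_metrics(
  dev, filter(reported_transport_metrics(), species == "dextran4"),
  free_params = c("exchange_area_POC", "exchange_area_LOC",
                  "channel_path_length"))
cal$params
evaluate_transport_metrics(cal$device, reported_transport_metrics())
```

**A structural limitation, stated plainly.** The calibrated model
reproduces the 4 kDa read-outs exactly and predicts the glucose
flow/no-flow fold at 1.84 (reported: 1.9 ± 0.1). It predicts ~30 %
downstream accumulation of the 70 kDa tracer at 24 h under flow, well
below the reported 70.6 ± 12.4 %. The tension is structural, not a fitting
failure: the 2.1× LOC fold forces a small LOC exchange area (a permissive
LOC membrane would make the flow/no-flow contrast much larger than 2.1),
while fast 70 kDa export from the LOC needs a large one — and both species
scale identically with area, so no species-independent membrane can
satisfy both. The reported read-outs themselves sit uneasily together (the
9.1× fold reported for the 70 kDa tracer implies, from its own
percentages, a ratio nearer 4.4×), so we keep the calibration protocol
fixed, report the 70 kDa prediction honestly, and flag it rather than
refit it away. A size-dependent membrane hindrance factor would
reconcile the numbers but is deliberately out of scope: the membrane's
1.0 µm pores are orders of magnitude larger than either tracer, so
hindered-diffusion theory offers no principled basis for one.

**Glucose initial condition.** The GTT and the glucose transport assays
inject a 13 mM glucose solution into the circulation; we therefore
initialise CC and LOOP at the dose and the chambers at the 5.5 mM media
baseline, under both flow states. With the pump off the LOOP fraction of
the dose is stranded, which is half of the predicted flow/no-flow glucose
contrast; the unstirred-path throttling supplies the rest.

## Apparent permeability

`estimate_permeability()` implements the donor/receiver estimator
$P = C_t V / (C_0 A \Delta t)$ (cm/s). It is unbiased only in the sink
regime $C_t \ll C_0$; the result carries a `sink_ok` flag and a warning
fires when $C_t > C_0$. Fed with early-time simulated data it recovers the
imposed conductance as $P A \to G$; the quasi-steady bias grows like
$k\Delta t/2$ with $k = G(1/V_d + 1/V_r)$, so short assays (or slow
species) keep it under 2 % — the regime the estimator consistency test
pins down.

## The minimal glucose–insulin model

No kinetic equations are reported for the biological read-outs, so the
feedback stage is this package's own construction — deliberately the
smallest model able to express the observed features: biphasic secretion,
normoglycemia within 2 h, sustained hyperinsulinemia under palmitate, and
faster glucose clearance with metformin. On top of the transport network
(insulin travels with the diffusivity of its 4 kDa size surrogate; the
mapping is declared in the configuration, not hard-coded):

* **Secretion** (into the POC, threshold-linear in POC glucose above
  $\theta$): $S(t) = f_s\,[a_1 (G_{POC}-\theta)_+ e^{-\lambda t}
  + a_2 (G_{POC}-\theta)_+]$ — a decaying first phase plus a sustained
  phase.
* **Turnover:** insulin relaxes everywhere toward its basal level $I_b$ at
  rate $k_I$ (a single first-order term standing in for all clearance
  routes, which the device itself lacks).
* **Hepatic uptake:** glucose is removed in the LOC at
  $f_u\,u\,I_{LOC}\,G_{LOC}$ (mass action in local insulin and glucose).
* **Conditions:** palmitate multiplies secretion and uptake by factors
  $f_s, f_u \in (0,1]$; metformin multiplies them back up (bounded
  below by 1), reflecting AMPK-mediated uptake restoration and
  aquaporin-7-mediated secretion support.

Fixed parameters, chosen once: $\theta = 5.5$ mM (the culture medium
glucose — the natural operating point separating basal from stimulated
states, inside the 2.8–20 mM bracket of the GSIS protocol),
$\lambda = 1.5$/h (a first phase that plays out within the 0–4 h window),
$k_I = 0.3$/h. The remaining four kinetic parameters and the two PA
factors are fitted by `fit_gtt_params()` — weighted least squares against
the seven reported GTT observations (weights 1/SD), jointly across
conditions with shared kinetics, from a fixed multistart list so the
result is deterministic. Seven observations cannot identify more than six
free parameters, hence the fixed trio; the under-determined case is
refused outright.

The fitted model reproduces the control 2 h glucose (7.7 vs 7.8 ± 0.5 mM),
the 24 h insulin under control (22.5 vs 22.6 ± 0.1 µg/L) and palmitate
(26.8 vs 27.1 ± 0.5 µg/L), the sustained-phase ordering (control < PA),
and a biphasic control insulin trajectory peaking near 4 h. Two honest
notes. First, the early control insulin point (21.1 µg/L at 1 h) sits
*below* the late plateau; the model, whose insulin starts at basal and
rises, cannot dip under basal and fits that point ~1.8 SD high. Second,
the reported GTT insulin alone attributes the palmitate phenotype entirely
to the uptake deficit ($f_u \to 10^{-4}$, its floor) and pushes
$f_s \to 1$: hyperinsulinemia follows from persistently elevated glucose
driving sustained secretion, with no secretion impairment needed. The
reported GSIS reduction under palmitate (for which no numbers are reported)
therefore does **not** emerge from the GTT fit; GSIS behaviour is tested
as a monotonicity property of $f_s$ instead.

**Mechanistic consequence worth knowing:** with mass-action uptake driven
by absolute insulin, basal insulin keeps clearing glucose after
normoglycemia is restored, so control glucose drifts below baseline over
24 h rather than holding at 5.5 mM. Holding a set point would need basal
hepatic glucose output, which is unmeasured here and deliberately not
modeled. Only the 2 h read-out is compared against data. A variant driven
by above-basal insulin was rejected during design: insulin reaches the LOC
through the calibrated (tight) membrane too slowly for above-basal excess
to clear the bolus within 2 h.

**GSIS** is simulated off-device (a static 300 µL well, matching the
protocol's transfer to a well plate): alternating 1 h at 2.8 mM and 1 h at
20 mM, three cycles. Released insulin per phase integrates basal release
$k_I I_b$ plus the secretion law; the stimulation index is the high/low
ratio, so it is exactly 1 for a glucose-insensitive parameterisation and
decreases monotonically with $f_s$.

## Numerical choices

* Integration: `deSolve::lsoda` (stiff-capable — the 40-fold diffusivity
  range makes the linear systems moderately stiff), relative tolerance
  10⁻⁸, absolute 10⁻¹² (10⁻¹⁰ for the coupled glucose–insulin system,
  whose states are O(10)). The transport systems pass a constant analytic
  Jacobian.
* Linear-system verification: every ≤3-compartment configuration is
  checked against an independently constructed matrix-exponential solution
  (`Matrix::expm`) to 10⁻⁶ relative; the two-compartment case additionally
  against the closed form $C_1(t) = C_{eq} + (C_1(0)-C_{eq})e^{-kt}$,
  $k = G(1/V_1 + 1/V_2)$.
* Mass balance: recomputed for every run and stored in provenance; closed
  systems must conserve total mass to 10⁻⁶ relative.
* Negative concentrations: values below −100 × atol abort with an
  integrity error (a model bug, not round-off); smaller negativity is
  clipped to zero.
* Optimisation: bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) with
  `epsfcn = 1e-8`, so finite-difference steps (~10⁻⁴ relative) stay well
  above the ODE solver's 10⁻⁸ noise floor — with the default
  machine-epsilon steps the Jacobian is noise and the fit stalls on a
  false plateau. Ties and multistarts are fixed lists; no randomness
  enters any fit.
* Fold enhancement with a zero no-flow denominator signals an overflow
  error instead of returning `Inf`.

## The synthetic-data generators

`generate_tracer_assay()` and `generate_gtt_series()` wrap the simulators
with replicate multiplicative Gaussian noise (default CV 13 % for tracer
assays and 4 % for insulin, matching the dispersion of the reported
replicate read-outs, e.g. 7.6/58.4 ≈ 13 %), seeded and exactly
reproducible, with negative draws floored at zero and counted. They
emulate: washout/accumulation curves for the three species under both flow
states, and sparse GTT series with SDs aggregated over replicates. They do
**not** emulate plate-reader optics, photobleaching, ELISA calibration
error, device-to-device geometric variation, or organoid biological
variability — so passing the simulate-then-recover tests demonstrates
estimator correctness under the assumed noise model, not robustness to
real-world systematics.

Problem sizes used throughout the tests — 4-compartment devices,
≤ 11-timepoint assays, ≤ 1000 synthetic replicates, 24 h GTT horizons —
are the scales at which every behaviour of interest is already expressed;
the device itself has no larger regime.

## Known limitations

* Well-mixed compartments: no spatial gradients inside chambers; the
  calibrated exchange areas absorb all geometric detail, so they are
  effective, not geometric, areas.
* A single species-independent exchange area per membrane cannot reconcile
  the 4 kDa LOC fold with the 70 kDa export (above).
* The insulin scale is arbitrary (organoid mass is not quantified);
  fitted secretion parameters absorb it, so they transfer to other devices
  only as ratios.
* Sampling is treated as non-perturbing (aliquot volumes are not
  modeled).
* Metformin's boosts default to plausible values; only qualitative
  behaviour (faster glucose fall, PA-like insulin) is expected of them,
  and no reported read-out constrains them quantitatively.
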