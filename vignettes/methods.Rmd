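---
title: "Methods: aerosol size reduction and respiratory dosimetry in aerodose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aerosol size reduction and respiratory dosimetry in aerodose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aerodose)
```

`aerodose` covers the chain from raw e-cigarette aerosol sizing
measurements to respiratory dose: gravimetric cascade-impactor reduction,
mobility-sizer reduction with diameter/density conversions, a
generation-by-generation lung deposition model, formulation-comparison
statistics, and a synthetic-data generator that stands in for the
instruments. This vignette records the models, the defaults and why they
were chosen, the numerical choices, and what the package deliberately does
not attempt.

## Lognormal size distributions and conversions

All size distributions are two-parameter lognormals, `lognormal_psd(median,
gsd)`, tagged with a weighting basis (number or mass) and a diameter kind
(physical or aerodynamic). The Hatch–Choate moment relation converts the
count median diameter to the median of the b-th moment distribution,
`CMD · exp(b ln²GSD)`; with `b = 3` that is the mass median diameter. The
aerodynamic diameter of a compact droplet is the physical diameter times
the square root of its density in g/cm³.

The effective droplet density is the humectant-fraction-weighted average of
the PG and VG component densities. The component defaults are 1.040 and
1.261 g/cm³ — standard handbook values near room temperature, chosen
because they reproduce the conventional two-decimal mixture constants
(1.11 g/cm³ at 70:30 PG:VG, 1.19 at 30:70) exactly; both are overridable.
Additives at the percent level (nicotine, flavourings, water/ethanol) are
folded into the humectant fractions rather than modelled separately, since
their effect on mixture density is below the two-decimal precision at
which densities enter the analysis.

## Impactor reduction

A cascade impactor stage with cut-point `d50_j` is treated as an ideal
sharp cut: it collects exactly the mass of particles with aerodynamic
diameter in `[d50_j, d50_{j+1})`. Stage concentrations are
`(M_post − M_pre) · 1000 / V_sampled` in μg/cm³; the sampled volume
defaults to the puff topography product (2 puffs × 55 cm³ = 110 cm³) and
is configurable, since per-puff concentrations are the quantity of
interest. Negative mass differences within one balance resolution
(default 0.1 mg) are clamped to zero.

The (MMAD, GSD) estimator is the classic log-probit regression. Cumulative
undersize fractions are accumulated from the backup filter upward — the
standard impactor convention, monotone in `ln d` — and cut-points with
`F = 0` or `F = 1` are excluded because the probit is undefined there; at
least three informative points are required, otherwise a classed
degenerate-fit condition carrying the cumulative table is raised. The
regression is unweighted least squares in probit space. On exact lognormal
cumulative points the probit line is exact, so the estimator recovers truth
to machine precision; this is a test invariant.

Two estimator properties are worth recording. First, under 0.1 mg rounding
roughly a fifth of narrow-GSD, low-mass trials genuinely have fewer than
three informative cut-points; the package reports these as degenerate
rather than guessing. Second, an independent reduction that fits the
lognormal CDF directly by nonlinear least squares agrees with the probit
line to well under 1% in median, but the two objectives weight rounded
tail points differently, so on a few percent of rounded trials the MMADs
differ by slightly more than 5%. Neither estimator is "right" on such
trials; the package follows the probit convention throughout.

## Mobility reduction

Mobility scans are channel-bounded number concentrations. Each channel is
represented by the geometric mean of its bounds (log-symmetric under the
lognormal assumption), and CMD/GSD are number-weighted geometric moments
rather than a fit — the conventional instrument-software reduction.
Truncation to a common range (e.g. 6–560 nm for SMPS/FMPS
inter-comparison) keeps channels by midpoint and never rescales. Mobility
diameter is treated as physical diameter for the density conversion.
Multiple-charge and diffusion-loss corrections are assumed already applied
by instrument software; inversion of raw signals is out of scope.

## The deposition model

`monodisperse_deposition()` marches one pause-free tidal breath through a
symmetric 24-generation airway tree with doubling airway counts
(Yeh/Schum-type whole-lung typical-path morphometry, embedded as a static
table and uniformly scaled so total model volume matches functional
residual capacity). Mechanism probabilities per generation:

* **Impaction** at bifurcation entry, `1 − (2/π)acos(θ·Stk) −
  (1/π)sin(2·acos(θ·Stk))` with the branching angle θ, applied on the
  inspiratory pass (the bifurcation carina is encountered going in);
* **Sedimentation** in an inclined tube over the transit time,
  `1 − exp(−4 v_s t cosφ / (π d))` with the gravity angle φ;
* **Diffusion** by the Gormley–Kennedy laminar penetration formula.

They combine independently as complements of survival products. Particle
mechanics (Cunningham slip, Stokes settling, Stokes–Einstein diffusion) are
evaluated at body temperature.

The tidal volume is discretised into plug-flow slices. Because inhaled air
is progressively stored in the expanding alveolar volume, the flow through
a generation tapers with the alveolar volume distal to it, distal transits
lengthen, and a slice's penetration depth is set by its time budget within
the inspiratory half-cycle. For volume consistency, the flow lost at each
respiratory generation carries a proportional part of the slice into
alveolar storage, where it resides until exhalation (quiescent settling
and first-eigenmode diffusion in alveolar dimensions) and then rejoins the
expiratory stream. In the alveolated respiratory generations the
sedimentation length scale is the alveolar sleeve dimension (default
0.028 cm at reference inflation, scaled with the lung) rather than the
duct lumen: a settling particle there reaches a septal wall long before it
could cross the full duct.

Head (extrathoracic) deposition uses empirical efficiency curves — a
saturating `1 − 1/(1 + a (d²Q)^p)` aerodynamic term and a
`1 − exp(−c √D Q^{−1/8})` diffusional term per route — blended by the oral
ventilation fraction and applied on both passes. The default
`mouth_fraction = 0.6` represents an oronasal mouth breather at rest:
measured ventilation splits for habitual mouth breathers at rest are near
60:40 oral:nasal, and purely oral extrathoracic collection at ~1 μm is only
1–3%, far below the head depositions regional models report for oronasal
breathing. The parameter is exposed for scenario analysis (e.g. pure mouth
puffing).

Breathing defaults are standard resting adult values: tidal volume
625 cm³, 12 breaths/min, half-cycle inspiration, FRC 3,300 cm³,
upper-airway volume 50 cm³. Regions: generations 1–16 are
tracheobronchial, 17–24 (plus alveolar storage) pulmonary; the exhaled
fraction is `1 − total` by construction, so the four fractions always
close to unity exactly.

`polydisperse_deposition()` integrates the monodisperse model over a
mass-basis lognormal with 64 log-spaced quadrature nodes spanning ±4
ln(GSD) and renormalised lognormal mass weights; halving or doubling the
node count changes every fraction by well under half a percentage point,
and GSD = 1 collapses to a single node.

With these defaults the six measured e-liquid distributions (MMAD
0.86–1.00 μm, GSD 1.36–1.43) give total depositions of about 21–26% with
head ≈ 7–10%, pulmonary ≈ 12–14%, tracheobronchial ≈ 2%, and ~77% exhaled
on average — the values `scripts/acceptance.R` computes. The
tracheobronchial share is the model's weakest point: at resting flows the
residence time in small conducting airways is short, and published regional
estimates that put ~6% there likely reflect different (unpublished)
ventilation parameters. Reported dose numbers should be read as
non-volatile-particle estimates with a few percentage points of model
uncertainty.

## Synthetic data

The generator exists so the whole pipeline can be exercised with known
truth. `simulate_impactor_trial()` allocates a prescribed total mass to
stages by exact lognormal interval masses under the ideal sharp-cut model
(top stage open above, backup filter below), draws substrate tares once,
and rounds pre- and post-masses to the balance resolution — rounding is
the only noise source, matching a gravimetric workflow whose dominant
uncertainty is the 0.1 mg balance. In the perfect-balance limit
(`balance_resolution = 0`) tares are omitted so net masses stay exact in
floating point. `simulate_mobility_scan()` applies a one-parameter
evaporation model — a volatile volume fraction `f` lost before sizing,
shrinking every diameter by `(1 − f)^{1/3}`, optionally inflating the GSD —
and bins the resulting number distribution onto the channel grid.
A single volume-fraction knob is deliberate: it reproduces the
impactor-vs-mobility-sizer discrepancy (a ~0.9 μm droplet shrinking to
~70 nm needs `f ≈ 0.9995`) without pretending to model evaporation
kinetics.

`simulate_study()` produces the default six-formulation study: two
humectant ratios, each plain / with flavourings / with nicotine, six trials
each, with per-formulation true MMAD/GSD (0.86–1.00 μm, 1.36–1.43) and
per-trial collected and consumed masses matching a two-puff low-flow
protocol; each trial pairs the impactor record with an undiluted
reference scan, an SMPS-like scan (moderate evaporation, widened spread)
and an FMPS-like scan (near-complete evaporation). True per-trial MMADs
carry a 2% lognormal jitter — trial-to-trial generation variability is not
separable from fit noise in gravimetric data, so a small configurable
value was fixed once. All randomness flows from one master seed through
deterministic child seeds; equal seeds give byte-identical studies.

What the generator does **not** emulate: impactor non-idealities (bounce,
wall losses, soft cut-point efficiency curves), counting statistics of
real mobility inversions (Poisson noise is available but off by default),
coil-temperature dynamics, and any time-dependent aerosol physics.
Passing recovery tests therefore demonstrates correctness of the
reduction chain under the stated instrument model, not robustness to every
real-world artefact.

## Statistics

`compare_formulations()` fits a one-way fixed-effects least-squares model
on trial-level values with formulation as the factor and runs Tukey HSD at
α = 0.05. A one-way six-level layout was preferred over a 2×3 factorial as
the default because the pairwise formulation contrasts are the quantities
of interest; the trial-level values can be re-grouped for a factorial
analysis if desired. The compact letter display is computed by
insert-and-absorb from the Tukey significance matrix itself, which
guarantees the letters are transitive-consistent with the reported
pairwise table (letter displays derived from a different simultaneous-
inference method can disagree with the studentized-range p-values on
borderline pairs).

## Numerical and interface choices

* Diameters are micrometres internally (channel bounds in nm at the I/O
  boundary); masses mg, concentrations μg/cm³, flows cm³/s.
* Validation failures raise classed conditions (`aerodose_invalid_input`,
  `aerodose_degenerate_fit`, `aerodose_empty_scan`) so pipelines can
  skip-and-log per trial; `run_study()` does exactly that and fails only
  if every trial of a formulation fails.
* CSV dialects carry metadata as `# key: value` comment lines above a
  plain table; `write_study_csv()` emits the same dialect the readers
  parse, plus a truth ledger.
* Problem sizes in the test suite (200 recovery trials, 50 oracle
  instances, 64-node quadrature, 40 breath slices) were chosen as the
  point where the measured quantities are stable to well inside the
  asserted tolerances.

## Known limitations

The deposition model treats droplets as non-volatile, insoluble spheres in
a single symmetric path: no hygroscopic growth, evaporation, coagulation,
cloud dynamics or vapour uptake, no asymmetric or stochastic lung
geometry, no mouth-hold. For semi-volatile e-cigarette aerosol these
dynamics are known to move regional doses by factors, not percent, so the
exhaled-fraction estimate is an indicator of secondhand-exposure
potential, not a prediction. The mobility route inherits whatever
evaporation occurred before sizing; its MMADs characterise the measured
(partially evaporated) aerosol, which is exactly the instrument bias the
synthetic generator reproduces.
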