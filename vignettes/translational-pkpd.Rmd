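---
title: "Translational PK-PD modelling for first-in-human dose selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Translational PK-PD modelling for first-in-human dose selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The modelling problem

Before a first-in-human trial of a bispecific HER2xHER3 IgG1 antibody there
are no human data at all.  What exists is (i) serum concentration-time data
from cynomolgus monkeys — the standard surrogate species for antibody
disposition, here with cross-reactive target binding, so the saturable
(target-mediated) clearance pathway is observable — and (ii) tumor-volume
data from a JIMT-1 breast-carcinoma xenograft study in mice, without any PK
sampling.  This package implements the chain that connects them: a
population PK model estimated on the monkey data, allometric projection of
its parameters to a 70 kg human and a 0.02 kg mouse, a
tumor-growth-inhibition model driven by the projected mouse exposure, and
the dose-selection calculus (safety margins against the monkey NOAEL
exposure, receptor occupancy, and exposure-matched dose translation) that
turns these models into a recommended flat dose range.

## The disposition model

Drug amount in the central compartment ($A_1$, mg; concentration
$C_1 = A_1/V_1$) and the peripheral compartment ($A_2$) follow

$$\frac{dA_1}{dt} = -\frac{CL}{V_1}A_1
  - \frac{V_{max}\,C_1}{K_m + C_1}
  - \frac{Q}{V_1}A_1 + \frac{Q}{V_2}A_2,
  \qquad
  \frac{dA_2}{dt} = \frac{Q}{V_1}A_1 - \frac{Q}{V_2}A_2 .$$

The parallel clearances reflect antibody physiology: a linear pathway
(FcRn-mediated catabolism, $CL$) and a saturable Michaelis-Menten pathway
approximating target-mediated disposition ($V_{max}$, $K_m$).  The full
binding/internalization machinery of a mechanistic TMDD model is
deliberately not modelled — with only serum concentrations to fit, the
Michaelis-Menten approximation is the identifiable reduction.  Internal
units are fixed at mg / L / h / kg throughout.

Typical values at the 70 kg human anchor (`human_default_params()`):
$CL$ 0.0125 L/h, $V_1$ 3.17 L, $Q$ 0.0313 L/h, $V_2$ 3.51 L,
$V_{max}$ 0.500 mg/h, $K_m$ 0.219 mg/L.

**Allometric scaling.**  Flows ($CL$, $Q$, $V_{max}$) scale with
$(W/70)^{0.75}$, volumes ($V_1$, $V_2$) with $(W/70)^{1}$.  $K_m$ is a
concentration, and because the antibody is fully cross-reactive with the
monkey receptors and the xenografts carry human target, it is carried
across species unchanged (a `scale_km` switch exists for sensitivity
work).  `mouse_default_params()` is exactly the human anchor projected to
0.02 kg.  Monkey body weights are not part of the published record;
`monkey_params(weight)` takes the weight explicitly and the study
generator draws weights uniformly from 2.5-3.5 kg, a typical cynomolgus
range.

**Dosing.**  Both intravenous and intraperitoneal administration are
modelled as instantaneous boluses into the central compartment.  For the
human simulations this choice is forced by consistency: the published
occupancy table is reproduced exactly by $C_{max} = \mathrm{dose}/V_1$,
i.e. by a bolus with no infusion duration.  For mouse i.p. dosing no
absorption model is available; bioavailability is exposed as a regimen
attribute and defaults to 1.

## The statistical model

Between-subject variability is lognormal,
$P_i = P_{pop} e^{\eta_i}$, $\eta_i \sim N(0, \omega^2)$, on $CL$ (CV
13.2%) and $V_1$ (14.6%) in the PK model and on $Base$ (20.6%), $K_G$
(55.1%) and $K_D$ (35.5%) in the tumor model.  Reported CVs are treated as
lognormal CVs and converted by $\omega^2 = \ln(1 + CV^2)$, the standard
pharmacometric convention.  Residual error is combined proportional +
additive for concentrations ($\sigma_p$ 0.108, $\sigma_a$ 0.039 mg/L
fixed) and proportional-only for tumor volumes ($\sigma_p$ 0.256); draws
are independent across observations.

**Quantification limit.**  The assay LLOQ is 0.078 mg/L.  Per subject, the
first observation below the limit is retained imputed at LLOQ/2
(0.039 mg/L) and later ones are dropped; the fixed additive error
component (itself LLOQ/2) carries the uncertainty of the imputed points in
the likelihood.  More elaborate censored-likelihood treatments (M3/M4) are
out of scope.

## Estimation

The original analysis used NONMEM's FOCE-I.  That algorithm is not
reproduced bit-for-bit; the published typical values, not objective
function values, are the reproduction surface.  Two marginal-likelihood
approximations are provided:

* **Laplace** (default): per subject, the conditional mode of
  $g(\eta) = -\log p(y\mid\eta) - \log\phi(\eta)$ is found and
  $-2\log L_i \approx 2g(\hat\eta) + \log\det H_g(\hat\eta) - d\log 2\pi$.
  The implementation is validated in the test suite against brute-force
  32-node Gauss-Hermite quadrature (agreement within 0.1 objective units
  on a toy dataset).
* **First-order (FO)**: linearization at $\eta = 0$.  Cheap and adequate
  for the PK model (moderate CVs; a 20-replicate probe shows about -2%
  median bias on $CL$), but demonstrably biased for the tumor model, whose
  55% CV on $K_G$ makes the linearization poor — the tests document that
  the FO objective prefers a distorted optimum there.  Replicate PK
  recovery therefore uses FO, replicate tumor recovery uses Laplace.

Optimization is over log-parameters (positivity by construction) with
`nlminb`.  Two structural speed paths matter:

* the FO PK objective stacks every subject and every $\eta$ finite
  difference into one batched ODE solve (compiled right-hand side), since
  solver-call overhead otherwise dominates;
* for the tumor model the course is conditionally structured in the
  random effects, $f(t;\eta) = e^{-K(t)}\,(Base\,e^{\eta_1} +
  K_G e^{\eta_2} J(t))$ with $K$ proportional to $K_D e^{\eta_3}$, so the
  per-mouse mode search uses fully analytic gradients over precomputed
  per-arm integrals, and the outer gradient uses the envelope theorem
  (modes frozen, $\partial g/\partial\eta = 0$ at the mode).  `nlminb` may
  label the final step "false convergence" because that gradient omits
  the slowly varying $\log\det H$ term; the returned optimum is kept and
  in practice improves on the start by a wide margin.

`fit_pk()` fixes $K_m$ and the additive SD by default — both were fixed in
the published monkey estimation (the table marks them "Fixed"); either can
be freed via `fix`.  $K_m$ identification requires saturation contrast, so
at least two dose levels are enforced.  Relative standard errors come from
the observed information matrix on the log scale (so they read directly as
percent); a seeded bootstrap was considered and rejected as unnecessary
for the reproduction surface.  Multi-start jitter is available
(`n_starts`); the default is a single start because fits initialized at
plausible values converge reproducibly here, and replicate studies are
initialized at the generating values, the standard convention in
simulation-estimation work.

Model comparison uses the likelihood-ratio rule at $p < 0.01$: a drop in
$-2\log L$ greater than $\chi^2_{0.99}(df)$, i.e. 6.63 for one added
parameter.

## Exposure metrics and dose selection

`exposure_table()` simulates a single typical-subject bolus per flat dose
(no variability — the published occupancy table is reproduced only under
typical-subject simulation) over a 504 h (q3wk) cycle and derives:

* **AUC(0-inf)** — by non-compartmental convention (default): linear-up /
  log-down trapezoid on a dense 1 h grid to cycle end, extrapolated by
  $C_{last}/\lambda_z$ with $\lambda_z$ the local terminal log-slope.
  This convention matters: with saturable clearance the local slope at
  504 h is shallower than the eventual linear washout whenever
  concentrations still exceed $K_m$ there, so the NCA value exceeds the
  true integral by several percent at high doses (900 mg: 41.1 vs
  39.3 g.h/L).  The published exposures follow the NCA convention, which
  reproduces every reported row to three significant figures;
  `auc_inf(method = "exact")` provides the true integral (integration
  until $C < 10^{-6}$ mg/L plus the analytic linear tail) and is the one
  with the theoretical limits $AUC/dose \to 1/(CL + V_{max}/K_m)$ and
  $\to 1/CL$.
* **$C_{max}$** = dose/$V_1$; **$C_{trough}$** = $C(504\,h)$;
  **$C_{ave}$** = AUC(0-inf)/504 h.  $C_{ave}$ is nowhere defined in the
  published analysis; this definition reproduces the reported average
  occupancies.
* **Receptor occupancy** $\%RO = 100\,C/(K_m + C)$ at each of the three
  concentrations — the half-saturation constant of the target-mediated
  clearance doubles as the binding constant.
* **Safety margin** = 193 g.h/L (mean monkey AUC at the 100 mg/kg NOAEL) /
  predicted AUC, reported rounded to the nearest integer.

Display rounding follows the reporting conventions: AUC to 3 significant
figures, occupancy to one decimal, margin to the nearest integer.  One
documented inconsistency: the published margins at 10/20/40 mg (226, 1930,
585) cannot be produced from the published AUCs by the stated formula
(which gives about 6100, 1911, 576); rows from 80 mg upward are internally
consistent.  The implementation reproduces the formula and treats the
low-dose printed margins as erroneous.

**Km sensitivity.**  Because $K_m$ is by far the least precisely estimated
parameter, `km_sensitivity()` re-simulates the ladder over a 100-fold
range (0.0219-2.19 mg/L; the exposure itself changes with $K_m$, not just
the occupancy formula) and reports the smallest dose meeting an occupancy
criterion.  The criterion is a required argument because no single
criterion reproduces all published sensitivity statements: 750 mg at
$K_m$ = 2.19 follows from "$RO(C_{max}) \ge 99\%$", while 160 mg at
$K_m$ = 0.0219 requires "$C_{max}$ and $C_{ave}$".  Occupancies are
compared after rounding to one decimal (the reporting precision).  Note a
knife-edge at the estimated $K_m$: the 360 mg $C_{ave}$ occupancy computes
to 98.95%, exactly on the 99.0% rounding boundary, so the combined
criterion can resolve to either 360 or 480 mg depending on sub-0.1%
differences in the AUC convention.

## The tumor model

Tumor volume $T$ (mm^3) and a dimensionless drug-effect state $I$ follow

$$\frac{dI}{dt} = K_{io}\Big(1 - \frac{E_{max,g}\,C}{EC_{50}+C}\Big)
  - K_{io}\,I, \qquad I(0)=1,$$
$$\frac{dT}{dt} = K_G\,(1+\lambda t)\,I
  - K_D\,\frac{E_{max,d}\,C}{EC_{50,KD}+C}\,T, \qquad T(0)=Base,$$

with $C(t)$ from the scaled mouse PK model and both maximum effects fixed
at 1.  Published estimates: $Base$ 177 mm^3, $K_G$ 0.338 mm^3/h, $K_D$
0.004 1/h, $K_{io}$ 0.143 1/h, $EC_{50}$ 2.60 mg/L, $EC_{50,KD}$
0.0102 ug/L (stored internally as 1.02e-5 mg/L), $\lambda$ 0.172 week^-1
(converted by /168 to hours).

Four structural choices deserve explanation:

* **Units of $K_G$ and $K_D$.**  The published parameter table prints
  $K_G$ in hr^-1 and $K_D$ in mm^3/h, while the accompanying summary
  describes a *zero-order* growth rate and a *first-order* dying rate.
  The units are treated as transposed: $K_G$ in mm^3/h (zero-order),
  $K_D$ in 1/h (first-order).
* **The kill term switches off without drug.**  The drug effect on $K_D$
  is a stimulatory Emax from a zero drug-free baseline.  Had the
  first-order kill acted in the vehicle arm, untreated tumors at the
  published values would shrink ($K_G - K_D \cdot Base = 0.338 - 0.708
  < 0$), contradicting the observed vehicle growth; and the extremely low
  $EC_{50,KD}$ is interpreted as the natural dying rate of a tumor whose
  growth signalling is blocked — present at any measurable exposure,
  absent without drug.
* **Progression.**  "Increasing growth rate over time" is implemented as
  the multiplicative inflation $K_G(1+\lambda t)$ with $t = 0$ at
  treatment start; an exponential variant $K_G e^{\lambda t}$ sits behind
  `progression = "exponential"`.  The linear form makes the vehicle curve
  a closed-form quadratic, $T = Base + K_G(t + \lambda t^2/2)$, used as an
  oracle throughout the tests.
* **The effect state gates the whole growth flux** $K_G(1+\lambda t)$,
  not $K_G$ alone — a single growth flux with one gate; the published
  schematic does not disambiguate the two readings.

`stasis_metric()` evaluates $T(\mathrm{day}\,21)/T(0)$ after three weekly
doses; a ratio at or below 1 is stasis-or-regression.
`auc_matched_mouse_dose()` finds by bisection the weekly mouse dose whose
total 3-dose exposure (true integral) equals the human single-dose AUC
(reporting convention).  The exact matching convention behind the
published 9.5/20/24 mg/kg translations of 360/750/900 mg is not stated;
this convention lands at 9.7/22/27 mg/kg — the right scale, not the exact
figures — and the stasis conclusion is insensitive to the difference
(every regimen from about 2 mg/kg weekly upward reaches stasis at the
published tumor parameters).

## The synthetic-data generator

No animal-level data are deposited with the original analysis, so the
generator recreates *study-shaped* datasets with exactly the statistical
structure the models assume:

* monkey PK: the single-dose design (3 dose groups x 2 animals, 14
  samples over 0-1007 h) and the first week of the repeat-dose design
  (6/6/10 animals, 10 samples over 0-168 h); weight-based doses; weights
  uniform on 2.5-3.5 kg; lognormal deviates on $CL$ and $V_1$; combined
  residual error; the LLOQ rule applied.  Exact sampling times within the
  reported windows are not published; the defaults are a conventional
  rich grid and are configurable.
* xenograft: vehicle/2.5/25 mg/kg arms of 10 mice; weekly i.p. dosing x4;
  twice-weekly caliper grid (days 0, 3, 7, 10, ...); proportional noise;
  informative dropout — records stop at the first *observed* volume at or
  above 800 mm^3, or day 68.

**Baseline truncation and what recovery can show.**  Per-mouse baselines
are drawn lognormally around $Base$ = 177 (CV 20.6%) and redrawn until
inside the reported 108-172 mm^3 window.  Since 177 lies above that
window, the realized baseline distribution has geometric mean ~149 mm^3,
and a lognormal location estimator fit to such data is consistent for
*that* value, not for 177.  The recovery tests therefore compare the
median $Base$ estimate to the truncated-lognormal geometric mean computed
in closed form from the generator settings.  This is the honest reading
of a recovery study: the estimator is validated against the distribution
that generated the data.

More generally, passing recovery tests on these datasets shows that the
estimation machinery is consistent *when the model is true*.  The
generator does not emulate model misspecification, anti-drug-antibody
kinetics (the reason only week-1 repeat-dose data are used), sex effects
(recorded, never used), assay drift, or the faster true clearance of
humanized antibodies in rodents — so recovery success says nothing about
structural model adequacy on real animals.

## Numerical choices

* Stiff solver (`lsoda`, compiled right-hand sides) at rtol 1e-8 /
  atol 1e-10 mg for user-facing simulation (1e-10/1e-12 where courses are
  compared against closed forms); dose events are hard integration
  breakpoints, with the post-dose state reported at a dose time.
* States below -1e-6 mg abort with a diagnostic; smaller negative
  excursions are clipped to zero.
* The tumor likelihood integrates on a fixed 1 h grid with trapezoidal
  quadrature and an exponential integrator for $I$ (exact for the vehicle
  closed form; within ~1% of the stiff solver for treated courses, which
  is well inside the 25.6% residual noise the likelihood weighs against).
* NCA AUC uses a 1 h grid, lin-up/log-down trapezoid, $\lambda_z$ from
  the last three grid points.
* Bisection for dose matching brackets from a linear-clearance guess and
  stops at 1e-4 relative AUC error.
* Replicate study sizes used by the tests: 100 monkey studies (28 animals
  each, FO likelihood) and 100 xenograft studies (30 mice each, Laplace
  likelihood), both initialized at the generating values with fixed
  seeds; the tumor Laplace machinery makes a full xenograft fit take a
  few seconds, which is what makes 100-fold replication practical.

## Known limitations

* No mechanistic TMDD, no FcRn model, no covariates (sex was recorded but
  never modelled), no inter-occasion variability, no random-effect
  correlations (none reported).
* FO remains the PK recovery workhorse; its small negative bias on $CL$
  (about -2%) is documented rather than corrected.
* The AUC-matched translation convention is underdetermined by the
  published record (see above); the implementation exposes it as an
  argument rather than pretending to know it.
* Human predictions inherit every allometric assumption; nothing in the
  package validates the 0.75/1.0 exponents themselves.
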