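# transpkpd

Translational PK-PD modelling and first-in-human dose selection for a
bispecific HER2xHER3 IgG1 antibody.

Before a first-in-human trial there are no human data: what exists is
serum PK from cynomolgus monkeys (the standard surrogate species for
antibody disposition, with cross-reactive target binding) and tumor-volume
data from a JIMT-1 breast-carcinoma xenograft study in mice with no PK
sampling.  This package implements the chain that connects those two
datasets to a clinical dose recommendation, for pharmacometricians and
translational scientists who want the whole calculation reproducible and
testable end to end.

## The models

**Disposition** — two-compartment model with parallel linear and
Michaelis-Menten (target-mediated) clearance:

    dA1/dt = -(CL/V1) A1 - Vmax C1/(Km + C1) - (Q/V1) A1 + (Q/V2) A2
    dA2/dt =  (Q/V1) A1 - (Q/V2) A2,          C1 = A1/V1

estimated on monkey data and projected across species by allometry
(`(W/Wref)^0.75` on CL, Q, Vmax; `^1` on V1, V2; Km carried unchanged).

**Tumor growth inhibition** — zero-order growth inflated by a progression
factor and gated by an indirect-response effect state, plus a drug-switched
first-order kill:

    dI/dt = Kio (1 - C/(EC50 + C)) - Kio I,            I(0) = 1
    dT/dt = KG (1 + lam t) I - KD C/(EC50_KD + C) T,   T(0) = Base

with C(t) from the mouse-scaled PK model.

**Dose selection** — per flat q3wk dose: AUC(0-inf) by non-compartmental
convention, safety margin = 193 g.h/L (monkey NOAEL exposure) / AUC,
receptor occupancy %RO = 100 C/(Km + C) at Cmax, Cave and Ctrough, a Km
sensitivity sweep, and AUC-matched translation of clinical doses into
weekly mouse regimens evaluated for day-21 tumor stasis.

The package also contains the statistical layer (lognormal between-subject
variability, combined residual error, quantification-limit handling),
maximum-likelihood estimation (Laplace approximation with analytic
conditional-mode machinery for the tumor model, validated against
Gauss-Hermite quadrature; a fast first-order option), and generators for
study-shaped synthetic datasets so every stage is testable without animal
data.  See the vignette (`vignettes/translational-pkpd.Rmd`) for the
modelling decisions and their rationale.

## Worked example

```r
library(transpkpd)

human <- human_default_params()
mouse <- mouse_default_params()   # allometric projection to 0.02 kg
signif(mouse$CL, 3)
#> [1] 2.75e-05

format_exposure_table(exposure_table(human, doses = c(360, 480)))
#>   dose_mg auc_g_h_L safety_margin ro_cmax ro_cave ro_ctrough
#> 1     360      10.4            19    99.8    98.9       23.8
#> 2     480      16.0            12    99.9    99.3       75.7
```

A 360 mg flat dose given every three weeks has a predicted exposure of
10.4 g.h/L — a 19-fold margin below the monkey no-adverse-effect exposure —
and keeps better than 99% of target receptors occupied at the concentration
peak (and ~99% on average over the cycle), though only 24% at trough.

```r
# which dose clears 99% occupancy at Cmax if Km were 10x larger?
km_sensitivity(human, km_values = 2.19, criterion = c(cmax = 99))
#>     km threshold_dose
#> 1 2.19            750

# translate 360 mg q3wk into a weekly mouse regimen and test for stasis
m <- auc_matched_mouse_dose(360)
round(m$weekly_dose_mg_per_kg, 1)
#> [1] 9.7
tc <- simulate_tumor(pd_params(), mouse,
                     weekly_regimen(m$weekly_dose_mg, 3), seq(0, 504, 6))
stasis_metric(tc, day = 21)$ratio
#> [1] 0.4932025
```

The exposure-matched mouse regimen roughly halves tumor volume by day 21
(ratio < 1 = stasis or regression), while the vehicle arm progresses.

## The analysis, as scripts

`analysis/01_simulate_studies.R` through `analysis/05_dose_translation.R`
run the chain as a narrative: generate the two synthetic studies, fit the
PK model and scale it, build the exposure / occupancy table and Km sweep,
fit the tumor model (including the likelihood-ratio check of the
progression term), and translate the proposed clinical doses back into
mouse regimens.  Each stage prints what it found and writes its tables
under `results/`.  `run_pipeline()` performs the same sequence as a single
seeded, config-driven call.

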