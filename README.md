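# edcrisk

Reverse dosimetry and probabilistic health-risk assessment for urinary
biomonitoring of parabens (methyl-, ethyl-, propyl-) and bisphenol A.

Human-biomonitoring surveys measure these short-lived endocrine-disrupting
chemicals in spot urine. Turning such measurements into a population risk
statement takes a chain of standard but error-prone steps: left-censored
concentrations must be handled (LOD/2 substitution), corrected for urine
dilution (creatinine adjustment), back-calculated to an external dose
(reverse dosimetry), compared against health-based reference doses
(hazard quotients and a dose-additive hazard index), propagated through a
Monte Carlo simulation to express population variability, and screened
against dietary-recall data for food-group drivers of exposure (Spearman,
mutually adjusted regression, g-computation). `edcrisk` implements that
chain as tested, seeded, composable R functions, for exposure scientists
and epidemiologists who need the pipeline to be reproducible end to end.

## The core model

Estimated daily intake by reverse dosimetry:

```
EDI = UE × CE / (F_UE × BW)        [µg/kg-bw/day]
```

where `UE` is the creatinine-adjusted urinary concentration
(µg/g-creatinine), `CE` the daily creatinine excretion (g/day) predicted
from age, sex, body weight and height via the Mage equations (adults:
`k·(140 − age)·BW^1.5·ht^0.5·10⁻⁶`, k = 1.93 males / 1.64 females; minors:
height-only forms), `F_UE` the urinary excretion fraction (17.4% MP,
13.7% EP, 8.6% PP, 100% BPA) and `BW` body weight (kg). Risk is
characterised as `HQ = EDI / (ADI or TDI)` with `HI = HQ_MP + HQ_EP +
HQ_PP`; HQ or HI ≥ 1 flags potential risk. Reference doses: EFSA ADI
10 mg/kg-bw/day (MP, EP), EMA ADI 1.25 mg/kg-bw/day (PP), EFSA 2023 TDI
0.2 ng/kg-bw/day (BPA).

Because individual-level survey data are not publicly deposited, the
package ships a synthetic-population generator
(`default_population_spec()`, `simulate_study()`) that emulates the survey
structure — four age strata (6–11, 12–18, 19–64, 65+ years; 706 subjects),
12 dietary-recall food groups, censored-lognormal biomarkers — with known
ground truth, so every estimator is testable.

## Worked example

One adult subject, then the population-level bound:

```r
library(edcrisk)

# 40-year-old male, 70 kg, 170 cm, at the population-median MP level
ce  <- creatinine_excretion(age = 40, sex = "male",
                            body_weight = 70, height = 170)
edi <- estimate_daily_intake(ue = 17.54, ce = ce, f_ue = 0.174, bw = 70)
c(ce = ce, edi = edi)
#>     ce    edi
#> 1.4738 2.1223
hazard_quotient(edi, 10, rfd_units = "mg")
#> 0.0002122
```

This subject excretes 1.47 g creatinine/day; his median-level MP burden
back-calculates to 2.12 µg/kg-bw/day, about 1/5000th of the ADI.

At the population level, the deterministic upper bound on cumulative
paraben risk (hazard index at the published intake maxima, per age group):

```r
hazard_index_bound()
#> # A tibble: 4 × 6
#>   stratum   hq_MP    hq_EP  hq_PP     hi exceeds
#> 1 6-11    0.0355  0.00364  0.0194 0.0586 FALSE
#> 2 12-18   0.00479 0.00163  0.0255 0.0319 FALSE
#> 3 19-64   0.0148  0.00145  0.0239 0.0402 FALSE
#> 4 65+     0.0143  0.000852 0.0190 0.0341 FALSE
```

Even at the most exposed group's maximum intakes the paraben hazard index
is 0.0586 — a factor ~17 below the risk threshold of 1. BPA is the
opposite story: reconstructing the 6–11-year EDI distribution from its
published quartiles and running the Monte Carlo against the 0.2
ng/kg-bw/day TDI,

```r
mc_exceedance_from_quantiles(c(0.25, 0.5, 0.75), c(0.02, 0.03, 0.05),
                             rfd = 0.2, rfd_units = "ng", seed = 1)$exceedance_pct
#> 100
```

every one of 10,000 simulated children exceeds the tolerable daily intake.

The full pipeline (synthetic generation → processing → dosimetry → risk →
Monte Carlo → dietary association, with a manifest of seeds and checksums)
runs as:

```r
run_pipeline(pipeline_config(seed = 1, output_dir = "out"))
# or from a shell:
# Rscript inst/scripts/run_pipeline.R --seed 1 --out out
```

## Package layout

- `R/synthetic-population.R` — survey-structure generator with calibrated
  defaults
- `R/biomarker-processing.R` — censoring, creatinine adjustment, summaries
- `R/dosimetry.R` — Mage creatinine-excretion equations, EDI
- `R/risk-characterization.R` — reference doses, HQ/HI, published-summary
  bounds
- `R/probabilistic-risk.R` — distribution fitting, K-S selection, Monte
  Carlo engine
- `R/dietary-association.R` — Spearman screen, adjusted regression,
  g-computation
- `R/pipeline.R` — configuration-driven runner and input validation
- `vignettes/edc-risk-methods.Rmd` — model assumptions, calibration
  choices, limitations
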