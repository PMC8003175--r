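# bonemed

Mediated multilevel models of muscle strength and bone development.

## The problem

The *functional model of bone development* holds that the dominant
mechanical stimulus for bone strength accrual in growing children is muscle
force: maturity, body size, physical activity and diet are expected to act
on bone largely *through* muscle. Testing this requires (i) longitudinal
bone and muscle measurements — here quantitative-ultrasound speed of sound
(SOS, m/s) at the radius and tibia, isometric grip strength and knee-extension
peak torque — and (ii) a model that splits each modulator's influence into a
direct bone effect and an indirect, muscle-mediated effect, while respecting
the hierarchical structure of repeated annual measurements nested in
participants.

`bonemed` implements that analysis as a reusable, tested pipeline for
biostatisticians working with mixed-longitudinal pediatric cohorts: a
two-equation mediated system estimated by maximum likelihood with participant
random intercepts, delta-method (Sobel) inference for mediated effects,
Chow-type Wald tests of coefficient equality between strata, and — because
such cohort data are typically under restricted access — a calibrated
synthetic-cohort generator so every stage can be exercised end to end.

## The model

For participant *i* at session *t*, with bone outcome *Y* (SOS z-score),
mediator *M* (muscle-strength z-score), bone-equation modulators **Z**
(NTX, PAQ-C, maturity offset, BMI) and muscle-equation modulators **W**
(maturity offset, BMI, bone age, WAeq, energy intake):

    Y_it = b0 + b1 M_it + Th' Z_it + g_i + e_it        (bone equation)
    M_it = W_it' Om     + d_i + u_it                   (muscle equation)

with normal random participant effects `g_i`, `d_i` (level 2) and residuals
`e_it`, `u_it` (level 1). The system is recursive, so the two equations are
fitted separately, each by profiled ML on its own complete cases
(`fit_random_intercept()`; a pooled two-site variant stacks radial and tibial
rows and adds a session-level intercept, `fit_nested_intercepts()`). Effects
per modulator *w*:

* direct: the bone-equation coefficient `Th_w` (0 if *w* is not in **Z**);
* indirect: `Om_w * b1`, with first-order delta (Sobel) standard error
  `sqrt(b1^2 var(Om_w) + Om_w^2 var(b1))`;
* total: `direct + indirect`, with the delta variance including
  `cov(Th_w, b1)` from the bone-equation coefficient covariance.

All variables are z-standardized once on the whole analysis set, so
coefficients are comparable across equations, sites and strata.

## Worked example

```r
library(bonemed)

out <- generate_cohort(cohort_config(seed = 1))   # 180 participants, 434 rows
exc <- apply_exclusions(out$table)
exc$log
#> <bm_exclusion_log> 434 -> 406 rows (diabetes_t1=6, fracture=8,
#>                                     sos_undetected=11, missed_visit=3)

vars <- c("radial_sos", "tibial_sos", "grip_strength", "knee_extension",
          "ntx", "paqc", "maturity_offset", "bmi", "bone_age", "waeq",
          "energy_intake")
std <- zstandardize(exc$table, vars)
sem <- fit_mediated_system(std, default_model_spec("pooled"))
render_table(sem, "table2")
```

```
                        modulator              bone           muscle         indirect            total
                  muscle_strength  0.255 ***(0.045)
   NTX (nmol BCE/mmol creatinine) -0.215 ***(0.034)
                    PAQ-C (score)    0.078 *(0.031)
Maturity offset (years from aPHV)  0.287 ***(0.048)  0.152 **(0.053)   0.039 *(0.015) 0.326 ***(0.047)
                      BMI (kg/m2)  -0.120 **(0.044) 0.170 ***(0.038) 0.043 ***(0.012)   -0.077 (0.045)
                 Bone age (years)                   0.537 ***(0.051) 0.137 ***(0.027) 0.137 ***(0.027)
                       WAeq (MET)                      0.025 (0.026)    0.006 (0.007)    0.006 (0.007)
         Energy intake (kcal/day)                     0.064 *(0.026)   0.016 *(0.007)   0.016 *(0.007)
```

Cells are standardized coefficients with standard errors in parentheses
(`*` p < 0.05, `**` p < 0.01, `***` p < 0.001). Reading this fit: muscle
strength has a strong positive direct effect on bone SOS (0.255) and NTX, the
bone-resorption marker, a negative one; maturity acts on bone both directly
(0.287) and through muscle (0.039) — partial mediation — while skeletal
maturity (bone age) has no direct bone path, so its entire effect (0.137) is
muscle-mediated:

```r
classify_mediation(sem, "bone_age")          #> "full"
classify_mediation(sem, "maturity_offset")   #> "partial"
```

Stratum comparisons and the whole-pipeline runner:

```r
boys  <- fit_mediated_system(std[std$sex == "male", ],
                             default_model_spec("pooled"), stratum = "male")
girls <- fit_mediated_system(std[std$sex == "female", ],
                             default_model_spec("pooled"), stratum = "female")
chow_test(boys, girls, equation = "bone", exclude = "bmi")

run_pipeline(run_config(input = cohort_config(seed = 1), out_dir = "out"))
```

`run_pipeline()` writes `table1.csv` (within/between summary moments),
`effects_<site>_<stratum>.csv`, the publication-shaped `table2/3/4.csv`,
`exclusions.json`, `chow.json` and a `manifest.json` with content hashes.
External CSV cohorts are read with `read_cohort(path, schema = ...)`; a tiny
synthetic example lives in `inst/extdata/tiny_cohort_synthetic.csv`.

## Scope

The package consumes maturity offset, bone age, BMI, PAQ-C, WAeq and energy
intake as inputs (instrument scoring, anthropometric regressions and assay
chemistry are out of scope; `correct_ntx()` and `compute_waeq()` cover the
two derivations the analysis itself defines). See the methods vignette
(`vignettes/bone-muscle-mediation.Rmd`) for the estimation details, the
generator's design and its limitations.
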