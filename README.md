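# anolechroma

Color-morph extraction and seasonal–thermal modeling for green anole
(*Anolis carolinensis*) field photographs.

Green anoles shift reversibly between **green** and **brown**
presentation. Whether that physiological color change serves crypsis,
social signaling, or thermoregulation can be probed at range scale by
scoring the presenting morph in thousands of segmented, geolocated,
dated field photographs and modeling it against season and reconstructed
ambient temperature. `anolechroma` implements that pipeline for
ecologists working with community-science imagery:

1. **Dominant color**: the masked organism pixels are quantized by
   k-means (k = 4); the largest cluster's centroid is the segment's color.
2. **Morph label**: *green* iff `G > R + 2`, *brown* iff `R > G + 5`,
   otherwise *unclear* (excluded from models, kept in outputs).
3. **Crypsis indices**: greenness `G/(R+G+B)` of the organism and of the
   **background ring** (pixels within Chebyshev distance 20 of the mask).
4. **Hourly temperature**: observations are assigned to 25-km grid cells;
   daily min/max are turned into the hour-of-observation temperature by a
   sine (daytime, period stretched by 4 h) / logarithmic-decay (night)
   diel model with solar sunrise/sunset.
5. **Models + AIC selection**, all with green = 1:
   - binomial GLMs: morph ~ temperature, + season (breeding = Apr 1–Sep 30),
     and the interaction with a separate temperature slope per season;
   - binomial GAMs (mgcv): morph ~ cyclic cubic spline of week (period
     52), rank-3 thin-plate smooth of latitude, and their tensor-product
     interaction;
   - OLS: organism greenness ~ background greenness, with a
     temperature-confounder check.
   `AIC = deviance + 2·edf` (exact for Bernoulli fits); `aic_compare`
   reports the best model and `delta_aic = best − runner-up (≤ 0)`.
6. **Synthetic world**: `gen_synth_bundle()` generates segment images,
   observation tables, and daily temperatures from a known
   logistic/thermal model (temperature effect only outside the breeding
   season; a latitude-amplified seasonal cosine; sinusoidal climate), so
   the whole pipeline is testable against planted truth.

## Worked example

```r
library(anolechroma)
cfg <- default_pipeline_config(seed = 42, n_records = 1000)
report <- run_pipeline(cfg)
print(report)
#> <anole_report: 1000 records in, 952 modeled
#>   unclear excluded: 28; missing-temperature drops: 20
#>   GLM best: temp_by_season_interaction (delta AIC -29.6); GAM best: week_by_lat_interaction (delta AIC -11.9)
#>   background matching: slope -0.159, R^2 0.004>
```

The retention log says 1000 simulated records entered, 28 were excluded
as unclear-colored, 20 lost their temperature lookup, and 952 reached the
models; both model families select the interaction structure that was
planted. The per-season temperature slopes recover the planted world
(0.12 logit/°C outside the breeding season, 0 within):

```r
report$glm$fits[[3]]$season_slopes
#>        season   slope     se     z  p_value
#> 1 nonbreeding  0.1696 0.0229  7.39 1.44e-13
#> 2    breeding -0.0167 0.0245 -0.68 4.96e-01

report$gam$table
#>                     model deviance     edf     aic
#> 1               week_only  1168.15 4.76258 1177.67
#> 2           week_plus_lat  1165.25 5.75704 1176.77
#> 3 week_by_lat_interaction  1147.11 8.87814 1164.87

validate_against_truth(report)[c("label_accuracy", "temp_rmse")]
#> $label_accuracy
#> [1] 0.956
#> $temp_rmse
#> [1] 0
```

Temperature reconstruction is an exact composition identity on synthetic
bundles (RMSE 0); the 4.4% label error is the planted-unclear organisms
that pixel noise pushed out of the narrow unclear band. Seasonal
prediction curves at the 10th/50th/90th latitude percentiles (with 95%
CIs back-transformed from the logit scale) are in
`report$curves$seasonal`; temperature curves per season in
`report$curves$temperature`.

## Command line

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","anole-chroma.R",package="anolechroma"))')" \
    run-all --config config.yaml --out report/
```

Subcommands: `simulate`, `extract-colors`, `attach-temperature`,
`fit-models`, `run-all`, `validate`; chained stages reproduce `run-all`
bit-for-bit on the same bundle.

## Further reading

The methods vignette (`vignettes/anolechroma-methods.Rmd`) documents the
models and their assumptions, the diel temperature formulas, every
numerical choice (tie-breaks, tolerances, degenerate inputs), what the
synthetic world does and does not emulate, and the design notes behind
the acceptance tests.
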