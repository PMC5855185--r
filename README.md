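# semgrip

Handgrip force estimation from surface electromyography (SEMG) by
wavelet scale selection.

## What it does, and for whom

SEMG amplitude tracks grip force well enough to serve as an indirect
force sensor, but during prolonged force-varying contractions the signal
is progressively contaminated — fatigue shifts power toward low
frequencies and motion artifact pollutes the low-frequency bands — and a
force estimator built on the whole signal degrades. `semgrip` is for
biomedical-signal researchers and ergonomists who want a principled way
to decide *which parts* of the SEMG time–scale decomposition to trust.

The pipeline:

1. **Features.** Continuous wavelet transform with the Daubechies-2
   wavelet at integer scales p = 1..10 (nominal central frequencies
   f(p) = 727.27/p Hz at 1000 Hz sampling), reduced to frame-wise RMS
   intensities e(p) with 200 ms frames and 200 ms moving-average
   smoothing.
2. **Model.** A no-intercept second-order polynomial fitted by ordinary
   least squares on MVC-normalized data:

   F̂ = Σₚ ( θ₁ₚ e(p) + θ₂ₚ e(p)² ),  F in %MVC.

3. **Sensitivity.** For each scale, the variance of its model term
   θ₁ₚu + θ₂ₚu² under 100,000 uniform draws u ~ U(0, 100) — the
   first-order variance contribution of that scale (the model is
   additive, so no interactions exist) — normalized to sum to one and
   averaged over per-minute segments. A finite-difference convergence
   experiment over draw counts justifies the 100,000.
4. **Selection (SCA).** Scales are ranked by ascending mean sensitivity;
   ten nested wavelet scale combinations (WSC I..X) are formed by
   removing the most sensitive remaining scale in turn; each combination
   is refit on training data and scored by validation RMSE
   (Eq: RMSE = sqrt(mean((F_actual − F̂)²))); the minimal mean windowed
   RMSE wins.

Baselines included: the classical linear RMS-envelope model (method A)
and the fixed scales-{2,3} polynomial model (method B). A synthetic
SEMG/force generator with force-coupled bands, fatigue-like drift and
broadband noise makes the whole pipeline testable without laboratory
data.

## Worked example

Simulate a training session (ramped force-varying analysis task) and a
held-out force-varying validation task with fatigue-like drift, then run
the full selection pipeline:

```r
library(semgrip)
res <- synthetic_force_study(seed = 7, drift_rate = 0.1,
                             train_task = "analysis")
round(res$mean_sensitivity, 3)
#>    s1    s2    s3    s4    s5    s6    s7    s8    s9   s10
#> 0.012 0.012 0.021 0.025 0.129 0.148 0.305 0.154 0.153 0.041
res$report
#> <selection_report> 10 combinations (windowed RMSE, 10-s windows)
#>  serial               scales rmse_mean rmse_overall rmse_min rmse_max flagged
#>       I 1,2,3,4,5,6,7,8,9,10     2.645        2.854   1.0066    5.713   FALSE
#>      II   1,2,3,4,5,6,8,9,10     2.647        2.856   1.0184    5.652   FALSE
#>     III     1,2,3,4,5,6,9,10     2.638        2.842   1.0227    5.598   FALSE
#>      IV       1,2,3,4,5,6,10     2.644        2.849   1.0202    5.614   FALSE
#>       V         1,2,3,4,5,10     2.671        2.890   1.0367    5.646   FALSE
#>      VI           1,2,3,4,10     2.673        2.885   1.0246    5.612   FALSE
#>     VII              1,2,3,4     2.524        2.672   0.9220    4.847   FALSE
#>    VIII                1,2,3     2.524        2.668   0.9578    4.810   FALSE
#>      IX                  1,2     2.761        2.918   1.0959    4.958   FALSE
#>       X                    2     2.932        3.081   0.9321    4.837   FALSE
res$chosen
#> <scale_combination> VIII: {1,2,3}
```

Reading the output: the low-frequency scales (6–10), which carry growing
force-uncorrelated noise in this simulation, absorb most of the
normalized sensitivity (e.g. scale 7 at 0.305), so SCA eliminates them
first. Validation RMSE is lowest for the compact combinations that keep
only the clean high-frequency scales: the selected combination VIII
estimates held-out force with an RMSE of 2.67 %MVC versus 2.85 %MVC for
the all-scales model — removing the fatigue-contaminated scales improves
out-of-session accuracy.

A command-line interface wrapping the same functions ships in
`inst/cli/semgrip.R`:

```sh
Rscript inst/cli/semgrip.R simulate --task force_varying --duration 600 \
    --seed 7 --out sim.csv
```

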