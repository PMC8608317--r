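# hazvis

Hazard visibility scoring for low-vision pedestrians.

Steps and walkway edges are fall hazards, and whether a pedestrian with
low vision can see one depends on whether its *geometric* edges coincide
with *visible luminance contrast*. `hazvis` turns that idea into a
number: given a luminance image of a scene and two routine clinical
measures of an observer's vision (logMAR acuity and Pelli-Robson log
contrast sensitivity), it computes a **Hazard Visibility Score (HVS)**
between 0 (no visible boundary anywhere near the hazard's edges) and 1
(every geometric edge lies on a visible luminance boundary).

The pipeline:

1. **Observer model** — a log-parabola contrast sensitivity function
   (CSF) anchored by the observer's acuity (cutoff frequency
   `30·10^-acuity` cpd) and contrast sensitivity (sensitivity `10^CS` at
   an acuity-shifted low reference frequency). CS can be imputed from
   acuity with a linear clinical rule when unmeasured.
2. **Appearance filter** — cosine-log band-pass decomposition with
   exact reconstruction; band content whose band-limited contrast falls
   below the observer's threshold is removed, leaving only structure
   this observer can resolve.
3. **Boundary extraction** — Canny detection on log-luminance (gradients
   are Weber contrast per pixel; output invariant to luminance scaling).
4. **Scoring** — exact Euclidean distances from ground-truth geometric
   edge pixels to the nearest detected boundary, mapped through
   `max(0, 1 - d/d_max)` with `d_max = 0.5°` of visual angle; HVS is the
   mean over a region of interest.
5. **Validation statistics** — a synthetic factorial experiment (5
   targets × 5 lightings × 5 viewpoints × 2 repetitions = 250 trials per
   observer), simulated forced-choice observers, per-subject and pooled
   accuracy-versus-HVS logistic fits, likelihood-ratio and Chow tests,
   and meta-regression of fitted slopes on clinical vision measures.

See the vignette (`vignettes/hazard-visibility.Rmd`) for the model in
detail, design rationale, and known limitations.

## Worked example

Score a 7-inch step-up, overhead lighting, frontal view, for an observer
with moderate vision loss:

```r
library(hazvis)

vp <- vision_params(acuity = 1.2, cs = 0.68)
csf <- build_csf(vp)
csf
#> Contrast sensitivity function (log-parabola template)
#>   peak sensitivity: 45.0 at 0.276 cpd
#>   cutoff frequency: 1.893 cpd
#>   anchored: S(0.063 cpd) = 4.79; bandwidth 0.65 log10 units

render <- render_scene(scene_spec("big-step-up", "overhead", "center"))
run_hvs(render, vp)
#> Hazard Visibility Scores
#>           roi       hvs n_geometry_pixels config_hash
#>    whole-step 0.7666843              1120    37063ccb
#>       corners 0.7830720               562    37063ccb
#>  central-edge 0.7501650               606    37063ccb
```

The same scene is much less visible to a severely impaired observer (CS
imputed from acuity):

```r
run_hvs(render, vision_params(1.62))$table[, c("roi", "hvs")]
#>           roi       hvs
#> 1   whole-step 0.3130435
#> 2      corners 0.3246117
#> 3 central-edge 0.3052424
```

Regressing fitted accuracy-versus-HVS slopes of the bundled ten
low-vision observers on their clinical measures:

```r
lv <- low_vision_subjects()
slope_vs_vision_regression(lv$slope, lv$acuity_logmar)
#> OLS: slope = -6.25, intercept = 12.57, R^2 = 0.35
slope_vs_vision_regression(lv$slope, lv$cs_pelli_robson)
#> OLS: slope = 4.12, intercept = 1.34, R^2 = 0.56
```

Run the full synthetic validation experiment (two groups of seven
observers, 250 trials each):

```r
ex <- run_validation_experiment(pipeline_config(seed = 1))
ex$pooled$moderate   # pooled logistic fit: slope, CI, deviances
ex$chow              # Chow test between the two groups' regressions
```

A thin command-line wrapper lives in `inst/scripts/hazvis-cli.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/hazvis-cli.R", package="hazvis"))')" \
  score --target big-step-up --lighting overhead --viewpoint center \
  --acuity 1.2 --cs 0.68 --out results/scene1
```

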