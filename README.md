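# comgait

Multimodal mobility analysis for older adults: dynamic gait features
from vision-based pose estimation, joined with static body-composition
indicators from bioimpedance, scored against the SPPB 4-metre walk, and
run through a correlation/regression battery with significance markers.
The intended users are researchers studying musculoskeletal ageing and
sarcopenia screening who have pose-estimator output (PoseNet-style
17-keypoint time series) and InBody-style indicator tables, and who want
a reproducible, fully tested pipeline from raw keypoints to report
tables.

## The model

Per frame, the center of mass (CoM) is the unweighted mean of five
upper-body keypoints (nose, both shoulders, both hips):

    x_center = (1/|K|) Σ_{i∈K} x_i,   y_center = (1/|K|) Σ_{i∈K} y_i,   |K| = 5

Between consecutive frames the **center displacement** (pixel/frame) and
**directional shift** (radians) are

    d_t = sqrt(Δx² + Δy²),     θ_t = arctan(Δy / Δx) ∈ (−π/2, π/2)

with θ = ±π/2 for purely vertical steps and 0 for a stationary CoM.
Per participant, the pipeline reports the mean and variance of |θ_t|
(or of |Δx_t| in horizontal mode) and the mean displacement, after
low-confidence keypoints are repaired by linear interpolation and the
displacement stream is cleaned at a percentile threshold (default 95th:
the stream is right-skewed with a long tail of frame-freeze spikes, so
the top 5% of frame pairs is removed). Pearson cells carry two-sided
p-values from the exact transform `t = r·√(n−2)/√(1−r²)`, which is also
the slope t-statistic of the matching simple regression; markers follow
***/**/* at 0.001/0.01/0.05. A seeded synthetic-cohort generator with
planted indicator–mobility correlations stands in for raw study data and
makes every stage testable end to end.

## Worked example

```r
library(comgait)

cohort   <- generateCohort(synthCohortConfig(seed = 42))   # 19 participants
repaired <- lapply(cohort$poses, function(p) interpolateMissing(p)$sequence)
dyn      <- lapply(repaired, function(p) computeDynamics(computeCoM(p)))
filt     <- filterDynamics(dyn, percentile = 95)
filt$reports[[1]]
#> ThresholdReport: pooled threshold 6.0625 px (percentile 95); removed 142 of 2829 (5.02%)

features <- featureTable(lapply(filt$dynamics, aggregateFeatures,
                                filterThreshold = filt$threshold))
head(features, 3)
#>      participant_id mean_directional_shift var_directional_shift mean_displacement n_frames_used    mode threshold
#> P001           P001                  0.290                0.0486              2.58           143 angular      6.06
#> P002           P002                  0.424                0.0993              2.80           145 angular      6.06
#> P003           P003                  0.227                0.0381              2.78           141 angular      6.06

scores <- scoreWalk(cohort$walkTrials)
cells  <- correlationMatrix(features, cohort$bodyComp, scores)
tab    <- formatCorrelationTable(cells)
tab[tab$variable %in% c("SMI", "SMM", "PBF"),
    c("variable", "mean_directional_shift")]
#>  variable mean_directional_shift
#>       SMM          0.144 (0.556)
#>       PBF       -0.628 **(0.004)
#>       SMI          0.357 (0.134)
```

The threshold report says one pooled 95th-percentile cut at 6.06 px
removed 5.02% of frame pairs. Each feature row is one participant: a
mean |θ| of 0.29 rad with a mean step of 2.6 px/frame over 143 retained
pairs. The formatted correlation cells read `r marker(p)`; at n = 19 the
estimates are noisy, which is exactly what the planted-correlation
recovery test demonstrates at n = 2000. Sarcopenia screening
(`flagSarcopeniaRisk(sex, SMI)`) applies the AWGS 2019 cutoffs (< 7.0
kg/m² male, < 5.7 kg/m² female, strict).

One call runs everything and writes the report bundle (features,
confidence summaries, threshold report, walk scores, normality screen,
correlation/regression tables, sex-stratified grids, path-density
histogram, run log, manifest):

```r
runPipeline(defaultRunConfig(outDir = "demo_run", seed = 42))
```

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/comgait-pipeline.R --out demo_run --seed 42
Rscript inst/scripts/comgait-pipeline.R --config run.yaml
```

See `vignettes/gait-body-composition.Rmd` for the methods: feature
definitions and conventions, repair and filtering rules, the statistical
battery, what the synthetic cohort does and does not emulate, and the
numerical choices.

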