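# lghdetect

Conflict-aware multi-task training for spatio-temporal behavior detection in
wildlife monitoring video, built around **Lightweight Gradient Harmonization
(LGH)**.

## The problem

Continuous field video of wetland birds (the motivating system is wintering
cranes observed by fixed infrared cameras) is annotated AVA-style: each row
of a CSV records one individual's bounding box at one keyframe, a behavior
class from a six-class ethogram — feeding, vigilance, social behavior,
maintenance, walk, flight — and a binary motion attribute (static/dynamic).
Detectors for this task benefit from a second, auxiliary supervision signal
(the motion attribute), but joint training of the two heads over a shared
video backbone suffers *negative transfer* when the two tasks' gradients on
the shared parameters point in conflicting directions.

LGH resolves this with a single scalar: at each optimisation step, compute
the cosine similarity of the two tasks' gradients over the shared parameters
only,

```
rho = (g_act . g_mov) / (|g_act| |g_mov|),
```

and set the auxiliary-task weight

```
lambda = lambda_base * (1 - alpha * |rho|)   if rho < 0
       = lambda_base                          otherwise,
```

with total loss `L = L_act + lambda * L_mov`. The combined shared-parameter
gradient `g_act + lambda * g_mov` stays in the cone spanned by the two task
gradients: unlike gradient-surgery methods (PCGrad and variants), LGH never
re-directs either task's gradient, it only rescales the auxiliary one.
`alpha = 0` reduces to fixed weighting; `alpha = 1` suppresses the auxiliary
task entirely under full conflict. The defaults `alpha = 0.2`,
`lambda_base = 0.10` are the values a sensitivity grid selects.

## What is in the package

* **`read_annotations` / `write_annotations`, `dataset_stats`,
  `split_allocate`, `video_level_split`** — AVA-style CSV IO, descriptive
  statistics (class proportions, static/dynamic marginals, box geometry) and
  largest-remainder train/val/test allocation.
* **`gen_conflict_dataset`, `gen_toy_clips`, `gen_loss_curve`** — synthetic
  generators: tabular two-task data with a controllable angle between the
  task-optimal directions, toy annotated clips (Gaussian blobs with
  behavior-keyed kinematics), and loss-curve fixtures.
* **`strategy_lgh`, `strategy_fixed` / `strategy_equal`,
  `strategy_uncertainty`, `strategy_gradnorm`, `strategy_pcgrad`,
  `strategy_ripcgrad`** — interchangeable weighting/gradient-combination
  policies over a shared-parameter registry.
* **`build_toy_model`, `build_conflict_mlp`, `train_toy`, `lgh_step`** — a
  desk-scale dual-pathway (slow/fast frame sampling), dual-head detection
  model with ROI feature pooling (`roi_pool`) and hand-written gradients,
  plus the SGD training loop (per-step decision log of rho, lambda,
  conflict flags).
* **`evaluate_detections`, `average_precision`, `mean_ap`, `iou`,
  `confusion_matrix`, `cohens_kappa`** — frame-level AP/mAP with greedy IoU
  matching, and annotation-agreement utilities.
* **`loss_reduction`, `reduction_gap`, `threshold_epoch`, `rolling_mean`,
  `conflict_summary`, `diagnostics_report`** — optimization diagnostics.
* **`frames_to_events`, `time_budget`, `coverage_change`,
  `efficiency_ratio`, `diurnal_profile`, `monitoring_comparison`** —
  behavioral-ecology analytics.
* **`lgh_cli`** (and the script `inst/cli/lghdetect.R`) — subcommands
  `simulate`, `train-toy`, `evaluate`, `diagnose`, `budget`, `grid`.

## Worked example

Train the small two-head MLP on a conflicting-task dataset and inspect the
conflict dynamics:

```r
library(lghdetect)

ds <- gen_conflict_dataset(conflict_spec(n_samples = 2000,
                                         conflict_level = -0.8, seed = 7))
fit <- train_toy(build_conflict_mlp(12, hidden = 8, seed = 7), ds,
                 strategy_lgh(lgh_config(alpha = 0.2, lambda_base = 0.10)),
                 epochs = 10, seed = 7, batch_size = 64)
summary(fit)
#> Strategy lgh over 10 epochs
#> final behavior loss 1.5065, motion loss 0.0424
#> conflicted steps: 45.3%; rho in [-0.521, 0.951]; mean lambda 0.0985
```

At `conflict_level = -0.8` nearly half the steps see a negative gradient
cosine; LGH responds by pulling the auxiliary weight below its base value
(mean lambda 0.0985 < 0.10), protecting the primary behavior loss.

The end-to-end monitoring pipeline on a synthetic 30-second scene — clip
generation, two epochs of dual-pathway training, evaluation and time-budget
analytics:

```r
sm <- run_smoke_pipeline(seed = 7)
sm$eval_oracle
#> Frame-level evaluation (IoU >= 0.50, 90 detections)
#>   feeding      AP 1.0000  (support 30)
#>   social       AP 1.0000  (support 30)
#>   maintenance  AP 1.0000  (support 30)
#>   ...
#>   overall      mAP 1.0000 over 3 classes
sm$budget
#> Time budget (seconds)
#>   feeding vigilance social maintenance walk flight
#> 0       0         0     30           0    0      0
#> 1      30         0      0           0    0      0
#> 2       0         0      0          30    0      0
#> overall: ... grand total 90.0 s
```

An oracle classifier reaches mAP 1.0 by construction (classes absent from
the scene have undefined AP and are excluded from the mean); the trained
model's mAP is reported alongside. Individual worked values:

```r
lgh_weight(-0.55, lgh_config(0.2, 0.1))       # 0.089
split_allocate(19926, c(8, 1, 1))             # 15941 1993 1992
mean_ap(c(0.8318, 0.5477, 0.9403, 0.7046, 0.2320, 0.8595))  # 0.686
```

## Command line

```sh
Rscript inst/cli/lghdetect.R simulate  --out runs/sim --seed 3
Rscript inst/cli/lghdetect.R train-toy --out runs/lgh --strategy lgh --seed 3
Rscript inst/cli/lghdetect.R evaluate  --annotations runs/sim/annotations.csv \
                                       --predictions runs/sim/predictions.csv \
                                       --out runs/eval
Rscript inst/cli/lghdetect.R budget    --events runs/sim/events.csv --out runs/bud
Rscript inst/cli/lghdetect.R grid      --out runs/grid --seed 3
```

Every run writes its fully resolved configuration (`run_config.yaml`) next
to its outputs.

See the methods vignette (`vignettes/gradient-harmonization.Rmd`) for the
model, its assumptions, the generator design, and known limitations.
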