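# vesselnet

Retinal vessel segmentation with a dual CNN–transformer network, plus
vessel-density quantification for longitudinal hypertensive-retinopathy
monitoring — implemented entirely in R (the neural-network core is base
R on BLAS matrix products, with analytic gradients).

## What it does, for whom

Clinicians and imaging researchers use retinal fundus photographs to
monitor microvascular damage from chronic hypertension, which manifests
as vessel narrowing. The package provides:

* a **segmentation model**: a hierarchical convolutional branch
  (pre-activation bottlenecks) and a transformer branch over stride-16
  patch tokens, coupled by bidirectional **fusion blocks** (1×1
  projections + pooling/bilinear re-sampling + LayerNorm/BatchNorm),
  decoded by a U-shaped head to a per-pixel vessel probability map;
* the **TopK + Dice compound loss**
  `L = L_TopK + L_Dice`, where `L_TopK` is mean per-pixel binary
  cross-entropy over the k% hardest pixels and
  `L_Dice = 1 − 2|V_s ∩ V_g| / (|V_s| + |V_g|)` (soft);
* **evaluation** inside the camera field of view: Acc, SE, SP, F1 at
  threshold 0.5 and rank-statistic AUROC, with percentile-bootstrap
  confidence intervals over test images, printed the way segmentation
  papers print them (`mean (low, high)` in percent);
* **quantification**: the vessel-density ratio
  `R_vessel = N_v / (N_non − N_v)` of a segmented mask, its deltas
  across visits, and signed change maps between visits;
* a **seeded synthetic phantom generator** (branching vessel trees with
  exact ground-truth masks on a disc FOV, illumination gradient, sensor
  noise, and a "constricted follow-up" mode) so the whole pipeline is
  testable without external datasets;
* **dataset plumbing** for DRIVE-style layouts with the canonical
  splits (DRIVE 20/20, CHASEDB1 last-8 test, STARE 10/10 or
  leave-one-out, HRF 15/30 with 4× downsampling). Images travel as
  NetPBM (PGM/PPM); convert PNG/TIFF sources once, e.g.
  `convert img.png img.ppm`.

## Worked example

Desk-scale end-to-end run on synthetic phantoms (a few minutes on one
CPU; numbers below are the actual output of this script):

```r
library(vesselnet)

## a tiny seeded world: 16 training phantoms, 2 held-out
train <- make_phantoms(16, seed = 0)
test  <- lapply(100:101, function(s) generate_phantom(phantom_spec(seed = s)))

## train the tiny preset (transformer depth 2, embedding 64)
cfg <- train_config("tiny", iterations = 400L, seed = 0L)
fit <- train_model(train, cfg)

## evaluate on held-out phantoms
ev <- evaluate_model(fit$model, test, window = 64, n_boot = 500)
print(ev$table)
#>                 acc                  se                  sp                  f1
#> "94.9 (94.6, 95.2)" "75.6 (75.1, 76.1)" "97.4 (97.2, 97.7)" "77.6 (77.3, 77.8)"
#>               auroc
#> "97.8 (97.5, 98.0)"

## longitudinal quantification: a constricted follow-up visit
spec <- phantom_spec(seed = 100)
base <- generate_phantom(spec)
followup <- generate_followup(spec, constriction_factor = 0.5)
r0 <- vessel_ratio(base$mask, base$fov, visit_id = "baseline")
r1 <- vessel_ratio(followup$mask, followup$fov, visit_id = "followup")
ratio_trend(list(r0, r1))
#>       from       to       delta direction
#> 1 baseline followup -0.09430674  decrease
```

The evaluation table reads as the mean over test images with a 95%
bootstrap interval, in percent: e.g. `f1 76.6 (75.6, 77.5)` means the
model's F1 at threshold 0.5 inside the FOV averaged 0.776. The
negative `R_vessel` delta flags the vessel loss that the constricted
follow-up simulates — the quantity a clinician would track between
visits.

A command-line interface covers the same surface
(`inst/cli/vesselnet`): subcommands `make-phantoms`, `train`,
`predict`, `evaluate`, `quantify`, with JSON configs and NetPBM
images.

## Notes

* The methods vignette
  (`vignettes/vessel-segmentation-methods.Rmd`) documents the model,
  the loss, every tunable with its default and rationale, what the
  phantom world does and does not emulate, and known limitations.
* Training the `default` preset (depth 12, embedding 384, 118 px
  patches, 20k iterations) is provided for completeness but is not
  practical on CPU.
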