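# cvmstage

Automatic cervical vertebral maturation (CVM) staging from cephalometric
landmarks.

Orthodontists assess skeletal maturity — and hence the timing of
growth-modification treatment — from the shape of the second to fourth
cervical vertebrae (C2–C4) on the lateral cephalogram, using the Baccetti
six-stage CVM scheme (CS1 immature … CS6 mature; CS3 marks the pubertal
growth spurt). `cvmstage` is an R implementation of the full automated
pipeline for this task, aimed at researchers building or evaluating
CVM-staging systems:

* **Landmark I/O** — LabelMe point-JSON annotations (15 named points:
  a 10 mm calibration pair `R1`/`R2` plus 13 anatomic points), per-image
  pixel→mm calibration, and a 100 × 200 px region-of-interest crop with an
  exactly invertible affine transform.
* **Morphometrics** — the five staging quantities: lower-border concavity
  depths (mm)

  `CxConc = dist(Cxm, chord(Cxlp, Cxla))`, clamped at 0 for flat/convex
  borders, and the base-to-anterior-height ratios

  `CxBAR = |Cxlp − Cxla| / |Cxua − Cxla|`,

  all invariant under rotation/translation of the annotation.
* **Staging** — the thresholded decision workflow: count concave borders
  (0 → CS1, 1 → CS2, 2 → CS3), then with all three concave let the C3/C4
  body shapes decide (vertical rectangle → CS6, square → CS5, else CS4),
  with configurable thresholds and an explicit flag for anatomically
  atypical concavity patterns.
* **Evaluation** — per-stage one-vs-rest precision/recall/specificity/F1,
  overall accuracy, Cohen's κ, ICC(2,1)/(3,1)/(2,k), landmark placement
  error in mm with the per-landmark `Total` convention, and reconstruction
  of full confusion counts from published per-stage summaries.
* **Synthetic generator** — stage-conditioned vertebral outlines and
  radiograph-like frames with exact ground truth (concavities drawn as
  circular arcs; measurements recovered to 1e-9 mm at zero jitter).
* **Detector** — a compact convolutional coordinate-regression network
  (3 × 3 conv stack + one fully connected layer, ReLU, Adam, MSE loss,
  batch 32, lr 1e-4), fully seeded, implemented in base R matrix algebra.

## Worked example

Generate a synthetic CS3 case, measure it, and stage it:

```r
library(cvmstage)
set.seed(42)
case  <- sample_case("CS3", render = TRUE)
scale <- compute_scale(case$record)
scale
#> <cvm_scale> 0.25 mm/pixel
m <- measure_landmarks(case$record, scale)
m
#> <cvm_measurements>
#>   concavity (mm): C2 2.248  C3 2.274  C4 0.243
#>   BAR:            C3 1.541  C4 1.475
cvm_stage(m)
#> <cvm_staging> CS3
#>   concave: C2 TRUE, C3 TRUE, C4 FALSE; shapes: C3 horizontal, C4 horizontal
```

C2 and C3 carry concavities above the 1 mm threshold while C4 is still
flat, so two concave borders give CS3; both bodies are still horizontal
rectangles, consistent with a pre-peak adolescent.

Staging robustness under annotation noise — 300 cases with 0.5 mm landmark
jitter, scored against their construction stages:

```r
set.seed(42)
p <- synth_params(jitter_sigma_mm = 0.5)
gold <- pred <- character(0)
for (s in stage_levels()) for (i in 1:50) {
  cs   <- sample_case(s, p)
  gold <- c(gold, s)
  pred <- c(pred, as.character(stage_record(cs$record)$stage))
}
metric_report(gold, pred)
#> <cvm_metric_report>
#>  stage tp fp fn  tn precision recall specificity   f1
#>    CS1 31  9 19 241      0.78   0.62        0.96 0.69
#>    CS2 30 33 20 217      0.48   0.60        0.87 0.53
#>    CS3 25 71 25 179      0.26   0.50        0.72 0.34
#>    CS4 28 13 22 237      0.68   0.56        0.95 0.62
#>    CS5 26  8 24 242      0.76   0.52        0.97 0.62
#>    CS6 23  3 27 247      0.88   0.46        0.99 0.61
#> accuracy 0.54  kappa 0.45  ICC 0.73
```

Half a millimetre of landmark noise already halves staging accuracy —
the stage boundaries are genuinely tight relative to clinical annotation
error, which is why the middle stages are the hard ones.

A command-line front end over the same functions lives in
`inst/cli/cvm.R` (`measure`, `stage`, `evaluate`, `synth`, `train`,
`predict` subcommands).

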