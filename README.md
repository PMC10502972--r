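# octchoroid

Automated choroid segmentation and subfoveal choroidal thickness (SfChT)
measurement for OCT B-scans, with the longitudinal statistics of a two-arm
myopia-control trial.

## What problem does this solve?

The choroid — the vascular layer between the retinal pigment epithelium
(RPE) and the sclera — thickens in response to myopic defocus, and its
short-term response is a candidate predictor of axial eye growth in
children. Monitoring it at scale requires segmenting the choroid on
thousands of OCT B-scans and extracting the thickness at the fovea, which
is impractical to do by hand. `octchoroid` provides the full measurement
pipeline for researchers in myopia control and ocular imaging:

* **Synthetic phantoms** — layered B-scans (vitreous / retina with a foveal
  pit / RPE / choroid with lacunae / sclera) with pixel-perfect ground-truth
  choroid masks, so the whole pipeline is testable without clinical data.
* **Segmentation networks** — a batch-normalized U-Net and a residual
  encoder–decoder, both with a *strip-pooling* bottleneck (average pooling
  along entire rows 1×W and columns H×1, per-axis 1-D mixing, broadcast and
  sigmoid-gated recombination) that widens the receptive field along the
  natural axes of layered OCT anatomy. Two models can be ensembled by *late
  fusion*: the elementwise mean of their probability maps.
* **Training & evaluation** — Adam + dice loss, seeded online augmentation
  (±10° rotations, horizontal flips, brightness/contrast jitter), and
  evaluation with the Dice similarity coefficient and the average symmetric
  surface distance:

  DSC(X, Y) = 2|X ∩ Y| / (|X| + |Y|),  ASSD = (Σᵢdᵢ + Σⱼdⱼ\*) / (N₁ + N₂)

  where dᵢ is the distance from the i-th surface point of one segmentation
  to the nearest surface point of the other.
* **Post-processing** — binarize at 0.5, keep the largest connected
  component, locate the fovea as the thinnest-retina column within the
  central 25 A-scans (Otsu threshold), and report SfChT averaged over
  3 horizontal + 3 vertical line scans, in µm.
* **Cohort statistics** — a seeded simulator of a two-year, two-arm trial
  (DIMS treatment vs. single-vision control; visits at 1 week, 1, 3, 6, 12,
  18, 24 months) and the analyses: change from baseline, baseline-adjusted
  group contrasts (mean ± SEM), percent change, Pearson associations, and
  hierarchical multiple regression with standardized betas and ΔR².

Everything user-facing takes and returns tibbles where the data are
tabular, with `tidy()`, `glance()` and `autoplot()` methods; images and
masks are lightweight matrix-backed objects. The CNN engine (layers,
backprop, Adam) is implemented in base R matrix algebra and its gradients
are verified against finite differences in the test suite.

## Worked example

```r
library(octchoroid)

# a tiny 64x96 phantom with known geometry
spec <- phantom_spec("tiny", seed = 42)
ph <- generate_phantom(spec)
ph$image
#> <bscan 64x96, horizontal, 3.87 µm/px>

# train the tiny strip-pooling U-Net on 30 phantoms
train_ds <- phantom_dataset(30, spec, seed = 1)
eval_ds  <- phantom_dataset(10, spec, seed = 2)
model <- build_network(network_config("unet", "tiny"), init_seed = 1)
fit <- train_network(model, train_ds, train_config(epochs = 20, seed = 1))
glance(fit)
#> # A tibble: 1 × 4
#>   epochs first_loss final_loss n_parameters
#> 1     20      0.436    0.00737        27889

# held-out evaluation after post-processing
evaluate_models(fit$model, eval_ds)
#> Segmentation evaluation on 10 image(s)
#>   DSC  100.00 ± 0.01 (max 100.00)
#>   ASSD 0.00 ± 0.00 px

# measure SfChT on a 6-scan set (3 horizontal + 3 vertical)
scans <- generate_scan_set(spec, jitter_seed = 9)
scans$mask <- purrr::map(scans$image,
                         ~ largest_component(binarize(predict(fit$model, .x))))
glance(measure_sfcht(scans, subject = "P01", visit = "baseline"))
#> # A tibble: 1 × 5
#>   subject visit    mean_sfcht_um n_scans n_used
#> 1 P01     baseline          83.2       6      6
```

The dice loss falls from 0.44 to 0.007 in 20 epochs (about a minute on one
CPU); the post-processed held-out Dice score is essentially 1 and the mean
surface distance is a small fraction of a pixel, so on phantoms the
pipeline recovers the choroid mask almost exactly. The measured 83.2 µm is
the mean over the six jittered scans (the unjittered spec value is
81.27 µm; per-scan jitter is ±2 px = ±7.7 µm).

Cohort side, at the trial's scale (n = 78/80):

```r
rec <- simulate_cohort(cohort_spec(seed = 11))
adjusted_group_change(change_from_baseline(rec), visit = "1w")
#> # A tibble: 2 × 4
#>   group adjusted_mean   sem     n
#> 1 DIMS           7.03  1.53    78
#> 2 SV            -3.55  1.51    80
```

i.e. a baseline-adjusted one-week thickening of ~7 µm under treatment
versus ~−3.5 µm thinning in controls — and
`percent_change(6.75, 280.95)` gives the configured relative treatment
effect of `2.4` %.

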