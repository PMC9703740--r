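# cardunet

Segmentation of short-axis cine cardiac MR — left-ventricular (LV) cavity,
LV myocardium and right-ventricular (RV) cavity — that stays accurate when
the images carry the susceptibility artifacts of cardiac implantable
electronic devices (CIEDs: pacemakers, defibrillators). The package is
aimed at scientists building or evaluating automatic ventricular
quantification: it contains the complete loop from data to clinical
numbers, with no external deep-learning framework.

**What's inside**

* **Phantom + artifact simulator** — synthetic cine studies (ED and ES
  phases) with analytic ground truth: LV annulus, RV crescent, linear
  base→apex taper, per-study contraction; septal signal voids with
  hyperintense rim and mild geometric warp, applied to intensities only.
* **Attention-gated U-Net** — encoder–decoder with (3×3 conv → batch norm
  → ReLU) blocks, attention gates on the two deepest skip levels and 1×1
  adapters on the shallowest, 1×1 conv + softmax head. Layers are dense
  BLAS matrix algebra with compiled (RcppArmadillo) convolution and
  batch-norm kernels and hand-derived, finite-difference-validated
  backprop.
* **Combined loss** — weighted cross-entropy (inverse median-frequency
  class weights) plus Focal Tversky,
  `TI_c = (TP + s)/(TP + α·FN + β·FP + s)`, loss `Σ_c (1 − TI_c)^{1/γ}`
  with α = 0.7, β = 0.3, γ = 4/3.
* **Training protocol** — Adam, lr 1e−4, batch 4, per-epoch exponential
  decay (rate 0.04), ≤60 epochs, on-the-fly rotation (±30°) and gamma
  ([0.8, 1.2]) augmentation, checkpoint selection by best mean validation
  Dice.
* **Metrics** — volume-level Dice `2|X∩Y|/(|X|+|Y|)`, recall, precision,
  and slice-wise Hausdorff distance in mm, summarized as median (IQR).
* **Clinical parameters & agreement** — EDV/ESV/EF per ventricle, LV mass
  (1.05 g/mL), ICC(2,1) with the 0.75 reproducibility threshold, and
  Bland–Altman bias ± 1.96 sd limits, with `tidy()`, `glance()` and
  `autoplot()` methods.

## Worked example

A two-minute smoke run — generate a small artifact cohort, train briefly,
inspect the fit:

```r
library(cardunet)

base <- phantom_config(n_slices = 6, image_size = 64, pixel_spacing = 2,
                       artifact = artifact_config())
man  <- generate_dataset(10, 10, "dataset", seed = 1, base_config = base)

fit <- train_model(
  build_model(model_spec(depth = 3, base_channels = 8), seed = 2),
  cardunet:::load_split(man, "train"),
  cardunet:::load_split(man, "val"),
  train_config(max_epochs = 10, seed = 3))
glance(fit)
#> # A tibble: 1 × 4
#>   epochs best_epoch best_val_dsc final_train_loss
#>    <int>      <int>        <dbl>            <dbl>
#> 1     10         10        0.715             2.75
```

`best_val_dsc` is the mean volume-level Dice over the three cardiac
structures on the validation studies at the selected epoch; `tidy(fit)`
holds the per-epoch, per-class curves and `autoplot(fit)` draws them. Ten
studies are far too few to train on — the reference experiment is the
phantom benchmark, which runs the whole pipeline (150 studies, half with
septal artifacts, 12 epochs; about 12 minutes on one CPU):

```r
bench <- run_phantom_benchmark(seed = 1)
as.data.frame(dplyr::filter(bench$summary_artifact, metric == "dsc"))
#>   structure phase metric    median        q1        q3
#> 1        lv    ed    dsc 0.9889838 0.9864830 0.9907939
#> 2        lv    es    dsc 0.9825882 0.9805642 0.9866798
#> 3       lvm    ed    dsc 0.9535291 0.9466999 0.9561278
#> 4       lvm    es    dsc 0.9576888 0.9554687 0.9604628
#> 5        rv    ed    dsc 0.9388196 0.9313822 0.9443031
#> 6        rv    es    dsc 0.8278044 0.7957450 0.8971815
bench$ef_icc_analytic
#> [1] 0.9862785
```

Those are volume-level Dice medians (IQR) on the *artifact-corrupted* test
studies: the LV cavity is segmented almost perfectly, the myocardium and
RV follow the expected difficulty ordering, and the ejection fraction
recovered from the predicted masks matches the analytic truth implied by
each phantom's contraction (ICC 0.99, far above the 0.75 reproducibility
threshold). `bench$ef_agreement` adds the Bland–Altman view: LVEF bias
−0.24% with 95% limits of agreement ±1.4%.

The same stages run individually — `evaluate_cohort()` /
`summarize_cohort()` for metrics, `clinical_parameters()` for volumes, EF
and mass, `agreement_report()` for ICC and Bland–Altman — or end to end
from one seeded configuration:

```r
res <- run_pipeline(run_config(out_dir = "run1", seed = 1))
```

A thin command-line front end with the same stages lives at
`inst/cli/cardunet.R` (`simulate`, `train`, `segment`, `evaluate`,
`clinical`, `agree`, `run-all`).

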