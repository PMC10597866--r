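# melanoscan

Melanoma screening from dermoscopy images, end to end: a reinforcement-
learning segmenter isolates the lesion, nineteen shape/texture/intensity
features describe it, the Enhanced Fish Migration Optimizer (EFMO) selects
a feature subset, and an EFMO-tuned radial-basis-function SVM classifies
the lesion as benign or malignant. A seeded synthetic-lesion generator
makes every stage testable and reproducible without any external imagery.

## Who this is for

Researchers in medical image analysis who want a tested, inspectable
implementation of this pipeline family — Q-learning thresholding against
manual masks, wrapper feature selection over a Fisher-score/accuracy cost,
and metaheuristic SVM tuning — plus the benchmark harness used to validate
the optimizer itself.

## The models in brief

* **Segmentation.** Images are smoothed by a neighborhood mean filter and
  tiled; competing agents select the tile size via a control agent that
  kills agents by the rule *D(k) > D(k−1) > D(k−2)* (and the worst agent at
  each pass end), where *D* = Σ XOR(machine, manual) / (rows × cols). Per
  tile, a Q-learned policy picks a (threshold τ, opening radius ν) action;
  reward is +1 when *D* strictly improves, −1 otherwise. A final
  opening+closing radius λ\* = argmin mean *D* cleans the stitched mask.
* **Features.** Rectangularity, elongation, area, form factor, solidity,
  irregularity index 4πA/P², border-walk perimeter, eccentricity; GLCM
  contrast/energy/homogeneity/correlation; mean, entropy, variance, SD; Hu
  invariants φ₁–φ₃.
* **Selection.** Maximize α·accuracy + β·(ΣF(selected)/ΣF(all)) with
  α = 0.65, β = 0.35, accuracy from 5-fold CV of an inner RBF SVM, F the
  Fisher score; EFMO searches [0,1]^19 thresholded at 0.5.
* **Classifier.** y = sgn(Σ yᵢαᵢK(z,zᵢ) + b) with the RBF kernel; EFMO
  tunes log₁₀γ ∈ [−4,2] then log₁₀C ∈ [−2,4]; evaluation reports
  sensitivity, specificity, accuracy, PPV, NPV and ROC/AUC.
* **Optimizer validation.** Four shifted/rotated benchmarks (elliptic,
  bent cigar, discus, Rosenbrock) whose optima are exactly 100, 200, 300,
  400 at their seeded shift points, and a Max/Min/Mean/STD comparison
  harness.

See `vignettes/melanoscan-methods.Rmd` for assumptions, parameter defaults
and numerical conventions.

## Worked example

```r
library(melanoscan)

# one synthetic lesion and its feature vector
im <- generateLesionImage(lesionSpec(seed = 42))
round(extractFeatures(im$image, im$mask)[c("area", "irregularity_index",
                                           "solidity", "eccentricity")], 4)
#>               area irregularity_index           solidity       eccentricity
#>           759.0000             0.8437             0.9768             0.4574

# full pipeline on the default synthetic study (20 train / 15 test per class)
config <- pipelineConfig(seed = 1)
man <- runTrain(config)
man$segmenter
#> Q-learning segmenter (trained)
#>   sub-image dims 64 x 64, post-processing radius 1, filter n = 1.5
#> QTable (mode 1): 11 visited states x 32 actions
runTest(config, man)$metrics
#> Classification metrics:
#>  Accuracy Sensitivity Specificity PPV NPV AUC
#>       100         100         100 100 100   1

# optimizer validation: the bent-cigar benchmark and one EFMO run
fn <- benchmarkFunction(10, 2, seed = 7)
benchmarkValue(fn, fn@shift)        # value at the global optimum
#> [1] 200
efmoOptimize(function(X) benchmarkValue(fn, X), fn@lower, fn@upper,
             seed = 1, vectorized = TRUE)
#> EFMO result: best value 200.304 after 28091 evaluations (200 iterations)
```

The feature row says the lesion covers 759 px, is moderately irregular
(index 0.84; a circle scores ≈ 0.94 at this raster resolution), nearly
convex, and mildly elongated. The pipeline block trains the segmenter,
selects features, tunes (γ, C), and classifies 30 held-out synthetic
lesions perfectly under this seed; the benchmark block confirms the
analytic optimum and shows one seeded EFMO run landing within 0.4 of it.

A thin CLI over the same functions ships in `inst/scripts/melanoscan`
(subcommands `synth`, `train-seg`, `segment`, `extract`, `select`, `tune`,
`classify`, `evaluate`, `benchmark`, `run-train`, `run-test`).

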