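# myoseg

Automatic myofibre segmentation in transverse H&E-stained skeletal-muscle
histology, with the evaluation statistics and morphometry used to judge it.

Fibre-size variation is the first morphological sign in most neuromuscular
disorders, and measuring it requires outlining every fibre in a biopsy
section — slow and operator-dependent by hand. `myoseg` automates the
outline: it treats the pale endomysial boundary network as the object to
enhance and segments fibres as its complement.

## Method

For an RGB region of interest `I` (default scale 0.899 µm/px):

1. **Stain unmixing.** Rank-2 non-negative matrix factorisation of the
   optical densities `OD = −log((I + ε)/(1 + ε))` splits the image into
   eosin and haematoxylin density maps with unit colour vectors; the eosin
   factor (identified by cosine similarity to a reference eosin OD
   direction) is rendered back to intensities, converted to grayscale and
   equalised with CLAHE. Result: boundaries light, fibre interiors dark.
2. **Coherence-enhancing diffusion.** The image evolves under
   `∂u/∂t = div(D ∇u)` where `D` shares eigenvectors with the structure
   tensor `J_ρ = G_ρ ∗ (∇u_σ ∇u_σᵀ)` and has eigenvalues `λ₁ = c₁` across
   the local structure and
   `λ₂ = c₁ + (1 − c₁)·exp(−c₂/(μ₁ − μ₂)²)` along it — strong smoothing
   along coherent boundary lines, almost none across them. Defaults:
   `τ = 1, σ = 1e−4 px, ρ = 4 px, c₁ = 1e−10, c₂ = 1e−3`, 20 steps
   (explicit non-negativity scheme, sub-stepped for stability).
3. **Morphological filtering.** Otsu threshold (exhaustive 256-bin
   between-class-variance search) → remove boundary components < 750 px →
   close with a radius-4 disk → complement into fibre regions.
4. **Marker-controlled watershed.** Markers are the components of the fibre
   mask eroded by a radius-10 disk (with a distance-transform fallback for
   thin fibres); Meyer's flooding on the negated Euclidean distance
   transform splits touching fibres. Regions < 750 px and fibres touching
   the image border are removed.

Evaluation follows the region-matching conventions of the field: one-to-one
fibre accuracy `TP/(TP+FP+FN)`, fragmentation `F = p/n` (over-segmentation),
congealment `C = q/n` (under-segmentation), per-image misclassification
percentages with a KDE-smoothed CDF, minor-axis fibre diameters from the
moment-equivalent ellipse, and the variability coefficient
`VC = 1000·sd/mean` (< 250 is clinically normal).

Because no public dataset accompanies the method, the package includes a
seeded synthetic generator (`generate_muscle_image()`): jittered-grid
Voronoi fibres with pale endomysium, peripheral nuclei, three speckle-noise
severities and controllable boundary weakening, with exact ground-truth
labels by construction.

## Worked example

```r
library(myoseg)

gen    <- generate_muscle_image(synthetic_spec(rng_seed = 3))  # 512x512, 36 seeds
labels <- segment(gen$image)
#> preprocess: NMF converged in 470 iterations
#> ced: 20 steps at tau = 1
#> otsu: threshold 0.4844, 34486 boundary px
#> postprocess: 36 watershed regions -> 36 after area filter -> 18 interior fibres

labels
#> <label_mask> 512 x 512 px, 18 fibres, 0.899 um/px

report <- evaluate_segmentation(labels, remove_border_fibres(gen$labels))
report
#> <metrics_report> accuracy 0.944 (TP 17 / FP 1 / FN 0), F 0.000, C 0.000
#>   misclassification 1.19%, mean diameter 70.8 um, VC 190.3

tidy(report)
#> # A tibble: 6 x 2
#>   metric                  value
#>   <chr>                   <dbl>
#> 1 accuracy                0.944
#> 2 fragmentation           0
#> 3 congealment             0
#> 4 misclassification_pct   1.19
#> 5 mean_diameter_um       70.8
#> 6 vc                    190.
```

Of the 36 generated fibres, 18 lie fully inside the frame after border
removal; the pipeline recovers 17 of them one-to-one with a single false
positive, misclassifies 1.19% of pixels, and measures a mean minor-axis
diameter of 70.8 µm with a variability coefficient of 190 — inside the
normal range (< 250), as the generator intends. `plot_image(labels)` and
`label_overlay(gen$image, labels)` visualise the result;
`autoplot(report)` plots the diameter histogram.

File-level runners mirror the R API: `run_segment()`, `run_evaluate()`,
`run_synth()`, also exposed as a command-line script
(`inst/exec/muscleseg.R`) with `segment`, `evaluate` and `synth`
subcommands. Configuration is a validated YAML file (see
`default_config()`).

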