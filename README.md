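# kidseg

Automatic kidney boundary extraction in 2D B-mode ultrasound, as a two-stage
coarse-to-refinement cascade:

1. **Coarse segmentation** — a deep fusion learning network: a U-Net whose
   skip connections are modulated by squeeze-and-excitation (SE) and
   attention-gate (AG) modules, in four fusion variants (two serial, two
   parallel), trained with Dice loss
   `1 − (2Σpq + ε)/(Σp + Σq + ε)` and Adam.
2. **Refinement** — automatic searching polygon tracking (ASPT): the coarse
   mask's boundary pixels `P = {p_1, …, p_iv}` are min-max normalized to
   `[−1,1]²`, vertices are *discovered* (never counted in advance) by
   adaptive mean-shift clustering with k-NN bandwidths, ordered into a
   closed polygon, and optimized by cyclic coordinate descent on the
   penalized distance

   `G′(v_i) = Δ(v_i)/iv + λ·MP(v_i)/(k+1)`,
   `λ = λ′·iv^{1/3}·√Δ̄ / r`, `λ′ = 0.13`,

   where `Δ(v_i)` is the summed squared distance of the data assigned to
   vertex `v_i` and its incident segments, `MP` the averaged curvature
   penalty (the classic angle penalty `CP(v_i) = r²(1 + cos γ_i)` is kept
   for ablations), and `r` the data radius. The optimized vertex sequence
   `D = {(t_i, (v_x, v_y))}` (chord-length `t`) is finally fit by a small
   adaptive-learning-rate backpropagation network (ABNN), whose trained
   weights constitute an explicit, exportable formula for the contour:

   `f(t) = (h₂(Σ_i h₁(t·w1_i − m_i)·w2_{i,x} − u_x), …)` with sigmoid `h₁`
   and ReLU `h₂`.

Because clinical kidney ultrasound cannot ship with a package, kidseg
includes a seeded synthetic phantom generator (kidney-like shapes with a
hilum indentation, speckle, low contrast, blurred boundaries, optional
shadow wedges, and a Gaussian-noise corruption protocol at
σ ∈ {0, 10, 25, 50}) with exact analytic ground truth, plus an experiment
harness: six-model component ablation, noise robustness, and a four-variant
fusion comparison. It is aimed at researchers studying contour-based
refinement of learned segmentations, and usable wherever a single closed
organ boundary must be extracted and expressed as a formula.

## Worked example

```r
library(kidseg)

# a synthetic kidney phantom with exact ground truth
ph <- generate_phantom(phantom_spec(shape_seed = 1))

# refinement alone: polygon-track the true mask's boundary, fit the contour net
res <- segment_refine(ph$image, coarse_mask_override = ph$mask,
                      truth_mask = ph$mask)
res$metrics
#> # A tibble: 2 × 5
#>   stage     dsc jaccard n_fg_a n_fg_b
#>   <chr>   <dbl>   <dbl>  <int>  <int>
#> 1 coarse  1       1       3521   3521
#> 2 refined 0.981   0.962   3527   3521

glance(res$aspt)
#> # A tibble: 1 × 5
#>   n_points n_vertices mode_count rounds final_objective
#>      <int>      <int>      <int>  <int>           <dbl>
#> 1      197         17         17     10          0.0430

# the explainable contour formula (weights ARE the map)
export_map(res$abnn, "contour_map.json")
head(eval_exported_map("contour_map.json", c(0, 0.25, 0.5)), 3)
#> # A tibble: 3 × 3
#>       t      x      y
#>   <dbl>  <dbl>  <dbl>
#> 1  0    -0.963 -0.361
#> 2  0.25  0.393 -0.917
#> 3  0.5   0.921  0.460
```

The `coarse` row scores the injected mask (here the ground truth itself, so
DSC = 1); the `refined` row scores the rasterized ABNN contour against
truth — 0.981 means the automatically discovered 17-vertex polygon plus the
smooth closed-form fit reproduce the phantom boundary to within about a
pixel. The exported-map rows are normalized coordinates; pass
`image_transform` to evaluate directly in pixels. The
exported JSON contains `s, w1, m, w2, u`, the head type and the output
transforms: the contour can be evaluated anywhere with plain arithmetic.

Training the coarse stage end to end (desk scale: 64 training phantoms,
30 epochs, about five minutes on one CPU):

```r
ds  <- phantom_dataset(64, 8, 16, master_seed = 1)
fit <- train_dfln(build_model(dfln_config(variant = "parallel2", seed = 1)), ds)
rep <- run_noise_robustness(ds, fit, seed = 1)
glance(rep)
```

A thin command-line interface over the same functions lives at
`inst/cli/kidseg.R` (`phantom`, `train`, `segment`, `refine`, `fit-contour`,
`ablation`, `noise`, `variants` subcommands).

## Package layout

| Area | Contents |
| --- | --- |
| `phantom_spec()`, `generate_phantom()`, `make_dataset()` | synthetic ultrasound phantoms with exact truth |
| `build_model()`, `train_dfln()`, `predict_mask()`, `se_block()`, `ag_block()`, `dice_loss()` | the fusion U-Net coarse stage |
| `run_aspt()`, `mean_shift_modes()`, `optimize_vertices()`, `penalized_distance()` | polygon tracking refinement |
| `train_abnn()`, `export_map()`, `eval_exported_map()`, `sample_contour()` | the closed-form contour network |
| `dsc()`, `jaccard()`, `rasterize_polygon()`, `extract_contour_vertices()` | geometry and evaluation |
| `segment_refine()`, `run_ablation()`, `run_noise_robustness()`, `compare_fusion_variants()` | end-to-end pipeline and experiments |

The methods vignette (`vignettes/kidseg-methods.Rmd`) documents the models,
parameter choices and limitations in detail.
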