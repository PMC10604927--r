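---
title: "Coarse-to-refinement kidney ultrasound segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-to-refinement kidney ultrasound segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

kidseg implements a two-stage contour-extraction cascade for kidney
boundaries in 2D B-mode ultrasound. Stage one is a learned *coarse*
segmenter: a U-Net whose skip connections are modulated by
squeeze-and-excitation (SE) and attention-gate (AG) modules. Stage two is a
geometric *refinement*: the coarse mask's boundary pixels are treated as a
noisy point cloud through which a closed principal curve is tracked — vertex
discovery by adaptive mean-shift clustering, vertex placement by minimizing a
penalized distance — and the resulting vertex sequence is finally compressed
into an explicit closed-form map $f(t) = (v_x(t), v_y(t))$ by a small
three-layer network whose weights *are* the contour formula.

This vignette records the models, the tunable parameters and their defaults,
the numerical choices, and what the synthetic phantom experiments do and do
not establish.

## The coarse segmenter

The backbone is a plain encoder/decoder U-Net (3×3 convolutions, ReLU, 2×2
max pooling, nearest-neighbour upsampling). At each skip connection two
modules recalibrate the features:

* **SE** squeezes a channel descriptor by *global max pooling* (the design
  uses max, not the conventional average; `se_pool = "avg"` switches for
  comparison), passes it through two 1×1 convolutions with ReLU then
  sigmoid, and scales each channel by the resulting gate in $(0,1)$.
* **AG** concatenates the skip features with the upsampled decoder features,
  applies ReLU, a 1×1 convolution and a sigmoid, and multiplies the
  per-pixel attention coefficient into the skip features.

Four fusion variants wire these together: `serial1` (AG→SE), `serial2`
(SE→AG), `parallel1` (AG alongside SE on the *decoder* stream) and
`parallel2` (AG alongside SE on the *encoder* skip — the default, which the
variant comparison favours). The parallel combiner is an element-wise sum of
the AG-attended skip and the SE-recalibrated stream; the fused features are
concatenated with the upsampled decoder features. The sum keeps the two
parallel paths symmetric and channel counts unchanged; the parallel wiring
is otherwise a free design choice, so it is recorded here and in the
checkpoint sidecar to keep variants comparable.

Training minimizes the smoothed Dice loss
$1 - (2\sum pq + \varepsilon)/(\sum p + \sum q + \varepsilon)$ with
$\varepsilon = 1$, using Adam (lr $10^{-3}$, batch 8) and rotation
augmentation within $[-20^\circ, 20^\circ]$. Masks are thresholded at 0.5
and reduced to the largest 4-connected component, because the refinement
stage assumes a single closed object. The network is implemented directly
over BLAS matrix products (im2col convolutions with a compiled gather and
hand-derived backward passes, verified against numerical differentiation in
the test suite); it is deliberately small and fully seeded, so training is
bit-reproducible on a fixed BLAS.

**Scale.** Defaults are desk-scale: 96×96 network inputs, depth 3, 8 base
channels (~135k parameters). Phantoms are generated at 128×128 and resized
internally on their way into the network, with the probability map resized
back — mirroring the clinical workflow in which acquisitions are resampled
to a fixed network resolution while evaluation stays at native resolution.
The bundled experiments train on 64 phantoms for 30 epochs (validation 8,
test 16); these sizes keep a full experiment on a single CPU in the minutes
range and are stated here as the package's reference conditions.

## Polygon tracking (the refinement core)

The coarse boundary pixels $P_{iv}$ are min-max normalized to
$[-1,1]^2$ per axis; all geometry happens there, and the transform is
inverted only on output.

**Vertex discovery.** Each point ascends the sample-point Gaussian KDE with
per-point bandwidths $h_i$ = distance to the $k$-th nearest neighbour
(default $k = 4$). Converged positions within half the median bandwidth are
merged greedily into modes: a position joins the first existing mode seed in
range, otherwise it seeds a new mode. Greedy centre-based merging matters:
boundary clouds are quasi-uniform closed curves, and single-linkage merging
at the same radius chains them into a single cluster. Trajectories that have
not converged after `max_iter = 500` iterations (tolerance $10^{-4}$ in
normalized units) join their nearest mode and are counted in a warning. The
number of modes — hence the polygon's vertex count — is never supplied by
the user; that is the method's defining property.

The default $k$ deserves a note. Bandwidths already grow with local spacing
through the $k$-NN distance, so $k$ itself can stay a small constant; a
percentage-of-$n$ rule re-coarsens exactly the dense boundaries where detail
is available. With $k = 4$, 128×128 phantom boundaries (~200 pixels) yield
15–25 vertices and truth-mask repolygonization DSC ≈ 0.97; $k = 10$
collapses the same boundaries to 5–6 vertices (DSC ≈ 0.89), which is too
coarse to represent the hilum indentation.

**Vertex ordering.** Modes are sorted by polar angle about their centroid
(ties by radius) into a counter-clockwise polygon; if that sort
self-intersects — possible for strongly non-star-convex mode sets — a
nearest-neighbour chaining fallback is used. Kidney sections are close to
star-convex, so the fallback is rarely taken.

**Vertex optimization.** The data are partitioned by nearest *feature*:
every point belongs to exactly one vertex set $V_i$ or segment set $S_i$,
whichever is closest (vertex-segment ties go to the vertex). This joint
Voronoi partition — the classic polygonal-line formulation — is what makes
on-curve data have zero fitting error; assigning every point to both a
vertex and a segment would charge mid-segment points a spurious
vertex-distance term and shrink the polygon. Each vertex carries an average
squared distance
$\Delta(v_i) = \sigma_-(v_i) + \tau(v_i) + \sigma_+(v_i)$ (vertex-assigned
points to the vertex, segment-assigned points to the two incident
segments; every vertex of a closed polygon is interior, so the open-curve
end cases never fire). The *modified* penalty is
$MP(v_i) = \frac{1}{is}\sum_j \overline{d^2}(S_j, v_i)$, the mean over
segments of the mean squared distance of each segment's points to $v_i$;
the *standard* penalty is the turn-angle form
$CP(v_i) = r^2(1 + \cos\gamma_i)$ with $r$ the data radius. The objective
per vertex is

$$G'(v_i) = \frac{1}{iv}\Delta(v_i) + \lambda\,\frac{1}{k+1}\,MP(v_i),
\qquad \lambda = \lambda'\, iv^{1/3}\, \sqrt{\bar\Delta} / r,$$

with $k$ the segment count and $\lambda' = 0.13$. Two design choices here
are worth flagging. First, the exact normalization of $\lambda$ admits
several formulations in the polygonal-line literature; the implementation
uses the Kegl-style scaling above ($iv^{1/3}$ times the root-mean average
squared distance over the data radius), and `lambda_prime` is exposed so an
alternate scaling is a one-line change. Second, $MP$'s summand could bind
its point variable in more than one way; the mean-over-segments reading
above degenerates gracefully (empty segments contribute 0) and is
scale-consistent with $\Delta$. The standard-penalty objective $G$ is kept
with the same $1/iv$ data-term weight so the ablation between the two
optimizers varies only the penalty term.

Optimization is cyclic coordinate descent: each vertex in turn minimizes the
*total* objective $\sum_i G'$ over its x then y coordinate by golden-section
search within ± half the median data bandwidth — additionally capped just
under the shorter incident edge, so a vertex can never overtake a
neighbour and tangle a densely-sampled polygon — with partitions and
$\lambda$ recomputed for every candidate. Moves are accepted only when the
total objective decreases, so the objective trace is non-increasing by
construction (an increase aborts as an internal error). The line search
evaluates an incremental form that updates only the moved vertex's column
and its two incident segments — including the first-index tie-break for
points equidistant to a shared vertex's two segments, which is a common
configuration, not an edge case — and the tests pin the incremental
evaluation to the reference implementation at $10^{-15}$ and both to an
exhaustive brute-force oracle at $10^{-10}$. Sweeps stop at `max_rounds`
(10) or when a round's relative improvement drops below `rel_tol`
($10^{-3}$); since the objective is nonnegative, a tolerance ≥ 1 returns
the initial polygon untouched.

**Parameterization.** Vertices receive $t$ by normalized cumulative chord
length ($t_1 = 0$, perimeter-normalized, so $t_{iv} < 1$), rather than by
index: the downstream contour network then sees arc-length-like geometry,
and near-uniform vertex spacing yields near-uniform $t$.

## The closed-form contour map

The vertex sequence $(t_i, (x_i, y_i))$ is fit by a 1–$s$–2 network:
$\text{hidden}_i = \text{sigmoid}(t\,w_{1i} - m_i)$,
$\text{output}_j = h_2(\sum_i \text{hidden}_i w_{2ij} - u_j)$ with $h_2$ the
ReLU (default) or an exponential. The exponential head is retained for
comparison with formulations that exponentiate the output pre-activation;
both are implemented, ReLU is the default, and the choice is recorded in
the exported map. After training, the weights are
exported as JSON; an independent scalar-loop evaluator reproduces the
network to $10^{-12}$, which is the "explainable formula" contract: the
contour is the formula, no network runtime required.

Numerical choices that made this trainable under the fixed protocol
(SGD, momentum 0.9, initial learning rate 0.4, at most 1000 epochs):

* **Output range.** ReLU outputs are nonnegative; normalized coordinates are
  signed. Targets are affinely mapped per axis into $[0.1, 0.9]$ before
  training and inverse-mapped on output; the transform travels with the fit
  and the exported map.
* **Initialization.** Hidden weights $w_1 \sim U(-8, 8)$; hidden thresholds
  $m_i = c_i w_{1i}$, $c_i \sim U(0,1)$, so the sigmoid transitions cover
  $t \in [0,1]$ (all-zero thresholds stack every transition at $t = 0$, a
  nearly collinear basis the optimizer cannot separate within the epoch
  budget). Output thresholds start at −0.5 so the ReLU head is active.
  The output layer then starts from the ridge least-squares solution on the
  random sigmoid basis (an extreme-learning-machine-style closed form,
  seeded and deterministic); gradient descent refines all layers jointly
  from there. Without that start, the circle benchmark stalls an order of
  magnitude short of its target accuracy.
* **Adaptive rate rule.** The rule named but not defined in the source
  literature is implemented as increase-on-improve (×1.05) /
  reject-and-damp-on-worsen (×0.7, parameters and velocity restored).
  Additionally, a ReLU output that turns off for the *entire* batch has an
  identically zero gradient forever; because the mapped targets are strictly
  positive that state is never optimal, so the trainer lowers that unit's
  threshold until it reactivates. The safeguard applies to the fixed-rate
  variant too, so the ablation between fixed and adaptive rates isolates
  the rate rule itself.
* **Closure.** For closed contours the first vertex is appended at $t = 1$
  so $f(0) \approx f(1)$; the residual closure gap is reported with the fit.
* **Stopping.** Epoch cap 1000 (the reference protocol) or a relative loss
  plateau below $10^{-10}$ sustained for 25 epochs.

"Stochastic" gradient descent is honoured by an optional minibatch flag; the
default is full batch, because a vertex sequence has tens of points.

## The phantom generator

Real trans-abdominal kidney data cannot ship with the package, so the
experiments run on a synthetic phantom whose ground truth is analytic. The
shape is an ellipse (default semi-axes 0.32·W × 0.22·H, i.e. roughly 2:1.5
aspect), plus a cosine-bump medial indentation (the hilum; depth a fraction
of the short semi-axis, angular half-width 0.6 rad) and a low-order Fourier
radial perturbation (orders 2–4, amplitude a fraction of the mean radius)
for inter-subject variation. The mask is the exact rasterization of this
radial function at pixel centres; the contour is the same function sampled
at 256 angles, so mask and contour agree by construction (DSC ≥ 0.99 is
asserted per sample).

The texture model is deliberately first-order: foreground mean = background
mean + `contrast_gap` (default 45 of 255 — low contrast is the point),
multiplied by unit-mean gamma speckle (shape $1/s^2$, default $s = 0.35$),
optionally attenuated in an angular wedge to mimic intestinal-gas shadowing,
then Gaussian-blurred (default σ 1.2 px) to soften the boundary. The noise
protocol adds seeded Gaussian noise on the 8-bit scale
(`clip(round(img + N(0, σ²)))`) at σ ∈ {0, 10, 25, 50}.

What the phantom does *not* emulate: beam-dependent anisotropic speckle and
point-spread, attenuation with depth, acoustic enhancement behind fluid,
neighbouring organs, and the full variability of clinical kidneys. Passing
the bundled experiments therefore demonstrates that the cascade's machinery
is correct and beneficial under controlled conditions — not that clinical
accuracy figures transfer. Published results on private clinical data are
accordingly not acceptance targets for this package; the experiments assert
directions (refinement ≥ coarse; accuracy non-increasing with noise), not
clinical numbers.

## Experiment harness

`run_ablation()` evaluates the six-model component grid, sharing one trained
Parallel-2 checkpoint across all rows (the ablation isolates refinement
components, and its rows all list the same coarse stage). "MSC" rows use a
single global bandwidth equal to the median of the adaptive ones, so the
AMSC-vs-MSC comparison changes exactly one factor; "BNN" rows disable the
adaptive-rate rule; model 1 is the coarse network alone; model 6 is the full
method. `run_noise_robustness()` applies the σ protocol to the test split
(σ = 0 is the identical uncorrupted evaluation by construction).
`compare_fusion_variants()` trains all four variants with identical seed and
budget and logs parameter counts. Every report stores per-image metrics, the
summary recomputes from them exactly, and identical seeds reproduce reports
byte-for-byte.

## Known limitations

* The refinement assumes one closed object; multi-object scenes are out of
  scope (the coarse stage keeps the largest component).
* Mean-shift vertex discovery needs boundaries dense enough relative to the
  bandwidth; very small masks (tens of boundary pixels) can yield too few
  modes, which surfaces as an explicit error suggesting a smaller `k`.
* The contour map is a function of $t$, not a closed periodic basis; the
  closure constraint is soft (trained, with its residual reported), not
  structural.
* Bit-reproducibility holds for fixed BLAS/compiler; across different BLAS
  builds, floating-point sums may differ in the last ulp.
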