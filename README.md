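# lumicode

Analysis pipeline for how the input and output layers of macaque primary
visual cortex (V1) encode the luminance of uniform surfaces versus edges.

When a uniform 4×4° luminance square is flashed over a neuron's receptive
field, laminar multi-unit recordings show two distinct signals: a *surface*
response (square interior over the receptive field) and an *edge* response
(luminance border over the receptive field). Between the thalamo-recipient
input layer (4C) and the output layers (2/3, 4B), surface responses are
strongly suppressed while edge responses survive — and the population code
for the square's luminance switches from surface-carried to edge-carried.
`lumicode` implements the complete analysis behind that observation for
anyone who wants to run it on laminar response tensors or study it on
synthetic data with known ground truth:

* **Response metrics** — edge/surface time courses from a response tensor
  R(x, y, l, τ) (sums over the band `1.7 < |x| < 2.3, |y| < 0.5` and the
  region `|x|, |y| < 0.5`), shared-max normalization, SNR (signal/blank
  variance ratio, reliable when > 3), sustain index
  (∫₁₂₀–₂₀₀ / ∫₄₀–₂₀₀), surface/edge (S/E) ratio in early (40–100 ms) and
  late (120–180 ms) windows, filling-in strength (late − early S/E), and
  the surface/edge suppression indices of the 20-ms reverse-correlation
  protocol.
* **Decoders** — an L1-regularized linear luminance decoder
  (`J = (1/m)Σ(Yᵢ − XW − w₀)² + (λ/m)|W|₁`, coordinate descent, 60/15/25
  stratified splits, λ fixed at 0.7 or selected over 20 log-spaced values
  in [0.001, 40]) scored by bootstrap rank-order accuracy
  (black < gray < white over 1000 sampled triples; chance = 1/6), a
  logistic L1 location decoder (edge vs surface, λ = 0.1), time-resolved
  accuracy in 50-ms bins, population-size curves, and a multiplexed
  location-then-luminance decoder.
* **Transmission model** — forward models of the input→output laminar
  transform on a 1-D axis of receptive-field offsets: Gaussian spatial
  pooling (extent σ_E), unit-sum log-Gaussian temporal kernels, and
  position-class gains (model A); plus a subtractive nonlocal inhibitory
  pathway (extent σ_I, model B). Fitting is bounded Levenberg–Marquardt
  with seeded multistarts; goodness of fit is the adjusted symmetric
  variance-explained score; the inhibition-range scan profiles fit quality
  against σ_I; the I/E ratio summarizes inhibition strength.
* **Synthetic generator** — laminar tensors, frame/square
  reverse-correlation pairs and single-trial populations with recorded
  ground truth; the default regime uses the fitted output-layer estimates
  (σ_I = 2σ_E; surface I/E 1.1 white / 0.74 black) as generator
  parameters.
* **Coding-strategy experiment** — simulates populations under
  excitation-only vs excitation+inhibition transforms and quantifies the
  redistribution of luminance information with paired t-tests.

## Worked example

```r
library(lumicode)

gt <- default_ground_truth()          # input tensor + calibrated model B
input  <- gt$input_tensor
output <- generate_output_layer_tensor(input, gt$model_params, model = "B")

## surface/edge ratio collapses from input to output layer
site_metrics(input, 1)[, c("se_ratio_early", "se_ratio_late", "filling_in")]
#>   se_ratio_early se_ratio_late filling_in
#> 1      0.4174811     0.5190243  0.1015432
site_metrics(output, 1)[, c("se_ratio_early", "se_ratio_late")]
#>   se_ratio_early se_ratio_late
#> 1      0.0678739    -0.3632468

## the coding-strategy switch
res <- run_strategy_experiment(input, gt$model_params,
                               strategy_config(n_populations = 10, seed = 3))
res
#> <strategy_result> mean rank accuracy (%) by condition set and location:
#>  condition_set location mean_accuracy       sem
#>          input  surface         91.48 2.9490413
#>          input     edge        100.00 0.0000000
#>        model_a  surface        100.00 0.0000000
#>        model_a     edge        100.00 0.0000000
#>        model_b  surface         97.09 0.9592184
#>        model_b     edge        100.00 0.0000000
#> surface model A vs B: mean diff 2.91, p = 0.0142
```

Reading the output: the white-square S/E ratio drops from ≈ 0.42 in the
input layer to ≈ 0.07 early (and below zero late, the suppressed "hole")
in the model-B output layer. In the experiment, pooled excitation alone
(model A) lets both readouts saturate, and adding nonlocal inhibition
(model B) significantly lowers surface-based luminance accuracy while
edge-based accuracy is untouched — the coding-strategy switch.

A command-line wrapper covers the same pipeline
(`inst/cli/lumicode simulate | metrics | decode | fit-model | experiment`),
writing datasets as plain-text directories (CSV tensors + JSON manifests)
with a run manifest beside every output.

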