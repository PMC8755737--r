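---
title: "Laminar processing and decoding of surface luminance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laminar processing and decoding of surface luminance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumicode)
```

## The scientific problem

When a uniform luminance square covers a V1 neuron's receptive field (RF),
the cell can respond to the square's *surface* (its uniform interior) or to
its *edges* (the luminance borders). Laminar recordings show that these two
signals are transformed differently between the thalamo-recipient input
layer (4C) and the output layers (2/3, 4B): edge responses survive the
transform largely intact, surface responses are strongly suppressed, and —
critically — the population code for the square's luminance *switches* from
being carried mainly by surface responses in the input layer to being
carried mainly by edge responses at the output. `lumicode` implements the
full analysis chain behind that observation: response-metric extraction,
L1-regularized population decoding with bootstrap rank-order scoring, a
spatiotemporal excitation–inhibition transmission model, and a synthetic
generator that ties everything to known ground truth.

## Response tensors and scalar metrics

The primitive data object is the trial-averaged response tensor
$R(x, y, l, \tau)$: the MUA response of one site as a function of the square
center's offset from the RF center ($x, y$, degrees), the luminance label
$l \in \{-1, 0, +1\}$ (black, gray/blank, white) and peristimulus time
$\tau$ (ms). The edge response sums the tensor over the band
$1.7 < |x| < 2.3,\ |y| < 0.5$ (vertical edges) or its transpose (horizontal
edges), keeping whichever orientation has the larger baseline-subtracted
peak over 0–300 ms; an exact tie goes to vertical. The surface response
sums $|x| < 0.5,\ |y| < 0.5$. Both are normalized by the maximum of their
concatenation, so relative strengths are comparable across sites.

Scalar indices derived from these time courses:

* **SNR** — sample variance over 0–300 ms after onset divided by sample
  variance over the 0–50 ms pre-onset blank; a site is reliable when
  SNR > 3. Whether these are sample or population variances is a
  convention; sample variance is used, and a zero blank variance returns
  `Inf` with a warning rather than an error.
* **Sustain index (SI)** — fraction of the rectified 40–200 ms response
  integral falling after 120 ms. Windows are half-open (`[40, 200)`,
  `[120, 200)`) so the discrete 1-ms sums match the continuum integrals: a
  flat response gives exactly 0.5. Negative (below-baseline) values are
  clipped before integration, keeping SI in [0, 1].
* **S/E ratio** — mean surface over mean edge response in a window; the
  early window is 40–100 ms, the late window 120–180 ms. **Filling-in
  strength** is the late-minus-early change in S/E.
* **Surface suppression** — for the 20-ms pulsed (reverse-correlation)
  protocol the surface response is biphasic; the index is
  $N/(N+P)$ with $P$ the integrated positive lobe and $N$ the absolute
  integrated negative lobe over 0–250 ms (the full post-stimulus window;
  the lobes' exact integration window is a convention).
* **Edge suppression** — $(\text{frame} - \text{square})/\text{frame}$ on
  window-integrated edge responses: the fractional weakening of a square's
  edge relative to the same edge shown as an empty frame.

Baseline handling is uniform: the mean of the −50–0 ms window is subtracted
before index computation, because the suppression indices need signed
lobes. Degenerate inputs (all-zero responses, zero denominators) return
flagged missing values, never divide-by-zero errors.

## Luminance and location decoders

The luminance decoder is linear, $L = XW + w_0$, fit on per-site-normalized
trial responses averaged over 40–250 ms by minimizing

$$J = \frac{1}{m}\sum_i (Y_i - L_i)^2 + \frac{\lambda}{m}\lVert W\rVert_1 .$$

The location decoder is a logistic classifier
$P(\text{edge}\mid X) = 1/(1+e^{-(XW+w_0)})$ with penalty
$\frac{\lambda}{2m}\lVert W\rVert_1$ and rule $p \ge 0.5 \Rightarrow$ edge.
The two penalty scalings ($\lambda/m$ vs $\lambda/2m$) are intentionally
different — each loss is implemented exactly as specified — and both map
onto the conventional lasso scale $\lambda_g = \lambda/(2m)$, which is how
the test suite cross-checks the solvers against an independent
implementation (glmnet). The in-package solvers are cyclic coordinate
descent with soft thresholding (linear) and FISTA proximal gradient
(logistic), with a 1e-8 objective-change tolerance: deterministic,
dependency-free, and verified to 1e-4 per weight. As printed, the logistic
link in the source formulation lacks the conventional negative sign; the
standard orientation (higher score → higher edge probability) is used so
that training labels are fit consistently.

Designs are split 60/15/25 into training/validation/test, stratified by
(luminance × location) cell and seeded. Per-site normalization scales are
computed from the *training split only*, so nothing about the test trials
— not even their maxima — touches the fit; a data-poisoning test (corrupt
the test rows, refit, compare weights) enforces this. λ can be fixed (0.7
for luminance, 0.1 for location, the canonical choices) or selected on the
validation split over 20 log-spaced values from 0.001 to 40.

Accuracy is **bootstrap rank-order accuracy**: sample one predicted
luminance per condition (black, gray, white), score the triple correct iff
the predictions order black < gray < white, repeat 1000 times. Chance is
1/6. Exact ties count as incorrect — a measure-zero event for continuous
predictions, made deterministic for degenerate ones (a fully shrunk decoder
predicts a constant and scores 0, not chance; chance calibration must
therefore be read out at small λ).

Time-resolved decoding applies a decoder trained on the 40–250 ms window to
responses averaged in serial 50-ms bins from −50 to 250 ms; pre-stimulus
bins sit at chance. Population-size curves resample sites without
replacement (100 populations per size) and refit; the split and bootstrap
streams are shared across populations so that at full size all populations
coincide and the s.e.m. is exactly zero.

## The transmission model

The input→output laminar transform is modeled on a 1-D spatial axis of
RF-center offsets $j$ (degrees). Model A is pooled excitation only:

$$E(i,\tau) = \Big[\sum_j R_{\mathrm{in}}(j,\cdot)\,
  e^{-(j-i)^2/2\sigma_E^2}\Big] \otimes K_E \times w^E_{c(i)},$$

with a log-Gaussian temporal kernel
$K(t) = \exp\!\big(-(\log t - \text{delay})^2/2\sigma_k^2\big)$ evaluated on
$t = 1\ldots250$ ms and normalized to unit sum, so the gains carry all
amplitude. The gain $w^E$ depends on the stimulus-position class of the
output site (surface vs edge). Model B subtracts a nonlocal inhibitory
pathway built the same way with its own extent $\sigma_I$, kernel and gain
$w^I$; setting $w^I = 0$ reduces B to A exactly, and the output is *not*
rectified — negative predictions are meaningful (suppression below
baseline). Convolution is causal with $t = 1$ acting instantaneously, so a
delta kernel is exactly the identity and the kernel mode sits at
$t = e^{\text{delay}}$ ms.

Because the pathway gains carry a site index in the model formulation, the
generator optionally uses a distinct inhibitory gain for edge-class sites
(`w_i_edge`); fitting always uses the single-gain form.

**Goodness of fit** is the adjusted symmetric variance-explained score

$$1 - \frac{2\sum_\tau (R_{\mathrm{data}} - R_{\mathrm{fit}})^2}
  {T(\mathrm{var}\,R_{\mathrm{data}} + \mathrm{var}\,R_{\mathrm{fit}})}
  \cdot \frac{T-1}{T-p_n},$$

with population variances (config-exposed) and $p_n$ the fitted model's own
free-parameter count (5 for A, 9 for B with shared kernels). It equals 1
only for a perfect fit and is scale-invariant.

**Fitting** is bounded nonlinear least squares: Levenberg–Marquardt on the
residual vector (tolerances 1e-14), with seeded random multistarts inside
the bounds ($\sigma \in [0.05, 3]°$, delays $\in [0, 6]$ log-ms, kernel
widths $\in [0.05, 3]$, gains $\in [0, 10]$). Quasi-Newton descent on the
scalar MSE was tried first and converges orders of magnitude less deeply on
this landscape's flat valleys, which matters because profile comparisons
(the inhibition-range scan) are decided by objective differences of order
1e-6. Targets are fit jointly with shared kernels and position-class excitatory
gains — either a surface and an edge time course (the per-site fit) or a
full response profile across stimulus positions (`target` matrix). The
distinction matters for identifiability: with only two fitted positions
and free class gains, the pooling extent $\sigma_E$ is constrained only by
subtle waveform mixing and its estimate scatters by tens of percent under
5% noise, whereas a profile target pins both extents through the spatial
decay across positions (recovery within a few percent). Position-resolved
tensors provide exactly that profile, so recovery and range-scan
experiments fit profiles. Known degeneracy: kernel amplitude trades off
against the gains, broken by unit-sum kernel normalization; recovery is
assessed on identifiable quantities (the $\sigma$'s, gain ratios, kernel
mode times). The inhibition-range scan clamps $\sigma_I$ at each grid
value and refits everything else, starting each point from its neighbor's
optimum, the unconstrained optimum (anchor), the default start and random
draws — without the anchor the constrained refits can lodge in local
minima whose depth differences exceed the profile's curvature near its
peak.
The **I/E ratio** is operationalized as time-integrated $|I|$ over
time-integrated $|E|$ at a given site for the fitted stimulus; it is
exactly proportional to $w^I$, which makes calibrating the gain to a target
I/E a closed-form solve.

## The synthetic generator and what it emulates

`generate_input_layer_tensor()` builds a noiseless input-layer tensor:
uniform surface drive over the square interior, edge drive over the border
band, nothing outside, zeros for the blank. The defaults are the study
conditions:

* 4×4° squares at 90% contrast, 300 ms flashed or 20 ms pulsed; frames
  with a 0.2° border carry edge drive only (interior exactly zero).
* Spatial grid: 0.2° bins, centers −3.4…3.4°, chosen so the edge band
  contains exactly three centers per side (the source analyses never state
  their binning; this is a declared convention).
* Time base: 1-ms bins, −50…300 ms.
* Temporal waveform: a saturating rise times a partial exponential decay —
  the simplest smooth transient-plus-plateau with independent latency
  (30 ms), rise (8 ms) and adaptation knobs. Surface drive is more
  sustained (adaptation fraction 0.3) than edge drive (0.6): this matches
  the recorded dynamics and is also what makes the spatial extents
  identifiable when fitting two positions (identical waveforms would make
  the targets scalar multiples of each other).
* Amplitudes are region-summed (surface 0.4, edge 1.0 for white), so the
  extracted time-course peaks equal the parameters and the early
  input-layer S/E ratio lands near the recorded input-layer value (~0.35–0.42).
* Black responses are white × 1.2 (black dominance).

`generate_output_layer_tensor()` pushes the tensor through the transmission
model along the axis perpendicular to the probed edge (rows along x where
$|x| \ge |y|$, columns along y otherwise) — the 1-D cross-section geometry
of a laminar track; pooling along an edge's own length would otherwise
manufacture spurious suppression of extended edges. 2-D pooling is out of
scope.

The **default ground truth** uses the fitted estimates for macaque V1
output layers as generator parameters: $\sigma_I = 2\sigma_E$ with
$\sigma_I$ = 0.80° (white) and 0.53° (black), surface-site I/E calibrated
to 1.1 (white) and 0.74 (black), and edge-site I/E at half those values
(edge inhibition is clearly the weaker of the two in the fitted estimates;
its exact values are not printed, so one half is a declared reading).

`generate_trial_population()` emulates an *aggregated* population — the
recordings were not simultaneous, so no noise correlations are imposed.
Each synthetic site gets a log-normal overall gain (sd 0.3) and a
log-normal black/white preference (sd 0.5) around the tensor's asymmetry;
real V1 contains both black- and white-preferring sites, and without that
diversity a linear decoder could not order black below gray (black and
white patterns would be collinear). Trial noise is additive homoscedastic
Gaussian, by default 0.2 of the site's peak response, independent across
trials, sites and time bins. What the generator does **not** emulate:
correlated variability, spiking statistics, eye movements, RF-size
diversity, and laminar depth profiles beyond the two modeled layers —
passing tests here validate the pipeline's computations, not those aspects
of real data.

## The coding-strategy experiment

`run_strategy_experiment()` rebuilds the information-redistribution
comparison at desk scale: three condition sets (input layer, model-A
transform, model-B transform), 50 populations of 32 sites each, surface-
and edge-based luminance decoders at fixed λ = 0.7, rank accuracies, and
paired t-tests. Populations are paired across condition sets (same site
gains and noise draws), and all sets share one *absolute* noise SD derived
from the input dataset, so accuracy differences reflect signal
transformation, not noise rescaling.

The noise level sets the operating point. The default is 0.5 × the
reference peak response — a trial CV of one half for 210-ms windowed MUA
features, in the range of awake-recording variability. This places the
excitation-only decoders at ceiling while keeping the inhibition-induced
surface deficit visible; with much less noise every decoder saturates and
the redistribution is invisible (a property of the design, not a bug), and
with much more even the edge readout degrades. Under the defaults the
experiment reproduces the qualitative switch: surface-based accuracy drops
significantly under model B relative to model A while edge-based accuracy
is preserved, across seeds.

## Numerical choices and limitations

* Strict inequalities in the band definitions apply to bin centers; a
  center at exactly |x| = 0.5 is excluded.
* The lasso tie (orientation selection, λ selection) rules are
  deterministic and documented (vertical; smaller λ).
* Optimizer tolerances: 1e-8 objective change for the decoders;
  Levenberg–Marquardt `ftol`/`ptol` 1e-14 for the transmission fits; model
  nesting (GoF(B) ≥ GoF(A)) is verified by seeding B's fit at A's optimum
  with $w^I = 0$.
* Problem sizes in the shipped tests and acceptance script — 20 recovery
  replicates, 30 chance-calibration populations, 100 resampled populations
  per size point, 50 strategy populations — are the package's chosen
  desk-scale study sizes; they reproduce structure and direction, not the
  absolute accuracy values of any particular recording set, which depend
  on parameters fitted to data not shipped here.
* The dataset container is a plain-text directory (long-CSV tensors with
  17-significant-digit values for exact round trips, CSV trials, JSON
  manifest with required axis units); readers validate schema and units
  and fail with named errors.
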