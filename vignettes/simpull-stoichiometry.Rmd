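---
title: "Counting subunits by photobleaching: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting subunits by photobleaching: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the generative model behind the synthetic data, the detection and
step-counting procedures, the classifier, the replicate statistics, and
the numerical choices made wherever the design was genuinely open.

## The measurement

A single-molecule pulldown (SiMPull) experiment captures protein
complexes on a coverslip and images them by TIRF in two channels: green
for the bait (one GFP per bait molecule) and far-red for the prey (a
HaloTag dye, here with unknown labeling efficiency). Under continuous
excitation each fluorophore photobleaches once, irreversibly; the number
of discrete downward steps in a spot's intensity trace therefore counts
its fluorescent subunits. The quantity of interest is the *oligomeric
fraction*: among complexes whose green trace shows exactly one
photobleaching step (single bait), the percentage whose far-red trace
shows two or more steps (multiple prey copies).

## The generative model

`simulate_complexes()`, `simulate_traces()` and `render_movie()` implement
a forward model of the acquisition:

* **Acquisition** (`acquisition_params()` defaults): 1000 frames per
  channel at 20 frames/s, 108 nm pixels, Gaussian PSF with sigma = 1.3 px,
  camera baseline 200 counts, read noise sd 8 counts, single-fluorophore
  amplitude lognormal with mean 120 counts and sd 20% of the mean.
  Amplitudes are *per-fluorophore constants*, not per-frame draws, so that
  intensity losses are sustained steps — the semantics the labeling rule
  assumes.
* **Bleaching** is memoryless: each fluorophore's bleach time is
  exponential with rate `log(2) / (halftime_frac * n_frames)`. The
  defaults place the far-red half-time at 1/5 and the green at 1/10 of
  total imaging time, the regime the lasers are tuned to in the real
  acquisition. A fluorophore whose drawn time exceeds the movie length
  never bleaches on camera and contributes no countable step; this
  right-censoring is kept (clamping it would bias the half-time).
* **Blinking** is modeled as the transient re-appearance of one previously
  bleached fluorophore for a geometric-duration interval (mean 10 frames),
  at most one event per trace, with probability-like rate
  `blink_rate = 0.05` per trace per movie. Upward steps are the reason the
  counting rule stops early, so the generator must produce them.
* **Stoichiometry** (`stoich_model()`): green count degenerate at 1 (the
  bait is pulled down as a monomer); far-red count categorical over 0..4
  with default weights (0.40, 0.35, 0.15, 0.07, 0.03), a realistic mix in
  which a substantial minority of complexes carry multiple prey.
  `labeling_efficiency` binomially thins the far-red counts; no published
  value exists for the dye used, so the default is 1 and the parameter is
  exposed for sensitivity studies. Because unlabeled prey is invisible,
  any measured stoichiometry is a lower bound.
* **Rendering**: each complex is a 2-D Gaussian whose *pixel-integrated*
  mass (error-function differences over unit pixels) is scaled to the
  current noise-free trace value; Poisson shot noise applies to the
  signal, then baseline and Gaussian read noise are added. The far-red
  field is the green field mapped through an affine channel offset, and a
  sparse fiducial-bead image pair carrying the same offset is rendered for
  registration.

One deliberate asymmetry: in trace-level simulation the read-noise sd is
per *trace*, while in rendered movies the same parameter applies per
*pixel*, so a trace extracted from a movie (a 25-pixel sum minus a
background estimate) carries several-fold more read noise than a directly
simulated trace. Image-based demonstrations therefore use a 2-count
per-pixel read noise (typical of sCMOS detectors), while trace-level
analyses keep the 8-count default.

What the generator does **not** emulate: evanescent-field depth and uneven
illumination, stage drift, EM-gain excess noise, spectral bleed-through,
non-specific surface binding, and dye dark states longer than a blink.
Passing tests on this generator show the *analysis* is correct and
unbiased under the stated model, not that real lysate data are free of
those effects.

## Detection, registration, colocalization, extraction

The detection image is the mean of the first 50 frames (before most
bleaching at the default half-times). A difference-of-Gaussians band-pass
(sigmas `psf_sigma` and `2 * psf_sigma`) removes background; candidates
are strict 8-neighbor local maxima above `median + 5 * MAD` of the
band-passed image; centroids are intensity-weighted centers of mass in a
5x5 window; candidates closer than `2 * psf_sigma` merge, keeping the
brighter. These details are standard single-molecule practice and all are
exposed as arguments. Coordinates are 0-based `(row, col)` with pixel
centers at integers, and the affine registration acts on subpixel
centroids — images are never resampled.

Over-dense fields are *flagged*, not dropped: the screening convention
caps accepted fields at `imgArea / 3e5` spots, but the divisor presumes a
full-frame sensor and its unit (pixels² vs nm²) is not fixed by
convention, so `max_spots` is configurable and a `rejected` field still
returns its spots.

Registration fits the 6-parameter affine map from far-red bead centroids
to green bead centroids by least squares after nearest-neighbor matching
within a 10 px gate; fewer than 3 matched beads is an error, and an RMS
residual above 1 px flags the map. Colocalization pairs **mutual** nearest
neighbors within 2 px — one-directional matching is ambiguous in dense
fields — with ties broken by distance, then lower spot id, making the
pairing deterministic and order-invariant.

Traces are extracted as the 5x5 window sum minus 25 times the median of
the surrounding 9x9-minus-5x5 ring; the median resists bias from
neighboring spots. Spots without a full 9x9 neighborhood are flagged and
excluded downstream.

## Step counting (the labeling oracle)

`count_steps_oracle()` encodes the manual labeling criteria as an
algorithm, so that labels are reproducible and the CNN has a well-defined
teacher:

1. Segment the raw trace (camera counts — the 25-count threshold is in
   counts, so normalization must *not* precede counting) into
   piecewise-constant levels by iterative binary changepoint splitting
   under a squared-error cost. A split must leave both sides at least
   `min_duration` frames long and change the level mean by more than
   `noise_gate` robust noise sd (noise estimated as
   `mad(diff(x)) / sqrt(2)`; the gate floors at 1e-9 so noiseless traces
   still split).
2. Walk the changepoints in time order. A downward level change larger
   than `step_threshold = 25` counts is one photobleaching event; the
   first upward change larger than the threshold terminates counting
   (`early_stopped`), because after a re-appearance the remaining
   downward steps are unattributable.
3. A trace whose residual sd around the fitted levels exceeds half the
   median accepted step size is `too_noisy` — the algorithmic analogue of
   a human rejecting a trace whose variability hides discrete drops.

Defaults that the underlying convention leaves open, fixed here once:
"sustained" means `min_duration = 5` frames (0.25 s at 20 frames/s); the
noise gate is 3 robust sd; the too-noisy fraction is 0.5. Degenerate
inputs (too short, non-finite) yield 0 steps and `too_noisy`. Binning is
a pure function: far-red {rejected, 1-step, 2-step, 3-and-higher} (zero
steps or too noisy reject), green {rejected, 1-step} (anything but exactly
one accepted event rejects). Labels are "at least x" counts when counting
stopped early; the 3-and-higher class absorbs every count of three or
more.

Bleach half-times use first-step survival: `S(t)` is the fraction of
accepted traces whose first event falls after frame `t`, and the
half-time interpolates the 0.5 crossing linearly. This is defined purely
from per-trace annotations (ensemble-intensity decay would need no
annotations but mixes amplitudes into kinetics). Right-censoring at the
movie end biases the estimate slightly low — about 5% at a true half-time
of 1/5 of the movie, where ~3% of fluorophores never bleach — which is
why recovered half-times of ~190 frames against a nominal 200 are
expected, not a defect.

## The CNN classifier

No deep-learning framework is available to R in this package's dependency
set, and the classifier is the methodological heart of the analysis, so
the 1-D CNN is implemented directly on BLAS matrix products: im2col
convolution, ReLU, non-overlapping max-pooling, dense layers, softmax,
class-weighted cross-entropy, backpropagation and Adam
(`beta1 = 0.9, beta2 = 0.999, eps = 1e-8`), with He initialization. All
randomness (initialization, shuffling, splits, folds) derives from seeds,
so training is reproducible; metrics agree across runs to ~1e-4
(floating-point accumulation order via BLAS is the only slack).

Inputs are Z-scored traces (zero mean, unit *population* sd — the
population convention is deterministic and length-independent; at 1000
frames the difference from the sample sd is negligible). Zero-variance
traces cannot be normalized and are classified rejected. Input length is
fixed at 1000 frames; shorter/longer traces are zero-padded/truncated and
flagged.

Class imbalance (in production-scale manual labels, roughly
42/36/17/5% across the four far-red classes) is handled by inverse class
frequency weights `w_c = N / (K * n_c)` — normalized so that
`sum(n_c * w_c) = N` exactly; the convention fixes only the
proportionality `w_c ∝ 1/n_c`, and this is the standard normalization.

Model selection mirrors exploratory practice: a grid of architectures
(default demonstration grid: 39 configurations spanning kernel sizes
{5, 9, 15}, filter counts {8, 16, 32}, dense configurations
{(32), (64), (64, 32)} and two learning rates) is trained once on a
shared stratified 80/20 split and ranked by validation accuracy, with
ties broken by macro-F1 then by fewer parameters; the top five go to
stratified 5-fold cross-validation and the final pick maximizes mean CV
accuracy, after which the chosen configuration is retrained on 100% of
the labeled set. Stratified splits assign `round(n_c * 0.8)` of each
class (clamped so both sides keep every class), keeping per-split
proportions within one trace of the global ones.

Synthetic training labels come from the ground-truth number of bleaching
events *observable within the movie*, not the raw fluorophore count: a
fluorophore that survives the movie shows no step, and manual labels are
of visible events. Two fluorophores bleaching within the same instant
merge into one step; at the default kinetics this affects ~2% of
two-copy complexes and is the main irreducible confusion.

## Replicate statistics

Retained pairs (green non-rejected AND far-red non-rejected) are
summarized at both replicate levels because the convention "percentage per
replicate" is ambiguous: technical replicates get class counts and
percentages; biological replicates pool their technical *counts* (the
primary convention here) and also report the mean of technical
*percentages* (`oligomeric_pct_avg`) since either pooling is defensible.
Genotype level reports mean ± SEM over biological replicates. No
labeling-efficiency correction is applied — the measured oligomeric
fraction is a lower bound by construction — but the simulator's
`labeling_efficiency` lets users quantify that bias.

Genotypes are compared by nested one-way ANOVA: technical measurements
nested in biological replicates, genotype tested against the
biological-replicate stratum (`aov(y ~ genotype + Error(bio))`). For
balanced designs this is algebraically identical to a one-way ANOVA on
biological-replicate means (verified to 1e-9 in the tests), which is also
where Tukey's HSD is computed. A genotype needs at least two biological
replicates; empty replicates are flagged and excluded from means.

## Determinism and problem sizes

A single global seed derives per-stage seeds as
`(seed * 7919 + stage * 104729) mod (2^31 - 2) + 1`, so stages rerun
standalone reproduce the pipeline run; `run_all()` writes a manifest
(seeds, config hash, per-stage counts satisfying
`pairs = retained + rejected + orphaned`) and two runs with one seed are
byte-identical.

The shipped tests and scripts run at sizes chosen to exercise the
statistics convincingly on a single CPU: 500 noiseless staircases for
step-count exactness, 200 random fields against the brute-force pairing
reference, 8000/2000 train/held-out traces for the CNN (held-out macro-F1
typically ≥ 0.95 at default SNR), 2000 pairs for oligomeric-fraction
recovery (±5 points of the simulated 40%), 5000 events for half-time
recovery (±5%), and a 4-field demo for byte-level reproducibility. The
production-scale numbers these mirror (tens of thousands of manually labeled
lysate traces) are not reproducible from a generator, and the package
does not claim otherwise: synthetic recovery shows the machinery is
correct, not that any particular biological estimate is.

## Known limitations

* Step counting is rule-based changepoint detection, not hidden-Markov or
  Bayesian step inference; closely spaced or sub-threshold steps merge.
* The 3-and-higher class truncates counts; no binomial deconvolution of
  true copy number is attempted.
* First-step survival half-times are biased low by end-of-movie censoring
  (quantified above) and by early-stopped traces contributing only their
  pre-stop first step.
* The affine registration model excludes field distortion beyond first
  order; real optics may need higher-order maps.
* CNN accuracies quoted anywhere in this package are on synthetic labels;
  accuracy on manually labeled lysate data is a property of those labels
  and cannot be inferred from here.
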