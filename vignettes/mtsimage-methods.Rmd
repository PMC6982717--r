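---
title: "Classifying multivariate time series as concatenated field images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying multivariate time series as concatenated field images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtsimage)
```

## The problem

Sensor batches from manufacturing equipment or physiological recordings
arrive as multivariate time series (MTS): an instance is a set of $m$
aligned univariate channels $X = (x_1, \dots, x_m)$, each of common length
$T$ within the instance (lengths vary across instances), together with a
binary label such as *normal* versus *abnormal*. `mtsimage` classifies such
instances by first turning every channel into a two-dimensional colored
image, concatenating the per-channel images into a single RGB input, and
training a convolutional network on the result. The attraction of the
image route is that spatially local structure — spikes, level changes,
periodicities — becomes visual texture that a small ConvNet can pick up
without hand-designed features.

## From one channel to one image

Each channel is processed independently through three steps.

**Rescaling.** $\tilde{x}(t) = (x(t) - \min x)/(\max x - \min x)$ maps the
channel into $[0,1]$. A constant channel has no range; it maps to 0.5
everywhere so a flat sensor does not abort a batch (the MTF encoder still
refuses it, because a single distinct value cannot be binned). Rescaling is
per channel and per instance, so channels with different physical units are
comparable.

**Length normalization.** Images must share a size $n$, but instance
lengths vary. Series with $T \ge n$ are reduced by piecewise aggregate
approximation (PAA): contiguous segments with boundaries
$\lfloor l \cdot T/N \rfloor$ (sizes differing by at most one, exact
whenever $N$ divides $T$) are replaced by their means. Series with $T < n$
are linearly interpolated onto $n$ equally spaced points; interpolation
preserves shape without inventing structure, and is needed because a fixed
image size can exceed the shortest series length (e.g. size 128 against
wafer batches of length 104).

**Field encoding.** Three encoders are provided, selected by `condition()`:

- *GASF* (Gramian angular summation field):
  $M_{ij} = \cos(\phi_i + \phi_j)$ with $\phi = \arccos \tilde{x}$,
  equivalently $\tilde{x}\tilde{x}' - \sqrt{1-\tilde{x}^2}\,
  \sqrt{1-\tilde{x}^2\,}'$. Symmetric; the diagonal $2\tilde{x}_i^2 - 1$
  makes the rescaled series recoverable as
  $\tilde{x} = \sqrt{(\mathrm{diag}+1)/2}$.
- *GADF* (difference field): $M_{ij} = \sin(\phi_i - \phi_j)$.
  Antisymmetric, zero diagonal. (The summation/difference pair differ only
  in the trigonometric combination; the difference form is the one whose
  algebraic expansion
  $\sqrt{1-\tilde{x}^2}\,\tilde{x}' - \tilde{x}\sqrt{1-\tilde{x}^2\,}'$
  is antisymmetric, and is what this package implements.)
- *MTF* (Markov transition field): values are assigned to $b$ empirical
  quantile bins (right-closed, the lowest closed on both ends, ties
  resolved toward the lower bin index); a first-order transition matrix
  $W$ is estimated from consecutive pairs, rows with no outgoing
  transitions staying all-zero; then
  $M_{ij} = W[\mathrm{bin}(x_i), \mathrm{bin}(x_j)]$. Entries are
  probabilities in $[0,1]$ and the field is generally asymmetric. The
  default $b = 8$ keeps a usable bin resolution at image sizes of 32-128;
  at very small $n$ the $n-1$ observed transitions make $W$ noisy whatever
  $b$ is.

Numerical guard: values within $10^{-12}$ of $[0,1]$ are clipped before
`arccos`/`sqrt` so floating-point residue from rescaling never produces
NaNs; anything further outside raises an error rather than being silently
clamped.

## Color and concatenation

A field matrix is rendered through a fixed five-anchor rainbow
(blue, cyan, green, yellow, red at $u = 0, .25, .5, .75, 1$), scaled by the
encoder's *theoretical* range ($[-1,1]$ for the Gramian fields, $[0,1]$ for
MTF) rather than the per-image minimum and maximum — colors then mean the
same thing in every image, so the network can compare instances. Larger
values are redder, smaller bluer; the anchors pin the extremes to pure red
and pure blue. The exact rainbow is this package's own pin; only the
qualitative convention is canonical.

The $m$ per-channel RGB images are then *channel-split concatenated*: for
each color plane, the like-colored monochrome planes are stacked vertically
in a configurable order, giving a 3-plane image of height $n \cdot m$ and
width $n$ (six sensors at size 128: $768 \times 128$). The stacking
introduces artificial block boundaries ("spurious edges") whose pattern
depends on the order; whether that pattern matters is an empirical question
the experiment harness can answer (below).

## Networks and training

Two architectures are built by `build_architecture()`:

- `simple`: two 5×5 convolutions (6 and 12 filters), each followed by ReLU
  and a 2×2/stride-2 max-pool, then one fully-connected output layer.
  Default learning rate 0.0023.
- `vgg16`: the canonical 13-conv (3×3) / 5-pool / 3-FC stack with filter
  counts 64…512 and FC sizes (4096, 4096, 2). Default learning rate
  0.00023. On a $(3, 768, 128)$ input its first FC layer alone holds
  $49152 \times 4096 + 4096 = 201{,}330{,}688$ parameters, and its total
  exceeds the simple net's by far more than two orders of magnitude.

Convolutions use same-padding so that only the pools change spatial size:
after each pool both dimensions halve exactly, which is why the image size
must be divisible by $2^{\#\text{pools}}$ (a shape error explains this at
construction time). Training is mini-batch stochastic gradient descent
with momentum 0.9 on the two-class softmax cross-entropy, with a
label-stratified internal validation split (default 10%) driving early
stopping: after `patience` epochs without a validation-loss improvement,
training stops and the best-validation weights are restored. The filter
counts, optimizer and loss are this package's own defaults in the spirit of
the architectures' source conventions; pixel inputs are centered by
subtracting 0.5 before the first convolution, which conditions the
first-layer gradients far better than all-positive inputs. Everything
downstream of a seed — initialization, shuffling, splits — is derived from
it, so a training run is bit-reproducible.

## The experiment harness

`run_condition()` executes the full evaluation protocol for one
(encoder, order, architecture) condition: repeated stratified $k$-fold
cross-validation (defaults 20 repeats × 5 folds; stratification prevents
single-class training folds in small fixtures), training a fresh network
per fold and scoring the held-out fold with the percentage error rate
$(1 - \#\text{correct}/N) \times 100$. The sampling unit for the
comparison tests is the per-repeat mean over folds, so 20 repeats yield 20
observations per condition; users who prefer per-fold granularity can pass
`error_rates` columns directly.

Three nonparametric comparisons mirror the three study questions:

- **Encoders** — `compare_encoders()` runs Dunn's post-hoc pairwise rank
  test (tie-corrected pooled ranks, two-sided normal p-values, reported raw
  and Holm-adjusted, since the adjustment convention is not universal).
- **Concatenation orders** — `compare_orders()` runs pairwise Wilcoxon
  signed-rank tests with samples paired by (repeat, fold); an all-zero
  difference vector is degenerate and reported as $p = 1$ with a flag.
- **Architectures** — `compare_architectures()` runs the Kruskal-Wallis
  rank ANOVA via `stats::kruskal.test()`.

## The synthetic generator

`generate_synthetic()` produces wafer-like fixtures: per instance a length
drawn uniformly from 104-198 steps, shared by all $m$ channels (lengths
vary across, never within, instances); each channel a low-frequency
sinusoid with random amplitude (0.6-1.2), period and phase plus Gaussian
noise (default sd 0.1); abnormal instances additionally get a downward
level shift (default 1) and two three-sample triangular spikes (default
height 2) at random interior positions — the "low values with obvious
spikes" fault signature of wafer sensor data. One integer seed fixes the
dataset bit for bit. The defaults were chosen once as a realistic
moderate-noise regime; difficulty is controlled by `spike_amplitude` and
`level_shift`, and setting both to zero yields an exactly label-free null
fixture on which any classifier should sit at chance.

**What the fixture does and does not show.** The class signal is
*amplitude-coded*: a level shift plus range-compressing spikes. The Gramian
fields see it directly (the rescaled baseline occupies a different band,
shifting the whole color field) and the simple ConvNet reaches near-zero
error on it. The MTF, by construction, is invariant to exactly this kind of
signal: per-series rescaling removes the level, and quantile binning adapts
to the compressed range, leaving only the spike transitions — a sparse,
position-random feature that does not generalize through a
position-sensitive fully-connected layer. On this fixture MTF therefore
performs near chance, and encoder comparisons on it are *not*
encoder-neutral. That is a property of the fixture, not evidence about real
wafer data, where slow multi-bin dynamics give MTF plenty to encode.
Passing tests on the fixture demonstrate that the pipeline is wired
correctly and can learn; they do not predict error rates on external
datasets.

## Scales used by the test suite

The shipped checks run at reduced scale so a complete run stays inside a
normal CI budget: the learning checks use 120 instances, 3 channels and
image size 32 (one repeat of five-fold CV); the encoder-comparison
analogue uses 90 instances at image size 16 with 3 repeats; the
order-comparison analogue uses 60 instances at image size 16, 2 repeats,
over 10 replicated datasets. The full-scale protocol (size 128, 20
repeats) is the same code path with different arguments.

## Known limitations

- Training is CPU-bound plain SGD; VGG16 at full $(3, 768, 128)$ scale is
  constructible and trainable in principle but not exercised by the tests.
- The MTF bin count is a free parameter with no canonical value; 8 is a
  sensible default for image sizes 32-128 but too fine below that.
- The rainbow colormap is a pinned convention, not a perceptually uniform
  map; it exists for comparability, not for human viewing quality.
- `read_instance_matrices()` expects one whitespace-delimited matrix per
  instance with the label in the file-name suffix; converters for other
  archive layouts are out of scope.
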