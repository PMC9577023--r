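---
title: "Fiber-based dropout from fractional Brownian motion: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fiber-based dropout from fractional Brownian motion: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Standard dropout silences each unit of a layer independently with a preset
probability *p*. This package implements a spatially structured
alternative, modeled on the meandering trajectories of brain serotonergic
axons: the layer is embedded in a Euclidean unit square, and "fibers" —
moving segments of superdiffusive stochastic paths — silence every neuron
they touch in a training iteration. Neurons that are close together are
therefore likely to be dropped together, while over many iterations every
neuron is eventually visited.

The three ingredients are:

**Fractional Brownian motion (FBM).** The fiber trajectories are sample
paths of FBM, the zero-mean Gaussian process with covariance

$$\mathrm{Cov}(B(s), B(t)) = \tfrac{\sigma^2}{2}\left(s^{2H} + t^{2H} -
|s-t|^{2H}\right),$$

so that $\mathrm{Var}(B(t)) = \sigma^2 t^{2H}$. The Hurst index
$H \in (0,1)$ controls the character of the motion: $H = 0.5$ is ordinary
Brownian motion with independent increments; $H > 0.5$ gives persistent
(superdiffusive) paths whose consecutive increments correlate as
$2^{2H-1} - 1 > 0$; $H < 0.5$ gives anti-persistent paths. Axon-like
trajectories are superdiffusive; the package default is $H = 0.9$.
Two-dimensional paths use independent 1-D processes per coordinate with
the same $H$ and $\sigma = 1$.

**Layer geometry.** A layer of $N^2$ neurons is laid out as an
$N \times N$ grid in $[0,1]^2$: per axis, cell $k$ occupies
$[k/N,\, k/N + 1/(2N))$ — square neurons of side $1/(2N)$ separated by
gaps of the same width, tiling the unit interval exactly. The covered
area is exactly $1/4$ of the layer for every $N$. Cell membership is
half-open so no point can belong to two neurons. The grid phase (cell
first, then gap) is the simplest layout consistent with a tiling that
extends from 0 to 1; under the periodic wrap the phase is statistically
irrelevant.

**Fiber dynamics.** Each fiber is a sliding window over a long 2-D FBM
backing path: at training iteration $i$ (0-based) it occupies the $L+1$
path points $i s, \dots, i s + L$, i.e. the closed time interval
$[(i s)\Delta t, (i s + L)\Delta t]$. With $s = L$ (the benchmark
setting, $L = s = 50$) the window starts each iteration where it ended in
the previous one; with $s < L$ it crawls, retaining $L - s + 1$ points.
Coordinates wrap periodically into $[0,1)^2$ — a fiber crossing a border
re-enters on the opposite side — and the backing path itself is generated
unwrapped so the wrap never distorts the FBM covariance. At the end of
each epoch every fiber *branches*: a fresh FBM path starts at a point
drawn uniformly from the $L+1$ points of the final window, and the old
path degenerates. Fibers do not interact; a neuron touched by several
fibers is simply dropped once.

A neuron is dropped in an iteration iff at least one active fiber point
lies inside its square. The number of fibers $n$ is the drop-rate dial:
`calibrate_fiber_count()` finds by Monte-Carlo search (the mean rate is
non-decreasing in $n$) the $n$ whose long-run mean realized rate is
closest to a target. There is no tractable closed form for the hit
probability of an $L$-point superdiffusive window, so calibration is
simulation-based.

## Exact path generation

The sample-path generator is exact, not approximate: fractional Gaussian
noise is drawn by Davies–Harte circulant embedding (an FFT method whose
output has exactly the target covariance when the embedding is
nonnegative definite), with the Hosking/Levinson–Durbin recursion as an
exact $O(n^2)$ fallback for the rare non-embeddable cases. The closed
forms `fbm_covariance()` and `fbm_increment_correlation()` serve as test
oracles, and the test suite additionally cross-checks both generators
against a third exact route (Cholesky factorization of the covariance
matrix). Endpoint-spread checks use a coarser time step than the
benchmark $\Delta t$, which is legitimate because the endpoint law
$N(0, \sigma^2 T^{2H})$ does not depend on the discretization.

## Backing-path horizon

The backing path must cover a full epoch of windows, which requires
$(\text{iterations} - 1)\,s + L$ steps; the package derives the horizon
from that identity rather than from a separate time-budget formula. For
the regression benchmark (50 iterations per epoch, $L = s = 50$,
$\Delta t = 1/500$) this gives $T = 5$; for the image benchmark (16
iterations) $T = 1.6$, within the stated budget of 2.

## Randomness and reproducibility

Every run derives all of its randomness from one master seed through
hashed substreams (per fiber, per epoch, per coordinate, per layer, per
replicate), so experiments are bit-reproducible while components remain
independent. Scoped generation (`with_seed`) restores the caller's RNG
state.

## The benchmark experiments

Two experiments compare three conditions — no dropout, standard Bernoulli
dropout, and fiber (FBM) dropout — with everything else identical,
including the weight-initialization seed within a replicate. The
networks are plain fully connected ReLU MLPs trained with Adam; the two
hidden layers are the droppable ones (their widths $N^2$ carry the
grids), the inputs and outputs are never masked, and the fiber
populations of the two layers are independent. Masks are rebuilt at
every mini-batch iteration. No inverted-dropout rescaling is applied by
default in either dropout mode — the model is plain zeroing, and the
baselines must be symmetric for the comparison to be fair — but
`rescale = TRUE` enables $1/(1-p)$ scaling in both modes simultaneously.

**Regression.** 50 points with $x \sim U[-1,1]$ and
$y = x + 0.3\,\varepsilon$, $\varepsilon \sim N(0,1)$; network
$1 \to 100 \to 100 \to 1$; MSE loss; Adam at learning rate 0.01;
50 epochs of 50 iterations; 12 fibers per layer ($N = 10$). The test set
is a fresh 50-point draw from the same law, fixed per run. Each of the
50 per-epoch iterations takes an Adam step on the *full* training set
(`batch_mode = "full"`). This is a deliberate design choice: per-sample
steps at this learning rate leave the training loss hovering at the 0.09
noise floor — the gradient noise of single-sample Adam acts as a strong
implicit regularizer — so no condition overfits and there is nothing for
dropout to repair. Full-set steps drive the unregularized network's
training loss well below the noise floor within 50 epochs, producing the
overfitting dynamic (training loss sinking, testing loss rising after an
early minimum, growing generalization gap) that the dropout conditions
are meant to suppress. The iteration count, and with it the fiber
schedule (one window advance per iteration, branch per epoch), is
unchanged.

**Classification.** 28×28 grayscale digit images, 10 classes, 1,000
train + 1,000 test; network $784 \to 1024 \to 1024 \to 10$;
cross-entropy; Adam at learning rate $10^{-4}$; 100 epochs of 16
mini-batches; 60 fibers per layer ($N = 32$). Here mini-batching is real
(`batch_mode = "split"`): the shuffled epoch is partitioned into exactly
16 nearly equal chunks (62–63 samples for 1,000 points, matching the
nominal 64 up to the set size).

The generalization gap — testing loss minus training loss, per epoch —
is the overfitting measure throughout.

## The synthetic glyph fixture

`make_synthetic_glyphs()` renders ten fixed 5×7 digit skeletons at 28×28
with random integer translation (±3 px), intensity scaling (0.7–1), and
additive Gaussian pixel noise (SD 0.15, clipped to $[0,1]$). It emulates
MNIST's *format* — enough to exercise the full classification pipeline,
mask geometry, and IDX-free training — but not its handwriting
variability: every image of a class shares one rigid skeleton. Two
consequences matter for interpreting tests. First, a small network
separates the classes almost perfectly (a $784 \to 64 \to 64 \to 10$ net
reaches >90% test accuracy in 40 epochs on 50 images per class), so the
fixture validates mechanics, not generalization benefits. Second,
because there is little harmful overfitting to suppress, dropout does
not improve the glyph test loss the way it does on real handwriting;
the package's tests therefore assert pipeline correctness on glyphs and
reserve the regularization-ordering claim for the regression benchmark,
where it is reproduced in full. Real MNIST IDX files can be substituted
via `load_mnist()` whenever they are available locally.

## Numerical and design notes

- **Cell membership at boundaries** is half-open ($[x_0, x_0 + \text{side})$
  per axis), eliminating double assignment; the measure-zero choice is
  otherwise inconsequential.
- **Branch-point distribution** is uniform over the final window's
  $L+1$ points, endpoints included — the maximum-entropy reading of
  restarting "at a random point" of the last segment.
- **Initial fiber origins** are uniform in $[0,1)^2$.
- **Window point count** is $L+1$ (the closed interval includes both
  endpoints); consecutive $s = L$ windows share exactly one point.
- **Weight initialization** is fan-in uniform
  $U(-1/\sqrt{\text{fan}_{in}}, 1/\sqrt{\text{fan}_{in}})$ for weights
  and biases, the common feed-forward default; the seed is recorded in
  the run record.
- **Losses** are MSE (regression) and softmax cross-entropy
  (classification), the standard choices for these tasks.
- **Monte-Carlo test tolerances** are stated in standard errors of the
  estimator concerned (3–5 SE; covariance-matrix checks allow the small
  expected fraction of >3-SE entries among thousands of correlated
  entries). Test problem sizes — e.g. 10,000 paths for endpoint spreads,
  20,000 for covariance and increment-correlation checks, 10 seed
  replicates of the full regression experiment — were chosen so these
  bands are decisive at interactive run times.
- **Degenerate inputs** are rejected with errors naming the offending
  field: empty fiber sets (no-dropout is a mode, not zero fibers),
  unattainable calibration targets (the achievable range is reported),
  unwrapped points outside $[0,1)^2$, mismatched mask/activation lengths.

## Known limitations

- Fibers live in 2-D within a layer; cross-layer (3-D) fibers, reflected
  boundaries, stochastic neuron placement, and convolutional feature-map
  dropout are out of scope.
- The drop rate realized by a given fiber count is geometry-dependent
  and only approximately matches nominal targets; the regression
  benchmark's 12 fibers realize a long-run mean rate near 0.16, the
  image benchmark's 60 fibers near 0.21 (both computed by the
  acceptance script; "around 0.2" at benchmark granularity).
- The glyph fixture's limits are described above; conclusions about
  real-data regularization rest on the regression benchmark and, when
  files are provided, on real MNIST.

## Worked example

```{r example}
library(fbmdropout)

# simulate the benchmark dropout process and inspect its rate
sim <- simulate_drop_rates(neuron_grid(10), fiber_params(12, 50),
                           n_epochs = 10, seed = 1)
print(sim)

# run the three-condition regression comparison (10 paired seeds)
cmp <- compare_conditions(
  regression_config("fbm", seed = 42),
  function(s) make_regression_split(seed = s),
  n_seeds = 10)
print(cmp)
plot(cmp)
```
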