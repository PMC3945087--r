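---
title: "Slowness versus sparseness in complex-cell learning: models, objectives, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slowness versus sparseness in complex-cell learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(slowsubspace)
```

## The model

Complex cells in primary visual cortex respond to oriented structure while
tolerating small changes in spatial phase. The classical account is the
energy model: the cell sums the squared outputs of two linear filters that
differ in phase. `slowsubspace` learns complete banks of such units. A bank
is an orthonormal matrix $W \in \mathbb{R}^{D\times D}$ over whitened input
coordinates whose rows are grouped, consecutively, into $I = D/2$ subspaces
of dimension $K = 2$. The output of subspace $i$ at time $t$ is the subspace
energy

$$y_i(t) = \sum_{k \in \text{subspace } i} \left(w_k^\top x(t)\right)^2,$$

the squared radial component of the stimulus in that plane. If the rows are
Fourier quadrature pairs (sine and cosine at one spatial frequency), $y$ is
exactly the power spectrum of the input patch.

Two normative principles compete to shape the filters:

* **Slowness.** Features should change little between consecutive frames.
  With discrete time and unit steps the per-subspace *inverse slowness* is
  $s_i = \operatorname{mean}_t\,(y_i(t+1) - y_i(t))^2$ and the objective is
  $\Psi_{\text{slow}} = \frac{1}{I}\sum_i s_i$, minimized subject to
  $WW^\top = I$. Zero means perfect invariance. (The general
  temporal-smoothness objective also carries difference-mean and variance
  terms; with unit time steps the difference mean vanishes and the variance
  terms are constant under the orthonormality constraint, so the raw mean
  squared energy difference is the whole objective. Constant factors rescale
  the objective without moving its optima; none is applied, so
  $E[y_i] = K$ on whitened data.)
* **Sparseness.** Subspace responses should be heavy-tailed and rarely
  active. Modeling each subspace with a spherical exponential density and
  dropping its scaling and normalization constants gives the negative
  log-likelihood $\Psi_{\text{sparse}} = \frac{1}{IT}\sum_{t,i}
  \sqrt{y_i(t)}$, also minimized.

The two are combined in a one-parameter family

$$\Psi_\gamma = (1-\gamma)\,\Psi_{\text{slow}} + \gamma\,\Psi_{\text{sparse}},
\qquad \gamma \in [0,1],$$

so that $\gamma = 0$ is slow subspace analysis (SSA), $\gamma = 1$ is
independent subspace analysis (ISA), and intermediate values trade the two
off (ISSA). Both terms are averaged over subspaces and time so they combine
on comparable per-unit scales; the raw weighted sum is used without any
further transformation. The sparsity term is evaluated on all frames of the
pair set (both members of every pair), since sparseness is a single-frame
property.

## Optimization

`optimize_filters()` is a Rosen-style gradient projection on the orthogonal
group: the analytic gradient is scaled by a step length $\mu$ and
subtracted, and the result is projected back with symmetric (Löwdin)
orthogonalization $M \mapsto M(M^\top M)^{-1/2}$, the Frobenius-closest
orthonormal matrix. A backtracking line search halves $\mu$ until the
candidate improves the objective; if no improving step exists within the
backtracking budget, the optimizer halts and reports convergence rather than
accepting an ascent, so accepted objective values are strictly decreasing.

Numerical choices (all configurable through `optimizer_config()`):

* `mu0 = 1` is the default cap on the step; the experiments in this package
  use `mu0 = 16`, which the line search quickly reduces when too large. The
  line search of iteration $k+1$ warm-starts at twice the step accepted at
  iteration $k$ (capped at `mu0`) rather than restarting at `mu0`; descent
  is unaffected and convergence to deep optima is far faster.
* `backtrack_factor = 0.5`, `max_backtracks = 30`, `tol = 1e-8` (relative
  objective change), `max_iter = 2000`. Gradients are full-batch.
* The inverse square root inside the projection uses the symmetric
  eigendecomposition with an eigenvalue floor of `1e-12`; a candidate step
  so large that $W - \mu G$ is numerically singular counts as a failed
  line-search trial.
* The ISA gradient divides by $\sqrt{y_i + \varepsilon}$ with
  $\varepsilon = 10^{-12}$, guarding the non-differentiable point $y = 0$ at
  the scale of whitened data.

**Entangled subspace pairs.** Plain gradient projection on these objectives
has a reproducible failure mode: two subspaces converge onto a configuration
in which each spans half of two invariant (or two source) planes. The joint
4-dimensional span is correct but its split is not, and the split is a
genuine local optimum — the tangent gradient is numerically zero and small
perturbations fall back into the same basin. `refine_subspace_blocks()`
resolves this by re-optimizing the $4\times 4$ rotation inside the joint
span of candidate subspace pairs from a few seeded random restarts, keeping
a re-split only when it lowers the objective, so overall descent remains
monotone and deterministic per seed. Candidates are slowness outliers
($s_i > 10\times$ the median) for large slowness-trained banks, and all
pairs for small banks or mixed objectives, where entangled blocks are not
outliers. Both objective terms decompose over subspaces, so the block
sub-problem optimizes the same functional. `train_subspace_bank(refine = n)`
interleaves up to `n` refinement rounds with full-bank polish runs.

## Preprocessing

Patches are vectorized column-major. Each patch's own mean (the DC
component) is projected out; the residual is expressed in a fixed
deterministic orthonormal basis of the 120-dimensional AC subspace (the
non-first columns of the Householder reflector exchanging $e_1$ with the
normalized constant vector — deterministic so that filter visualizations
are reproducible), and whitened symmetrically with $C^{-1/2}$ from the
eigendecomposition of the AC covariance. No low-pass filtering or
dimensionality reduction is applied. Symmetric (ZCA-style) whitening is used
rather than PCA whitening: it treats all AC directions symmetrically and
avoids the bandwidth bias that PCA truncation introduces. The covariance is
regularized by `1e-10` times its mean eigenvalue, which guards the
near-degenerate directions of the disc dataset. Learned filters are mapped
back to pixel space by the response-preserving transform
$v = B\,C^{-1/2}w$, which is exact and keeps every filter DC-free.

**Circulant covariance estimation.** For the cyclic-shift dataset the
population covariance is circulant by construction. Estimating it with the
unconstrained sample covariance breaks the exact rotation symmetry of torus
shifts in whitened coordinates at order $1/\sqrt{T}$, which puts an $O(1/T)$
floor on the achievable slowness objective (about $10^{-4}$ of the
random-filter objective at $T = 20{,}000$) — far above machine precision.
`fit_preprocessor(circulant_side = )` therefore projects the sample
covariance onto the circulant class by averaging the autocovariance over
torus offsets. Under that estimator the whitened shift operator is exactly
orthogonal, the Fourier quadrature bank attains an exactly zero empirical
objective, and the optimizer can recover it to machine precision — the
analytic ground truth the cyclic experiment is designed around. (For odd
patch sides the shift-averaging also cancels all pseudo-covariance terms,
so cosine and sine coordinates of each frequency have exactly equal
variance.)

## Synthetic stimuli

The generators emulate the study conditions with seeded pink-noise
surrogates:

* `make_pink_noise_image()`: DFT amplitudes $\propto 1/f$ (configurable
  exponent, amplitude exponent 1 by default — the canonical natural-image
  surrogate with $1/f^2$ power), uniform Hermitian phases, zero mean, unit
  variance.
* `translation_pairs()`: a 2-D random walk of an $11\times 11$ window, with
  per-axis displacement magnitudes uniform on $[0, 2]$ px and independent
  random signs, reflected at the image borders; subpixel sampling by
  bilinear interpolation.
* `make_circulant_pink_patches()` + `cyclic_shift_pairs()`: patches
  stationary on the torus (independent DFT coefficients, $1/f$ amplitude,
  zero DC), shifted in the frequency domain so torus translation is exact
  for any real-valued displacement.
* `rotation_pairs()`: windows rotated about their center pixel, base angle
  uniform, increments uniform on $\pm 10^\circ$ by default (the increment
  law is a free parameter of the study conditions); the disc variant keeps
  the 121 pixels closest to the center of a $13\times 13$ grid. An odd
  frame is used because a both-axes-symmetric 121-pixel disc does not exist
  on an even grid; the customary $14\times 14$ frame is for visualization
  only (`embed_in_frame()`).
* `scaling_pairs()`: windows with per-axis sizes in $[11, 22]$ px resampled
  to $11\times 11$, per-step multiplicative factors uniform on
  $[0.95, 1.05]$ per axis (also a free parameter).
* `movie_surrogate_pairs()`: one walk composing all three increment types
  over a pink-noise scene, standing in for natural movie sequences.

Default `n_pairs` is 50,000; the experiments in the test suite use 20,000,
which is large enough for stable fourth-order statistics at $D = 120$ while
keeping a full training run in minutes on one core. Translation training
images are $1024\times 1024$: pairs drawn from a small image reuse the same
patch area so heavily that long optimizations start fitting the particular
realization (the quadrature-phase structure visibly degrades), which the
larger area prevents at unchanged pair count.

**What the surrogates do not emulate.** Pink noise matches only the
second-order statistics of natural images; it is a Gaussian process. After
whitening, Gaussian data look *identical* to every orthonormal filter bank,
so the sparsity objective is population-constant on these surrogates and
ISA is driven only by residual sampling structure. Two consequences for
interpreting results on synthetic data:

* The slowness-versus-sparsity divergence in filter localization is
  attenuated relative to natural images. On open-boundary translation data
  the localization medians of SSA- and ISA-trained banks differ only at
  noise level (~0.002, seed-dependent sign), so the divergence check runs
  on the cyclic-translation dataset, where the contrast is structural:
  slowness provably drives the bank to the global Fourier basis while the
  sparsity objective leaves the bank near its random start. The check
  asserts the direction of the contrast, not its magnitude.
* A meaningful slowness-sparseness trade-off curve cannot be measured on
  pink-noise sequences at all — the sparse axis is noise. The trade-off
  analysis therefore runs on `competing_structure_pairs()`, a source model
  built so that the two optima provably differ: within each 4-D block a
  single heavy-tailed radius $\rho \sim \Gamma(1,1)$ is shared by two
  planes that rotate independently (phase steps uniform on $\pm\pi/2$).
  The plane pairing has exactly constant energies $\rho^2$ (inverse
  slowness 0), while the cross pairing has energies
  $\rho^2(\cos^2\varphi_1 + \cos^2\varphi_2)$, whose square root has
  strictly smaller expectation (concavity) — sparser, but fast. These
  parameters are part of the model's definition, fixed at design time.

## Evaluation

* `rank_subspaces()` orders subspaces by ascending $s_i$ (slowest first,
  ties by original index).
* `pair_phase_difference()` estimates quadrature structure: the dominant
  frequency bin shared by the two filters of a subspace (peak of the
  product of their DFT magnitude spectra, DC excluded) and the absolute
  principal-value phase difference there, in $[0, \pi]$. If the shared bin
  carries less than a configurable fraction (default 25%) of either
  filter's own spectral peak, the estimate is flagged rather than raised —
  phase is meaningless for non-matching filters. This deliberately avoids a
  full Gabor fit; the dominant-bin estimate is deterministic and robust.
* `fourier_match_score()` and `subspace_overlap()` compare subspace
  *decompositions*, not filters: mean over subspaces of the best mean
  squared principal-angle cosine against the reference, invariant to
  within-pair rotations and subspace permutation. Reference quadrature
  pairs are mapped into whitened coordinates through the preprocessor, so
  the comparison happens in the learning space.
* `localization_index()` is one minus the normalized spatial entropy of a
  filter's energy map: 1 for a single-pixel filter, near 0 for a global
  wave.
* `tradeoff_curve()` optimizes $\Psi_\gamma$ over a $\gamma$ grid from one
  shared random initialization and reports performances as percentages of
  the maximal achievable gain, anchored at that shared random start:
  $\text{perf}_{\text{slow}}(\gamma) = 100\,\frac{\Psi_{\text{slow}}(W_{\text{rand}}) - \Psi_{\text{slow}}(W_\gamma)}{\Psi_{\text{slow}}(W_{\text{rand}}) - \Psi_{\text{slow}}(W_0)}$
  and analogously against the pure-ISA endpoint. The random start is the
  only baseline the whole family shares, and it makes the pure endpoints
  exactly 100% by construction. The break-even $\gamma$ is located by
  linear interpolation between grid points; failed optimizations flag their
  curve point and the run continues.

## The quadratic-neuron supplement

To ask how many invariant dimensions slowness *wants* (rather than fixing
$K = 2$), slow feature analysis runs on the full quadratic feature space of
a reduced stimulus representation: patches are projected onto the lowest
Fourier components, expanded into all monomials $z_az_b$ ($a \le b$) plus
linear terms, centered, whitened, and the temporal-difference covariance is
eigendecomposed; the slowest eigenvectors map back to explicit quadratic
forms. Each form becomes a model neuron: responses to white-noise stimuli
are centered at their median and split into an excitatory stream (positive
part) and an inhibitory stream (negative part, absolute value), scaled so
the mean rate is 0.5 spikes/frame (the rate scale is a reporting
convention, not a fitted quantity), and turned into Poisson spike counts.
Spike-triggered covariance (spike-weighted stimulus covariance about the
spike-triggered average, minus the identity prior of the white stimuli) is
eigendecomposed, and significance is assessed against spectra recomputed
with randomly permuted spike counts: outside mean $\pm\,4.4$ SD of the
shuffled eigenvalue distribution counts as significant (excitatory above,
inhibitory below).

The significance band is **pooled** over all shuffled eigenvalues by
default — the two flat dashed lines of an eigen-spectrum panel. A per-rank
band (`band = "per_rank"`) is also available but is only calibrated when
genuine signal dimensions are a negligible fraction of the stimulus
dimension: a rank-$k$ cell's data eigenvalue at rank $k+1$ is the *maximum*
over the remaining null directions, yet the per-rank band compares it to
the shuffles' $(k{+}1)$-th order statistic, an upward-biased comparison
that at a few dozen stimulus dimensions yields spurious detections in a
substantial fraction of realizations. At a hundred or more dimensions with
a low-rank signal the two bands nearly coincide.

Desk scale replaces the original cluster scale: 16 lowest Fourier
components (152 quadratic features), 50,000 white-noise frames, 100
shuffles; significant eigenvalues are counted from the excitatory and the
inhibitory spike train together. The qualitative contrast is the point: a
planted rank-2 energy cell yields exactly its two excitatory eigenvalues,
while an SFA-derived quadratic neuron lights up the majority of stimulus
dimensions.

## Known limitations

* All image surrogates are Gaussian; conclusions about sparsity-driven
  structure on these inputs are directional only (see above). Real-image
  ingestion is out of scope.
* Subspace dimension is fixed at $K = 2$ except in the quadratic-neuron
  analysis; learning $K$ is delegated to that analysis.
* The optimizer is full-batch; datasets must fit in memory (a 20,000-pair
  set at $D = 120$ is ~40 MB).
* `pair_phase_difference()` assumes a dominant shared frequency; for
  non-grating filters (e.g. the scaling dataset's boundary-localized
  filters) the flagged fraction rises and phase summaries should be read
  accordingly.
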