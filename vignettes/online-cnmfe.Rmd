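---
title: "Online source extraction for 1-photon microendoscopic imaging: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Online source extraction for 1-photon microendoscopic imaging: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(oncnmfe)
```

# The model and its assumptions

A microendoscopic movie is a matrix $Y \in \mathbb{R}_+^{d\times T}$
(pixels by frames) modelled as $Y = AC + B + E$. The columns of $A$ are
sparse, spatially localized, nonnegative footprints; the rows of $C$ are
calcium traces driven by nonnegative spiking through a stable
autoregressive process $c(t)=\sum_p \gamma_p c(t-p)+s(t)$; $E$ is
zero-mean Gaussian noise with diagonal covariance. The 1-photon
background $B$ is decomposed into a per-pixel constant baseline
$\bar b$ and a fluctuating part modelled autoregressively in *space*:
the fluctuation at pixel $i$ is a linear combination of fluctuations on
the annulus of pixels at Euclidean distance $[l, l+1)$ around it,

$$B = \bar b\,\mathbf 1^\top + W\,(Y - AC - \bar b\,\mathbf 1^\top),
\qquad W_{ij}=0 \text{ unless } \mathrm{dist}(x_i,x_j)\in[l,l+1).$$

The model assumes the background is spatially much coarser than a soma,
which is why $l$ defaults to $1.5\times$ the neuron radius: the ring is
far enough from its center that the neuron's own fluorescence does not
contaminate its background predictors. Rows of $W$ are estimated
independently by per-pixel least squares; the normal-equation blocks are
read off one global second-moment matrix $\chi = XX^\top$ of the
neuron- and baseline-subtracted data $X$.

Pixels are indexed 1-based in column-major order
(`i = (col-1)*rows + row`), the native layout of R matrices; one fixed
convention is used in every module. Frames are `rows x cols` matrices,
movies `rows x cols x T` arrays.

# Initialization on a short batch

`initialize_batch()` processes the first `init_frames` frames offline:

1. Every frame is filtered with a zero-sum Gaussian band-pass (Gaussian
   of width half the neuron radius minus the box mean over the same
   support). This removes both the coarse background and, partially,
   pixel noise, and acts as a matched filter for somata.
2. Two summary images are computed from the filtered data: the local
   correlation image (mean Pearson correlation with the 8-connected
   neighbors) and the peak-to-noise image (temporal maximum over the
   spectrally estimated noise level). While the pixel maximizing their
   product passes both thresholds (`min_corr`, `min_pnr`), a component
   is seeded there.
3. Each seed is initialized by a local rank-1 NMF of the raw residual in
   a square window of four neuron radii, after subtracting the per-frame
   median of the window border (a local background estimate). The
   temporal factor is *anchored* at the band-pass-filtered trace of the
   seed pixel: if the alternation drifts away from the anchor
   (correlation < 0.5) it is restarted from a plain regression against
   it. This prevents the factorization from locking onto a brighter
   neighbor that overlaps the window. Seeds whose fit does not match the
   anchor, falls below an amplitude floor, or that lie within one neuron
   radius of an accepted seed or of the FOV border are suppressed (the
   border is excluded because the band-pass filter leaks the coarse
   background there).
4. The component set is refined by `outer_iter` (default 2) alternations
   of: baseline and ring-weight estimation, block-coordinate trace
   updates followed by OASIS, and footprint HALS restricted to the seed
   windows.

# Streaming updates

For each incoming frame the engine performs, in order: optional rigid
alignment; warm-started block-coordinate trace updates, with components
partitioned greedily into spatially non-overlapping groups that are
updated jointly and with the background term expanded through the cached
projections $A^\top W$, $A^\top W A$ and $A^\top(W\bar b - \bar b)$;
streaming OASIS; the running-mean baseline update; the residual-buffer
update; detection; and, every `update_every` frames, the sufficient-
statistic fold, the ring-weight solve and footprint HALS.

Two bookkeeping choices deserve explanation:

* **Denoised traces feed the statistics.** The per-frame deconvolution
  precedes the baseline and sufficient-statistic updates, so the values
  entering $\bar b$, $L$, $M$, $\chi$ and the residual buffer are the
  OASIS-denoised estimates available at that moment. This matters:
  nonnegative least-squares traces absorb a share of the local
  background fluctuation, and feeding them to the background statistics
  hides exactly that share from the ring estimator — a self-consistent
  bias. Denoising breaks the loop because background fluctuations do not
  look like calcium transients to the AR prior.
* **Unnormalized sums.** $L$, $M$ and $\chi$ are stored as plain sums
  over all seen frames; the running-mean recursions divide by the frame
  counter, but that common factor cancels in both the HALS ratio and the
  ring normal equations, so it is applied only in the accessor
  (`suff_stats()`). $\chi$ is kept dense in the (optionally decimated)
  background space and folded in blocks of `update_every` frames with
  one matrix product.

The state contains only the component set, the caches, the sufficient
statistics, a rolling block of background residuals and the detection
buffer: its size does not grow with the stream (the traces, which are
the output, do).

Deconvolution itself is the pool-based active-set algorithm for AR(1)
dynamics, in both $\ell_1$ (`lambda`) and minimal-spike-size (`s_min`,
which takes precedence when both are set) modes; streaming and batch
solutions agree exactly at the end of the stream. AR(2) traces are
solved in batch as a box-constrained convex program on the spike vector;
streaming AR(2) is not provided. AR coefficients default to a per-
component autocovariance estimate on the initial batch (the noise does
not bias autocovariances beyond lag zero); `lambda` defaults to the
spectral noise estimate of the trace.

# Detecting new components

The last `buffer_frames` residual frames $r_t = y_t - Ac_t - b_t$ are
kept in a ring buffer together with incrementally maintained first and
second moments ($\mu$, $\nu$ over the 8-neighborhood), the running
residual maximum, and (in variance mode) the energy of the smoothed
buffer. The summary image is the product of the local correlation image
(from $\mu,\nu$) and the peak-to-noise image (running maximum over the
noise level of the *initial batch*, which is not refreshed afterwards;
pixels with zero noise level are masked). Candidate locations are local
maxima, with an exclusion zone of one neuron radius and a border margin,
that pass the same `min_corr`/`min_pnr` gates used at initialization.

Each candidate is fit by an anchored local rank-1 NMF of the buffer and
screened: the footprint must correlate at least `theta_sp` with the
time-averaged buffer on its support; it must fill at most `max_fill` of
its window above 10% of peak (somata are compact, background blobs are
not); if it overlaps an existing component its trace must not correlate
above 0.85 with that component's buffered trace (duplicate); and the
trace SNR (peak over a median-absolute-deviation noise estimate) must
reach `theta_snr`. Accepted components are incorporated exactly: $L$ and
$M$ are augmented from the buffered window, caches and groups are
extended, the buffer is corrected by the new component's contribution,
the local moments are recomputed from the corrected buffer (equivalent
to the incremental correction formulas, and immune to sign slips), and
the running maximum is zeroed on the new support.

After the run, overlapping components with trace correlation above 0.8
are merged (footprints summed, trace refit by rank-1 factorization of
their joint activity) and all components are re-screened on their
full-length traces. The post-hoc spatial screen projects the
background-subtracted movie onto the component's centered trace before
correlating with the footprint, so background that does not co-fluctuate
with the component cancels; the post-hoc compactness screen binarizes at
20% of peak (converged footprints legitimately develop faint skirts).

# Motion correction

The template is the mean of the last `template_frames` (default 50)
denoised frames, so a single corrupt frame moves it by at most $1/M$ of
its scale. Frame and template are high-pass filtered (subtraction of a
wide Gaussian blur, default three neuron radii) and the shift is the
argmax of the normalized cross-correlation computed on the valid
interior overlap over all integer lags within `max_shift` — the
valid-overlap formulation has no wrap-around or border artifacts, so an
exactly shifted frame scores 1 at the true lag and is recovered exactly
(a perfect raw-pixel match skips refinement); otherwise the peak is
refined to subpixel precision by quadratic interpolation. Shifts are
applied by bilinear interpolation with edge replication.

# The convolutional (ring-CNN) background

The ring model estimates $\approx d\,[2\pi l]$ free weights. The
convolutional alternative shares them:
$f(y) = \sum_{k=1}^K w_k \odot (h_k * y) + \bar b$ with $K$ kernels
supported on an annulus of inner radius $l$ and width `width`, i.e.
$K(d + |\text{annulus}|) + d$ parameters. It is trained on the raw
first `ringcnn$init_frames` frames with the quantile loss
$\ell_q(x,y) = q(x-y)$ if $x \ge y$, else $(1-q)(y-x)$ (total
$2\sum \ell_q$), with $q = 0.02$ so the background under-approximates
the movie and the nonnegative neural activity survives subtraction.
Training is minibatch Adam with a $1/\sqrt{\text{epoch}}$ learning-rate
decay (the pinball loss has a kinked optimum around which fixed-step
updates oscillate); gradients are analytic (the model is linear; the
subgradient at ties takes the under-approximation branch); the split is
`val_frac` validation, and the best-validation parameters are kept.
Because the baseline has a closed-form optimum for fixed kernels — the
per-pixel $q$-quantile of the residual — training closes with that exact
coordinate step. The baseline is trained jointly (initialized at half
the per-pixel median, with the first kernel an annulus mean at half
weight, so the initial prediction is close to the data even at the
zero-padded border). The output is invariant to joint rotations of
$(W, H)$; `svd_normalize()` orders kernels by singular value and can
truncate.

`run_ringcnn()` trains the model, freezes it, compiles it to a sparse
matrix, and streams: each frame is background-subtracted
($x_t = y_t - f(y_t - Ac_{t-1})$, approximating current with previous
activity) and processed by the same engine with the ring solve disabled
and a rank-`bg_rank` (default 2) nonnegative residual background whose
columns ride along as full-FOV components (no deconvolution, excluded
from duplicate screens). Initialization estimates the low-rank
background *first* (the smooth remainder dominates the leading singular
vectors because transients are temporally sparse) and seeds on the
low-rank-subtracted movie; seeding without that step lets the smooth
remainder leak into footprints as a pedestal. Three epochs are the
convention for this pipeline, the last with detection disabled
(tracking only).

# The simulator

`simulate_movie()` emulates the structure of miniscope recordings:
isotropic Gaussian somata (sd half the neuron radius, truncated at 2.5
radii, unit peak) at minimum-separation centers; Bernoulli spikes
(`firing_rate/frame_rate` per frame) with amplitudes uniform in
$[0.5, 1.5]\times$ `amplitude` filtered by stable AR dynamics; a
background composed of a per-pixel constant baseline (scalar plus a
static texture of width one neuron radius — vessels and speckle — which
the model's $\bar b$ absorbs and which gives registration its static
content), three smooth spatial modes (Gaussian-filtered noise, width six
neuron radii, so the background autocorrelation length is well above
three neuron radii and the ring model applies) with slow AR(1) time
courses; pixel-wise Gaussian noise; and optional smooth rigid drift
applied last. The default `amplitude = 16 * sigma` keeps the peak SNR of
the dimmest transient at 8 or above — the bright, well-separated regime.
Defaults (64 × 64, 20 neurons, 1500 frames at 10 Hz, $\gamma = 0.9$)
define the simulated benchmark; `simulate_ring_background()` additionally
constructs movies that satisfy the ring fixed-point identity exactly
(least-norm ring weights reproducing a smooth low-rank basis), for
parameter-recovery checks.

What the simulator does **not** emulate: dendrites and neuropil, optics
(PSF rendering), photobleaching, non-rigid deformation, spatially
correlated noise, and overlapping somata at sub-radius separations. A
perfect score on these movies therefore demonstrates the correctness of
the streaming estimator under its own model assumptions, not performance
on arbitrary real data, where the detection thresholds must be adjusted
per dataset (see `config_preset()` for four sets used on typical
striatum, PFC, hippocampus and BNST recordings).

# Parameters

| parameter | default | meaning |
|---|---|---|
| `neuron_radius` | 4 px | soma radius; sets filter widths and windows |
| `ring_radius` | `1.5 * neuron_radius` | inner ring radius $l$ |
| `init_frames` | 200 | offline initialization batch $T_b$ |
| `update_every` | 200 | period $T_p$ of shape/background updates |
| `buffer_frames` | 100 | residual buffer length $l_b$ |
| `min_corr`, `min_pnr` | preset | seed gates $L_{\min}$, $P_{\min}$ |
| `theta_sp`, `theta_snr` | preset | candidate screens |
| `max_candidates` | 3 | candidates examined per frame |
| `max_fill` | 0.6 | compactness gate (fraction of window) |
| `ar_order`, `gamma` | 1, estimated | calcium dynamics |
| `lambda`, `s_min` | noise-scaled, 0 | deconvolution sparsity |
| `decimate` | 1 | background-space decimation factor |
| `inner_iter` | 5 | per-frame trace iterations (warm-started) |
| `epochs` | 1 | passes over the movie (ring-CNN convention: 3) |
| `ringcnn$n_kernels`, `$width`, `$quantile` | 2, 5, 0.02 | CNN background |

# Numerical choices and degenerate inputs

Rank-deficient ring blocks get a ridge of $10^{-9}\,\mathrm{tr}/|r|$
(falling back to a least-norm QR solve), which also selects the
minimum-norm solution on exactly low-rank data. Trace updates stop at a
relative change of $10^{-4}$ or `inner_iter` rounds. Boundary rings are
clipped to the FOV and solved on the clipped support without
renormalization. Spatial decimation (block means down, nearest neighbor
up) applies to the background only; footprints and traces stay at full
resolution. Flat frames in motion estimation warn and return a zero
shift. Zero-noise pixels are masked in the peak-to-noise image — with no
noise floor a peak-to-noise criterion is undefined, which is why the
no-neuron sanity case is specified with a constant background.
Components with zero temporal or spatial energy are skipped with a
warning in the HALS updates. Degenerate candidate fits are suppressed
rather than subtracted.

The test suite exercises the full pipelines on 40 × 48-pixel movies with
6–8 neurons and 500–600 frames, and one 64 × 64 / 20-neuron / 1500-frame
benchmark — sizes chosen so the whole suite runs in about a minute while
every module still operates in its intended regime.

# Known limitations

* Motion correction is rigid only; piecewise-rigid registration is out
  of scope.
* Minimal-spike-size deconvolution is AR(1) only; AR(2) is batch-only.
* Candidate screening is threshold-based; no learned classifier.
* The ring-CNN is trained once on the initial batch and frozen; slow
  background reorganization later in a session is absorbed only by the
  low-rank terms.
* The peak-to-noise denominator is estimated once on the initial batch.
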