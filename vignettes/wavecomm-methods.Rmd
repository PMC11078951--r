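---
title: "Models and methods behind wavecomm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wavecomm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wavecomm)
```

This vignette is the package's own account of its science: the circuit and
walker models, the estimators, the numerical choices made where the design
was genuinely open, and the limitations a user should know about. Nothing
here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The two-area spiking circuit

Each area tiles the periodic square $[-32, 32)^2$: excitatory neurons on the
unit lattice (half-integer coordinates, $N_e = 4096$), inhibitory neurons on
the double-spaced lattice ($N_i = 1024$). Membrane potentials follow a
conductance-based leaky integrate-and-fire equation with capacitance
$C = 0.25$ nF, leak $g_L = 16.7$ nS (excitatory) or $25$ nS (inhibitory)
to $V_L = -70$ mV, threshold $-50$ mV, reset $-70$ mV, and a 4 ms
refractory period. Excitatory neurons carry spike-frequency adaptation: a
potassium conductance toward $V_K = -85$ mV that jumps by $\Delta g_K$ per
spike (1.9 nS in area 1, 6.5 nS in area 2) and decays with
$\tau_K = 60$ ms. Adaptation is the slow variable of the circuit: it
locally exhausts an ignited wave packet, which is what turns sustained
activity into On/Off episodes and sets the theta timescale (Section 6).

Synapses are double-exponential conductances: a rise variable $x$
incremented by the weight $w$ at each (delayed) presynaptic spike with
$\tau_r = 1$ ms, feeding a decay variable $g$ with $\tau_d = 5$ ms
(excitatory) or 4.5 ms (inhibitory), and reversal potentials 0 / $-80$ mV.
Connection probability decays exponentially with periodic distance,
$P = P_0 e^{-d/\tau_P}$, with per-class peaks and ranges that make
excitation short-range ($\tau_P = 7.5$ for e$\to$e) and inhibition
long-range ($\tau_P = 19$ for i$\to$e) — a Mexican-hat arrangement that
produces a *localized* packet rather than global synchrony. Intra-areal
weights are Gaussian per postsynaptic neuron with mean $J/\sqrt{K_{in}}$,
where $J$ is normalized so the class-wide mean weight equals the prescribed
overall mean; inter-areal projections (excitatory only, from a designated
random half of each excitatory group, 8–10 ms delays) use a fixed mean
without indegree scaling. All weights carry a 5% coefficient of variation.

External drive is an independent 1600 Hz Poisson train per neuron through
5 nS excitatory synapses. Stimuli add Gaussian rate bumps (width 6 grid
points) on area-1 excitatory neurons; the attention cue multiplies nothing
— it *subtracts* adaptation: area-2 increments become
$\Delta g_K(y) = 6.5 - 6 f_{att}(\lVert y - y_{att}\rVert)/f_{att}(0)$ nS
with a plateau profile (product of two sigmoids, radius 8.2, sharpness 2.2),
reaching 0.5 nS at the cued location.

### Numerical scheme

Forward Euler at $dt = 0.1$ ms, delays rounded to the step grid, initial
potentials uniform in $[-85, -50]$ mV. Synaptic state is aggregated per
(presynaptic class $\to$ postsynaptic neuron); because the rise variable is
linear in its per-synapse increments, aggregation is exact. One master seed
spawns independent streams for connectivity, initial conditions, and drive,
so connectivity can be held fixed across conditions for paired comparisons.
The kernel was validated against closed-form leak decay, the analytic LIF
inter-spike interval under quasi-constant conductance drive, an exact
synaptic-delivery integral, and an independent scalar Euler reimplementation.

### A known regime limitation

With the default parameter set, the realized connectivity
statistics check out exactly — mean indegrees 270 (e$\to$e), 350 (e$\to$i),
130 (i$\to$e), 180 (i$\to$i), class-mean weights equal to their prescribed
values — and the emergent dynamics are qualitatively as intended: a
localized packet over a silent background, propagating superdiffusively,
producing On/Off episodes, gamma bursts, theta-band structure, and all the
interareal effects the analysis stack measures. Quantitatively, however,
the packet interior saturates near the refractory bound (interior rates
$\sim$200 Hz rather than tens of Hz), so area-mean spontaneous rates come
out around 47/67 Hz instead of single digits, with correspondingly larger
CV, Fano factors, and On-state rates. Our analysis (documented with the
package's development notes) locates the cause in how fully the long-range
inhibition is expressed inside a finite packet: the weight set places both
populations within a few percent of exact synaptic balance at
$V \approx -55$ mV, making the interior operating point sensitive to
details that the parameterization leaves open. We verified
the behaviour is invariant to the integration step, initial conditions, and
inhibitory refractory assumptions, and chose to keep the reference parameter set exactly as specified
rather than tune hidden factors; the acceptance
machinery reports the honestly computed values. All *structural* and
*relational* results (state-selective phase locking, delay-peaked transfer
entropy, low-dimensional S-On subspaces, cue effects, disconnection
directions) are produced by the same pipeline and do not depend on the
overall rate scale.

## 2. Observables

**Wave-packet tracking** uses the circular (resultant-vector) mean of
spike-count-weighted coordinates per axis in a 10 ms window; samples with
no spikes or a vanishing resultant are carried as `NA` gaps, and downstream
statistics use the periodic metric with minimal-image unwrapping.

**MUA** is the mean rate of the 80 excitatory neurons within 5 grid points
of a site, in sliding windows of 10 ms (state detection) or 1 ms (spectra,
phase locking, transfer entropy), sampled at 1 kHz. **LFP** is the
Gaussian-distance-weighted sum ($\sigma = 7$) of absolute intra-excitatory,
inter-excitatory, and intra-inhibitory synaptic currents onto excitatory
neurons, recorded online at 1 kHz.

**Spectra** use epoch-averaged FFT periodograms (5 s epochs, mean removal
only) with the aperiodic component estimated by irregular-resampling
auto-spectral analysis using factors 1.1–1.9 in steps of 0.05 (the method's
original defaults). Linear-interpolation resampling attenuates the floor
only near the Nyquist frequency, well above the 1–100 Hz analysis band.
**Gamma bursts** threshold Morlet amplitudes (30–80 Hz in 2 Hz steps,
7-cycle mother wavelet — a standard trade-off, recorded in the call
signature), smoothed by a 3 ms Gaussian, at the pooled 85th percentile.

**Narrowband phases** come from an order-8 Butterworth band-pass applied
forward-backward and the analytic-signal argument. The filter is realized
as a cascade of bilinear-transformed second-order sections because the
expanded transfer-function form is numerically unstable for narrow
low-frequency bands (e.g. theta 3–6 Hz at 1 kHz).

## 3. On/Off segmentation

The 10 ms-binned MUA is smoothed with a Savitzky–Golay filter (window 91
samples $\approx$ 90 ms, order 3 — recorded parameters; the method is
insensitive to $\pm 10$ samples, which the tests check). Mean-shift
changepoints are found by PELT with an L2 cost; the penalty comes from a
slope heuristic on the cost-versus-number-of-changepoints curve (twice the
magnitude of the high-count slope), which is deterministic and needs no
per-realization tuning. Segments are replaced by their means; a threshold
grid of 100 values between the 5th and 95th percentiles is scanned, and the
threshold minimizing the squared error between the re-averaged binarized
signal and the smoothed MUA is chosen — separately for each realization.
Joint S-On/S-Off/1-On/2-On labels are the pointwise cross-product of two
areas' labels. Evoked analyses exclude the first 200 ms of each trial and
concatenate MUA across trials per condition.

On a synthetic two-level telegraph MUA with known switch times (rates
2/40 Hz, dwell times 50/250 ms), the pipeline recovers the hidden state at
better than 90% per-sample agreement, degrading gracefully (>80%) when the
rate contrast halves.

## 4. Coupling and information measures

**Phase-amplitude coupling** bins the phase series into 20 vigintiles,
forms the normalized amplitude-per-bin distribution, and reports
$MI = 1 - H(p)/\log 20$, minus the mean over 200 random amplitude-series
permutations. The correction removes most but not all of the bias induced
by filter autocorrelation, so the null sits at $|MI| \lesssim 10^{-3}$ —
two orders below genuine coupling.

**Phase-locking values** are mean resultant lengths of phase differences in
$[f_c - 5, f_c + 5]$ Hz bands, restricted to S-On or S-Off samples, minus
the mean over 200 surrogate pairs in which each channel is permuted across
time before filtering (white-noise surrogates).

**Transfer entropy** is the conditional mutual information
$I(T_{t+1}; S^{(l)}_{t+1-u} \mid T^{(k)}_t)$ estimated with the
Kraskov–Stögbauer–Grassberger nearest-neighbour construction
(Frenzel–Pompe conditioning, max-norm, $k_{nn} = 4$ — the common default).
Embedding vectors are built only from samples whose entire history window
lies inside one masked epoch, so state-conditioned estimates never straddle
epoch boundaries. A seeded jitter of $10^{-8}$ SD breaks the ties of
discrete-valued MUA. History lengths are either fixed or selected by an
exhaustive Ragwitz-style search over $(k, l) \in [1, 8]^2$ minimizing the
one-step nearest-neighbour prediction error of the target, ties toward
smaller embeddings. On a delay-coupled Gaussian pair the estimator matches
the closed form $-\tfrac12 \log(1-\rho^2)$ within a few percent at
$n = 5 \times 10^4$.

## 5. Communication subspaces

Spike counts in non-overlapping 20 ms windows for the two areas' 80-neuron
site groups are centered per neuron *within state* (On means removed from
On windows, Off from Off) — without this, the shared On/Off mean difference
masquerades as cross-area correlation. The full model is ridge regression
$B = (X^TX + \lambda I)^{-1} X^T Y$ with 10-fold cross-validation on
contiguous time blocks (random folds leak autocorrelation; the tests check
the sensitivity); performance is $1 - NSE$, so that larger is better and
weakly predictable data sit just above zero, and $\lambda$ follows the
one-SEM rule (largest $\lambda$ within one SEM of the best). Reduced-rank
predictions project the ridge predictions onto their top-$m$ principal
subspace, computed on training folds only. The number of predictive
dimensions is the smallest $m$ within one cross-validation SEM of the full
model; on synthetic low-rank maps this recovers the true rank in at least
18 of 20 repetitions.

## 6. The Lévy-walker reduced model

The wave packet's essential dynamics reduce to a random walker with
momentum on the same periodic plane:
$dx = \gamma b(x)\,dt + \beta v\,dt + \gamma^{1/\alpha} dL^\alpha$ and
$dv = \beta b(x)\,dt$, with tail index $\alpha = 1.2$, noise strength
$\gamma = 100$, damping $\beta = 1$, and time in seconds at $dt = 1$ ms
steps (the only reading under which the per-step noise scale
$(\gamma\,dt)^{1/\alpha} \approx 0.15$ grid points is commensurate with the
plane; treating $dt$ as a unit interval would give 46-grid-point steps).
Stable increments use the Chambers–Mallows–Stuck construction. The momentum
equation carries no decay term and is integrated exactly as written; the
boundary wraps periodically, mirroring the circuit's torus (the center and
corner wells reproduce the two-input geometry). Stimuli are
truncated-quadratic wells, $\rho_i = (D_s + D_a)(d^2/\sigma_p^2 - 1)$ for
$d < \sigma_p = 15$ and 0 outside (continuous at the rim), with drift
$b = -\nabla\rho\,\Gamma(\alpha-1)/\Gamma(\alpha/2)^2$. Firing rates are a
20 Hz Gaussian bump (width 12) on the walker plus a 3 Hz baseline, raised
by $0.2\,D_{a,1}(1 - d^2/\sigma_p^2)$ inside the cued well; spikes are
Bernoulli-per-millisecond thinning, which at these rates is
indistinguishable from Poisson (Fano $1 - p \approx 0.98$ at worst, inside
every tolerance used).

Attention is the extra depth $D_{a,1} \in [0, 50]$ of the center well.
Deeper wells hold the walker longer (longer On episodes at the center) and
— because the rate bump then moves less — lower both the Fano factor and
the pairwise noise correlation of the 80 center neurons (55 ms windows,
20 trials of 200 s per depth, initial positions randomized per trial).
This is the package's fully quantitative endpoint: the full stated scale
runs in well under a minute per depth pair, and the computed values sit
within a few percent of their reference magnitudes (slightly high for the
correlations, as the acceptance report shows).

## 7. Synthetic fixtures: what passing tests do and do not show

`generate_fixture()` builds the data each analysis assumes, with ground
truth: telegraph MUA with known switch times; phase-modulated fast
oscillations on 1/f floors; delay-coupled Gaussian pairs with closed-form
transfer entropy; low-rank linear maps between count matrices; homogeneous
Poisson rasters; spectrally shaped noise. Passing these tests shows the
estimators are correctly implemented and calibrated on data satisfying
their assumptions. Real (or simulated-circuit) data violate several of
them — MUA is discrete-valued and autocorrelated, On/Off dwell times are
only approximately exponential, count fluctuations are neither Gaussian
nor exactly low-rank — so fixture-level accuracy bounds the best case, not
the typical one.

## 8. Problem sizes and reproducibility

The test suite uses scaled-down lattices (half-width 8, with connectivity
ranges scaled proportionally) for fast structural checks, one 15 s
full-size spontaneous realization shared across the end-to-end checks, and
the full stated scale for the walker. `scripts/acceptance.R` runs a 60 s
full-size spontaneous realization and the full walker ladder. All
randomness in kernels derives from integer seeds through a counter-seeded
xoshiro256++ generator, so results are bit-reproducible across runs and
platforms; R-level sampling restores the caller's RNG state.
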