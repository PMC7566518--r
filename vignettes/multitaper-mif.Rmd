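---
title: "Multitaper estimation of mutual information in frequency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multitaper estimation of mutual information in frequency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mift` estimates frequency-domain coupling between two trialized time
series, either as multitaper magnitude-squared coherence or as mutual
information in frequency (MIF), and provides the simulation models,
benchmarks and sliding-window statistics needed to study those estimators
and to relate coupling to task behaviour. This vignette explains the models
and procedures, the defaults and why they were chosen, and what the
package's tests do and do not establish.

## Coupling measures

For two discrete-time random processes $X(t)$ and $Y(t)$ with power spectral
densities $S_X(f)$, $S_Y(f)$ and cross-spectral density $S_{XY}(f)$, the
magnitude-squared coherence is

$$C_{XY}(f) = \frac{|S_{XY}(f)|^2}{S_X(f)\,S_Y(f)} \in [0, 1].$$

Coherence captures all dependence between the processes only when they are
jointly Gaussian. MIF drops that assumption. Writing the Cramér spectral
representation $X(t) = \int e^{j2\pi f t}\, d\tilde X(f)$ and treating each
complex increment $d\tilde X(f)$ as the random 2-vector of its real and
imaginary parts, MIF is the mutual information between increments at a
frequency pair,

$$\mathrm{MI}(f_i, f_j) = h(d\tilde X(f_i)) + h(d\tilde Y(f_j)) -
  h(d\tilde X(f_i), d\tilde Y(f_j)),$$

which is defined for cross-frequency pairs as well as the diagonal. All
logarithms in the package are natural, so every information quantity is in
nats; this makes the Gaussian-process identity
$\mathrm{MI}(f,f) = -\log(1 - C_{XY}(f))$ (`coherence_to_mif()`) and the
simulation ground truth below mutually consistent.

## Estimation

Both measures are estimated the same way up to the final step. Trials are
demeaned (on by default, to keep DC leakage out of low-frequency bins),
multiplied point-wise by $K$ orthonormal Slepian (DPSS) tapers, and Fourier
transformed at on-grid frequencies $f = f_s m / N$, giving one complex
increment sample per (trial, taper) pair with the fixed normalization $1/N$.
The normalization is cosmetic: coherence is invariant to it, and MIF is
invariant to any invertible linear map applied to a channel's samples.

*Coherence* averages $|d\tilde X|^2$, $|d\tilde Y|^2$ and
$d\tilde X\,\overline{d\tilde Y}$ across all (trial, taper) pairs and plugs
the averages into the definition. Pooling all pairs and averaging per-taper
spectra are algebraically identical here (equal-sized groups), so the
"naive" and taper-averaged routes to coherence coincide exactly — a property
the test suite checks to $10^{-10}$.

*MIF* feeds increment samples to the Kozachenko–Leonenko k-nearest-neighbour
entropy estimator through the three-entropies (3H) route, with the same $k$
in all three calls. The three taper-combination strategies differ in what
counts as a sample:

| strategy | samples per estimate | default $k$ | aim |
|---|---|---|---|
| `naive` | all $n K$ trial × taper samples, pooled | $\lfloor nK/2 \rfloor$ | — |
| `pre` | $n$ per-trial complex means across tapers | 3 | low bias |
| `post` | $n$ per taper; $K$ estimates averaged | $\lfloor n/2 \rfloor$ | low variance |

The per-strategy defaults encode the two working regimes: a small $k$ tracks
the density closely (low bias, high variance), a large $k$ smooths
aggressively (low variance, substantial bias). When coupling is correlated
with behaviour, variance — not bias — caps the measurable Pearson
correlation, so `post` is the default strategy; when absolute MIF values are
the object (as in the Gaussian/non-Gaussian comparison below), `pre` is the
right tool. The benchmark functions accept explicit `estimator_config()`
objects, so any $k$ rule can be imposed uniformly.

Numerical choices worth knowing: DPSS tapers are computed from the standard
symmetric tridiagonal Slepian matrix and ordered by in-band concentration
(computed independently from the sinc Toeplitz matrix); at most
$\lfloor 2\,nw \rfloor - 1$ tapers are allowed without an explicit override.
The default taper set is $nw = 2$, $K = 3$ — small enough to suit the
~100-trial windows the sliding analysis uses. Off-grid frequencies are an
error unless `nearest_bin = TRUE`. Exact duplicate samples make the k-NN
distance zero and are an error by default; an optional deterministic
sub-resolution jitter (`jitter_scale`) breaks ties reproducibly without
touching the RNG stream. Negative MI estimates are reported raw by default
(`clip_negative` exists for band summaries) because clipping would distort
the variance structure the benchmarks measure.

### Estimator facts the tests rely on

Two properties of the 3H k-NN route shape several tests. First, at the
variance-oriented setting $k = n/2$ the marginal and joint entropy biases do
not cancel, leaving a large, slowly varying offset (about $-0.14$ nats for
independent scalar Gaussians at $n = 1000$, and near $-1$ nat on the
sinusoid model at 100 trials). This offset barely harms correlation studies
— it is close to constant across nearby true values — but it means
"independence implies an estimate near zero" holds only at small $k$.
Second, the Euclidean-metric estimator is affine-invariant only within
estimator tolerance: moderate axis rescalings move the estimate by less than
0.05 nats, but extreme anisotropy (thousands to one) degrades it badly.
Standardize inputs with wildly different scales before estimating.

## Simulation models and ground truth

The reference model draws, independently per trial,

$$X(t) = A\cos(2\pi f_0 t + \Theta), \quad W(t) = B\cos(2\pi f_0 t + \Phi),
\quad Y(t) = X(t) + W(t),$$

with $\Theta, \Phi \sim \mathrm{Uniform}(0, 2\pi)$. Under the Rayleigh
family ($A \sim \mathrm{Rayleigh}(1)$, $B \sim \mathrm{Rayleigh}(\sigma_B)$)
every marginal is Gaussian and the true MIF at $(f_0, f_0)$ is

$$\mathrm{MI}(f_0, f_0) = \log\!\left(1 + \tfrac{1}{\sigma_B^2}\right),$$

with coherence $C(f_0) = 1/(1 + \sigma_B^2)$; `sigma_b_for_true_mif()`
inverts the identity for truth sweeps. Under the uniform family
($A, B \sim \mathrm{Uniform}(-0.5, 0.5)$) the process is non-Gaussian: the
marginal kurtosis is $\tfrac32\,E[A^4]/E[A^2]^2 = 2.7$ rather than the
Gaussian 3 (`analytic_kurtosis()`), and the coherence-to-MIF transform
underestimates the true information — the gap the package's non-Gaussian
comparison measures.

The default geometry is $N = 128$ samples at $f_s = 128$ Hz with
$f_0 = 8$ Hz, which puts $f_0$ exactly on an FFT bin; only the number of
paths matters statistically, so path length and $f_0$ are otherwise
arbitrary. For the uniform-family comparison no trial count is canonical;
the benchmark exposes it as configuration and the packaged checks use 2000
paths with 100 repetitions to form Monte-Carlo error bars.

```{r, eval = FALSE}
library(mift)
sim <- simulate_random_sinusoids(sinusoid_model_params(n_paths = 2000,
                                                       sigma_b = 1,
                                                       seed = 42))
estimate_coherence(sim$x, sim$y, frequencies = 8)$coherence  # ~ 0.5
estimate_mif_at(sim$x, sim$y, 8, 8, strategy = "pre")        # ~ log(2)
```

### A leakage caveat for noiseless line spectra

One honest and initially surprising property: on this *noiseless* model the
estimated MIF is far from zero even at frequency pairs away from $f_0$,
although the true process MIF is zero there. Every trial's waveform is a
deterministic function of its amplitude–phase draw, so the increment at
*any* bin is an invertible linear image of the same underlying complex
amplitude — spectral leakage through the taper sidelobes — and mutual
information is invariant to such maps. The estimator therefore recovers
nearly the full on-coupling information at off-coupling bins (about 0.6–0.7
nats at $\sigma_B = 1$). This is not an estimator defect: any broadband
noise floor, which all real recordings have, makes off-coupling increments
noise-dominated and restores the null. It does mean the noiseless sinusoid
model cannot be used to check off-diagonal nulls, and the corresponding
packaged check documents this failure rather than hiding it.

Relatedly, because all tapers see linear images of the same per-trial
amplitude, the pre and post strategies at a *matched* $k$ are nearly
identical on this model, and the naive pooling — fed three times the
samples — is smoother than a small-$k$ pre estimate. Strategy separations
measured on this model therefore reflect the $k$ regimes as much as the
combination rule; on real data, where tapers carry quasi-independent noise,
the post estimator's variance advantage is the operative effect.

## Benchmarks

`run_correlation_benchmark()` draws true MIF values uniformly within
$\pm 0.2$ nats of a centre (the sampling law within the stated range is a
package choice), simulates 100 paths per repetition, estimates under each
configuration, and reports the Pearson correlation between estimates and
truths — the figure of merit for behaviour-correlation studies, since a
zero-variance estimator scores 1 regardless of bias. A constant estimator is
reported as correlation 0 with a `degenerate` flag. Estimator variances
(`run_variance_benchmark()`) are comparable only within an estimator family
and are labelled accordingly. `run_asymptotic_benchmark()` tracks the pre
($k = 3$) bias and post ($k = n/2$) variance across sample sizes. The
single-Hamming-taper comparator rides along in all sweeps. Default scale is
300 repetitions per centre, which one CPU completes in seconds; the
publication-scale 10,000 repetitions is a flag away. All per-repetition
seeds derive deterministically from the master seed, so runs reproduce
bit-for-bit.

## Sliding-window inference

The behavioural pipeline mirrors a trialized delayed match-to-sample
analysis. Per 100-trial window (slid by 10 trials), band coupling (theta,
4–8 Hz, by default) is estimated in three 300 ms sub-windows starting at
1.6, 1.65 and 1.7 s and averaged; per-window task accuracy is the fraction
of correct trials. Significance testing uses a permutation max-statistic
null: the trial pairing of one channel is permuted, per-bin band coupling
recomputed, and the maximum across bins recorded; the 95th percentile of
these maxima controls the family-wise error rate across band bins.
Sub-threshold windows have their coupling zeroed before correlating with
accuracy (a config switch retains raw values instead — which of the two the
original significance-testing practice used is not documentable, so both are
implemented). The coupling–accuracy Pearson correlation gets a percentile
CI from a circular moving-block bootstrap with block length
$\lceil n^{1/3} \rceil$ by default, which absorbs the autocorrelation the
overlapping windows induce; a double-bootstrap CI refinement used by some
packages is deliberately not implemented. Two coupling measures sharing the
accuracy series are compared with the Meng–Rosenthal–Rubin Z-test
(`dependent_correlation_ztest()`).

Two design details are package decisions rather than received practice: the
permutation threshold in `task_coupling_analysis()` is computed once from
the first window's trials and applied to all windows (a per-window null is
available by calling `permutation_max_threshold()` per window at higher
cost), and the observed statistic compared to the max-statistic threshold is
the window's maximum band-bin coupling, which keeps the permutation test
exactly calibrated.

## The synthetic task session

`simulate_task_session()` is the package's stand-in for a real recording
session. Each trial carries a shared random-phase oscillation (Rayleigh(1)
amplitude) at 20/3 Hz — on the frequency grid of a 0.3 s sub-window and
inside the default theta band — mixed into channel Y with per-trial weight
$\sqrt{c_i}$ against an independent copy, so the oscillatory coupling in
trial $i$ equals the profile value $c_i$; independent Gaussian noise
(sd 0.5) is added to both channels, and per-trial accuracy is Bernoulli with
a logistic link from the centred coupling profile (slope 4 around a 0.75
base rate). The default profile is a smooth rise from 0.2 to 0.7 with a
small oscillation, emulating learning-related drift across a 400-trial
session of 3.6 s trials at 120 Hz.

What the generator emulates: band-limited inter-channel coupling that drifts
across trials, broadband background, and a behavioural series statistically
tied to coupling. What it does not: 1/f spectra, nonstationarity within
trials, volume conduction, cross-frequency structure, or non-Gaussian noise.
Passing the pipeline's recovery tests on these sessions therefore shows the
statistics are wired correctly and calibrated under the stated model — not
that the method is robust to everything real LFPs do.

## Problem sizes used by the packaged checks

The test suite runs everything at desk scale, chosen so the full suite
completes in a few minutes of one CPU: $10^6$ draws for kurtosis checks,
2000 paths (10 repetitions for means, 100 for error bars) for the
Gaussian/non-Gaussian comparisons, 300 repetitions for strategy orderings
and asymptotics over sizes 50–400, 1000 seeded repeats at 200 permutations
for the family-wise error calibration, and 50 seeded sessions for
end-to-end recovery. The corresponding publication-scale settings (10,000
repetitions, 5000 permutations, 2000 bootstrap resamples) are the function
defaults or a configuration flag away.

## Known limitations

* The off-coupling leakage effect above: noiseless line-spectrum inputs
  yield non-zero MIF estimates at uncoupled frequency pairs; add or accept a
  broadband floor before interpreting off-diagonal structure.
* The 3H large-$k$ offset makes absolute `post` MIF values uninterpretable
  without a calibration reference; use `pre` (small $k$) when levels matter.
* Window segmentation is non-overlapping trials only — no Welch overlap and
  no time–frequency output beyond the fixed sub-window scheme.
* The permutation unit is the whole trial; within-trial exchangeability is
  never assumed, but slow drifts shared by both channels can inflate the
  null if they co-vary with the permuted labels.
* Histogram estimators use 2 (fixed-width) or 3 (equal-occupancy) bins per
  axis by default; they are comparators, not recommended estimators.
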