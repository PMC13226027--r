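---
title: "Methods: scaling, fractional-order networks, and outcome classification for after-discharge trials"
author: "adsuppress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scaling, fractional-order networks, and outcome classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

During functional brain mapping, brief electrical stimulation of implanted
electrodes can trigger epilepsy-associated after-discharges (EAADs) on the
intracranial EEG. Engaging the patient in an effortful cognitive task
(arithmetic, spelling) sometimes suppresses these discharges. Each trial is
a multichannel recording segmented by behavioural markers into a phase
**W1** (discharge onset to question onset) and a phase **W2** (question
onset to discharge end), labelled by whether the suppression succeeded.

`adsuppress` implements the full analysis chain for such trials:

1. windowed **DFA** Hurst exponents and **MFDFA** generalized Hurst
   exponents per channel (temporal, single-channel scaling);
2. **fractional-order dynamical network (FODN)** identification per
   window, summarised by its dominant eigenmode (spatial organisation);
3. **Kolmogorov–Smirnov** comparison of W1 vs W2 exponent distributions,
   pooled and channel by channel;
4. **leave-one-trial-out logistic regression** on a fixed-length
   per-trial descriptor vector.

Because clinical iEEG of this kind is not publicly available, the package
ships a first-class synthetic cohort generator that reproduces the
statistical structure each stage assumes, with known ground truth. Every
claim the test suite makes is a claim about this generator's output; the
section on the generator below states explicitly what that does and does
not show about real data.

## Windows and coordinates

Recordings are samples × channels at 1000 Hz, z-scored per channel over
the whole trial (whether the original normalisation was per window or per
trial is not documented for this paradigm; per trial is the default and
per-window statistics would be configurable at the scan level). Sample
coordinates are 0-based half-open intervals; marker times are converted by
rounding to the nearest sample. W1 = [AD_Start, Qes_Start) and
W2 = [Qes_Start, AD_End) tile the discharge interval exactly once.

Analysis windows are 500 ms, laid within each inter-marker span from the
span start, stepping one window (`nonoverlap`) or half a window
(`overlap50`). Intermediate behavioural markers (`Qes_End`, `Ans_Start`,
`Ans_End`) restart the grid, so no window straddles a marker; trailing
partial windows are dropped.

## DFA and MFDFA conventions

For a window `x(1..N)` the profile is `Y(i) = sum_{k<=i}(x(k) - mean(x))`.
Segments of length `s in {16, 32, 64, 128}` (2^4..2^7, suited to 500 ms
windows at 1000 Hz) are detrended by a first-order polynomial;
`F^2(nu, s)` is the mean squared residual.

* **DFA** uses the `Ns = floor(N/s)` forward segments,
  `F(s) = sqrt(mean F^2)`, and `H` is the least-squares slope of
  `log2 F(s)` on `log2 s`. No crossover detection is attempted.
* **MFDFA** uses segments from both ends of the profile (`2 Ns` per
  scale), `Fq(s) = ((1/2Ns) sum [F^2]^{q/2})^{1/q}` for
  `q in {-5..5}`, with `q = 0` by logarithmic averaging. The two
  segmentations differ deliberately — they follow the defining equations
  of each method as printed in the literature — and the package keeps both
  rather than harmonising them; `h(2)` and the DFA `H` therefore agree
  only up to the segmentation difference (tested at 0.1).

Log base 2 is used throughout (slopes are base-invariant). Zero-variance
windows are flagged missing rather than raising errors, and flagged cells
are excluded from channel means with counts reported. At `s = 128` a
500-sample window has only 3 segments; the fit still uses all four scale
points — a documented small-sample caveat of short-window scaling
estimation, exercised for crash-freedom in the tests. On strongly
nonstationary spiking segments the estimates can exceed 1, which is
expected for transient integrated dynamics; no correction is applied.

At the implementation level the linear detrend is computed from segment
moment sums (an O(s) closed form per segment, verified against the
explicit projector to 1e-13) and integer-q moments use iterated products
of the segment RMS; both are exact rewrites, chosen so a full cohort scan
stays inside a desk-scale time budget.

## The fractional-order network model

Per channel, a fractional order `alpha_i` is estimated and the discrete
Grünwald–Letnikov (GL) derivative applied:

`z_i[k] = sum_{j=0}^{J} c_j^{alpha_i} x_i[k-j]`,
`c_j = Gamma(j - alpha)/(Gamma(-alpha) Gamma(j+1))`,

computed by the stable recursion `c_0 = 1, c_j = c_{j-1}(j-1-alpha)/j`
(the Gamma form has poles at integer orders; the recursion does not). The
truncation depth is `J = 50` samples by default — at least 99% of the
coefficient mass for orders up to about 1 — and the first `J` samples of
each window are dropped from the regression.

The network model is `z[k] = A x[k-1] + B u[k] + eps[k]` with `B = I`
(the convention of the FODN literature; it makes the input refinement a
per-time-step soft threshold). Estimation alternates:

1. ridge: `A = (Z - U) X^T (X X^T + lambda_r I)^{-1}`;
2. LASSO inputs: `u[k] = sign(r) max(|r| - lambda_l, 0)` with
   `r = z[k] - A x[k-1]`;

for at most 3 iterations or until the relative change in `A` falls below
1e-6. Each step minimises the joint objective
`||Z - AX - U||_F^2 + lambda_r ||A||_F^2 + 2 lambda_l sum|U|` in one
block, so the objective (recorded per iteration) is non-increasing — this
is asserted on every fit. Defaults: `lambda_r = 0.1 * mean diag(XX^T)`
(scales with window energy), `lambda_l = 2 *` the MAD scale of the
initial residuals, which leaves over 90% of input entries at zero on
input-free data.

### Estimating the fractional order

`alpha` comes from a Haar wavelet log-scale regression: detail energies
`mu_j` at levels `j = 1..4` (the usable range of a 500-sample window),
slope `p` of `log2 mu_j` on `j`, and `alpha = p/2`. Two refinements:

* **Discretisation correction** (default on). The discrete fractional
  operator has spectrum `|2 sin(w/2)|^{-2 alpha}`, which departs from the
  ideal power law at exactly the fine scales short windows can use; the
  raw slope is therefore biased towards zero (by about 0.06–0.10 over
  levels 1–4). The estimator maps the raw slope through the numerically
  exact inverse of the alpha-to-slope relation (a one-dimensional
  integral per level, no free parameters). With the correction, ARFIMA
  fractional orders are recovered essentially unbiased.
* **Damping-aware refinement** (`refine_alpha`, off by default). When a
  fitted self-coupling `A[i,i]` is strongly negative the channel's
  low-frequency spectrum flattens and the slope under-estimates `alpha`;
  a second pass re-inverts the slope through the response conditioned on
  the fitted self-coupling.

**Identifiability limit.** The estimator is a *single-channel* regression:
it assumes the channel's own fractional pole dominates its spectrum. On a
coupled network this fails in both directions — cross-channel power-law
drive steepens the slope, self-damping flattens it — and no level range
fixes it, because at frequencies below roughly `|A|^(1/alpha)` the network
response, not the fractional operator, shapes the spectrum. On planted
networks at realistic coupling strength the per-channel error can reach
0.5 even with both refinements; on uncoupled channels the same estimator
is accurate to about 0.1. The package therefore treats window-level
`alpha` tracks as *descriptive features* (their mean and variance feed the
classifier, where a consistent bias is harmless) rather than as consistent
estimates of the generative orders, and the recovery tests report the
error honestly instead of hiding the regime where the method's own
assumption breaks. Recovering orders consistently under coupling would
require joint spectral identification of `(alpha, A)`, which is outside
this pipeline's scope.

### Dominant eigenmode

Per window, the eigenvalue of `A` with the largest modulus is selected
(ties broken deterministically toward the first of the modulus-sorted
spectrum). The spatial weight vector is real and unit-norm: absolute
values after fixing the largest entry positive in the real case, the
componentwise modulus for a complex pair (which preserves the 2-norm).
Summaries: maximum weight, participation ratio `1/(n sum w^4)` (1 =
fully distributed, 1/n = single channel), and the mean cosine similarity
of consecutive windows' weight vectors (mode stability).

## Group statistics

One value per (trial, channel): the time-averaged exponent over a phase's
windows. Pooled per outcome class, W1 vs W2 distributions are compared
with the two-sample KS test using the asymptotic p-value (effective size
`n1 n2/(n1+n2)`), which is the appropriate regime at these pool sizes.
Channel-by-channel tests within a trial use the window-level exponents and
are reported as raw p-values — deliberately no multiple-testing
correction, matching how such screens are read in this literature; the
output labels them raw.

## Classification

Each trial is reduced to a fixed-length descriptor vector regardless of
channel count: mean and variance (over windows and channels) of the FODN
fractional orders, the three dominant-eigenvector summaries above, and
the generalized Hurst summary (mean `h(2)`; the width `h(-5) - h(5)` is
optional and off by default, since a handful of trials cannot support
higher-dimensional multifractal descriptors). The scalar reduction of the
eigenvector is the minimal permutation-stable way to feed a
patient-specific, variable-length vector into a fixed-length model. Phase
handling defaults to W2 − W1 deltas — the scientific claims concern the
*change* induced by cognitive effort — with absolute-W2 and concatenated
modes available.

Evaluation is leave-one-trial-out: features are standardized with
training-fold statistics only (a global normalisation would leak the
held-out trial; the stricter protocol is adopted deliberately and the
per-fold scalers are exposed so the no-leakage property is itself
testable), then an L2-penalised logistic regression with a fixed penalty
(`lambda = 0.05`; a few dozen trials cannot support nested tuning) is fit
and the held-out trial predicted at threshold 0.5. The ROC and AUC come
from the pooled out-of-fold probabilities. Degenerate folds are handled
explicitly: a single-class training fold predicts the training majority;
an all-constant feature matrix yields majority predictions at probability
0.5, hence AUC 0.5.

## The synthetic cohort generator

Defaults are fixed at the study scale: 43 trials, 20 successes, 60
channels (within the 56–110 range of implanted montages, at the low end
to keep a desk-scale runtime), 1000 Hz. Phase durations draw uniformly
from 3–6 s (W1) and 4–8 s (W2) — short relative to real trials, chosen
once as the desk-scale operating point so the full cohort analysis and
its replications run in minutes; amplitude is in z-score units by
construction (filtering and gain of the clinical recordings are not
documented). Each trial is:

* a channelwise long-memory background: ARFIMA fractional noise whose
  order is redrawn every 500 ms per channel from a phase-specific
  distribution (W1: mean 0.30, sd 0.12), each block normalised to unit
  variance;
* one-step network mixing `x[k] = A x[k-1] + background[k]` through a
  planted sparse directed coupling matrix;
* after-discharge transients throughout [AD_Start, AD_End): a 3 Hz
  jittered train of ~60 ms biphasic (Hann-windowed sine) kernels on a
  random 40% of channels — the discharge morphology is not parameterised
  in the literature; any sharp-transient morphology serves the pipeline;
* roughly every third trial carries intermediate markers inside W2 to
  exercise grid restarts.

The suppression effect is injected on exactly the signature the analysis
claims to detect: during W2 of successful trials the fractional-order
distribution tightens (mean 0.30 → 0.18, sd 0.12 → 0.04 at full effect)
and spike amplitude drops by 80%, both scaled linearly by `effect_delta`;
`effect_delta = 0` gives a null cohort in which success and failure
trials are exchangeable. The generator emulates the *statistical
structure* the methods assume — long-range dependence, block
nonstationarity, sparse coupling, transient spikes, a variance-reduction
effect. It does not emulate real iEEG artifacts, volume conduction,
patient-level heterogeneity beyond channel count and durations, or
physiologic seizure dynamics; a green test suite therefore shows the
pipeline detects this class of effect when present and invents nothing
under the null — it does not show the real-data effect size.

### Stability of planted networks

The truncated GL integrator is marginally stable, so *any* coupling
eigenvalue with positive real part diverges — a spectral radius below 1
is not sufficient for these dynamics. Planted truths therefore rescale
the sparse couplings, shift every eigenvalue to real part ≤ −0.05, add
heterogeneous per-channel leak (uniform on [0, 0.4]; electrode
populations damp at different rates, and homogeneous damping would make
the diagonal of `A` uninformative), and then verify the exact
linearisation — the `nJ × nJ` block companion matrix of the truncated-GL
recursion — has spectral radius below 1, shrinking the couplings until it
does. Every returned truth simulates stably for any horizon.

A noiseless free response of such a damped system decays to numerical
zero, so round-trip identification tests use near-marginal rotation
(skew) couplings with near-unit orders and initialise the full GL history
randomly (a single initial vector excites only a low-dimensional Krylov
subspace); under those conditions the ridge stage recovers a planted `A`
to below 1e-3 relative Frobenius error from exact data.

## Numerical and reproducibility choices

* fGn by circulant embedding: exact autocovariance, eigenvalues clipped
  only within 1e-10 of round-off, error otherwise; ARFIMA by the
  truncated MA(∞) recursion applied as an FFT convolution after a
  burn-in equal to the kernel length.
* The binomial cascade is the deterministic dyadic measure, so its
  generalized Hurst exponent `h(q) = 1/q - log2(a^q + (1-a)^q)/q` is an
  exact oracle for the MFDFA chain.
* All randomness flows through explicit seeds; every generator restores
  the caller's RNG state, and identical seed + config gives
  byte-identical pipeline output (tested).
* Problem sizes in the shipped analyses: 43-trial cohorts for the main
  runs; 10-channel, 2000-sample simulations × 10 seeds for recovery;
  n = 8192 × 20 seeds for scaling oracles. These are the package's
  desk-scale choices and are stated in the scripts that use them.

## Known limitations

* Window-level `alpha` estimates are biased on coupled channels (see the
  identifiability discussion); they are features, not consistent
  parameter estimates.
* The A-recovery guarantees hold for the identification stage given the
  orders; end-to-end recovery of both `A` and `alpha` from coupled data
  is not claimed.
* The KS comparison treats pooled per-channel means as exchangeable
  across trials and patients, as the source analyses do; no hierarchical
  structure is modelled.
* Real-data ingestion is limited to the TSV + JSON bundle format; EDF or
  vendor formats would need an adapter.
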