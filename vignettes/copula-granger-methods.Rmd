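---
title: "Methods: copula-based Granger causality for mixed spike/LFP data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copula-based Granger causality for mixed spike/LFP data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copulagc)
```

## The problem

Simultaneously recorded spike trains and local field potentials (LFPs) are a
mixed pair: one channel is binary at millisecond resolution, the other
continuous. Classical Granger causality assumes jointly Gaussian linear
series and is awkward for point processes; transforming spikes into rates
throws away timing. `copulagc` implements a joint likelihood model in which
each channel keeps a natural marginal and the cross- and same-bin dependence
is explicit, so directional influence can be tested by likelihood ratios
between nested fits.

The motivating application is cortical area V4 during a contour-detection
task: 1 kHz LFP, sorted spikes binned at the same rate, trials of 300 ms
fixation, 500 ms stimulus and 300 ms delay, and two stimulus conditions
("1-bar" noise vs "7-bar" contour) expected to differ in coupling strength.
That recording is not publicly deposited, so everything here is validated
against the package's own generative simulator, which reproduces the trial
structure rather than the data.

## The model

For bin $t$ within a trial, with order-$p$ histories of the LFP $y$ and the
binary spike indicator $x$:

$$\mu_t = c_y + \sum_{i=1}^{p} a_i\, y_{t-i} + \sum_{i=1}^{p} b_i\, x_{t-i},
\qquad
\eta_t = c_x + \sum_{i=1}^{p} d_i\, x_{t-i} + \sum_{i=1}^{p} e_i\, y_{t-i}.$$

The margins are $y_t \sim N(\mu_t, \sigma^2)$ and
$P(x_t = 1) = \Phi(\eta_t)$ (probit). Dependence beyond the histories is a
Gaussian copula with correlation $\rho$ between the two per-bin innovations,
realized by a latent threshold: $x_t = 1$ iff a standard normal $z_x$ with
$\mathrm{corr}(z_x, z_y) = \rho$ exceeds $-\eta_t$. This gives the exact,
quadrature-free conditional

$$P(x_t = 1 \mid y_t)
 = \Phi\!\left(\frac{\eta_t + \rho z_t}{\sqrt{1-\rho^2}}\right),
 \qquad z_t = \frac{y_t - \mu_t}{\sigma},$$

so the per-bin likelihood is the Gaussian density times this conditional
Bernoulli term. At $\rho = 0$ the joint likelihood factorizes exactly into
the two marginal likelihoods (the tests assert this as an identity of
floating-point expressions). The latent-threshold route was chosen over
CDF-interval integration because for a binary margin the two are equivalent
and the former is closed-form; a Poisson-margin variant is out of scope.

Why a probit rather than logistic margin: under the latent-Gaussian copula
the probit link is the internally consistent choice — the marginal and the
copula construction then agree without approximation, which is what makes
the margin-consistency identity $\int P(x=1\mid y) f(y)\,dy = \Phi(\eta)$
hold exactly (acceptance criterion 3 verifies it by quadrature).

## Estimation

The likelihood is conditional: the first $p$ bins of every trial condition
only (standard conditional-likelihood treatment of an AR model; trials stay
independent contributions and no stationary-distribution term is needed).
Parameters are optimized by BFGS with an analytic gradient (compiled in
C++), with $\sigma$ on the log scale and $\rho$ on the arctanh scale so the
constraints $\sigma > 0$, $|\rho| < 1$ are automatic. The warm start is
two-stage: ordinary least squares for the continuous margin, then probit
IRLS for the discrete margin with the standardized continuous residual as an
extra covariate (its coefficient is $\rho/\sqrt{1-\rho^2}$, giving a
consistent starting $\rho$). The free-parameter count is $k = 4p + 4$ for
the full model and $3p + 4$ when one cross-history block is fixed at zero.

Standard errors, when requested, come from the inverse observed information
at the optimum and are used for diagnostics only.

**Order selection.** AIC $= -2\ell + 2k$ across a candidate set, all fitted
with a common conditioning length of $\max(\text{candidates})$ initial bins
so the AICs compare likelihoods over identical observations; ties break
toward the smaller order. Selection is done on the whole analysis epoch (a
per-window order could in principle differ; windows are short, so a single
epoch-level order is both more stable and the conventional choice).

## Granger causality

Directional GC is a per-observation deviance between nested fits:

$$\mathrm{GC} = \frac{2}{n_{\mathrm{obs}}}\left(\ell_{\mathrm{full}} -
\ell_{\mathrm{reduced}}\right) \ge 0,$$

with the reduced model dropping $b$ (spike→LFP) or $e$ (LFP→spike). The
per-observation scaling makes the two directions — whose targets are a
continuous and a binary variable — commensurable, and makes windowed values
comparable across window lengths. Nonnegativity follows from nested
maximization; numerically it is enforced by restarting the full fit from the
reduced optimum whenever the default start ends below it (the restart can
only increase the full likelihood, so the nesting inequality holds on every
run).

**Inference.** P-values come from per-trial circular shifts of the source
channel (spikes for spike→LFP), which preserve each channel's
autocorrelation and trial structure while destroying cross-channel
alignment; at least 200 permutations are recommended and the p-value is
$(1 + \#\{\mathrm{perm} \ge \mathrm{obs}\})/(n_{\mathrm{perm}} + 1)$, which
lives in $[1/(n_{\mathrm{perm}}+1),\,1]$. An optional early-stopping rule
abandons the loop once non-rejection at a stated level is certain; this
changes the reported p-value to a valid lower bound but never the decision
at that level — it exists so that large replicate studies (null calibration)
stay inside a CI budget.

**Time course.** A sliding window (defaults 100 ms / 10 ms step; the
recording's own analysis parameters are not published, so these are
config-exposed conventions, not reproduced values) pools each window's bins
across trials and computes the pooled GC. The SEM per window is the standard
deviation of the GC over bootstrap resamples of trials, matching the
trial-count-tied uncertainty bands of the motivating figures.

**Normalization and contrast.** Normalized GC divides the curve by its mean
over a baseline window (default the fixation period, $[-300, 0)$ ms). The
source text says "normalized" without defining it; divisive normalization
was chosen because it makes the curve dimensionless and scale-invariant
(doubling all GC values leaves it unchanged) and is idempotent. A
subtractive variant would need an additional variance convention for the
SEM. The condition contrast is the mean post-onset difference of normalized
curves divided by the pooled bootstrap SEM
$\sqrt{\overline{\mathrm{sem}_a^2} + \overline{\mathrm{sem}_b^2}}$ — a
standardized separation, positive when the second (contour) condition is
larger.

## The simulator

`simulate_mixed()` draws from exactly the model above: per bin a correlated
standard-normal pair, AR recursion for the LFP, thresholded latent normal
for the spike. Histories start at zero and a burn-in of $10p$ bins is
discarded per trial. Defaults mirror the recorded design — 146 trials, 1100
bins at 1 kHz with onset at bin 301 (300 ms fixation, 500 ms stimulus,
300 ms delay). Coupling can switch at onset (`post_onset_model`), and
`make_condition_pair()` builds matched "1-bar"/"7-bar" pairs differing only
in post-onset cross-coupling magnitude (seeds `seed`, `seed + 1`).

Spike contamination is modeled as a short waveform added to the LFP at every
spike; the default is a 3 ms biphasic pulse at 1 kHz (no published waveform
exists to copy; the template is config-replaceable).

What the simulator does *not* emulate: 1/f LFP spectra, oscillatory bands,
nonstationary rates within an epoch, multi-unit interactions, electrode
geometry, and non-Gaussian noise. A green simulation test therefore
establishes correctness of the estimation and inference machinery under the
model's own assumptions, not robustness to real-data violations of them.

Desk-scale choices: acceptance simulations use a spike-margin intercept
$c_x = -1.5$ (rate $\Phi(-1.5) \approx 6.7\%$ of 1 ms bins, i.e. ~67 Hz —
the high end of V4 single-unit rates, chosen once so that small fixtures
still contain enough events to be informative), a stable AR(2)/AR(3) LFP
with roots well inside the unit circle, and refractory-like negative spike
self-history. Replicate counts follow the stated designs; per-replicate
trial counts and lengths are scaled to desk size so the full suite fits a
CI budget. None of these values were revisited after seeing test outcomes.

## Despiking

The cited removal algorithm for the original analysis is Bayesian and its
details are not in the source text; this package substitutes a deterministic
stand-in: the artifact is a single trial-invariant template estimated by
least squares — LFP regressed on shifted copies of the spike train over the
artifact window. Under linear superposition this is exact even with
overlapping spikes (unlike a plain spike-triggered average), which the tests
verify. The substitution is adequate for the contamination *control* (does
spike-locked energy in the LFP masquerade as spike→LFP causality?), not a
re-implementation of the original algorithm.

One consequence to understand: least squares makes the despiked LFP exactly
orthogonal, in sample, to the spike-train lags inside the removal window. If
the analysis order's cross-history lags all lie inside that window, the
spike→LFP GC after removal is mechanically biased toward zero and the
permutation test becomes conservative. The contamination-control fixture
therefore states a world in which the artifact is fast (2 ms, as a waveform
leak is) and genuine coupling is synaptic-latency slow (2–3 ms lags), so the
removal window covers the artifact but not the genuine effect. This matches
the physical rationale for despiking: waveform leakage is instantaneous,
synaptic influence is not.

## Numerical choices and degenerate inputs

* Butterworth low-pass, order 4, applied forward-backward with steady-state
  initial conditions and odd-reflection padding: zero phase (event times
  stay aligned), squared magnitude response, DC gain exactly 1. No filter
  family is named in the source; this is the field's default. The cutoff for
  LFP separation is likewise unstated; the CLI default of 250 Hz mirrors the
  conventional spike/LFP boundary.
* Spike binning uses half-open 1 ms bins, left edge inclusive; binary mode
  (default at 1 kHz) clips multi-spike bins to 1 with a warning, count mode
  conserves events.
* Degenerate inputs are rejected rather than coerced: constant spike
  channels, non-binary spikes under the binary model, unstable AR
  generators (reported with their spectral radius), baseline windows with
  zero mean GC, windows too short for the order ($< 10p$ bins).
* Optimizer non-convergence is flagged in the `copula_fit`, excluded from
  order-selection tables, and is an error in `gc_directional` for the
  observed-data fits.

## Known limitations

Bivariate only (no conditional GC on more channels); Gaussian copula only;
binary spike margin only (1 kHz bins make multi-spike bins negligible);
time-domain GC only (no spectral decomposition); the despiker assumes a
trial-invariant linear template. The AIC-selection consistency and GC
calibration results here are desk-scale simulation checks, not guarantees
for arbitrarily short windows or near-degenerate spike rates.
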