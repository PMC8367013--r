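---
title: "Noise-corrected model-to-neuron correlation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise-corrected model-to-neuron correlation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(r2er)
```

# The estimation problem

A sensory neuron is driven with $m$ distinct stimuli, each repeated $n$
times, giving responses $Y_{i,j}$ (stimulus $i$, repeat $j$).  A model
predicts a value $\nu_i$ per stimulus.  The quantity of scientific interest
is the squared correlation between the predictions and the *expected*
responses $\mu_i = E[Y_{i,j}]$ — the tuning curve the neuron would show
with infinite repeats:

$$r^2_{ER} = \frac{\left(\sum_i(\nu_i-\bar\nu)(\mu_i-\bar\mu)\right)^2}
{\sum_i(\nu_i-\bar\nu)^2\,\sum_i(\mu_i-\bar\mu)^2}.$$

The usual practice of correlating predictions with trial averages
$\bar Y_{i\cdot}$ estimates something else.  Writing $\sigma^2$ for the
trial-to-trial variance (assumed constant across stimuli — see
"Variance stabilization" below), each trial average carries sampling
variance $\sigma^2/n$, which inflates the denominator of the squared
correlation by $(m-1)\sigma^2/n$ per unit of prediction variance and the
numerator by $\sigma^2/n$.  The naive $\hat r^2$ is therefore biased
downward, by an amount that depends on the neuron's noise level rather
than on the model.  Two recordings of the same tuning curve at different
noise levels get different "model performance".

# The corrected estimator

Both sums of squares in the naive estimator are (scaled) noncentral
chi-squared variates, so their noise contributions have known
expectations.  `r2_er()` subtracts unbiased estimates of those
contributions from numerator and denominator separately:

$$\hat r^2_{ER} =
\frac{\left(\sum_i(\nu_i-\bar\nu)(\bar Y_{i\cdot}-\bar Y)\right)^2
 - \frac{\hat\sigma^2}{n}\sum_i(\nu_i-\bar\nu)^2}
{\sum_i(\nu_i-\bar\nu)^2\sum_i(\bar Y_{i\cdot}-\bar Y)^2
 - (m-1)\frac{\hat\sigma^2}{n}\sum_i(\nu_i-\bar\nu)^2}.$$

$\hat\sigma^2$ defaults to the pooled per-stimulus sample variance
(`pooled_sample_variance()`), but any unbiased or assumed value may be
substituted — notably $1/4$ for square-root transformed Poisson counts,
which makes the estimator usable in single-repeat ($n = 1$) designs where
no sample variance exists.

Three deliberate properties:

* **No truncation.**  The ratio may exceed 1 or fall below 0.  When the
  true correlation is 1 roughly half of all estimates land above 1;
  clipping them would push the mean back below the truth.  Anyone needing
  a display value can clip at presentation time.
* **Instability is reported, not hidden.**  For very weak tuning the
  corrected denominator can be zero or negative.  The raw ratio is still
  returned with `unstable = TRUE`; the confidence machinery, not the point
  estimate, is the right way to communicate that such a recording carries
  little information.
* **Ratio-of-unbiased is not unbiased.**  The numerator and denominator
  are individually unbiased, but their ratio is only approximately so
  (Jensen's inequality plus a covariance term).  The residual bias is
  small relative to the estimator's spread at moderate SNR, shrinks as
  $m$ grows (the estimator is consistent in $m$, unlike the naive one),
  and is measured directly by the package's simulation tests.

Internally the predictions are rescaled to unit centered sum of squares;
the estimate is invariant to this and the tests assert as much.  The
linear-model generalization `r2_er_linear()` applies the same logic to
least-squares fitted values with $d$ coefficients, using $m-d$ residual
degrees of freedom; at $d = 2$ it is algebraically identical to
`r2_er()`, which the tests verify to $10^{-12}$.

# Variance stabilization

The constant-variance assumption is what makes the corrections exact.
For Poisson-like counts the square root brings the variance to
approximately $1/4$ regardless of rate; more general mean–variance
relationships $\sigma^2(\mu) = a\mu^b$ (with $b < 2$) are handled by the
power transform in `apply_stabilizer()`.  The approximation degrades at
very low rates — at a mean count of 5 the stabilized variance is nearer
0.28 than 0.25 — which is worth remembering when substituting the assumed
$1/4$.  Automatic estimation of $(a, b)$ (e.g. Box–Cox) is intentionally
out of scope; users supply the exponents.  Zero counts are legal input
($\sqrt 0 = 0$).

# The SNR quality metric

A recording's usefulness for model evaluation is governed by the
signal-to-noise ratio $SNR = d^2/\sigma^2$, where
$d^2 = \frac1m\sum_i(\mu_i-\bar\mu)^2$ is the dynamic range of the tuning
curve.  Plugging trial averages into $d^2$ inflates it by
$(m-1)\sigma^2/(mn)$; `dynamic_range_hat()` subtracts that inflation, and
`snr_hat()` forms the corrected ratio.  Negative estimates are possible
for untuned neurons and are returned as-is for the same reason the
correlation estimator is not truncated.

The metric earns a concrete interpretation through the one-way F-test for
stimulus modulation: the F statistic follows a noncentral F distribution
with $(m-1,\ m(n-1))$ degrees of freedom and noncentrality $mn\,SNR$.
`f_test_power()` evaluates its power; `min_snr_for_power()` inverts it
(bracketed root-finding on $[10^{-6}, 10^3]$ with expansion, converged to
$|power - \beta| < 10^{-8}$) to give the minimal SNR at which tuning is
reliably detectable — with the defaults $\alpha = 0.01$, $\beta = 0.99$,
about 0.5 for an $(m{=}8, n{=}10)$ design and about 0.1 for
$(m{=}350, n{=}5)$.  `snr_time_normalize()` rescales SNR linearly with
the spike-counting window under a constant-firing-rate assumption; that
assumption is optimistic for transient responses, so normalized values
should be read as upper bounds for windows longer than the recorded one.

# The synthetic-data engine

`simulate_responses()` draws $Y_{i,j} \sim N(\mu_i, \sigma^2)$ around a
sinusoidal tuning curve $\mu_i = a + b\sin((i-1)2\pi/m + \theta)$ while
the model predicts $\nu_i = \sin((i-1)2\pi/m)$.  Over a full cycle the
phase sets the correlation exactly, $r^2_{ER} = \cos^2\theta$, and only
$(d^2, \sigma^2, r^2_{ER}, m, n)$ matter to any estimator — the sinusoid
is a convenience, not an assumption.  Design choices:

* The amplitude $b$ is solved from the realized discrete sum so that
  $\frac1m\sum_i(\mu_i-\bar\mu)^2 = d^2$ holds exactly for every $m$,
  rather than using the continuum approximation $b = \sqrt{2d^2}$; the
  nominal SNR of a configuration is then exact.
* The baseline $a$ is 0 in Gaussian mode (estimators are
  mean-invariant).  In `poisson_sqrt` mode — counts drawn Poisson with
  rates $\mu_i^2$, then square-rooted — the baseline defaults to the
  smallest value keeping every $\mu_i \ge 0.5$ (rates of at least 0.25
  per window), and $\sigma^2 = 0.25$ is the matching configuration on the
  stabilized scale.  The rate scale is exposed through `a` because
  benchmark behavior is insensitive to it at rates above a few spikes.
* One master seed drives derived per-replicate substreams
  (`sim_sweep()`), so replicate $k$ is identical whether the sweep is run
  whole or in pieces.

What the generator does **not** emulate: correlated trial-to-trial noise,
stimulus-dependent variance, temporal structure within trials, and
non-Gaussian heavy tails beyond the Poisson mode.  Passing benchmarks
therefore certify the estimators under the stated model, not robustness
to those violations; the estimator itself assumes independent responses
across stimuli and repeats.

# Confidence intervals

The corrected estimator's sampling distribution depends on the unknown
$(\sigma^2, d^2, r^2_{ER})$.  The interval procedure (`ecci()`, an
estimate-centered credible interval) inverts the estimator's distribution
over candidate true correlations:

1. **Posterior for the nuisances.**  The pooled variance statistic
   $\hat s^2$ and the between-stimulus variance $\hat d^2$ are independent
   scaled (noncentral) chi-squared variates; under flat nonnegative priors
   a Metropolis–Hastings chain (`posterior_draws()`) samples
   $(\sigma^2, d^2)$ given them.  The chain starts at the estimates (near
   the mode — no burn-in), and proposes from a zero-truncated normal
   centered at the estimates with the statistics' own sampling variances,
   truncation implemented by redraw.
2. **Conditional estimator distribution.**  For a candidate $r^2_c$,
   `sample_estimator_given_r2()` repeatedly resamples a posterior
   $(\sigma^2, d^2)$, simulates a fresh response matrix at that candidate,
   and re-estimates — giving the distribution the observed estimate would
   have come from if the truth were $r^2_c$.
3. **Bracketing search.**  The upper endpoint is the candidate at which
   the observed estimate sits at the $(1-\alpha)/2$ lower tail of that
   distribution (the lower endpoint symmetric).  Candidates are accepted
   when a z-test at significance 0.01 cannot distinguish the simulated
   tail proportion from its target; otherwise the bracket is bisected at
   a uniformly drawn point, up to `max_splits` refinements.  Endpoints
   that cannot reach their target inside $[0,1]$ are clamped, and the
   interval is declared empty when the upper endpoint clamps to 0 or the
   lower to 1 — the non-inclusive boundary convention that keeps coverage
   honest at the edges of the parameter space.

Throughout, `alpha` is the *coverage level* (0.8 gives an 80% interval);
the endpoint tail targets are $(1-\alpha)/2$.

One methodological caveat is documented rather than hidden.  The default
acceptance ratio is the plain likelihood ratio.  Because the proposal is
centered at the estimates (an independence sampler), a textbook
acceptance ratio would include the proposal densities; omitting them
tilts the chain's stationary distribution toward the proposal's center.
On a small design ($m{=}40$, $n{=}4$) the default chain's histogram
deviates visibly from a dense grid evaluation of the posterior (total
variation ≈ 0.3) while the corrected ratio, available via
`corrected = TRUE`, matches it (TV < 0.1; asserted in the tests).  The
default nevertheless remains the plain ratio for two reasons: it is the
procedure the interval method was validated with, and measured interval
coverage at the validation design is at the nominal 0.8 under *both*
rules — the tilt mostly reweights a region over which the estimator's
conditional distribution changes slowly.  Users doing posterior inference
on $(\sigma^2, d^2)$ itself should set `corrected = TRUE`.

Degenerate data with $\hat s^2 = 0$ (all repeats identical) makes the
posterior improper; `ecci()` refuses with an explanatory error, while the
bootstrap baselines return the zero-width interval at the point estimate.
The stochastic-ordering assumption behind the inversion — the conditional
CDF at the observed value decreases in the candidate — is asserted
empirically over a candidate grid in the tests, not proven.

`bootstrap_ci()` provides the generic baselines (within-stimulus
non-parametric resampling, parametric simulation from the fitted model,
and BCa with a jackknife over stimuli).  They are included because their
failure is instructive: at high true correlation the non-parametric
percentile interval sits almost entirely below the truth (its center is
the naive-biased estimate's sampling distribution), and
`coverage_experiment()` reproduces that collapse alongside the ECCI's
nominal coverage.

# Problem sizes in the shipped tests and benchmarks

The package's acceptance checks run the benchmark designs at 1000
replicates (means and quantiles of the estimators at $m{=}362$, $n{=}4$),
500 replicates for the ten-estimator comparison, and 200 intervals per
true-correlation level (with 2500 conditional draws per candidate
evaluation and 2000-iteration chains) for the coverage experiment.  These
sizes put Monte-Carlo error comfortably inside the tolerances they are
checked against while keeping a full run in the minutes range on one
core; the same code scales to larger runs by changing the `reps`,
`n_sims` and `n_samples` arguments.

# Known limitations

* Rectangular designs only: stimuli with unequal repeat counts must be
  subset before analysis.
* The correlated-response case (adjacent time bins, neuron-to-neuron
  signal correlation) is outside the model.
* Regularized model fits have no well-defined degrees of freedom here;
  `r2_er_linear()` trusts whatever `dof` the caller asserts.
* The residual small-sample bias of the corrected estimator at very low
  SNR is characterized empirically but not corrected; population averages
  over many low-SNR neurons inherit it.
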