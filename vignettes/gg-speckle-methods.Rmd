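---
title: "Generalized Gamma modeling of ultrasound speckle: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalized Gamma modeling of ultrasound speckle: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speckleGG)
```

## The model

Ultrasonic B-mode speckle arises from the interference of echoes returned
by sub-resolution scatterers. When many scatterers contribute, the
envelope of the backscattered signal is Rayleigh distributed (fully formed
speckle); a dominant specular reflection shifts it toward a Rician law,
and a small effective scatterer count produces heavier-tailed statistics.
Rather than switching between families, `speckleGG` models the envelope
with the three-parameter Generalized Gamma (GG) distribution

$$f(x \mid a, \nu, p) \;=\; \frac{p\,x^{p\nu-1}}{a^{p\nu}\,\Gamma(\nu)}\,
  e^{-(x/a)^p}, \qquad x > 0,$$

with scale $a > 0$ and shape parameters $\nu, p > 0$. The GG nests the
families commonly used for speckle — Exponential $(a, 1, 1)$, Rayleigh
$(\sigma\sqrt2, 1, 2)$, Weibull $(\lambda, 1, \kappa)$, Gamma
$(\theta, k, 1)$ and Nakagami $(\sqrt{2\Omega/m}, m, 2)$ — so a single fit
adapts across tissue types and speckle regimes (`special_case_to_gg()`
provides the mappings; for the Nakagami we follow the convention in which
$E\{R^2\} = 2\Omega$, equivalent to the usual one up to a rescaling of
$\Omega$, so that $m = 1$ reduces exactly to the Rayleigh with
$\sigma^2 = \Omega$).

## Maximum likelihood by profiling the power shape

The GG has no closed-form ML estimates, and its three joint score
equations are notoriously awkward. The estimator at the core of the
package (`fit_ml_proposed()`) exploits the power transform
$Y = X^{p_0}$: exactly at $p_0 = p$ the transformed variable is Gamma
distributed, whose ML sub-problem is benign. For a fixed $p$:

1. $\hat\nu$ solves $\log\nu - \Psi(\nu) = A(p)$ with
   $A(p) = \log\bar y - \overline{\log y} \ge 0$ (AM–GM; zero only for
   degenerate all-equal data, which is rejected). Because
   $1/(2\nu) < \log\nu - \Psi(\nu) < 1/\nu$, the root is bracketed in
   $(1/(2A),\, 1/A)$; `solve_shape_nu()` runs Brent's method on that
   interval expanded by 1% against endpoint round-off.
2. $\hat a^{\,p} = \sum_i y_i / (n \hat\nu)$ in closed form.

The resulting profiled likelihood is maximized over $\log p$ (positivity
by parametrization) with Nelder–Mead started at $p = 1$, restarted from
$p \in \{0.5, 2\}$ if the simplex fails, and finished with a short
golden-section polish; the outer search is confined to
$p \in [10^{-3}, 10^3]$, outside which the GG is numerically
indistinguishable from its lognormal limit ($p \to 0$,
$\nu \to \infty$) that heavily discretized data can favor without an
interior maximum, and $A(p)$ is computed through `expm1`/`log1p` so that
small powers do not lose it to cancellation. The equivalence theorem
behind the method — the
profiled $(\hat a, \hat\nu)$ at the optimal $\hat p$ are the GG ML
estimates — is verified in the test suite by re-solving the inner
equations at $\hat p$ and by checking that all three score residuals
(`score_residuals()`) vanish to $10^{-6} n$.

### Reference estimators

* `fit_stacy_moments()` matches the first three central moments of
  $\log X$ against the polygamma moments of the log-Gamma law. The
  attainable log-skewness magnitude is $(0, 2)$ and its sign must be
  negative; samples outside that set raise a `gg_out_of_space` condition
  — a real failure mode of the method, not of the data.
  Following the defining moment identities, the scale estimate includes
  the $1/\hat p$ factor, $\hat a = \exp(\bar y - \Psi(\hat\nu)/\hat p)$.
* `fit_gomes()` scans a grid of candidate powers, fits the transformed
  sample as a Gamma by moments, and scores each candidate with a
  chi-squared statistic on bins equiprobable under the candidate (bins
  with expected count below 5 are merged by coarsening); the smallest
  statistic — the best fit — wins. Grid resolution bounds its accuracy,
  and the histogram dependence makes it sample-size sensitive.
* `fit_noufaily()` iterates the log-scale (Lawless) likelihood equations
  in $(\mu, \sigma, k)$: $\sigma = 1/(p\sqrt\nu)$,
  $\mu = \log a + \log(\nu)/p$, $k = \nu$. Each cycle solves
  $\log k - \Psi(k) = L/\sqrt k$ (root in $(1/(4L^2), 1/L^2)$), then the
  monotone scale equation
  $S_1/S_0 - \bar y - \sigma/\sqrt k = 0$ with
  $S_j = \frac1n\sum_i y_i^j e^{y_i/(\sigma\sqrt k)}$ (root in
  $(0, \sqrt k\,(y_{\max}-\bar y))$, evaluated with a max-shift so small
  $\sigma$ cannot overflow), then $\mu = \sigma\sqrt k \log S_0$. The
  plain alternation converges only linearly (we measured a contraction
  rate near 0.87, i.e. well over 100 cycles to an absolute tolerance of
  $10^{-8}$), so each outer iteration applies the cycle twice and an
  Aitken $\Delta^2$ extrapolation on $(\log k, \log\sigma)$; the
  extrapolated point is accepted only when it does not decrease the
  likelihood, which both restores fast convergence and guards against
  extrapolating into the map's slow-drift region far from the optimum.
  The equations being solved are unchanged.

## Mixture models

Tissues mix speckle regimes, so the package fits $J$-component GG
mixtures by EM (`fit_mixture()`). The E-step (`e_step()`) is Bayes' rule
computed with a log-sum-exp guard (no NaN responsibilities even under
total underflow); weights update as responsibility means. Two M-step
variants mirror the two single-sample ML routes:

* **GGMM1** (`m_step_ggmm1()`): per component, Nelder–Mead over
  $\log p_j$ with $\hat a_j$ and $\hat\nu_j$ profiled out through the
  responsibility-weighted analogues of the shape equation (weighted
  $A_j = \log(\sum_i \gamma_{ij} x_i^{p_j}/\sum_i\gamma_{ij}) -
  \sum_i \gamma_{ij}\log x_i^{p_j}/\sum_i\gamma_{ij}$, Brent in
  $(1/(2A_j), 1/A_j)$) and
  $\hat a_j^{p_j} = \sum_i\gamma_{ij}x_i^{p_j}/(\nu_j\sum_i\gamma_{ij})$.
  The inner maximization is run to its own tolerance at every EM
  iteration (warm-started at the current $p_j$), rather than as a single
  ascent step; with a full inner solve the M-step is exact and the EM
  ascent property is clean.
* **GGMM2** (`m_step_ggmm2()`): the weighted Lawless alternation —
  $k_j$ from the weighted shape equation, $\sigma_j$ from the weighted
  scale equation (root bracketed in
  $(0, \sqrt{k_j}(y_{\max}-\bar y_w))$), iterated with the same
  likelihood-guarded Aitken acceleration as the single-sample version.

Constrained variants pin $p_j = 1$ (Gamma mixture), $p_j = 2$ (Nakagami
mixture) or $p_j = 2, \nu_j = 1$ (Rayleigh mixture) and skip the
corresponding updates; with $J = 1$ every variant reduces exactly to its
single-component estimator (the package special-cases $J = 1$ so the
reduction is an identity, not merely a numerical agreement).

Design choices where the procedure was genuinely open:

* **Initialization.** Sorted samples are split into $J$ quantile groups,
  each fitted singly, with equal starting weights. Restarts (after a
  component collapse, i.e. responsibility mass below 2 samples) jitter
  the initial parameters multiplicatively under the run's seed, at most
  3 times.
* **Label identifiability.** Components are always reported sorted by
  their mean $a\,\Gamma(\nu + 1/p)/\Gamma(\nu)$, ties broken by $\nu$.
* **Degeneracy on quantized images.** 8-bit pixel data are discrete, and
  a continuous mixture can drive its likelihood to a spike by shrinking
  one component onto a quantization atom (we observed $\nu \to 10^{-9}$,
  $p \to 10^9$ on a phantom, with a catastrophic CDF fit). The component
  log-scale width $\sigma_j = 1/(p_j\sqrt{\nu_j})$ is therefore floored
  at `sigma_min = 0.01` — roughly the 8-bit quantization width on the
  log scale — implemented as a constrained M-step (the weighted
  likelihood is unimodal in $\nu$, so the constrained maximum sits on
  the boundary and EM monotonicity is preserved). The component power
  shape is likewise confined to $[0.05, 100]$: below the lower bound the
  component is a lognormal-limit shape whose Stacy scale
  $a = \exp(\mu - \log\nu/p)$ leaves double-precision range, above it
  nothing an envelope image can express. Both bounds are inactive on
  continuous data; set `sigma_min = 0` to disable the floor. For fitting
  quantized images directly, `phantom_samples(..., dither = TRUE)`
  additionally dequantizes integer intensities with uniform
  $(-0.5, 0.5)$ jitter — the honest continuous-density treatment of
  8-bit data, used by the command-line `mix` front end.
* **Stopping.** Absolute change of the data log-likelihood below `tol`
  ($10^{-8}$ by default) or `max_iter` (100) iterations, whichever comes
  first; the full `loglik_trace` is returned and its monotonicity (slack
  $10^{-8}$) is asserted in the tests for all five variants. On strongly
  overlapping mixtures the GG mixture likelihood has a long, weakly
  identified ridge and EM approaches its plateau sublinearly; the
  package's own validation studies therefore run the EM with
  `max_iter = 400`, the budget at which the two M-step variants agree in
  final log-likelihood to well within $10^{-4}N$ on the two-component
  study.

## Synthetic data

`simulate_gg_experiment()` reproduces the estimator-validation protocol:
$a = 1$ (scale only rescales the data), $\nu, p$ drawn uniformly from
$[0.3, 5]$ — smaller shapes give densities unbounded at the origin or
unrealistically heavy tails for envelope data — and GG samples generated
by the Gamma-power construction ($\Gamma(\nu)$ variates raised to $1/p$),
the same path used by `gg_sample()`, so the simulator and the estimators
share no inverse-CDF shortcuts. The acceptance suite runs 50 replicates
of $n = 10^4$ (and $n = 500$ for the small-sample study); these sizes
keep the full suite to a few minutes while leaving Monte-Carlo errors an
order of magnitude below the effects being asserted.

`render_phantom()` builds B-mode phantoms from the random-walk scatterer
model: at each polar sample site the envelope is the modulus of a
complex phasor sum — `N` scatterers with Normal amplitudes
($\sigma = 8$ by default) and uniform phases, plus the local
echogenicity as a deterministic (specular) real component. The carrier
is not simulated: under the quadrature decomposition it drops out of the
envelope. The fan geometry (50 angular × 100 radial sites by default)
is inscribed in the image so every site lies inside; the Cartesian
rearrangement is bilinear interpolation on the structured $(r, \theta)$
grid, with out-of-fan pixels set to 0 and excluded from fitting
(`phantom_samples()` floors residual zeros to the smallest positive
intensity). Each site gets an independent phasor sum — the resolution-
cell footprint is not modeled. The built-in scenes are an echogenicity
ramp (0→255 left to right, constant $N = 20$: fully formed → fully
resolved speckle, with clipping at 255 reported as `clip_fraction`) and
a scatterer-density ramp ($N$: 256→1, zero specular component). What the
phantoms do *not* emulate: point-spread functions, attenuation,
log-compression, and spatial correlation of real scanners — so passing
phantom tests demonstrates the statistical machinery, not equivalence to
clinical data.

## Goodness of fit

`kl_divergence()` is the histogram Kullback–Leibler divergence on 150
equal-width bins spanning the sample range, with model bin probabilities
taken as CDF differences; a zero model probability on an occupied bin
yields `Inf` explicitly rather than a silent floor. `ks_statistic()` is
the exact sup-norm distance evaluated at the sorted sample points; it
needs no histogram and is the preferred score at small $n$.
`compare_families()` fits Exponential, Rayleigh, Weibull, Normal,
Nakagami, Gamma and GG (each by ML — the nested families via their
constrained GG profiles, the Normal directly) and ranks them by
$D_{KS}$; `welch_t_test()` (closed form, Welch–Satterthwaite df,
verified against `stats::t.test`) supports replicate-level comparisons.

## Posterior-map applications

`posterior_map()` evaluates per-pixel Bayes posteriors of tissue class
under a fitted mixture (zero pixels floored to the smallest positive
intensity and flagged). Three consumers:

* **POSRAD** (`posrad_filter()`): per class, the structure tensor
  $T_j = G_\sigma * (\nabla_\sigma p_j \nabla_\sigma p_j^{T})$
  (one shared scale $\sigma$, default 1.5 px, for both smoothings — the
  two-scale generalization is not exposed). At each pixel the class with
  maximal leading eigenvalue supplies the eigenbasis; diffusivities are
  $\lambda_1 = 1 - \|\nabla_{e_1,\sigma}p\|^2$ clamped to $[0,1]$ across
  the most probable boundary and $\lambda_2 = 1$ along it, so a flat
  probability field gives the identity tensor and plain heat diffusion.
  The PDE is advanced by an explicit finite-volume scheme (interface
  fluxes, central cross-derivatives, zero-flux boundaries) with
  `dt = 0.2` — inside the 0.25 stability bound of the 2-D explicit
  scheme — chosen because the finite-volume form conserves total
  intensity exactly, which the tests assert to $10^{-6}$ relative over
  40 iterations.
* **LBP** (`lbp_coherence()`): min-sum belief propagation on the
  4-connected grid, synchronous schedule, damping 0.5, 30 sweeps by
  default; convergence is not guaranteed on a cyclic graph, so the final
  message change is reported rather than enforced. The default pairwise
  cost charges each neighbor the negative log-posterior, at its own
  pixel, of the center's label — a data-driven smoothness cost under
  which the energy decomposes per node and min-sum is exact (the test
  suite checks it against exhaustive enumeration on a 4×4 grid). A
  standard Potts penalty is available behind `pairwise = "potts"`; the
  energy sums over directed neighbor pairs, so each undirected edge
  effectively carries twice the nominal weight, and the messages account
  for that factor.
* **Classification** (`classify_max_posterior()`): per-pixel argmax with
  ties resolved toward the lower-mean class.

## Numerical conventions

All densities and weighted moments are computed in log-space; ratios of
exponential moment sums use a max-shift so $\sigma \to 0$ cannot
overflow. Brent brackets are expanded 1% against endpoint round-off.
Root tolerances are $10^{-12}$ for scalar solves, $10^{-8}$ for outer
likelihood convergence, matching the protocol the estimators are
validated under. Sampling is reproducible given a seed, and the mixture
fitter derives its restart jitter from the run's seed.

## Known limitations

* K and homodyned-K envelope laws are out of scope (no closed-form
  density for the latter); the GG covers their practical regimes only
  approximately.
* Model order $J$ is user-supplied; no BIC/AIC selection.
* The phantom simulator omits RF-level acoustics (PSF, attenuation),
  so it validates estimators, not scanners.
* Wall-clock complexity: each EM iteration costs $J$ single-component
  solves; GGMM2's inner alternation is the slower of the two M-steps
  despite the acceleration.
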