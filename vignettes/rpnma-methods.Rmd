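---
title: "One-step Bayesian network meta-analysis of survival data with spline baselines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-step Bayesian network meta-analysis of survival data with spline baselines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`rpnma` fits a one-step Bayesian (network) meta-analysis of individual
participant right-censored time-to-event data. Each trial $j$ keeps its own
baseline, modelled on the log cumulative hazard scale as a restricted cubic
spline (RCS) in log time — the flexible parametric (Royston-Parmar) form:

$$
\ln H_j(t \mid x_i) \;=\; s_j(\ln t_i) + \beta_1\,\mathrm{trt}_{1i} + \dots +
\beta_q\,\mathrm{trt}_{qi},
$$

where $s_j(\ln t) = \gamma_{1j} + \gamma_{2j} u_0(\ln t) + \dots +
\gamma_{(p+2)j} u_p(\ln t)$ is the spline with $p$ interior knots and
$\mathrm{trt}_{ki} \in \{-1, 0, 1\}$ are treatment-contrast variables coding
the network's $q$ basic comparisons. Contrasts for arms not compared
directly with the network reference are built from the consistency
equations (for treatments $A, B, C$: $\mu_{BC} = \mu_{AC} - \mu_{AB}$), so
a patient on the non-reference arm of a loop-closing design carries a $-1$
and a $+1$ on the two basic contrasts that route through the loop's apex.

The likelihood is evaluated exactly, per patient, on the log-time scale:

$$
\log \ell_i \;=\;
\begin{cases}
\log\!\big(\eta_i'\big) + \eta_i - e^{\eta_i} & \text{event}\\[2pt]
-\,e^{\eta_i} & \text{censored,}
\end{cases}
$$

with $\eta_i$ the linear predictor above and $\eta_i'$ its derivative with
respect to $\ln t$. The derivative must be positive at every event time for
the density to exist; states violating this return $-\infty$ and are
rejected by the sampler rather than being excluded by reparameterisation.
(An equivalent formulation via the Poisson "zeros trick" is common in
general-purpose Gibbs software; evaluating the likelihood natively is exact
and faster, and the equivalence is retained as a unit test.)

Model variants:

* **Random treatment effects (RTE).** Trial-specific effect vectors
  $\beta_j \sim \mathrm{MVN}(\mu, T)$ with unstructured between-study
  covariance $T$. The fixed-effect model (FTE) is the $T \to 0$ limit.
* **Treatment-ln(time) interactions.** Adding
  $\alpha_k\,\mathrm{trt}_{ki}\ln t_i$ terms relaxes proportional hazards
  (PH); testing $\alpha = 0$ is a *global* non-PH test. Optionally a
  trial-level random deviation $u_j \sim N(0, \sigma_u^2)$ is added to every
  interaction coefficient within trial $j$, whose posterior gives a
  shrinkage estimate of each trial's departure from PH.
* **Inconsistency.** For a three-treatment loop closed by a two-arm design,
  a fixed offset enters as $-\,\omega\,\mathrm{trt}_{a i}\mathrm{trt}_{b i}$
  with $a, b$ the two basic contrasts touched by the closing design. Because
  the product is nonzero only on the closing design's non-reference arm,
  $\omega$ measures the gap between that design's direct evidence and the
  indirect route through the loop apex. Loops must be edge-disjoint — each
  closing design may carry one inconsistency parameter; richer structures
  (node-splitting) are out of scope. Multiarm designs never activate the
  product coding: they are internally consistent by construction.

# Spline basis, knots, orthogonalisation

The raw RCS basis of $\ln t$ is the standard restricted-cubic form: the
linear column $x$ plus, for each interior knot $k_j$,

$$
v_j(x) = (x-k_j)_+^3 - \lambda_j (x-k_{\min})_+^3 -
(1-\lambda_j)(x-k_{\max})_+^3,\qquad
\lambda_j = \frac{k_{\max}-k_j}{k_{\max}-k_{\min}},
$$

which is twice continuously differentiable and exactly linear outside the
boundary knots. Boundary knots sit at the minimum and maximum *uncensored*
log times of the trial; interior knots default to centiles of the
uncensored log times ($\{50\}$, $\{33, 67\}$, $\{25, 50, 75\}$ for 1-3
knots, empirical quantiles with linear interpolation). Custom per-trial
knots are accepted on either the time or the log-time scale. Times are
never rescaled: everything is in the user's time unit, so knot locations
are unit-dependent by design.

Per trial, the basis evaluated at that trial's observation times (censored
included, since the likelihood needs the basis at every time) is
Gram-Schmidt orthogonalised against the intercept and each other — a QR
factorisation with the intercept first, rescaled so the intercept stays
$1$, with each orthogonal column's sign fixed by a positive inner product
with its raw source. The invertible transform from $[1, \text{raw}]$ to
$[1, \text{ortho}]$ is stored, so bases and their analytic derivatives can
be evaluated at new times and so a fit is invariant (to numerical
precision) to whether the raw or the orthogonalised basis is used:
orthogonalisation is purely a conditioning device. Ties in event times need
no correction in this fully parametric likelihood.

# Priors

Defaults follow weakly-informative convention for this model family:
$\gamma \sim N(0, 10000)$ (variance), fixed $\beta$ and interaction
coefficients $\sim N(0, 1000)$, $\omega \sim N(0, 10)$, $\sigma_u$
half-normal with variance $1000$, random-effect means
$\mu_k \sim N(0, 1000)$, and $T \sim \mathrm{InvWishart}(I_q, q)$ — the
smallest degrees of freedom giving a proper prior. One reading note: the
convention for the $\mu$ prior is stated in precision form (0.001) in the
literature this model family comes from; it is implemented here as variance
1000, matching the scale of the other treatment-effect priors. All prior
variances are user-overridable.

# Sampling, DIC, diagnostics

The posterior is sampled by adaptive blockwise random-walk Metropolis: one
block per trial for $\gamma_j$ (mirroring the trial-stratified baseline), a
global block for $\beta$ (or per-trial $\beta_j$ blocks with conjugate
Gibbs updates for $\mu$ and inverse-Wishart Gibbs updates for $T$), a
global interaction block, and scalar blocks for $u_j$, $\sigma_u$ and each
$\omega$. Proposal scales adapt toward a 0.3 acceptance rate during burn-in
only; after burn-in the scales are frozen so the stored chain targets the
exact posterior. Two chains are the default, the second started from a
jittered (overdispersed) version of the first chain's initial values;
initial $\gamma_j$ come from a least-squares fit of the Nelson-Aalen log
cumulative hazard on the trial's basis, pulled back toward that base point
if jittering leaves the likelihood's support. Any exact MCMC targeting this
posterior would be admissible; random-walk blocks were chosen for
robustness to the $\eta' \le 0$ support boundary, where gradients are
undefined.

Default settings are 2 chains with 20000 burn-in and 20000 stored
iterations (`mcmc_settings()`); `mcmc_desk()` (2000/2000) is the desk-scale
preset used by the command-line interface, and the test suite uses smaller
presets still (hundreds to a few thousand iterations on datasets of a few
hundred to ~1500 patients) so that the full suite runs in minutes.

Model comparison uses the deviance information criterion with
$D(\theta) = -2\log\text{likelihood}$: $\mathrm{DIC} = \bar D + p_D$,
$p_D = \bar D - D(\bar\theta)$. A negative $p_D$ (possible when the
posterior mean fits worse than a typical draw) is flagged, not an error.
Convergence reporting uses split-chain potential scale reduction with a
1.05 flag threshold (the model family's literature reports visual checks
only; 1.05 is this package's own default) and an initial-positive-sequence
effective sample size.

# Analysis layer

* **Pairwise meta-analysis** (`fit_pairwise_ma`): the same one-step model
  restricted to a single two-treatment design; adding interactions gives
  the per-comparison global non-PH test.
* **Global Wald tests** (`wald_global_nonph`): $W = \hat m^\top \hat
  V^{-1} \hat m$ with $\hat m, \hat V$ the posterior mean and covariance of
  the interaction block, compared to $\chi^2_{df}$ with $df$ = number of
  tested parameters; $\sigma_u$ counts as one parameter when included
  (testing a variance at its zero boundary is conservative, which is
  accepted and documented rather than corrected).
* **Direct/indirect separation** (`separate_direct_indirect`): from the
  $\omega$-augmented fit, each loop comparison's direct and indirect
  estimates are computed per draw (direct $\pm\ \omega$ per the loop
  orientation), alongside network estimates from the $\omega$-free fit —
  computed per-draw, never by differencing posterior summaries, so
  correlations are preserved.
* **Q decomposition** (`q_decomposition`): with per-trial estimates
  $\hat\theta_{ij}$ (variance $\hat\sigma_{ij}^2$), design-level
  inverse-variance pools $\hat\theta_j$ (pooled variance
  $\hat\sigma_j^2 = 1/\sum_i \hat\sigma_{ij}^{-2}$) and network estimates
  $\hat\theta_{Nj}$:
  $Q = \sum_j\sum_i (\hat\theta_{ij}-\hat\theta_{Nj})^2/\hat\sigma_{ij}^2$,
  $Q^{inc} = \sum_j (\hat\theta_j-\hat\theta_{Nj})^2/\hat\sigma_j^2$,
  $Q^{het} = \sum_j\sum_i (\hat\theta_{ij}-\hat\theta_j)^2/\hat\sigma_{ij}^2$.
  The pooled-variance choice for $\hat\sigma_j^2$ is what makes
  $Q = Q^{inc} + Q^{het}$ an exact algebraic identity, which the tests
  verify to $10^{-10}$. Degrees of freedom: $\sum_j (n_j - 1)$ within,
  $D - q^*$ between, with $q^*$ the rank of the designs' contrast matrix.
  Per-trial inputs default to frequentist Cox fits (Breslow ties) — the
  cheap, standard estimator, consistent with the model under PH; per-trial
  flexible-parametric estimates can be substituted. Multiarm trials enter
  through their constituent contrasts, one stratum per comparison,
  ignoring their within-trial correlation (the exact multiarm matrix
  decomposition is not implemented); this slightly misallocates Q between
  strata for multiarm-heavy networks.
* **Ranking** (`rank_treatments`): per draw, treatments are ranked by
  their effect versus the common reference (smallest log hazard ratio =
  rank 1 = most effective) and tallied as percentages; rows and columns of
  the resulting table each sum to 100%.

# Screening diagnostics

Before modelling, each trial is screened with a Cox fit (Breslow ties) and
a Schoenfeld-residual test against the ln(t) time transform — chosen to
align the screen with the model's linear-in-ln(t) interaction alternative; a
Kaplan-Meier-rank transform is available by flag. Because trials are
independent, the per-trial $\chi^2_1$ statistics add into a pooled screen
on (number of trials) degrees of freedom. Spline fit quality is checked by
overlaying the fitted log cumulative hazard's posterior band on the
nonparametric Nelson-Aalen estimate at its step times (times beyond the
boundary knots use the spline's linear tails), and by comparing candidate
knot counts per trial via DIC and band coverage.

# Synthetic data generator

Because patient-level oncology network data are rarely shareable, the test
bed is simulated. `sim_spec()`/`simulate_network()` draw, per trial,
effect vectors $\beta_j \sim \mathrm{MVN}(\beta, T_{true})$, and per
patient invert $H(t) = -\ln U$ where
$H(t) = H_{0j}(t)\, e^{c^\top\beta_j + \delta}\, t^{c^\top\alpha}$ —
non-PH drift applied on the cumulative-hazard scale *exactly as the fitted
model assumes*, so recovery of $\alpha$ is a sharp test with no
approximation bias. Weibull baselines invert in closed form; explicit
spline baselines by bracketed bisection on $\ln t$ (tolerance $10^{-10}$;
the cumulative hazard is monotone, so bisection is unconditionally safe).
Censoring is the minimum of an administrative horizon and exponential
dropout; it is non-informative by construction. Per-trial random substreams
derive deterministically from one global seed.

`default_cervical_like_spec()` is the default study shape: 4 treatments
(RT, CTRT, CT+RT, CT+S), three pairwise designs against RT plus a two-arm
CT+RT vs CT+S design closing one loop, trial counts 6/5/3/1 (a scaled-down
version of a real chemoradiotherapy network's 18/16/5/2 shape, with the
multiarm design replaced by the two-arm loop-closer so the inconsistency
parameterisation applies), ~1500 patients, true log hazard ratios
$(-0.2, 0.1, -0.4)$ for CTRT, CT+RT, CT+S versus RT, Weibull baselines with
rates 0.12-0.3 and shapes 0.9-1.3, a 5-unit administrative horizon and
0.02 dropout rate — magnitudes typical of multi-year oncology follow-up.
These defaults are the package's fixed study conditions; they were chosen
once, on the scale of the motivating application, and the acceptance checks
run against them unchanged.

What the generator does *not* emulate: patient covariates and
treatment-covariate interactions, informative censoring, staggered accrual
or calendar-time effects, and reporting artefacts of real trial data. Tests
passing on this generator therefore demonstrate correctness of the
estimation machinery under the model's own assumptions, not robustness to
real-data violations of them.

# Numerical choices and limitations

* Hazard positivity is enforced softly ($-\infty$ likelihood) rather than
  by constraining $\gamma$; samplers reject, optimisers must start inside
  the support.
* Orthogonality of the basis is verified to $10^{-8}$ relative; the
  raw-vs-orthogonal fit invariance to $10^{-6}$ (likelihood optima; priors
  are parameterisation-dependent in principle, but at variance $10^4$ the
  difference is far below this tolerance).
* Interior knots equal to a boundary knot, duplicate knots, or fewer
  distinct uncensored times than knots $+2$ are errors, as is a basis made
  singular by degenerate times.
* Problem sizes in the test-suite and acceptance runs: recovery checks use
  15-trial, ~1500-patient networks with 2 chains of 2000/2000 iterations
  over 50 replicates; calibration checks use 4-6 trial networks of 60-300
  patients per arm over 200 replicates with shorter chains. These sizes
  were chosen as the smallest at which the binomial tolerance bands around
  nominal rates are informative.
* No aggregate-data synthesis, no left truncation, no time-dependent
  covariates, no node-splitting, no SUCRA curves, no
  maximum-likelihood/variational fitting path.
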