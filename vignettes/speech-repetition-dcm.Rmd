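---
title: "Dynamic causal modelling of auditory speech repetition: model, inversion and degeneracy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic causal modelling of auditory speech repetition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repdcm)
```

## The model

`repdcm` analyses effective connectivity — directed causal influence,
expressed as rate constants in Hz — among four left-hemisphere regions
engaged by auditory speech repetition: primary auditory cortex (A1), the
posterior superior temporal sulcus (pSTS, a Wernicke-area proxy), the pars
opercularis (pOp, a Broca-area proxy, dorsal or ventral subdivision) and
primary motor cortex (M1, face or tongue-and-larynx subdivision).

### Neural dynamics

The neural state equation is the deterministic linear system

$$\dot{x} = A x + C u,$$

where $x$ is the 4-vector of regional neuronal activity, $u$ a box-car
driving input entering A1 only, $C$ the input gain, and $A$ the effective
connectivity matrix. Every ordered pair of regions is connected except
A1 → M1 (auditory input does not project monosynaptically to motor cortex),
giving 15 connections of which 4 are self-connections. There is no bilinear
(input-dependent modulation) term: each task run is modelled by its own
average connectivity, and word and pseudoword runs are estimated and
aggregated entirely separately.

Self-connections are parameterised as $-0.5\,e^{s_i}$ Hz with $s_i$ a
dimensionless log-scaling. At the prior mean ($s_i = 0$) every region decays
at $-0.5$ Hz, which precludes run-away excitation; a *positive* estimate
means *greater* self-inhibition. Off-diagonal rates are estimated directly
in Hz.

The neural system is integrated exactly: on each microtime bin (default 16
bins per TR) the input is constant, so
$x_{k+1} = e^{A\,\Delta t} x_k + A^{-1}(e^{A\,\Delta t} - I)\,C\,u_k$.
The propagator is computed once per evaluation; tests verify agreement with
a 100-fold-finer Runge–Kutta integration to below $10^{-6}$.

### Hemodynamics

Neuronal activity drives the balloon–Windkessel observation model per
region: vasodilatory signal $s$, inflow $f$, venous volume $v$ and
deoxyhemoglobin content $q$,

$$\dot s = x - \kappa s - \gamma (f - 1), \quad \dot f = s, \quad
\tau \dot v = f - v^{1/\alpha}, \quad
\tau \dot q = f\,\frac{1 - (1 - E_0)^{1/f}}{E_0} - v^{1/\alpha}\frac{q}{v},$$

with BOLD signal
$y = V_0\,[k_1 (1 - q) + k_2 (1 - q/v) + k_3 (1 - v)]$. Constants are fixed
at standard 3 T values for a 30 ms echo time: $\kappa_0 = 0.64\,s^{-1}$,
$\gamma = 0.32\,s^{-1}$, $\tau_0 = 2.0$ s, $\alpha = 0.32$, $E_0 = 0.4$,
$V_0 = 0.04$, $k_1 = 4.3\,\nu_0 E_0\,TE$ ($\nu_0 = 40.3\,s^{-1}$),
$k_2 = \varepsilon r_0 E_0\,TE$ ($r_0 = 25\,s^{-1}$, $\varepsilon = 1$),
$k_3 = 1 - \varepsilon$. Only per-region log-scalings of the decay
($\kappa$) and transit ($\tau$) rates are estimated, with tight priors
(variance 1/64). The hemodynamic ODEs are integrated by RK4 on the microtime
grid; at the resting fixed point $(s,f,v,q) = (0,1,1,1)$ the predicted BOLD
is identically zero.

The prediction is sampled at the end of each TR and mean-centred per region
— the only confound handling applied, since the synthetic data contain no
drift. The repetition time is taken as 3.085 s (it is also printed as
3080 ms in the source acquisition protocol; the difference is immaterial and
the value is an argument of `make_design()`).

## Subject-level inversion: variational Laplace

`fit_dcm()` maximises a free-energy bound on the log evidence under a
Gaussian fixed-form posterior: $F = \text{accuracy} - \text{complexity}$,
where accuracy is the expected log-likelihood of the residuals (including
the Jacobian-propagated posterior-variance correction) and complexity is the
closed-form KL divergence of the parameter posterior from its prior plus the
KL of the noise log-precisions from their hyperprior.

Priors (all means zero): extrinsic rates variance 0.25 (sd 0.5 Hz, placing
over 95% of prior mass in the ±1 Hz range), self log-scalings 1/16, input
gain 1, hemodynamic log-scalings 1/64. Noise is i.i.d. Gaussian per region
with one log-precision $\lambda_r$ each, hyperprior $N(0, 1/8)$; serial
correlations are not modelled, matching the white noise of the generator.

Numerical scheme:

* Jacobian of the forward model by central finite differences with step
  $10^{-3}\max(1, |\theta_i|)$.
* Levenberg–Marquardt ascent: damping starts at 1/8, doubles on a rejected
  step, halves on an accepted one; a candidate is accepted only if its fully
  re-evaluated free energy increases, so the accepted-step trace is
  non-decreasing by construction.
* Noise log-precisions are updated by damped Newton steps interleaved with
  the covariance update (three alternations per evaluation).
* Convergence: four consecutive accepted steps each gaining less than
  0.01 nats, within a budget of 64 iterations; non-convergence returns the
  current estimate with a warning.
* On a linear forward model the fixed point coincides with the conjugate
  Gaussian posterior and the free energy equals the exact log marginal
  likelihood; the test suite asserts both to $10^{-6}$ relative error.

**Data scaling.** Each run is scaled by a single pooled factor to standard
deviation 4 (the conventional "percent signal"-sized amplitude), applied
identically to data and model prediction so parameter estimates are
unaffected. This choice makes the residual variance of a typical run at the
study's 25% noise level close to 1, the centre of the noise hyperprior;
scaling to unit amplitude instead biases the log-precision downward by the
hyperprior pull and measurably over-shrinks strong connections.

## Model space and Bayesian model reduction

The evidence for any model whose prior is a shrunk version of the fitted
prior follows in closed form from the identity that the evidence ratio
equals the prior ratio times the posterior ratio at any parameter value.
`score_model_space()` applies this over all on/off combinations of the
switchable connections, converts evidence changes to model probabilities by
softmax under uniform model priors, and aggregates per-connection presence
probabilities (Pp) and Bayesian-model-averaged means.

The switchable set defaults to the 8 extrinsic connections excluding the
three afferents *to* A1 and all self-connections, reproducing the 256-model
space of the original analysis. The source analysis never lists its 8 on/off
families explicitly, so this reconstruction — the only one of the natural
choices that yields $2^8$ — is flagged as an assumption and is configurable
through `network_spec(switchable = ...)`. Switched-off connections get prior
mean 0 and variance $10^{-8}$ (exact zeros would break the determinants).
Reduced evidences agree with full refits of the reduced model within about a
nat on synthetic runs (BMR is approximate when posteriors shift; the test
suite documents the 1-nat tolerance).

## Group level: parametric empirical Bayes

`fit_peb()` places a linear-Gaussian hierarchy over subject posteriors,
$\theta_i = X_i \beta + \varepsilon_i$, $\varepsilon_i \sim N(0, \Sigma_b)$,
over the 16 connectivity parameters (hemodynamic scalings stay first-level).
Each subject's contribution is re-weighted from its original prior to the
empirical prior $N(X_i\beta, \Sigma_b)$ by the same reduction identity,
which makes the $\beta$ posterior closed-form for fixed $\Sigma_b$. The
between-subject covariance is a single log-scaling $\gamma_b$ of a base
matrix (the first-level prior covariance divided by 16), optimised on a grid
from −4 to 4 with a 0.05-step local refinement; the design matrix defaults
to the group mean. The group-effect prior inherits the first-level prior,
per empirical-Bayes convention. `peb_model_search()` then runs the 256-model
search on the group effects.

## Degeneracy taxonomy

Each fitted model is classified by the presence of *significant excitatory*
motor afferents — model-averaged posterior mean > 0 **and** Pp strictly
greater than 0.75:

* **A** — both pOp→M1 and pSTS→M1 excitatory;
* **B** — pSTS→M1 only; **C** — pOp→M1 only; **D** — neither
  (definite inhibitory afferents also fall in D, since the taxonomy keys on
  excitation).

Whether the excitatory criterion should use model-averaged or full-model
means is not fixed by the source analysis; the default is model-averaged
(`use = "bma"`), configurable. A model is consistent with the classical
serial "neurological model" (pSTS → pOp → M1) iff it is in group C with an
excitatory pSTS→pOp connection. Within-subject variability is summarised as
the Shannon entropy (nats) of a subject's group-membership frequencies over
the four configurations, per task (an across-task variant exists but is off
by default); task differences in group counts use two-sided
Mann–Whitney–Wilcoxon tests with Bonferroni correction across the four
groups.

## The synthetic cohort

`simulate_cohort()` emulates the study design: per run, 40 stimuli in 4
blocks of 25 s separated by 16 s of rest, TR 3.085 s, 66 volumes (3.4 min).
Because the stated block and rest durations sum to less than the run, the
generator inserts a 16 s lead-in rest and leaves the remainder as trailing
rest. Each subject × task draws an archetype from a mixture (default 0.55 A,
0.2 B, 0.05 C, 0.2 D, close to the reported cohort composition); base
connectivity uses the group-level word-repetition estimates (e.g. A1→pSTS
0.51, pSTS→M1 0.66, pOp→M1 0.31, inhibitory pSTS↔pOp and M1 feedback), with
archetype-absent afferents exactly zero. Between-subject variation adds
Gaussian deviations (sd 0.2 Hz — the scale used for the group-level planted
effect) to the archetype-present connections, and per-configuration jitter
(sd 0.1 Hz) perturbs them again, deliberately placing some models near the
excitatory threshold so cohorts show nonzero membership entropy by
construction. Measurement noise is white Gaussian at 25% of each region's
signal sd. Draws that destabilise the dynamics are resampled (bounded
retries). Everything is deterministic given the cohort seed, and the
caller's RNG state is restored.

What the generator does *not* emulate: physiological (serially correlated)
noise, scanner drift, motion, regional hemodynamic variability beyond the
two log-scalings, and behavioural variation. Passing tests therefore show
correctness of the estimation machinery under the model's own assumptions,
not robustness to real-data artefacts.

## Problem sizes and tolerances

The test suite runs desk-scale problems chosen to exercise every stage: the
demonstration cohort is 12 subjects × 2 tasks × 4 configurations at 25%
noise (96 fits), the group-level planted-effect cohort is 12 subjects × 1
task, and the conjugate oracles use 25–30 observations with 2–3 parameters.
Matrix-exponential integration is checked against RK4 at $10^{-6}$,
reduction against exact conjugate evidence at $10^{-8}$, variational Laplace
against the conjugate posterior at $10^{-6}$ relative.

## Known limitations

* **Subject-level power for the motor afferents is intrinsically limited.**
  In a 66-volume block-design run the activities of pSTS and pOp are highly
  correlated (both are driven by A1 on the same slow input), so their
  afferents to M1 compete: posterior correlations near −0.65 and marginal
  sds above 0.3 Hz are typical, and pruning one afferent often costs less
  than a nat even when its true rate exceeds 0.5 Hz. Consequently a
  substantial fraction of archetype-A cells are classified B (or C) at the
  Pp > 0.75 criterion — on demonstration cohorts about a third of cells miss
  their planted archetype, with essentially no false positives in
  archetype-D cells. Truth-initialised optimisation reaches the same free
  energy, confirming this is an information limit of the design rather than
  an optimiser failure. It is also, precisely, the phenomenon the degeneracy
  analysis measures: many architecturally different models explain the same
  short run equally well.
* BMR assumes the posterior of the full model is adequate for all reduced
  models; for strongly shifted posteriors the 1-nat agreement with refits
  degrades.
* The noise model is white; applying the package to real ROI series with
  serial correlations would require pre-whitening upstream.
* The PEB between-subject covariance is a single scaled diagonal; per-field
  scalings are not estimated.
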