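---
title: "Race models of the antisaccade task: model, priors, inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Race models of the antisaccade task: model, priors, inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The behavioural problem

In a mixed antisaccade block a participant sees, on each trial, a cue
instructing either a saccade toward it (prosaccade trial) or away from it
(antisaccade trial).  Two quantities are observed per trial: the action
(pro or anti) and the reaction time (RT).  Error rates and RT
distributions — in particular the conspicuous mixture of fast and slow
prosaccades — carry information about two putative processes: a fast
reactive response that must be inhibited, and a slower voluntary
cue-action mapping.  `seriar` implements generative race models that make
this decomposition explicit and estimable from trial tables alone.

## Units, rates and arrival times

Every model is built from *units*: linear rise-to-threshold processes
with a stochastic increase rate $r > 0$ drawn fresh each trial.  Because
only arrival order and arrival time matter, the threshold is not
identifiable separately from the rate scale; we fix it to 1, so a unit's
arrival time is the reciprocal rate, $T = 1/r$.  Four rate families are
supported — gamma, inverse gamma, lognormal, and normal truncated to
$r>0$ — and all arrival-time quantities are derived from the rate density
through the change of variables $f_T(t) = f_R(1/t)\,t^{-2}$.  This single
convention keeps the rate table and the arrival-time table consistent by
construction (reciprocal-gamma arrival times for gamma rates, gamma
arrival times for inverse-gamma rates, and so on); closed forms for
density, CDF and moments are used throughout, so quadrature only ever
enters through one integral (below).

Internal time units are **deciseconds** (rates in 1/ds).  Millisecond
I/O is converted at the boundary, where a fixed 50 ms non-decision floor
is subtracted from every RT before modelling (`preprocess_trials()`);
this keeps the numerical scales of rates and times near 1.

## The three model structures

* **PROSA** — three units: pro ($U_p$), stop ($U_s$), anti ($U_a$).  The
  first arrival determines the action; if the stop unit beats the pro
  unit, the antisaccade unit's arrival produces an antisaccade.  Unit
  identity *is* the action.
* **SERIA** — early ($U_e$), inhibitory ($U_i$) and late ($U_l$) units
  determine *when* and *which class* of response occurs (early vs late),
  while separate probabilities $\pi_e$, $\pi_l$ map response class to
  action.  Both actions can therefore be early or late, and RT
  distributions can be bimodal.  The probability of an early antisaccade
  $1-\pi_e$ is fixed to $10^{-3}$ rather than estimated: early responses
  are treated as reactive prosaccades, with a sliver of mass protecting
  the likelihood from rare very fast antisaccades.
* **SERIA_lr** — replaces $\pi_l$ by a second race (GO/GO) between a
  late prosaccade unit $U_p$ and a late antisaccade unit $U_a$, making
  the late action time-dependent.  The early unit produces only
  prosaccades.

For, e.g., SERIA_lr prosaccade-action trials the density at decision
time $u$ is

$$p(\mathrm{pro}, u) = f_e(u)S_i(u)S_a(v)S_p(v) + f_p(v)S_a(v)\Big[S_e(u) + \int_0^u f_e(\tau)F_i(\tau)\,d\tau\Big],$$

with $v = u - \delta_a$ and $f$, $F$, $S$ arrival densities, CDFs and
survivals.  The bracket is the probability that no early response
occurred before $u$; it has two algebraically identical decompositions
(early survives, or early was beaten by inhibition), and we use the same
one in all three structures so that the PROSA = SERIA($\pi_e{=}1,
\pi_l{=}0$) nesting holds to numerical precision (tested at 1e-10).

**Delays.**  $\delta$ (non-decision time) shifts all responses;
$\delta_a$ delays late actions (in PROSA, the antisaccade unit), entering
every late density/survival as $u - \delta_a$.  **Outliers.**  Saccades
earlier than $\delta$ get probability mass $\eta$, uniform on
$[0,\delta]$ and split 100:1 pro:anti ("approximately 100 times" is
implemented as exactly 100:1); the race density is renormalized by
$1-\eta$.

## The single quadrature and its accuracy

The only integral without closed form is the inhibition term
$J(u) = \int_0^u f_e F_i$.  The compiled likelihood computes $J$
cumulatively over the sorted trial times with Gauss–Legendre panels of
bounded width (0.2 ds), using 15 nodes per panel for density evaluation
and 7 nodes (3 on panels narrower than 0.05 ds) in the sampler's hot
path.  A pure-R reference implementation using adaptive quadrature
(`stats::integrate`, tolerance 1e-10) is exported via
`trial_density(..., method = "reference")` and the two paths are held to
1e-8 agreement in the tests; total probability mass
$\sum_A \int p(A,t)\,dt = 1$ is verified to 1e-4 over random prior
draws for all three structures.

## Model space and priors

`model_registry()` enumerates 30 models: the 3 structures × 5 rate
configurations (all inverse gamma; all gamma; gamma early/inhibitory
with inverse-gamma late; all lognormal; all truncated normal), each full
(per-trial-type unit parameters) or constrained (early/inhibitory — in
PROSA, the pro unit — tied across trial types), giving the conventional
counts 15/13, 19/13 and 19/15.

Sampling is performed in an unconstrained space: log unit-rate means and
variances, log $\delta$, $\delta_a$, and logits of $\eta$ and $\pi_l$.
Priors (see `default_prior()`): the log rate mean is
$N(-1.08, 0.97)$ and the log rate variance $N(-2.64, 0.69)$ (second
parameter a variance), giving prior expectations 0.55 and 0.1 with
variances 0.5 and 0.01 on the natural scale; $\ln\delta \sim
N(-1.58, 1.79)$ and $\ln\delta_a \sim N(-0.87, 1.17)$ (expectations 0.5
and 0.75 ds); $\eta, \pi_l \sim$ Beta(0.5, 0.5) (Jeffreys), with the
logit Jacobian applied.  Truncated-normal units are parametrized
natively: $\mu \sim N(0.55, 0.09)$ — 96% prior mass on positive
locations — plus the usual log-variance prior.  All but the truncated
normal share the same first two prior moments, so evidence comparisons
across rate families are calibrated.

**Moment existence.**  The parameter space is restricted so the first
two moments of rates and RTs exist wherever the restriction can bind:
gamma-rate units need shape $k = m^2/v > 2$, enforced through the prior
support.  SERIA_lr late units are exempt, deliberately allowing flat
late-rate distributions with infinite arrival mean (a unit that rarely
fires).  For inverse-gamma and lognormal rates the moments always exist;
for truncated-normal rates the arrival mean never exists (the rate
density is positive at 0, so $E[1/r]$ diverges logarithmically) — the
restriction cannot be enforced there, and `arrival_mean()` reports
`Inf`, with such draws excluded and counted in posterior summaries.

## Inference

`fit_model()` runs adaptive Metropolis–Hastings with parallel tempering:
by default 16 chains on the 5th-order schedule
$\beta_j = (j/15)^5$ (60 000/20 000 total/burn-in draws for
truncated-normal models, 41 000/16 000 otherwise).  The proposal scale
follows a vanishing Robbins–Monro recursion toward 23.4% acceptance and
the proposal covariance is re-estimated from the chain history every 100
burn-in iterations (frozen afterwards); adjacent chains attempt a
Metropolis swap sweep every 10 iterations.  Convergence is monitored by
the split potential-scale-reduction statistic on the target chain
(`gelman_rubin()`, threshold 1.1).

The log model evidence is computed by thermodynamic integration over the
schedule.  We use the variance-corrected trapezoid,
$\sum_j \tfrac{h_j}{2}(E_j + E_{j+1}) - \sum_j \tfrac{h_j^2}{12}(V_{j+1} - V_j)$,
where $E_j$ and $V_j$ are the posterior mean and variance of the
log-likelihood at $\beta_j$: because $dE/d\beta = V_\beta$, this removes
the leading discretization bias, which for the plain trapezoid on coarse
(8-point) schedules we measured at 0.07–0.28 nats on conjugate toys —
an order of magnitude above the corrected rule.  Since $E(\beta)$ is
nondecreasing, each segment's trapezoid error is bounded by
$\Delta\beta\,(E_{j+1}-E_j)/2$ and the correction is clamped there;
without the clamp the enormous log-likelihood variance of near-prior
chains can destabilize the correction on very coarse schedules.  The
evidence machinery is validated against closed-form evidences
(Beta–Bernoulli, conjugate Gaussian) to 0.05 nats at 8 temperatures ×
5 000 kept draws.

**Initialization** defaults to prior draws (retrying up to 100 times for
a finite likelihood).  The posterior has a known pathology at desk-scale
chain lengths: a spurious local mode trades a small non-decision time
against the outlier rate.  `init = "map"` therefore starts all chains at
a mode located by multi-start Nelder–Mead from the best prior draws;
this is what the package's own recovery study uses, and is recommended
whenever chains are much shorter than the reference settings.

Model comparison: `fixed_effects_posterior()` (softmax of summed LMEs),
`random_effects_bms()` (variational Dirichlet fixed point, uniform
$\alpha_0 = 1$, tolerance 1e-6), and `family_comparison()`, which
aggregates member evidences with an equal within-family prior
(log-sum-exp minus log family size) before the random-effects step.

## The simulator and what the tests do (and do not) show

`simulate_experiment()` draws each unit's rate, inverts to arrival
times, applies the race rules, delays and the outlier mechanism, and
emits both the observable schema (`rt_ms`, on the raw scale including
the fixed 50 ms) and latent columns (arrival times, response class).
Blocks use exact trial-type counts by default (e.g. 38 prosaccade cues
in a 192-trial block at 20%), mirroring the usual design; generator
defaults in the tests use gamma early/inhibitory and inverse-gamma late
units with arrival scales and an outlier rate (2%) typical of healthy
adults, $\delta = 50$ ms (on top of the fixed 50 ms) and
$\delta_a = 30$ ms.

Because the simulator implements exactly the generative structure the
likelihood integrates over, agreement between the two (KS distance
< 0.02 at $n = 10^5$, verified per structure) validates the *internal*
consistency of the implementation — not the model's adequacy for real
eyes.  Real data differ in ways the generator does not emulate:
measurement quantization at the tracker's sampling rate, within-block
nonstationarity (fatigue, learning), express-saccade peaks, and
trial-to-trial dependencies.  Passing tests therefore certify the
machinery, and the scaled-down recovery study (20 replications of
600-trial blocks; 95% credible intervals cover the generating
$\delta$, $\eta$ and late-antisaccade probability in ≥ 90% of runs)
certifies estimability at realistic block sizes — nothing more.

## Numerical choices and edge cases

* Zero-density trials are floored at 1e-300 before the log, keeping the
  sampler finite on outlier RTs under $\eta = 0$ draws.
* Late-unit terms vanish for $u \le \delta_a$ (`p(U < 0) = 0`), and
  their survivals are 1 there.
* `density_total_mass()` integrates from $\delta$ and adds $\eta$; it is
  the package's own normalization proof, not an assumption.
* The 110 ms lower RT bound for antisaccades is applied per *action* by
  default (the wording is ambiguous between trial and action scoping);
  `anti_min_by = "trial_type"` switches the scoping, and the exclusion
  audit attached to `preprocess_trials()` output always partitions the
  input rows.
* Summary point estimates are posterior means; arrival-time summaries
  report $E[U_i] + \delta$ (ms), while late *response times* add
  $\delta + \delta_a$ — the convention used when comparing late
  antisaccade response times with corrective antisaccades.
* Draws with non-existent arrival means are excluded from arrival
  summaries and reported as a fraction (`frac_infinite`).

## Scale of the shipped checks

The test suite runs everything at desk scale on one CPU: normalization
over 50 prior draws per structure, simulator oracles at $10^5$ trials,
evidence toys at 8 temperatures × 5 000 draws, and the recovery study at
4 chains × 2 700 iterations per replication.  These sizes are the
package's own verification choices; the reference settings above remain
the defaults for real fits.

## Known limitations

Lateral-inhibition variants and explicit rate/threshold decompositions
are out of scope; corrective saccades are predicted but not jointly
modelled; the outlier action split for simulated corrective saccades is
undefined (the mechanism never generates them); hierarchical
multi-subject priors are not provided — fits are per subject and
condition, with population structure handled post hoc by the
random-effects comparison.
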