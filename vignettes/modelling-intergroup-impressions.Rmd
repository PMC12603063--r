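---
title: "Modelling how intergroup experiences reshape expectancies, closeness and impressions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling how intergroup experiences reshape expectancies, closeness and impressions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intergroupRL)
```

## The problem

In intergroup learning tasks, a participant repeatedly interacts with
members of their own group (ingroup) and another group (outgroup) who
deliver monetary outcomes. The same objective payoffs can be framed as
gains (a partner gives 5 of 5 possible MU) or losses (a partner takes 5 of
a 10 MU endowment); the frames are mathematically equivalent, ending every
positive trial at 5 MU and every negative trial at 0 MU. On each trial the
participant rates their expectancy of a positive outcome and their social
closeness to both groups; impressions of both groups are measured before
and after the task. The scientific question is which learning signals —
in particular, prediction errors generated by unexpected ingroup or
outgroup behaviour — drive changes in closeness and, ultimately, in
intergroup impressions, and how ingroup identification moderates this.

`intergroupRL` implements the full modelling pipeline for such data:
schedule construction, the candidate learning and closeness models,
per-participant maximum-likelihood fitting, group-level model selection,
simulation-based validation, a synthetic study generator, and the
parameter-to-impression linkage analyses.

## The models

### Expectancy: Rescorla–Wagner learning

The latent value $V_i(t)$ of group $i$ is updated after each outcome
$R(t) \in \{0, 1\}$ delivered by that group:

$$V_i(t+1) = V_i(t) + \alpha_i\,\delta_i(t), \qquad
  \delta_i(t) = R(t) - V_i(t),$$

and the observed expectancy rating (normalised to $[0,1]$, a subjective
probability) is a linear read-out

$$\widehat{\text{rating}}_i(t) = \beta\, V_i(t),$$

computed *before* the trial's outcome. Three nested variants differ in the
learning-rate structure: **M1** a single $\alpha$; **M2** one $\alpha$ per
group; **M3** one $\alpha$ per group × prediction-error valence (four free
rates). The valence of $\delta$ selects the rate cell; a tie
($\delta = 0$) routes to the positive cell, which is inert but fixes
determinism. A group's value never changes on the other group's trials.

Each group's *first* observed rating serves as the initial value
$V_i(1)$. It is therefore a prior, not data: it is excluded from the
fitted residuals. This follows from the read-out equation — the first
prediction $\beta V_i(1)$ only reproduces the first rating when
$\beta = 1$, so treating that rating as data would penalise every
$\beta \neq 1$ for a datum the model is conditioned on.

### Closeness: discounted prediction-error integration

Trial-wise changes in closeness toward group $i$ (on the 0–10 scale,
defined as $\text{rating}(t{+}1) - \text{rating}(t)$ because closeness is
rated before the outcome) are a linear function of exponentially
discounted sums of that group's past prediction errors:

$$\Delta C_i(t) = W_0 + W \sum_{j \le t} \gamma^{\,t-j}\, \delta_{ij}
  \quad (\textbf{C1}), \qquad
  \Delta C_i(t) = W_0 + W_{pos} S^{+}_i(t) + W_{neg} S^{-}_i(t)
  \quad (\textbf{C2}),$$

where $S^{\pm}_i(t)$ are the discounted sums of the positive
($\max(\delta,0)$) and negative ($\min(\delta,0)$) parts. On trials where
group $i$ is not the partner, an additional prediction error of zero
enters: the running sums are still discounted by $\gamma$, so the clock
runs in absolute trial time, but the other group's outcome never leaks in.
At $\gamma = 0$ only the current trial's error matters; at $\gamma = 1$
all past errors weigh equally. The final trial's prediction error has no
observable consequence and is dropped from residuals.

Each group's closeness series is fitted separately with its own
parameters, so a participant contributes e.g. a `W_neg` for the ingroup
(`W_neg_in`) — the weight of unexpected negative ingroup behaviour —
which is the parameter the linkage analyses focus on. Although the
intercept $W_0$ is reported with the other three parameters, it is a
nuisance drift term; we fit all four ($W_0$, $W_{pos}$, $W_{neg}$,
$\gamma$), with bounds $W \in [-10, 10]$, $W_0 \in [0, 10]$,
$\gamma \in [0, 1]$.

## Parameters at a glance

| parameter | meaning | units / scale | bounds | default draw in simulations |
|---|---|---|---|---|
| $\alpha$ | learning rate per group×valence cell | proportion of PE integrated | $[0,1]$ | uniform $[0,1]$ (validation) |
| $\beta$ | response scaling of $V$ to ratings | rating units per value unit | $(0,3]$ | uniform $(0,3]$ (validation) |
| $V_i(1)$ | initial value | $[0,1]$ expectancy scale | $[0,1]$ | first observed rating |
| $W_0$ | closeness drift | rating steps per trial | $[0,10]$ | uniform (validation) |
| $W_{pos}, W_{neg}$ | PE weights on closeness | rating steps per unit discounted PE | $[-10,10]$ | uniform (validation) |
| $\gamma$ | decay of past PEs | per-trial discount | $[0,1]$ | uniform (validation) |

## Estimation

Parameters are fitted per participant by least squares under a Gaussian
observation model, which is the maximum-likelihood estimate: the Gaussian
log-likelihood is evaluated at the profiled noise variance
$\hat\sigma^2 = SSE/n$. Because $\hat\sigma^2$ is profiled identically for
every candidate model, the parameter count $k$ entering
$AIC = -2\ln L + 2k$ counts structural parameters only (2/3/5 for
M1/M2/M3; 3/4 for C1/C2).

The bounded parameter spaces make plain BFGS ill-posed at the edges, so
optimisation uses the bounded quasi-Newton variant (L-BFGS-B) with
multiple restarts drawn uniformly within the bounds from a seeded stream
(default 10). Restarts are drawn sequentially, so the attained SSE is
non-increasing in the restart count under a fixed seed. For the closeness
models the problem is linear in $(W_0, W_{pos}, W_{neg})$ given $\gamma$,
so the fit first profiles $\gamma$ on a 201-knot grid (ordinary least
squares at each knot, estimates projected into the bounds) and then
polishes jointly with L-BFGS-B; this makes the 1-D ridge in $\gamma$
robust to local minima. Degenerate inputs are flagged rather than thrown:
constant rating series warn (learning rate unidentifiable) and return a
flagged result.

Fit quality is summarised by the squared Pearson correlation between
observed and predicted series ($r^2$ stays positive under weak but
directionally correct fits; the $1 - SSE/SST$ definition is available as
an option) and by the mean squared error.

## Model selection

Per-participant AICs are converted to approximate log model evidence
($-AIC/2$; any convention differing by a participant-constant gives
identical results) and fed to the standard random-effects Bayesian model
selection scheme: a Dirichlet prior (uniform, $\alpha_0 = 1$) over
population model frequencies, variational updates of per-participant
model assignments to convergence, and the exceedance probability — the
posterior probability that a model is the most frequent in the population
— estimated from $10^6$ seeded Monte-Carlo draws of the posterior
Dirichlet. An XP above 0.95 is conventionally treated as decisive. A
fixed-effects summed-AIC ranking is reported alongside; ties within 0.01
XP mark the winner unresolved.

## Validation protocols

Two simulation protocols ship as first-class operations.

**Parameter recovery** (`run_parameter_recovery`): 100 simulated agents
on fresh 96-trial schedules, parameters drawn uniformly across the full
fitting bounds, refitted with the same estimation procedure; reports the
per-parameter Pearson correlation between generating and recovered
values. Expectancy observations are $\beta V$ plus Gaussian noise
(sd 0.15 on the $[0,1]$ scale by default), *unclipped*: with $\beta$ up
to 3 most predicted ratings would pin at the scale ceiling under
clipping, destroying the identifiability the protocol is meant to
measure; the unclipped Gaussian observation model matches the estimator's
likelihood. Closeness observations are the predicted trial-wise changes
plus Gaussian noise (sd 1.0 on the change scale), driven by prediction
errors from a known learning trajectory, exactly as the real pipeline
feeds the winning learning model's errors into the closeness fits.

Two corners of the parameter space are intrinsically weakly identified
under these noise levels, and recovery correlations reflect that
honestly: when $\beta$ is near 0 the ratings span a small fraction of the
scale and the four learning rates carry little signal, and when both
closeness weights are small relative to the change noise, $\gamma$ is
nearly irrelevant to the likelihood. We verified that in these corners
the optimiser still attains an SSE at or below the SSE of the generating
truth — the limits are informational, not numerical.

**Model identifiability** (`run_identifiability`): for each generating
model, 30 simulated agents are fitted with every candidate and the
group-level winner (summed AIC by default, XP optionally) is recorded;
repeated 10 times per generating model. A diagonal-dominant confusion
matrix shows the candidate models can be told apart under the task
design. These are also the problem sizes used by the package's own test
suite (100 recovery simulations per winning model; 30 × 10 identifiability
over M1–M3), chosen to match the protocols' standard configuration.

## The synthetic study generator

`sample_population` and `simulate_study` generate complete synthetic
datasets with the statistical structure the linkage analyses assume.
Questionnaire descriptives follow the two culture profiles (the
east-asian profile has higher mean identification, 5.75 vs 4.57, and a
larger initial ingroup bias; initial bias correlates with identification
at about $r = 0.25$). Generative model parameters are drawn from
realistic sub-ranges rather than the full fitting bounds: positive
learning rates exceed negative ones on average, and closeness weights are
sized so per-trial predicted changes are a visible fraction of the report
noise while cumulative prediction-error drives remain of the order of the
0–10 scale over 96 trials. Closeness ratings are noisy, scale-censored
reports of the latent integrated closeness state (report noise does not
accumulate into a random walk); agents with strong net drives do spend
stretches of the session at a scale bound, as human raters with extreme
attitudes would.

Impression change is *measured, not modelled*, in the source analyses, so
the generator defines a transparent synthetic convention: post-learning
impressions equal pre-learning impressions plus a frame-dependent
coupling (0.60 loss, 0.08 gain) times the *latent* net closeness change
(the attitude shift, of which the clipped rating is a censored readout),
attenuated linearly by ingroup identification, plus noise. The coupling
was calibrated once so that loss-frame populations of ~54 agents carry a
`W_neg_in`–impression-change association detectable at conventional
significance, with the identification moderation pattern in the expected
direction. Consequences: passing linkage tests show the analyses *detect
structure of that strength when it exists*; they say nothing about
whether real impression change is generated this way.
Features of real data the generator does not emulate include rating
discreteness (10-step scales are generated as continuous), sequential
rating dependencies beyond the modelled dynamics, missing data, and any
feedback from closeness to expectancy learning.

## Numerical choices

* Expectancy ratings are normalised to $[0,1]$
  (`normalize_expectancy` maps raw 1–10 ratings by $(x-1)/9$).
* $0^0 = 1$ in the discount weights, so the $\gamma = 0$ limit keeps
  exactly the current trial's error.
* The Gaussian log-likelihood floors $\hat\sigma^2$ at $10^{-12}$ so
  perfect fits stay finite.
* Zero prediction errors route to the positive-valence learning-rate
  cell (inert; determinism only).
* Stepwise selection uses conventional thresholds (entry $p = 0.05$,
  removal $p = 0.10$), ties broken by smaller p then lexical name;
  near-duplicate candidates ($|r| > 0.999$) are dropped with a warning.
* Influence diagnostics flag $|DFFITS| > 2\sqrt{k/n}$, Cook's
  $D > 4/n$, leverage $> 2k/n$, or any standardised $|DFBETA| > 1$, and
  report the refit excluding flagged cases whether or not significance
  survives. With these standard cutoffs, some observation is flagged in
  most clean datasets of moderate size — the tests therefore calibrate
  the flags against their definitions and against spike-in detection
  rather than against a "no flags on clean data" ideal.
* All stochastic operations take explicit integer seeds and are exactly
  reproducible; child simulation seeds are spawned inside the seeded
  stream and stay within 32-bit range.

## Design choices where the design was open

* **Single $\beta$ across groups.** The read-out equation indexes $V$ by
  group but carries one $\beta$; we fit one $\beta$ per participant and
  note the per-group alternative would add one parameter to every
  variant without changing the model ordering.
* **Exact 75% positive outcomes per group.** The positive rate is met
  exactly within each group condition per session (deterministic counts,
  permuted order), because equalised experiences with both groups are the
  point of the design; group identity is additionally balanced within
  block (12/12), outcomes only at session level. Configurations where the
  rate × per-group count is not an integer are rejected rather than
  rounded.
* **$r^2$ as squared correlation.** Reported fit quality stays positive
  under weak fits, matching how such values are conventionally reported;
  the $1-SSE/SST$ option is exposed.
* **First-trial ratings excluded from residuals** (see above): they are
  the prior, not data.
* **Recovery simulations unclipped** (see above): clipping would measure
  the scale's censoring, not the estimator.

## Limitations

* Per-participant maximum likelihood only; no hierarchical pooling, MAP
  or MCMC.
* The exceedance probability is the classic variant, not the protected
  version; with genuinely indistinguishable models it splits evidence
  rather than detecting the null.
* Linear mixed models on the rating time-courses are out of scope; the
  package exports tidy long-format tables for external mixed-model
  tools.
* The impression-coupling convention in the generator is a synthetic
  assumption, clearly labelled as such; real coupling strength and form
  are unknown.

## A compact end-to-end example

```{r, eval = FALSE}
study <- simulate_study(20, culture_profile = "western", seed = 1)
sess <- study$sessions[[1]]

fits <- lapply(c("M1", "M2", "M3"), function(m)
  fit_learning(sess, m, n_restarts = 10, seed = 1))
best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "aic"))]]

traj <- simulate_learning(sess$schedule,
  learning_params(best$estimates[1:4], best$estimates[["beta"]],
                  v0_ingroup = sess$expectancy[
                    match("ingroup", sess$schedule$group)],
                  v0_outgroup = sess$expectancy[
                    match("outgroup", sess$schedule$group)],
                  variant = "M3"))
fit_closeness(sess, traj, "C2", "ingroup", seed = 1)
```
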