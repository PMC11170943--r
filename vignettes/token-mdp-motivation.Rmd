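---
title: "State values and motivation in a token reinforcement task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{State values and motivation in a token reinforcement task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The task and why it needs a state-based model

In the stochastic tokens task an animal chooses between two of four
images each trial. Each image maps to a token outcome (+2, +1, −1,
−2) delivered with probability 0.75 (no change otherwise); tokens can
never go below zero. Every four to six trials — uniformly — the
accumulated tokens cash out, one juice drop per token. Blocks last 108
completed trials with four novel images; each of the six cue pairs
appears 18 times, twice (opposite sides) in every disjoint 12-trial
window. Aborted attempts (broken fixation, no choice, insufficient
hold) are repeated immediately with the same cues and sides.

Tokens and cues both predict reward, but differently: cues predict
tokens stochastically and must be re-learned each block, while tokens
predict juice deterministically but on a delay. A stateless
learning model tracks only cue values, so it cannot express how
motivation should vary with accumulated tokens, proximity to
cash-out, or position in the trial. The package therefore combines a
Rescorla–Wagner (RW) account of *learning* with a Markov decision
process (MDP) account of *valuation*, and tests the MDP's state
values against motivation-linked behaviour.

# Rescorla–Wagner layer

The RW model uses one learning rate per cue and a shared softmax
inverse temperature. Two substantive conventions:

- **The prediction error uses the realized token change**, which is 0
  on non-delivered outcomes. The 25% no-change trials therefore damp
  the asymptotic values toward `0.75 × delta`.
- **Values reset to zero at block starts**: the images are novel, so
  they carry no prior value.

Fitting maximizes the likelihood of completed choices only; an
attempt that was aborted and then completed contributes its eventual
choice once. (Aborted attempts never carry token outcomes, so they
are uninformative about cue values.) Optimization is bounded L-BFGS-B
(α in [0,1], β in [0,50]) from a fixed five-point start grid; with
~1,000 trials per session the likelihood surface is well behaved and
the multi-start is belt-and-braces against edge plateaus.

**Curve extraction.** Value trajectories are replayed under the
fitted learning rates, recording each cue's value *before* each of
its observations (so every cue starts at exactly 0). Each cue is seen
54 times per block (three conditions × 18); averaging across blocks
and collapsing consecutive triples yields one curve per cue over the
18 cue-pair observations (NObs), the learning-progress feature of the
MDP. The dispersion σ(NObs) is the across-block standard deviation of
the collapsed value, averaged over the four cues — one dispersion per
learning stage, shared by all cues, matching the transition-model
assumption that variance varies across trials but not across cues.

# From values to transition probabilities

The animal's uncertainty about which cue yields which outcome is
modelled as a Bayesian posterior. Given the scaled mean cue values
`k·μ_j` at a learning stage and the chosen cue's mean `x`:

- p(no change) = 0.25 exactly (the delivery mechanism is known);
- the remaining 0.75 is split over the four token outcomes in
  proportion to Gaussian likelihoods `N(x; k·μ_j, σ)` — the uniform
  0.75/4 priors cancel.

The 0.75 rescaling matters: a plain four-way posterior maximum can
never fall below 0.25, while early-learning transition probabilities
near 0.24 are expected — only the rescaled form produces them. With
the printed example means, `posterior_from_means()` gives 0.24 (σ =
0.175, early) and 0.52 (σ = 0.23, late); since σ is not given with
those examples, `calibrate_sigma()` recovers it by 1-D root finding —
the posterior of the chosen best cue is strictly decreasing in σ,
from 0.75 down to the uniform 0.1875.

Two boundary conventions:

- **NObs = 1 is naive by construction** (`naive_first = TRUE`): on a
  pair's first presentation the animal has no experience, so the
  posterior is uniform and the two action values are exactly equal.
  Estimated curves at the first collapsed index are averaged over the
  pair's first three appearances and already contain a little
  learning, so indexing them directly would leak future information
  into the first state.
- **σ = 0 with distinct means is an error** (degenerate likelihood);
  exactly tied means yield the uniform posterior for any σ.

The value scale `k` multiplies the means but not σ; scaling both
would cancel and make `k` inert. Equivalently, `k` controls the
separability of the cue means relative to their dispersion, which is
what the choice-probability fit constrains.

# The MDP

States are (NTk 0–12, TSCO 1–6, TE 1–10, NObs 1–18) — 14,040 in the
full grid; `enumerate_states(prune_infeasible = TRUE)` drops token
counts above `2 × TSCO` (a maximum of 8 tokens is reachable by TSCO
4). Epochs are 1 = fixation, 2–7 = the cue conditions in canonical
order (+2v+1, +1v−1, +2v−1, +1v−2, +2v−2, −2v−1), 8 = token outcome,
9 = cash-out, 10 = ITI. Transitions:

- fixation → each cue condition at 1/6;
- cue + action → outcome via the posterior above, with the token
  count clamped to [0, 12];
- outcome → cash-out with the hazard (0, 0, 0, 1/3, 1/2, 1 by TSCO)
  implied by the uniform interval, else → ITI with TSCO advanced;
- cash-out (reward = NTk juice drops; a cash-out with zero tokens is
  still a cash-out) → ITI with tokens 0 and TSCO reset;
- ITI → next fixation, advancing NObs with probability
  `nobs_max / block_length` = 1/6 per completed trial.

**NObs bookkeeping.** The task shows each pair once per six trials,
so a single block-level counter advancing every six completed trials
tracks all six pairs at once; the MDP realises the same average rate
with a memoryless 1/6-per-trial increment, keeping the state Markov
without a within-cycle position feature. Trial records map to states
with `NObs = floor((trial − 1)/6) + 1`.

**The final NObs level is absorbing by default.** A wrapping
transition (18 → 1, emulating the block boundary) makes late-block
states anticipate the imminent reset to naive learning, which
produces state values that peak mid-block and *decline* toward NObs
18 — for any discount factor and for truncated value iteration alike
(a one-line cyclic-chain computation shows this). The documented
phenomenology of the model, by contrast, is a fixation-state value
that rises monotonically with NObs, consistent with a state space
defined over a single block. The default is therefore the absorbing,
single-block model; `nobs_wrap = TRUE` is available for
cross-block experiments.

**Value iteration.** Synchronous Bellman backups over structured
epoch arrays, capped at 100 sweeps (with a policy-stability and
value-change early exit). At γ = 0.999 the fixed point is far beyond
100 sweeps, so absolute utilities scale with the sweep cap — they are
finite-horizon values, spanning roughly 14–30 juice drops with the
default generator, similar in range to fitted animals. All downstream
regressions are invariant in sign under affine rescaling of the value
table (slopes scale by the inverse factor); the test suite asserts
this, so the cap affects units, not conclusions.

# Calibration and the discount factor

`fit_k_beta()` minimizes the RMSE between the model's
choice-probability curves and the empirical 6 × 18 choice-fraction
matrix over all cells with data, equally weighted. Model choice
probabilities average the two action values over feasible (NTk, TSCO)
states before the softmax: choice probabilities vary only weakly with
tokens and cash-out proximity, and the averaged form keeps the
objective smooth. Optimization is Nelder–Mead on log-parameters from
a fixed four-start grid (deterministic); after fitting, transitions
are rebuilt at the fitted `k` and value iteration is re-run (up to
five alternations, early exit on a stable policy). Self-consistency
recovery of (k, β) from model-generated curves is within a few
percent; fits on synthetic monkey-like cohorts land near k ≈ 0.6–1.1,
β ≈ 1.5–2.5, inside the plausible range for real animals.

`sweep_gamma()` screens the canonical candidates (0.8, 0.85, 0.9,
0.95, 0.99, 0.999), scoring each by the mean residual variance of the
three motivation regressions across sessions, and returns the
minimizer. The discount factor is screened, not fit continuously: the
regression error surface over γ is shallow, and a continuous fit
would chase noise.

# Motivation regressions and group statistics

Per session, on completed attempts: `log RT_fix ~ V_fix` and
`log RT_choice ~ V_cue + ΔV` (ΔV = V_cue − V_fix), each after Tukey
fencing (q0.75 + 1.5 IQR and the symmetric lower fence) of the raw
RTs within the session; and logistic `abort ~ V_cue + ΔV` over all
attempts, completed and aborted. Conventions and their reasons:

- **Tukey filtering is applied per session per RT type before every
  RT regression** — the conservative uniform reading of
  outlier-removal practice for this task.
- **The choice-RT model regresses the choice RT** (its occasional
  description as a fixation RT in source material is a typographical
  slip; the regressors and surrounding logic are unambiguous).
- **Aborted attempts contribute no RTs** (their RTs are censored, not
  realized) but do contribute abort outcomes.
- **Fixation-stage aborts** precede cue onset, so the feature-level
  abort regressions split: fixation aborts on (NTk, TSCO, NObs),
  choice aborts on (NTk, TSCO, NObs, condition), condition 1 as the
  reference level.
- **Separation fallback**: small sessions can separate perfectly in
  the logistic fit; a ridge-penalized (λ = 1e−6) Newton fit is used
  and flagged.
- **Group inference** is a per-animal one-sample t across sessions,
  then an exact one-sided Wilcoxon signed-rank across the per-animal
  means. One-sided because the hypotheses are directional and because
  with five animals the exact null has 32 equiprobable sign patterns:
  the extreme pattern gives p = 1/32 = 0.0312, the smallest
  attainable value, which is what a uniformly negative sign pattern
  should report.

`marginalize_values()` averages the table over all *feasible* levels
of one feature (e.g. NTk 0–8 at TSCO 4) so regressions can be re-run
without that feature's contribution; marginalizing TE averages across
every epoch, which makes cue and fixation lookups identical and ΔV
vanish — the package raises an error rather than fit the degenerate
design. Removing the feature a generator actually couples to
attenuates the fitted slope, which the tests assert as the structural
marginalisation effect.

# The synthetic generator: what it states and why

The generator (`behavior_truth()`) is the package's testing
instrument: monkey-like sessions with known ground truth. Defaults,
with units and rationale:

| parameter | default | units | why |
|---|---|---|---|
| α (+2, +1, −1, −2) | 0.3, 0.3, 0.1, 0.1 | per outcome | gain cues are learned faster than loss cues, which animals sample rarely and discriminate poorly |
| β_RW | 2 | per token-value unit | produces ~80–95% asymptotic better-option choice in gain conditions and weak loss–loss discrimination |
| rt_fix: b0, b1 | −0.4, −0.05 | log s; per juice drop | ≈ 250 ms typical fixation acquisition at mid-range state values, mildly faster at high value |
| rt_choice: c0, c1, c2 | −1.1, −0.02, −0.05 | log s; per juice drop | ≈ 200 ms choice latency, faster for valuable cues and positive value changes |
| abort: a0, a1 | 1.5, −0.2 | logit; per juice drop | ≈ 8% aborts at typical state values, ranging ~1–20% across the value span; the slope is anchored to the strong per-animal abort effects reported for this task family (per-session slope z ≈ 2.5–3), after an initial weaker placeholder proved inconsistent with that effect scale |
| rt_noise_sd | 0.2 | log-units | ≈ 20% lognormal RT scatter, typical of primate RT distributions |

RTs are log-normal around linear predictors of the latent state
values — exactly the functional form the regressions assume, which
makes slope recovery a sharp test (a noiseless generator is recovered
to machine precision). Fixation-stage aborts use the fixation-state
value (the condition is not yet visible); choice-stage aborts use the
cue-state value. Aborted attempts are repeated with the same
condition and sides and advance nothing.

**What a green test establishes — and does not.** The generator
reproduces the task's mechanics and the regression structure of real
behaviour, so green recovery tests establish that the pipeline is
unbiased and correctly wired at realistic scales. They do not
establish that real animals obey log-linear value couplings, nor
calibrate absolute effect sizes: satiety, slow drifts within
sessions, inter-animal heterogeneity beyond parameter values, and
any behaviour of the real scheduler beyond the 12-trial balancing
rule are all outside the generator.

# Numerical choices

- Token counts clamp to [0, 12] inside the transition model; the
  upper clamp is unreachable in simulation and exists only for
  full-grid sweeps.
- Greedy policies break exact action-value ties toward the first
  (left) slot; ties occur only at NObs = 1, where both actions are
  identical by construction, so the break is inconsequential.
- Value-iteration tolerance (1e−6 on the max value change, plus
  policy stability) matters only for γ well below 0.999; at the
  default discount the sweep cap binds first.
- The RW likelihood floors choice probabilities at 1e−12 to keep the
  objective finite under extreme parameters.
- `with_seed()` scopes every stochastic routine, so identical inputs
  give byte-identical outputs and the caller's RNG state is never
  disturbed.

# Known limitations

- The MDP has no abort action: aborting is strictly dominated under
  discounting (the trial repeats), so modelling it would require
  extra parameters the behaviour cannot validate. Aborts are treated
  purely as a dependent measure.
- Epoch time, not clock time: delays enter as state transitions, so
  "discounting per epoch" is an approximation to temporal
  discounting.
- Absolute state values depend on the sweep cap (see above); only
  comparisons and regression signs are interpretable across models.
- The mixed-effects ANOVA on abort frequencies by condition is not
  implemented; the categorical-condition logistic regression covers
  the same scientific question at the session level.
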