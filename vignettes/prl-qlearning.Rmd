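---
title: "Q-learning models of probabilistic reversal learning: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Q-learning models of probabilistic reversal learning: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prlqlearn)
```

## The task and the question

In a probabilistic reversal learning (PRL) task an animal chooses repeatedly
between two stimuli. One is designated "correct" and rewards 80% of choices;
the other rewards 20%. After 8 consecutive correct choices the designation
flips, and the animal must relearn. Sessions run to 200 trials. Performance
on this task mixes several latent processes — how fast reward and
non-reward update the animal's value estimates, how deterministically values
drive choice, and how much the animal simply repeats itself — which
trial-by-trial modelling can separate where summary statistics cannot.

This package implements that modelling pipeline: a task/agent simulator, three
nested Q-learning models fitted per animal per session by exhaustive
grid-search maximum likelihood, model comparison, the conventional PRL
measures, and a Pearson/FDR correlation analysis linking the two families of
measures.

## The models

All three models share the delta-rule update for the chosen option $c_t$:

$$Q_{t+1}(c_t) = Q_t(c_t) + \alpha\,(r_t - Q_t(c_t))$$

with reward $r_t \in \{0,1\}$ and learning rate $\alpha$. The unchosen
option is neither updated nor decayed — no forgetting term is modelled.
Choice follows a softmax with a stickiness bonus:

$$P(c_t = L) = \frac{e^{Q_t(L)/\beta + \kappa L_{t-1}}}
  {e^{Q_t(L)/\beta + \kappa L_{t-1}} + e^{Q_t(R)/\beta + \kappa R_{t-1}}}$$

where $\beta$ is the temperature (low = exploitation, high = exploration)
and $\kappa$ rewards repeating the previous response regardless of outcome
($L_{t-1}, R_{t-1}$ are previous-choice indicators, both 0 on a session's
first trial). The variants are nested:

| model    | free parameters                                         | k |
|----------|---------------------------------------------------------|---|
| `M_ab`   | $\alpha, \beta$ (no stickiness, $\kappa = 0$)           | 2 |
| `M_abk`  | $\alpha, \beta, \kappa$                                 | 3 |
| `M_a2bk` | $\alpha_{rew}, \alpha_{nonrew}, \beta, \kappa$          | 4 |

`M_a2bk` with $\alpha_{rew} = \alpha_{nonrew}$ reproduces `M_abk` exactly,
and `M_abk` with $\kappa = 0$ reproduces `M_ab`; the tests assert these
identities to machine precision.

Session log-likelihood is the sum over trials of the log-probability of the
observed choice (the log of the product of per-trial probabilities; summing
logs avoids underflow beyond ~1000 trials). Sessions are fitted
independently: Q-values reset to `q0` at session start and the first trial
carries no stickiness.

## Fitting

Fitting is an exhaustive grid search, exactly as in grid-quantized ML
pipelines for this task class: $\alpha$-type axes run 0.001 to 1 in steps of
0.05, $\beta$ 0.005 to 5 in steps of 0.15, $\kappa$ $-1$ to 1 in steps of
0.1. Because neither the $\alpha$ nor the $\beta$ range divides evenly by
its step, an endpoint rule is needed: axes step up from the lower bound and
append the printed upper bound when the last stepped value falls more than
half a step short of it (so the $\alpha$ axis has 21 values ending at 1.0;
the $\beta$ axis has 34 ending at 4.955). The rule is configurable
(`grid_spec(include_upper = ...)`) since the original endpoint handling is
not recoverable.

Numerics: the hot loop lives in C++. The Q trajectory depends only on the
$\alpha$ values, so it is computed once per $\alpha$ combination; the
per-trial choice probability reduces to a logistic in
$\sigma_t(d_t/\beta + \kappa s_t)$ (with $d_t$ the Q-gap, $\sigma_t$ the
choice sign, $s_t$ the previous-choice sign), and the sum of `log1p` terms
is accumulated as a running product with overflow flushing. At the stated
bounds $|d_t/\beta| \le 200$, so no individual factor overflows a double.
The R-level `session_loglik()` is the readable reference implementation; the
tests pin the C++ path to it and to a from-scratch literal-product oracle at
$10^{-9}$.

Ties (rare, but possible when a parameter is inert for a given choice
sequence) are broken by first occurrence in lexicographic grid order —
axes ordered $\alpha_{rew}, \alpha_{nonrew}, \alpha, \beta, \kappa$, values
ascending — for bit-for-bit reproducibility. Estimates are grid-quantized;
no local refinement is applied, so a fitted parameter is never more accurate
than half a step.

## Model comparison

Three measures, per session: the log-likelihood ratio
$d = 2(\log P_2 - \log P_1)$; a pseudo-$r^2 = 1 - \log P / (n \log 0.5)$
measuring improvement over the chance model (0 at chance, 1 at perfect
prediction); and a BIC in the **log-evidence convention**,
$\log P - (k/2)\log m$ with $k$ free parameters and $m$ trials, where larger
is better. This differs by a factor of $-2$ from the textbook
$-2\mathrm{LL} + k\log m$; `bic_classic()` converts, and both rank models
identically. The winner is the model with the best mean BIC across sessions.
Note the two distinct sample-size symbols: trials enter the pseudo-$r^2$,
while the BIC penalty uses the free-parameter count and the trial count —
`ComparisonRow`-style outputs keep `n_trials` and `n_free` as separate
columns so the two cannot be conflated.

## Conventional measures

Win-stay is the percentage of trials repeating the previous choice among
trials whose *previous* trial was rewarded; lose-shift the percentage
switching among trials whose previous trial was unrewarded. Both are split
by the correctness of the *previous* response — the previous-trial reading
of the compact "after a correct/incorrect trial" phrasing, chosen because
the probabilistic feedback decouples reward from correctness (the
alternative current-trial conditioning is not implemented; the convention is
documented here precisely because the phrasing is ambiguous). Empty
denominators yield `NA`, never 0. Trials-to-criterion is the mean number of
trials per completed contingency block, inclusive of the
criterion-completing trial, with the pre-first-reversal block counted (both
choices configurable). Perseverative responses count post-reversal choices
of the previously correct stimulus before the first choice of the newly
correct one, summed within session (reported as a count; a
per-reversal average is available).

## Correlation analysis

The per-session measure table (4 RL parameters + 7 conventional measures) is
averaged within subject by default — matching a subjects-as-units
degrees-of-freedom reading of the source analysis; `aggregate = "session"`
keeps sessions as units. Each measure is screened with Shapiro–Wilk
(warning, not refusal, on failure), all pairwise Pearson correlations are
computed with pairwise deletion, and Benjamini–Hochberg FDR control at
$q = 0.05$ is applied across the unique off-diagonal pairs. Constant
columns and pairs with $n < 3$ yield `NA` rather than errors. Linear
mixed-effects modelling of group effects is deliberately out of scope: the
pipeline exports the tidy per-subject-per-session table such a fit would
consume.

## The simulator: what it emulates, and what it does not

`simulate_session()` generates choices from the same softmax/delta-rule
agent the models fit, inside the stated task: 80/20 contingencies, reversal
after 8 consecutive correct choices, 200-trial cap.
`simulate_cohort()` arranges agents in a 2 (control vs maternal
separation) × 2 (sex) design across pre/post-stress phases, with per-cell
parameters so group effects are stated directly, and optional truncated
Gaussian between-subject jitter (off by default, so recovery tests have
exact ground truth). Default agent parameters
($\alpha_{rew} = 0.5, \alpha_{nonrew} = 0.3, \beta = 0.4, \kappa = 0.2$)
describe a moderately proficient animal — roughly 70–80% asymptotic accuracy
with mild stickiness, the performance regime of a trained rat on this task.

Deliberate simplifications: "correct" for the reversal counter means
choosing the designated side irrespective of reward delivery, and an
unrewarded correct choice does not reset the counter (configurable — the
task description does not pin this down); the 40-minute session clock is not
modelled, so `max_trials` is the only stopping rule; `q0` defaults to 0.5,
the chance expectation of a 0/1 reward, since initialization is otherwise
unstated; no latency, satiety, or engagement processes exist. A green
cohort-level test therefore establishes that the *pipeline* recovers what
the *model family* generates — it cannot certify behaviour the model family
does not express (lapses, drifting motivation, side bias unrelated to
stickiness).

## Numerical and design choices

- **Filters**: the reference analysis uses trials up to completion of the fourth
  reversal and the first 3 sessions per phase. `filter_to_reversals()` cuts
  where `reversal_index` reaches 4 — i.e. the trials of the fourth
  post-reversal block are *excluded*; the cut point is configurable since
  the inclusive reading is also defensible.
- **Stored reversal indices**: `reversal_index` travels with the data file
  rather than being recomputed on read, insulating fitting from
  criterion-detection bugs; `check_reversal_index()` replays the rule when
  verification is wanted.
- **Chance calibration**: $\alpha = 0$, equal `q0` and $\kappa = 0$ force
  $P = 0.5$ every trial and the log-likelihood $n \log 0.5$ exactly; this
  anchors the pseudo-$r^2$ zero point and is asserted to $10^{-12}$.
- **Seeds**: a master seed spawns per-subject substreams via an integer
  mixing function, so cohorts are byte-reproducible and growing the design
  never perturbs earlier subjects' data.
- **Identifiability**: with ≤ 200-trial sessions the $\alpha$ parameters
  are weakly identified (flat likelihood ridges trading $\alpha$ against
  $\beta$); recovery tests therefore hold $\kappa$ and $\beta$ to ≤ 2 grid
  steps median error at 500 trials but allow the $\alpha$s looser recovery.

## Known limitations

Grid-quantized estimates inherit the grid's resolution; no standard errors
or hierarchical shrinkage are provided. The BIC sign convention must be
minded when comparing against other toolchains. The simulator's stated
world is the fitted model family itself, which makes recovery tests
well-posed but optimistic relative to real animals. Session-level fitting
ignores slow within-phase learning carried across sessions.
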