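---
title: "Valuing direct versus prize-based funding of antibiotic development"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valuing direct versus prize-based funding of antibiotic development}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package addresses

New antibiotics are scarce partly because their expected private value is
poor: development takes a decade, most candidates fail, and successful
products face small, stewarded markets. Two public remedies are commonly
discussed. *Indirect funding* announces a prize — a lump sum paid on entry
into a named development phase (phase entry reward) or on reaching the
market (market entry reward) — so that enough private projects turn a
financial no-decision into a go-decision. *Direct funding* simply pays for
development at-cost, possibly inflated by an operational inefficiency of a
plan-based funder. This package implements a Monte Carlo framework that
prices both options per observed market approval and asks which is cheaper,
where, and by how much.

```{r setup}
library(abxfund)
params <- abx_parameters()
```

## Project model

A project targets one of six clinical indications (acute bacterial otitis
media, skin and skin-structure infections, community-acquired pneumonia,
complicated intra-abdominal infections, complicated urinary tract
infections, hospital-acquired/ventilator-associated pneumonia). Each passes
through five development stages — pre-clinical (PC), clinical phases 1-3,
and a phase-4 stage covering everything between the end of phase 3 and
first sales — followed by 20 years of market life. Per indication and stage
the packaged tables give triangular distributions of duration (months),
cost (million USD) and probability of success, alongside market size,
a year-by-year market-share envelope, launch-success, generic-entry and
discount-rate parameters, and six additional cost items (supply-chain,
non-clinical, post-approval studies) spread over named stages. All units
are converted on load: years, fractions, million USD.

`sample_projects()` draws every stochastic quantity once per project. Two
choices deserve comment:

* **Market share.** The share envelope gives a lower and upper bound per
  market year. Rather than sampling each year independently, one
  launch-success draw is rescaled linearly onto `[0, 1]` and used as the
  position between the bounds in *every* year. Shares therefore never
  decrease before their plateau and a strong launch lifts the whole curve.
  The launch draw is used only for this interpolation; it is not an
  additional survival factor, because the decision model defines the
  probability of reaching market as the product of the five stage
  probabilities.
* **Market size.** Five indications print a single annual market size,
  which we treat as fixed; one (CABP) prints a `(min, max)` pair and is
  sampled uniformly over it, since no mode is given that would justify a
  triangular.

## Periodization

Valuation needs discrete yearly cashflows. A stage of duration $d$ years
starting at time $s$ becomes $n = \lceil d \rceil$ steps at
$t = s, s+1, \dots, s+n-1$; the next stage starts at $s + d$, so steps are
equidistant within a stage but not across (for example PC of 2.5 years and
phase 1 of 1.75 years give steps at $t = 0, 1, 2$, then $2.5, 3.5$, with
phase 2 starting at $4.25$). The stage's cost draw is split equally across
its steps; additional cost items are first split across their target stages
by the printed weights (equally when none are printed) and then equally
across steps, with post-approval studies spread over exactly the first
three market years. The stage's success probability is split
*geometrically*: each step's conditional survival is $p^{1/n}$, a constant
hazard whose product recovers the stage draw exactly — the conservation
property the test suite checks. Distributing the probability additively
(e.g. $1 - (1-p)/n$ per year) would not conserve it. Market years are unit
steps aligned to integer offsets from the total development time.

## Four valuation perspectives

With $R_t$, $C_t$, $Z_t$ the revenue, cost and prize at step $t$,
$S_t$ the probability of reaching step $t$ from the pre-clinical outset
($S_0 = 1$; $S_t = P_0$, the product of the five stage probabilities, on
market steps), $r$ the private and $r'$ the social discount rate:

$$
\begin{aligned}
\text{private} &= \sum_t (R_t - C_t)\, S_t\, (1+r)^{-t}, &
\text{intervened} &= \sum_t (R_t - C_t + Z_t)\, S_t\, (1+r)^{-t}, \\
\text{indirect} &= \sum_t (-Z_t)\, S_t\, (1+r')^{-t}, &
\text{direct} &= \sum_t -(1+i)\, C_t\, S_t\, (1+r')^{-t},
\end{aligned}
$$

with $i$ the direct funder's inefficiency fraction. Exponents are real
(fractional years are not rounded). A developer goes ahead without an
intervention iff the private value is non-negative, and with one iff the
intervened value is. The two benefactor perspectives only contain costs,
so they are never positive; dividing them by $P_0$ converts an expected
cost per funded project into an expected cost per observed market
approval, the unit all comparisons use. The *cost savings of direct
funding* is the per-approval direct minus indirect value: positive when
the prize is the dearer instrument.

Revenues are the market-size draw times the interpolated share, and from
the first market year strictly after the sampled generic-entry year they
are reduced by the sampled generic-entry fraction and held constant.
Prizes are lump sums placed on the first step of their phase and sampled
logarithmically, $10^X$ USD with $X \sim U(5, 11)$, because most of the
response happens at small prizes while near-certain stimulation requires
orders of magnitude more; a project never carries more than one prize,
and pre-clinical entry prizes are excluded since they would be
undiscounted from the valuation point.

`value_projects()` evaluates all of this vectorized, with the prize term
added analytically from each phase's entry time and survival; the test
suite pins it, to $10^{-9}$ relative tolerance, to the transparent
per-schedule route (`build_schedule()` plus the `enpv_*` functions) and to
an independently coded brute-force summation.

## Incentive response and prize sizing

Because a prize always improves the intervened value, the improvement is
regressed as $\log_{10}(\text{improvement}) = \beta_0 + \beta_1 \log_{10}
(\text{prize})$ — per indication and prize phase, to avoid extra
covariates. The lump-sum mechanics make this fit nearly exact with unit
slope. The decision response is a logistic regression, fitted only on
projects facing a no-decision without the intervention:

$$\operatorname{logit} P(\text{go}) = \beta_0 + \beta_1 \log_{10}(\text{prize}),$$

giving the *conditional* probability of converting a no-decision, and its
closed-form inverse sizes the prize for a target $P(\text{go})$
(`solve_prize()`). One sampled prize per project enters the fit. Complete
separation — possible in small subsets — is refitted with a mild ridge
penalty and flagged rather than returned silently; p-values are reported
raw, without multiplicity correction.

## Experiments and their problem sizes

* `run_baseline()` — 2,000 projects per indication by default: go-ratios,
  both response fits per indication × prize phase, and solved prizes at a
  90% target.
* `run_grid()` — by default 40 targets on $[0.5, 0.9875]$ × 41
  inefficiencies on $[0, 1]$, 10 fresh projects per cell, prizes solved
  from the baseline fits (10 samples per cell could not support refits).
  Cells whose prize stimulates no sampled project are recorded as missing,
  not zero — an unpaid prize has no meaningful cost. `fit_frontier()`
  extracts, per inefficiency column with a sign change, the cell nearest
  zero savings and fits a quadratic of the target on inefficiency: the
  frontier beyond which direct funding is cheaper.
* `run_scenario()` — 1,000 projects per indication at inefficiency 0.5 and
  prizes targeting 90%: mean per-approval savings per indication × phase
  and the per-project cost distributions of both funding routes.

Grid spacing is uniform (the endpoints and counts are fixed, the spacing
is the natural default), and scenario prizes are solved per indication ×
phase rather than pooled. Each experiment derives one RNG substream per
indication (and per indication × phase block in the grid) from the user
seed, so runs are byte-reproducible and adding indications does not
perturb the draws of others; grid cells consume disjoint blocks of their
stream, equivalent to an independent redraw per cell.

## What the generator does and does not emulate

The sampler *is* the data source — there is no external dataset. It
reproduces the study conditions: published per-stage triangulars, the
share envelope mechanism, a private discount rate sampled per project
from its printed triangular, and a social rate uniform on
$[0.035, 0.045]$. It does not model correlation across stages or
indications, time-varying discount rates, drug reimbursement, existing
grants, or candidate acquisition costs. Passing tests therefore show that
the valuation, response fitting and inversion machinery is correct under
these stylized conditions — not that the parameter tables themselves
predict any real market.

Two further caveats matter when reading results. First, solved prizes at
high targets extrapolate a logistic tail from a finite no-decision
subset; at the default sample sizes the phase-4 and market-entry prize
estimates carry substantial Monte Carlo spread (tens of percent across
seeds), which propagates into the scenario's savings for those phases.
Second, go-ratio levels are sensitive to how the within-stage survival
split, the cost timing and the revenue risk-adjustment are resolved; the
package resolves each the way described above and keeps the conservation
property exact, and robustness to these readings is best explored by
editing a copy of the parameter tables and passing it via
`abx_parameters(path)`.

## Numerical choices

* Degenerate triangulars (a value printed only as a mode, like the
  phase-4 cost) return the constant.
* Discounting never rounds: $(1+r)^{-t}$ with real $t$.
* The generic-entry year is sampled as a real number; reduction applies
  from the first market year strictly greater than it.
* `ceiling()` on durations decides step counts; each step carries weight
  $1/n$ of the stage cashflow even though the last sub-interval may be
  shorter.
* Ties in the frontier's nearest-zero cell selection resolve to the first
  (smallest-target) cell; combinations with fewer than three crossing
  columns are flagged, not fitted.
* Logistic fits guard against non-finite or absurd slopes
  (`|beta1| > 100`) and fall back to the flagged ridge fit.

## A small worked run

```{r baseline, eval = FALSE}
baseline <- run_baseline(params, n_samples = 500, seed = 1)
baseline$decisions
solve_prize(
  abxfund:::pgo_fit_for(baseline, "ABOM", "M1"), 0.9
)
scenario <- run_scenario(baseline, params, n_samples = 500, seed = 1)
tidy(scenario)
plot_cost_distributions(scenario)
```

At full scale the pattern the experiments produce is stable: early-phase
rewards (phases 1-2) are cheaper than direct funding per market approval,
late-phase rewards (phase 4, market entry) are substantially dearer
unless the funder's inefficiency is high or the targeted conversion
probability low, and market-entry prizes differ by billions across
indications at the same target — a warning against one-size-fits-all
prize design.
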