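# abxfund

Monte Carlo comparison of two ways a public benefactor can pay for new
antibiotics: **indirect funding** — announcing a lump-sum prize on entry
into a development phase or on reaching the market, large enough to turn
private no-decisions into go-decisions — and **direct funding** — paying
development at-cost, inflated by an operational inefficiency. The package
samples hypothetical development projects for six clinical indications
from published per-phase time/cost/probability distributions, values each
project as a risk-adjusted discounted cashflow from four perspectives, and
compares the two funding routes per observed market approval.

It is aimed at health-economics and pharmaceutical-policy researchers who
want a reproducible, tested implementation of the staged-development ENPV
framework and of prize-sizing via incentive-response inversion.

## The model in brief

A project is a sequence of stages (pre-clinical, phases 1–4) followed by
20 market years, periodized into yearly steps. With revenue $R_t$, cost
$C_t$, prize $Z_t$, survival-to-step $S_t$ (product of per-stage success
probabilities; $S_t = P_0$, the probability of reaching market, on market
steps) and discount rates $r$ (private) and $r'$ (social):

- private ENPV $= \sum_t (R_t - C_t)\,S_t\,(1+r)^{-t}$ — the go/no
  criterion (go iff $\ge 0$);
- intervened ENPV adds $Z_t$ to the cashflow;
- indirect ENPV $= \sum_t -Z_t\,S_t\,(1+r')^{-t}$ — the benefactor's
  expected prize bill;
- direct ENPV $= \sum_t -(1+i)\,C_t\,S_t\,(1+r')^{-t}$ — the at-cost bill
  under inefficiency $i$.

Dividing the benefactor perspectives by $P_0$ prices a market approval.
The conditional probability that a prize converts a no-decision,
$P(\mathrm{go})$, is fitted by logistic regression on
$\log_{10}(\text{prize})$ over the no-decision subset and inverted in
closed form to size prizes for a target conversion rate.

## Worked example

```r
library(abxfund)
params   <- abx_parameters()                      # packaged tables
baseline <- run_baseline(params, n_samples = 2000, seed = 1)
baseline$decisions
#> # A tibble: 6 × 4
#>   indication     n     go    no
#>   <chr>      <dbl>  <dbl> <dbl>
#> 1 ABOM        2000 0.339  0.661
#> 2 ABSSSI      2000 0.502  0.498
#> 3 CABP        2000 0.777  0.223
#> 4 CIAI        2000 0.320  0.680
#> 5 CUTI        2000 0.812  0.188
#> 6 HABP/VABP   2000 0.0425 0.958
```

`go` is the share of sampled projects a private developer would pursue
unaided: four in five urinary-tract projects, almost no
hospital-acquired-pneumonia projects (small market, expensive phase 3).
The solved prizes that would convert 90% of the remaining no-decisions
(million USD, per prize phase):

```r
tidyr::pivot_wider(baseline$prizes[c("indication", "prize_phase", "prize_size")],
                   names_from = prize_phase, values_from = prize_size)
#>   indication    P1    P2    P3    P4    M1
#> 1 ABOM         117   282   748  2162  2658
#> 2 ABSSSI       111   298   845  1773  2127
#> 3 CABP         101   312   762  2234  2585
#> 4 CIAI          94   282   755  1978  2677
#> 5 CUTI          97   261   666  1560  3301
#> 6 HABP/VABP    115   366   930  3261  4004
```

Later prizes must be orders of magnitude larger: a phase-1 entry reward of
~100 million is worth as much, to a discounting developer facing failure
risk, as a market-entry reward of 2–4 billion. The scenario experiment
(prizes held at the 90% sizes, direct funding at 50% inefficiency) prices
the difference per market approval:

```r
scenario <- run_scenario(baseline, params, seed = 1)
tidy(scenario)   # mean cost savings of direct funding, million USD
#>   indication    P1    P2    P3    P4    M1
#> 1 ABOM        -156  -147    92   626   724
#> 2 ABSSSI      -189   -81   248   403   451
#> 3 CABP        -275   -65   100   709   713
#> 4 CIAI        -338  -149   104   503   747
#> 5 CUTI        -310  -219   -25   194  1158
#> 6 HABP/VABP   -282    -6   233  1249  1388
```

Negative numbers (phases 1–2) mean the prize is cheaper than paying
at-cost; positive numbers (phase 4, market entry) mean the benefactor pays
hundreds of millions *extra* per approved antibiotic by stimulating
indirectly instead of funding directly. `run_grid()` sweeps targets and
inefficiencies to map where that sign flips, `fit_frontier()` extracts the
break-even frontier, and `plot_pgo_curves()`, `plot_savings_heatmap()`,
`plot_frontier()` and `plot_cost_distributions()` draw the standard
figures. `write_tables()` serializes any result with a reproducibility
manifest, and `inst/cli/abxfund.R` exposes `baseline`/`grid`/`scenario`
subcommands for shell use.

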