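# adcea

Markov cohort cost-utility modelling of antidepressant therapy in major
depressive disorder (MDD).

`adcea` is for health economists and modellers who need a transparent,
fully tested implementation of a monthly-cycle cohort state-transition
model comparing antidepressants — agomelatine versus venlafaxine,
sertraline, fluoxetine and escitalopram (branded and generic) in the
packaged base case — over a two-year horizon, with quality-adjusted life
years (QALYs) and euro costs from a societal or payer perspective.

## The model

Six health states on a one-month cycle: depressive episode on treatment,
remission on treatment, episode off treatment, remission off treatment,
well, dead. Remission is expanded into six monthly tunnel states so that
(i) six consecutive months of remission are required before "well" and
(ii) the relapse hazard can follow a Weibull curve in time since remission
entry, S(t) = exp(−(t/λ)^k), with per-cycle probability
1 − S(t+1)/S(t). Comparator relapse uses relative risks versus placebo on
the rate scale, p ↦ 1 − (1 − p)^RR. Background mortality comes from an
annual life table; during an episode it is multiplied (rate scale) by
20.35 to reflect suicide risk.

Each cycle accrues utility (0.86 well / 0.81 remission / 0.57 episode,
minus expected adverse-drug-reaction disutility Σ freqᵢ·decrementᵢ),
state costs, medication (with a double-dose uplift after the first
cycle), ADR management, hepatic monitoring (agomelatine) and one-time
discontinuation-symptom burdens. Streams beyond month 12 are discounted
at 3.5%/year. Pairwise comparison yields incremental cost ΔC, incremental
QALYs ΔQ, the ICER ΔC/ΔQ or a dominance label, and net monetary benefit
λ·ΔQ − ΔC. One-way deterministic sensitivity analysis, named scenarios, a
break-even remission search, and a second-order Monte Carlo probabilistic
sensitivity analysis (beta/lognormal by method of moments, sd = 10% of
mean by default) with cost-effectiveness acceptability curves complete
the tool chain. See the methods vignette
(`vignettes/cost-utility-methods.Rmd`) for assumptions and defaults.

## Worked example

```r
library(adcea)
cfg  <- base_case_config()          # packaged published input set, 9 arms
arms <- run_all_arms(cfg)

arms[["Agomelatine"]]
#> <arm_result> Agomelatine: total cost EUR 5209, QALYs 1.515

incremental_analysis(arms[["Agomelatine"]], arms[["Sertraline"]],
                     cfg$econ$wtp_thresholds)
#> <ce_result> Agomelatine vs Sertraline: dCost EUR -69, dQALY 0.028 -> Agomelatine dominant

incremental_analysis(arms[["Agomelatine"]], arms[["Venlafaxine"]],
                     cfg$econ$wtp_thresholds)
#> <ce_result> Agomelatine vs Venlafaxine: dCost EUR 244, dQALY 0.021 -> EUR 11736/QALY
```

Agomelatine accrues 5209 discounted euro and 1.515 QALYs per patient over
24 months. Against sertraline it is *dominant* — cheaper by €69 and more
effective by 0.028 QALYs — while against venlafaxine it costs €244 more
for 0.021 extra QALYs, an ICER of €11,736/QALY, well below the €40–60k
thresholds. (Unpublished inputs — the national life table, the fitted
relapse Weibull, the PSA variances — are package defaults, so totals are
regime-level, not digit-level, reproductions; the methods vignette
details this.)

Probabilistic sensitivity analysis and an acceptability curve:

```r
res <- run_psa(cfg, n = 200, seed = 1)
ceac(res, "Venlafaxine", c(0, 25000, 50000))
#>     wtp prob_cost_effective
#> 1     0               0.245
#> 2 25000               0.625
#> 3 50000               0.695
```

At a willingness to pay of €50,000/QALY, agomelatine is cost-effective
versus venlafaxine in 69.5% of the 200 simulated parameter sets.

Configurations are plain YAML (`load_config()` / `save_config()`; the
packaged base case ships at
`inst/extdata/mdd_base_case.yaml`), and a thin command-line wrapper over
the report functions lives at `inst/cli/adcea.R`
(`base-case`, `psa`, `dsa`, `breakeven` subcommands).

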