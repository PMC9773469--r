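# survjack

Jackknife (leave-one-out cross-validation) estimation of the value of
individualized treatment rules for right-censored survival outcomes, with
inverse probability of censoring weighting.

## The problem

Precision medicine asks which of two treatments each patient should get. A
candidate rule `d(X) ∈ {0, 1}` is judged by its *value* — the expected
outcome if everyone were treated per the rule. With a survival outcome
restricted at a horizon τ, `T = min(T̃, τ)`, the value is

    V(d) = E[ T · 1{A = d(X)} / P(A | X) ].

Estimating V(d̂) honestly requires out-of-sample decisions, and censoring
deletes exactly the long survival times the value rewards. `survjack`
scores each subject with a rule trained on the other n − 1 subjects and
re-weights observed events by the inverse probability of remaining
uncensored:

    V̂ʲᵏ = Σᵢ Uᵢ / Σᵢ Wᵢ,
    Wᵢ  = 1{Aᵢ = d̂⁽⁻ⁱ⁾(Xᵢ)} / P(Aᵢ|Xᵢ) · δᵢ / S_c(Tᵢ|Xᵢ,Aᵢ),
    Uᵢ  = Tᵢ · Wᵢ,

with variance from the influence residuals
`Rᵢ = Uᵢ/W̄ − Ū Wᵢ/W̄²`, `Var = Σ Rᵢ² / (m(m−1))`, and a paired Z-test
`(V̂₁ − V̂₂) / √(Σ(R₁ᵢ−R₂ᵢ)²/(m(m−1)))` for comparing two rules fitted by
different learners (random survival forest, Cox regression with treatment
interactions, or the one-size-fits-all zero-order model — each recommending
the arm with the larger restricted mean survival time). A partial jackknife
(`partial_r`) scores a random subset to cut computation on large samples.

The package is aimed at biostatisticians evaluating and comparing
treatment-rule learners on randomized or observational survival data, and
at simulationists reproducing the method's operating characteristics
(consistency, variance calibration, normality of the test statistic, power
patterns) from the built-in scenario generators.

## A worked example

```r
library(survjack)

d <- simulate_scenario(1, n = 120, censoring = 0.2, seed = 7)  # AFT, tau = 1.8
w <- estimate_weights(d)   # logistic propensity + Cox censoring model + 90% winsorization

est_cox <- jackknife_estimate(d, itr_learner("cox"), weights = w, seed = 1)
est_zom <- jackknife_estimate(d, itr_learner("zom"), weights = w, seed = 1)

glance(est_cox)
#> # A tibble: 1 × 7
#>   learner value     se variance     m     n   tau
#>   <chr>   <dbl>  <dbl>    <dbl> <int> <int> <dbl>
#> 1 cox      1.12 0.0492  0.00242   120   120   1.8

glance(est_zom)
#> # A tibble: 1 × 7
#>   learner value     se variance     m     n   tau
#>   <chr>   <dbl>  <dbl>    <dbl> <int> <int> <dbl>
#> 1 zom      1.03 0.0469  0.00220   120   120   1.8

tidy(z_test(est_cox, est_zom))
#> # A tibble: 1 × 8
#>   learner_1 learner_2 value_1 value_2 statistic p_value se_diff     m
#>   <chr>     <chr>       <dbl>   <dbl>     <dbl>   <dbl>   <dbl> <int>
#> 1 cox       zom          1.12    1.03      2.10  0.0358  0.0433   120
```

Read: the Cox-learned rule's estimated value is 1.12 restricted survival
time units (upper-bounded by the scenario's restricted optimal value
≈ 1.118 up to sampling error), the one-size-fits-all rule's is 1.03, and
the paired Z-test (statistic 2.10, p = 0.036) suggests that on this draw
tailoring beats the best single arm at the 5% level.

Batch studies use `run_power_grid()` (per-cell power, value distributions,
per-replicate records), `qq_data()` + `autoplot()` for normality of the
statistic, and `plot_value_distribution()` / `plot_power_curves()` for the
standard displays. `inst/cli/survjack.R` wraps simulate / estimate /
compare / experiment for shell use.

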