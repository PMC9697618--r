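# nlivr

Simulation and exact-power machinery for evaluating an average-bioequivalence
(ABE) acceptance rule for narrow therapeutic index (NTI) drugs in which the
acceptance limits are **narrowed in proportion to the within-subject
variability of the reference product**, with an optional constraint on the
geometric mean ratio (GMR) point estimate.

## The decision rule

For NTI drugs the conventional 80.00–125.00% acceptance range is considered
too permissive, and a fixed tighter range of 90.00–111.11% is commonly
applied instead. The scaled alternative evaluated here estimates the
within-subject log-scale standard deviation of the reference product,
`s_WR`, in the same replicate trial and sets the limits for the 90%
confidence interval of the GMR to

```
[L, U] = exp(∓ k · s_WR),   k = 0.760
```

subject to a floor and a cap that make the rule continuous:

* `s_WR ≤ 0.1386` (WSCV ≤ 13.93%): the tighter 90.00–111.11% range applies;
* `s_WR ≥ 0.29356` (WSCV ≥ 30%): the conventional 80.00–125.00% range applies;
* in between: the scaled limits above.

Optionally, the GMR point estimate itself must also lie within
90.00–111.11%. Because the limits depend on an *estimated* variance they are
random variables, so the two one-sided tests (TOST) procedure is no longer
exact and the rule's power, consumer's risk (type-I error, T1E) and sample
size requirements have to be studied by simulation. The package implements
that study for the 2×3×3 partial replicate crossover design (sequences
TRR/RTR/RRT), the smallest standard design in which `s_WR` is estimable:

* `nlivr_criterion()`, `fixed_criterion()`, `acceptance_limits()` — the
  limit geometry;
* `simulate_trial()` / `analyze_trial()` — a subject-level data engine and
  its ANOVA (the gold standard), matching `lm()` to machine precision;
* `draw_summary_stats()` — a fast engine that draws the analysed statistics
  directly from their exact joint sampling law;
* `decide_be()`, `tost_ci()` — the TOST decision;
* `be_power()`, `be_t1e()`, `estimate_power()`, `estimate_t1e()` —
  Monte-Carlo power/T1E surfaces over (n, CV) grids, with common random
  numbers across criteria and order-insensitive seed substreams;
* `owens_q()`, `exact_tost_power()`, `sample_size_fixed()`,
  `sample_size_scaled()` — exact Owen's-Q power for fixed limits and the
  simulation-based minimal-balanced-n search for the scaled rule;
* a command line (`exec/nlivr`, see `?run_cli`) with `power`, `t1e`,
  `samplesize`, `decide` and `simulate` subcommands.

## Worked example

Analyse a bundled (synthetic) 24-subject trial and apply the scaled rule
with the point-estimate constraint:

```r
library(nlivr)

trial <- read_trial_csv(system.file("extdata", "example_trial_synthetic.csv",
                                    package = "nlivr"))
stats <- analyze_trial(trial)
stats
#>       pe  se_pe df_pe  s2_wr df_wr     n
#> 1 0.0188 0.0398    45 0.0204    21    24

decide_be(stats, nlivr_criterion(pe_constraint = TRUE))
#>   point_estimate ci_lower ci_upper range_lower range_upper regime bioequivalent
#> 1           1.02    0.953     1.09       0.897        1.11 scaled TRUE
```

The estimated `s_WR` is `sqrt(0.0204) = 0.143`, just above the lower switch,
so the limits scale to `exp(±0.76·0.143)` = 89.7–111.5%; the 90% CI
(95.3–108.9%) and the point estimate (101.9%) both fall inside, so the trial
concludes bioequivalence.

Sample sizes show the point of the rule. For a true GMR of 0.95 and a
reference WSCV of 25%, 80% power requires:

```r
tidy(sample_size_scaled(gmr = 0.95, cv = 0.25, nlivr_criterion(), seed = 42))
#>     gmr    cv     n achieved_power target_power method
#> 1  0.95  0.25    36          0.825          0.8 simulated

tidy(sample_size_fixed(gmr = 0.95, cv = 0.25))   # fixed 90.00–111.11% rule
#>     gmr    cv     n achieved_power target_power method
#> 1  0.95  0.25   195          0.804          0.8 exact
```

36 subjects under the scaled rule against 195 under the fixed tighter
limits. The price is a consumer-risk inflation concentrated just above the
lower switch point:

```r
estimate_t1e(n = 72, cv = 0.14, nsims = 1e5, seed = 7)
#>   criterion engine  n   cv   gmr   nsims prop_be    mc_se
#> 1 nlivr    summary 72 0.14 0.900 100000  0.0722 0.000819
```

a 7.2% rejection rate at the null boundary where an exact-level procedure
would give 5% (the one-sided significance bound for 1e5 simulations is
`inflation_threshold(1e5)` = 0.0511).

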