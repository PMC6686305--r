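# temponull

Null-model analysis of **temporal species associations** in community time
series. Given species-by-year matrices of breeding densities (the output of
long-term territory-mapping censuses), temponull asks whether species
co-occur and covary across years more (*aggregation*), less
(*segregation*), or no differently (*random*) than expected under
randomizations that hold part of the matrix structure fixed — the standard
way to test whether communities are driven by compensatory, correlated, or
random dynamics. It is aimed at community ecologists analyzing long-term
census data or studying the behaviour of co-occurrence null models
themselves.

## What it implements

**Binary indices** on presence/absence matrices, each with its null
ensemble and a two-tailed empirical test:

- `CHECKER` — species pairs that never co-occur;
- C-score — mean checkerboard units per pair,
  `CU = (r_i − S_ij)(r_j − S_ij)`;
- V-ratio — `Var(yearly species totals) / Σ_i Var(occurrence of species i)`.

**Randomizations**: `SIM2` (row sums fixed, years equiprobable) and `SIM9`
(both marginals fixed) via a sequential-swap Markov chain whose symmetric
proposal samples the fixed-marginal ensemble uniformly.

**Quantitative indices** on count matrices with one-tailed tests per
direction: standardized abundance checkerboards and aggregations
(`CA_ST`, `AA_ST`, counts of 2×2 submatrices with opposing/concordant
abundance shifts) and `MA`, the n-community Morisita–Horn similarity of
year compositions. **Randomizations**: `IT` (individuals placed with
probability ∝ row total × column total until both marginals are met) and
`IA` (only the grand total constrained).

Downstream, outcomes from the 5 binary and 6 quantitative
index × algorithm combinations across data sets and foraging guilds are
tabulated and fed to **Bayesian logistic meta-analyses** (binomial,
baseline-category multinomial, and a binomial GLMM with a per-dataset
random intercept) under Cauchy(0, 25) priors — robust to the complete
separation that guild outcome tables produce — fitted by an adaptive
random-walk Metropolis sampler and compared by DIC. A synthetic community
generator with compensatory / correlated / random regimes makes the whole
pipeline testable without any data download.

## Worked example

Simulate a 24-species, 40-year community with compensatory dynamics
(balanced opposite responses to a shared driver within foraging guilds,
persistent territory-count observation), then test it:

```r
library(temponull)
set.seed(2024)

g <- generate_community(
  sim_config("compensatory", n_species = 24, n_years = 40,
             env_sd = 1, obs_model = "territory", n_tracing = 0),
  dataset_id = "beech_forest")
x <- g$matrix

characteristics(x)
#> # A tibble: 1 × 8
#>   dataset_id   plot_size_ha n_species n_years matrix_size prop_zeros mean_density
#>   <chr>               <dbl>     <int>   <int>       <int>      <dbl>        <dbl>
#> 1 beech_forest           10        24      40         960      0.285         2.57

run_binary_null(binarize(x), index = "C_SCORE", algorithm = "SIM9",
                n_sim = 2000, seed = 1)
#> <null_result> C_SCORE / SIM9 on 'beech_forest'
#>   observed 29.0870 | null 24.7051 +/- 0.3385 (n_sim 2000)
#>   p_low 1, p_high 0.0004998, p_two 0.0009995 -> segregation (two-tailed, alpha 0.05)

cm <- scale_to_counts(x, scale_factor = 1)   # counts are already integers
run_quant_null(cm, index = "CA_ST", algorithm = "IT", n_sim = 2000, seed = 2)
#> <null_result> CA_ST / IT on 'beech_forest'
#>   observed 0.2598 | null 0.2012 +/- 0.0057 (n_sim 2000)
#>   p_low 1, p_high 0.0004998 -> segregation (one-tailed, alpha 0.05)

grid <- run_quant_grid(cm, n_sim = 2000, seed = 3)
tabulate_outcomes(grid)
#> # A tibble: 3 × 4
#>   outcome         n n_group   pct
#>   <chr>       <int>   <int> <dbl>
#> 1 aggregation     0       6     0
#> 2 random          0       6     0
#> 3 segregation     6       6   100
```

The observed C-score sits ~13 SD above its fixed-marginal null
(p = 0.001, the smallest value a 2,000-replicate two-tailed add-one test
can produce), and every quantitative combination classifies the community
as segregated — the compensatory signal planted by the generator.
`run_null_study()` scales this to a manifest of data sets (optionally per
guild), returning a tidy outcome table with per-dataset covariates ready
for `fit_bayes_binomial()` / `fit_bayes_multinomial()` /
`fit_bayes_glmm()`, and `inst/cli/temponull.R` exposes the same pipeline
as shell commands (`simulate`, `run-null`, `run-guilds`, `summarize`,
`meta-glm`).

See the vignette (`vignettes/temporal-association-nulls.Rmd`) for the
models, priors, chain presets, and the design of the synthetic generator.

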