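# sirel — single-item reliability estimation and simulation

Single-item assessments (one Likert item measuring a whole construct) are
common in organizational, clinical and educational psychology, but their
reliability cannot be estimated by internal consistency, and test–retest
designs are often impossible for transient constructs. `sirel` estimates
the reliability of a single item from one administration of the item
together with a multi-item scale of the same construct, using five
estimators, and ships the Monte Carlo machinery to compare them.

With $\rho_{xx} = \sigma_T^2/\sigma_X^2$ the classical true-score to
observed-score variance ratio, the estimators are:

* **CA** — correction for attenuation: $r_{yy} = r_{xy}^2 / r_{xx}$, with
  $r_{xy}$ the Pearson correlation between the single item and the scale's
  total score and $r_{xx}$ the scale's Cronbach $\alpha$ (or Guttman
  $\lambda_2$).
* **FA** — the single item's communality from one-factor iterated
  principal-axis factoring of all items' correlation matrix.
* **DMM** — the double-monotonicity estimator: the unobservable test–retest
  joint cumulative probabilities $\pi_{x(i)y(i')}$ are reconstructed from
  neighboring cells of the marginal-ordered joint cumulative probability
  grid (eight ratio/complement-ratio estimates, averaged and clipped into
  $[P_r P_c, \min(P_r, P_c)]$), then
  $\rho_{ii'} = \sum_{x,y}(\pi_{x(i)y(i')} - \pi_{x(i)}\pi_{y(i)}) / \sigma^2_{x_i}$.
* **L6** — Guttman's $\lambda_6$ for the single item:
  $\sigma_i' \Sigma_{ii}^{-1} \sigma_i / \sigma^2_{x_i}$.
* **LCM** — a $Q$-class latent class model fitted by EM; the implied
  same-item joint cumulative probabilities
  $\sum_q P(q) P(X \ge x|q) P(X \ge y|q)$ are pushed through the same
  reliability formula.

A graded-response-model simulator generates 5-point item scores under a
36-condition design (scale length 6/12/18, equal vs. unequal
discrimination, latent correlation 0.65/0.75/0.85 between the two
constructs, n = 400/1000), and the study harness compares the estimators
on median/IQR of bias and relative bias, boxplot-outlier rate, and the
standard deviation of absolute errors, selects the most precise method per
condition via Kruskal–Wallis tests with Dunn/Holm post-hocs, and regresses
bias on the design factors. See the vignette
(`vignettes/single-item-reliability.Rmd`) for the model details and design
choices.

## Worked example

```r
library(sirel)
set.seed(1)
pm <- draw_item_params(15, "multi")    # 18 equally discriminating items
ps <- draw_item_params(15, "single")   # the single item, a ~ U[0.4, 2.8]
scores <- simulate_scores(15, pm, ps)  # 400 persons x 19 items, rho = 0.85
estimate_reliability(scores, method = c("ca", "fa", "dmm", "l6"))
#> # A tibble: 4 × 4
#>   method estimate   raw diagnostics
#>   <chr>     <dbl> <dbl> <list>
#> 1 CA        0.461 0.461 <named list [3]>
#> 2 FA        0.458 0.458 <named list [3]>
#> 3 DMM       0.328 0.328 <named list [4]>
#> 4 L6        0.406 0.406 <named list [3]>
```

For this draw the single item's true reliability (Monte Carlo over the
latent trait; `true_reliability(ps)`) is 0.58, so all four estimates
underestimate — CA and FA by about 0.12 (the latent correlation of 0.85
attenuates CA by roughly $1 - \rho^2 \approx 0.28$ in relative terms), DMM
by more here because this item's discrimination is well above its
neighbors'. Which method is least biased varies with the drawn item
parameters; that is exactly what the study harness quantifies:

```r
res  <- run_study(conditions = c(1, 15), n_reps = 200, root_seed = 20240101)
summarize_condition(res)     # median/IQR bias, outlier %, RMSE per method
select_all_conditions(res)   # most precise method(s) per condition
```

The worked 4-item example grid used throughout the tests is shipped as a
fixture:

```r
jm <- load_fixture("mokken_4item")$payload
estimate_cell(jm, 1, 5)
#> $estimate 0.2   $raw_mean 0.211   $lower 0.12   $upper 0.2   $clipped TRUE
```

A thin CLI wraps the same functions:

```sh
Rscript inst/scripts/sirel.R simulate --condition 1 --reps 10 --seed 7 --out sims/
Rscript inst/scripts/sirel.R estimate --scores sims/condition01_rep0001.csv --method all
Rscript inst/scripts/sirel.R study --conditions 1,15 --reps 200 --seed 7 --out results.csv
Rscript inst/scripts/sirel.R report --results results.csv --out report.md
```

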