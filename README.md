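# sepsurv

Identifying genes with a common prognostic effect across several survival
studies is hard when the studies differ in size: hazard-ratio rankings ignore
the variability of the data, and every test statistic (and hence every
p-value ranking) grows with the sample size, so large cohorts dominate any
intersection of per-study gene lists. `sepsurv` implements a **separability
index** for censored time-to-event outcomes that is designed to be stable in
the sample size, so that per-study rankings can be intersected on a common
scale. It is aimed at biostatisticians screening gene-expression cohorts
(genes × samples matrices with a follow-up time and 0/1 event indicator per
sample), but applies to any single-covariate survival screen.

## The index

For one covariate \(Z\), let \(t_1 < \dots < t_N\) be the distinct observed
times, \(D_j\) the subjects failing at \(t_j\) (\(d_j = |D_j|\)), and
\(R_j\) the risk set (\(n_j = |R_j|\)). The score contribution of \(t_j\) to
the Breslow partial likelihood at \(\beta = 0\) is

\[ U_j = \sum_{i \in D_j} Z_i - d_j \bar Z_{R_j}
      = \frac{d_j (n_j - d_j)}{n_j}\,(\bar Z_{D_j} - \bar Z_{R^*_j}), \]

a scaled difference between the mean covariate of the subjects failing at
\(t_j\) and of those at risk but not failing. The global statistic
\(\Delta_0 = \sum_j U_j\) is rewritten as a sum of Lin–Wei robust score
components \(W_j\) (identical in total, approximately i.i.d. across times),
which gives a robust score test
\(S_0 = (\sum_j W_j)^2 / \sum_j W_j^2 \sim \chi^2_1\) under the null.
The index is

\[ \mathrm{index} = \frac{|\Delta_0|}{D_{max}} \in [0, 1], \]

where \(D_{max}\) is the value \(\Delta_0\) would take if, at every failure
time, the failing subjects were the members of the risk set with the most
extreme covariate values in the direction of the observed effect (the
\(\beta \to \infty\) limit). It reads as the percentage of separation over
time between the failing and the surviving subjects, with the direction of
the effect (HR above/below 1) reported separately.

The package also provides the four classical likelihood-based
predictive-accuracy indices used as comparators (Allison
\(1 - e^{-LR/n}\), modified Allison \(1 - e^{-LR/k}\), Nagelkerke, and the
Kullback–Leibler-based Xu–O'Quigley index), calibrated survival simulators
(proportional hazards and proportional odds with uniform or exponential
censoring solved for a target censoring fraction), a synthetic two-study
gene-expression generator with clumpy dependence and quantile normalization,
and the cross-study machinery: Storey q-values, intersection meta-selection,
the Blangiardo–Richardson observed/expected ratio curve, and TPF/TNF
operating characteristics.

## Worked example

A single simulated covariate with hazard ratio 3 under 25% uniform
censoring:

```r
library(sepsurv)
d <- simulate_survival(500, model = "ph", hr = 3,
                       censoring = "uniform", p_c = 0.25, seed = 42)
separability_index(d, z)
#> # A tibble: 1 × 6
#>   delta0  dmax index direction score_stat  p_value
#>    <dbl> <dbl> <dbl> <chr>          <dbl>    <dbl>
#> 1   89.2  240. 0.371 HR>1            136. 2.39e-31
```

The covariate separates failing from surviving subjects at about 37% of its
theoretical maximum over time; the robust score test rejects the null
decisively, and the effect is adverse (`HR>1`).

Cross-study selection on the bundled two-study generator (150 and 50
subjects, 1,000 genes of which the first 100 are truly prognostic):

```r
ex <- simulate_meta_example(effect = 5, model = "ph", rho = 0.5, seed = 7)
screens <- lapply(ex$studies, function(s)
  separability_screen(s$expression, s$survival))
long <- dplyr::bind_rows(screens, .id = "study")

ir <- intersection_ratio(long, index)   # observed/expected common genes
attr(ir, "chosen")                      # loosest top fraction with ratio > 2
#> [1] 0.2
sel <- meta_select(long, index, ir$threshold[ir$top_fraction == 0.2])
tpf_tnf(sel$gene, ex$truth)
#> # A tibble: 1 × 3
#>     tpf   tnf n_selected
#>   <dbl> <dbl>      <int>
#> 1  0.88 0.949        134
```

At the chosen threshold the intersection recovers 88% of the truly
prognostic genes while keeping 95% of the non-prognostic ones out.
`autoplot(ir)` draws the ratio curve; `run_index_study()` reproduces the
index-comparison simulation tables, and
`meta_operating_characteristics()` the TPF/TNF comparison of all five
indices.

A thin command-line wrapper over these functions is installed under
`inst/cli/sepsurv.R` with `compute`, `meta`, `simulate` and `make-fixture`
subcommands.

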