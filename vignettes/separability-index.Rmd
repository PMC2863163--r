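---
title: "A separability index for censored outcomes and cross-study gene selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A separability index for censored outcomes and cross-study gene selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepsurv)
```

## Motivation

Meta-selection of prognostic genes across heterogeneous survival cohorts
needs a per-gene criterion that (i) reflects both the magnitude of the
effect and the variability of the data, and (ii) does not grow with the
sample size, so that rankings from a 300-patient cohort and a 30-patient
cohort can be intersected on a common scale. Test statistics and p-values
fail (ii); raw hazard ratios fail (i). The separability index implemented
here is built from the score of the Cox partial likelihood but normalized
by a data-dependent maximum, which makes it an effect-size-like quantity
on $[0, 1]$.

## The model and the statistic

One covariate $Z$ (one gene) per model. Follow-up is
$\tilde X_i = \min(T_i, C_i)$ with event indicator
$\delta_i = 1\{T_i \le C_i\}$ and independent censoring. Ties are handled
throughout by the Peto–Breslow convention: at each of the $N$ distinct
observed times $t_j$, the $d_j$ failures at $t_j$ share the risk-set
denominator $R_j$ (subjects with $\tilde X_i \ge t_j$; subjects censored at
$t_j$ stay in $R_j$). The per-time score contributions at $\beta = 0$,

$$U_j = \sum_{i \in D_j} Z_i - d_j \bar Z_{R_j}
      = \frac{d_j(n_j - d_j)}{n_j}\left(\bar Z_{D_j} - \bar Z_{R^*_j}\right),$$

measure how far the covariate separates the subjects failing at $t_j$ from
those at risk but not failing. Their sum $\Delta_0 = \sum_j U_j$ is the
score statistic of the Breslow partial likelihood at $\beta = 0$.

Because the $U_j$ are serially dependent, the package rewrites $\Delta_0$
as a sum of robust components: the Lin–Wei score residuals at $\beta = 0$,
aggregated over the subjects exiting (failing or censored) at each
distinct time,

$$W_j = U_j - \sum_{t_l \le t_j} \frac{d_l}{n_l}
        \sum_{i \in E_j} (Z_i - \bar Z_{R_l}).$$

The subtracted term is a weighted average of score contributions at earlier
times; summing the inner residuals over all subjects shows that
$\sum_j W_j = \sum_j U_j$ *exactly* — this identity is enforced to machine
precision in the test suite, and in the absence of ties the $W_j$ equal the
per-subject Lin–Wei residuals aggregated by exit time (an independent
per-subject implementation is the test oracle). The robust score statistic
$S_0 = (\sum_j W_j)^2 / \sum_j W_j^2$ is referred to $\chi^2_1$; its
p-values feed the per-gene q-values.

## The normalization constant

The index is $|\Delta_0| / D_{max}$, where $D_{max}$ is the value the sum
of score components takes in the limit of perfect separation: at every
failure time the $d_j$ failing subjects are replaced by the $d_j$ members
of the observed risk set with the most extreme covariate values in the
direction of the observed effect ($\mathrm{sign}(\Delta_0)$), i.e. the
$\beta \to \infty$ limit conditioned on the observed risk sets. Term by
term this dominates $U_j$, so $D_{max} \ge |\Delta_0|$ and the index lies
in $[0, 1]$; it equals 1 exactly on data where the high-covariate group
fails first and empties as failures occur, and approaches 1 on simulated
proportional-hazards data with extreme effects ($e^\beta = 50$ gives a mean
index above 0.85 at $n = 200$). The index is invariant to location-scale
changes of the covariate, and the direction of the effect is reported
separately (`HR>1` / `HR<1`), so protective and adverse effects are ranked
on the same nonnegative scale.

Two design points deserve emphasis.

* **Conditioning on the observed risk sets.** $D_{max}$ keeps the observed
  censoring pattern and risk-set composition and only reassigns which
  members fail. A tighter alternative — sequentially removing the extreme
  members so that the high group empties as it fails — yields a smaller
  maximum and a larger index; a looser alternative — bounding each
  mean difference by the covariate range — yields a much larger maximum
  under which the index can no longer approach 1 on proportional-hazards
  data. The implemented choice is the only one of the three that keeps
  both the $[0,1]$ range with an attainable upper end and the monotone
  approach to 1 with growing effects. **The absolute scale of the index is
  therefore tied to this normalization choice**: under it, a Bernoulli(0.5)
  covariate with hazard ratio 1.5 at $n = 1{,}000$ has a mean index near
  0.17 (near 0.024 under the null), and thresholds quoted for one
  normalization do not transfer to another. Rankings, which drive the
  meta-selection, are far less sensitive.
* **Orientation.** $\Delta_0$ is signed (negative for protective effects);
  the index uses $|\Delta_0|$ so that one threshold applies to both
  directions, with concordance of directions across studies reported by
  `meta_select()`. A consequence is that the null mean of the index is a
  small positive number of order $1/\sqrt{n}$ (folded-normal noise over a
  $O(n)$ maximum), not exactly 0.

## Comparison indices

Four likelihood-based predictive-accuracy measures are evaluated at the
one-covariate Cox MLE (Newton–Raphson from $\beta = 0$ on the Breslow
partial likelihood, tolerance $|U| < 10^{-8}$, at most 50 iterations with
step-halving; a monotone likelihood is flagged non-converged with
$\hat\beta$ capped at $\pm 20$):

* Allison: $1 - e^{-LR/n}$;
* modified Allison: $1 - e^{-LR/k}$ with $k$ the **total number of
  failures** (the less censoring-sensitive variant; the count of distinct
  failure times is exposed separately in `glance()`);
* Nagelkerke: Allison divided by $R^2_{max} = 1 - e^{2\ell(0)/n}$;
* Xu–O'Quigley: $1 - e^{-2\Gamma}$, where $\Gamma$ is the Kaplan–Meier-jump
  weighted average over failure times of the Kullback–Leibler divergence
  between the fitted and null conditional failure probabilities
  $\pi_i(\beta, t_j) = e^{\beta Z_i} / \sum_{l \in R_j} e^{\beta Z_l}$;
  the weights are renormalized to sum to 1 over observed failure times
  when the last observation is censored.

## Simulation designs

`simulate_survival()` draws $Z$ either Bernoulli(0.5) or uniform on
$[0, \sqrt 3]$ — both have variance $1/4$, so effects are comparable across
covariate laws — and survival times by inverse transform from
$S(t; z) = e^{-t e^{\beta z}}$ (proportional hazards) or
$S(t; z) = (1 + t e^{\beta z})^{-1}$ (proportional odds, where the hazard
effect wanes with time). Censoring is uniform on $(0, r)$ or exponential
with rate $\gamma$; `solve_censoring_parameter()` solves, by 1-D
root-finding on closed-form or numerically integrated censoring
probabilities marginalized over the covariate law, for the parameter giving
a target expected censoring fraction (e.g. $r \approx 3.92$ for 25% under
the null exponential model). `run_index_study()` evaluates all five indices
on the same replicate datasets, so the differences
$\delta = \text{separability} - \text{competitor}$ are paired, and reports
means, standard errors and 95% CIs.

The two-study generator `simulate_meta_example()` emulates a small
meta-analysis: $n = 150$ and $50$ subjects split into equal low-risk
($\xi = 0$) and high-risk ($e^\xi \in \{3, 5\}$) halves; uniform censoring
calibrated to an expected 30%; 1,000 genes of which 1–50 and 51–100 are
over-expressed in the low-risk group (log-normal with meanlog 4 and 3
versus 0, sdlog 1.5 throughout), 101–150 / 151–250 / 251–350 differ along
random binary subject factors (one factor per block, drawn independently of
risk), and 351–1,000 are noise. Clumpy dependence adds a shared standard
log-normal subject factor per 10-gene block, scaled by $\rho$ (additive
form $Z' = Z + \rho A$); each study is then quantile-normalized
(via limma). What this emulates — block-correlated, heavy-tailed,
quantile-normalized expression with structured non-prognostic factors —
and what it does not — platform/batch effects, probe-level artifacts,
between-study biological heterogeneity — bounds what passing tests show
about real cohorts: they validate the statistics and the selection
machinery, not robustness to cross-platform artifacts.

## Meta-selection

Per-study screens are intersected at quantile (top-fraction) thresholds so
grids are comparable across studies (default 40 points spanning the top
0.5%–20%, ranked with a stable gene-id tie-break). For each threshold the
observed number of genes common to all studies is compared with the count
expected under independent rankings, $E = G \prod_k |S_k|/G$; thresholds
with ratio $> 2$ qualify, and the default choice is the loosest qualifying
one (all qualifying thresholds are exposed, since any finer preference
between them — e.g. clinical relevance of the implied survival difference —
is not computable from the data). Storey q-values use the
$\hat\pi_0(\lambda)$ smoother on $\lambda \in \{0.05, \dots, 0.95\}$ (cubic
smoothing spline, evaluated at the largest $\lambda$, clamped to $(0, 1]$;
with fewer than 100 p-values the estimate falls back to $\pi_0 = 1$, i.e.
Benjamini–Hochberg). TPF/TNF operating characteristics average correct
selections and correct non-selections over simulated iterations of the
two-study example.

## Numerical choices and degenerate inputs

* Distinct times with $d_j = 0$ (censoring-only) are retained in the
  decomposition; they contribute nothing to $\ell$, $U$ or $D_{max}$ but do
  carry robust components $W_j$.
* The inner $\log \sum e^{\beta z}$ is computed with a max-shift;
  suffix sums over the time-sorted subjects make every per-gene quantity
  $O(n \log n)$, and the risk-set decomposition is computed once per study
  and shared across genes.
* A covariate constant on every risk set with a failure has no
  separability scale ($D_{max} = 0$): `separability_index()` errors, and
  `separability_screen()` returns `NA` rows for such genes.
* Ties between failures and censorings at one time place both in $E_j$
  with the censored subjects kept at risk.
* `q_values()` monotonizes q-values from the largest p downwards.
* Genes with missing expression are dropped per study (with a message).

## Study sizes used in the test suite

The packaged checks run the null and hazard-ratio-1.5 summaries at 500
replicates of $n = 1{,}000$; monotonicity across
$e^\beta \in \{1, 1.5, 2, 3, 5\}$ at $n = 500$ (60 replicates per effect);
paired $\delta$ comparisons at $n = 100$ with 200 replicates; null
calibration of the robust score test at $n = 500$ with 1,000 replicates
(the test is asymptotic: at $n = 100$ the 5% level is exceeded by about
1.5–2 points, which is why the calibration study uses a moderate cohort
size); and the meta-selection comparison at 25 iterations of the full
two-study design under both survival models. These sizes are the package's
documented study conditions for its own regression checks; the functions
default to the full designs (e.g. 1,000 replicates, 100 iterations).

## Known limitations

* Single covariate only: no multivariable models, stratification,
  time-varying effects, or baseline-hazard estimation.
* The Breslow tie approximation degrades with heavy ties; the Efron
  correction is deliberately not offered, to keep the score components
  consistent with the index definition.
* The absolute index scale depends on the $D_{max}$ normalization (see
  above); comparisons should be made within one normalization.
* The index targets monotone (proportional-hazards-like) effects; under
  proportional odds it remains usable but attenuated, and crossing-hazards
  effects can cancel within $\Delta_0$.
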