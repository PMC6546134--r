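---
title: "Simulating case-control GWAS summary statistics from reference haplotypes"
author: "sumstatsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating case-control GWAS summary statistics from reference haplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sumstatsim)
```

## The procedure and its assumptions

`sumstatsim` simulates the per-SNP output of a case-control genome-wide
association study — Z scores from the Cochran-Armitage trend test, log odds
ratios, standard errors and p-values — directly from (i) phased reference
haplotypes for a genomic region and (ii) a causal model: a set of causal
SNPs $W$ with log odds ratios $\gamma$, and the study's case and control
counts $N_1$, $N_0$. No individual genotypes are generated at any point, so
the cost of a replicate is independent of $N_0$ and $N_1$.

The statistical assumptions are:

* **Additivity.** Disease risk is logistic-additive in allele dosage across
  causal SNPs: $P(Y=1 \mid G_W = w) = \mathrm{logit}^{-1}(\gamma_0 +
  \gamma\cdot w)$. Dominant/recessive and haplotype-effect models are out of
  scope.
* **Reference equals controls.** The reference panel's haplotype frequencies
  are treated as *control* frequencies. This makes the retrospective
  conditioning closed-form: the case genotype distribution at the causal
  SNPs is $P_1(w) = P_0(w)e^{\gamma\cdot w}/C$ with $C = \sum_w
  P_0(w)e^{\gamma\cdot w}$, and the intercept satisfies $e^{\gamma_0} =
  (N_1/N_0)/C$, so the sample case fraction is exactly $N_1/N$. No population
  prevalence is needed. (The closed form is verified in the tests against a
  numeric root solve of the same normalization.)
* **Hardy-Weinberg random union.** Genotype probabilities — both the joint
  probabilities $P_0(G_X = g \cap G_W = w)$ entering $E(U_X)$ and the
  genotypes of forward-simulated individuals — arise from pairing two
  independently drawn reference haplotypes.
* **Score-Wald asymptotic equivalence.** Log odds ratios and standard errors
  are back-calculated from the score statistic: $\sigma^* =
  1/\sqrt{(N-1)V_X^* V_Y}$ and $\gamma^* = \sigma^* Z^*$, appealing to the
  equivalence of the trend (score) test and the single-SNP logistic Wald
  test, and to the identity that the variance of the score statistic is the
  inverse variance of $\hat\gamma$ under the null.

The deterministic core computes, for every SNP $X$ in the region,

$$E(U_X) = \frac{(N-1)N_0N_1}{N^2}\sum_{w}\left(\frac{e^{\gamma\cdot w}}{C}
  - 1\right)\left[2P_0(G_X{=}2 \cap G_W{=}w) + P_0(G_X{=}1 \cap
  G_W{=}w)\right],$$

the exact first two moments of the genotype sample variance $V_X$ under the
case-control mixture ($N_0$ genotypes i.i.d. from $p_0$, $N_1$ from $p_1$),
a method-of-moments inverse-gamma fit
$\alpha = (2e_2 - e_1^2)/(e_2 - e_1^2)$, $\beta = e_1 e_2/(e_2 - e_1^2)$
(where $e_1 = E(V_X)$, $e_2 = E(V_X^2)$), and the first-order expected Z
score $Z_E = E(U_X)\,E(V_X^{-1/2})/\sqrt{(N-1)V_Y}$ with
$E(V_X^{-1/2}) = \beta^{-1/2}\Gamma(\alpha + \tfrac12)/\Gamma(\alpha)$.
The stochastic layer draws $Z^* \sim \mathrm{MVN}(Z_E, \Sigma)$ with
$\Sigma$ the haplotype-allele (equivalently genotype) correlation matrix,
and $V_X^* \sim \Gamma^{-1}(\alpha,\beta)$ independently per SNP and
replicate.

The exact moments of $V_X$ are derived internally from power sums of the
group genotype moments (inclusion-exclusion over distinct index patterns)
rather than quoted from any external source; they are pinned down by two
independent oracles in the test suite — exhaustive enumeration over all
$3^N$ genotype assignments for $N \le 6$, and Monte-Carlo at moderate $N$.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `n0`, `n1` | control / case counts | 2000 / 2000 | the scale used throughout validation; any values $\ge 1$ work and only enter through closed forms |
| `or` / `log_or` | causal odds ratios | — | the effect sizes under study; enumeration supports $m \le 12$ causal SNPs ($3^m$ genotype vectors) |
| `lambda` | Laplace smoothing of haplotype pattern counts | 0 | plain counting matches the reference panel; small $\lambda$ guards tiny panels against empty causal-genotype classes |
| `clip` (PSD repair) | eigenvalue floor for $\Sigma$ | `1e-8` | finite panels give numerically indefinite correlation matrices; clipping then rescaling to unit diagonal changes a PSD input by $<10^{-6}$ (tested) |
| `n_hap` | synthetic panel haplotypes | 600 | emulates a reference cohort of a few hundred subjects; below 100 a warning is issued |
| `n_rep` | replicates | — | each replicate is one simulated study |
| `seed` | master seed | — | per-component streams (panel, Z, SE, oracle) are derived by fixed offsets and recorded in the JSON sidecar |

## What the synthetic panel generator does and does not emulate

`generate_panel()` thresholds a latent correlated Gaussian vector at
$\Phi^{-1}(1-\mathrm{MAF})$ per SNP (a Gaussian copula), giving exact
marginal allele-frequency control and tunable pairwise LD. Background LD is
an autoregressive latent chain (adjacent-SNP latent correlation 0.9 by
default, decaying geometrically with SNP distance), which is always positive
semi-definite by construction. `scenario_panel()` embeds the five validation
scenarios — causal MAFs, odds ratios, and pairwise correlation $r$ — in such
a background: a linked causal pair is placed adjacent with its latent link
calibrated by bisection against the bivariate-normal orthant probability so
the realized *binary* correlation hits the target; "unlinked" causal SNPs
keep local LD but the chain is cut midway between them.

This emulates the frequency/LD structure a real reference cohort provides,
but **not** coalescent realism: no recombination maps, no allele-frequency
spectrum, no population-specific haplotype blocks. A green validation test
therefore establishes that the direct simulator matches individual-level
forward simulation *conditional on a panel*; it does not establish realism
of any particular panel.

Two scenario-specification caveats discovered during implementation, both
handled explicitly:

* The quoted strong-LD scenario ($r = 0.8$ at MAFs 0.1 and 0.15) is
  infeasible: the Frechet bound on the correlation of two binary variables
  with those marginals is $\sqrt{0.1\cdot0.85/(0.15\cdot0.9)} = 0.7935$.
  The builder clamps the target just inside the bound and warns; the
  realized LD is as strong as the MAF pair permits (~0.79), which preserves
  the scenario's defining feature (near-maximal linkage with opposing
  effects).
* Whether the quoted linkage value is $r$ or $r^2$ is convention-dependent;
  the builder exposes `r_is_r2` (default `FALSE`, the direct $r$ reading).

## Numerical choices

* **Degenerate variance fit.** For near-monomorphic SNPs in tiny panels the
  moment inequality $E(V_X^2) > E(V_X)^2$ can fail numerically; such SNPs
  fall back to a *constant* $V_X = E(V_X)$ (deterministic $\sigma^*$) and are
  flagged, rather than failing the run.
* **$(N-1)$ placement.** $\sigma^{*-2} = (N-1)V_X^* V_Y = V_X^* N_0N_1/N$,
  which is what makes $Z = U/\sqrt{\mathrm{Var}(U)}$ dimensionally
  consistent and gives unit null variance; the forward oracle's Wald
  standard errors confirm this scaling.
* **Rank-deficient LD.** $Z^*$ uses a pivoted Cholesky factor with
  zeroed trailing rows, so perfectly correlated (duplicated) SNPs yield
  *exactly* identical Z columns.
* **Monomorphic SNPs** are dropped at load time with a warning: their
  trend-test variance is zero and no Z score exists.
* **Case sampling in the oracle** is exact rejection from the enriched law:
  accept a haplotype pair with probability $e^{\gamma\cdot w -
  \max_{w'}\gamma\cdot w'}$. This provably targets $P_1(w)$ without
  simulating a population and discarding individuals; a guard rejects
  models whose mean acceptance probability underflows ($<10^{-6}$).
* **Logistic Wald fits** use Newton-Raphson on the collapsed genotype
  $\times$ phenotype table to gradient norm $<10^{-8}$, with observed-
  information standard errors; separation is detected both by divergence and
  by gradient vanishing at saturated fitted probabilities ($|\hat\beta| >
  15$) and flagged `NA`.
* **Integer safety.** All $N_0N_1$ products are computed in double
  precision (they overflow 32-bit integers beyond $N \approx 92$k).

## Design choices where the design was open

* **$E(V_X^{-1/2})$ interpretation.** The gamma-ratio expression used in the
  expected-Z formula is implemented as the $-1/2$ moment of the
  inverse-gamma variance, $\beta^{-1/2}\Gamma(\alpha+\tfrac12)/
  \Gamma(\alpha)$ — the quantity the Z-score denominator actually needs
  ($E(1/V_X)$ proper would be $\alpha/\beta$ and dimensionally wrong).
* **Cross-SNP variance draws** are independent: the LD structure of the
  statistics is carried entirely by the MVN Z draws; variance draws only
  perturb the standard errors.
* **Antisymmetry in $\gamma$** ($Z_E(-\gamma) = -Z_E(\gamma)$) is exact only
  when the haplotype pattern distribution is allele-flip symmetric; on
  general panels it holds to first order. The tests check it exactly on a
  symmetrized panel and loosely on a general one.
* **Closed-form $\gamma_0$** rather than a numeric solve; the two agree to
  $10^{-10}$ (tested), so the choice is one of transparency and speed.

## Known limitations

* $E(Z_X)$ multiplies $E(U_X)$ and $E(V_X^{-1/2})$, ignoring their
  covariance — a first-order approximation. Forward-oracle comparisons at
  1000 replicates show no detectable mean bias, but simulated statistics can
  show slightly heavier variability at the most extreme SNPs than
  individual-level simulation.
* The method targets one region at a time. Genome-wide simulation requires
  splitting chromosomes into approximately independent LD blocks, which is
  left to the user.
* Covariates, non-additive genetic models, imputation uncertainty and
  quantitative (extreme-sampling) designs are out of scope.

All quantitative statements above are computed by the test suite
(`tests/testthat/`, in particular `test-acceptance.R`) or by
`scripts/acceptance.R`; the vignette asserts nothing the code does not
verify.
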