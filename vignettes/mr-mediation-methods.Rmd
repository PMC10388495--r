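---
title: "Methods: summary-statistics MR with multivariable and mediation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summary-statistics MR with multivariable and mediation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The model

Two-sample MR treats genetic variants as instrumental variables for an
exposure. For SNP $j$, let $\gamma_j$ ($\sigma_{\gamma j}$) be its estimated
association with the exposure from one GWAS and $\Gamma_j$
($\sigma_{\Gamma j}$) its association with the outcome from another. Under
the three instrumental-variable assumptions (relevance, independence from
confounders, exclusion restriction), $\Gamma_j = \theta\,\gamma_j$ and each
Wald ratio $\hat\beta_j = \Gamma_j/\gamma_j$ estimates the causal effect
$\theta$. For binary traits the betas are log-odds ratios, so $\theta$ is a
log-OR per unit of exposure and is reported as OR with a 95% CI.

The estimators differ in how they pool the ratios and in which violations
they tolerate:

* **IVW** solves the precision-weighted regression of $\Gamma$ on $\gamma$
  through the origin, $w_j = 1/\sigma_{\Gamma j}^2$. It is efficient when
  all instruments are valid and is the primary analysis. The random-effects
  variant inflates the SE by $\max(1,\sqrt{Q/(J-1)})$ (multiplicative
  overdispersion), so it equals fixed effects when Cochran's $Q \le J-1$ and
  widens smoothly under heterogeneity.
* **MR-Egger** frees the intercept; the intercept estimates average
  directional pleiotropy under the InSIDE assumption, and a significant
  intercept is the pleiotropy alarm. Inference uses $t(J-2)$, matching the
  reduced residual degrees of freedom.
* **Weighted median** is consistent while valid instruments carry more than
  half the total weight $w_j = \gamma_j^2/\sigma_{\Gamma j}^2$. We use the
  midpoint convention ($s_j = \sum_{i\le j} w_{(i)} - w_{(j)}/2$,
  interpolated at 0.5), with ties in the ratio order broken by SNP id for
  determinism.
* **Mode estimators** (simple/weighted) take the argmax of a normal-kernel
  density over the ratios and are consistent when the largest homogeneous
  cluster of instruments is valid.
* **MR-PRESSO** simulates the null distribution of the leave-one-out
  residual sum of squares to give a global pleiotropy p-value, per-SNP
  outlier p-values (Bonferroni-corrected), and a distortion test for the
  estimate shift after outlier removal.

Multivariable MR regresses $\Gamma$ on the $J \times K$ matrix of exposure
betas (no intercept for MV-IVW; with intercept and first-exposure-positive
orientation for MV-Egger), so each coefficient is a direct effect
conditional on the other exposures. The mediation decomposition combines
the univariable total effect $\beta_{XY}$, the exposure-on-mediator effect
$\beta_{XZ}$, and the **MVMR-adjusted** mediator-on-outcome effect
$\beta_{ZY}$:

$$\text{indirect} = \beta_{XZ}\beta_{ZY},\qquad
  \text{direct} = \beta_{XY} - \text{indirect},\qquad
  R = 100\,\frac{\text{indirect}}{\beta_{XY}}\,\%.$$

Using the adjusted rather than univariable mediator effect is required for
the decomposition to be internally consistent: the univariable
mediator-outcome effect already absorbs part of the exposure's effect, and
only the mutually adjusted coefficient makes
$\text{direct} + \text{indirect}$ equal the total. `mediate()` stores the
total as `direct + indirect` so that identity holds bit-exactly.

```{r}
mediate(total = log(0.703), exposure_mediator = log(2.103),
        mediator_outcome_adjusted = -0.277)
```

Note a percentage computed from effects rounded to 3 decimals
(`100*0.206/0.352` = 58.52) differs in the second decimal from the
exact-input value above (58.43); published mediation percentages are often
of the former kind.

## Tunable parameters

| parameter | default | meaning / why |
|---|---|---|
| `p_threshold` | 5e-8 | genome-wide significance for instrument selection |
| `relaxed_p_threshold` | 5e-6 | fallback when fewer than `min_instruments` strict hits (typical for small-case-count outcome GWAS used in reverse analyses) |
| `min_instruments` | 3 | smallest J for Egger and a heterogeneity df ≥ 1 |
| `clump_r2` / `clump_window_kb` | 0.001 / 10000 | discard needs **both** LD ≥ r² and distance ≤ window (kb); conjunction matches the common clumping convention |
| `palindrome_band` | 0.08 | A/T & C/G SNPs with governing eaf in [0.42, 0.58] are strand-ambiguous and removed; "intermediate" is not standardized, so the band is a knob |
| `freq_source` | exposure | which study's frequency governs palindrome decisions (exposure GWAS more often report frequencies) |
| `weak_f_cutoff` | 10 | conventional weak-instrument F threshold; the statistic always flags, removal is pipeline policy (`remove_weak`) |
| `n_boot` | 5000 | parametric-bootstrap replicates for median/mode SEs; seed mandatory |
| `phi` | 1 | mode bandwidth multiplier on 0.9·min(sd, IQR/1.349)·J^(−1/5); 512-point grid padded by 3 bandwidths |
| `n_sim` | 1000 | MR-PRESSO simulations; p-values are floored at 1/(n_sim+1), so outlier flags are only reachable when J × floor < α |
| `alpha` | 0.05 | two-sided significance language in reports; no multiplicity correction across exposure-outcome pairs |

## The synthetic benchmark

`simulate_triplet()` draws, per SNP: a minor-allele frequency uniform on
`maf_range` (default 0.1–0.4, the range where well-powered instruments
live), alleles uniform over distinct ordered pairs (so about a third are
palindromic, as in real data), and a role — exposure instrument (effect
$\gamma_j$, magnitude uniform 0.05–0.15 in SD units, matching the
per-variant effect sizes of strong lipid loci), direct mediator locus, or
direct outcome locus. True associations follow the structural model
$Z = \theta_{XZ} X + \dots$, $Y = \theta_{dir} X + \theta_{ZY} Z + \dots$;
observed betas add normal noise with the standardized-trait SE
$1/\sqrt{2n\,\mathrm{maf}(1-\mathrm{maf})}$, and p-values follow from the
z-statistics. One master seed drives independent per-trait substreams, so
changing one study never perturbs another's draws.

Design choices worth knowing:

* **Mediator- and outcome-specific loci.** A world in which every SNP acts
  only through the exposure cannot identify MVMR (the two exposure-beta
  columns are collinear in truth) and gives the outcome no associations of
  its own for a reverse-direction analysis to select. The generator
  therefore supports `n_mediator_snps` and `n_outcome_snps` with direct
  effects, mirroring the real situation where the mediator disease has its
  own susceptibility loci.
* **Binary traits** are simulated on the log-odds scale with the
  quantitative-trait variance form; `n` should therefore be an effective
  sample size, $4/(1/n_{cases} + 1/n_{controls})$. Exact logistic SEs are
  out of scope; for the calibration questions asked here only the
  noise scale matters.
* **Pleiotropy modes**: balanced $\alpha_j \sim N(0, 0.01^2)$ — roughly two
  to three times the per-SNP sampling SE of a biobank-scale binary GWAS, a
  magnitude that matters without dominating; directional
  $\alpha_j \sim N(s, (s/2)^2)$; InSIDE-violating $\alpha_j$ proportional to
  $\gamma_j$ plus noise. Pleiotropy attaches to exposure instruments, the
  SNPs whose validity is at stake.
* **`paper_shaped_scenario()`** packages truth
  $\theta_{XZ} = \ln 2.103$, $\theta_{ZY} = -0.277$,
  $\theta_{dir} = -0.146$ (implied total $-0.352$, implied proportion
  mediated 58.5%) with study sizes 72,866 / ~101,000 / ~7,400 (the last two
  are effective case-control sizes). Direct outcome loci are drawn at the
  detection margin ($|z| \sim U(3.6, 4.8)$), so the reverse analysis
  usually needs the relaxed threshold — exactly the regime a 1,866-case
  outcome GWAS puts you in.
* **LD** is an input matrix (identity plus configured blocks); betas of
  linked SNPs are *not* correlated in the generator. Clumping logic is
  fully exercised, but the benchmark says nothing about estimator behavior
  under residual LD, reference-panel mismatch, sample overlap, or winner's
  curse — a green suite establishes correctness of the statistical
  machinery under its stated assumptions, not robustness to those
  real-data pathologies.

## Numerical and degenerate-case policy

* P-values are floored at the smallest normalized double; extreme
  z-statistics otherwise underflow `2*pnorm(-|z|)` to an invalid 0.
* Overdispersion scales are floored at 1 (never deflate a fixed-effects SE).
* All-identical Wald ratios give a zero kernel bandwidth; the mode
  estimator then returns the common ratio.
* A single instrument yields the Wald ratio; `mr_ivw()` refuses (J ≥ 2),
  Egger/median/mode need J ≥ 3, MR-PRESSO J ≥ 4. The pipeline skips stages
  whose preconditions fail and logs why, rather than aborting the run.
* If MR-PRESSO flags *every* instrument (possible in heterogeneous
  reverse-direction sets mixing exposure-driven and outcome-specific SNPs),
  the corrected set falls back to the input with a warning.
* Clumping ties (equal p) break by SNP id; the weighted median pre-sorts by
  SNP id — both purely for run-to-run determinism.
* Harmonization resolves non-intermediate palindromes by frequency
  concordance: governing and outcome frequencies on opposite sides of 0.5
  imply a strand flip (= sign flip). With a missing governing frequency the
  palindrome is removed.

## Known limitations

* The delta-method CI for the proportion mediated treats the total and
  indirect estimates as independent; their covariance is not identifiable
  from the summary data alone. When indirect and total have opposite signs
  the proportion is flagged as not interpretable.
* The weighted-median/mode bootstrap resamples betas from their reported
  sampling distributions, which ignores between-study correlation (none in
  a strict two-sample design).
* The Egger intercept test inherits mild anti-conservatism (empirically
  ~6% at α = 0.05) when pleiotropy variance is additive while weights
  assume multiplicative dispersion; this is a property of the standard
  estimator, not of this implementation.
* Joint statements over several confidence intervals (e.g. "both MVMR CIs
  cover") hold at roughly the product of the marginal levels, ~90% for two
  95% intervals, not 95%.
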