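---
title: "Ranking reference genes for RT-qPCR normalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking reference genes for RT-qPCR normalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The model and its assumptions

RT-qPCR reports a quantification cycle Ct per gene and sample; one PCR
cycle corresponds to a factor E (the amplification efficiency, 2 for
perfect doubling) in transcript abundance, so differences in Ct are log
differences in quantity. A *reference gene* is useful when its quantity
varies across samples only through the shared technical/loading component
(RNA input, RT efficiency, pipetting) that also affects every target
gene. All four algorithms implemented here quantify, in different ways,
how far a candidate deviates from that ideal:

* **geNorm** never looks at a gene alone: it scores the pair ratio
  $\log_2(q_j/q_k)$, whose sample SD is zero exactly when two genes share
  the same sample pattern. A gene's M value is its mean pairwise SD over
  all partners; stepwise exclusion of the largest M re-estimates M on the
  shrinking panel until the final pair, which is reported tied. This
  makes geNorm robust to the overall loading shift (it cancels in the
  ratio) but co-regulated gene pairs can protect each other — a known
  caveat of the method, not corrected here.
* **NormFinder** fits the additive model $y_{ij} = \mu_i + b_j + e_{ij}$
  on $y = \log_2 q$ (gene effect, sample effect, residual) and estimates
  a per-gene residual variance with a shared-noise correction,
  $\hat\sigma^2_i = \max\!\big(0,\,(u_i - U/(g(g-1)))\,g/(g-2)\big)$ with
  $u_i$ the per-gene residual variance (denominator $n-1$) and
  $U = \sum_i u_i$; the stability value is $\hat\sigma_i$. Unlike geNorm
  it scores genes individually and is insensitive to co-regulation among
  a minority of candidates. Each species panel here is a single
  condition, so the single-group form of the estimator is the right one;
  the grouped inter/intra-group variant is out of scope.
* **BestKeeper** stays on the raw Ct scale (its published definition) and
  uses robust descriptives: the dispersion `sd_cp` is the *mean absolute
  deviation* about the geometric-mean CP — not the root-mean-square SD,
  which would be ~25% larger for Gaussian noise
  ($\mathrm{E}|x-\mu| = \sigma\sqrt{2/\pi}$). Genes with SD > 1 cycle
  (a two-fold swing) are flagged unusable; remaining genes form the
  BestKeeper index (per-sample geometric mean CP) against which each
  candidate is Pearson-correlated, with two-sided t-based p-values
  ($t = r\sqrt{(n-2)/(1-r^2)}$, $n-2$ df), uncorrected as is conventional
  in these reports.
* The **comparative ΔCt method** averages $\mathrm{SD}(Ct_j - Ct_k)$ over
  all partners $k$. With E = 2 this is *identical* to the full-panel
  geNorm M, since $Ct_j - Ct_k = \log_2(q_j/q_k)$ up to a constant: the
  package exploits the identity as a cross-method oracle in its test
  suite (agreement to 1e-12).
* The **consensus** assigns each gene an integer rank per method —
  geNorm by exclusion order with the final pair sharing rank 1,
  NormFinder/ΔCt by their scores, BestKeeper by `sd_cp` — and aggregates
  by the geometric mean of the four ranks (competition/minimum ranking
  for ties by default; `ties = "average"` is available). The score lies
  between the best and worst rank by construction.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `efficiency` | 2 | fold/cycle | Perfect doubling; the packaged study's printed statistics are reproduced exactly under E = 2, so that is the analysis default. Per-gene factors (from `efficiency_from_slope()` or a `gene,amplification_factor` file) may be supplied; they must lie in (1, 3]. |
| `v_threshold` | 0.15 | V units | Conventional ceiling for the pairwise variation below which adding the (n+1)-th reference gene no longer pays. `recommend_n()` returns the smallest such n, or the gene count flagged `all_above`. |
| `sd_threshold` | 1 | cycles | BestKeeper's exclusion rule: SD > 1 cycle means a two-fold expression swing, too unstable to normalize with. |
| `ties` | `"min"` | — | Competition ranking for the consensus; the tied geNorm final pair both hold rank 1. |

geNorm and the ΔCt method apply their published SD with denominator
$n-1$ throughout; BestKeeper intentionally does not (its SD is a mean
absolute deviation, see above).

## The reported geNorm M series

geNorm offers two per-gene "M values": the gene's own M at the step where
it was excluded, and the *average* M of the panel still in play at that
step — the increasing series that geNorm's stability charts display.
The two differ and the own-M series need not be monotone (on the packaged
cattle panel the 7th and 8th exclusions invert). `genorm()` returns both
(`m_gene` and `m_value`); `m_value`, the chart convention, is the
reported one, and the consensus ranks follow the exclusion order itself,
which is what reproduces the published comprehensive scores. Exclusion
ties (equal largest M) are broken against the gene later in input order,
making the whole procedure deterministic; the tied final pair is reported
in input order.

## Numerical and degenerate-input choices

* Negative NormFinder corrected variances (possible at small g, and
  actually occurring on the packaged yak panel) truncate to stability 0;
  ties at 0 then share the top rank.
* A zero-variance gene has undefined Pearson correlations: reported as
  `NA` with a warning, never silently dropped.
* `|r| = 1` maps to p = 0 rather than tripping the closed form's
  division by zero.
* Missing Ct cells are a hard error naming the gene and sample. All
  algorithms assume a complete matrix; imputation would silently bias
  every statistic, so none is offered.
* Panels need ≥ 3 genes (NormFinder's correction divides by g − 2;
  geNorm's stepwise needs a third gene to exclude) and ≥ 2 samples
  (≥ 3 for correlation p-values).

## The packaged data set

`ladakh_pbmc()` returns the study matrix the package reproduces: 10
candidate genes × 32 PBMC samples across six Himalayan livestock species
(6 cattle, 6 yak, 5 donkey, 5 goat, 5 camel, 5 pony), transcribed at the
3-decimal precision of the published table. Those printed values are the
ground truth from which the study's own statistics were computed — several
are reproduced exactly from them — so no attempt is made to recover more
digits. The per-species analyses run in well under a second each; the
full six-species pipeline plus consensus completes in a few seconds on
one CPU.

## What the synthetic generator emulates — and what it does not

`simulate_ct()` draws
$Ct_{gs} = \beta_g + b_s + e_{gs}$, $b_s \sim N(0, \tau)$,
$e_{gs} \sim N(0, \sigma_g)$: a per-gene baseline, a shared per-sample
loading shift (additive on the Ct scale = multiplicative on quantities,
exactly the component geometric-mean normalization factors remove), and
independent per-gene Gaussian noise. Defaults are chosen to mirror the
packaged data: 10 genes × 6 samples, baselines uniform on 14–30 cycles
(the observed Ct range), τ = 0.5 cycles (a realistic ~1.4-fold loading
spread), and σ_g spread evenly from 0.05 to 1 cycle so the panel spans
near-perfect to clearly unstable candidates.

This is the statistical structure the four algorithms *assume*. Real
data also contain co-regulated gene groups, heteroscedastic and outlying
Ct values, plate effects and amplification-efficiency error — none of
which the generator models (v1 deliberately has no outlier or dropout
component). Passing the parameter-recovery tests therefore shows the
estimators recover their own model's parameters (Spearman correlation
between injected σ_g and estimated stability > 0.8 at 10 genes ×
20 samples in ≥ 45 of 50 seeded replicates, via
`recovery_experiment()`); it does not certify behaviour under model
violations, which is why validation against the packaged real data set
is tested independently.

## Problem sizes used in the test suite

Simulation-backed tests run at desk scale chosen once: 50 replicates of
10 × 20 panels for parameter recovery, 20 seeds of 3 × 50 panels for the
large-n geNorm consistency check, and one 3 × 200 panel for the Gaussian
mean-absolute-deviation calibration of BestKeeper's SD
(within 3 standard errors of $\sigma\sqrt{2/\pi}$). All seeds are fixed
in the tests.

## Known limitations

* geNorm's co-regulation blindness (above) is inherent to the method;
  the consensus mitigates but does not remove it.
* The grouped (multi-condition) NormFinder estimator and its two-gene
  combined recommendation are not implemented.
* BestKeeper's regression of each gene on the index (intrinsic-variance
  decomposition) and weighted index variants are not implemented.
* Efficiency estimation itself (from dilution series or raw fluorescence)
  is out of scope; only the slope → E conversion
  $E = 10^{-1/\text{slope}}$ is provided, and published efficiency
  tables computed from unrounded slopes will not be matched exactly by
  applying it to rounded slopes.
* The consensus follows the strict "smallest n with V < 0.15" rule for
  `recommend_n`; a practitioner may still prefer a third gene when V
  values hover near the threshold, as domain judgement sometimes does.
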