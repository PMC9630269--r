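# refstab

Reference-gene stability analysis for RT-qPCR normalization.

## The problem

Relative quantification by RT-qPCR reports a target gene's expression as a
ratio against one or more *reference genes* assumed stable across samples.
Choosing those references badly silently distorts every downstream fold
change, and no gene is universally stable — each tissue, condition and
species needs its own validated panel. `refstab` takes a genes × samples
matrix of quantification-cycle values (Ct/Cq) with a sample→group
annotation and ranks the candidate genes with the four algorithms the
field standardly combines, plus their consensus:

- **geNorm** — gene *j*'s stability is
  M<sub>j</sub> = mean<sub>k≠j</sub> SD<sub>s</sub>[ log₂(q<sub>js</sub>/q<sub>ks</sub>) ],
  on relative quantities q = E^(minCt − Ct); the least stable gene is
  removed repeatedly until the best pair remains. The pairwise variation
  V(n/n+1) = SD[ log₂(NF<sub>n</sub>/NF<sub>n+1</sub>) ] between
  geometric-mean normalization factors built from the top n and n+1 genes
  tells how many references are enough (V < 0.15 by convention).
- **NormFinder** (single group) — a model-based variance per gene after
  removing gene and sample main effects from log₂ q, with shared-variance
  correction; stability = √ of the corrected variance.
- **BestKeeper** — descriptive statistics on *raw* Ct: the SD is the mean
  absolute deviation about the geometric-mean CP, genes with SD > 1 cycle
  are excluded, all gene pairs and each gene against the geometric-mean
  BestKeeper index are Pearson-correlated with t-based p-values.
- **comparative ΔCt** — mean over partners of SD(Ct<sub>j</sub> −
  Ct<sub>k</sub>); with E = 2 this is algebraically the full-panel geNorm M.
- **consensus (RefFinder-style)** — the geometric mean of a gene's four
  method ranks (competition ranking for ties).

The package ships the study data it was validated against: Ct values for
10 candidate genes in PBMCs of 32 animals from six livestock species
native to the trans-Himalayan Leh-Ladakh region (`ladakh_pbmc()`), and a
synthetic Ct generator for parameter-recovery experiments.

## Worked example

```r
library(refstab)
fit <- refstab(ladakh_pbmc())     # all four methods + consensus, per species
summary(fit)
```

```
 group n_samples n_genes  genorm_top genorm_n normfinder_top bestkeeper_top
   LAC         6      10 EEF1A1/RPL4        2         EEF1A1          RPS15
   LAY         6      10  GAPDH/RPS9        3          GAPDH            UXT
   LAD         5      10   B2M/HPRT1        3          HPRT1           ACTB
   CHG         5      10  HPRT1/RPS9        2           RPS9           RPS9
   DHC         5      10    B2M/RPS9        3          HPRT1          HPRT1
   ZAP         5      10   RPL4/RPS9        2         EEF1A1            UXT
 deltact_top      consensus_top3
      EEF1A1 EEF1A1, RPL4, RPS23
       GAPDH   GAPDH, RPS9, ACTB
       HPRT1    HPRT1, B2M, ACTB
        RPS9   RPS9, HPRT1, ACTB
       HPRT1    HPRT1, ACTB, B2M
        RPS9     RPS9, RPL4, UXT
```

Each row is one species panel: `genorm_top` is the most stable gene pair
(tied by construction), `genorm_n` the number of reference genes whose
combined normalization factor is sufficient (smallest n with
V(n/n+1) < 0.15), and `consensus_top3` the genes a practitioner would
normalize with. Drilling into one panel:

```r
lac <- subset_group(ladakh_pbmc(), "LAC")
gn  <- genorm(lac)
round(gn$m_value[gn$ranking[1:3]], 3)
#> EEF1A1   RPL4  RPS23
#>  0.147  0.147  0.186

cons <- consensus_ranking(gn, normfinder(lac), bestkeeper(lac), delta_ct(lac))
round(cons$score[cons$ranking], 2)
#> EEF1A1   RPL4  RPS23    UXT  RPS15    B2M  GAPDH   RPS9  HPRT1   ACTB
#>   1.41   2.11   3.98   4.36   4.76   5.05   5.12   5.32   9.00  10.00
```

The M value 0.147 is the shared stability of the best LAC pair
(EEF1A1/RPL4): the SD of their log₂ expression ratio across the six
animals, well under the 1.5 acceptability ceiling. The consensus score
1.41 for EEF1A1 is the geometric mean of its ranks under the four methods
(1, 1, 4, 1). Batch output for all species — one CSV per method per
species plus a one-line-per-species summary — comes from
`run_report(ladakh_pbmc(), "out/")`, or from the command line via
`Rscript inst/cli/refstab.R run --input ct.csv --annotation ann.csv --out out/`.

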