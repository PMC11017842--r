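# mirtally

Multi-target miRNA evidence tallying, coverage ranking, and the validation
analytics used to vet ranked candidates.

## The problem

A single miRNA can repress many mRNAs at once through its 5′ seed region,
which makes miRNAs attractive multi-target agents against cancers that
escape single-target drugs. A practical screen starts from a small set of
clinically validated drug-target genes (here, by default, the six
prostate-cancer targets *AR, PIK3CA, PIK3CB, MET, FGFR4, EGFR*) and asks:
**which miRNAs are supported — by experimentally validated and by
computationally predicted interaction databases — as hitting as many of
these genes simultaneously as possible?**

`mirtally` implements that consensus procedure and the downstream analytics
a study of this kind uses to validate its candidates:

* **Consensus ranking** (`summarize_mirnas()`, `rank_mirnas()`). Every
  (miRNA, gene, source) assertion is one evidence record with a class
  (`validated`/`predicted`), a direction (`positive`/`negative`), and a
  confidence in [0, 1]. Per miRNA the package tallies, over the candidate
  set *G*:
  * validated score = #{g ∈ G with ≥ 1 validated record} (the ranking
    statistic),
  * predicted score = #{g ∈ G with ≥ 1 predicted record},
  * net evidence = (positive − negative) validated record counts,
  * integrated score = Σ_g max per-source confidence — a reproducible
    multi-source aggregate defined by this package.

  miRNAs covering fewer than `min_coverage` genes are dropped; the rest are
  sorted by (validated, predicted, net, integrated) descending with a
  lexicographic tie-break.
* **Duplex characterization** (`find_seed_sites()`, `align_duplex()`,
  `duplex_free_energy()`, `report_sites()`): canonical 8mer/7mer-m8/
  7mer-A1/6mer seed matching, wobble-aware affine-gap complementarity
  alignment of the miRNA 3′ region, and nearest-neighbor hybridization
  ΔG from a packaged Turner-style stacking table.
* **Over-representation** (`enrich()`): exact hypergeometric upper tail in
  log space with Benjamini–Hochberg FDR (significant at FDR < 0.05).
* **qRT-PCR relative quantification** (`delta_delta_ct()`): 2^−ΔΔCt against
  a reference assay (GAPDH for genes, SNORD-47 for miRNAs) and an
  empty-vector control group, with one-way ANOVA + Tukey HSD and a
  Kolmogorov–Smirnov normality check.
* **Cell-cycle deconvolution** (`fit_phases()`, `compare_conditions()`):
  G0/G1, S and G2/M fractions from propidium-iodide DNA-content
  histograms via a constrained mixture (4N peak at ≈ 2 × the 2N peak,
  shared CV, uniform S plateau) fitted by EM.
* **Synthetic data with planted truth** (`simulate_evidence()`,
  `simulate_utrs()`, `simulate_ct()`, `simulate_cellcycle()`,
  `simulate_study()`) and a one-call orchestrator (`run_pipeline()`).

Everything takes and returns tibbles and composes with the pipe; fitted
objects have `tidy()`/`glance()` methods and `autoplot()` figures.

## Worked example

```r
library(mirtally)

sim <- simulate_evidence(seed = 42)        # planted 3-hub evidence table
ranking <- rank_mirnas(sim$evidence, sim$genes, min_coverage = 2, top_k = 3)
tidy(ranking)
#>    rank mirna_id       validated_score positive_evidence negative_evidence net_evidence integrated_score
#> 1     1 hsa-miR-16-5p                6                15                 1           14             5.86
#> 2     2 hsa-miR-124-3p               6                 7                 2            5             5.71
#> 3     3 hsa-miR-27a-3p               5                 6                 2            4             5.58
```

All three planted hub miRNAs are recovered: the top candidate has validated
evidence for all six genes (validated score 6), 15 positive vs 1 negative
validated records (net 14). Duplex scanning on simulated UTRs with planted
8mer sites:

```r
utr <- simulate_utrs(seed = 42)
report_sites(utr$mirnas, utr$utrs, top_n = 1)
#>   mirna_id       utr_id start   end site_type delta_g
#> 1 hsa-miR-sim-03 PIK3CB    92   100 8mer        -19.7
#> 2 hsa-miR-sim-01 MET       39    47 8mer        -19.1
```

Sites are ranked by hybridization free energy (kcal/mol; more negative =
stronger). Expression knockdown with a planted 0.4-fold change and
cell-cycle fractions planted at 0.60/0.25/0.15:

```r
ct <- simulate_ct(fold_changes = c(AR = 0.4), seed = 42)
glance(delta_delta_ct(ct$ct, "AR"))
#>   assay reference mean_fold_change  p_anova normality_p significant
#> 1 AR    GAPDH                0.527 0.000304       0.986 TRUE

fit_phases(simulate_cellcycle(seed = 42)$events)
#> Cell-cycle fit (n = 10000)
#>   G0/G1 0.601  S 0.248  G2/M 0.151
#>   mu1 = 99.9, mu2 = 199.6 (ratio 2.00), cv = 0.051
```

The fold change is recovered within replicate noise (three replicates at
0.15 Ct cycles of noise) and flagged significant; the phase fractions are
recovered within 0.005.

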