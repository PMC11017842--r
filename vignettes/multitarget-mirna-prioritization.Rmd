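---
title: "Methods: multi-target miRNA prioritization and its validation analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-target miRNA prioritization and its validation analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtally)
```

This vignette documents the models and procedures `mirtally` implements,
the parameters that matter, the design choices made where the design was
genuinely open, and what the synthetic-data generators do and do not
emulate.

## 1. Evidence model and consensus ranking

The unit of input is one **evidence record**: a (miRNA, gene, source)
assertion carrying a source class (`validated` for experimentally
supported databases, `predicted` for computational tools), a direction
(`positive` or `negative` regulation evidence), and a confidence in
[0, 1]. Gene symbols are canonicalized to uppercase and miRNA identifiers
are matched case-insensitively (the literature mixes `Hsa-miR` and
`hsa-miR` spellings); duplicate (miRNA, gene, source) keys are rejected
rather than deduplicated so that tallies are exactly reproducible from the
input file. A `confidence` column is optional and defaults to 1, since
most interaction databases do not export a comparable score.

Per miRNA, restricted to the candidate gene set:

* `validated_score` = number of candidate genes with at least one
  validated record — the ranking statistic, i.e. the breadth of
  experimentally supported simultaneous coverage;
* `predicted_score` = same for predicted records;
* `positive_evidence` / `negative_evidence` = validated record counts by
  direction, and `net_evidence` = positive − negative. Counting is at
  record level (one database row = one unit of evidence); whether a
  database entry summarizes one or several experiments is not modeled.
* `integrated_score` = Σ over covered genes of the maximum per-source
  confidence. Published "integrated scores" from meta-databases are not
  reproducible without the underlying databases, so this package defines
  its own aggregate with the same intended semantics — rewarding
  multi-gene, high-confidence support — and bounded by the gene-set size.
  Published integrated-score values are treated as data, never as a
  numeric target.

`rank_mirnas()` filters to miRNAs covering at least `min_coverage`
candidate genes with evidence of *either* class (validated and predicted
search results are pooled before asking which miRNAs have multiple
targets), then sorts by validated score, predicted score, net evidence and
integrated score, all descending. Ties after all four keys are broken
lexicographically by miRNA id; the full criteria are recorded in the
result's `ranking_key` attribute so a ranking is always auditable.
`n_sources` counts distinct source names per miRNA across all candidate
genes (not summed per gene pair). Records for genes outside the candidate
set are ignored rather than rejected, because database exports typically
cover the whole genome. Defaults `min_coverage = 2` and `top_k = 3` mirror
the screening design the package supports: miRNAs with multiple targets,
three final candidates.

## 2. Seed sites, duplex alignment and free energy

**Seed matching.** The seed is miRNA nucleotides 2–8 from the 5′ end, and
the four canonical site classes are supported: `6mer` (perfect
Watson–Crick match to positions 2–7), `7mer-m8` (2–8), `7mer-A1` (2–7
plus an adenine opposite position 1), and `8mer` (both). Written 5′→3′ on
the UTR, the position-8 match is the site's 5′-most base and the A1
adenine its 3′-most. The scan is exhaustive and left-to-right; overlapping
sites are all reported, and each core match is reported once with the most
specific class its flanks support. G:U wobbles are *not* accepted inside
the seed — wobble pairing is allowed only in the 3′-supplementary
alignment — mirroring the strict-seed behavior of the standard scanning
tools. Coordinates are 0-based half-open on the UTR sense strand.

**Alignment.** `align_duplex()` performs a global affine-gap alignment of
the miRNA (displayed 3′→5′, the usual duplex convention) against the UTR
window (the seed site plus its 5′ flank, up to one miRNA length), scoring
complementarity: +5 for Watson–Crick, +1 for G:U, −3 for a mismatch, −8
gap open, −2 gap extend. These are MIRANDA-flavored magnitudes; the exact
values are a package choice. Traceback is fully deterministic: on ties a
paired column is preferred, then a gap in the miRNA strand, then a gap in
the UTR strand, so outputs are bit-reproducible across runs and platforms.

**Free energy.** ΔG of an aligned duplex is the sum of nearest-neighbor
stacking terms over consecutive paired columns, plus a duplex initiation
penalty, plus a linear penalty (`loop_base + loop_per_nt × L`, with `L`
the number of unpaired bases on both strands) for each interior unpaired
stretch between helices; dangling ends cost nothing. The packaged table
(`inst/extdata/rna_stacking_dg37.tsv`, readable via
`duplex_energy_params()`) carries the 16 Watson–Crick/Watson–Crick stack
free energies at 37 °C following the Turner free-energy set, one generic
entry (−1.0 kcal/mol) for any stack containing a wobble pair, initiation
+0.5 and loop parameters 0.5 + 0.3·L kcal/mol. The simplified initiation
and loop terms are deliberate: they keep the invariant that any duplex
with at least one Watson–Crick stack has ΔG < 0, which makes the ranking
of seed-anchored sites by ΔG well behaved. Absolute energies are therefore
*not* comparable with RNAhybrid/UNAFold outputs — within-analysis ranking,
not thermodynamic bit-compatibility, is the goal.

## 3. Over-representation analysis

`enrich()` tests each annotation term for over-representation of the query
set with the exact hypergeometric upper tail
P[X ≥ k] for X ~ Hypergeom(N, K, n), accumulated in log space
(log-binomials + log-sum-exp) so small tails do not underflow; exactness
is verified against plain combinatorial enumeration to 1e−10 in the test
suite. Adjustment is Benjamini–Hochberg step-up across the reported terms
(those overlapping the query), and `significant` means FDR < 0.05 by
default. The universe defaults to the union of annotated genes when not
supplied, the common behavior of enrichment web services. The p-values are
one-sided (over-representation only) and *plain* hypergeometric — not the
EASE-adjusted variant some services use — so numerical agreement with any
particular web service's printed FDRs is not expected.

## 4. 2^−ΔΔCt expression analysis

For each replicate, ΔCt = Ct(target) − Ct(reference assay in the same
sample); ΔΔCt subtracts the *mean* control-group ΔCt (wells are unpaired
in the supported design); the fold change is 2^−ΔΔCt. Reference assays
default to GAPDH for genes and SNORD-47 for miRNA assays. Replicate fold
changes are aggregated by **geometric** mean, because fold changes live on
a log scale — an arithmetic mean would bias upward. Group differences are
tested by one-way fixed-effects ANOVA on the replicate ΔCt values with
Tukey HSD contrasts from the studentized-range distribution (delegated to
`stats::aov`/`TukeyHSD`); with exactly two groups the ANOVA p equals the
equal-variance t-test p. Normality of the group-centered ΔCt residuals is
checked by the one-sample Kolmogorov–Smirnov test with estimated mean and
SD and the asymptotic p-value — the plain (SPSS-dialog) variant.
Because parameters are estimated, this test is conservative (the
Lilliefors correction is deliberately not applied, and that caveat is part
of the contract). Significance is declared at p < 0.05 per comparison,
with no multiple-testing adjustment across the genes × miRNAs grid —
mirroring common wet-lab reporting practice; `bh_fdr()` is available when
adjustment is wanted.

## 5. Cell-cycle deconvolution

DNA-content histograms are modeled as a three-component mixture: a 2N
(G0/G1) Gaussian at μ₁, a 4N (G2/M) Gaussian at μ₂ constrained to
1.7–2.3 × μ₁ (DNA doubling, with instrument slack), a **shared
coefficient of variation**, and an S-phase plateau uniform in intensity
between the two peaks. Fitting is EM in log-intensity space, where
constant CV becomes constant σ and the constrained mean/variance M-steps
are closed-form weighted least squares. Initialization is moment-based:
the two dominant modes of the log-intensity kernel density a DNA-ratio
apart seed μ₁ and μ₂. Within one EM pass the S support is held fixed so
every M-step is an exact maximizer and the log-likelihood is provably
non-decreasing (asserted in the tests); up to three outer rounds then
re-anchor the support at the fitted means, which converges by the second
round in practice. Numerical guards: EM tolerance 1e−8 (relative
log-likelihood), 500 iterations cap, σ floored at 1e−4.

Degenerate inputs are handled explicitly: a zero-variance sample or a
histogram in which no second mode can be bracketed yields a flagged
degenerate fit with g2m = 0 rather than an error. After a provisional fit,
debris and doublets outside [0.3 μ₁, 1.3 μ₂] are excluded once and the
model refitted — standard practice in DNA-content gating. Fractions are
renormalized to sum to exactly 1 and are invariant under multiplicative
intensity rescaling (log-space shift). Replicate fraction estimates across
conditions are compared per phase by the same ANOVA/Tukey machinery as the
expression module.

This mixture-based gating was chosen over manual marker gates or the
historical polynomial S models because it is the simplest fully
reproducible rule consistent with how the 2N/4N/S structure arises; it is
a package design choice, not a reimplementation of any instrument
vendor's algorithm.

## 6. What the simulators emulate — and what they do not

Each generator returns machine-readable planted truth, so every analysis
stage has closed-loop recovery tests. All randomness flows through R's
Mersenne-Twister generator under an explicit seed; the same seed gives
byte-identical outputs.

* `simulate_evidence()` plants hub miRNAs with controllable coverage,
  validated fraction and negative-record rate against a sparse background
  (coverage ≤ 1). The default layout is three hubs shaped like the study
  candidates — e.g. the first hub emits 16 validated records over 6 genes
  with 1 negative, realizing a net evidence of 14. It does *not* emulate
  any real database's score distribution or version drift.
* `simulate_utrs()` plants seed sites of requested types at
  non-overlapping offsets with guard flanks chosen so a planted 6mer
  cannot silently upgrade to a longer class; chance background sites are
  flagged in the truth table. Generated miRNAs are 22 nt with a 5′ U
  (the typical human composition); base composition is otherwise uniform,
  which real UTRs are not.
* `simulate_ct()` writes Ct = assay baseline − log2(fold change) ×
  1[treated] + N(0, σ) for targets, and the same noise without a group
  effect for the reference. Defaults — fold change 0.4, σ = 0.15 cycles,
  3 replicates per group — are the study conditions under which the
  recovery guarantees are stated: the replicate-mean fold change then
  lands in [0.3, 0.53] in ≥ 95% of simulations. Amplification-efficiency
  deviations from 2.0 (Pfaffl correction) are not modeled.
* `simulate_cellcycle()` draws from exactly the constrained mixture the
  fitter assumes (defaults 0.60/0.25/0.15 at μ₁ = 100, CV 0.05, 10,000
  events, the conditions for the ±0.03 recovery guarantee). Real
  cytometry adds debris, doublets, and asymmetric peak broadening the
  generator omits — so passing recovery tests demonstrate correctness of
  the estimator under its own model, not robustness to every instrument
  artifact (the debris gate addresses only the simplest part of that).

Test and acceptance problem sizes (200 random tables / alignment pairs,
1000 ΔΔCt and 2000 null-ANOVA simulations, 10,000-event histograms) were
chosen once as the smallest sizes at which the stated statistical bands
are stable.

## 7. Pipeline

`run_pipeline()` executes rank → sites → enrich → ddct → cellcycle from
one YAML/list configuration, writing per-stage TSVs and a consolidated
JSON report. The report's key order is stable and its timestamp is
isolated in a single field, so end-to-end determinism is testable by
string comparison. Any stage failure aborts with the stage name; outputs
already written are retained. `simulate_study()` writes a complete
synthetic study (all input formats plus `truth.json` and `config.yaml`),
and the closed-loop property — the pipeline's top-3 equals the planted
hubs — is part of the test suite.

## 8. Known limitations

* The integrated score is a surrogate aggregate; it is order-compatible
  with coverage but numerically unrelated to any proprietary database
  score.
* Duplex ΔG values rank sites within this package only; no
  secondary-structure accessibility or conservation scoring is applied.
* The KS normality p-value is conservative with estimated parameters.
* The cell-cycle fitter assumes two resolvable peaks; heavily aneuploid or
  apoptotic (sub-G1) samples fall outside its model, and FCS parsing is an
  extension point (input is plain CSV of intensities).
* The enrichment module does not propagate annotations over an ontology
  graph; terms are treated as flat gene sets.
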