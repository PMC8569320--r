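# acnesig

Paired transcriptomic signatures of acne papule resolution under topical
treatment.

`acnesig` is an R package for studies in which each subject contributes
biopsies from non-involved skin (`L_NI`), a baseline acne papule (`L1`),
the papule site after vehicle treatment, i.e. spontaneous resolution
(`L3`), and the papule site after topical retinoid (trifarotene) treatment
(`R3`). From log2-scale expression matrices it answers: which genes does
the lesion change, which of those changes resolve on their own, and which
are specifically driven by treatment — and which cell populations move
with them.

## What it computes

* **Paired differential expression.** Each contrast is a one-sample
  empirical-Bayes moderated t-test on within-subject log2 differences:
  per-gene variances `s2` (df `ν = n−1`) are shrunk toward a
  scaled-inverse-chi-square prior `(d0, s0²)` estimated by method of
  moments from the log-variances, the posterior variance is
  `(d0·s0² + ν·s2)/(d0 + ν)`, and p-values use `d0 + ν` degrees of
  freedom with Benjamini–Hochberg FDR control. Candidates satisfy
  |FC| > 2 and q < 0.05 (both strict), with signed fold changes
  (`±2^|Δ|`).
* **Signature partitioning.** The papule (`L1` vs `L_NI`), vehicle
  (`L3` vs `L1`) and trifarotene (`R3` vs `L1`) candidate sets are
  partitioned into the seven Venn regions; treatment-specific genes are
  classified by their reversal pattern (up in lesion, down after
  treatment, or the mirror) and ordered by UPGMA clustering on
  1 − Pearson correlation of z-scored profiles.
* **Preranked gene-set enrichment.** The weighted Kolmogorov–Smirnov
  running-sum score with a random-gene-set permutation null, add-one
  p-values, signed NES and BH correction across sets; GMT input.
* **Cell-type scoring.** Mean log2 expression of marker panels per
  sample (11 built-in major skin cell types plus M0/M1/M2/SPP1+
  macrophage panels), compared between conditions by Wilcoxon rank-sum
  tests (exact by enumeration for small tie-free groups, normal
  approximation with tie/continuity corrections otherwise).
* **Synthetic studies with ground truth.** `simulateStudy()` generates
  the paired 9×4 design with subject random effects, planted per-contrast
  effects with controlled Venn structure, heavy-tailed per-gene variances
  and configurable cell-type composition shifts — every pipeline stage is
  validated against it.

## Worked example

```r
library(acnesig)

sim   <- simulateStudy(studyDesignConfig(nGenes = 1200, effectLog2fc = 3,
                                         noiseSd = 0.3, seed = 1))
study <- filterLowExpression(sim$study)        # ≥ 2^6 in ≥ 5 samples of a condition
sig   <- deriveSignatures(study)               # three paired contrasts + Venn

sig$results$trifarotene
#> ContrastResult "trifarotene": R3 vs L1 (paired, 9 subjects)
#>   genes tested: 964; prior df d0 = 3.875, prior variance s0^2 = 0.1673
#>   candidates at |FC|>2, q<0.05: 60

sig$partition
#> SignaturePartition over contrasts: papule, vehicle, trifarotene
#>   papule_only            20
#>   vehicle_only           8
#>   trifarotene_only       8
#>   papule_vehicle         10
#>   papule_trifarotene     10
#>   vehicle_trifarotene    5
#>   all_three              37
#>   union: 98 genes

rev <- classifyReversal(regionGenes(sig$partition, "all_three"),
                        sig$results$papule, sig$results$trifarotene)
table(rev$pattern)
#> down_in_papule_up_after_treatment up_in_papule_down_after_treatment
#>                                 8                                29
```

The moderated fit pools information across genes: `d0 = 3.9` extra
degrees of freedom recovered from the variance prior (the study was
simulated with `d0 = 4`). The partition recovers the planted structure —
e.g. all 37 recovered shared-response genes show the reversal pattern
implied by their planted directions (raised or lowered in the lesion and
pushed back by both resolution routes). With planted effects at the
candidate threshold boundary some planted genes legitimately fall short
(8/10 vehicle-specific genes recovered here).

`runDemo("out/", seed = 7)` runs every stage — simulation, filtering,
three contrasts, Venn partition, reversal, clustering, GSEA against
truth-derived and random gene sets, cell-type scoring and comparisons —
writing TSV/JSON artifacts and a machine-readable run report; outputs are
bit-identical under a fixed seed. A thin command-line wrapper is
installed at `inst/cli/acnesig.R` (`demo`, `run --config run.yaml`,
`simulate --config design.yaml`).

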