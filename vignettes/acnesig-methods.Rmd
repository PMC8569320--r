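---
title: "Methods: paired signatures, enrichment and cell-type scoring in acnesig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired signatures, enrichment and cell-type scoring in acnesig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acnesig)
```

# The study design and what the package computes

`acnesig` analyses paired multi-condition skin transcriptomics studies of
acne papule resolution. The design it targets has nine subjects, each
contributing four biopsies: non-involved skin (`L_NI`), an inflammatory
papule at baseline (`L1`), the papule site after topical vehicle treatment,
i.e. spontaneous resolution (`L3`), and the papule site after topical
trifarotene treatment (`R3`). Expression values are log2-scale intensities
(e.g. RMA-normalized microarray data); the package never works on the linear
scale, and any linear input must be log2-transformed by the caller.

Three paired contrasts define the biology of interest:

* **papule signature** — `L1` vs `L_NI`: what the lesion does to the skin;
* **vehicle signature** — `L3` vs `L1`: what spontaneous resolution does;
* **trifarotene signature** — `R3` vs `L1`: what treatment does.

Candidate genes per contrast (absolute linear fold change strictly greater
than 2 and BH FDR strictly below 0.05) are partitioned into the seven
disjoint regions of the three-set Venn diagram. The treatment-specific
region — genes moved by trifarotene but not by spontaneous resolution — is
the scientifically interesting set: the package classifies each of its
genes by whether it was raised in the lesion and pushed back down by
treatment (or the mirror pattern), clusters it for heatmap display, and the
enrichment and cell-type modules ask what processes and cell populations
those changes reflect.

# The statistical model

## Paired moderated t

Each two-condition contrast is fitted as a one-sample problem on
within-subject differences: for gene $g$ and subject $s$ with both
biopsies, $d_{gs} = y_{gs,A} - y_{gs,B}$ on the log2 scale. This is
equivalent to a subject-blocked linear model for a two-condition contrast
and removes the subject random effect exactly. With $n$ complete subjects,
$\hat\beta_g = \bar d_g$, $s_g^2$ the sample variance and $\nu = n-1$
residual degrees of freedom.

Per-gene variances at $n = 9$ are unstable, so they are shrunk by
empirical Bayes toward a common prior. The prior is the scaled-inverse-
chi-square family: $\sigma_g^2 \sim s_0^2\, d_0/\chi^2_{d_0}$. The
posterior variance is the degrees-of-freedom-weighted blend

$$\tilde s_g^2 = \frac{d_0 s_0^2 + \nu s_g^2}{d_0 + \nu},$$

and the moderated statistic $t_g = \hat\beta_g / \sqrt{\tilde s_g^2 / n}$
is referred to a t distribution with $d_0 + \nu$ degrees of freedom
(two-sided). With $d_0 = 0$ this is the classic one-sample t; with
$d_0 = \infty$ all genes share one variance.

Hyperparameters are estimated by method of moments on $e_g = \log s_g^2$:
under the model $\mathrm{var}(e) = \psi'(d_0/2) + \psi'(\nu/2)$, so $d_0$
solves $\psi'(d_0/2) = \mathrm{var}(e) - \psi'(\nu/2)$ (bisection on
$[0.1, 500]$; solutions beyond 500 are treated as total shrinkage), and

$$\log s_0^2 = \overline{e} - \psi(\nu/2) + \log(\nu/2)
             + \psi(d_0/2) - \log(d_0/2).$$

When the observed dispersion of log-variances does not exceed the pure
sampling dispersion $\psi'(\nu/2)$, $d_0 = \infty$. Two numerical
edge cases are handled explicitly: exactly constant observed variances
return the common value itself as $s_0^2$ (no sampling-dispersion
correction, so the moderated t then equals the classic t), and genes with
$s_g^2 = 0$ obtain a finite posterior variance through shrinkage whenever
$d_0 > 0$; if $d_0 = 0$ as well, the p-value is `NaN` and excluded from
multiplicity adjustment with a logged count.

BH adjustment is the plain step-up procedure, applied per contrast over
all tested genes (the standard multiplicity universe for this design). It
is implemented directly in the package — five lines — so that the test
suite can validate it against `stats::p.adjust` as a genuinely independent
reference rather than testing a function against itself.

## Candidate selection and the Venn partition

A gene is a candidate iff $|\mathrm{FC}| > 2$ and $q < 0.05$, both strict,
where FC is the signed linear fold change $\pm 2^{|\Delta|}$ (a halving is
reported as $-2$). Strictness matters at the boundary: a gene at exactly
FC = 2.0 is not selected. The partition itself is exact set algebra; its
invariant — region sizes sum to the size of the three-set union — is
asserted at run time by the pipeline, not only in tests.

Reversal classification uses only the signs of the papule and trifarotene
log2 fold changes. A consequence worth stating: genes planted in the
simulator as treatment-specific have a *zero* papule effect, so at zero
noise their estimated papule fold change is exactly zero and they classify
as `other`; the genes that classify as reversal are those with a genuine
lesion effect undone by treatment (the papule-and-trifarotene overlap
regions). On real data, treatment-specific genes typically carry
sub-threshold lesion effects and the classifier reports how many follow
the reversal pattern.

## Clustering for display

The treatment-specific genes are ordered by agglomerative clustering with
average linkage (UPGMA) on the distance $1 - r$, where $r$ is the Pearson
correlation between per-gene z-scored profiles restricted to the `L_NI`,
`L1`, `R3` samples. Samples are never clustered. Genes are sorted
lexicographically before clustering, which fixes tie-breaking and makes
the merge tree invariant to input order; a zero-variance profile is
assigned correlation 0 (distance 1) to everything, with a message.
Pearson rather than Spearman correlation is used because the rows are
z-scored, which makes Pearson the natural choice and matches the default
of the heatmap tools this display convention comes from.

## Preranked gene-set enrichment

Genes are ranked by the moderated t (default) or log2 fold change,
descending, ties broken by gene ID. The enrichment score is the classic
weighted Kolmogorov–Smirnov running sum: hits increment by
$|m|^p / \sum_{hits} |m|^p$, misses decrement by $1/(N - n_{hits})$, and
the score is the signed extremum (an exact positive/negative tie resolves
positive; with $p = 0$ the score is exactly the two-sample KS statistic
on ranks, which the tests exploit). The default weight is $p = 1$.

The null is gene-label permutation: random same-size gene sets, not
sample-label permutation — nine pairs cannot support label permutation,
and this matches the preranked tools used for this kind of data. P-values
use the add-one estimator restricted to same-sign null scores, so
$p > 0$ always and $p = 1$ is attainable; NES normalizes by the mean
absolute same-sign null score, per the original convention. Null score
distributions are shared across sets of equal size within one call, which
is what makes calibration experiments with hundreds of sets cheap.

## Cell-type scoring and group comparison

A cell type's score in a sample is the arithmetic mean of the log2
expression of its marker genes present in the matrix — a deliberately
transparent proxy for cell-type abundance, linear in per-sample shifts.
Missing markers are dropped, never imputed, and per-panel coverage is
always reported so that low-coverage scores are visible. The packaged
panels are the 11 major skin cell types (B cells through vascular smooth
muscle) plus four macrophage subclasses (M0, M1, M2 and the
fibrosis-associated SPP1+ subset); the lists are taken as printed in
their sources, including the deliberate overlap of CD68 between the
myeloid panel and macrophage panels — panels are scored independently.

Group comparisons are unpaired Wilcoxon rank-sum tests on pooled
mid-ranks. The p-value is exact by full enumeration of all
$\binom{n_x+n_y}{n_x}$ rank assignments when $n_x + n_y \le 12$ and there
are no ties (enumeration stays well under a second at that size);
otherwise the normal approximation with tie and continuity corrections is
used. With nine samples per condition the comparisons in this design use
the approximate path, whose smallest attainable two-sided p at 9 vs 9 is
about $4 \times 10^{-4}$.

Significance stars default to the annotation scheme `* < 0.05`,
`** < 0.01`, `*** < 0.0001` — the `***` level is unusual but kept as the
authoritative convention of the display this reproduces; note that it is
unattainable for 9-vs-9 rank-sum comparisons, so such boxplots can show
at most `**`. A `conventional` switch uses `*** < 0.001`. No multiplicity
adjustment is applied across panels or pairs, matching the per-comparison
annotation practice; this is flagged here deliberately.

# The synthetic-study generator

Every downstream stage is validated on studies generated by
`simulateStudy()`, with full ground truth. The model is additive on the
log2 scale:

$$y_{gsc} = \mu_g + b_s + \delta_{gc} + m_{gc} + \varepsilon_{gsc},$$

with baselines $\mu_g \sim U(4, 12)$, subject effects
$b_s \sim N(0, 0.3^2)$ shared across genes, planted condition effects
$\delta$, marker-panel shifts $m$, and Gaussian noise whose per-gene
variances are drawn from the same scaled-inverse-chi-square family the
moderated t assumes ($d_0 = 4$, scale $0.4^2$ by default) so the
empirical-Bayes estimator has a recoverable target. Gaussian noise on the
log2 scale is appropriate because RMA-style normalized intensities are
approximately Gaussian there, and it matches the t-statistics downstream.

Planted effects are parameterized per contrast: a gene's Venn region
determines in which contrasts it is differentially expressed, with
$|\Delta| =$ `effectLog2fc` exactly; the condition effects are
$\delta(L_{NI}) = 0$, $\delta(L1) = e_p$, $\delta(L3) = e_p + e_v$,
$\delta(R3) = e_p + e_t$, so each planted contrast effect is recovered
exactly by group means at zero noise. By default 80% of planted genes are
"up in the lesion", and the vehicle/trifarotene effects mirror (reverse)
the lesion direction — the reversal narrative of lesion resolution.

Default study conditions: 9 subjects, 2000 genes, noise scale 0.4,
subject SD 0.3, effect 2 (log2), and region sizes
(20, 10, 10, 10, 10, 5, 40) for (papule-only, vehicle-only,
trifarotene-only, papule∧vehicle, papule∧trifarotene,
vehicle∧trifarotene, all-three) — a scaled-down echo of the reported
real-data structure in which the shared resolution response is the
largest region and the treatment-specific and vehicle-specific regions
are of similar size. These were chosen once for testability at desk
scale, not for biological fidelity; no variance or effect-size estimates
are available for the real study.

What the generator does **not** emulate: probe-level structure (multiple
probes per gene), batch effects, missing values, intensity-dependent
variance trends, or correlated gene modules. Passing tests therefore
demonstrate correctness of the algorithms under the stated model, not
robustness to every artefact of real microarray data.

# Calibration and validation experiments

The test suite treats independent re-implementation as the ground truth
wherever possible: the expression filter against a brute-force double
loop; the enrichment score against a step-by-step walk and against the
classical KS statistic at weight 0; BH against `stats::p.adjust`; the
moderated t against `limma`'s empirical-Bayes fit; the exact Wilcoxon
against `stats::wilcox.test`'s exact distribution; UPGMA against a
re-averaging agglomeration oracle.

Monte-Carlo experiments use these problem sizes, chosen to keep the whole
suite fast while leaving the binomial noise of estimated rates well inside
the asserted bands: type-I error of the moderated t on 20 null studies of
2000 genes x 9 subjects (band 0.03–0.07 at $\alpha = 0.05$); prior-df
recovery at $d_0 = 10$ with 10,000 genes over 20 seeds (band 6–16,
established by pilot runs of the estimator); signature recovery with
planted regions (10, 10, 10, 5, 5, 5, 5) at effect 3, noise 0.3 (median
region Jaccard at least 0.8 over 20 seeds); GSEA null calibration over
200 random sets (rejection at 0.05 within 0.02–0.08); cell-type null
calibration over 400 replicates and SPP1-shift detection over 50.

One calibration subtlety: the Wilcoxon null-calibration harness sets the
subject SD to zero. The rank-sum test's uniformity-of-p property assumes
exchangeable groups; with the shared subject effects of the paired design
the unpaired test becomes (sometimes extremely) conservative, which the
suite asserts separately as an inequality. This conservativeness is a
real property of applying unpaired rank-sum tests to paired designs and
is worth knowing when reading the per-comparison stars.

# Reproducibility

All stochastic stages are driven by explicit seeds; a pipeline run derives
per-stage substreams from its single configured seed, so changing the
number of GSEA permutations does not perturb the simulated data. Pipeline
outputs are bit-identical under a fixed seed (asserted in the tests by
byte-comparing two runs), RNG state is always restored, and the run
report echoes every threshold that affected results. The bundled demo
(`runDemo()`) executes every stage on a 1200-gene study in a few seconds.

# Known limitations

* Paired two-condition fits only; no multi-factor design matrices,
  batch correction, or intensity trend on the prior variance.
* The permutation GSEA p-value has resolution $1/(n_{perm}+1)$; no
  adaptive refinement of very small p-values.
* Marker-panel scores are abundance proxies; they are not a
  proportion-resolving deconvolution and panels are not orthogonalized.
* The probe-to-gene collapse rule of the original analyses of this kind
  is typically unstated; both `max_mean_probe` and `gene_mean` are
  provided and the choice is recorded in the run report.
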