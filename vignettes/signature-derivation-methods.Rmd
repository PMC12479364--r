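---
title: "Deriving and projecting follicular helper T cell signatures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and projecting follicular helper T cell signatures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfhsig)
```

## The problem

T follicular helper (T~FH~) cells drive germinal centre B cell responses,
and their transcriptional state differs between immune challenges. Given
bulk RNA-seq of sorted T~FH~ (IL-21^+^ and IL-21^−^ subsets), T~FR~ and
T~eff~ populations across several infection models, `tfhsig` derives three
kinds of gene signatures by consensus rules over directional
differential-expression (DE) calls, and projects them onto new datasets —
bulk profiles, pseudobulked single cells, or spatial spots — with a
bounded, rank-based single-sample score. Because the real sorted-population
datasets are large external downloads, the package ships a synthetic-data
module that generates inputs with the same statistical structure and known
planted truth, so every stage of the workflow is testable end to end.

## The DE engine

All signature rules consume per-gene, per-contrast directional calls
$D \in \{-1, 0, +1\}$ produced by a single engine:

1. **Filtering.** Technical replicates are summed; samples with library
   size strictly below 1 million reads are dropped; a gene is kept if its
   CPM reaches `min_count` (default 10) re-expressed on the median library
   in at least $k$ samples, $k$ = the size of the smallest
   condition × celltype group, and its total count is at least 15.
2. **Normalization.** Trimmed mean of M-values (TMM): against a reference
   sample (75th-percentile CPM closest to the mean of those), log-ratios
   M and abundances A are doubly trimmed (30% / 5% two-sided) and the
   factor is 2 to the precision-weighted mean of the surviving M-values,
   with inverse delta-method variances as weights. Factors are rescaled to
   geometric mean 1. Expression is carried as
   $\log_2\!\big((y + 0.5)/(L + 1) \cdot 10^6\big)$ with effective library
   sizes $L$; the simple $(y+p)/(L+2p)$ prior variant is used because it is
   closed-form and hand-checkable.
3. **Precision weights.** Per-gene residual standard deviations from an
   ordinary fit are smoothed (fourth-root scale, lowess span 0.5) against
   mean log-CPM; each observation's predicted sd at its fitted value gives
   the weight $\hat\sigma^{-4}$. This down-weights the noisy low-count
   part of the mean–variance trend.
4. **Moderated fits.** Gene-wise weighted least squares against one
   group-means design (one coefficient per condition × celltype). The
   residual variances are shrunk toward a prior estimated by
   method-of-moments on the log variances: prior df $d_0$ solves a
   trigamma equation, and the posterior variance is the convex combination
   $\tilde s_g^2 = (d_0 s_0^2 + d\, s_g^2)/(d_0 + d)$. $d_0 = 0$ recovers
   the ordinary $t$ exactly; $d_0$ is capped at $10^6$ to represent an
   effectively infinite prior.
5. **Threshold test.** Each contrast is tested against
   $H_0: |\beta| \le \tau$ with $\tau = \log_2 1.1$ (the fold-change floor
   the workflow standardizes on): with moderated standard error $s$, the
   p-value combines the two one-sided tails
   $P(T > (|\hat\beta| - \tau)/s) + P(T > (|\hat\beta| + \tau)/s)$ at
   $d_0 + d$ df. At $\tau = 0$ this is exactly the two-sided moderated
   $t$-test. BH adjustment follows, and a gene is called at $q \le 0.05$
   (boundary inclusive) with $D = \mathrm{sign}(\hat\beta)$.

The engine is deliberately self-contained so each step has a closed-form
oracle; the test suite also cross-checks the variance moderation and the
complete weighted TREAT pipeline against limma, and the TMM factors
against edgeR, on shared inputs.

## Signature rules

With per-condition T~FH~ vs T~eff~ calls and a combined contrast that
averages the celltype effect over conditions (one model, group-means
parameterization; IL-21^+^ and IL-21^−^ T~FH~ pooled with equal weight by
default, switchable):

* **Core signature** — a gene is core-up iff called up in ≥ 3 conditions
  *with the same direction* and up in the combined contrast; symmetric for
  down. Raising the condition floor can only shrink the signature.
* **T~FR~ signature** — the ≥ 3-of-5 consensus is applied independently to
  the T~FR~-vs-T~FH~ and T~FR~-vs-T~eff~ families and intersected,
  requiring direction agreement. Consensus-then-intersect was chosen for
  symmetry with the core rule; a pooled-model variant is possible through
  the same engine by supplying a pooled contrast.
* **Context (pathogen-specific) signatures** — for each condition,
  one-vs-rest contrasts of T~FH~ and T~eff~ are combined into `shared`
  (same-direction DE in both), `tfh_unique` and `teff_unique`; the
  exported per-pathogen T~FH~ signature is `shared ∪ tfh_unique`. A gene
  may appear in several conditions' signatures.
* **Core partition** — core genes split into four groups by whether the
  T~FR~-vs-T~eff~ consensus call is +1 ("co-expressed by T~FR~"); a −1
  call groups with "not co-expressed".

Open design points resolved here: the combined contrast must agree in
*direction* with the consensus (not merely be significant), because the
signatures are directional by construction; and annotation sets (cell
surface, transcriptional regulators, Bcl-6 network) are taken as GMT
inputs rather than hard-coded gene lists.

## Rank-based scoring

For one sample, genes are ranked ascending with average ties. A
signature's up-score is the mean rank of its genes, min–max normalized by
the analytic extremes — $(n+1)/2$ and $(2N-n+1)/2$ for $n$ of $N$ genes —
and centred, so it lives in $[-0.5, +0.5]$ and reaches the bounds exactly
when the signature occupies the top (bottom) of the ordering without ties
across the boundary. Down-sets are scored on reversed ranks and added,
giving bidirectional totals in $[-1, +1]$. Scores depend only on the
within-sample ordering, so any strictly monotone transform of the
expression values (counts, CPM, log-CPM) gives identical results.

Signature genes missing from a dataset's panel are dropped with a warning
and the bounds recomputed on the present subset; this keeps scores
comparable on restricted panels (targeted spatial assays) instead of
silently treating absent genes as bottom-ranked. Region scoring
additionally enforces a 25% minimum panel coverage per signature.
Projection scores external data with **upregulated genes only** by
default; bidirectional scoring is used for T~FH~-like cell selection,
which keeps cells with a strictly positive total core score.
"Normalized to baseline" summaries subtract the baseline group's mean by
default; a guarded ratio mode exists because the field uses both.

## Enrichment

Preranked GSEA uses the classic weighted running-sum walk (hit increment
$|s|^p / \sum_{set} |s|^p$, miss decrement $1/(N - n)$, default $p = 1$,
$p = 0$ exposed for hand-checkable tests), with the positive extremum
chosen on exact ties. The null permutes *gene sets* (random same-size
sets): when $\binom{N}{n} \le 10{,}000$ every placement is enumerated and
the p-value is the plain signed-tail proportion; otherwise Monte-Carlo
draws use the add-one estimator $(1 + b)/(1 + m)$. NES divides the
observed ES by the mean |ES| of same-sign null scores — a declared
convention, since normalizations differ between tools. The single-cell
competitive rotation test is deliberately not reimplemented; the same
permutation machinery applied to the pseudobulk contrast statistic is the
package's documented substitution. Gene-set themes come from connected
components of the overlap-coefficient graph
($|A \cap B| / \min(|A|,|B|)$) at a chosen threshold.

## Single-cell stage

Cells with mitochondrial fraction ≥ 20% (inclusive) are removed, as are
cells whose totals or detected genes fall strictly below the 10th
percentile (type-7, linear interpolation). Normalization divides by
median-scaled library size factors — a closed-form stand-in for pooled
size-factor estimation, chosen for testability and recorded as a known
divergence from heavier alternatives. The top 2,000 variance-ranked genes
(deterministic id tie-break) feed a gene-centred PCA (component signs
fixed by the largest loading), a k = 9 nearest-neighbour graph with
Jaccard edge weights over the neighbour sets (self excluded), and Louvain
community detection with a seeded visiting order.

Pseudobulks are exact integer column sums per cluster × sample group;
groups under 10 cells are dropped. Pseudobulk DE runs the same bulk engine
with donor as a **fixed-effect covariate** — the package's substitution
for estimating a donor random effect by consensus correlation; the
difference is documented here and flagged in the result metadata (donor
appears in the design). Antibody-tag counts are CLR-normalized per cell:
$v_i = \ln(x_i + 1) - \overline{\ln(x + 1)}$, summing to zero per cell.

**Louvain resolution.** The default resolution is 1.0. kNN graphs of
homogeneous cell populations carry internal modularity regardless of how
well-separated the populations are, so at desk scale (hundreds of cells,
a handful of populations) resolution 1.0 tends to split pure populations
into pure sub-communities. The package's recovery analyses therefore run
clustering at resolution 0.3, the documented coarse setting for small
datasets; cluster *count* is never treated as a target, only recovery of
planted structure.

## The synthetic-data module

`simulate_bulk()` emulates the study design: 5 conditions × 4 sorted
populations × 3 replicates, 5,000 genes, lognormal library sizes (mean
2 × 10^6^ reads, CV 0.3 — desk-scale but large enough that the 1M-read
filter and CPM thresholds behave realistically), NB counts with
$\mathrm{Var} = \mu + \phi\mu^2$ at $\phi = 0.1$, and planted structure at
$|\log_2 \mathrm{FC}| = 1.5$: 200 core-up and 200 core-down genes shifted
in T~FH~ vs T~eff~ in *every* condition, 100 T~FR~-shared genes shifted in
both T~FH~ and T~FR~, and 100 per-condition genes shifted in that
condition's T~FH~ only. The analytic mean matrix is returned, and the mean
model is exact: planted ratios of $\mu$ (after removing the library-size
component) equal $2^{\Delta}$ to machine precision.

Two generator choices matter for interpreting recovery results:

* **T~FR~-shared genes satisfy the core rule.** They are up in T~FH~ vs
  T~eff~ in all conditions by construction, so a correct core derivation
  *must* include them. `expected_signatures()` therefore returns the
  analytic expectation of each rule (core-up = core_up ∪ tfr_shared), and
  recovery is measured against that, not against the raw category labels.
  Conversely these genes are flat between T~FR~ and T~FH~, so the expected
  T~FR~ signature of the default design is empty — the T~FR~ rule is
  exercised by constructed call matrices instead, and the T~FR~-shared
  genes exercise the core partition (they land in the "co-expressed by
  T~FR~" groups).
* **Planted genes are drawn from the expressed transcriptome** (baseline
  expected count ≥ 50 at the mean library size). Marker genes of sorted
  populations are robustly detected in practice; planting effects on
  near-zero genes would make recovery measure the expression filter, not
  the rule.

The single-cell generator plants disjoint marker blocks per cluster
(Poisson counts around per-cell scaled profiles — sufficient for
clustering and scoring behaviour), donor labels, `mt-`-prefixed
mitochondrial genes pinned at 5% of expected counts for ordinary cells
and 30% for a 5% fraction of damaged cells (cleanly across the 20% QC
boundary), and one elevated protein tag per cluster. The spatial
generator places cells uniformly on a plane with circular
signature-positive regions (Xenium-like; a mode aggregating cells into
square bins approximates spot-level data).

What the generators do **not** emulate: gene-length/GC bias, batch
effects, ambient RNA, doublets, zero-inflation beyond NB/Poisson
sampling, or realistic spatial morphology. Passing recovery tests
demonstrates that the rules and scores behave as specified under the
assumed noise model — not that the workflow is robust to artefacts absent
from that model.

## Numerical choices

* All randomness flows through a pinned Mersenne-Twister/Inversion RNG;
  derived child seeds stay below 2^31.
* Enrichment extremum ties compare with an absolute epsilon of 10^−12^
  (|ES| ≤ 1), absorbing accumulator-precision differences.
* Zero-variance genes in moderation are floored at 10^−12^; zero-variance
  rows in z-scoring become zero rows with a warning.
* BH adjustment delegates to `stats::p.adjust`; Louvain to
  `igraph::cluster_louvain`; MTX I/O to the Matrix package.
* Degenerate TMM trims (empty after double trim) fall back to the
  untrimmed weighted mean; a sample sharing no positive genes with the
  reference is an error.

## Problem sizes

The package's own analyses run at: 5,000 genes × 60 samples for signature
recovery; 20 replicate null simulations at 1,000 genes for error control;
360 cells × 600 genes for clustering and pseudobulk DE; 10 independent
end-to-end repeats (derive on 3 training replicates, score 3 held-out
replicates pseudobulked per condition) for projection dominance. These
sizes give stable Monte-Carlo behaviour while a full run of suite plus
acceptance script completes in a few minutes on one CPU.

## Known limitations

* Donor variation enters pseudobulk DE as a fixed effect; with very few
  donors per cluster this costs residual df relative to a random-effect
  treatment.
* The mean–variance weights are computed on log-CPM rather than log-count
  fitted values; on homoskedastic data the weights are near-flat either
  way, and the trend direction is what matters for count data.
* The permutation NES is not comparable across tools that normalize
  differently; compare NES values only within one run.
* Missing values are unsupported throughout; genes must be complete after
  filtering.

## A minimal run

```{r example, eval = FALSE}
sim <- simulate_bulk(sim_config(seed = 1))
de <- run_bulk_de(sim$counts, sim$samples)
sigs <- derive_signatures(de)
sigs
exp <- expected_signatures(sim$truth)
mean(sigs$core$up %in% exp$core_up)   # precision of the up-set
```
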