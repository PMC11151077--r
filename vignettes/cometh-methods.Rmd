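---
title: "Methods: co-methylation-aware quantification and paired DMR calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-methylation-aware quantification and paired DMR calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cometh)
```

## The problem

Bulk bisulfite sequencing averages over a heterogeneous population of cells.
Two regions can both show 50% methylation at every CpG site yet be entirely
different biologically: in one, half the molecules are fully methylated and
half fully unmethylated (a mixture of two epigenetic states); in the other,
methylated sites are scattered across molecules (a disordered state). The
classical per-site rate, here called **Meanm** — methylated calls over total
calls — cannot distinguish these. Read-level quantifiers can, because a
sequenced read is (approximately) a single molecule from a single cell.

`cometh` implements four per-site quantifiers computed from the reads
covering a CpG site $S$. Covering reads split into *methylated* reads
(carrying at least one methylated CpG anywhere on the read; count $n_m$) and
*unmethylated* reads (all calls unmethylated; count $n_u$); $n_p$ counts
methylated reads whose call at $S$ itself is unmethylated (the partially
methylated group):

* **Wemics** $= A / (A + n_u)$, with $A = \sum_{i=1}^{n_m} m_i / c_i$,
  where $c_i$ is the CpG count of read $i$ and $m_i$ the length of the
  maximal run of consecutive methylated calls containing $S$ (with
  $m_i = 1$ when the call at $S$ is unmethylated). The weight $m_i/c_i$
  rewards co-methylation of neighbouring sites on the same molecule.
* **CHALM** $= n_m / (n_m + n_u)$ — the fraction of "touched" molecules.
* **CAMDA** $= n_p / (n_m + n_u)$ — the discordant fraction.
* **Meanm** $= (n_m - n_p) / (n_m + n_u)$ — the classical rate.

By construction `Meanm + CAMDA = CHALM` and
$0 \le \text{Wemics} \le \text{CHALM} \le 1$; both identities are asserted
on randomly generated pileups in the test suite, along with exact agreement
between the vectorised production path and a deliberately naive
direct-from-definition oracle.

### The weight's algebraic form

The flattened source typography of the Wemics numerator admits three
readings ($m_i/c_i$, $c_i/m_i$, $c_i \cdot m_i$). This package pins
$w_i = m_i / c_i$: it is the only reading under which weights lie in
$[0,1]$, a fully methylated read contributes weight 1 (collapsing Wemics to
CHALM when no read is partially methylated), and Wemics $\le$ CHALM always —
the behaviour the method's "in between" narrative requires. The other
readings would weight short methylation runs *above* long ones. The weight
lives in one isolated routine (`run_weight()`), so a revision is a one-line
change.

$m_i$ is measured in read CpG order; genomic gaps between consecutive CpGs
on the read are irrelevant. Reads with a single CpG are retained; their
weight degenerates to 1 when methylated, a documented limitation of
run-length weighting in CpG-poor regions.

### Missing values

A site with zero qualifying coverage yields `NA`, never 0 — an unmeasured
site is not an unmethylated site.

## Paired DMR detection

Matched tumor/normal designs allow each patient to serve as their own
control. The caller consumes a site × patient × {tumor, normal} matrix and
works per pre-windowed block of CpGs (inter-site gap ≤ `max_gap`, default
300 bp, the conventional segmentation window for RRBS data):

1. **Recursive binary segmentation.** Within a block the candidate
   breakpoint maximizes the absolute difference of the two children's mean
   per-site paired differences. Every visited segment with at least
   `min_cpg` sites is a candidate.
2. **Scoring.** Each candidate is scored with a Wilcoxon signed-rank test
   on *per-patient segment-mean differences* — one difference per patient,
   keeping the pairs independent. (A pooled per-site × patient variant is
   available behind `per_site = TRUE`; it trades independence for
   sensitivity and is not the default.) The unpaired mode scores per-sample
   segment means with a Mann–Whitney U test, for comparison with the paired
   design.
3. **Selection.** Candidate p-values are Benjamini–Hochberg corrected;
   emitted DMRs must satisfy `n_cpg >= 3`, `|mean_diff| >= 0.1` and
   `q <= 0.05` (all defaults), and are made non-overlapping greedily.

Separately, `merge_dmrs()` merges same-direction DMRs closer than 200 bp,
the convention used when comparing DMR sets.

### The signed-rank test

$W = \sum_i \mathrm{sgn}(d_i) R_i$ with $R_i$ the rank of $|d_i|$ (average
ranks on ties) after dropping zero differences. For $n \le 25$ tie-free
differences the two-sided p-value is exact, from a dynamic-programming
enumeration of the signed-rank null (verified in the tests against full
$2^n$ enumeration for $n \le 10$); otherwise a normal approximation with
tie-corrected variance $\sum R_i^2$ and a continuity correction is used.
All-zero differences yield $W = 0$, $p = 1$: no evidence.

### Numerical choices

* **Tie stabilization.** Segment-mean differences are rounded to 10
  decimals before ranking, and the greedy selector's effect-size key
  likewise. Differences below $10^{-10}$ are floating-point residue, not
  methylation signal; without this, noise-free fixtures acquire arbitrary
  tie patterns and the tie-corrected variance makes p-values jump
  non-monotonically between nested segments.
* **Greedy tie-breaks.** Candidates are ranked by ascending p, then
  *larger absolute mean difference*, then longer span, then leftmost start;
  recursion descends when a child's p is less than **or equal to** its
  parent's. Both choices matter in the noise-free limit: an exact
  discrete test assigns the identical p to every segment whose differences
  are all positive, so a p-then-length rule would select an entire block
  and never localize a planted sub-region. Ranking by effect size among
  p-ties recovers exact boundaries; tests assert recovery within ±1 CpG.
* p-values from saturated sign patterns are floor-limited at $2/2^n$; with
  the default q-threshold this implies paired designs need roughly 9+
  patients for any single region to survive multiplicity correction.

### Known divergences from common segmentation tools

The 2D Kolmogorov–Smirnov pre-filter and circular (as opposed to plain
recursive binary) segmentation used by some DMR callers are deliberately
not implemented; the procedure here is the described algorithm — binary
segmentation with the paired test swap — not a bug-compatible port.
Zero differences are dropped (classical Wilcoxon convention); Pratt's
method is not offered.

## Integration statistics

* **Correlation**: product-moment, with Spearman as Pearson-on-midranks;
  p from the t distribution with $n-2$ df (including for Spearman, which
  therefore differs slightly from exact-permutation implementations).
* **Signal strength**: $\log_2(\text{count}/\text{length} \times 1000 + 1)$,
  reads per kilobase with a pseudocount.
* **Promoters**: TSS ± 2 kb, symmetric irrespective of strand — the
  defining phrase ("upstream and downstream") is symmetric, so no
  strand-flip is applied. Clipped at coordinate 0.
* **DMR→gene assignment**: nearest gene *span* strictly closer than 2 kb
  ("less than" is strict; a DMR exactly 2,000 bp away is unassigned). Ties
  break to the lexicographically smaller gene id, making output
  deterministic. A TSS-anchored variant (`anchor = "tss"`, measured to the
  zero-width TSS point) is available; the span reading is the default
  because gene-body DMRs should count as distance 0.
* **CGI context**: inside → `CGI`; border distance in (0, 2000) → `shore`;
  [2000, 4000] (closed, "between 2 and 4 kb") → `shelf`; beyond → `inteCGI`.
* **Motif occupancy**: the DMR is extended 200 bp on both flanks; motif
  lengths are clipped to the window but *not* de-overlapped ("all
  individual motifs" read literally), so rates can exceed 1 under heavy
  overlap — documented rather than silently capped.
* **Activity score**: $r \times \log_2(\text{fold change})$, $r$ the
  Spearman correlation between TFBM methylation and target expression over
  all samples; fold change is the ratio of *linear-scale* mean expression
  (input is log2(FPKM+1); means are taken after back-conversion
  $2^x - 1$ — the source does not specify the scale, and the linear mean is
  what a fold change of expression conventionally means; a `"log"` switch
  is provided). Motifs with $r \ge 0$ are dropped; multiple motifs in a
  DMR average; reporting applies $|{\rm activity}| > 1.2$.
* **Variance explained**: four nested OLS fits (methylation; TF; both;
  both + interaction), each reported as adjusted
  $R^2 = 1-(1-R^2)(n-1)/(n-p-1)$. Raw $R^2$ is monotone over the nest
  (asserted); adjusted values need not be.

## The synthetic cohort: what it emulates and what it does not

The generator writes reads as two-state Markov chains along a region's
CpGs: stationary methylation level $\theta$ and persistence $\rho$, with
$P(M \to M) = \rho + (1-\rho)\theta$ and $P(U \to M) = (1-\rho)\theta$, so
the marginal stays $\theta$ for every $\rho$. A Markov epiallele model was
chosen over per-site beta-binomial noise because run structure *is* what
the quantifiers measure; persistence moves the CHALM−Meanm gap without
moving Meanm, which is exactly the contrast the method family exploits.

Stated-world defaults: ~5 CpGs per read (typical RRBS read content), 30×
coverage, planted DMR shift |Δ| = 0.3 (the observed mean paired
tumor−normal difference within DMRs), 20 patient pairs, 200 regions with
10 planted, persistence ρ = 0.8 (most reads fully methylated or fully
unmethylated, as observed in real libraries), patient-level baseline noise
sd 0.05, per-region baselines uniform in [0.15, 0.55] (raised by Δ for
hypo regions so the shift stays feasible). The expression layer solves the
linear coefficient and noise variance so the population correlation with
promoter methylation equals a target $r$, then shifts onto a non-negative
log2(FPKM+1)-like scale (mean 6, sd 1.5; the ≥0 clip is active with
probability < $10^{-4}$ and is ignored thereafter).

Per-sample RNG streams derive from the global seed via a stable FNV-style
hash of the sample/region key, so enlarging a cohort never reshuffles
existing samples.

**Not emulated:** sequencing error, incomplete bisulfite conversion,
MspI fragment-level digestion, paired-end mate overlap, CpH contexts,
chromosome-scale position structure. A green recovery test therefore
establishes that the pipeline detects planted rank-shift signals of the
stated magnitude under idealized noise — not that it matches any
particular cohort's DMR counts, which depend on real data.

## Limitations

* Wemics is a per-site summary; it does not quantify methylation of a
  single read, and its weight saturates at 1 for single-CpG reads.
* The exact signed-rank path requires tie-free differences; heavily
  quantized methylation values at low coverage fall back to the normal
  approximation even at small $n$.
* Interval utilities assume modest input sizes (thousands of features);
  they favour clarity over asymptotic cleverness.
* Paired-end deduplication is by read id only; mate-overlap clipping is
  not implemented (reads sharing an id contribute once per id).
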