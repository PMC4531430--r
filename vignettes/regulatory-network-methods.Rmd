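---
title: "Methods: miRNA–gene regulatory network inference from paired tag counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA-gene regulatory network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirgnet)
```

## Overview

`mirgnet` identifies candidate miRNA and gene biomarkers of stem-like
cancer-cell populations from paired deep-sequencing count data and
infers the regulatory structure connecting them. The design follows a
fixed stage order: normalization → per-pair differential expression →
cross-pair consistency → consensus target integration → differential
restriction → anti-correlation filtering → bipartite network statistics
→ pathway enrichment → tripartite assembly. This vignette documents the
models, the tunable parameters, the numerical choices, and what the
synthetic-data validation does and does not demonstrate.

## The count model and the exact tag-count test

Digital tag counts from a sequencing library are modeled as Poisson:
the count $x$ of a feature in a library of $N_1$ total mapped reads has
mean $\lambda N_1$ for an unknown concentration $\lambda$. To compare
$x$ with the count $y$ of the same feature in a second library of size
$N_2$, the test integrates $\lambda$ out under a flat prior, giving the
predictive distribution of $y$ conditional on $x$, with
$r = N_2/N_1$:

$$P(Y = k \mid x) = \frac{r^k\,(x+k)!}{x!\,k!\,(1+r)^{x+k+1}},$$

a negative binomial with size $x + 1$ and success probability
$1/(1+r)$. The two-sided p-value is
$\min\{1,\, 2\min[P(Y \le y),\, P(Y \ge y)]\}$.

Numerical contract: log-space terms are computed in closed form via
`lgamma` and combined with log-sum-exp; the shorter tail (relative to
the predictive mean $(x+1)r$) is summed directly in chunks with early
termination at relative mass $e^{-45}$, and the longer tail is obtained
as its complement plus the point mass at $y$. This keeps the test exact
and overflow-free at deep-sequencing magnitudes (tested to counts of
$2 \times 10^5$). The test suite pins the implementation to an
independent direct-summation oracle at $10^{-12}$ over a
$51 \times 51 \times 3$ grid of counts and library ratios, and to the
negative-binomial tail identity at larger counts.

One property worth stating explicitly: because the distribution
conditions on the *first* count, the doubled-tail p-value is **not** an
exactly symmetric function of $(x, N_1)$ and $(y, N_2)$. At small
counts the two orientations can differ noticeably (e.g. $x=5, y=0$,
$N_1 = N_2$ gives 0.031 one way and 0.063 the other); the discrepancy
vanishes as counts grow. The package fixes the convention that the
condition (stem) sample supplies $x$ and the reference (parental)
sample supplies $y$, and the tests verify both orientations against the
oracle rather than asserting a symmetry the statistic does not have.

Empirical calibration: on 10,000 null draws with equal Poisson means
the rejection rate at nominal $\alpha = 0.05$ is close to nominal
(slightly conservative, as expected for a discrete doubled-tail test);
the acceptance checks require it to lie in $[0.03, 0.07]$.

## Differential calls and cross-pair consistency

Fold changes are computed on normalized values (TPM for miRNA tags —
the length-free tag-count reading, since small-RNA tags have a fixed
effective length; RPKM for genes) with a pseudocount added to both
sides:

$$\log_2\mathrm{FC} = \log_2\frac{\text{stem} + c}{\text{parental} + c},
\qquad c = 0.5 \text{ by default}.$$

The pseudocount keeps zero-count features finite; 0.5 is half the
smallest observable count, the conventional choice. P-values are
BH-adjusted per feature class and per pair (`stats::p.adjust`,
step-up), not pooled across pairs, so each pair's call set is
self-contained. A feature is called when $|\log_2\mathrm{FC}| \ge 1$
and $\mathrm{FDR} \le 0.01$ — both boundaries inclusive — and survives
only if called in the same direction in both cell-line pairs.
Discordant features are discarded from both sets, making the up and
down sets disjoint by construction.

Defaults (`threshold_config()`): `min_abs_log2fc = 1`,
`max_fdr = 0.01`, `min_sources = 2`, `enrichment_alpha = 0.05`,
`pseudocount = 0.5`. The FDR-scope choice (within-pair) is exposed only
through the API (calls are per pair); pooling across pairs is not
implemented because the per-pair call percentages are the quantities
the downstream consistency intersection consumes.

## Consensus targets and the anti-correlation filter

Predicted miRNA→gene pairs from any number of prediction tools are
ingested as two-column tables, deduplicated within each source, and
merged into per-pair source sets. A pair is a consensus interaction
when supported by at least `min_sources = 2` sources — raising the
threshold can only shrink the set. The prediction algorithms themselves
are out of scope: they are external published tools whose outputs are
inputs here, and gene identifiers are assumed pre-harmonized across
sources by the caller.

Consensus interactions are then restricted to pairs whose miRNA and
gene are both consistently differentially expressed, and finally
filtered to *anti-correlated* pairs (miRNA and gene moving in opposite
directions), reflecting miRNA-mediated repression. miRNAs whose
candidate set is empty are excluded from the network node set but keep
their all-zero rows in the per-miRNA summary table, which reconciles a
summary of 9 up-regulated miRNAs with a network of 7.

The packaged reference summary (`hcsc_target_summary()`) records, for
the 18 consistently differentially expressed miRNAs of the hepatic
cancer stem-cell system, the per-miRNA predicted/DE/candidate target
counts. Two rows whose printed digit runs are typographically ambiguous
are resolved by the row invariant
`de_targets = up_de_targets + down_de_targets` together with the
published column totals (651, 103, 1460). The summary's
total-predicted column sums to 54,952, slightly off the 54,933 quoted
alongside it in the source material; the discrepancy is inherent to the
printed table and is left unreconciled.

## Network statistics

Candidates form a directed bipartite miRNA→gene network. Per-miRNA
**NOD** (novel out degree) counts target genes whose only regulator in
the network is that miRNA; it always satisfies
$\mathrm{NOD}(m) \le \deg(m)$ and
$\sum_m \mathrm{NOD}(m) \le$ number of distinct targets, with equality
iff no target is shared. Connectivity uses `igraph` with the network
treated as undirected; components are ordered by decreasing size with
lexicographic tie-breaks, and all exports order nodes lexicographically
so identical networks serialize byte-identically.

The exact 2×2 test (`fisher_exact_2x2`) conditions on both margins; the
two-sided p-value sums hypergeometric point probabilities not exceeding
the observed one, with a $10^{-7}$ relative tie tolerance. An
exclusivity helper compares unique-vs-shared regulation between the up-
and down-miRNA subnetworks; the 2×2 framing of that comparison is one
plausible reconstruction among several, and is labeled as such rather
than presented as canonical.

## Pathway enrichment

Each miRNA's candidate target genes are tested against each pathway by
the hypergeometric upper tail $P(X \ge k)$ (`stats::phyper`;
overlap-zero pathways are omitted, since their one-sided p is 1).
Default background is the union of the collection's gene sets unless an
explicit universe is supplied — the most deterministic choice when the
annotation service's true background is unknown. Raw p-values are
thresholded at $\alpha = 0.05$ (inclusive) without multiple-testing
correction, matching the thresholding convention of annotation-service
workflows this mirrors; the conservative EASE variant (overlap reduced
by one) is available behind `ease = TRUE`. Significant pathways extend
the bipartite network into a tripartite miRNA–gene–pathway graph with
`member_of` edges for overlap genes and a flag on genes with a unique
regulator.

## The synthetic-data generator

`sim_config()` fixes the emulated study conditions: two stem/parental
cell-line pairs; library sizes $10^7$ (miRNA) and $10^6$ (genes),
echoing the magnitudes of the profiled libraries; 5% of features per
class truly differentially expressed at $\pm 2$ on the log2 scale
(4-fold), concordant across pairs by default; Poisson counts, with a
negative-binomial option (variance $\mu + \phi\mu^2$) for stressing the
aligned-null assumption. Null abundances are log-uniform over 30–3000
per million — the working range of features retained by a standard
min-count filter at these depths, chosen (once, by a pilot sweep of the
detectability of 4-fold effects at depth $10^6$) so that planted
effects lie in the regime the test is designed for. Seven prediction
sources include each true target pair with probability 0.8 and each
false pair with probability $10^{-4}$; consensus recall therefore has
the closed form $P[\mathrm{Bin}(7, 0.8) \ge 2] \approx 0.9996$, which
the tests verify empirically. Targets of a differentially expressed
miRNA are drawn with 10-fold weight on oppositely regulated genes,
producing anti-correlated candidate sets of the same order as the
reference summary (tens per miRNA). Pathway collections hold 40 sets of
30–120 genes; the planted pathway includes each candidate target of a
chosen miRNA with probability $\min(1, 5K/N)$ instead of $K/N$.

Every generator is a pure function of its config (seed included):
identical bytes on re-run, verified by the suite.

**What passing the synthetic checks shows — and what it does not.** The
generator matches the test's distributional assumptions (independent
Poisson counts, no between-replicate dispersion, no mapping or
annotation artifacts, identifier-harmonized sources, uniform pathway
membership). Recovery there demonstrates correctness of the
implementation and calibration of the statistics under their own model,
not robustness to overdispersed biological replicates — real designs
with biological replication should prefer dispersion-modeling tests,
which are deliberately out of scope here (the study design emulated has
no replicates, which is exactly when the Poisson exact test is the
standard choice). The NB noise option exists to probe, not to fix, that
gap.

## Problem sizes used by the checks

The shipped validation uses 2,000 genes × 300 miRNAs per replicate (20
replicates for differential-expression recovery; 50 seeds for
planted-pathway recovery; 10,000 draws for test size), and scaled-down
universes (300–600 features) for IO, consensus and pipeline tests —
sizes at which every property asserted is statistically decisive while
a full run of the suite stays inexpensive.

## Known limitations

- No dispersion modeling and no multi-group designs; exactly two
  condition/reference pairs feed the consistency intersection.
- Identifier harmonization across prediction sources is the caller's
  responsibility.
- The enrichment background defaults to the collection union; with a
  sparse collection this is smaller than a genome-wide universe and
  p-values are correspondingly conservative or liberal depending on the
  query's coverage — supply an explicit background when one is known.
- The reference summary supports interaction *counting*; distinct-gene
  statistics (shared targets across miRNAs) require the original
  interaction lists, which are not part of the fixture.
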