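---
title: "Identifying enhancer-mediated regulatory loops: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying enhancer-mediated regulatory loops: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`enhloops` identifies four classes of enhancer-mediated regulatory loops —
TF–enhancer–miRNA, TF–enhancer–gene and enhancer–miRNA–gene feed-forward
loops (FFLs), and TF–enhancer feedback loops (FBLs) — from enhancer
intervals, TF binding peaks, TSS annotations and multi-source miRNA-target
evidence. This vignette explains the model behind each stage, the
parameters that matter, the numerical and design choices that were
genuinely open, and what the synthetic validation does and does not show.

```{r setup}
library(enhloops)
```

## Coordinate model

All intervals are 0-based half-open (`[start, end)`), the BED convention;
readers convert at the boundary and optionally normalize a `chr` prefix so
mixed chromosome naming styles compare equal. Two intervals overlap iff
they share a chromosome and `max(starts) < min(ends)`, so book-ended
intervals do not overlap. Whether region boundaries are inclusive is a
convention, not a biological fact; half-open was chosen because every
input format here is BED-like and it makes coverage arithmetic exact.

The center of an enhancer is `floor((start + end) / 2)`: flooring makes
the even-length case deterministic in integer arithmetic. Strand is
ignored for enhancer and binding-site overlap — enhancer activity is not
strand-directional — and is mandatory only for promoter windows, which are
asymmetric around the TSS.

## Edge rules and their parameters

| Edge | Rule | Default |
|---|---|---|
| enhancer → gene/miRNA | TSS within ± flank of the enhancer center | 100 kb, inclusive |
| TF → enhancer | integrated binding site overlaps the enhancer | — |
| TF → miRNA | binding site overlaps the miRNA promoter window | 10 kb up / 1 kb down |
| TF → gene | binding site overlaps the gene promoter window | 5 kb up / 1 kb down |
| enhancer → TF | the enhancer's target genes include the TF-coding gene | — |
| miRNA → gene | integrated target evidence with score S > 1 | strict |

The ±100 kb rule reflects the empirical distance distribution between
enhancers and the promoters of their regulated genes; it is implemented as
the inclusive comparison `|tss − center| <= flank` ("within 100 kb" reads
naturally as inclusive; the boundary case is negligible but must be fixed
one way). Shrinking any window can only remove edges — a monotonicity the
test suite checks by property.

Curated enhancer–miRNA tables, where available, *replace* the proximity
rule for that edge type (these relationships are typically assembled from
dedicated external evidence rather than distance); a configuration flag
switches to the union of both. TFs with no binding data in a tissue simply
contribute no TF edges there — no imputation is attempted.

### Binding-site integration

When one TF has several ChIP-seq peak sets in a tissue, the final binding
regions are the basepair intersection of the per-dataset *merged*
coverages: a region counts only where every dataset shows a peak.
Intersection is deliberately region-level (not reciprocal-overlap peak
matching, which the source description does not require); within one
dataset overlapping peaks are unioned first, since multiple fragmented
peaks are an artifact of peak calling, not evidence of two sites. With a
single dataset the merged peaks pass through unchanged. Conserved-track
binding sites — the fallback when no tissue-matched ChIP-seq exists —
are filtered to score > 500 (strict) *before* any overlap computation,
because the filter defines which sites exist at all.

### miRNA-target integration

Each (miRNA, gene) pair present in at least one source database is scored

$$S = 0.5 \cdot N_i + N_c,$$

where $N_i$ counts distinct *prediction* databases and $N_c$ distinct
*experimentally validated* databases supporting the pair. Counting is per
database, never per row: the same pair recorded twice by one source counts
once. "Supporting" means the pair is present in that source; requiring
the predictors to agree on finer detail (site, seed class) is not
recoverable from pair-level evidence tables, so presence is the
implemented (and configurable) reading. With the default two prediction
and two validation sources, $S$ ranges over $\{0.5, 1.0, \dots, 3.0\}$;
with $P$ prediction and $V$ validation sources the range generalizes to
$[0.5,\ 0.5P + V]$. Only pairs with $S > 1$ (strict) are kept, which
discards all patterns supported by predictions alone or by any single
source. Conservation labels are pass-through metadata used only for
optional filtering of assembled loops, never for scoring.

## The co-regulation test

For a (TF, enhancer) pair the universe $M$ is the set of targets of the
family's target class that have **both** at least one TF regulator and at
least one enhancer regulator in that tissue (the intersection reading of
"co-regulatable"; a union universe is available by flag). This guarantees
$x \le \min(N, k) \le M$ for every tested pair. With $N$ and $k$ the
pair's marginal target counts inside the universe and $x$ their joint
count, the default ("printed") statistic is

$$P = 1 - \sum_{i=0}^{x} \frac{\binom{k}{i}\binom{M-k}{N-i}}{\binom{M}{N}},$$

computed by log-space summation of the upper tail so small values lose
nothing to cancellation; the suite verifies agreement with exhaustive
subset enumeration to $10^{-12}$ for all $M \le 12$.

Note that this sum runs to $x$, so it equals $P(X > x)$ — one notch beyond
the conventional enrichment tail $P(X \ge x)$. In particular it is exactly
0 whenever $x = \min(N, k)$, e.g. for every pair whose joint targets
exhaust one margin. The conventional tail is available as
`mode = "ge"`, and because only `"ge"` is a valid null p-value (the
printed form is anti-conservative by construction), the package's null
false-discovery validation is run in `"ge"` mode. The discrepancy is
documented rather than silently corrected; neither mode is claimed to be
what any particular resource used.

Pairs sharing no target are never tested — they cannot form loops, and
testing them would only dilute the FDR correction. Benjamini–Hochberg
q-values are computed independently per (tissue, family), mirroring
per-sample, per-loop-type identification, and the filter keeps `q < alpha`
strictly (default 0.05). `alpha = 1` is interpreted as "filter disabled"
so that permissive inspection keeps every tested pair, including those
with $q = 1$; any `alpha < 1` applies the strict inequality.

## Loop assembly

A loop row is emitted per joint target: a significant (TF, enhancer) pair
regulating three miRNAs jointly yields three TF–enhancer–miRNA rows. The
q-filter acts at the pair level before assembly — a non-significant pair
contributes no loops for any target. Enhancer–miRNA–gene loops carry the
target score and conservation of their (miRNA, gene) pair; whether this
family is itself subjected to the joint-target test is configurable and
off by default, since the test's quantities are defined for TF–enhancer
pairs (the family can be enabled with `test_enhancer_mirna_gene = TRUE`).
FBLs carry no enrichment statistic at all: the joint-target test is
defined over shared target sets, which a two-node mutual-regulation motif
does not have — fidelity was preferred over inventing a statistic.
Conservation and minimum-score refinements (`filter_loops()`) are
post-assembly, user-facing options.

The participation summary counts, per miRNA, the distinct samples whose
TF–enhancer–miRNA or enhancer–miRNA–gene loops contain it; "master"
status defaults to presence in at least 14 samples, the conventional cut
when screening 16 samples.

## The synthetic landscape

`generate_landscape()` emulates exactly what the pipeline consumes —
enhancer BEDs split by class, per-TF peak BEDs, TSS tables, per-source
evidence tables, a TF-coding-gene map — with a truth ledger of planted
loops. Planting is constructive: each planted loop occupies its own
400 kb slot and places exactly the features the edge rules require, so
100% recall at permissive settings is a logical consequence of the rules,
not a statistical outcome. The ledger also records the realized
$(M, N, k, x)$ of every planted pair, obtained by running the edge rules
on the generated data.

Each chromosome is split into a feature half and a reserved region where
background peaks land when `background_edge_density = 0`; because the
reserved region is disjoint from all enhancers and promoters, a
zero-density, zero-noise, unplanted landscape provably yields zero loops —
the generator's null is exact, not merely improbable. With density > 0,
background peaks are wired into random enhancers or promoters with that
probability.

Defaults were chosen once as desk-scale realistic: 3 chromosomes × 4 Mb,
40 enhancers with a super-enhancer fraction of 0.12 (approximately the
typical/super ratio in large human enhancer catalogs), 12 TFs, 25 miRNAs,
50 genes, 3 + 3 + 3 planted FFLs and 2 planted FBLs, 2% background
densities. What the generator does **not** emulate: realistic genome
composition, chromatin-state structure, correlated peak widths and signal
strengths, the heavy-tailed degree distributions of real regulatory
networks, or read-level noise. Passing tests therefore demonstrate the
correctness of the rules, statistics and bookkeeping — not that the
pipeline's biological discoveries on real catalogs would be well
calibrated, which depends on the quality of the input annotations.

Validation problem sizes are kept small by design: oracle equivalence uses
exhaustive enumeration up to $M \le 12$ and brute-force loop assembly on
landscapes with tens of elements per class; the null false-discovery
property uses 200 seeded random edge landscapes and checks the fraction of
replicates with any $q < 0.05$ discovery against a binomial band around
5%.

## Degenerate inputs, ties, determinism

Readers are strict by default — malformed records abort with their line
number; a lenient mode logs and skips. Empty peak files, empty evidence
and empty universes are valid (they produce empty results, with a logged
note), but an empty dataset map for binding-site integration is an error.
Tied p-values share a BH q by construction of the step-up minimum. All
writers emit canonical row sorts and fixed float formatting (6 significant
digits, scientific below 1e-4), so identical inputs give byte-identical
outputs, and the run manifest records parameters, input checksums and
per-stage counts. The generator drives all randomness from one integer
seed and restores the caller's RNG state.

## Known limitations

* Enhancer-target assignment is purely distance-based; chromatin-contact
  (Hi-C) or expression-correlation assignment is out of scope.
* No liftover: all inputs must share one assembly.
* The printed-form test statistic is anti-conservative as a null tail (see
  above); users wanting calibrated significance should select
  `pvalue_mode = "ge"`.
* Motif-based binding-site prediction is out of scope; binding sites must
  be supplied as precomputed peaks or conserved-track intervals.
* All-pairs interval joins are quadratic per chromosome, sized for
  annotation-scale inputs (thousands of features), not for genome-wide
  basepair tracks.
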