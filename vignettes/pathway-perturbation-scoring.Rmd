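---
title: "Scoring pathway perturbation from ranked gene lists"
author: "sppa package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring pathway perturbation from ranked gene lists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sppa)
```

## The problem

Exposure experiments — a toxicant, a drug, cigarette smoke on an airway
epithelial cell line — rarely act through a handful of marquee genes. A
coordinated 20% shift across an entire signaling pathway can matter more
than a ten-fold change in one gene, and a differential-expression cutoff
discards exactly that coordinated signal. `sppa` quantifies perturbation at
the pathway level and aggregates it into a single, comparable number: the
total effect score (TES). Larger TES means a broader and stronger
transcriptomic response; comparing TES across doses, time points or
products ranks their biological impact.

The package consumes (a) one per-gene differential statistic per gene (any
upstream DE tool's Wald Z or t statistic; optionally a raw count matrix
with two-group labels and a built-in statistic), and (b) a pathway
collection in GMT format with an optional two-column map from pathway to
top-level functional category, mirroring how the Reactome hierarchy groups
its pathways under ~27 topics.

## The model

**Step 1 — per-pathway effect score.** All N profiled genes are ranked by
decreasing |stat| into a list L; position 1 is the most perturbed gene.
For a pathway S with N_H member genes in L, a running sum is accumulated
along L:

$$P_{hit}(S,i)=\sum_{g_j\in S,\; j\le i}\frac{|r_j|}{N_R},\qquad
  P_{miss}(S,i)=\sum_{g_j\notin S,\; j\le i}\frac{1}{N-N_H},\qquad
  N_R=\sum_{g_j\in S}|r_j|$$

The effect score ES(S) is the maximum deviation from zero of
$P_{hit}-P_{miss}$, signed: near +1 when member genes crowd the top of the
ranking, near −1 when they crowd the bottom, near 0 when they scatter. Both
components end at 1, so the profile always returns to 0 — a conservation
property the test suite checks on every random instance.

Significance comes from a permutation null. The default (`gene_set` mode)
redraws N_H positions from L uniformly without replacement, 500 times, and
rescores; `sample_label` mode instead reshuffles the condition labels of a
supplied count matrix, recomputes the gene statistic and the ranking, and
rescores the original set. The one-sided nominal p compares |ES| with the
same-signed portion of the null (counts floored at one, so p is never 0),
and a Z-score standardizes ES against the full null (n−1 denominator).

**Step 2 — size weighting.** Pathways range from a few genes to over a
thousand; their leverage on the total should reflect that. Each pathway
contributes $\log_2(N_g)\times Z$, with $N_g$ the member genes present in
the ranked universe.

**Step 3 — category scores.** For each top-level category, the weighted
scores of its *significant* pathways (nominal p < alpha, default 0.05, no
multiplicity correction on this path) are averaged and scaled:
$NES = \overline{W}\times\log_2(n)$ with n the number of significant member
pathways.

**Step 4 — total effect score.** $TES=\sum_{\text{categories}} NES$.

## Worked instance

Five genes with metrics 5, 4, 3, 2, 1 and the set {g1, g3}: the profile is
0.6250, 0.2917, 0.6667, 0.3333, 0.0000 and ES = 2/3. The bottom pair
{g4, g5} gives ES = −1. With sets of size 2 there are only
$\binom{5}{2}=10$ permutations, so the null can be enumerated exactly; the
observed ES of 2/3 sits at p = 5/7 of the positive portion. These values
anchor the unit tests and the acceptance script.

```{r worked}
L <- build_ranked_list(data.frame(gene = paste0("g", 1:5),
                                  stat = c(5, 4, 3, 2, 1)))
prof <- running_sum(L, c("g1", "g3"))
round(prof$values, 4)
effect_score(prof)
null <- build_null(L, c("g1", "g3"), mode = "gene_set", exhaustive = TRUE)
nominal_p(effect_score(prof), null)
```

## Parameters that matter

- `n_perm` (default 500): permutations per pathway. The p floor is
  roughly 1/(n_perm/2) because only the same-signed portion counts;
  500 resolves p down to ~0.004, enough for a 0.05 gate.
- `alpha` (default 0.05): the significance gate between Step 1 and
  Step 3. Nominal by design; a Benjamini–Hochberg column is reported for
  inspection but never used in the TES path.
- `min_size` (default 2): single-gene pathways carry weight
  log2(1) = 0 and a degenerate running sum, so they are dropped.
- `log_base` (default 2): base of the size weight. The category formula
  is log2 by definition; the size weight defaults to log2 for coherence,
  with natural log available (`log_base = exp(1)`). TES scales linearly
  with this choice, so comparisons must hold it fixed.
- `mode`: `gene_set` permutation is the default because it needs only the
  ranked list; `sample_label` is the fuller null (it propagates
  between-sample variability through the statistic) but requires raw
  counts and is hundreds of times more expensive.
- `seed`: every pathway's permutation stream is derived from the seed and
  the pathway id, so results are bit-identical regardless of evaluation
  order or collection order.

## Design choices in ambiguous corners

- **Ranking metric.** The method ranks by the magnitude of the per-gene
  statistic, |Z|, treating up- and down-regulation symmetrically. The
  signed statistic is retained for reporting.
- **Ties.** Ties in |stat| are broken lexicographically by gene id; an
  exact tie between a positive and a negative running-sum extreme returns
  the positive one. Null scores of exactly 0 count toward the positive
  portion. All three rules exist for determinism.
- **Z against the full null.** The Z-score standardizes against both signs
  of the null; a matching-sign variant is available
  (`matching_sign_z = TRUE`) and recorded in provenance.
- **n = 1 categories.** A category whose single significant pathway gets
  NES = 0 through log2(1). This is the formula's documented behavior; the
  `nes_n_plus_one = TRUE` switch uses log2(n+1) instead.
- **Unmapped pathways** go to a reserved `Uncategorized` category and
  still contribute to TES (excludable via `exclude_uncategorized`);
  multi-parent pathways contribute to every parent category.
- **Degenerate nulls** (zero spread) yield an undefined Z; the pathway is
  flagged and contributes 0 downstream.
- **Built-in statistic.** The two-group statistic (Welch t on log2-CPM
  with pseudocount 0.5, converted to a signed normal quantile) exists so
  the sample-label null can re-rank genes; it is not a negative-binomial
  DE fit, and users with an edgeR/DESeq2 analysis should supply its
  statistics directly.

## What the synthetic data emulate — and what they do not

`simulate_pathways()`, `simulate_de_stats()` and `simulate_count_matrix()`
generate the three inputs at a reduced default scale chosen to keep the
full test suite at desk runtime: 1,000 genes, 50 pathways in 5 categories
(sizes log-uniform in 10–40), 5 planted perturbed pathways. Planted genes
draw their statistic from sign·Normal(3, 1) with a random sign — a strong
acute response — against a standard normal background; the count branch
uses log-normal base abundances, negative-binomial noise at common
dispersion 0.1, 3 samples per group at one million reads, and a planted
log2 fold-change of 2. These defaults were fixed once as a realistic
reduced-scale study; a paper-scale profile (15,000 genes, 2,263 pathways,
27 categories) is exercised in the runtime test.

The generators capture the statistical structure the scorer consumes — a
ranked list in which perturbed pathways' genes concentrate near the top —
but not features of real transcriptomes: correlated co-expression within
pathways, gene-length and GC biases, composition effects, dropout, or
dose–response kinetics. Passing tests therefore demonstrate correctness
and calibration of the algorithm, not biological validity on any
particular dataset; and the absolute TES scale depends on the collection
and data, so TES values are comparable only within a fixed collection,
universe and parameter set.

## Numerical notes

- The running-sum profile is O(N) per pathway; permutation scoring uses a
  hit-only O(N_H log N_H) evaluation of the extremum, verified exactly
  against the brute-force per-position oracle on random instances.
- Profiles end at 0 within 1e−9; all values lie in [−1, 1].
- Serialized tables round to 6 significant digits; reruns with an
  identical configuration are byte-identical.
- Test and acceptance problem sizes: 1,000 random oracle instances
  (N ≤ 12), 1,000 null calibration tests at 500 permutations, 100
  recovery replicates, a 4-point effect-size grid with 6 replicates per
  point, and one full-scale 15,000 × 2,263 × 500 run.

## Known limitations

- Nominal p-values gate the TES; with thousands of pathways some
  significant calls are false positives by construction, and TES inherits
  that (the reported BH column quantifies it).
- Gene identifiers are matched case-sensitively with no translation;
  mixed identifier schemes between the statistics table and the GMT will
  silently shrink effective sizes (the dropped-set log is the guard).
- The `sample_label` null with few samples per group is coarse: with
  3 vs 3 there are only 20 balanced relabelings, and many permutations
  repeat.
- Reaction-level structure inside pathways is not modeled; a pathway is
  its gene set.
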