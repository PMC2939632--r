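---
title: "Deterministic trio phasing: model and implementation notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deterministic trio phasing: model and implementation notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triophaser)
```

## The trio phase model

Genotypes are encoded per site as `0` (homozygous major allele), `1`
(homozygous minor), `2` (heterozygous) and `NA` (missing). A phased trio
is a 4 x L matrix with rows `f.t`, `f.u`, `m.t`, `m.u`: the father's
transmitted and untransmitted haplotypes and the mother's. The child's
haplotypes are exactly the two transmitted rows, so the child's genotype
is determined by `(f.t, m.t)`.

At a single site there are 16 possible phased tuples. The observed
father/mother/child genotype triple constrains them:

* if any member is homozygous, or only one parent is heterozygous, the
  site is **resolved** — exactly one tuple is consistent;
* if all three members are heterozygous, the site is **ambiguous** — two
  tuples are consistent (which parent transmitted the minor allele);
* missing genotypes leave more tuples open;
* if no tuple is consistent the site is a **Mendelian error**.

Because sites constrain solutions independently, a complete trio with
`L'` ambiguous sites has exactly `2^L'` consistent solutions:

```{r law}
trio <- trio_genotypes(father = c(2, 2, 0), mother = c(2, 2, 1),
                       child = c(2, 2, 2))
count_ambiguity(trio)$n_solutions_bound
length(enumerate_trio_solutions(trio))
```

`enumerate_trio_solutions()` generates solutions in a fixed order (site
tuples are tried in descending lexicographic order over
`(f.t, f.u, m.t, m.u)`), which every downstream tie-break relies on.

## Entropy block partition

Long marker ranges are split into blocks before phasing. For a genotype
matrix over all cohort members, the entropy of the marker interval
`[i, j]` is `-sum(p_k log p_k)` over the empirical frequencies of the
distinct genotype segments in that interval (missing entries count as a
distinct symbol). `optimal_partition()` minimizes the summed entropy
over all partitions whose blocks are at most `W` markers wide, by
dynamic programming over the last block boundary. Ties prefer fewer
blocks, then later split points. Intervals are 1-based and closed, and
the returned block table tiles `1..L` exactly.

Low-entropy blocks contain few distinct local haplotypes, so per-trio
solution counts stay small and haplotype sharing across trios is strong.

## The deterministic sampling engine

Within a block, trios are sorted by ascending solution count (stable
sort) and processed sequentially. The engine state is a set of at most
`K` *streams*; each stream is one choice of solution for every processed
trio plus a vector of Dirichlet pseudocounts `rho` over the haplotype
catalog. Every catalog haplotype starts at `epsilon` (default 0.1), plus
1 for each occurrence in an optional reference panel.

Extending a stream by a candidate solution with haplotypes
`h1, h2, h3, h4` multiplies its weight by

    rho[h1] * rho[h2] * rho[h3] * rho[h4] / (sum(rho))^4

i.e. the product of posterior-mean haplotype frequencies under that
stream's counts, and then increments the four used counts by one (so
`sum(rho)` grows by exactly 4 per trio — an invariant the tests check).
After each trio only the `K` heaviest streams survive; ties are broken
lexicographically on the solution-choice path. Initialization enumerates
the largest prefix of trios whose product of solution counts fits in
`K`, so easy trios are handled exhaustively. When `K` covers the full
product for all trios, the engine provably equals brute-force joint
enumeration; the suite verifies this bit-for-bit.

An exact-moment variant of the scoring factor (rising factorials,
`solution_factor(..., exact = TRUE)`) is available but off by default;
the posterior-mean product is the standard update.

## Ligation

Adjacent phased blocks are merged pairwise. Every pair of streams (one
per block) gets a *ligation weight*, the product of its source weights.
Pairs are pruned to the top `K` by ligation weight, the concatenated
solutions are re-scored by running the sequential update over the merged
interval from scratch (trios ordered by ascending local solution
diversity), and final weights are the ligation weight times the
re-score, renormalized. The merge schedule is greedy minimum-entropy:
at each step the adjacent pair whose merged interval has the lowest
genotype-segment entropy is merged, leftmost first on ties. On two-block
toys with `K` large enough this reproduces direct joint phasing of the
whole interval exactly (up to exact weight ties, which both routes break
by their own deterministic rules).

`finalize_phasing()` takes the top stream, asserts that every
reconstructed genotype matches the observed input, and imputes the
originally missing entries from the chosen haplotypes.

## Simulator and study conditions

`simulate_dataset()` draws a block-mosaic haplotype pool: founder
haplotypes per block (at most `block_diversity` lineages, Zipf-skewed
lineage weights), lineage switching between blocks at rate
`recomb_hotspot_rate`, a minor-allele-frequency floor `maf_min` (columns
below it are dropped and regenerated), and the convention that `0` is
the pooled major allele. Each trio receives four *distinct* pool
haplotypes; one haplotype per parent is chosen (uniformly) as
transmitted; missingness is masked uniformly at rate `missing_rate`.
All randomness derives from one master seed via four stage seeds, each
below 2^31.

The defaults — 30 trios, 200 markers, pool of 120 haplotypes, 8
lineages per 10-marker block, hotspot rate 0.1, MAF floor 0.05, no
missingness — are the package's study conditions, used unchanged by the
test suite and the acceptance report.

Accuracy is reported as the **transmission error rate** (wrong
transmitted/untransmitted assignments over non-missing parental entries
at truly ambiguous sites), the number of **incorrect trios** (at least
one phase or imputation error), and the **allelic imputation error
rate** (mismatched alleles over masked entries, comparing unordered
genotype pairs). `phase_random()` provides the chance baseline, which
errs on about half of the ambiguous entries.

## Numerical and determinism notes

* Stream weights are kept in log space and renormalized with a
  log-sum-exp after every step.
* All sorts are stable (`order()` with explicit tie-break columns), so
  identical inputs give bit-identical output across runs and platforms.
* Cohorts larger than `slice_size` (default 100) are phased in
  consecutive slices; later slices receive the earlier slices'
  top-stream haplotypes as extra prior pseudocounts, and slice stream
  sets are recombined by weight product.
* Per-trio, per-block enumeration is capped at `max_solutions` (default
  4096); heavily missing trios beyond the cap are enumerated under a
  catalog restriction derived from the rest of the cohort.

## Limitations

* Biallelic markers only; multiallelic sites must be recoded upstream.
* Trios only — larger pedigrees are not modeled.
* Recombination within a child is not modeled: each parent transmits one
  intact haplotype, which is appropriate for the short regions (up to a
  few hundred markers) the method targets.
* Genotyping error is not modeled beyond Mendelian screening; an
  impossible site is masked, not corrected.
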