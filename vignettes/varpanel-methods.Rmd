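---
title: "Methods: from filtered variants to a minimal discriminating SNP panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from filtered variants to a minimal discriminating SNP panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varpanel)
```

varpanel analyzes a joint-genotyped, multi-sample VCF of a small diploid
cohort — its motivating case is 22 Mediterranean rice varieties called
against the Nipponbare reference — and carries the analysis from hard
filtering through diversity statistics, relatedness, functional-impact
screening, and the selection of a minimal SNP panel that tells every
variety apart. This vignette explains the models and conventions behind
each stage, the tunable parameters and their defaults, and what the
synthetic-data generator does and does not emulate.

## Coordinates, genotypes, and missing data

All positions are 1-based; QTL intervals are end-inclusive, matching how
VCFs and QTL databases print coordinates. Windows tile chromosomes with
1-based starts and half-open spans `[start, start + size)`, which makes
window counts sum exactly to chromosome counts (the conservation
invariant several tests assert). Chromosome names are compared after
stripping an optional `chr` prefix, tolerating IRGSP versus MSU naming.

Genotypes are unphased: `1/0`, `0|1` and `0/1` are the same call, and
`normalize_gt()` canonicalizes them by sorting allele indices. Any call
containing `.` is missing. For panel work, genotypes become
alternate-allele dosages 0/1/2, and heterozygous is deliberately a
*distinct* state from both homozygotes: in the published 5-SNP panel,
two long-grain varieties differ only through a `0/1` versus `1/1` call,
so collapsing heterozygotes would destroy discrimination.

Two different missing-data policies apply downstream. Diversity and
distance statistics use *pairwise deletion* — every site contributes
whatever non-missing alleles it has. Panel selection instead requires
*complete rows*: a matrix row with any missing call is excluded before
the search, so every variety profile is fully observed and the search
never reasons about wildcards. The reader also offers an `"all"` policy
(drop only rows missing in every variety), but since a partially missing
row cannot form a complete profile it errors rather than silently
keeping `NA`s.

## Hard filtering

A variant record is a SNP when the reference and all alternates have
length 1, an InDel when every alternate differs in length from the
reference, and MIXED otherwise; MIXED records are routed to neither
stream but tallied, so nothing is silently lost. Filtering uses fixed
thresholds with strict comparisons — a SNP is removed iff

QD < 5, SOR > 3, FS > 50, MQ < 50, MQRankSum < −2.5,
ReadPosRankSum < −1.0 or ReadPosRankSum > 3.5,

and an InDel iff QD < 2.0, FS > 200.0 or ReadPosRankSum < −20.0. Values
exactly at a threshold pass; a dedicated boundary test pins this. The
rank-sum annotations only exist at sites with heterozygous carriers, so
absent metrics pass by default (`missing_metric_passes = TRUE`) —
failing on absence would discard most homozygous-only sites. The report
attributes each removal to the *first* failing condition in a fixed
order (QD, SOR, FS, MQ, MQRankSum, ReadPosRankSum low/high), which
makes per-condition tallies well defined even for multiply-failing
records.

## Summaries: rate, density, spectra, windows

Per chromosome, the variant *rate* is mean base pairs per variant,
`length / (n_snps + n_indels)`, and the *density* is variants per 1-kbp
window, so `rate × density = 1000` identically — a definitional check
applied to every summary row. The `"All"` row pools counts and lengths;
it is not an average of per-chromosome values. The substitution
spectrum counts all 12 ordered base changes without strand collapsing
(C>T and G>A stay separate), with multi-allelic records contributing one
count per alternate allele while record-level counts stay record-based.
InDel lengths are signed (`nchar(alt) − nchar(ref)`), negative for
deletions.

## Windowed diversity: π, Watterson's θ, Tajima's D

Each diploid variety contributes two haploid alleles, so V varieties
give n = 2V sequences. At one site with m non-missing alleles and
alternate frequency p, the unbiased diversity contribution is
2·p·(1−p)·m/(m−1) — exactly the probability that two alleles drawn
without replacement differ, as the test suite verifies by brute-force
pair enumeration. A site's alleles count as long as m ≥ 2, so a single
typed heterozygote is a genuine segregating site. Sites missing more
than `max_missing` (default 20%) of their alleles are excluded, because
the m/(m−1) correction degrades at high missingness.

Tajima's D is the classic normalized difference
(π − S/a1) / sqrt(e1·S + e2·S·(S−1)) with the standard constants on
n sequences; the implementation is checked against an independently
coded version to 1e-10 on random windows. Windows with S = 0 are
*undefined*, never reported as 0 — sign is the scientific signal
(positive peaks suggest balancing selection), and a fabricated zero
would be a silent lie. D is computed directly per window (default
100 kb); computing it at finer scale and averaging would be an
alternative reading of a windowed-mean track, but direct per-window
computation is the convention adopted here.

## Relatedness

The pairwise distance is the allele-sharing (IBS) distance
`Σ|dose_i − dose_j| / (2·n)` over jointly non-missing sites, lying in
[0, 1]. The cited upstream tree tool's "default parameters" are not
reproducible from its description, so the distance is defined here
explicitly and both neighbor-joining (default) and UPGMA are offered;
the choice is recorded in the output metadata. NJ recovers additive
matrices exactly (topology and branch lengths, tested to 1e-9); on
non-additive input, negative branch lengths are clamped to zero with
the deficit logged. Allele-sharing distances may violate the triangle
inequality; violations are counted and reported, not fatal. Newick
output single-quotes labels containing whitespace (variety names like
"Basmati Type III"), and `read_newick()` reverses the quoting so
round-trips are exact.

Per-chromosome density-profile clustering normalizes each variety's
windowed SNP counts to unit sum before Euclidean average-linkage
clustering cut at k = 4: the object of interest is the *pattern* of
where a variety's variants fall, not its total count, which is
confounded with sequencing depth. The module is deterministic — no
random steps, ties resolved by `hclust`'s fixed agglomeration order.

## HIGH-impact × QTL screening

SnpEff-style `ANN` strings are parsed into (allele, effect, impact,
gene) tuples; only the four canonical impact levels are accepted and
blocks with fewer than four subfields are skipped with a warning, not
an error. Every (record, HIGH annotation) pair yields one impact record
with per-variety carrier states taken directly from GT — missing stays
missing, never imputed. QTL matching is positional and end-inclusive on
both boundaries; a gene's QTL list is the union over all its
HIGH-impact positions, and duplicate interval ids in the source table
count once per listed interval (databases list an id once per interval
row), with a dedup switch. Genes matching nothing are reported with
empty lists by default so the screen's denominator stays visible.
Functional enrichment is out of scope: it requires an external
annotation service.

## Minimal discriminating panels

A panel discriminates when all variety profiles restricted to it are
pairwise distinct — a test-cover problem over the
`choose(V, 2)` variety pairs, where SNP s covers pair (i, j) iff their
dosages differ at s. Two solvers share this pair-cover bookkeeping:

* `exact_min_panel()` enumerates subsets in increasing size
  (lexicographic within a size, giving deterministic tie-breaks) and
  returns the first cover — a certified minimum. It is capped at 25
  SNPs by default, as subset enumeration beyond desk scale is the
  heuristic's job.
* `crs_min_panel()` is a seeded greedy random-restart heuristic in the
  conditional-random-selection family: each trial shuffles the SNPs
  with a seed derived as `seed + trial`, greedily adds the SNP covering
  the most uncovered pairs (ties to the earlier shuffled position),
  then backward-prunes redundant members; the best panel over
  `n_trials` (default 1000) wins. Results are replayable from
  (matrix, seed, n_trials) and always pass `validate_panel()`; the
  exact solver lower-bounds the heuristic wherever both run, and a
  heuristic result is never labelled a proven minimum.

On the published 5-SNP × 22-variety matrix, exhaustive search confirms
that the full panel discriminates all 22 varieties and that no 4-SNP
subset does — dropping the fifth SNP collides Ariete with Gageron,
among others.

## The synthetic cohort generator

Real whole-genome cohorts are not shippable, so `generate_cohort()`
emits a cohort whose every downstream answer is known at generation
time. The default spec uses 12 chromosomes of 1 Mb (a full pipeline run
in seconds; real rice chromosomes are 23–45 Mb), SNP rate 5e-4/bp and
InDel rate 1e-4/bp (desk-scale stand-ins for the ~10× denser real
data), Ti/Tv 2.5, missing rate 2%, and 22 varieties.

Population structure is a two-level Balding–Nichols model: a Beta(0.4,
1.2) ancestral frequency per site, two clusters diverged at Fst 0.3, and
inside the first (6-variety) cluster a 4-variety subgroup at Fst 0.05
emulating the Basmati-like quartet. The subgroup's frequencies are
additionally enriched (to at least U(0.3, 0.8)) at sites inside
"signature" windows — 30% of each chromosome's 100-kb windows — which
raises its overall non-reference density roughly 1.4–1.5× and, after
unit-sum normalization, leaves a window *pattern* that profile
clustering recovers. InDel lengths are geometric with modal magnitude
1. Filter-failure records violate exactly one named condition each, so
every removal is single-fault attributable; passing records draw their
INFO metrics uniformly inside passing ranges, rounded to three decimals
so text round-trips are exact. The planted panel is constructed from
"twin" variety pairs that differ at exactly one panel SNP each —
making every SNP necessary — and certified by the exact solver before
emission. Planted HIGH-impact sites carry two heterozygous and two
homozygous-alternate carriers each, with QTL intervals placed to cover
a known subset of genes (including a start-boundary case) plus decoys
covering none.

For diversity tests, `generate_popgen_window()` produces windows of
four regimes; the `"neutral"` kind draws each site's alternate count k
from the neutral sample frequency spectrum (P(k) ∝ 1/k) with uniform
assignment to haploid slots, which makes E[π] equal Watterson's θ
exactly, so Tajima's D centers on zero by construction — the right
null for a sanity band on the statistic. (Drawing binomial dosages from
Beta population frequencies, the obvious alternative, biases sample D
noticeably and is not a neutral emulation.)

What the generator does *not* emulate: linkage disequilibrium and
recombination (sites are independent), demographic history beyond the
two-level Fst hierarchy, sequencing or caller error models, genotype
uncertainty, and the empirical INFO-metric distributions of a real
caller. Passing tests therefore certify the *algorithms* — exact
bookkeeping, estimator correctness, planted-structure recovery — not
calibration against real rice data, whose headline counts depend on
deep WGS of the actual cohort.

## Worked example

```{r example, eval = FALSE}
coh <- generate_cohort(cohort_spec(seed = 1), out_dir = "data")
run_pipeline(coh$paths$vcf, coh$paths$qtls, coh$paths$chroms,
             out_dir = "results", crs_trials = 200, seed = 1)

gm <- table4_genotypes()
validate_panel(gm, gm$keys)$discriminating # TRUE, 22 distinct profiles
length(exact_min_panel(gm)$panel)          # 5 — certified minimum
```

## Limitations

The exact solver is exponential and intentionally capped; CRS panel
sizes on large matrices are upper bounds, not certified minima. Tajima's
D windows assume a fixed n = 2V; heavy, systematically uneven
missingness would make the fixed-n constants optimistic. The
allele-sharing distance is model-free: branch lengths are not
substitution rates and should not be read as divergence times.
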