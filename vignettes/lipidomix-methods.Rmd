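---
title: "lipidomix: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lipidomix: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: what
each analysis computes, under which assumptions, which tunable parameters
matter, and where the design was genuinely open, which choice was made and
why. The companion `README.md` shows a worked example; here we concentrate
on the methods.

## The analysis unit

All analyses consume a `lipid_experiment`: a lipids x samples matrix of
log2 abundances with every sample assigned to `case` or `control`.
`preprocess()` builds it from a raw nonnegative abundance matrix in four
recorded steps:

1. **Missing-value filtering.** Species missing in more than
   `max_missing_fraction` (default 0.5) of samples are dropped. Lipidomics
   intensity tables routinely contain values missing because a species was
   below the detection limit in some runs; a species absent from most
   samples carries too little information for a two-group comparison.
2. **Half-minimum imputation.** Remaining missing values are replaced by
   half the per-species observed minimum — the standard left-censoring
   surrogate in metabolomics. Note its cost: when a species is truly
   higher in cases, the minimum comes from controls, so an imputed case
   value drags the estimated effect toward the null. The power figures
   below include this effect.
3. **Optional per-sample normalization.** `"median"` or `"sum"` scaling
   to the across-sample mean of the respective statistic; default
   `"none"` because many lipidomics matrices arrive already normalized.
4. **log2 transform** with a pseudocount of 1 only when zeros remain
   (otherwise 0), so strictly positive data are transformed exactly.

Re-running `preprocess()` on processed data with `log2_transform = FALSE`
and no normalization is the identity, which keeps the pipeline idempotent.

## Nomenclature and characterization

The parser implements sum-composition (`"TAG 48:0"`) and
molecular-species (`"PE 18:0_20:4"`) shorthand for a registry of 20
common classes (glycerolipids, glycerophospholipids and their lyso forms,
sphingolipids, cholesteryl esters, fatty acids), with synonyms
(`TG`→`TAG`), the parenthesized dialect, `O-`/`P-` ether prefixes on
classes that admit them, and `d`/`t` sphingoid hydroxylation prefixes.
The registry is a TSV and can be replaced or extended by the user.

Separators `/`, `_`, `-` and the en-dash are treated as equivalent and
normalized to `_` in the canonical name, with chains sorted by (carbons,
double bonds, hydroxyls). This deliberately discards sn-position
information: retaining `/` as "position known" would conflict with
canonical sorting and break the round-trip guarantee
(`parse(canonicalize(x))` reproduces `x`), which we consider the more
valuable property for ID reconciliation across datasets. Unknown adducts,
isotope labels and unregistered head groups are rejected with a reason
code rather than guessed: a logged failure is recoverable, a silent
misparse is not.

Characteristic aggregation sums **linear-scale** abundances of all
species sharing a characteristic value. Sum (not mean) preserves
conservation — per-sample level sums equal the total annotated abundance
for the partition characteristics — and gives class totals the additive
semantics the reaction network needs. Chain-level characteristics
(`chain_carbons`, `chain_double_bonds`) are deliberately *not* a
partition: a `PC 16:1_20:3` genuinely contains both a 16- and a
20-carbon chain and contributes its full abundance to both levels.

## Differential analysis

Species are tested with a two-sided Welch t test on log2 values (default)
or the Wilcoxon rank-sum test; p-values are Benjamini-Hochberg adjusted
across all tested species, and a species is called `up`/`down` only when
both `fdr < alpha` (default 0.05) and `|log2_fc| > fc_cut` (default 1,
i.e. two-fold). Welch is the default because log-intensity data are
approximately normal after the transform and group variances need not be
equal; Wilcoxon (exact where sample size permits) is offered for heavier
tails. A species with zero variance in both groups has no defined t
statistic; it falls back to the exact Wilcoxon comparison and is listed
in the `fallback_features` attribute — a sentinel statistic would
misrepresent the evidence.

Characteristic-level testing applies the identical machinery to the log2
of aggregated matrices, with BH within the characteristic's levels.

The **dual-characteristic grid** bins one class's species by (total
carbons, total double bonds). Each cell reports the mean species-level
log2 fold change of its members, and a p-value from testing the cell's
*summed* linear abundance between groups — a well-defined single test
even when a cell holds several species — BH-adjusted across the
non-empty cells. We do not compute a single chain-length x unsaturation
correlation coefficient: per-cell significance flags are the readout,
because a single coefficient cannot localize which structural region of
the class responds.

Under the reference study conditions (10 vs 10 samples, per-sample noise
SD 1 on the log2 scale, 5% missingness), the per-cell power of a +2 log2
shift in a single-species cell is roughly 0.6-0.85 once BH and the
imputation drag are accounted for. Qualitative claims about "which cells
light up" are therefore assessed in expectation over repeated
simulations, not on a single draw.

## Enrichment

Lipid sets are derived from characteristics (one set per class, ether
variants such as `PC O-` kept separate, since ether lipids respond as
their own functional family), from binned numeric characteristics
(default widths: 4 carbons, 2 double bonds), or read from a GMT-style
TSV with unknown members dropped and logged.

**ORA** forms the 2x2 table of set membership against the up- (or down-)
called features, over the universe of *tested* lipids — conditioning on
the tested universe, not on everything parseable, avoids detection bias —
and computes the one-sided Fisher exact p (equivalently the
hypergeometric upper tail). Odds ratios come from the same table with a
Haldane 0.5 correction when a cell is zero.

**LSEA** is a GSEA-family running-sum statistic on a ranked list: at each
set member the sum rises by `|statistic|^weight_p` normalized over
members (default `weight_p = 1`; 0 gives the classical
Kolmogorov-Smirnov form), at each non-member it falls by
`1/(N - set size)`; the enrichment score is the maximum signed deviation.
At an exact tie between the positive and negative extreme the positive
one is returned; the tie-break uses a 1e-12 slack so the choice is stable
under floating-point reordering.

The null permutes set labels over lipids (gene-set style), not sample
labels: with 10 samples per group there are too few sample permutations
for stable tail estimates, whereas label permutations are valid at any
sample size. The p-value ranks the observed ES among the permuted scores
**of the same sign**, `p = (b + 1) / (n_same + 1)`. Dividing by the
same-sign count rather than the total permutation count is essential for
calibration: the observed ES is exchangeable only with the same-sign
subset, and dividing by all permutations would double the type-I rate at
the nominal level. `NES = ES / mean(|permuted ES| of the same sign)`.
Defaults `n_perm = 1000`, minimum set size 3, maximum 500 follow
gene-set-analysis convention; everything is reproducible given `seed`.

## Reaction-network activity

The package ships a small curated directed graph of established
lipid-class conversions (Kennedy pathway, PEMT methylation, base
exchange, phospholipase remodeling to lyso species, the
ceramide-sphingomyelin cycle). It is a convenience default, clearly
replaceable by an edge-list TSV; no claim is made that it reproduces any
particular platform's network.

Edge activity is scored as follows: per sample,
`r_s = log2(product-class total) - log2(substrate-class total)`; the edge
z-score is the case-control difference of mean `r` over its Welch
standard error, with a two-sided normal p. The score is direction-aware
(a rising product/substrate ratio in cases is positive), scale-free
(ratios cancel normalization), and testable. When the ratio is constant
within both groups the standard error is zero; the edge then receives a
sentinel z of `sign(difference) * 1e6` (0 for no difference) with a
warning — never a division by zero. Edges whose classes are absent from
the data are skipped and logged.

Path scores are the mean z over a simple path's edges, enumerated up to
`max_path_len = 4` edges (class graphs are small; the bound keeps
combinatorics trivial and is configurable). Paths with
`|score| > 1.5` are flagged as highlighted — the conventional cutoff for
emphasizing strong routes in network diagrams — while single-edge calls
use `|z| > 1.96`.

## Profiling

PCA operates on samples as observations, centered, optionally scaled,
via singular value decomposition, with a deterministic sign convention
(the largest-magnitude loading of each component is positive) so results
are reproducible and exactly invariant to lipid row order. The t-SNE and
UMAP embeddings are compact implementations of the standard algorithms —
exact-gradient t-SNE, and a fuzzy k-NN graph with full-batch
cross-entropy layout for UMAP — sized for the tens-of-samples designs of
two-group lipidomics, seeded and deterministic given the seed. They are
labeled stochastic: tests and downstream logic rely only on shape and
seed-determinism, never on their geometry. Sample correlation
(Pearson/Spearman) is ordered by average-linkage clustering of `1 - r`;
zero-variance samples, for which correlation is undefined, are excluded
and reported.

## The synthetic generator

`sim_spec()` encodes the reference study the package is exercised on: a
10 vs 10 case-control design over ~200 species of the common classes,
per-lipid log2 baselines N(20, 2), per-sample noise SD 1, 5% of values
missing completely at random, and planted case effects mirroring a
heart-failure-like remodeling — all TAGs up one log2 unit, short-chain
low-unsaturation TAGs (C <= 50, DB <= 2) up one further unit, ether PCs
down 1.5 units. Effects are additive on the log2 scale, matching the
differential model's assumptions so that power and FDR readouts are
interpretable.

The generator emulates: parseable names with valid random compositions,
log-normal abundance, MCAR missingness, planted group effects with
structural selectors. It does **not** emulate instrument noise models,
intensity-dependent (MNAR) missingness, batch effects, correlated lipid
modules, or isotope interference. Tests passing on this generator
therefore demonstrate the statistical machinery under its stated
assumptions — they do not certify behavior on data violating them (e.g.
strongly MNAR tables, where half-minimum imputation is known to bias
effect estimates).

Simulation sizes used by the test suite — 200 null datasets of 300
lipids for calibration, 60 datasets for recovery, 500 replicates at 500
permutations for the LSEA null, 200 replicates for the network sign
check — were chosen as the smallest sizes at which the 99% binomial
bands are meaningfully narrow.

## Known limitations

- Two groups only; no paired designs, covariates, or moderated variance
  estimators.
- The nomenclature grammar covers the registry classes and shorthand
  dialects listed above, not a full grammar (oxidized lipids, glycan
  head groups, isotope labels are rejected by design).
- The bundled reaction topology is a curated convenience; conclusions
  about specific routes should use a study-appropriate graph.
- Half-minimum imputation attenuates true effects in proportion to
  missingness; with high missing rates prefer filtering.
- LSEA p-value resolution is bounded by `1/(n_same + 1)`; increase
  `n_perm` when very small adjusted p-values matter.
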