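---
title: "Virtual pulldown: from discriminant metabolites to protein network modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual pulldown: from discriminant metabolites to protein network modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metapull)
```

## The problem and the model

Metabolomic studies routinely end with a list of discriminant metabolites
and little machinery to say which cellular processes they touch, because
curated metabolite-to-pathway annotation is sparse. `metapull` works around
that gap by using proteins as a functional intermediary: each discriminant
metabolite is resolved to the proteins it is known to bind or functionally
associate with, and each such *seed protein* is expanded into its
first-order interaction neighborhood within a confidence-weighted
protein-protein interactome — a *virtual pulldown*, the computational
analogue of a physical pulldown experiment. The resulting subnetworks are
cleaned of known PPI artifacts, merged when redundant, and prioritized by
over-representation statistics.

The pipeline has five stages:

1. **Omics QC.** Metabolite intensity tables are filtered (metabolites with
   more than 30% missing values are eliminated — strictly greater than, so
   exactly 30% is retained), optionally divided by per-sample volume
   (plasma block), rescaled so each metabolite's observed median is 1,
   imputed by half the observed minimum of each metabolite, and
   natural-log transformed, in that fixed order. Amplicon (ASV) count
   tables are filtered (taxa that are both present in fewer than 10% of
   samples and have median count 0 are removed) and transformed to
   centered log-ratios. Multivariate outliers are flagged by projecting
   samples onto the first two principal components and comparing squared
   Mahalanobis distances in score space with the 99th percentile of a
   chi-squared distribution with 2 degrees of freedom (cutoff 9.2103).
2. **Seed mapping.** Queries are matched against an association table in
   three precedence tiers — exact primary identifier, exact structural key,
   case-insensitive name/synonym — and links supported only by text-mining
   co-mentions are excluded before matching.
3. **Pulldown.** Interactome edges below confidence 0.1 are dropped (and
   nodes left isolated with them). Each seed yields the induced subgraph on
   itself plus its direct neighbors. Non-seed nodes that are globally
   promiscuous (degree above the interactome's 99th percentile) *and*
   weakly engaged in the module (within-module degree under 10% of global
   degree) are pruned. Modules above 200 nodes are capped to the seeds plus
   the neighbors with the highest edge confidence to any seed (ties broken
   by ascending protein id), unless their pre-cap seed-protein enrichment
   q-value is at or below 1e-4, in which case they are kept whole. Finally
   modules overlapping by more than 75% are merged to a fixpoint.
4. **Enrichment and classification.** Every module is tested against every
   gene set by a one-sided Fisher exact test (hypergeometric upper tail)
   against the filtered-interactome background, with Benjamini-Hochberg
   correction per gene-set class. Modules significant (q ≤ 0.05) against a
   disease-associated set form the *core* set; modules significant against
   the seed-protein set and linked to at least three discriminant
   metabolites form the *exploratory* set.
5. **Summaries.** Across a fixed module subset, each annotation is scored
   by the geometric mean of its corrected significance values (missing
   tests counted as 1.0, values floored at 1e-300 before the log) and the
   arithmetic mean of its enrichment scores (k/n)/(K/M); the 20 annotations
   with the lowest averages are shortlisted and then filtered at
   significance ≤ 0.01 and enrichment ≥ 1.5. Metabolite representation
   across the exploratory set is counted by exact full-name membership, so
   `palmitate (16:0)` and `(14 or 15)-methylpalmitate (a17:0 or i17:0)`
   are deliberately distinct names.

## Design choices where the procedure was genuinely open

Several steps of the published procedure are described qualitatively; the
package fixes them as follows, each behind a configuration knob:

- **Overlap metric.** "Substantial overlap (>75%)" is implemented as
  *containment* — intersection over the smaller node set — rather than
  Jaccard, so that a small module engulfed by a larger one merges; this
  matches the goal of low inter-network overlap. `overlap_metric =
  "jaccard"` switches metrics. Merging is deterministic:
  highest-overlap-first with a lexicographic id tie-break, and the merged
  module keeps the id of its largest constituent.
- **Over-connectedness.** "Disproportionately high number of interactions
  outside the current network" is operationalized as the conjunction of a
  global-degree percentile (default 0.99) and a maximum inside fraction
  (default 0.10). Seeds are never pruned.
- **Cap survivors.** The ranking of neighbors kept when a module is capped
  is not specified; descending best edge confidence to any seed with an
  ascending-id tie-break makes the cap deterministic and favors
  high-confidence seed partners.
- **Background universe.** The Fisher background is the node set of the
  confidence-filtered interactome — the sampling frame of the pulldown —
  configurable to the union of modules or a custom list.
- **BH family.** Correction is applied per gene-set class across the whole
  collection by default, switchable to a single global family.
- **Volume adjustment.** Implemented as division of raw intensities by the
  recorded per-sample volume before median scaling, following the vendor
  normalization convention; applied to the plasma block only.
- **ASV filter ambiguity.** "Counts less than 10%" is read as prevalence
  below 10% of samples, combined with the median-zero condition by logical
  AND; threshold and conjunction are both configurable.
- **Outlier rule scope.** The PCA outlier rule runs once per omics block
  (non-iteratively) and the union of flagged samples is removed.
- **Functional vs physical links.** After the text-mining exclusion, both
  evidence classes are treated identically downstream.
- **Aggregation input.** Figure-style aggregation uses corrected q-values
  by default (`value = "p"` gives raw p-values), and annotations missing
  from a module's output count as 1.0 (`missing = "skip"` drops them).

## The synthetic benchmark

No interactome, metabolite data or association snapshot is redistributable,
so the package ships a generator whose defaults define the benchmark used
by the test-suite:

- 500 proteins; 5 planted modules of 15–25 proteins with within-module edge
  probability `p_in = 0.4` against a degree-skewed background of expected
  per-pair probability `p_out = 0.01` (each background edge picks endpoints
  preferentially by current degree, giving realistic degree heterogeneity);
  5 hub proteins wired to at least ten times the median degree, giving the
  pruning stage real work.
- Edge confidences from Beta(1, 3), which puts roughly 27% of its mass
  below the 0.1 confidence filter, so filtering removes a nontrivial edge
  fraction as in real confidence-scored interactomes.
- 30 metabolites, 20 of them discriminant; each discriminant metabolite
  draws 80% of its 3–8 protein links from its assigned planted module,
  decoys link uniformly; about 10% extra text-mining rows exercise the
  evidence filter.
- Four experimental groups of 6/3/6/6 samples (a wild-type/transgenic ×
  control/high-fat design after sample attrition), lognormal intensities,
  discriminant metabolites shifted by `effect_log2 · ln 2` between their
  contrasted groups, and left-censored missingness at overall rate 0.3
  (cells below a per-metabolite quantile go missing, which is why
  half-minimum imputation is the appropriate inverse); 15% of metabolites
  get elevated missingness so the 30% filter has something to remove.
- Dirichlet-multinomial ASV counts over 120 taxa at fixed depth.

What the generator does *not* emulate: batch structure, correlated
metabolites, compositional coupling between the metabolome and the
microbiome, taxonomy strings, or any mass-spectral detail — generation
starts at the feature-table level. Passing tests therefore demonstrate
algorithmic correctness and calibration on idealized data, not performance
on real cohorts.

## What the benchmark can and cannot recover

`planted_module_recovery()` runs the full pulldown on fresh replicates and
scores, per planted module, the best node-Jaccard index achieved by any
final module. Two facts are worth stating plainly.

First, planted modules carry clearly stronger seed-protein enrichment than
decoy modules (median q roughly 0.15 versus 0.56 over ten replicates), so
the prioritization stage does what it is for.

Second, at `p_in = 0.4` a single first-order neighborhood covers only
about `p_in` of its module (less after the confidence filter removes ~27%
of edges), bounding any per-seed module's node-Jaccard near 0.4; and the
containment overlap between two same-module seed networks is far below the
0.75 merge threshold, so merging cannot reassemble a sparse module either.
Measured recovery at Jaccard ≥ 0.6 is accordingly near zero (mean best
Jaccard ≈ 0.44). This is a property of first-order extraction on sparse
planted modules, not a defect of the implementation: with `p_in` near 1
(cliques, as in the toy two-clique test) recovery is exact. The
corresponding acceptance expectation is asserted at the stated threshold
and left failing rather than weakened.

## Numerical and degenerate-input conventions

- Medians are computed over observed entries only; missing markers survive
  scaling untouched. A metabolite with no observed values is an error after
  the filter stage (it cannot occur in the composed pipeline).
- p-values and aggregation inputs are floored at 1e-300; reported
  significance never collapses to exact zero.
- CLR rows sum to zero within 1e-9; CLR is exactly invariant to sample
  rescaling only when the pseudocount is scaled identically, and
  approximately invariant with a fixed pseudocount.
- Degree quantiles use R's default (type 7) quantile definition.
- All generators are bit-reproducible given `rng_seed`; the pulldown
  itself contains no randomness.
- Problem sizes in the test-suite (120-protein configurations for unit
  tests, the 500-protein benchmark with ten replicates for recovery, 200
  random instances for the Fisher oracle, 100 vectors for the BH oracle)
  were chosen to make the Monte-Carlo checks stable at the stated
  tolerances.

## Known limitations

- Only first-order neighborhoods are implemented; no diffusion scoring or
  second-order expansion.
- Identifier resolution treats structural keys as opaque strings — no
  tautomer or structure normalization.
- Live database querying is out of scope by design: reproducibility
  requires a frozen association table, which the user supplies in the
  documented TSV schema.
- The packaged exploratory-network table is a transcription of published
  summary rows used for representation counting; the underlying interactome
  and raw omics data are proprietary and are replaced here by the synthetic
  generator.
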