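---
title: "Detecting heatwave-responsive indicator taxa: models and design choices"
author: "blobind maintainers"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Detecting heatwave-responsive indicator taxa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Marine heatwaves restructure plankton food webs, but separating a heatwave
response from ordinary seasonality and depth zonation in an amplicon time
series is not a single test — it is a chain of inferences. `blobind`
implements that chain for a depth-stratified prokaryotic OTU table from a
subarctic Pacific time series spanning a major heatwave (the 2014–2016
"Blob"): descriptive community structure, asymmetric indicator-species
analysis against a pre-heatwave/heatwave partition, ensemble co-occurrence
network inference with a compositionality-aware null, a network-connectivity
filter on the indicators, and family-level summary scores (CIS/CIC).

The real survey comprises 271 samples over 16 depths, three cruises per
year (February, June, August), and 1,310 OTUs, with library sizes from
44,681 to 268,405 reads. Samples are stratified into an upper epipelagic
zone (10–100 m) and a lower epipelagic zone (150–200 m), and dated samples
are labelled `pre_blob` (June 2010 – August 2013), `blob` (February 2014 –
February 2016), or `unassigned` (the gap between the windows; such samples
take part in ordination and clustering but not in indicator or network
stages). Depth-zone bounds are closed on both ends; the source survey never
states open/closed bounds, so the literal reading was fixed once.

# The inference chain

## Descriptive stages

Community structure uses Bray–Curtis dissimilarity on relative abundances
(the analyses are relative-abundance-based throughout, so `brayCurtis()`
refuses unnormalised input). Ordination is non-metric MDS: Kruskal stress-1
minimised with monotone (weak-tie) regression, one metric (PCoA) start plus
`nStarts = 20` random starts, convergence at a relative stress change of
1e-6. Hierarchical clustering is an average-linkage (UPGMA) tree cut to a
fixed `k = 4` — the dendrogram-cut interpretation of a "k-means = 4"
annotation on a dendrogram figure, with `kmeansOrdinationClusters()`
available as an independent cross-check. Alpha diversity exposes Shannon
(default; the source profiles do not name their index), richness and
Pielou evenness.

## Asymmetric indicator analysis

For OTU $i$ and group $g$ (one of `pre_blob`, `blob`) within a zone:

* specificity $A_{ig} = \bar{x}_{ig} / (\bar{x}_{ig} + \bar{x}_{ig'})$,
  the group mean relative abundance against the sum of both group means;
* sensitivity $B_{ig}$, the fraction of group-$g$ samples where the OTU is
  present (count > 0 on the raw counts — the standard IndVal definition,
  not a relative-abundance floor);
* the indicator statistic $\mathrm{IndVal}_{ig} = \sqrt{A_{ig} B_{ig}}$.

The asymmetric (one-sided) form associates each OTU with the group
maximising the statistic; exact ties leave the OTU unassigned and never
selected. The group-equalised variant was deliberately not used: the survey
groups are unbalanced and no equalisation is stated, so the plain IndVal.g
form is the default (`indval`), with the threshold applied to the
statistic, not its square — the "sensitivity and specificity" phrasing of
the family-score definition supports the combined square-root statistic.

Significance is a permutation test on the condition labels (group sizes
preserved), with the per-permutation statistic being the best-group
statistic, and

$$p = \frac{1 + \#\{\text{perm stat} \ge \text{obs stat}\}}{1 + n_{perm}},
\qquad n_{perm} = 999.$$

When the number of distinct balanced assignments is enumerable
($\binom{n}{n_1} \le n_{perm}$) the test switches to complete enumeration
and returns the exact p. P-values are not multiplicity-corrected by
default, matching the stated selection rule; selection retains OTUs with
statistic strictly $> 0.7$ and $p$ strictly $< 0.05$. OTUs selected in both
zones with opposite associations are contradictory and removed from both
(`reconcileZones()`), the same reconciliation the source analysis applied
to seven OTUs.

## Ensemble co-occurrence networks

Pairwise association is scored by the canonical ensemble quartet — Pearson
and Spearman correlation of relative-abundance profiles, Bray–Curtis
dissimilarity between the profiles, and symmetric Kullback–Leibler
divergence on per-OTU-normalised profiles (pseudocount $10^{-6}$). The null
is the renormalised permutation ("ReBoot") scheme: the two OTUs' counts are
permuted independently across samples and each sample's composition is
renormalised with the permuted counts in place, so the part of an observed
correlation that is merely the closed-sum constraint is present in the
null too and cancels. The hot loop is compiled (Rcpp).

Three design choices here deserve explicit statement.

* **Per-measure p-values are Gaussian tails of the ReBoot z-score**
  ($2\Phi(-|z|)$ with the null mean and SD), not empirical ranks. An
  empirical rank p is floored at $1/(n_{perm}+1)$; after merging and BH
  correction over tens of thousands of pairs no edge could ever be
  retained at that floor. The z-score tail is how the original ensemble
  tool computes its p-values; the empirical rank form remains available
  (`pMethod = "empirical"`).
* **Brown's method with null-estimated covariance.** The four measures are
  computed on the same data, so their $-2\ln p$ are dependent; Brown's
  scaled-$\chi^2$ merge needs their covariance. That covariance is
  estimated from each pair's own permutation null (each null draw is
  converted to its Gaussian-tail p). Estimating it across observed
  candidates instead — the obvious shortcut — conflates between-pair
  signal heterogeneity with within-pair dependence and destroys the merge
  (a merged p can then never be much smaller than its best component).
  Single-measure candidates reduce exactly to their own p.
* **BH against the full family of pairs.** The prefilter (per-measure
  extreme 1% score quantiles, the standard edge-initialisation heuristic)
  is a computational screen only; the BH denominator is
  $\binom{n_{OTU}}{2}$, because correcting only among candidates selected
  on the same statistics is anti-conservative.

Retained edges need BH $q \le 0.05$, at least `minSupport = 2` supporting
measures, and a unanimous copresence/exclusion vote among the supporting
measures. A measure *supports* an edge when its own p-value is at most
`supportAlpha = 0.05`; measures without evidence neither vote nor veto.
(The magnitude-sensitive dissimilarity measures are near-uninformative for
pairs at very different abundance levels; letting them cast coin-flip
votes would veto most true edges.) Correlation signs vote directly;
dissimilarities vote copresence when the observed score falls below the
null mean. Edge weight is the mean over supporting measures of a $[0,1]$
mapping: $|r|$ for correlations, and the two-sided fold $|1-2u|$ of the
normalised null rank $u$ for dissimilarities. Networks are inferred per
zone, matching the subsets used for the indicator analysis; `zone =
"mixed"` supports pooled analyses.

## Connectivity filter and family scores

Selected indicators are filtered on network connectivity — strictly more
than three copresence edges (`minDegree = 4`) — instead of a minimum
relative-abundance threshold, so conditionally rare but ecologically
embedded taxa survive. Per family-level taxon (the family rank, or
`unclassified_<deepest assigned rank>` when the family is unresolved) and
condition:

* **CIS** — cumulative indicator score: the sum of member OTUs' indicator
  statistics;
* **CIC** — cumulative indicator connectivity: the summed weight of
  retained edges incident to member indicator nodes. The node-centric
  convention (an edge joining two same-family indicators counts once per
  incident node) is the default because it keeps CIC additive over
  disjoint family partitions; the edge-centric variant is a flag.

# The synthetic community generator

Every downstream stage is tested against planted ground truth, so the
generator is first-class code, not a fixture. Counts arise from a
latent-Gaussian compositional chain: per-OTU log-baselines
$\mu_i \sim N(0, 1.5^2)$; per-sample latent deviations, standard normal;
planted indicators receive a $\log(\text{effect})$ mean shift in their
associated condition (default fold change 8); softmax to a composition;
multinomial sampling at a library size drawn uniformly from
44,681–268,405 reads (the survey's printed extremes); optional
post-sampling zeroing (`zeroInflation`, default 0 — multinomial sampling
of a long-tailed composition already yields realistic sparsity, and the
zeroing mask models under-detection, so counts are never renormalised).

Dependence is planted twice:

* **Co-occurrence modules** — blocks (default 3 × 5 OTUs) sharing a latent
  factor at equicorrelation 0.8. The factor is centred within each
  condition, making modules condition-neutral *by construction*: a
  chance-imbalanced module factor would otherwise read as a block of
  spurious indicators and make the planted truth ambiguous.
* **Indicator guilds** — planted indicators of the same condition share a
  latent factor at equicorrelation 0.8 (`indicatorCorrelation`). Taxa
  responding to the same environmental driver co-occur; that is the very
  premise of a connectivity filter. Without guild structure an indicator's
  only shared variation is the binary condition shift, its pairwise
  correlations hover near 0.25, and no indicator can honestly acquire four
  positive edges at 60 samples.

Planted OTUs (indicators, contradictory OTUs, module members) share a
common baseline ($\mu = 0$, a typical community abundance). Two reasons:
a baseline lottery between the two response guilds would unbalance their
biomass across conditions, and the compositional denominator would then
hand every abundant background OTU a genuine relative-abundance
association with the opposite condition; and near-absent module members
cannot carry recoverable co-occurrence at finite sequencing depth.

Samples are balanced over the four zone × condition strata (the spec-level
balance is a modelling choice: per-cruise counts of the real series are
unpublished), with seasons alternating deterministically within each
stratum and cruise dates cycled through the months the series actually
samples. Contradictory OTUs (for reconciliation tests) shift towards
opposite conditions in the two zones. All randomness flows through one
master seed with deterministically derived per-stage child seeds
(`childSeed()`, a 31-bit string hash), so any stage can be regenerated
independently and a repeated run is byte-identical.

## What the generator does and does not emulate

It reproduces the shape of the processed survey (strata, depths, cruise
calendar, library-size range, long-tailed abundances, planted effects and
dependence). It does not simulate raw reads, chimeras, primer bias,
phylogenetically coherent taxonomies (lineages are arbitrary but
rank-complete), temporal autocorrelation within a condition, or the real
series' unbalanced sampling. Passing recovery tests therefore demonstrate
that the chain detects the planted signal classes under realistic depth
and noise — not that the original biological findings are correct.

# Study sizes used by the test-suite and acceptance script

The recovery experiment uses a 60-sample (15 per stratum), 300-OTU
community with 20 planted indicators at 8-fold effect and 3 modules of 5
at correlation 0.8, analysed as one pooled pre/Blob subset — the method is
zone-agnostic and 30-sample per-zone subsets carry too little information
for any pair to clear a family-wide BH correction; the per-zone chain with
reconciliation is exercised end-to-end on a separate 150-OTU two-zone run
with three planted contradictions. Null calibration uses 1,000 OTUs
(indicator test) and 200 OTUs (network) with no planted signal. Module
recovery is scored on the copresence edges induced on the planted module
OTUs: under BH at FDR 5% with ~200 true discoveries, a community-wide
false-edge count of ~10 is *expected*, and those false edges land in the
vastly larger background stratum by mass, so a background-wide precision
denominator would measure the FDR arithmetic, not module recovery.

# Numerical choices and degenerate inputs

* Ties in the indicator group assignment → unassigned, never selected.
* OTUs absent from a stratum are dropped and logged; samples with zero
  totals are dropped with a warning at construction.
* Correlation measures abstain on constant profiles; a candidate with all
  measures abstaining is dropped and logged.
* nMDS ties are handled by weak-tie monotone regression; non-convergence
  is flagged, not an error.
* Pielou evenness of a single-OTU sample is undefined and returned `NA`.
* `selectIndicators` applies both inequalities strictly (`> 0.7`,
  `< 0.05`), exactly as the rule is printed; the connectivity filter
  enforces strictly more than 3 positive edges (`>= 4`).
* The KLD pseudocount is $10^{-6}$, added before per-OTU profile
  normalisation.

# Known limitations

* The Gaussian-tail p-values are approximate in the extreme tails; the
  network null-calibration tests bound the consequences (retained-edge
  fraction under a global null stays within binomial slack of zero).
* Brown's merge with a scaled-$\chi^2$ is itself an approximation; with
  four dependent measures its effective degrees of freedom are estimated
  per pair from 999 null draws.
* CIC depends on the edge-weight convention; both the node-centric and
  edge-centric counts are implemented, and weights are ensemble scores,
  not biological interaction strengths.
* The pipeline treats condition windows as hard calendar boundaries;
  samples in the gap are excluded from inference rather than modelled.
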