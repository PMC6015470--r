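---
title: "Finding metacommunity hubs in plant–fungus association networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding metacommunity hubs in plant–fungus association networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metahub)
library(dplyr)
```

## The problem

Root-associated fungi — arbuscular and ectomycorrhizal fungi, root
endophytes, latent pathogens — form dense webs of associations with the
plants of a forest. Amplicon sequencing of root samples gives, per locality,
a sample × OTU read-count matrix with a host-plant label on every sample.
Within one locality, a bipartite network built from those data identifies
fungi with broad local host ranges. But fungi disperse between localities,
and a fungus that is central in *many* local networks *and* spans them
geographically — a **metacommunity hub** — is a different, more consequential
object than a locally central one: it is the kind of organism one would
shortlist for inoculation trials across a climatic region. `metahub`
implements the full chain from read tables to that classification, plus the
composition statistics and the specificity index that accompany such
analyses.

## Data model and preprocessing

The canonical input is a long tibble `site, sample, host, otu, reads`
(readers for per-site wide TSV and XLSX workbooks are provided). Three
preprocessing rules matter, all in `preprocess_samples()`:

* **Rare-association filter** (`threshold = 0.001`): within each sample,
  associations under 0.1% of the sample's total reads are removed as likely
  PCR/sequencing carry-over. The inequality is strict — a cell exactly at
  the threshold is kept.
* **Rarefaction** (`depth`, e.g. 1000): each sample is subsampled without
  replacement to a fixed depth so per-sample read totals are comparable;
  each retained OTU count is then hypergeometric. Samples below the target
  depth are *dropped with a warning* rather than up-sampled, because a
  without-replacement draw larger than the total is undefined.
* **Order**: the filter is applied to raw per-sample totals *before*
  rarefaction, and this is deliberate: at depth 1000 the 0.1% threshold
  equals a single read, so a post-rarefaction filter would do no work at
  all. The order is configurable (`order = "rarefy_first"`) for users who
  need the other convention.

`as_species_table()` then collapses samples onto host taxa: cell
(plant, OTU) = number of samples of that plant in which the OTU was present.
Only presence/absence enters this conversion, so a 500-read and a 1-read
detection count equally. Host labels that cannot be resolved to species are
kept as distinct opaque taxa — discarding them would bias networks toward
well-characterized flora. The pipeline is idempotent: re-applying
filter/rarefy/convert to its own output changes nothing.

## Networks and centrality

`build_local_network()` turns one site's species-level table into a strictly
bipartite graph; edge weight = number of supporting samples.
`build_metacommunity_network()` merges sites, with two asymmetric rules:
plant populations from different sites remain **different nodes**
(`site::plant`), while each fungal OTU is **one node** across all sites.
This is the crux of the construction — conspecific plants in different
forests cannot exchange symbionts directly, whereas a fungal OTU present in
two forests genuinely interconnects them. Consequently, the merged graph's
plant-node count equals the *sum* of per-site plant richness, and the OTUs
occupying ≥ 2 sites are exactly the connectors between local sub-networks.

Betweenness (`node_betweenness()`) is Freeman shortest-path betweenness,
unnormalized, over the whole possibly-disconnected graph, with tied shortest
paths splitting each pair's contribution equally. Two choices deserve
explanation:

* **Binary topology by default.** Association frequencies are retained on
  the edges, but the headline metric treats links as present/absent; the
  weighted variant (traversal cost = `1/weight`, so stronger associations
  shorten paths) is available for robustness comparisons. The reciprocal
  cost is our documented choice among the possible weight transforms; when
  all weights are equal the two variants coincide exactly, which the test
  suite asserts.
* **No normalization of raw scores.** Downstream min–max standardization
  makes any global normalization constant cancel, and the tests verify
  invariance of standardized scores under positive rescaling.

The rest of the suite follows stated conventions: degree is the edge count;
closeness on disconnected graphs is component-restricted with
Wasserman–Faust reachable-fraction scaling `(r/(n−1))·(r/Σd)`; eigenvector
centrality is the principal eigenvector of the binary adjacency of the
largest connected component (unit norm, zeros outside it), computed by power
iteration on `A + I` to tolerance 1e-10 — the `+I` shift is necessary
because a bipartite adjacency has a symmetric spectrum (±λ₁) and unshifted
power iteration oscillates between the paired eigenvectors. Only betweenness
drives the hub classification; the other centralities are descriptive
companions (degree and betweenness correlate strongly on these networks,
which `centrality_table()` lets you check per site).

## Standardization and the four categories

Within each network, betweenness is standardized over the *fungal OTUs
only*: `B' = (B − min B)/(max B − min B)`. Excluding plant nodes from the
range is our reading of the per-OTU definition; in practice `min B = 0`, so
`B' = B/B_max` and the top OTU of every network scores exactly 1. If all raw
scores tie, everything maps to 0 with a warning. For each OTU, standardized
local scores are averaged over the sites where it occurs — absent sites are
*omitted*, not counted as zeros; standardization within a site likewise uses
only the OTUs present there. Per-site standardization precedes averaging and
the mean is unweighted across occupied sites.

`classify_otus()` then cuts the (mean B̄'_local, B'_meta) plane into four
quadrants at a threshold of 0.5, boundary values falling on the "high" side.
The threshold is a parameter (`hub_classification(threshold = )`) because
the appropriate stringency depends on the downstream purpose; 0.5 is the
conventional default, at which roughly 1–2% of OTUs typically exceed the
metacommunity cut on heavy-tailed networks. `regional_subset()` reruns the
identical machinery on any subset of sites (e.g. a northern versus southern
half of a transect), which is how climatic-region-specific hub lists are
produced.

## The d′ specificity index

For OTU *i* with association counts `a_j` over plants *j* (total *t*),
`p'_j = a_j/t`, and `q_j` = plant *j*'s share of all associations in the
matrix, the raw index is the Kullback–Leibler divergence
`d = Σ p'_j ln(p'_j/q_j)`, standardized to
`d' = (d − d_min)/(d_max − d_min) ∈ [0, 1]` where the extremes are taken
over reallocations of *t* across plants holding `q` and each plant's
marginal total (capacity) fixed. The extremes are found by a candidate
search: for `d_max`, the greedy ascending-availability fill *plus*, for each
plant, the allocation concentrating as much as possible on that plant first
— pure ascending-`q` filling alone is provably suboptimal when capacities
force splitting, which is why the candidate set is widened. The observed
allocation is always a candidate, so `d' ≤ 1` exactly; `d_min` is a
proportional fill with greedy integer-remainder placement, clamped by the
observed value, so `d' ≥ 0` exactly. On small matrices the test suite
verifies all four quantities against an exhaustive enumeration of feasible
integer allocations. Note that d′ is noisy for OTUs seen in few samples —
one reason betweenness, not d′, drives the classification.

## Community statistics

`bray_curtis()`, `permanova()` and `permdisp()` are implemented directly
from their definitions (vegan's `vegdist`/`adonis2`/`betadisper` serve as
independent cross-checks in the tests, never as the implementation):

* Bray–Curtis `d = Σ|x−y| / Σ(x+y)` on sample read vectors.
* PERMANOVA (one-way): `SS_total = (1/N) Σ_{i<j} d²`, within-group sums
  analogous, pseudo-`F` and `R²` from the partition, p-value by freely
  permuting whole sample labels, `p = (1 + #{F* ≥ F})/(n_perm + 1)`. On a
  Euclidean distance matrix this reproduces the classical coordinate-space
  pseudo-F, and under a random-label null its p-values are uniform (both
  asserted in the tests).
* PERMDISP: principal-coordinates embedding keeping negative-eigenvalue
  axes as imaginary coordinates (their squared distances subtract,
  truncated at 0), distances to group *centroids* (not spatial medians —
  the conventional default), one-way ANOVA F on those distances, p-value by
  permuting labels over the fixed embedding.

Defaults: 999 permutations; a seed argument controls reproducibility and the
pipeline records it in its manifest. For composition questions the
sample-level table can first be aggregated to taxonomic orders or functional
guilds via `aggregate_by_annotation()` (annotations are consumed as input —
the package does not infer taxonomy or guilds); whether to compute distances
on aggregated or raw OTU-level tables is left as an explicit switch, since
both conventions are defensible and give different emphases.

## The synthetic metacommunity generator

`simulate_metacommunity()` exists so every stage, including the end-to-end
classification, is testable without any external data. It emulates the
structure of the target study design — its defaults are 8 sites, 240 root
samples per site at a fixed depth of 1000 reads, a pool of 150 plant taxa
with per-site subsets partially shared across sites, and an OTU pool (2000
by default, the order of magnitude of per-site richness in such data) whose
members vary in geographic range and host specificity:

* **Range**: sites-occupied `k` follows a truncated power law
  `P(k) ∝ k^(−2.5)` — most OTUs are single-site, few are widespread.
* **Specificity**: each OTU draws one host-preference vector from a
  symmetric Dirichlet over the plant pool (restricted and renormalized to
  each site's plant list), with the concentration parameter as the single
  specificity knob: 0.3 (specialist-leaning background) versus 50 for
  planted hubs (near-uniform generalists). Drawing a single global
  preference vector, rather than independent per-site ones, keeps an OTU's
  host identity consistent across its range.
* **Reads**: each sample's host comes from the site's log-normal plant
  abundances; its read vector is multinomial over the OTUs occupying the
  site with weights occupancy × host preference × log-normal OTU abundance.
* **Planted hubs** occupy many sites (≥ ⌈n_sites/2⌉, all sites by default)
  with maximal generality and elevated abundance; `recovery_experiment()`
  reruns the whole pipeline over replicates and reports sensitivity and
  precision of hub detection against this ground truth, plus the Spearman
  correlation between true range and standardized metacommunity
  betweenness. Replicate seeds derive from the master seed by unit
  increments.

What the generator deliberately does *not* emulate: sequencing error and
chimeras (the 0.1% filter is exercised only statistically), phylogenetic
structure among hosts or fungi, spatial autocorrelation between
neighbouring samples, and environmental gradients in OTU identity beyond
site membership. Passing recovery tests therefore demonstrate that the
pipeline's machinery is correct and sensitive under its own assumptions, not
that real data meet those assumptions.

## Numerical choices and degenerate inputs

* Ranking ties (e.g. `top_k_table()`) break lexicographically by OTU id, so
  outputs are reproducible across platforms.
* All-equal betweenness standardizes to all-zero with a warning rather than
  NaN; graphs without edges get zero eigenvector scores with a warning;
  PERMDISP returns F = 0 when both dispersion sums vanish.
* Permutation p-values are bounded below by `1/(n_perm + 1)`; tests use
  199–999 permutations depending on required resolution.
* Problem sizes in the test suite and acceptance script are scaled-down
  study analogues chosen by us — e.g. 8 sites × 60 samples × 1000 reads and
  800 OTUs for the headline run, and a 5-site, 150-OTU strong-signal
  configuration for the 20-replicate recovery experiment. These sizes keep
  the betweenness, permutation and d′ oracles exact or near-exact while
  exercising every code path at realistic shape ratios.

## Limitations

Associations are co-occurrence in a root sample, not demonstrated
interaction; the networks inherit that caveat. Betweenness on the binary
topology ignores association strength except through the filter; the
weighted variant is provided but has no settled biological interpretation.
The d′ extremes come from a heuristic candidate search that is exact on all
enumerable cases we test but is not a proven global optimizer for arbitrary
marginals (the clamps guarantee `d' ∈ [0, 1]` regardless). PERMANOVA
conflates location and dispersion effects — significant dispersion
heterogeneity (PERMDISP) means compositional differences must be read with
care. Finally, hub status is relative to the sites sampled: adding or
removing localities changes both standardizations and therefore the
classification.
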