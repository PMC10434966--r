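---
title: "Comparative clustering of co-fractionation interaction data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative clustering of co-fractionation interaction data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(profclust)
```

## The problem

Complexome profiling separates native protein complexes — typically by
blue-native gel electrophoresis — into fractions that are measured by mass
spectrometry, giving every protein a migration profile across fractions.
Proteins that comigrate are candidate members of the same complex. A single
experiment is noisy, and experiments from different species use different
protein identifier namespaces, so evidence that is individually weak but
consistent across many experiments and species is easy to miss.

`profclust` integrates many such experiments at once. Datasets are grouped
into *collections*: all datasets profiling one complexome (one species ×
tissue/cell-type/life-stage context). Datasets of one species share an
identifier namespace; across species, user-supplied one-to-one orthology
pairs define which proteins are comparable. The pipeline produces clusters
that span datasets and species, scores how consistently each protein and
each cluster is supported, and optionally annotates and evaluates the
clusters against a set of known reference complexes.

## The method, stage by stage

### Within-dataset interaction scores

Each profile dataset is converted to a symmetric interaction matrix by
Pearson correlation of the migration profiles (`correlation_matrix()`).
Precomputed score matrices — any symmetric score that ranks a protein's
interactors — are accepted as-is (`load_score_matrix()`), and feeding the
correlation matrices back through this route reproduces the profile-path
results exactly (a tested invariant). Proteins with zero variance across
fractions have no defined correlation and are excluded from rankings.

### Interactor profiles and rank-biased overlap

For every protein, its *interactor profile* is the list of all other
proteins of its dataset ranked by interaction score (ties broken by
identifier so results are reproducible). Two proteins from different
datasets are compared through the similarity of their interactor profiles,
not through their own orthology: the rank-biased overlap (RBO) of the two
ranked lists is

$$\mathrm{RBO}(A, B) = \sum_{d=1}^{K} (1-p)\,p^{d-1} \, \frac{|A_{1:d} \cap B_{1:d}|}{d},$$

the weighted average of prefix-overlap fractions, with geometrically
decaying rank weights. Orthologous proteins count as common elements of the
two lists; proteins without an ortholog are unique to their list. We use
the *truncated* (non-extrapolated) form: the sum stops at the evaluation
depth $K$ and no correction is added for unseen ranks, so identical lists
of length $L < K$ score exactly $1 - p^{L}$ and all scores lie in $[0, 1)$.

Two parameters control the comparison:

* `p` (default **0.9**) — top-heaviness. Rank $d$ carries weight
  $(1-p)p^{d-1}$, so with $p = 0.9$ roughly the top ten ranks carry two
  thirds of the total weight. This focuses the comparison on the
  high-scoring interactors, the ones likely to be genuine.
* `coverage` (default **0.99**) — the share of total rank weight that must
  be evaluated. The implied depth is the smallest $k$ with
  $1 - p^{k} \ge$ `coverage`; for the defaults, $k = 44$
  (`rbo_depth(0.9, 0.99)`). Ranks beyond $k$ would contribute less than 1%
  of the score and are skipped, bounding the cost of each of the
  $n_A \times n_B$ comparisons per dataset pair. The per-pair depth is
  additionally capped by the longer list's length, which is what makes the
  $1 - p^L$ closed form exact.

### Reciprocal top hits and normalization

Within each dataset pair, a protein pair is kept only if its RBO score is
in the top `top_fraction` (default **0.01**, i.e. top 1%) of *both*
proteins' scores against the opposite dataset. The cutoff is a count,
`ceiling(top_fraction * n_opposite)`, with ties at the cutoff value kept;
zero scores are never edges. Because dataset pairs differ in size and in
shared (orthologous) content, raw scores are not comparable across pairs:
the retained edges of each dataset pair are rescaled so every pair's mean
weight is 1 before they are combined. Any common target mean would do —
the subsequent column normalization of the clustering stage absorbs the
constant.

### Markov clustering of the hypernetwork

The union of all normalized edge sets is a hypernetwork whose nodes are
`dataset::protein` *elements*. It is clustered with a native implementation
of the Markov Cluster algorithm (`run_mcl()`): add a self-loop per node
(weight = the node's maximum incident weight), column-normalize, then
alternate expansion (matrix power, default 2) and inflation (element-wise
power `inflation`, default **2.0**, followed by pruning below `1e-5` and
re-normalization) until the flow matrix changes by less than `1e-8`, with
an iteration cap of 100. Clusters are read off the attractor structure;
every node is assigned to exactly one cluster (a node reached by several
attractor systems goes to the one holding most of its column's flow, ties
to the cluster with the lexicographically smallest member, so the partition
is deterministic and independent of input order). Clusters can never span
disconnected components, and the implementation makes no claim of
bit-compatibility with the reference `mcl` binary's pruning schedule.

### From raw clusters to superclusters and subclusters

Raw MCL clusters (*superclusters*) are split by collection into
*subclusters* and scored:

* **Fraction clustered (FrC).** Per protein and subcluster, the number of
  the collection's datasets contributing the protein to this cluster,
  divided by the collection's *total* dataset count — explicitly not the
  number of datasets the protein was detected in, since absence of a
  protein is treated as lack of evidence. Three of four datasets gives
  FrC = 3/4 regardless of detection.
* **Best-guess members.** All proteins with FrC > `best_guess_threshold`
  (default **0.5**), plus proteins below the threshold whose equivalent —
  the same identifier in another collection of the same species, or a
  one-to-one ortholog across species — exceeds it in another subcluster of
  the *same* supercluster.
* **Matches and coherence.** A *match* is a pair of equivalent elements
  from two datasets inside the same supercluster. For a dataset pair with
  $n$ and $k$ elements in the cluster, at most $\min(n,k)$ matches are
  possible; totals sum over all unordered dataset pairs, and coherence is
  total actual over total possible matches. Per-collection coherence
  restricts the aggregation to dataset pairs touching that collection.
* **Filtering.** A cluster is retained when it has at least `min_matches`
  (default **2**) matches *and* at least one protein with FrC at or above
  `min_frc` (default **0.5**, inclusive). Non-passing clusters are kept in
  the output but flagged.
* **Annotation.** For each reference complex, the supercluster whose
  reference-collection subcluster contains most of its members is
  annotated with the complex name if it contains strictly more than
  `annotation_threshold` (default **0.5**) of them; ties go to the larger
  contained count, then the smaller cluster, then the lower cluster id.

### Evaluation against a reference

For quantitative evaluation, the reference set is first pruned to what the
data could possibly support (`process_reference_set()`): duplicate
complexes, complexes that are proper subsets of others (sub-assemblies),
member proteins detected in fewer than 2 of the reference collection's
datasets, and complexes left with fewer than 3 members are removed, in that
order. Agreement is then the *maximum matching ratio* (MMR): a
maximum-weight bipartite matching between reference complexes and
subcluster member sets with overlap weight
$\omega = |A \cap B|^2 / (|A||B|)$, candidate edges requiring
$\omega \ge 0.25$, and the matched weight divided by the number of
reference complexes. The matching itself is standard machinery and is
delegated to `igraph`; the test suite checks it against exhaustive search
over all assignments on small instances. By default MMR uses all clustered
proteins of the reference collection per cluster; best-guess-only selection
is available (`selection = "best_guess"`), since either convention is
defensible and the choice matters mostly for precision-flavoured
comparisons.

## The synthetic complexome generator

`generate_collections()` emulates the shape of a multi-species comparative
study so the whole pipeline can be exercised without external data. Each
planted complex receives a migration position; its subunits share a
Gaussian elution peak (width `peak_width`, default 2 fractions) whose
centre is jittered per dataset (`peak_jitter`, default ±1 fraction), with
per-protein log-normal amplitudes and multiplicative log-normal noise
(`noise_sd`, default 0.1). A share of each complex
(`taxon_specific_fraction`, default 0.1) is private to each species; the
conserved core is linked across species by emitted one-to-one orthology
pairs, optionally thinned by `ortholog_dropout`. Background proteins elute
at independent positions.

Defaults are chosen to mirror a realistic desk-scale study: 2 species × 1
collection × 2 replicate datasets, 60 fractions (a typical blue-native
fractionation depth), 10 complexes of 5–10 subunits, and a proteome of
about a thousand proteins per species (`background_proteins = 950`). The
proteome size matters more than it may appear: the reciprocal top-hit
stage keeps the top 1% of partners per protein, and with only a few
hundred proteins that cutoff degenerates to one or two partners — a regime
the method is not designed for, since real complexome profiles contain
thousands of proteins. Two structural choices keep the planted truth
recoverable *in principle*: complex positions sit on a shuffled grid
across the fractionation range (distinct complexes occupy distinct
apparent masses), and background peaks keep a minimum distance of
`background_margin` (default 2) fractions from every complex centre. The
latter is a model limitation worth stating plainly: under a
single-Gaussian profile model, a background protein placed exactly on a
complex's position is mathematically indistinguishable from a member, so
exact comigration of non-members is deliberately not modeled. Real data
contain such proteins (as well as multi-peak profiles, sub-assemblies,
detector missingness and abundance-dependent noise, none of which are
modeled), so passing the synthetic recovery tests demonstrates the
machinery is correct and calibrated for well-separated complexes — not
that real complexomes will be recovered at the same rates.

The recovery property the test suite enforces at these defaults: over five
generator seeds, best-guess selections recover every planted complex with
Jaccard ≥ 0.8 against the planted membership in at least four of the five
runs, and taxon-specific subunits appear only in their own species'
subclusters.

## Numerical and design choices

* **Truncated RBO.** The non-extrapolated variant is the plain weighted
  agreement sum — no residual extrapolation and no $1/(1-p^k)$
  renormalization. This is the conservative lower-bound reading of the
  metric; scores are compared only with each other, so a monotone
  transform of the scale would not change the downstream pipeline.
* **Tie-breaking.** Interactor ranks break ties by identifier (C-locale);
  MCL cluster assignment breaks attractor ties lexicographically. Both
  exist solely to make results independent of input order.
* **Zero-variance profiles** are excluded from rankings entirely rather
  than carried with a sentinel score, so depth cutoffs are not distorted.
* **Top-hit cutoff as a count.** "Top 1%" is implemented as the
  `ceiling(fraction × n)`-th largest score with ties kept, per protein and
  per opposite dataset, rather than a global quantile; the rule is local
  to a dataset-pair comparison.
* **Within-species, cross-collection equivalence** is identifier identity
  (an implicit self-orthology); species with several collections are
  common in comparative designs and need no extra mapping files.
* **Per-collection coherence** uses all dataset pairs in which at least
  one dataset belongs to the collection, retaining cross-system evidence
  while localising the score.
* **Degenerate inputs.** Empty edge sets pass through normalization; an
  all-zero score table yields no edges; isolated elements are excluded
  from the network but reported; MCL non-convergence at the iteration cap
  warns and reads clusters from the final matrix.

## Problem sizes used by the test suite

Unit tests run on toy instances (tens of proteins); the end-to-end
recovery tests use the generator defaults above (≈1,025 proteins per
species, 4 datasets, ≈4,000 hypernetwork elements), five seeds, about
15 seconds per run. These sizes were chosen so the whole suite documents
the method's behaviour at a realistic operating point while remaining
quick to run.

## A minimal session

```{r example, eval = FALSE}
sim <- generate_collections(sim_config(seed = 1))
res <- profclust(sim$datasets, sim$orthologies)
print(res)
head(res$members)
plot(res)
write_cluster_tables(res, "profclust_out")
```

## Known limitations

* Orthology must be one-to-one; paralog families collapse to at most one
  comparable pair, and no transitive closure across three or more species
  is attempted.
* The native MCL is faithful to the algorithm but not bit-compatible with
  the external `mcl` binary's pruning schedule.
* The all-pairs RBO stage is quadratic in proteome size per dataset pair;
  the pure-R implementation is comfortable to a few thousand proteins per
  dataset and several datasets, beyond which it becomes the dominant cost.
* The synthetic generator models single-peak profiles only; see above for
  what that implies about transferring test results to real data.
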