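---
title: "Protein family trees for proteome annotation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein family trees for proteome annotation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protofam)
```

## The problem and the model

Newly sequenced proteomes arrive largely uncharacterized: most open
reading frames have no experimentally supported function and a
substantial fraction has no recognizable homolog in model organisms.
protofam implements an annotation protocol that sidesteps per-protein
database searches: the entire protein space of interest is organized
once into a hierarchical family tree, and each uncharacterized protein
is then *mapped* onto the tree and inherits the functional terms of the
clusters it lands in.

The hierarchy is grown by agglomerative clustering of pairwise
similarities expressed as E-values:

* Every pair of proteins receives an E-value; values less significant
  than the **cap** of 100 are stored at the cap, so the matrix encodes
  "no detectable similarity" explicitly rather than sparsely.
* All proteins start as singletons; at each step the two clusters with
  the lowest **average linkage** merge, where the linkage of clusters
  $A$ and $B$ is the arithmetic mean of the $|A|\cdot|B|$ pairwise
  E-values between their members.
* Each node of the resulting binary merge tree carries two intrinsic
  coordinates. The **ProtoLevel** (PL) is the node's depth expressed as
  a percentage of the merge process: $\mathrm{PL} = 100\,i/n_{\mathrm{merges}}$
  for the cluster created at merge $i$, so singletons sit at PL 0 and
  the final merge at PL 100. The **LifeTime** (LT) is the number of
  merge steps a cluster survives between its creation and its
  absorption into a parent; long-lived clusters are robust to the exact
  order of merges and are treated as real families, short-lived ones as
  transitional.

Two thresholds turn the raw hierarchy into an annotation scaffold. The
stable mapping set ("Map10") keeps clusters with LT ≥ 10. The family
roots ("ProRoot70") are obtained by climbing from a mapped cluster to
its highest ancestor with PL ≤ 70; clusters that themselves sit above
PL 70 are excluded from annotation transfer because merges that late in
the process mostly join unrelated material.

## Mapping and annotation transfer

A query protein is compared against all tree proteins (capped
E-values); a stable cluster is *eligible* when the mean E-value between
the query and the cluster's members is below `tau_map` (default 1.0 —
permissive, but cap-level noise can never qualify). Among eligible
clusters the **minimal-sized** one wins; ties go to the better score,
then the lower node id. The minimal-size rule deliberately picks the
most specific family context available. Map targets must in addition be
merged clusters of at least 2 proteins (`min_map_size`): a stable
singleton is not a family, and allowing it as a target would let every
self-similar query escape into its own leaf, emptying the paralog
analysis. Queries with no eligible cluster are *unmapped*; mapped
queries whose cluster sits above the root ceiling are reported
separately as *excluded*.

Annotation terms are scored per cluster against an external term table
(GO, InterPro, Pfam, keywords, ...):

* **Correspondence Score** (CS) = $|C \cap T| / |C \cup T|$, the
  intersection-over-union between cluster members $C$ and term carriers
  $T$ within the analysis universe. The denominator is configurable
  (`cs_scope = "carriers"` uses $|T|$) because the historical wording
  of the union is ambiguous; intersection-over-union is the default as
  the standard, symmetric choice.
* **Specificity** (purity) = $|C \cap T| / |C|$.

A cluster's **ProtoName** is, per annotation source, the
highest-CS term among those with specificity ≥ 0.2, computed only for
clusters of ≥ 5 proteins; the specificity filter is applied per term
*before* CS ranking so a low-purity term can never win on CS alone.
Uninformative labels ("complete proteome", "taxonomy", "hypothetical
protein"; case-insensitive substrings) are blacklisted at load time and
again at selection. A mapped protein inherits the ProtoNames of its map
cluster and of every ancestor up to and including its family root.

## Paralog statistics

Clusters with ≥ 2 mapped proteins of the subject species carry
*paralogs*. Three statistics describe them:

* **Tree Score** (TS). For a guide tree over a cluster's proteins plus
  the mapped subject proteins, TS is the number of subject leaves
  divided by the leaf count of the smallest rooted clade containing all
  of them — the clade of their lowest common ancestor. TS = 1 means the
  paralogs form a pure clade (they diverged from each other after
  separating from everything else); values near 0 mean they intermix
  through the cluster. "Subtree" is interpreted as a rooted clade
  (a node with all its descendants): under the alternative
  connected-subgraph reading the minimal subtree is always the Steiner
  tree of the leaves and the score degenerates, so that reading is
  rejected. Guide trees are built by UPGMA on a distance matrix
  (default: 1 − k-mer Jaccard); whether the historical pipeline rooted
  its guide trees differently is unknowable from the outside, so the
  rooted UPGMA output is used as-is.
* **Taxonomy Balance** (TB) between two proteomes is the ratio of their
  protein counts within a shared family root, defined only when both
  species contribute at least one protein. TB ≥ 10 and TB ≤ 0.1 flag
  lineage-specific amplifications. The inversion identity
  (swapping species inverts the ratio) is exact on the integer counts
  carried in the result; the floating-point product of the two ratios
  is correct to one ulp.
* **Amplification ratio** of a family root is the number of subject
  proteins under the root divided by the number of distinct stable map
  clusters they occupy, rounded half-up to two decimals (the reporting
  precision of the reference tables). Ratios near 1 are steadily grown
  subfamilies; large ratios are blocks of recent, low-divergence
  duplications.

## The similarity surrogate

The package does not wrap an external aligner. Its default scorer maps
the Jaccard index $J$ of two sequences' k-mer sets onto an E-value-like
scale, $10^{\,2 - s J}$ clamped to $[10^{-180}, 100]$, with $k = 3$ and
$s = 40$. Unrelated random sequences share few k-mers and land at the
cap; near-identical sequences land many orders of magnitude below it.
The surrogate is deterministic, symmetric and monotone in $J$, which is
all the clustering consumes; externally computed score tables can be
ingested instead at any time (`load_pairwise_scores()`), with directed
pairs symmetrized by the minimum — the more significant — of the two
directions (a deterministic, conservative choice; how the historical
matrix combined reciprocal searches is not recorded).

## What the synthetic generator emulates

`synth_spec()` plants protein families with a controlled geometry:

* within-family E-values $10^U$, $U \sim \mathrm{Uniform}(-60, -20)$ —
  far below the cap, as homologous pairs are;
* between-family and orphan pairs exactly at the cap;
* per-member species drawn from a three-species mix (default
  0.5/0.3/0.2) to exercise the Venn and Taxonomy Balance views;
* one planted term per family assigned at a configurable purity;
* optional orphans and decoy terms.

The default of **19 families** is `2 * lt_min - 1` for the default
stability threshold. With between-family values exactly at the cap, the
final merges are all ties at 100 and proceed pairwise in node-id order;
19 families is the count at which every completed family survives at
least `lt_min = 10` steps before being absorbed, while every composite
of unrelated families is absorbed sooner. The planted partition is then
*exactly* the set of maximal stable clusters (stable nodes with no
stable proper ancestor, `stable_clusters(maximal = TRUE)`), which is
what the recovery tests assert (adjusted Rand index 1.0 across seeds).
Family sizes default to 4–20 members.

Two caveats delimit what passing tests show about real data. First, the
generator's separation is idealized: real between-family E-values
scatter below the cap, merge order interleaves, and recovery is no
longer exact (the sequence-mode pipeline typically reaches ARI ≈ 0.99
rather than 1.0). Second, with families of $m$ members the within-family
merges occupy roughly a fraction $(m-1)/m$ of all merges, so completed
family nodes sit at PL ≈ 90, *above* the default root ceiling of 70 —
at desk scale the ProRoots are sub-family fragments. Ground-truth tests
that need family-granular roots therefore place the ceiling at the
family boundary (`family_pl_root()` in the test helpers: halfway
between the last family completion and the first cap-phase composite).
The default of 70 is kept as the protocol's reference value, which was
tuned for a tree of millions of proteins, not hundreds. The generator
makes no attempt at realistic substitution processes (no rate matrices,
no indels) nor at reproducing any particular organism's gene content.

## Numerical choices

* **Linkage bookkeeping.** Average linkage is maintained as accumulated
  pair sums $S(A,B)$ with linkage $S/(|A||B|)$ — algebraically the
  Lance–Williams mean update, but exact for tied values at the cap
  (sums of 100s divide out exactly), which the deterministic tie-break
  requires. Tests validate every merge against a direct $O(n^3)$
  recomputation, tie cases included.
* **Tie-breaking.** Equal linkages merge the pair with the
  lexicographically smallest (min node id, max node id); equal
  map-eligibility ties go to size, then score, then node id; CS ties to
  the larger intersection, then the term id. All outputs are
  bit-reproducible.
* **Floors and caps.** Self-similarity is pinned to
  $10^{-180}$ rather than 0 so log-space operations stay finite.
* **LifeTime units.** LT is counted in integer merge steps (birth to
  death; surviving roots die at $n_{\mathrm{merges}}+1$). The
  historical measure is only described as "approximating stability";
  steps are the natural unit of this implementation and the threshold
  is configurable.
* **Rounding.** Amplification ratios round half-up at the second
  decimal, with a $10^{-7}$ guard absorbing the binary representation
  of exact .005 boundaries.
* **Degenerate inputs.** Empty stable sets error on mapping (and warn
  at extraction); empty annotation databases yield zero-coverage
  summaries rather than failures; forests (from a finite
  `merge_cutoff`) export one Newick tree per root.

## Problem sizes

The shipped tests and the acceptance script run entirely on generated
data: trees of roughly 100–230 proteins, 200 random guide trees of up
to 12 leaves against an exhaustive clade-enumeration oracle, 55 random
matrices of up to 15 proteins against the $O(n^3)$ merge oracle, and 20
seeds of the default planted-family spec for partition recovery. These
sizes keep a full run in the low minutes on one core while exercising
every code path; the implementation itself is comfortable up to a few
thousand proteins (dense matrices, $O(n^2)$ memory), and is not
intended for the multi-million-protein regime of the production
hierarchies it models.

## Known limitations

* No GO-graph-aware propagation: terms are transferred verbatim, not
  closed under is-a/part-of.
* The mapping never alters the frozen tree; there is no incremental
  insertion.
* Guide trees are UPGMA on surrogate distances, not alignment-based
  phylogenies; TS values on real sequences inherit that approximation.
* The Venn partition is defined for exactly three species (the study
  design it mirrors); a flag generalizes it, unvalidated beyond counts.
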