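---
title: "Taxonomy inheritance over gene-sharing networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Taxonomy inheritance over gene-sharing networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(votunet)
```

## The problem

Viral contigs recovered from metagenomes — dereplicated into vOTUs —
rarely match any named genome directly, but they do share predicted
protein families (protein clusters, PCs) with curated reference phage
genomes. Gene-sharing network clustering places vOTUs and references in
one weighted graph and groups them into viral clusters (VCs,
approximating phage (sub)families) and subclusters (approximating
genera), attaching to each node a *status* describing how cleanly it
clustered. What it does not do is name each vOTU. `votunet` closes that
gap: it walks the network once per vOTU and inherits a lineage from the
most similar reference, cut back to a depth the evidence supports.

## Edge weights

The weight between two genomes is the significance of their PC overlap.
With profiles of sizes $a$ and $b$ sharing $c$ of $n$ total PCs,

$$S \;=\; -\log_{10}\!\big(P(X \ge c)\, \cdot\, T\big), \qquad
X \sim \mathrm{Hypergeometric}(n,\, b,\, a),$$

where $T = M(M-1)/2$ counts all genome pairs (references and vOTUs
alike — `score_context()` reads "total pairwise comparisons" literally).
Design constants, recorded here because the score family admits
variants:

* **Log base 10.** Scores read as orders of magnitude of the corrected
  P value.
* **Floor at 0.** When $P \cdot T \ge 1$ the pair is indistinguishable
  from chance; negative similarities are meaningless for this graph.
* **Default edge threshold $S \ge 1$** (corrected $P \le 0.1$),
  configurable in `build_network()`.
* **Set semantics for profiles.** Duplicate PC memberships collapse;
  no cap is applied to scores.

The tail is summed in log space (log-sum-exp over `lchoose` terms), so
weights like $S = 300$ (tails near $10^{-302}$) remain accurate;
arguments are canonicalized to make $S$ exactly symmetric in $(a, b)$.
PC inference itself (all-vs-all protein alignment plus Markov
clustering) is upstream of this package: profiles are inputs.

## The inheritance algorithm

For a vOTU $v$ with cluster label $C$:

1. **Same-cluster stage.** Sort $v$'s direct neighbors by descending
   edge weight (ties: ascending node id — the upstream tools never
   specify tie order, and determinism requires a rule). Keep those whose
   cluster is $C$; scan for the first reference genome. Found one —
   inherit its lineage, record path `same-cluster`.
2. **Any-neighbor stage.** Only if stage 1 finds nothing (or $v$ has no
   cluster): scan all neighbors in the same order for a reference;
   inherit with path `any-neighbor`.
3. Otherwise $v$ is unclassified. Inheritance never chains through
   another vOTU.

"Cluster" here means the top-level VC, not the subcluster; subclusters
(approximate genera) are deliberately not given priority in the scan —
the edge weight already encodes proximity, and preferring subcluster
mates would double-count the same signal.

**Truncation.** The assignment level is a function of the vOTU's status
and the path: `any-neighbor` always caps at family (the inheritance
crossed a cluster boundary, so genus- and subfamily-level trust is
gone, whatever the status); `same-cluster` caps at subfamily for
`Overlap` and `Clustered/Singleton` vOTUs and runs to genus otherwise.
The two published rules are not ordered with respect to each other; the
path rule dominates here because family is the more conservative stop.
The level records the *policy* depth: a reference lacking, say, a
subfamily name still yields `level = "subfamily"` with that cell empty,
so the column answers "how far was this vOTU allowed to inherit", not
"how complete is the reference annotation". Reference genomes are never
re-classified.

Statuses: nodes absent from the overview default to `Outlier`
(conservative: it blocks the same-cluster path), and `Singleton` is
accepted and treated like `Outlier` for cluster membership. Both
choices keep a run alive on slightly inconsistent inputs rather than
failing.

## File dialects

The edge list is the whitespace-separated `source target weight`
triplet format (no header). Duplicate unordered pairs merge to the
maximum weight with a warning — symmetric dumps and concatenations are
common and a deterministic rule beats an error. The overview CSV's
column names default to `Genome` / `VC Status` / `VC` and are
remappable; the combined token `VC_22_1` splits into cluster `VC_22`
and subcluster `VC_22_1`. Reference tables treat blank, `NA` and
`Unclassified` cells (case-insensitive) as unassigned. The output
taxonomy table prints weights with 3 decimals so repeated runs diff
cleanly.

## The synthetic generator

`simulate_network()` emulates exactly the data structure the classifier
consumes: reference genomes as PC profiles organized into families and
genera, vOTUs derived from them, and cluster labels taken from the
ground truth (clustering is an *input* to the classifier, so fixtures
must control it exactly rather than re-derive it with a community
detection step).

Defaults — chosen once as a small but structured phage-like population:
2 families x 3 genera x 4 genomes, 30 PCs per genome (a few dozen
ORF families is typical of a tailed phage), genus core 40% and family
core 20% of the genome, 60 vOTUs, dropout 0, no noise PCs, seed 42.
Each vOTU copies a uniformly chosen parent, loses each PC independently
with probability `dropout` (emulating fragmentary assemblies), and
gains `noise_pcs` fresh private PCs (emulating spurious ORF calls;
fresh identifiers, so noise never creates false sharing).
`status_overrides` forces fractions of vOTUs into `Overlap`, `Outlier`
or `Clustered/Singleton`; for the first two the cluster field is
blanked, since a real clustering would have left them unplaced. A
single seeded RNG stream makes equal seed + config produce
byte-identical fixture files.

What the generator does *not* emulate: sequence content, uneven genome
sizes, shared mobile elements between families, or hosts beyond a
cycled label. Passing tests therefore demonstrate algorithmic
correctness on structured inputs, not classifier performance on real
viromes — real networks have weaker cores, inter-family sharing and
mis-clustered nodes that these fixtures exclude by construction.

One observed consequence: conditional genus recovery (among vOTUs still
connected to a same-genus reference) stays near 100% even at dropout
0.6, because a vOTU retaining ~12 of 30 parent PCs still scores
overwhelmingly against chance at this data-set size. Degradation shows
up in *eligibility* (vOTUs losing all reference edges), so the dropout
sweep reports a non-increasing, often flat, curve.

## Report layer

Conventions follow the dominant community-ecology implementations, via
`vegan` where it provides the statistic:

* Shannon with natural log; Simpson as the Gini–Simpson complement
  $1-\sum p_i^2$.
* Chao1 in the bias-corrected form $S_{obs} + F_1(F_1-1)/(2(F_2+1))$;
  ACE with the classical rare-abundance threshold of 10.
* Fisher's $\alpha$ solved from $S = \alpha\ln(1+N/\alpha)$ by
  bracketed root finding plus a Newton polish (relative error below
  $10^{-10}$); $S = N$ has no finite solution and errors.
* Jaccard on presence/absence (the classical index), Bray–Curtis on
  abundances.
* RPM divides by the column sums of the supplied table — the mapped
  reads — since whole-library read totals are not among this package's
  inputs.
* `miner_overlap()` counts *exact* assignment sets (UpSet semantics),
  so counts always sum to the number of vOTUs.

The report layer is descriptive; group comparisons and multiple-testing
corrections are out of scope.

## Subgraph export

`extract_subgraph()` returns the first-order ego graph (direct
neighbors, induced edges — the radius the interactive views show) with
the display contract: target vOTU red, source reference green,
same-subcluster orange, same-cluster yellow, other neutral; references
triangles, vOTUs circles. Edge strength is the weight normalized by the
subgraph maximum, in $(0,1]$ — the color/width ramp itself is a viewer
concern. GraphML and JSON node-link serializations carry every
attribute; rendering is delegated to downstream viewers.

## Numerical and degenerate-input choices

* Hypergeometric tails are clamped at 1 after log-space summation.
* Weight ties anywhere resolve by ascending id; all sorts use radix
  order, so results are locale-independent.
* Degree-0 vOTUs classify as unclassified rather than erroring;
  all-zero count-table samples are errors for RPM and for distances
  between two such samples.
* `classify_all()` emits rows in sorted vOTU order, making the output
  table independent of input file permutations.

## Problem sizes

The shipped tests run the full stack on fixtures of 84 genomes
(24 references, 60 vOTUs, ~370 PCs, ~600 edges); the dropout sweep uses
20 replicate seeds per level. These sizes give stable statistics for
the properties under test while keeping a full suite run under a
minute; the generator scales to larger populations if needed.

## Known limitations

* The rank list ends at genus; species-level assignment is not
  attempted (the inheritance rules never justify it).
* Whether the scan should prefer same-subcluster references before
  other same-cluster references is an open question upstream; this
  implementation uses pure weight order within the cluster.
* Host information is copied from the reference table, never inferred.
* Clustering itself (MCL/ClusterONE), protein clustering, and
  report rendering (HTML/UpSet plots) are out of scope by design.
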