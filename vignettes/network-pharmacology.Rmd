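---
title: "Network pharmacology of herb pairs: models and methods"
author: "HerbNetPharm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network pharmacology of herb pairs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

HerbNetPharm implements the inference pipeline of herb-pair network
pharmacology: from the observation that two herbs are habitually
co-prescribed, through ADME screening of their candidate compounds and
protein-target mapping, to a protein--protein interaction (PPI) network whose
topology nominates "key targets", their functional clustering and enrichment,
and finally a bipartite compound--target network that shows which targets are
reached by both herbs' chemistry. Every stage that a published study performs
against live web databases (TCMSP, STRING, GeneCards, DisGeNET, DAVID) is
represented here by an explicit file-based input, and a seeded synthetic-data
generator produces all six input kinds with planted, recoverable structure,
so the whole pipeline is testable offline.

This vignette explains the models, the tunable parameters and their defaults,
the numerical conventions, and what the synthetic benchmark does and does not
demonstrate about real data.

## Herb co-prescription networks

A corpus of prescriptions is arranged as a binary incidence matrix $B$ (the
2-mode network) with herbs in rows and prescriptions in columns; $B_{hp}=1$
when herb $h$ is part of prescription $p$. Every prescription must contain at
least two herbs, and a herb occurring in no prescription is rejected rather
than carried as an all-zero row, which keeps all similarity coefficients well
defined.

The 1-mode herb network is the matrix-product projection $BB^{\mathsf T}$:
off-diagonal cells count prescriptions containing both herbs, the diagonal is
each herb's frequency. Similarity is quantified two ways:

* **Jaccard**, $J(h_1,h_2) = |P_1 \cap P_2| / |P_1 \cup P_2|$ over presence
  sets $P_i$. We deliberately use the standard presence-set definition:
  a matching coefficient that also rewards co-*absence* inflates the
  similarity of rarely used herbs (a known artifact of some spreadsheet
  implementations), and the presence-set form does not.
* **Pearson** correlation between binary rows (the phi coefficient). A herb
  present in *every* prescription has a zero-variance profile and an
  undefined correlation; we map such rows to $r = 0$ with a warning rather
  than propagate `NaN`, so heatmaps never fail on ubiquitous herbs.

The heatmap ordering comes from average-linkage hierarchical clustering of
the distance $1-r$. Average linkage is the least extreme of the common
linkages and a reasonable default when the source analysis does not state
one. The drawn network includes an edge for every observed co-occurrence
(count $\ge 1$), with the Jaccard coefficient as edge weight and frequency
and degree as node attributes.

## ADME screening and source-herb partition

Candidate compounds carry two TCMSP-style descriptors: oral bioavailability
(OB, percent) and drug-likeness (DL, unitless in $[0,1]$). The screen
retains compounds with OB $\ge$ 30 and DL $\ge$ 0.18, the conventional
cutoffs; both comparisons are inclusive because the criteria are stated with
"$\ge$". The filter is monotone in both thresholds and preserves row order.
Compounds listed once per source herb under the same PubChem CID are merged
into a single record attributed to all of its herbs before partitioning, so
a shared constituent (e.g. stigmasterol found in both herbs) occupies the
shared Venn block exactly once.

## Target sets and the disease overlap

Each herb's target set is the union of the targets of its attributed
compounds; shared compounds contribute to every herb that contains them.
Disease-associated genes usually come from two databases; "selecting
overlapping targets" is read as the set **intersection** by default, with a
`union` switch, because the phrase is genuinely ambiguous and the choice
cannot be arbitrated without the 2021 database snapshots. The herb--disease
overlap (here: obesity-related targets of the combined herbs) is the node
universe of the PPI stage.

## PPI topology and key-target screening

Edges are scored functional associations; the construction threshold is the
STRING convention 0.4 on the unit scale (STRING exports integer scores
0--1000, which the reader auto-detects and rescales whenever any score
exceeds 1). Self-loops are dropped, duplicate unordered pairs keep the
maximum score — conservative toward inclusion — and nodes without surviving
edges are removed as isolates *after* construction so their number can be
reported.

Two topological statistics drive screening:

* **degree**, the incident-edge count;
* **betweenness centrality**, computed by Brandes' shortest-path
  accumulation over *unweighted* geodesics — confidence scores gate edge
  existence, not path length — and normalized by $(n-1)(n-2)/2$, the
  undirected network-analyzer convention, so values lie in $[0,1]$. Pairs in
  different components simply contribute nothing. With fewer than three
  nodes betweenness is reported as 0 with a warning.

A target is **key** when it is *strictly* above the arithmetic mean on both
statistics. Strictness matters: in a regular graph every node ties at the
mean and nothing is selected, which is the behaviour one wants from an
"above average" rule.

The package follows a two-pass convention: screening uses centrality
measured on the full isolate-free network, and the reported key-target table
recomputes degree and betweenness *inside* the induced key-target
subnetwork. The published form of such tables supports this reading: a
printed 31-row degree column summing to 616 equals exactly twice the
stated 308 subnetwork interactions (the handshake lemma,
$|E| = \tfrac12\sum_i d_i$), which can only hold for subnetwork-internal
degrees. Isolate means are likewise taken after isolate removal, since
isolates cannot carry the metrics being averaged.

## Clustering and over-representation

Key-target clusters are obtained by spectral k-means: the subnetwork is
embedded with the eigenvectors of the $k$ smallest eigenvalues of the
symmetric normalized Laplacian $L = I - D^{-1/2} A D^{-1/2}$ (rows unit
normalized), then k-means is run with k-means++ initialization and 100
restarts, keeping the lowest within-cluster sum of squares. The upstream
web tool's k-means feature space is undocumented; spectral embedding is the
nearest documented analogue and, importantly, is deterministic for a fixed
seed — cluster ids are relabelled by first appearance so identical runs give
identical assignments. Disjoint components separate exactly because their
indicator vectors span the null space of $L$. `k` defaults to 3, and
`k = n` returns singleton clusters directly (k-means centers would not be
distinct there).

Enrichment is the hypergeometric upper tail: for a query of $n$ genes from a
background of $N$, and a term with $K$ members after intersection with the
background, $p = P[X \ge k]$ with $X \sim \mathrm{Hypergeom}(N, K, n)$.
Only terms overlapping the query are reported. We use the plain
hypergeometric, not the EASE-modified ($k-1$) score some web tools apply —
the published analyses do not state which was used, and the plain form is
the textbook test. Benjamini--Hochberg adjustment is applied within each
category (KEGG/BP/CC/MF) separately by default, matching per-ontology
reporting, with a global switch. The default background is the union of all
genes in the annotation collection — configurable, because externally
curated backgrounds cannot be bundled.

## The compound--target network

The final network restricts compound--target edges to the key targets.
Compounds with no surviving edge are dropped and reported (this is the
natural reading of published node counts that fall short of
compounds + targets). A key target is *shared* when its adjacent compounds
cover at least two distinct herbs; shared compounds carry all their source
herbs and count as evidence for each.

## The synthetic benchmark

`genBundle()` emits every pipeline input with planted structure, driven by
one master seed from which per-generator sub-seeds are derived (so partial
regeneration is stable). Defaults mirror the magnitudes of a published
two-herb anti-obesity case study, chosen once and fixed:

| quantity | default |
|---|---|
| prescriptions x herbs | 9 x 17, pair co-occurrence 0.8, background 0.25 |
| compounds (A-only / B-only / shared) | 15 / 7 / 2, decoy fraction 0 |
| target universe / nested B targets | 223 / 31 |
| disease list / overlap | 2199 / 152 |
| PPI hubs / attachment / background density | 10 / 0.6 / 0.05 |
| planted isolates / dual-herb key targets | 17 / 3 |
| scores | background U(0.15, 0.99), hub edges U(0.4, 0.99) |
| clusters / term size / noise terms per category | 3 / 5 / 15 |

Three deliberate repair steps keep the planted truth exact rather than
merely probable: (a) a herb drawn into no prescription is inserted into one
random prescription, so the herb legend size is exact (skipped when the
background probability is 0, where pair-only prescriptions are the point);
(b) a non-isolate PPI node whose sampled edges all fell below 0.4 receives
one above-threshold edge to a random hub, so the planted isolates are
exactly the post-filter isolates; (c) every second-herb target also receives
a first-herb edge (the nested-subset property), and each designated
dual-herb target is wired to at least one exclusive compound of each herb.
The designated dual-herb targets are planted as hubs, which is what makes
them recoverable as *key* targets.

The planted enriched term is a subset of one k-means cluster of the key
subnetwork, surrounded by equal-sized noise terms drawn uniformly; because
no noise term can overlap the query more fully than the planted term, the
planted term attains the minimal p-value in its category with very high
probability.

**What passing recovery tests show — and what they do not.** The generators
produce clean, block-structured data: independent background herbs,
uniformly scored edges, equal-sized annotation terms, no measurement noise
in OB/DL beyond the sampling ranges, and no synonym ambiguity in gene
symbols. Recovery of the planted pair, hubs, isolates, dual-herb targets
and enriched term demonstrates that the pipeline's algebra and topology are
implemented correctly, not that the method is robust to the biases of real
databases (annotation bias toward well-studied proteins, correlated STRING
evidence channels, database-version drift). Database-dependent counts from
any particular study (e.g. 223/31/152 targets or exact betweenness decimals)
are snapshots of 2021 web resources and are intentionally not reproduction
targets; printed tables are instead used as fixtures where their internal
arithmetic (the handshake lemma) can be checked.

## Numerical choices and degenerate inputs

* Score-scale auto-detection divides by 1000 whenever any score exceeds 1.
* Ties at the screening mean are excluded (strict inequality).
* Enrichment sorting breaks p-value ties by term id, so reports are stable.
* k-means restarts improve only on strictly lower within-cluster sums
  (tolerance $10^{-12}$), making the restart loop order-independent.
* Zero-variance Pearson rows give $r=0$ with a warning; a single-column
  incidence matrix is an error (variance undefined).
* An odd degree sum is rejected as an invalid degree sequence.
* Reports contain no timestamps; two runs of the same configuration are
  byte-identical.

Test problem sizes are chosen to keep the suite quick while remaining
exhaustive where it counts: betweenness is verified against geodesic
enumeration on *every* labelled graph up to 5 nodes plus 500 random graphs
on 6--7 nodes, enrichment against $10^5$-draw Monte Carlo on small cases,
and recovery properties over 20 seeded replicates at the defaults above.

## Limitations

* Gene symbols are opaque validated tokens; no live identifier resolution
  is attempted (a synonym map can be applied upstream).
* OB and DL are inputs, never computed from structures.
* The spectral embedding is an analogue, not a re-implementation, of any
  specific web tool's clustering; cluster *boundaries* on real data may
  differ even when cluster *count* matches.
* Enrichment depends entirely on the supplied GMT; no ontology hierarchy or
  term redundancy handling is provided.
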