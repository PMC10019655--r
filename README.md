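# HerbNetPharm

Network-pharmacology inference for herb pairs, in R.

Traditional multi-herb prescriptions are built around habitual pairings —
two herbs co-prescribed for a combined effect. HerbNetPharm is for
computational pharmacologists and systems biologists who want to analyse
such a pair end to end, offline and reproducibly: mine the co-prescription
structure of a prescription corpus, screen the herbs' candidate compounds by
ADME criteria, map compounds to protein targets, intersect with disease
genes, screen *key targets* by PPI network topology, cluster and
functionally characterize them, and assemble the bipartite compound–target
network that shows which targets both herbs reach.

Every web-database step of the published workflow (TCMSP, STRING,
GeneCards/DisGeNET, DAVID) is replaced by an explicit file input, and a
seeded synthetic-data generator produces all of them with planted,
recoverable structure — so the pipeline is fully testable without a network
connection.

## The core quantities

* **2-mode → 1-mode projection.** Prescriptions form a binary incidence
  matrix *B* (herbs × prescriptions); the herb co-prescription network is
  *BB*ᵀ, with Jaccard similarity *J* = |P₁∩P₂|/|P₁∪P₂| over presence sets
  and Pearson (phi) correlation between binary herb profiles.
* **ADME screen.** Keep compounds with oral bioavailability OB ≥ 30 % and
  drug-likeness DL ≥ 0.18 (inclusive).
* **Key-target rule.** On the isolate-free PPI network (edges at combined
  score ≥ 0.4), a target is key when it is strictly above the mean on both
  degree and normalized betweenness centrality
  C_B(v) = Σ_{s≠v≠t} σ_st(v)/σ_st / [(n−1)(n−2)/2]
  (Brandes' algorithm, unweighted geodesics).
* **Handshake lemma.** |E| = Σᵢ dᵢ / 2 converts a printed degree column into
  the subnetwork interaction count.
* **Over-representation.** p = P[X ≥ k], X ~ Hypergeom(N, K, n), with
  Benjamini–Hochberg adjustment per category (KEGG/BP/CC/MF) and top-20
  bubble-chart reporting.

## Worked example

The package ships the printed 24-compound table of the Ephedrae herba (EH) –
Coicis semen (CS) pair as a fixture. Screening and partitioning it:

```r
library(HerbNetPharm)

tab  <- readCompoundTable(system.file("extdata", "eh_cs_compounds.tsv",
                                      package = "HerbNetPharm"))
part <- partitionBySource(filterCompounds(tab))   # OB >= 30, DL >= 0.18
part
#> Venn partition: 24 items in 3 block(s)
#>    CS CS&EH    EH
#>     7     2    15
```

All 24 printed compounds pass the screen; 15 are exclusive to EH, 7 to CS,
and 2 (mandenol, stigmasterol) are shared. The printed 31-row key-target
table closes under the handshake lemma:

```r
cent <- read.delim(system.file("extdata", "key_target_centrality.tsv",
                               package = "HerbNetPharm"))
edgeCountFromDegrees(cent$degree)
#> [1] 308
```

A full synthetic run — generate a bundle, then drive every stage from one
configuration:

```r
b   <- genBundle(seed = 1, outDir = "bundle")
cfg <- pipelineConfig(prescriptions = b$files[["prescriptions"]],
                      compounds     = b$files[["compounds"]],
                      ctEdges       = b$files[["ctEdges"]],
                      diseaseGenes  = b$files[["disease"]],
                      ppiEdges      = b$files[["ppi"]],
                      geneSets      = b$files[["annotations"]],
                      outDir = "out", seed = 1)
rep <- runPipeline(cfg)
```

On this seed the report shows the planted structure recovered exactly:
17 isolated proteins removed, 10 key targets (the planted hubs), shared
key targets `T001, T002, T003` (the three planted dual-herb targets), and
the planted term `BP016` at the minimum enrichment p (2.4e-05). All
artifacts (centrality tables, GraphML/SIF exports for Cytoscape, cluster
and enrichment tables, `report.json`) land in `out/`.

A thin command-line wrapper with `simulate` and `run` subcommands is
installed at `inst/scripts/netpharm.R`.

## Package layout

* `R/` — S4 classes (`HerbIncidence`, `PPINetwork`, `GeneSetDb`,
  `CTNetwork`, `SyntheticTruth`) and the stage functions.
* `inst/extdata/` — the transcribed printed tables used as fixtures.
* `vignettes/network-pharmacology.Rmd` — models, parameter rationale,
  numerical conventions, and what the synthetic benchmark does and does not
  show.
* `tests/testthat/` — unit, property and acceptance suites, including
  exhaustive betweenness verification against geodesic enumeration.
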