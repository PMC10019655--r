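#' @import methods
#' @importFrom igraph is_igraph gorder gsize is_directed any_loop edge_attr
#'   vertex_attr V E degree
NULL

setOldClass("igraph")

#' Binary herb-by-prescription incidence matrix (the 2-mode network)
#'
#' Wraps a strictly binary matrix with herbs in rows and prescriptions in
#' columns; a cell is 1 when the herb is part of the prescription. Herbs that
#' occur in no prescription are not representable (all-zero rows are
#' rejected), which keeps downstream Jaccard coefficients well defined.
#'
#' @slot mat binary integer matrix, rownames = herb codes, colnames =
#'   prescription ids.
#'
#' @seealso [buildIncidence()], [projectComembership()], [jaccardMatrix()]
#' @export
setClass("HerbIncidence", representation(mat = "matrix"))

setValidity("HerbIncidence", function(object) {
    m <- object@mat
    if (is.null(rownames(m)) || is.null(colnames(m)))
        return("incidence matrix needs herb rownames and prescription colnames")
    if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
        return("duplicate herb or prescription labels")
    if (!all(m %in% c(0L, 1L)))
        return("incidence values must be strictly binary (0/1)")
    if (any(rowSums(m) == 0))
        return(sprintf("all-zero herb row(s): %s",
                       paste(rownames(m)[rowSums(m) == 0], collapse = ", ")))
    TRUE
})

#' Scored protein-protein interaction network
#'
#' An undirected simple graph over gene symbols in which every retained edge
#' carries a STRING-style combined confidence score on the unit scale, at or
#' above the construction threshold (default 0.4). Nodes without surviving
#' edges are kept until [removeIsolates()] so the number discarded can be
#' reported.
#'
#' @slot graph undirected `igraph` with vertex attribute `name` (gene symbol)
#'   and edge attribute `score` in `[minScore, 1]`.
#' @slot minScore numeric(1), the confidence threshold the graph was built at.
#'
#' @seealso [buildPPIGraph()], [centralityMetrics()], [screenKeyTargets()]
#' @export
setClass("PPINetwork",
         representation(graph = "igraph", minScore = "numeric"))

setValidity("PPINetwork", function(object) {
    g <- object@graph
    if (!igraph::is_igraph(g)) return("graph slot must be an igraph")
    if (igraph::is_directed(g)) return("PPI graph must be undirected")
    if (igraph::any_loop(g)) return("self-loops are not allowed")
    if (length(object@minScore) != 1 || object@minScore < 0 ||
        object@minScore > 1)
        return("minScore must be a single value in [0, 1]")
    if (igraph::gsize(g) > 0) {
        sc <- igraph::edge_attr(g, "score")
        if (is.null(sc)) return("edges must carry a 'score' attribute")
        if (any(sc < object@minScore - 1e-12) || any(sc > 1))
            return("edge scores must lie in [minScore, 1]")
    }
    TRUE
})

#' Collection of annotation gene sets (GMT-style)
#'
#' Term-indexed gene sets with a category tag per term (KEGG, BP, CC, MF or
#' other), the substrate of over-representation analysis.
#'
#' @slot ids character, unique term identifiers.
#' @slot names character, human-readable term names (parallel to `ids`).
#' @slot categories character, one of `"KEGG"`, `"BP"`, `"CC"`, `"MF"`,
#'   `"other"` per term.
#' @slot genes list of character vectors of member gene symbols (non-empty,
#'   uppercase, deduplicated).
#'
#' @seealso [readGeneSets()], [hypergeomEnrich()]
#' @export
setClass("GeneSetDb",
         representation(ids = "character", names = "character",
                        categories = "character", genes = "list"))

setValidity("GeneSetDb", function(object) {
    n <- length(object@ids)
    if (length(object@names) != n || length(object@categories) != n ||
        length(object@genes) != n)
        return("ids, names, categories and genes must have equal length")
    if (anyDuplicated(object@ids)) return("term ids must be unique")
    if (n > 0 && any(lengths(object@genes) == 0))
        return("every gene set must be non-empty")
    bad <- setdiff(unique(object@categories),
                   c("KEGG", "BP", "CC", "MF", "other"))
    if (length(bad))
        return(sprintf("unknown categories: %s", paste(bad, collapse = ", ")))
    TRUE
})

#' Bipartite compound-target network
#'
#' Two-layer network connecting herbal compounds (upper layer) to key targets
#' (lower layer). Compound vertices carry a source-herb class (single-herb or
#' shared); target vertices may carry a cluster id. Compounds with no edge to
#' any key target are dropped at assembly and recorded.
#'
#' @slot graph bipartite `igraph`; vertex attributes `layer`
#'   (`"compound"`/`"target"`), `herbs` (semicolon-joined codes, compounds
#'   only), `herbClass`, `cluster`.
#' @slot dropped character, pubchem ids of compounds dropped for having no
#'   surviving key-target edge.
#'
#' @seealso [assembleCTNetwork()], [sharedKeyTargets()]
#' @export
setClass("CTNetwork",
         representation(graph = "igraph", dropped = "character"))

setValidity("CTNetwork", function(object) {
    g <- object@graph
    if (!igraph::is_igraph(g)) return("graph slot must be an igraph")
    layer <- igraph::vertex_attr(g, "layer")
    if (igraph::gorder(g) > 0 &&
        (is.null(layer) || !all(layer %in% c("compound", "target"))))
        return("vertices need a layer attribute: 'compound' or 'target'")
    if (igraph::gsize(g) > 0) {
        el <- igraph::as_edgelist(g, names = FALSE)
        if (!all(layer[el[, 1]] != layer[el[, 2]]))
            return("network must be bipartite: edges only compound-target")
    }
    TRUE
})

#' Ground truth planted by the synthetic-data generators
#'
#' Everything needed to score recovery of planted structure without re-running
#' a generator: the dominant herb pair, hub and isolate genes of the synthetic
#' PPI, the dual-herb key targets, the enriched annotation term, whether the
#' second herb's targets were nested inside the first's, and the full
#' parameter set with the seed.
#'
#' @slot plantedPair character(2), codes of the dominant co-prescribed pair.
#' @slot plantedHubs character, designated hub genes.
#' @slot plantedIsolates character, genes with no interactions at all.
#' @slot plantedSharedTargets character, targets wired to both herbs'
#'   compounds.
#' @slot plantedEnrichedTerm character(1) or NA, id of the planted term.
#' @slot nestedSubset logical(1), whether CS-side targets are a subset of
#'   EH-side targets.
#' @slot params named list of every generator parameter, including sub-seeds.
#' @slot seed numeric(1), the master seed.
#'
#' @export
setClass("SyntheticTruth",
         representation(plantedPair = "character", plantedHubs = "character",
                        plantedIsolates = "character",
                        plantedSharedTargets = "character",
                        plantedEnrichedTerm = "character",
                        nestedSubset = "logical", params = "list",
                        seed = "numeric"))

## ---- show methods -------------------------------------------------------

setMethod("show", "HerbIncidence", function(object) {
    m <- object@mat
    cat(sprintf("HerbIncidence: %d herbs x %d prescriptions\n",
                nrow(m), ncol(m)))
    cat(sprintf("  herb frequency range: %d..%d\n",
                min(rowSums(m)), max(rowSums(m))))
})

setMethod("show", "PPINetwork", function(object) {
    g <- object@graph
    cat(sprintf("PPINetwork: %d nodes, %d edges (score >= %.3g)\n",
                igraph::gorder(g), igraph::gsize(g), object@minScore))
    iso <- sum(igraph::degree(g) == 0)
    if (iso > 0) cat(sprintf("  %d isolated node(s)\n", iso))
})

setMethod("show", "GeneSetDb", function(object) {
    cat(sprintf("GeneSetDb: %d sets over %d genes\n", length(object@ids),
                length(unique(unlist(object@genes)))))
    if (length(object@ids))
        print(table(factor(object@categories,
                           c("KEGG", "BP", "CC", "MF", "other"))))
})

setMethod("show", "CTNetwork", function(object) {
    layer <- igraph::vertex_attr(object@graph, "layer")
    cat(sprintf(
        "CTNetwork: %d compounds, %d targets, %d edges (%d compound(s) dropped)\n",
        sum(layer == "compound"), sum(layer == "target"),
        igraph::gsize(object@graph), length(object@dropped)))
})

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth\n")
    cat("  planted pair: ", paste(object@plantedPair, collapse = "-"), "\n")
    cat(sprintf("  hubs: %d, isolates: %d, dual-herb targets: %d\n",
                length(object@plantedHubs), length(object@plantedIsolates),
                length(object@plantedSharedTargets)))
    cat("  enriched term:", object@plantedEnrichedTerm,
        "| nested subset:", object@nestedSubset, "| seed:", object@seed, "\n")
})
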