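#' Union of targets of one herb's compounds
#'
#' Collects the targets of every compound attributed to a herb (shared
#' compounds contribute to each of their source herbs) and returns the
#' deduplicated union. Edges referencing compounds absent from `compounds`
#' are skipped with a warning.
#'
#' @param herb herb code, e.g. `"EH"`.
#' @param compounds compound data.frame, typically after [filterCompounds()].
#' @param edges compound-target edge data.frame with columns `compound`
#'   (pubchem_cid) and `target` (gene symbol).
#' @return sorted character vector of unique uppercase target symbols.
#' @export
herbTargetUnion <- function(herb, compounds, edges) {
    unknown <- !(edges$compound %in% compounds$pubchem_cid)
    if (any(unknown)) {
        warning(sprintf("skipped %d edge(s) referencing unknown compounds",
                        sum(unknown)))
        edges <- edges[!unknown, , drop = FALSE]
    }
    mine <- compounds$pubchem_cid[vapply(compounds$herbs,
                                         function(h) herb %in% h, logical(1))]
    sort(unique(.normSymbols(edges$target[edges$compound %in% mine])))
}

#' Combine two disease gene sets
#'
#' Disease-associated genes are typically pulled from more than one database;
#' this combines two lists by set intersection (the default reading of
#' "overlapping targets") or union.
#'
#' @param s1,s2 character vectors of gene symbols.
#' @param mode `"intersection"` (default) or `"union"`.
#' @return sorted character vector.
#' @export
combineDiseaseSets <- function(s1, s2, mode = c("intersection", "union")) {
    mode <- match.arg(mode)
    s1 <- .normSymbols(s1); s2 <- .normSymbols(s2)
    sort(unique(if (mode == "intersection") intersect(s1, s2)
                else union(s1, s2)))
}

#' Overlap of herb targets with a disease gene set
#'
#' @param herbTargets character vector of target symbols.
#' @param disease character vector of disease-associated symbols.
#' @return sorted character vector of the overlap.
#' @export
overlapWithDisease <- function(herbTargets, disease)
    sort(intersect(.normSymbols(herbTargets), .normSymbols(disease)))

#' Venn counts over labelled gene sets
#'
#' Generalizes [partitionBySource()] to arbitrary labelled gene sets: every
#' gene in the union is assigned to exactly one block keyed by the sorted
#' `&`-joined labels of the sets containing it.
#'
#' @param sets named list of gene-symbol vectors.
#' @return object of class `venn_partition` (see [partitionBySource()]).
#' @examples
#' vennCounts(list(EH = c("A", "B", "C"), CS = c("B", "C", "D")))$counts
#' @export
vennCounts <- function(sets) {
    if (is.null(names(sets)) || any(!nzchar(names(sets))))
        stop("sets must be a named list with non-empty labels")
    sets <- lapply(sets, function(s) unique(.normSymbols(s)))
    genes <- sort(unique(unlist(sets)))
    member <- lapply(genes, function(g)
        names(sets)[vapply(sets, function(s) g %in% s, logical(1))])
    blocks <- .partitionByKey(genes, member)
    arity <- vapply(strsplit(names(blocks), "&", fixed = TRUE), length,
                    integer(1))
    structure(list(blocks = blocks,
                   exclusive = blocks[arity == 1],
                   shared = blocks[arity > 1],
                   counts = vapply(blocks, length, integer(1))),
              class = "venn_partition")
}
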