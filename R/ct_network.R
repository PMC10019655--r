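#' Assemble the compound-(key)target bipartite network
#'
#' Restricts the compound-target edge list to the screened key targets and
#' builds the two-layer network: compound nodes (upper layer) classified by
#' source herb (`"<code>-only"` for single-herb compounds, `"shared"` for
#' multi-herb ones), target nodes (lower layer) optionally tagged with their
#' cluster id. Compounds left without any key-target edge are dropped from
#' the network and reported in the `dropped` slot.
#'
#' @param compounds compound data.frame (after ADME filtering).
#' @param edges compound-target edge data.frame (`compound`, `target`).
#' @param keyTargets character vector of key-target gene symbols.
#' @param clusters optional named integer vector (gene -> cluster id) from
#'   [spectralKmeans()].
#' @return a [CTNetwork-class].
#' @export
assembleCTNetwork <- function(compounds, edges, keyTargets, clusters = NULL) {
    if (!length(keyTargets)) stop("keyTargets must be non-empty")
    keyTargets <- unique(.normSymbols(keyTargets))
    edges <- edges[edges$compound %in% compounds$pubchem_cid, , drop = FALSE]
    edges$target <- .normSymbols(edges$target)
    edges <- edges[edges$target %in% keyTargets, , drop = FALSE]
    edges <- unique(edges[, c("compound", "target")])
    kept <- unique(edges$compound)
    dropped <- setdiff(compounds$pubchem_cid, kept)
    if (length(dropped))
        message(sprintf("dropped %d compound(s) with no key-target edge",
                        length(dropped)))
    if (nrow(edges) == 0) {
        warning("no compound-target edge survives the key-target filter")
        return(new("CTNetwork",
                   graph = igraph::make_empty_graph(directed = FALSE),
                   dropped = as.character(sort(dropped))))
    }
    idx <- match(kept, compounds$pubchem_cid)
    tgt <- sort(unique(edges$target))
    vdf <- data.frame(
        name = c(as.character(kept), tgt),
        layer = c(rep("compound", length(kept)), rep("target", length(tgt))),
        label = c(compounds$name[idx], tgt),
        herbs = c(.joinHerbs(compounds$herbs[idx]), rep(NA, length(tgt))),
        herbClass = c(ifelse(lengths(compounds$herbs[idx]) > 1, "shared",
                             paste0(vapply(compounds$herbs[idx], `[`,
                                           character(1), 1L), "-only")),
                      rep(NA, length(tgt))),
        cluster = c(rep(NA_integer_, length(kept)),
                    if (is.null(clusters)) rep(NA_integer_, length(tgt))
                    else as.integer(clusters[tgt])),
        stringsAsFactors = FALSE)
    edf <- data.frame(from = as.character(edges$compound), to = edges$target,
                      stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
    new("CTNetwork", graph = g, dropped = as.character(sort(dropped)))
}

#' Key targets shared by the herbs' compounds
#'
#' A key target counts as shared when, within the compound-target network,
#' it is adjacent to compounds attributed (in union) to at least two
#' distinct herbs — i.e. at least one compound of each herb for a pair.
#' Shared compounds carry all of their source herbs and therefore count as
#' evidence for each.
#'
#' @param net a [CTNetwork-class].
#' @return sorted character vector of shared key-target symbols.
#' @export
sharedKeyTargets <- function(net) {
    stopifnot(is(net, "CTNetwork"))
    g <- net@graph
    if (igraph::gorder(g) == 0) return(character(0))
    layer <- igraph::V(g)$layer
    herbs <- igraph::V(g)$herbs
    targets <- which(layer == "target")
    shared <- vapply(targets, function(v) {
        nb <- as.integer(igraph::neighbors(g, v))
        hb <- unique(unlist(strsplit(herbs[nb], ";", fixed = TRUE)))
        length(hb) >= 2
    }, logical(1))
    sort(igraph::V(g)$name[targets[shared]])
}
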