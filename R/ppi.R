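#' Build a scored PPI network over a target universe
#'
#' Keeps edges whose combined confidence score is at or above `minScore`
#' (the "minimum required interaction score", default 0.4 on the unit scale)
#' and whose endpoints both belong to the node universe. Nodes left without
#' edges remain in the graph as isolates until [removeIsolates()], so the
#' number discarded can be reported.
#'
#' @param edges data.frame with columns `a`, `b`, `score` (see
#'   [readPPIEdges()]).
#' @param universe character vector of gene symbols; the graph's node set.
#' @param minScore inclusion threshold in `[0, 1]`, default 0.4.
#' @return a [PPINetwork-class].
#' @export
buildPPIGraph <- function(edges, universe, minScore = 0.4) {
    stopifnot(minScore >= 0, minScore <= 1)
    universe <- sort(unique(.normSymbols(universe)))
    if (!length(universe)) stop("empty node universe")
    outside <- !(edges$a %in% universe & edges$b %in% universe)
    if (any(outside)) {
        warning(sprintf("dropped %d edge(s) with endpoints outside universe",
                        sum(outside)))
        edges <- edges[!outside, , drop = FALSE]
    }
    edges <- edges[edges$score >= minScore & edges$a != edges$b, , drop = FALSE]
    if (nrow(edges)) {  # collapse duplicate unordered pairs, keep max score
        from <- pmin(edges$a, edges$b)
        to <- pmax(edges$a, edges$b)
        score <- vapply(split(edges$score, paste(from, to, sep = "\r")), max,
                        numeric(1))
        parts <- strsplit(names(score), "\r", fixed = TRUE)
        edf <- data.frame(from = vapply(parts, `[`, character(1), 1L),
                          to = vapply(parts, `[`, character(1), 2L),
                          score = unname(score), stringsAsFactors = FALSE)
        edf <- edf[order(edf$from, edf$to), , drop = FALSE]
    } else {
        edf <- data.frame(from = character(), to = character(),
                          score = numeric())
    }
    g <- igraph::graph_from_data_frame(edf, directed = FALSE,
                                       vertices = universe)
    new("PPINetwork", graph = g, minScore = minScore)
}

#' Remove isolated nodes from a PPI network
#'
#' Discards target nodes without any known interaction (degree zero) and
#' reports them.
#'
#' @param x a [PPINetwork-class].
#' @return list with `network` (the pruned [PPINetwork-class]) and
#'   `removed` (character vector of discarded gene symbols).
#' @export
removeIsolates <- function(x) {
    stopifnot(is(x, "PPINetwork"))
    g <- x@graph
    iso <- igraph::V(g)$name[igraph::degree(g) == 0]
    g2 <- igraph::delete_vertices(g, iso)
    list(network = new("PPINetwork", graph = g2, minScore = x@minScore),
         removed = sort(iso))
}

# Brandes' accumulation for betweenness centrality on an unweighted,
# undirected graph given as an adjacency list (1-based integer vectors).
# Returns raw (unnormalized) betweenness; undirected double counting halved.
.brandes <- function(adj) {
    n <- length(adj)
    cb <- numeric(n)
    for (s in seq_len(n)) {
        sigma <- numeric(n); sigma[s] <- 1
        dist <- rep(-1L, n); dist[s] <- 0L
        pred <- vector("list", n)
        queue <- integer(n); queue[1L] <- s
        qh <- 1L; qt <- 1L
        order <- integer(0)
        while (qh <= qt) {
            v <- queue[qh]; qh <- qh + 1L
            order[length(order) + 1L] <- v
            for (w in adj[[v]]) {
                if (dist[w] < 0L) {
                    dist[w] <- dist[v] + 1L
                    qt <- qt + 1L; queue[qt] <- w
                }
                if (dist[w] == dist[v] + 1L) {
                    sigma[w] <- sigma[w] + sigma[v]
                    pred[[w]] <- c(pred[[w]], v)
                }
            }
        }
        delta <- numeric(n)
        for (v in rev(order)) {
            for (p in pred[[v]])
                delta[p] <- delta[p] + sigma[p] / sigma[v] * (1 + delta[v])
            if (v != s) cb[v] <- cb[v] + delta[v]
        }
    }
    cb / 2
}

#' Degree and normalized betweenness centrality
#'
#' Degree is the incident-edge count. Betweenness is computed by Brandes'
#' shortest-path accumulation over unweighted geodesics (confidence scores
#' gate edge existence, not path length) and normalized by
#' \eqn{(n-1)(n-2)/2}, the undirected network-analyzer convention, so values
#' lie in `[0, 1]`. Pairs in different components have no geodesic and
#' contribute nothing. With fewer than 3 nodes the normalization is
#' undefined and betweenness is reported as 0 with a warning.
#'
#' @param x a [PPINetwork-class].
#' @return data.frame with columns `gene`, `degree`, `betweenness`, sorted
#'   by decreasing degree (ties broken by gene symbol).
#' @export
centralityMetrics <- function(x) {
    stopifnot(is(x, "PPINetwork"))
    g <- x@graph
    n <- igraph::gorder(g)
    deg <- igraph::degree(g)
    if (n < 3) {
        warning("fewer than 3 nodes: betweenness reported as 0")
        btw <- numeric(n)
    } else {
        adj <- igraph::as_adj_list(g)
        adj <- lapply(adj, as.integer)
        btw <- .brandes(adj) / ((n - 1) * (n - 2) / 2)
    }
    out <- data.frame(gene = igraph::V(g)$name, degree = as.integer(deg),
                      betweenness = as.numeric(btw),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$degree, out$gene), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Screen key targets by the dual above-average rule
#'
#' A target is "key" when it is strictly above the network-wide arithmetic
#' mean on both degree and betweenness centrality. Ties at the mean are not
#' above it, so e.g. a regular graph (all centralities equal) selects
#' nothing. The means are taken over the table passed in — conventionally
#' the isolate-free network.
#'
#' @param tab centrality data.frame from [centralityMetrics()].
#' @return character vector of key-target gene symbols (sorted).
#' @export
screenKeyTargets <- function(tab) {
    if (nrow(tab) == 0) stop("empty centrality table")
    keep <- tab$degree > mean(tab$degree) &
        tab$betweenness > mean(tab$betweenness)
    sort(tab$gene[keep])
}

#' Induced subnetwork on a node subset
#'
#' Keeps only the named nodes and the edges internal to them; used for the
#' second pass in which centrality is recomputed inside the key-target
#' subnetwork.
#'
#' @param x a [PPINetwork-class].
#' @param keep character vector of gene symbols, a subset of the nodes.
#' @return a [PPINetwork-class] on `keep`.
#' @export
inducedSubgraph <- function(x, keep) {
    stopifnot(is(x, "PPINetwork"))
    keep <- unique(.normSymbols(keep))
    missing <- setdiff(keep, igraph::V(x@graph)$name)
    if (length(missing))
        stop(sprintf("node(s) not in network: %s",
                     paste(missing, collapse = ", ")))
    new("PPINetwork", graph = igraph::induced_subgraph(x@graph, keep),
        minScore = x@minScore)
}

#' Edge count from a degree sequence (handshake lemma)
#'
#' For an undirected graph the degree sum equals twice the edge count, so a
#' printed degree column determines the number of interactions:
#' \eqn{|E| = \sum_i d_i / 2}.
#'
#' @param degrees non-negative integer degree sequence.
#' @return integer edge count.
#' @export
edgeCountFromDegrees <- function(degrees) {
    if (any(degrees < 0) || any(degrees != round(degrees)))
        stop("degrees must be non-negative integers")
    s <- sum(degrees)
    if (s %% 2 != 0)
        stop("invalid degree sequence: odd degree sum")
    as.integer(s / 2)
}
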