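# Independent oracles used to check the package's graph and enrichment code.
# These deliberately take the naive route (exhaustive enumeration, Monte
# Carlo) so they share no code path with the implementation.

# Betweenness by exhaustive geodesic enumeration: for every ordered pair,
# all shortest paths are enumerated by distance-pruned DFS and each interior
# vertex credited with its fraction. Normalized by (n-1)(n-2)/2.
oracleBetweenness <- function(g) {
    n <- igraph::gorder(g)
    adj <- lapply(igraph::as_adj_list(g), as.integer)
    bfsDist <- function(s) {
        d <- rep(Inf, n); d[s] <- 0; q <- s
        while (length(q)) {
            v <- q[1]; q <- q[-1]
            for (w in adj[[v]]) if (!is.finite(d[w])) {
                d[w] <- d[v] + 1; q <- c(q, w)
            }
        }
        d
    }
    D <- t(vapply(seq_len(n), bfsDist, numeric(n)))
    btw <- numeric(n)
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
        if (!is.finite(D[s, t]) || D[s, t] == 0) next
        total <- 0; through <- numeric(n)
        rec <- function(v, interior) {
            if (v == t) {
                total <<- total + 1
                if (length(interior))
                    through[interior] <<- through[interior] + 1
                return(invisible())
            }
            for (w in adj[[v]])
                if (is.finite(D[w, t]) && D[w, t] == D[v, t] - 1)
                    rec(w, if (w == t) interior else c(interior, w))
        }
        rec(s, integer(0))
        btw <- btw + through / total
    }
    stats::setNames(btw / ((n - 1) * (n - 2) / 2), igraph::V(g)$name)
}

# co-membership by explicit pair-and-column counting
oracleComembership <- function(mat) {
    n <- nrow(mat)
    out <- matrix(0L, n, n, dimnames = list(rownames(mat), rownames(mat)))
    for (i in seq_len(n)) for (j in seq_len(n))
        out[i, j] <- sum(mat[i, ] == 1 & mat[j, ] == 1)
    out
}

# Monte Carlo estimate of the hypergeometric upper tail P[X >= k]
oraclePermHyper <- function(N, K, n, k, reps = 1e5) {
    hits <- vapply(seq_len(reps),
                   function(i) sum(sample.int(N, n) <= K) >= k, logical(1))
    mean(hits)
}

# wrap an edge data.frame (or none) into a PPINetwork over given nodes
makePPI <- function(nodes, edges = NULL, minScore = 0) {
    if (is.null(edges))
        edges <- data.frame(a = character(), b = character(),
                            score = numeric())
    if (is.null(edges$score)) edges$score <- 1
    buildPPIGraph(edges, nodes, minScore)
}

# undirected graph on `n` labelled nodes from an edge-presence bitmask
graphFromMask <- function(n, mask) {
    pairs <- utils::combn(n, 2)
    keep <- as.logical(bitwAnd(mask, 2^(seq_len(ncol(pairs)) - 1)) > 0)
    nodes <- LETTERS[seq_len(n)]
    if (!any(keep))
        return(makePPI(nodes))
    makePPI(nodes, data.frame(a = nodes[pairs[1, keep]],
                              b = nodes[pairs[2, keep]], score = 1))
}

# Erdos-Renyi edge table over labelled nodes
randomEdges <- function(nodes, p) {
    if (length(nodes) == 1) nodes <- sprintf("N%02d", seq_len(nodes))
    pairs <- utils::combn(nodes, 2)
    keep <- stats::runif(ncol(pairs)) < p
    if (!any(keep))
        return(data.frame(a = character(), b = character(),
                          score = numeric()))
    data.frame(a = pairs[1, keep], b = pairs[2, keep], score = 1)
}
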