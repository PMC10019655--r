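# k-means++ seeding: D^2-weighted center choice (Arthur & Vassilvitskii)
.kppCenters <- function(x, k) {
    n <- nrow(x)
    centers <- integer(k)
    centers[1L] <- sample.int(n, 1L)
    d2 <- rowSums((x - matrix(x[centers[1L], ], n, ncol(x),
                              byrow = TRUE))^2)
    for (i in seq_len(k - 1L)) {
        prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
        centers[i + 1L] <- sample.int(n, 1L, prob = prob)
        nd <- rowSums((x - matrix(x[centers[i + 1L], ], n, ncol(x),
                                  byrow = TRUE))^2)
        d2 <- pmin(d2, nd)
    }
    centers
}

#' Spectral k-means clustering of a PPI subnetwork
#'
#' Embeds the nodes with the eigenvectors belonging to the k smallest
#' eigenvalues of the symmetric normalized Laplacian
#' \eqn{L = I - D^{-1/2} A D^{-1/2}} (rows unit-normalized), then runs
#' k-means with k-means++ initialization and `nstart` restarts, keeping the
#' solution with the lowest total within-cluster sum of squares. The
#' procedure is deterministic for a fixed `seed`. Disjoint connected
#' components are separated exactly (their indicator vectors span the null
#' space of L).
#'
#' @param x a [PPINetwork-class] with at least `k` nodes.
#' @param k number of clusters (default 3).
#' @param seed integer seed driving initialization.
#' @param nstart number of k-means++ restarts (default 100).
#' @return named integer vector: gene symbol -> cluster id in `1..k`,
#'   cluster ids relabelled in order of first appearance over the node
#'   ordering.
#' @export
spectralKmeans <- function(x, k = 3, seed = 1, nstart = 100) {
    stopifnot(is(x, "PPINetwork"), k >= 2)
    g <- x@graph
    n <- igraph::gorder(g)
    if (n < k) stop(sprintf("cannot form %d clusters from %d nodes", k, n))
    genes <- igraph::V(g)$name
    if (n == k)  # singleton clusters; k-means centers would not be distinct
        return(stats::setNames(seq_len(n), genes))
    A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    d <- rowSums(A)
    dhalf <- ifelse(d > 0, 1 / sqrt(d), 0)
    L <- diag(n) - (dhalf %o% dhalf) * A
    ev <- eigen(L, symmetric = TRUE)
    embed <- ev$vectors[, n - seq_len(k) + 1L, drop = FALSE]
    rn <- sqrt(rowSums(embed^2))
    embed <- embed / ifelse(rn > 0, rn, 1)
    .withSeed(seed, {
        best <- NULL
        for (r in seq_len(nstart)) {
            ctr <- embed[.kppCenters(embed, k), , drop = FALSE]
            km <- tryCatch(suppressWarnings(
                stats::kmeans(embed, ctr, iter.max = 100,
                              algorithm = "Lloyd")),
                error = function(e) NULL)
            if (is.null(km)) next
            if (is.null(best) || km$tot.withinss < best$tot.withinss -
                1e-12)
                best <- km
        }
        if (is.null(best)) stop("k-means failed on the spectral embedding")
        cl <- best$cluster
        relabel <- match(cl, unique(cl))  # stable ids: order of appearance
        stats::setNames(as.integer(relabel), genes)
    })
}

#' Hypergeometric over-representation analysis
#'
#' For each annotation term, tests whether the query gene set overlaps the
#' term more than expected under uniform sampling from the background:
#' the upper-tail probability \eqn{p = P[X \ge k]} for
#' \eqn{X \sim \mathrm{Hypergeom}(N, K, n)} with `N` background genes, `K`
#' term members (after intersection with the background), and `n` query
#' genes. Terms with no query overlap are omitted. Benjamini-Hochberg
#' adjusted values are computed within each category separately (DAVID-style
#' per-ontology reporting) or globally.
#'
#' @param query character vector of gene symbols; intersected with the
#'   background before testing.
#' @param db a [GeneSetDb-class].
#' @param background character vector of background gene symbols; defaults
#'   to the union of all genes in `db`.
#' @param bhScope `"per-category"` (default) or `"global"`.
#' @return data.frame with one row per overlapping term: `term_id`,
#'   `term_name`, `category`, `k_overlap`, `K_term`, `n_query`,
#'   `N_background`, `p`, `q`, `gene_ratio`, `genes` (slash-joined overlap
#'   symbols), sorted by increasing `p` (ties by term id).
#' @examples
#' db <- GeneSetDb("T1", list(c("A", "B", "C")), categories = "BP")
#' hypergeomEnrich(c("A", "B"), db, background = c("A", "B", "C", "D", "E"))
#' @export
hypergeomEnrich <- function(query, db, background = NULL,
                            bhScope = c("per-category", "global")) {
    bhScope <- match.arg(bhScope)
    stopifnot(is(db, "GeneSetDb"))
    if (is.null(background)) background <- unlist(db@genes)
    background <- unique(.normSymbols(background))
    if (!length(background)) stop("empty background")
    query <- unique(.normSymbols(query))
    if (!length(query)) stop("empty query")
    query <- intersect(query, background)
    if (!length(query)) stop("query does not intersect the background")
    N <- length(background)
    n <- length(query)
    rows <- lapply(seq_along(db@ids), function(i) {
        members <- intersect(db@genes[[i]], background)
        hit <- intersect(query, members)
        k <- length(hit)
        if (k == 0) return(NULL)
        K <- length(members)
        p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        data.frame(term_id = db@ids[i], term_name = db@names[i],
                   category = db@categories[i], k_overlap = k, K_term = K,
                   n_query = n, N_background = N, p = p,
                   gene_ratio = k / n,
                   genes = paste(sort(hit), collapse = "/"),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        return(data.frame(term_id = character(), term_name = character(),
                          category = character(), k_overlap = integer(),
                          K_term = integer(), n_query = integer(),
                          N_background = integer(), p = numeric(),
                          q = numeric(), gene_ratio = numeric(),
                          genes = character(), stringsAsFactors = FALSE))
    out$q <- if (bhScope == "global") bhAdjust(out$p)
             else stats::ave(out$p, out$category, FUN = bhAdjust)
    out <- out[order(out$p, out$term_id), c("term_id", "term_name",
            "category", "k_overlap", "K_term", "n_query", "N_background",
            "p", "q", "gene_ratio", "genes")]
    rownames(out) <- NULL
    out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment,
#' \eqn{q_{(i)} = \min_{j \ge i} \min(1, p_{(j)} m / j)}; preserves the
#' order of p-values and never yields `q < p`.
#'
#' @param pvalues numeric vector of p-values in `(0, 1]`.
#' @return adjusted values in the input order.
#' @export
bhAdjust <- function(pvalues) stats::p.adjust(pvalues, method = "BH")

#' Top enriched terms by p-value
#'
#' Sorts ascending by `p` (ties broken by term id) and truncates to the `n`
#' lowest-p terms, within each category when `byCategory = TRUE` (the usual
#' "top 20 per category" bubble-chart selection).
#'
#' @param rows enrichment data.frame from [hypergeomEnrich()].
#' @param n number of terms to keep (default 20).
#' @param byCategory truncate per category (default TRUE).
#' @return the truncated data.frame.
#' @export
topTerms <- function(rows, n = 20, byCategory = TRUE) {
    rows <- rows[order(rows$p, rows$term_id), , drop = FALSE]
    out <- if (byCategory)
        do.call(rbind, lapply(split(rows, rows$category), utils::head, n))
    else utils::head(rows, n)
    out <- out[order(out$p, out$term_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Bubble-chart data for enrichment results
#'
#' Plot-ready table: term name, `-log10(p)`, gene count and gene ratio per
#' term, the quantities drawn in enrichment bubble charts.
#'
#' @param rows enrichment data.frame from [hypergeomEnrich()].
#' @return data.frame with `term_id`, `term_name`, `category`,
#'   `neg_log10_p`, `gene_count`, `gene_ratio`.
#' @export
bubbleData <- function(rows)
    data.frame(term_id = rows$term_id, term_name = rows$term_name,
               category = rows$category, neg_log10_p = -log10(rows$p),
               gene_count = rows$k_overlap, gene_ratio = rows$gene_ratio,
               stringsAsFactors = FALSE)
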