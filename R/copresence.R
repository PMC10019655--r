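#' Build the herb-by-prescription incidence matrix
#'
#' Arranges herbal compositions of prescriptions as a binary matrix (the
#' 2-mode network) with herbs in rows and prescriptions in columns: 1 marks
#' presence of the herb in the prescription, 0 absence. Rows are the sorted
#' union of all herbs mentioned; every prescription must contain at least two
#' distinct herbs.
#'
#' @param prescriptions named list; each element is a character vector of
#'   herb codes for one prescription, the element name its id.
#' @return a [HerbIncidence-class].
#' @examples
#' inc <- buildIncidence(list(P1 = c("A", "B"), P2 = c("B", "C")))
#' incidenceMatrix(inc)["B", ]  # present in both
#' @export
buildIncidence <- function(prescriptions) {
    if (length(prescriptions) < 1) stop("need at least one prescription")
    ids <- names(prescriptions)
    if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids))
        stop("prescriptions must carry unique non-empty ids as names")
    herbsets <- lapply(prescriptions, function(h) unique(trimws(h)))
    few <- lengths(herbsets) < 2
    if (any(few))
        stop(sprintf("prescription(s) with fewer than 2 herbs: %s",
                     paste(ids[few], collapse = ", ")))
    herbs <- sort(unique(unlist(herbsets)))
    mat <- matrix(0L, length(herbs), length(herbsets),
                  dimnames = list(herbs, ids))
    for (j in seq_along(herbsets)) mat[herbsets[[j]], j] <- 1L
    new("HerbIncidence", mat = mat)
}

#' One-mode projection: herb co-prescription counts
#'
#' Transforms the 2-mode incidence matrix into the 1-mode herb-by-herb
#' network by matrix-product projection \eqn{B B^T}: the off-diagonal cell
#' (h1, h2) counts prescriptions containing both herbs, the diagonal is each
#' herb's frequency of appearance.
#'
#' @param x a [HerbIncidence-class].
#' @return symmetric integer matrix with attribute `kind =
#'   "cooccurrence-count"`.
#' @export
projectComembership <- function(x) {
    stopifnot(is(x, "HerbIncidence"))
    m <- x@mat
    co <- m %*% t(m)
    storage.mode(co) <- "integer"
    attr(co, "kind") <- "cooccurrence-count"
    co
}

#' Jaccard similarity between herbs
#'
#' Standard set Jaccard over presence sets: \eqn{J(h_1,h_2) =
#' |P(h_1) \cap P(h_2)| / |P(h_1) \cup P(h_2)|} where \eqn{P(h)} is the set
#' of prescriptions containing herb \eqn{h}. Co-absence contributes nothing,
#' so rarely used herbs are not rewarded for being jointly missing.
#'
#' @param x a [HerbIncidence-class].
#' @return symmetric numeric matrix in `[0, 1]` with unit diagonal and
#'   attribute `kind = "jaccard"`.
#' @export
jaccardMatrix <- function(x) {
    stopifnot(is(x, "HerbIncidence"))
    m <- x@mat
    co <- m %*% t(m)
    freq <- rowSums(m)
    uni <- outer(freq, freq, "+") - co
    j <- co / uni  # uni > 0 because all-zero rows are rejected at build
    attr(j, "kind") <- "jaccard"
    j
}

#' Pearson correlation (phi) between herb presence profiles
#'
#' Pairwise Pearson correlation between the binary herb rows (equivalently
#' the phi coefficient). Herbs present in every prescription (or absent in
#' none sampled) have zero-variance rows; their correlations are undefined
#' and mapped to 0 with a warning so heatmaps never fail on ubiquitous herbs.
#'
#' @param x a [HerbIncidence-class] with at least two prescriptions.
#' @return symmetric numeric matrix in `[-1, 1]`, unit diagonal where
#'   defined, attribute `kind = "pearson"`.
#' @export
pearsonMatrix <- function(x) {
    stopifnot(is(x, "HerbIncidence"))
    m <- x@mat
    if (ncol(m) < 2)
        stop("Pearson correlation undefined for a single prescription")
    r <- suppressWarnings(stats::cor(t(m)))
    zv <- apply(m, 1, function(v) stats::var(v) == 0)
    if (any(zv)) {
        warning(sprintf("zero-variance herb row(s) set to r = 0: %s",
                        paste(rownames(m)[zv], collapse = ", ")))
        r[zv, ] <- 0
        r[, zv] <- 0
    }
    attr(r, "kind") <- "pearson"
    r
}

#' Heatmap leaf order for a similarity matrix
#'
#' Orders labels by average-linkage hierarchical clustering of the distance
#' `1 - value`, the ordering used when writing the clustered heatmap matrix.
#'
#' @param s symmetric similarity matrix (Pearson or Jaccard).
#' @return character vector: row labels in dendrogram leaf order.
#' @export
orderForHeatmap <- function(s) {
    if (nrow(s) < 3) return(rownames(s))
    hc <- stats::hclust(stats::as.dist(1 - s), method = "average")
    rownames(s)[hc$order]
}

#' Build the attributed 1-mode herb network
#'
#' Nodes are herbs; an undirected edge joins two herbs whenever they co-occur
#' in at least one prescription. Edge weights carry the Jaccard coefficient
#' (drawn as edge width), node attributes carry frequency of appearance
#' (node colour) and degree (node size).
#'
#' @param co co-occurrence count matrix from [projectComembership()].
#' @param jac Jaccard matrix from [jaccardMatrix()] over the same herbs.
#' @return an igraph with edge attribute `weight` (Jaccard) and
#'   `cooccurrence` (count), vertex attributes `frequency` and `degree`.
#' @export
herbNetwork <- function(co, jac) {
    if (!identical(rownames(co), rownames(jac)))
        stop("co-occurrence and Jaccard matrices must share herb labels")
    adj <- co
    diag(adj) <- 0L
    g <- igraph::graph_from_adjacency_matrix(adj >= 1, mode = "undirected")
    el <- igraph::as_edgelist(g)
    if (nrow(el)) {
        igraph::E(g)$weight <- jac[cbind(el[, 1], el[, 2])]
        igraph::E(g)$cooccurrence <- co[cbind(el[, 1], el[, 2])]
    }
    igraph::V(g)$frequency <- diag(co)[igraph::V(g)$name]
    igraph::V(g)$degree <- igraph::degree(g)
    g
}
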