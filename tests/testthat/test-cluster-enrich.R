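cliquePair <- function() {
    nodes <- c(paste0("A", 1:5), paste0("B", 1:5))
    pairs <- rbind(t(utils::combn(paste0("A", 1:5), 2)),
                   t(utils::combn(paste0("B", 1:5), 2)))
    makePPI(nodes, data.frame(a = pairs[, 1], b = pairs[, 2], score = 1))
}

test_that("spectral k-means separates disjoint components exactly", {
    net <- cliquePair()
    cl <- spectralKmeans(net, k = 2, seed = 1)
    comp <- igraph::components(ppiGraph(net))$membership
    expect_equal(length(unique(cl[paste0("A", 1:5)])), 1)
    expect_equal(length(unique(cl[paste0("B", 1:5)])), 1)
    expect_false(cl[["A1"]] == cl[["B1"]])
    expect_setequal(names(cl), names(comp))
})

test_that("spectral k-means is deterministic and handles k = n", {
    net <- cliquePair()
    expect_identical(spectralKmeans(net, 3, seed = 42),
                     spectralKmeans(net, 3, seed = 42))
    singles <- spectralKmeans(net, k = 10, seed = 1)
    expect_equal(sort(unname(singles)), 1:10)
    expect_error(spectralKmeans(net, k = 11), "11 clusters from 10 nodes")
})

test_that("hypergeometric p matches the closed form and edge cases", {
    db <- GeneSetDb("T1", list(letters[1:5]), categories = "BP")
    rows <- hypergeomEnrich(letters[1:5], db, background = letters[1:10])
    expect_equal(rows$p, 1 / choose(10, 5))   # 1/252
    expect_equal(rows$k_overlap, 5)
    expect_equal(rows$gene_ratio, 1)

    dbU <- GeneSetDb("ALL", list(letters[1:10]))
    rowsU <- hypergeomEnrich(letters[1:3], dbU, background = letters[1:10])
    expect_equal(rowsU$p, 1)                  # term is the universe

    expect_error(hypergeomEnrich(character(0), db, letters[1:10]), "empty")
    expect_error(hypergeomEnrich("zz", db, background = letters[1:10]),
                 "does not intersect")
})

test_that("hypergeometric p agrees with a permutation oracle", {
    set.seed(11)
    for (i in 1:5) {
        N <- sample(12:30, 1)
        K <- sample(3:(N - 2), 1)
        n <- sample(3:(N - 2), 1)
        bg <- sprintf("g%02d", seq_len(N))
        db <- GeneSetDb("T", list(bg[seq_len(K)]))
        qry <- sample(bg, n)
        k <- length(intersect(qry, bg[seq_len(K)]))
        if (k == 0) next
        p <- hypergeomEnrich(qry, db, background = bg)$p
        est <- oraclePermHyper(N, K, n, k, reps = 1e5)
        se <- sqrt(max(est * (1 - est), 1e-9) / 1e5)
        expect_lt(abs(p - est), 3 * se + 1e-12)
    }
})

test_that("enrichment p decreases as overlap grows", {
    N <- 40; bg <- sprintf("g%02d", 1:N)
    db <- GeneSetDb("T", list(bg[1:10]))
    ps <- vapply(2:8, function(k) {
        qry <- c(bg[seq_len(k)], bg[11:(20 - k)])  # always 10 query genes
        hypergeomEnrich(qry, db, background = bg)$p
    }, numeric(1))
    expect_true(all(diff(ps) < 0))
})

test_that("BH adjustment reproduces the step-up formula", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.2), 0.2)
    set.seed(4)
    p <- runif(25)
    q <- bhAdjust(p)
    expect_true(all(q >= p))
    expect_equal(order(q[order(p)]), seq_len(25))  # order preserved
})

test_that("top-term selection sorts by p and truncates per category", {
    rows <- data.frame(term_id = sprintf("T%02d", 1:6),
                       term_name = "t", category = rep(c("BP", "CC"), 3),
                       k_overlap = 2, K_term = 5, n_query = 10,
                       N_background = 50,
                       p = c(0.5, 0.01, 0.2, 0.02, 0.3, 0.3),
                       q = 1, gene_ratio = 0.2, genes = "A/B")
    top <- topTerms(rows, n = 2, byCategory = TRUE)
    expect_equal(sum(top$category == "BP"), 2)
    expect_equal(sum(top$category == "CC"), 2)
    expect_equal(top$term_id[1], "T02")
    expect_equal(nrow(topTerms(rows, n = 100, byCategory = FALSE)), 6)
})

test_that("a term planted inside a cluster attains the minimum p", {
    b <- genBundle(seed = 31)
    net <- buildPPIGraph(b$ppiEdges, truthParams(b$truth)$diseaseOverlap,
                         0.4)
    pruned <- removeIsolates(net)$network
    keys <- screenKeyTargets(centralityMetrics(pruned))
    rows <- hypergeomEnrich(keys, b$annotations)
    inCat <- rows[rows$category == "BP", ]
    expect_equal(inCat$p[inCat$term_id == b$truth@plantedEnrichedTerm],
                 min(inCat$p))
})
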