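test_that("PPI construction keeps scores at or above the threshold", {
    edges <- data.frame(a = c("A", "B", "C"), b = c("B", "C", "D"),
                        score = c(0.39, 0.40, 0.95))
    net <- buildPPIGraph(edges, c("A", "B", "C", "D"), 0.4)
    expect_equal(igraph::gsize(ppiGraph(net)), 2)  # inclusive threshold
    expect_equal(igraph::gorder(ppiGraph(net)), 4)

    empty <- buildPPIGraph(edges[0, ], c("A", "B"), 0.4)
    expect_equal(igraph::gsize(ppiGraph(empty)), 0)
    expect_equal(igraph::gorder(ppiGraph(empty)), 2)

    expect_warning(buildPPIGraph(data.frame(a = "A", b = "ZZ", score = 0.9),
                                 c("A", "B"), 0.4),
                   "outside universe")
})

test_that("isolate removal reports exactly the zero-degree nodes", {
    net <- makePPI(c("A", "B", "C"),
                   data.frame(a = "A", b = "B", score = 1))
    out <- removeIsolates(net)
    expect_equal(out$removed, "C")
    expect_equal(igraph::gorder(ppiGraph(out$network)), 2)

    full <- makePPI(c("A", "B", "C"),
                    data.frame(a = c("A", "A", "B"), b = c("B", "C", "C"),
                               score = 1))
    out2 <- removeIsolates(full)
    expect_equal(out2$removed, character(0))
    expect_equal(igraph::gorder(ppiGraph(out2$network)), 3)
})

test_that("betweenness matches closed forms on path and star", {
    path <- makePPI(c("A", "B", "C"),
                    data.frame(a = c("A", "B"), b = c("B", "C"), score = 1))
    cm <- centralityMetrics(path)
    expect_equal(cm$betweenness[cm$gene == "B"], 1.0)
    expect_equal(cm$betweenness[cm$gene == "A"], 0.0)

    star <- makePPI(LETTERS[1:5],
                    data.frame(a = "A", b = LETTERS[2:5], score = 1))
    cmS <- centralityMetrics(star)
    expect_equal(cmS$betweenness[cmS$gene == "A"], 1.0)  # 6 leaf pairs / 6
    expect_true(all(cmS$betweenness[cmS$gene != "A"] == 0))

    tiny <- makePPI(c("A", "B"), data.frame(a = "A", b = "B", score = 1))
    expect_warning(cmT <- centralityMetrics(tiny), "fewer than 3")
    expect_equal(cmT$betweenness, c(0, 0))
})

test_that("betweenness agrees with igraph and the enumeration oracle", {
    set.seed(7)
    for (i in 1:20) {
        n <- sample(5:12, 1)
        net <- makePPI(sprintf("N%02d", 1:n), randomEdges(n, 0.3))
        cm <- centralityMetrics(net)
        ours <- setNames(cm$betweenness, cm$gene)
        ig <- igraph::betweenness(ppiGraph(net), directed = FALSE,
                                  normalized = TRUE)
        expect_equal(ours[names(ig)], ig, tolerance = 1e-10)
        if (n <= 7) {
            orc <- oracleBetweenness(ppiGraph(net))
            expect_equal(ours[names(orc)], orc, tolerance = 1e-10)
        }
        # handshake lemma and bounds
        expect_equal(sum(cm$degree), 2 * igraph::gsize(ppiGraph(net)))
        expect_true(all(cm$betweenness >= 0 & cm$betweenness <= 1))
    }
})

test_that("key-target screening applies the strict dual above-mean rule", {
    cycle <- makePPI(LETTERS[1:4],
                     data.frame(a = c("A", "B", "C", "D"),
                                b = c("B", "C", "D", "A"), score = 1))
    expect_equal(screenKeyTargets(centralityMetrics(cycle)), character(0))

    star <- makePPI(LETTERS[1:5],
                    data.frame(a = "A", b = LETTERS[2:5], score = 1))
    expect_equal(screenKeyTargets(centralityMetrics(star)), "A")

    set.seed(3)
    net <- makePPI(sprintf("N%02d", 1:30), randomEdges(30, 0.15))
    cm <- centralityMetrics(net)
    expect_equal(screenKeyTargets(cm),
                 sort(cm$gene[cm$degree > mean(cm$degree) &
                                  cm$betweenness > mean(cm$betweenness)]))
    # invariant to row order
    expect_equal(screenKeyTargets(cm[sample(nrow(cm)), ]),
                 screenKeyTargets(cm))
    expect_error(screenKeyTargets(cm[0, ]), "empty")
})

test_that("induced subgraphs keep internal edges only", {
    net <- makePPI(LETTERS[1:4],
                   data.frame(a = c("A", "B", "C"), b = c("B", "C", "D"),
                              score = 1))
    expect_equal(igraph::gsize(ppiGraph(inducedSubgraph(net, LETTERS[1:4]))),
                 3)
    expect_equal(igraph::gsize(ppiGraph(inducedSubgraph(net, "A"))), 0)
    expect_equal(igraph::gsize(ppiGraph(inducedSubgraph(net, c("A", "B")))),
                 1)
    expect_error(inducedSubgraph(net, "ZZ"), "not in network")
})

test_that("handshake lemma converts printed degrees to edge counts", {
    tab <- read.delim(system.file("extdata", "key_target_centrality.tsv",
                                  package = "HerbNetPharm"))
    expect_equal(edgeCountFromDegrees(tab$degree), 308L)
    expect_error(edgeCountFromDegrees(c(1, 2)), "odd degree sum")
    expect_error(edgeCountFromDegrees(c(-1, 1)), "non-negative")
})

test_that("planted hubs are recovered by the dual screen", {
    recalls <- vapply(1:20, function(s) {
        genes <- sprintf("G%03d", 1:100)
        ppi <- genPPI(genes, nHubs = 10, hubAttach = 0.6, bgDensity = 0.05,
                      nIsolates = 0, scoreRange = c(0.15, 0.99), seed = s)
        net <- buildPPIGraph(ppi$edges, genes, 0.4)
        pruned <- removeIsolates(net)$network
        keys <- screenKeyTargets(centralityMetrics(pruned))
        mean(ppi$hubs %in% keys)
    }, numeric(1))
    expect_gte(mean(recalls), 0.9)
})
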