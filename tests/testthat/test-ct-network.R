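simpleCompounds <- function() {
    cmp <- data.frame(name = c("c1", "c2", "c3"), pubchem_cid = 1:3,
                      mw = 1, ob = 50, dl = 0.5)
    cmp$herbs <- list("EH", "CS", "EH")
    cmp
}

test_that("assembly drops compounds without key-target edges", {
    edges <- data.frame(compound = c(1, 2), target = c("t1", "t9"))
    expect_message(
        net <- assembleCTNetwork(simpleCompounds(), edges, "t1"),
        "2 compound")
    g <- ctGraph(net)
    expect_setequal(igraph::V(g)$name, c("1", "T1"))
    expect_equal(igraph::gsize(g), 1)
    expect_setequal(droppedCompounds(net), c("2", "3"))

    expect_warning(
        empty <- suppressMessages(
            assembleCTNetwork(simpleCompounds(), edges, "t404")),
        "no compound-target edge")
    expect_equal(igraph::gorder(ctGraph(empty)), 0)
    expect_equal(sharedKeyTargets(empty), character(0))
})

test_that("shared key targets require compounds of both herbs", {
    edges <- data.frame(compound = c(1, 2, 3), target = c("t1", "t1", "t2"))
    net <- suppressMessages(
        assembleCTNetwork(simpleCompounds(), edges, c("t1", "t2")))
    expect_equal(sharedKeyTargets(net), "T1")

    onlyEH <- simpleCompounds()[c(1, 3), ]
    net2 <- suppressMessages(
        assembleCTNetwork(onlyEH, edges, c("t1", "t2")))
    expect_equal(sharedKeyTargets(net2), character(0))
})

test_that("shared compounds count as evidence for both herbs", {
    cmp <- data.frame(name = "shared", pubchem_cid = 5, mw = 1,
                      ob = 50, dl = 0.5)
    cmp$herbs <- list(c("EH", "CS"))
    net <- assembleCTNetwork(cmp, data.frame(compound = 5, target = "t7"),
                             "t7")
    expect_equal(sharedKeyTargets(net), "T7")
    expect_equal(igraph::V(ctGraph(net))$herbClass[1], "shared")
})

test_that("bipartiteness and attributes survive a GraphML round-trip", {
    edges <- data.frame(compound = c(1, 2, 3), target = c("t1", "t1", "t2"))
    net <- suppressMessages(
        assembleCTNetwork(simpleCompounds(), edges, c("t1", "t2"),
                          clusters = c(T1 = 1L, T2 = 2L)))
    f <- withr::local_tempfile(fileext = ".graphml")
    writeNetwork(ctGraph(net), f, "graphml")
    back <- readNetworkGraphml(f)
    expect_setequal(igraph::V(back)$layer,
                    igraph::V(ctGraph(net))$layer)
    el <- igraph::as_edgelist(back)
    lay <- setNames(igraph::V(back)$layer, igraph::V(back)$name)
    expect_true(all(lay[el[, 1]] != lay[el[, 2]]))  # still bipartite
})

test_that("planted dual-herb targets are recovered from the bundle", {
    b <- genBundle(seed = 17)
    net <- buildPPIGraph(b$ppiEdges, truthParams(b$truth)$diseaseOverlap,
                         0.4)
    keys <- screenKeyTargets(centralityMetrics(removeIsolates(net)$network))
    passing <- filterCompounds(b$compounds)
    ct <- suppressMessages(assembleCTNetwork(passing, b$ctEdges, keys))
    expect_true(all(b$truth@plantedSharedTargets %in% sharedKeyTargets(ct)))
})
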