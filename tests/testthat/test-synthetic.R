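test_that("prescription generator honours degenerate settings", {
    only <- genPrescriptions(pairProb = 1, bgProb = 0, seed = 1)
    for (p in only$prescriptions)
        expect_setequal(p, only$plantedPair)

    gen <- genPrescriptions(seed = 8)
    expect_equal(length(gen$prescriptions), 9)
    expect_equal(length(gen$herbs), 17)
    expect_true(all(lengths(gen$prescriptions) >= 2))
    expect_setequal(unique(unlist(gen$prescriptions)), gen$herbs)

    expect_error(genPrescriptions(pairProb = 2), "\\[0, 1\\]")
})

test_that("compound generator plants exactly the decoys below threshold", {
    gen <- genCompounds(failFraction = 0.5, seed = 9)
    tab <- gen$compounds
    expect_equal(nrow(tab), 48)            # 24 passing + 24 decoys
    kept <- filterCompounds(tab)
    expect_setequal(setdiff(tab$pubchem_cid, kept$pubchem_cid), gen$decoys)
    expect_equal(partitionBySource(kept)$counts[["CS&EH"]], 2)

    noShared <- genCompounds(nShared = 0, seed = 1)$compounds
    expect_equal(length(partitionBySource(noShared)$shared), 0)
})

test_that("PPI generator plants exact isolates and above-threshold hubs", {
    genes <- sprintf("G%03d", 1:120)
    ppi <- genPPI(genes, nIsolates = 17, seed = 3)
    net <- buildPPIGraph(ppi$edges, genes, 0.4)
    out <- removeIsolates(net)
    expect_equal(length(out$removed), 17)
    expect_setequal(out$removed, ppi$isolates)
    # some background edges fall below the threshold and exercise filtering
    expect_true(any(ppi$edges$score < 0.4))
    # no edge touches an isolate at any score
    expect_false(any(c(ppi$edges$a, ppi$edges$b) %in% ppi$isolates))
    expect_error(genPPI(genes[1:20], nHubs = 15, nIsolates = 10), "more")
})

test_that("generators are deterministic: same seed, byte-identical files", {
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    b1 <- genBundle(seed = 5, outDir = d1)
    b2 <- genBundle(seed = 5, outDir = d2)
    for (k in names(b1$files)) {
        expect_identical(readLines(b1$files[[k]]), readLines(b2$files[[k]]),
                         label = sprintf("file %s", k))
    }
    b3 <- genBundle(seed = 6)
    expect_false(identical(b1$ctEdges, b3$ctEdges))
})

test_that("the bundle truth is sufficient to score recovery", {
    b <- genBundle(seed = 21)
    tr <- b$truth
    expect_equal(length(tr@plantedHubs), 10)
    expect_equal(length(tr@plantedIsolates), 17)
    expect_equal(length(tr@plantedSharedTargets), 3)
    expect_true(tr@nestedSubset)
    expect_true(all(tr@plantedSharedTargets %in% tr@plantedHubs))
    p <- truthParams(tr)
    expect_equal(length(p$diseaseOverlap), p$overlapK)
    expect_true(all(tr@plantedIsolates %in% p$diseaseOverlap))
    # planted term is a real term of the annotation collection
    expect_true(tr@plantedEnrichedTerm %in% setIds(b$annotations))
})

test_that("annotation generator plants a term inside the largest cluster", {
    cl <- setNames(rep(1:3, times = c(8, 5, 4)), sprintf("K%02d", 1:17))
    ann <- genAnnotations(cl, genes = sprintf("K%02d", 1:17), seed = 2)
    expect_equal(ann$plantedCluster, 1L)
    planted <- geneSets(ann$db)[[ann$plantedTerm]]
    expect_true(all(planted %in% names(cl)[cl == 1]))
    expect_equal(length(ann$db), 4 * 15 + 1)
    expect_true(validObject(ann$db))
})
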