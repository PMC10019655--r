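ehCsTable <- function()
    readCompoundTable(system.file("extdata", "eh_cs_compounds.tsv",
                                  package = "HerbNetPharm"))

test_that("OB/DL filter is inclusive at the thresholds", {
    tab <- ehCsTable()
    expect_equal(nrow(filterCompounds(tab)), 24)   # all printed rows pass

    edge <- data.frame(name = c("x", "y", "z"), pubchem_cid = 1:3,
                       mw = 300, ob = c(30.0, 29.99, 80),
                       dl = c(0.18, 0.5, 0.17))
    edge$herbs <- list("EH", "EH", "CS")
    kept <- filterCompounds(edge)
    expect_equal(kept$name, "x")  # boundary retained, below-threshold not
})

test_that("filter is monotone in both thresholds", {
    tab <- ehCsTable()
    set.seed(1)
    for (i in 1:20) {
        ob1 <- runif(1, 0, 60); ob2 <- ob1 + runif(1, 0, 20)
        dl1 <- runif(1, 0, 0.5); dl2 <- dl1 + runif(1, 0, 0.3)
        loose <- filterCompounds(tab, ob1, dl1)
        tight <- filterCompounds(tab, ob2, dl2)
        expect_true(all(tight$pubchem_cid %in% loose$pubchem_cid))
    }
})

test_that("source-herb partition reproduces the printed Venn blocks", {
    part <- partitionBySource(filterCompounds(ehCsTable()))
    expect_equal(part$counts[["EH"]], 15)
    expect_equal(part$counts[["CS"]], 7)
    expect_equal(part$counts[["CS&EH"]], 2)
    expect_equal(sum(part$counts), 24)
    # blocks are pairwise disjoint and exhaustive
    all_cids <- unlist(part$blocks)
    expect_equal(length(all_cids), length(unique(all_cids)))
})

test_that("partition handles singletons, triples and duplicate CIDs", {
    one <- data.frame(name = "a", pubchem_cid = 1, mw = 1, ob = 50, dl = 0.5)
    one$herbs <- list("X")
    p1 <- partitionBySource(one)
    expect_equal(p1$counts, c(X = 1L))
    expect_equal(length(p1$shared), 0)

    tri <- data.frame(name = "t", pubchem_cid = 9, mw = 1, ob = 50, dl = 0.5)
    tri$herbs <- list(c("X", "Y", "Z"))
    expect_equal(names(partitionBySource(tri)$shared), "X&Y&Z")

    # stigmasterol-style duplicate: one CID listed once per herb
    dup <- data.frame(name = c("s", "s"), pubchem_cid = c(7, 7),
                      mw = 1, ob = 50, dl = 0.5)
    dup$herbs <- list("EH", "CS")
    expect_equal(names(partitionBySource(dup)$blocks), "CS&EH")
})

test_that("filtering commutes with partitioning", {
    gen <- genCompounds(failFraction = 0.4, seed = 11)
    tab <- gen$compounds
    a <- partitionBySource(filterCompounds(tab))
    whole <- partitionBySource(tab)
    for (key in names(a$blocks)) {
        inBlock <- tab[tab$pubchem_cid %in% whole$blocks[[key]], ]
        expect_setequal(a$blocks[[key]],
                        filterCompounds(inBlock)$pubchem_cid)
    }
})
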