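test_that("incidence construction follows the binary-matrix contract", {
    inc <- buildIncidence(list(P1 = c("A", "B"), P2 = c("B", "C")))
    m <- incidenceMatrix(inc)
    expect_equal(rownames(m), c("A", "B", "C"))
    expect_equal(unname(m["B", ]), c(1L, 1L))
    expect_equal(unname(m["A", ]), c(1L, 0L))

    single <- buildIncidence(list(P1 = c("A", "B")))
    expect_equal(dim(incidenceMatrix(single)), c(2L, 1L))
    expect_true(all(incidenceMatrix(single) == 1L))

    expect_error(buildIncidence(list(P1 = c("A", "B"), P2 = "A")), "P2")
})

test_that("one-mode projection equals brute-force pair counting", {
    m <- matrix(c(1, 1, 0,
                  0, 1, 1,
                  0, 0, 1), 3, 3, byrow = TRUE,
                dimnames = list(c("A", "B", "C"), c("P1", "P2", "P3")))
    inc <- new("HerbIncidence", mat = m)
    co <- projectComembership(inc)
    expect_equal(co["A", "B"], 1L)
    expect_equal(co["A", "C"], 0L)
    expect_equal(unname(diag(co)), c(2L, 2L, 1L))

    for (s in 1:5) {
        set.seed(s)
        r <- matrix(rbinom(60, 1, 0.4), 10, 6,
                    dimnames = list(paste0("H", 1:10), paste0("P", 1:6)))
        r[rowSums(r) == 0, 1] <- 1L
        storage.mode(r) <- "integer"
        inc <- new("HerbIncidence", mat = r)
        co <- projectComembership(inc)
        expect_equal(unclass(co)[, ], oracleComembership(r)[, ],
                     ignore_attr = TRUE)
        # co-occurrence can never exceed either herb's frequency
        freq <- rowSums(r)
        expect_true(all(co <= pmin(outer(freq, freq, pmin),
                                   matrix(Inf, 10, 10))))
    }
})

test_that("Jaccard uses presence sets only and stays in [0, 1]", {
    inc <- buildIncidence(list(P1 = c("A", "X"), P2 = c("A", "B"),
                               P3 = c("B", "X")))
    j <- jaccardMatrix(inc)
    expect_equal(j["A", "B"], 1 / 3)       # {1,2} vs {2,3}
    expect_equal(unname(diag(j)), rep(1, 3))
    expect_true(all(j >= 0 & j <= 1))
    expect_equal(j, t(j))

    # consistently co-absent herbs gain no similarity from co-absence
    many <- c(list(PA = c("R1", "Z"), PB = c("R2", "Z")),
              setNames(replicate(6, c("Z", "Y"), simplify = FALSE),
                       paste0("P", 1:6)))
    j2 <- jaccardMatrix(buildIncidence(many))
    expect_equal(j2["R1", "R2"], 0)
})

test_that("Pearson matrix handles identical, complementary and flat rows", {
    inc <- buildIncidence(list(P1 = c("A", "B"), P2 = c("C", "Z"),
                               P3 = c("A", "B", "Z")))
    r <- suppressWarnings(pearsonMatrix(inc))
    expect_equal(r["A", "B"], 1)           # identical profiles
    expect_equal(r["A", "C"], -1)          # complementary (1,0,1)/(0,1,0)

    ubiq <- buildIncidence(list(P1 = c("U", "A"), P2 = c("U", "B")))
    expect_warning(r2 <- pearsonMatrix(ubiq), "zero-variance")
    expect_equal(unname(r2["U", ]), rep(0, 3))

    one <- buildIncidence(list(P1 = c("A", "B")))
    expect_error(pearsonMatrix(one), "single prescription")
})

test_that("heatmap ordering is a permutation of the labels", {
    inc <- buildIncidence(list(P1 = c("A", "B"), P2 = c("B", "C"),
                               P3 = c("C", "D"), P4 = c("A", "B")))
    r <- suppressWarnings(pearsonMatrix(inc))
    ord <- orderForHeatmap(r)
    expect_setequal(ord, rownames(r))
    expect_equal(length(ord), nrow(r))
})

test_that("herb network carries degrees, frequencies and Jaccard weights", {
    inc <- buildIncidence(list(P1 = c("A", "B"), P2 = c("B", "C")))
    g <- herbNetwork(projectComembership(inc), jaccardMatrix(inc))
    expect_setequal(igraph::as_edgelist(g)[, 1], c("A", "B"))
    expect_equal(igraph::degree(g)["B"], c(B = 2))
    expect_equal(igraph::V(g)$frequency[igraph::V(g)$name == "B"], 2)

    f <- withr::local_tempfile(fileext = ".graphml")
    writeNetwork(g, f, "graphml")
    back <- readNetworkGraphml(f)
    expect_equal(sort(igraph::E(back)$weight), sort(igraph::E(g)$weight))

    expect_error(herbNetwork(projectComembership(inc),
                             jaccardMatrix(inc)[c(2, 1, 3), c(2, 1, 3)]),
                 "labels")
})

test_that("a planted dominant pair tops the co-occurrence ranking", {
    gen <- genPrescriptions(seed = 42)
    inc <- buildIncidence(gen$prescriptions)
    expect_equal(dim(incidenceMatrix(inc)), c(17L, 9L))
    co <- projectComembership(inc)
    diag(co) <- 0L
    expect_equal(co[gen$plantedPair[1], gen$plantedPair[2]], max(co))
})
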