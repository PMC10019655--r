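# herb codes used when emulating a 17-herb anti-obesity prescription corpus;
# the studied pair comes first
.herbCodePool <- c("EH", "CS", "AS", "ZR", "GF", "MH", "CR", "AGR", "PAR",
                   "AR", "GR", "SF", "CAS", "LT", "ACR", "PLR", "RS")

.herbCodes <- function(nHerbs) {
    if (nHerbs <= length(.herbCodePool)) .herbCodePool[seq_len(nHerbs)]
    else c(.herbCodePool,
           sprintf("H%02d", seq_len(nHerbs - length(.herbCodePool))))
}

#' Generate prescriptions with a planted dominant herb pair
#'
#' Emulates a small corpus of multi-herb prescriptions: the two designated
#' herbs (the planted pair, first two codes) co-occur in each prescription
#' with probability `pairProb`; every other herb is included independently
#' with probability `bgProb`. Prescriptions with fewer than two herbs are
#' re-drawn, and any herb that ends up in no prescription is inserted into
#' one random prescription so the herb legend has exactly `nHerbs` entries.
#'
#' @param nPresc number of prescriptions (default 9).
#' @param nHerbs number of herbs, at least 4 (default 17).
#' @param pairProb probability the planted pair co-occurs (default 0.8).
#' @param bgProb background inclusion probability (default 0.25).
#' @param seed integer seed.
#' @return list with `prescriptions` (named list of herb-code vectors),
#'   `herbs` (all codes) and `plantedPair` (character(2)).
#' @export
genPrescriptions <- function(nPresc = 9, nHerbs = 17, pairProb = 0.8,
                             bgProb = 0.25, seed = 1) {
    stopifnot(nHerbs >= 4, nPresc >= 1)
    if (pairProb < 0 || pairProb > 1 || bgProb < 0 || bgProb > 1)
        stop("pairProb and bgProb must lie in [0, 1]")
    herbs <- .herbCodes(nHerbs)
    pair <- herbs[1:2]
    bg <- herbs[-(1:2)]
    .withSeed(seed, {
        draw <- function() {
            repeat {
                inPair <- stats::runif(1) < pairProb
                sel <- c(if (inPair) pair
                         else pair[stats::runif(2) < bgProb],
                         bg[stats::runif(length(bg)) < bgProb])
                if (length(sel) >= 2) return(sel)
            }
        }
        presc <- replicate(nPresc, draw(), simplify = FALSE)
        names(presc) <- sprintf("P%d", seq_len(nPresc))
        if (bgProb > 0) {  # coverage repair: every samplable herb appears
            unused <- setdiff(herbs, unlist(presc))
            for (h in unused) {
                j <- sample.int(nPresc, 1)
                presc[[j]] <- c(presc[[j]], h)
            }
        }
        list(prescriptions = presc, herbs = herbs, plantedPair = pair)
    })
}

#' Generate an ADME compound table with known pass/fail structure
#'
#' Draws passing compounds with `ob ~ U(obRange)` and `dl ~ U(dlRange)`
#' (defaults start exactly at the screening cutoffs 30 and 0.18, so all pass)
#' split into herb-A-only, herb-B-only and shared blocks, plus decoys built
#' to fail at least one threshold. The decoy count is chosen so that a
#' fraction `failFraction` of the final table fails the filter.
#'
#' @param nEH,nCS,nShared passing compounds exclusive to the first herb,
#'   exclusive to the second, and shared (defaults 15, 7, 2).
#' @param obRange,dlRange sampling ranges for passing compounds.
#' @param failFraction fraction of the output table that should fail the
#'   screen (default 0).
#' @param herbA,herbB source-herb codes (defaults `"EH"`, `"CS"`).
#' @param obMin,dlMin thresholds the decoys must fail (defaults 30, 0.18).
#' @param seed integer seed.
#' @return list with `compounds` (data.frame as from [readCompoundTable()])
#'   and `decoys` (pubchem_cids of planted failures).
#' @export
genCompounds <- function(nEH = 15, nCS = 7, nShared = 2,
                         obRange = c(30, 80), dlRange = c(0.18, 0.8),
                         failFraction = 0, herbA = "EH", herbB = "CS",
                         obMin = 30, dlMin = 0.18, seed = 1) {
    stopifnot(nEH >= 0, nCS >= 0, nShared >= 0,
              failFraction >= 0, failFraction < 1)
    nPass <- nEH + nCS + nShared
    nDecoy <- round(failFraction / (1 - failFraction) * nPass)
    .withSeed(seed, {
        n <- nPass + nDecoy
        herbs <- c(rep(list(herbA), nEH), rep(list(herbB), nCS),
                   rep(list(c(herbA, herbB)), nShared),
                   lapply(seq_len(nDecoy),
                          function(i) sample(c(herbA, herbB), 1)))
        ob <- c(stats::runif(nPass, obRange[1], obRange[2]), numeric(nDecoy))
        dl <- c(stats::runif(nPass, dlRange[1], dlRange[2]), numeric(nDecoy))
        if (nDecoy > 0) {
            mode <- sample(c("ob", "dl", "both"), nDecoy, replace = TRUE)
            failOb <- mode %in% c("ob", "both")
            failDl <- mode %in% c("dl", "both")
            i <- nPass + seq_len(nDecoy)
            ob[i] <- ifelse(failOb, stats::runif(nDecoy, 0, obMin * 0.999),
                            stats::runif(nDecoy, obRange[1], obRange[2]))
            dl[i] <- ifelse(failDl, stats::runif(nDecoy, 0, dlMin * 0.999),
                            stats::runif(nDecoy, dlRange[1], dlRange[2]))
        }
        cids <- 90000000 + sample.int(999999, n)
        df <- data.frame(name = sprintf("synthetic compound %03d",
                                        seq_len(n)),
                         pubchem_cid = cids,
                         mw = round(stats::runif(n, 250, 600), 2),
                         ob = round(ob, 2), dl = round(dl, 3),
                         stringsAsFactors = FALSE)
        df$herbs <- herbs
        ord <- sample.int(n)  # shuffle so decoys are not positional
        df <- df[ord, , drop = FALSE]
        rownames(df) <- NULL
        list(compounds = df, decoys = cids[nPass + seq_len(nDecoy)])
    })
}

#' Generate compound-target edges with nested and dual-herb structure
#'
#' Builds a synthetic compound-to-target edge list over a universe of
#' `nTargets` genes. The second herb's target set (`nCSTargets` genes)
#' contains the `nDualHerbTargets` designated dual-herb targets and, when
#' `nestedSubset = TRUE`, is a strict subset of the first herb's targets
#' (every target also receives an edge from a first-herb compound). Shared
#' compounds target only the dual-herb genes, and each dual-herb gene is
#' wired to at least one exclusive compound of each herb, so the dual-herb
#' targets are exactly the targets attributed to both herbs among any
#' key-target restriction that contains them.
#'
#' @param compounds compound data.frame (the screened set).
#' @param nTargets size of the target gene universe (default 223).
#' @param nCSTargets size of the second herb's target set (default 31).
#' @param targetsPerCompound integer range of targets drawn per first-herb
#'   compound (default `c(8, 25)`).
#' @param csTargetsPerCompound same for second-herb compounds
#'   (default `c(3, 8)`).
#' @param nDualHerbTargets number of designated dual-herb targets
#'   (default 3).
#' @param nestedSubset plant the second herb's targets inside the first's
#'   (default TRUE).
#' @param herbA,herbB herb codes (defaults `"EH"`, `"CS"`).
#' @param seed integer seed.
#' @return list with `edges` (data.frame `compound`, `target`), `targets`
#'   (the universe), `csTargets` and `dualTargets`.
#' @export
genCTEdges <- function(compounds, nTargets = 223, nCSTargets = 31,
                       targetsPerCompound = c(8, 25),
                       csTargetsPerCompound = c(3, 8),
                       nDualHerbTargets = 3, nestedSubset = TRUE,
                       herbA = "EH", herbB = "CS", seed = 1) {
    stopifnot(nDualHerbTargets <= nCSTargets, nCSTargets <= nTargets)
    universe <- sprintf("T%03d", seq_len(nTargets))
    dual <- universe[seq_len(nDualHerbTargets)]
    csPool <- universe[seq_len(nCSTargets)]
    nReserved <- if (nestedSubset) 0L else min(5L, nTargets - nCSTargets)
    ehPool <- if (nestedSubset) universe
              else universe[seq_len(nTargets - nReserved)]
    if (!nestedSubset) {  # give the second herb a few private targets
        priv <- universe[nTargets - seq_len(nReserved) + 1L]
        csPool <- c(csPool[seq_len(nCSTargets - length(priv))], priv)
    }
    isA <- vapply(compounds$herbs, function(h) herbA %in% h, logical(1))
    isB <- vapply(compounds$herbs, function(h) herbB %in% h, logical(1))
    aOnly <- compounds$pubchem_cid[isA & !isB]
    bOnly <- compounds$pubchem_cid[isB & !isA]
    sharedC <- compounds$pubchem_cid[isA & isB]
    .withSeed(seed, {
        per <- function(rng) sample(seq(rng[1], rng[2]), 1)
        pick1 <- function(x) x[sample.int(length(x), 1)]  # safe for length 1
        edges <- list()
        for (c in aOnly)
            edges[[length(edges) + 1L]] <- data.frame(
                compound = c,
                target = sample(ehPool, min(per(targetsPerCompound),
                                            length(ehPool))))
        for (c in bOnly)
            edges[[length(edges) + 1L]] <- data.frame(
                compound = c,
                target = sample(csPool, min(per(csTargetsPerCompound),
                                            length(csPool))))
        for (c in sharedC)
            edges[[length(edges) + 1L]] <- data.frame(
                compound = c,
                target = sample(dual, min(per(c(1, length(dual))),
                                          length(dual))))
        ed <- do.call(rbind, edges)
        # dual-herb guarantee: each dual target touched by both herbs'
        # exclusive compounds
        for (t in dual) {
            if (length(aOnly))
                ed <- rbind(ed, data.frame(compound = pick1(aOnly),
                                           target = t))
            if (length(bOnly))
                ed <- rbind(ed, data.frame(compound = pick1(bOnly),
                                           target = t))
        }
        # coverage: every second-herb target is reachable from herb B
        missB <- setdiff(csPool, ed$target[ed$compound %in% c(bOnly, sharedC)])
        for (t in missB)
            ed <- rbind(ed, data.frame(compound = pick1(c(bOnly, sharedC)),
                                       target = t))
        # nesting/coverage: every universe target reachable from herb A
        aSide <- c(aOnly, sharedC)
        covA <- if (nestedSubset) universe else ehPool
        missA <- setdiff(covA, ed$target[ed$compound %in% aSide])
        # shared compounds only target dual genes, so top up via aOnly
        for (t in missA)
            ed <- rbind(ed, data.frame(compound = pick1(aOnly),
                                       target = t))
        ed <- unique(ed)
        ed <- ed[order(ed$compound, ed$target), , drop = FALSE]
        rownames(ed) <- NULL
        list(edges = ed, targets = universe, csTargets = sort(csPool),
             dualTargets = dual)
    })
}

#' Generate a disease gene list with a controlled target overlap
#'
#' Builds a disease-associated gene list that overlaps the target universe
#' in exactly `overlapK` genes (forced to contain `include` and to avoid
#' `exclude`) plus `nExtra` disease-only genes.
#'
#' @param targetUniverse character vector of target symbols.
#' @param overlapK exact overlap size (default 152).
#' @param nExtra disease genes outside the target universe (default 2047).
#' @param include genes that must be part of the overlap.
#' @param exclude target genes that must not be part of the overlap.
#' @param seed integer seed.
#' @return list with `genes` (the disease list) and `overlap` (the planted
#'   overlap, sorted).
#' @export
genDiseaseSet <- function(targetUniverse, overlapK = 152, nExtra = 2047,
                          include = character(0), exclude = character(0),
                          seed = 1) {
    pool <- setdiff(targetUniverse, union(include, exclude))
    if (overlapK > length(pool) + length(include))
        stop("overlapK larger than the eligible target universe")
    if (overlapK < length(include))
        stop("overlapK smaller than the forced include set")
    .withSeed(seed, {
        overlap <- sort(c(include,
                          sample(pool, overlapK - length(include))))
        extra <- sprintf("DIS%04d", seq_len(nExtra))
        list(genes = sample(c(overlap, extra)), overlap = overlap)
    })
}

#' Generate a scored PPI edge list with planted hubs and isolates
#'
#' Wires `nHubs` designated hub genes to a random fraction `hubAttach` of
#' the other non-isolate nodes with scores at or above the inclusion
#' threshold, adds background edges between non-hub pairs at density
#' `bgDensity` scored across `scoreRange` (so a controlled share falls below
#' the threshold and exercises score filtering), and leaves `nIsolates`
#' genes without any edge. Any non-isolate node whose sampled edges all fell
#' below the threshold is repaired with one above-threshold edge to a random
#' hub, so the planted isolates are exactly the post-filter isolates.
#'
#' @param genes gene universe for the network.
#' @param nHubs number of hubs (default 10).
#' @param hubAttach hub attachment probability (default 0.6).
#' @param bgDensity background edge density (default 0.05).
#' @param nIsolates number of planted isolates (default 17).
#' @param scoreRange background score range (default `c(0.15, 0.99)`).
#' @param threshold inclusion threshold hub edges must clear (default 0.4).
#' @param hubs,isolates optional explicit gene choices; sampled otherwise.
#' @param seed integer seed.
#' @return list with `edges` (data.frame `a`, `b`, `score`), `hubs`,
#'   `isolates`.
#' @export
genPPI <- function(genes, nHubs = 10, hubAttach = 0.6, bgDensity = 0.05,
                   nIsolates = 17, scoreRange = c(0.15, 0.99),
                   threshold = 0.4, hubs = NULL, isolates = NULL, seed = 1) {
    genes <- unique(genes)
    if (hubAttach < 0 || hubAttach > 1 || bgDensity < 0 || bgDensity > 1)
        stop("hubAttach and bgDensity must lie in [0, 1]")
    if (nHubs + nIsolates > length(genes))
        stop("more hubs plus isolates than genes")
    .withSeed(seed, {
        if (is.null(hubs)) hubs <- sample(genes, nHubs)
        if (is.null(isolates))
            isolates <- sample(setdiff(genes, hubs), nIsolates)
        stopifnot(!length(intersect(hubs, isolates)))
        active <- setdiff(genes, isolates)
        nonhub <- setdiff(active, hubs)
        hubLo <- max(threshold, scoreRange[1])
        ed <- list()
        for (h in hubs) {
            others <- setdiff(active, h)
            sel <- others[stats::runif(length(others)) < hubAttach]
            if (length(sel))
                ed[[length(ed) + 1L]] <- data.frame(
                    a = h, b = sel,
                    score = stats::runif(length(sel), hubLo, scoreRange[2]))
        }
        if (length(nonhub) >= 2) {
            pairs <- utils::combn(nonhub, 2)
            keep <- stats::runif(ncol(pairs)) < bgDensity
            if (any(keep))
                ed[[length(ed) + 1L]] <- data.frame(
                    a = pairs[1, keep], b = pairs[2, keep],
                    score = stats::runif(sum(keep), scoreRange[1],
                                         scoreRange[2]))
        }
        edges <- do.call(rbind, ed)
        if (is.null(edges))
            edges <- data.frame(a = character(), b = character(),
                                score = numeric())
        # repair: keep every active node connected above the threshold
        strong <- edges[edges$score >= threshold, , drop = FALSE]
        uncovered <- setdiff(active, c(strong$a, strong$b))
        for (v in uncovered)
            edges <- rbind(edges, data.frame(
                a = v, b = sample(setdiff(hubs, v), 1),
                score = stats::runif(1, hubLo, scoreRange[2])))
        swap <- edges$a > edges$b
        tmp <- edges$a[swap]; edges$a[swap] <- edges$b[swap]
        edges$b[swap] <- tmp
        edges <- edges[!duplicated(edges[, c("a", "b")]), , drop = FALSE]
        edges <- edges[order(edges$a, edges$b), , drop = FALSE]
        rownames(edges) <- NULL
        list(edges = edges, hubs = sort(hubs), isolates = sort(isolates))
    })
}

#' Generate annotation gene sets with one planted enriched term
#'
#' Plants a single term as a strict subset of a designated cluster (the
#' largest) and surrounds it with noise terms of the same size drawn
#' uniformly from the gene universe, `nNoiseTerms` per category across
#' KEGG, BP, CC and MF.
#'
#' @param clusters named integer vector (gene -> cluster id) from
#'   [spectralKmeans()].
#' @param genes gene universe noise terms are drawn from.
#' @param termSize genes per term (default 5).
#' @param nNoiseTerms noise terms per category (default 15).
#' @param plantCategory category of the planted term (default `"BP"`).
#' @param seed integer seed.
#' @return list with `db` (a [GeneSetDb-class]), `plantedTerm` (its id) and
#'   `plantedCluster` (the designated cluster id).
#' @export
genAnnotations <- function(clusters, genes, termSize = 5, nNoiseTerms = 15,
                           plantCategory = "BP", seed = 1) {
    sizes <- table(clusters)
    target <- as.integer(names(sizes)[which.max(sizes)])
    members <- names(clusters)[clusters == target]
    sz <- min(termSize, length(members))
    cats <- c("KEGG", "BP", "CC", "MF")
    .withSeed(seed, {
        planted <- sample(members, sz)
        ids <- character(0); nms <- character(0); cc <- character(0)
        sets <- list()
        for (cat in cats) {
            for (i in seq_len(nNoiseTerms)) {
                ids <- c(ids, sprintf("%s%03d", cat, i))
                nms <- c(nms, sprintf("synthetic %s term %d", cat, i))
                cc <- c(cc, cat)
                sets[[length(sets) + 1L]] <- sample(genes,
                                                    min(termSize,
                                                        length(genes)))
            }
        }
        pid <- sprintf("%s%03d", plantCategory, nNoiseTerms + 1L)
        ids <- c(ids, pid)
        nms <- c(nms, "planted cluster term")
        cc <- c(cc, plantCategory)
        sets[[length(sets) + 1L]] <- planted
        list(db = GeneSetDb(ids, sets, names = nms, categories = cc),
             plantedTerm = pid, plantedCluster = target)
    })
}

#' Generate a complete synthetic input bundle
#'
#' Runs every generator with sub-seeds derived from one master seed and
#' returns (optionally writes) a coherent pipeline input set: prescriptions,
#' an ADME compound table, compound-target edges, a disease gene list, a
#' scored PPI edge list (written on the STRING 0-1000 integer scale) and a
#' GMT annotation collection — together with the [SyntheticTruth-class]
#' recording all planted structure. Defaults mirror the magnitudes of a
#' published two-herb anti-obesity case: 9 prescriptions over 17 herbs,
#' 15/7/2 compounds, a 223-gene target universe with a 31-gene nested
#' second-herb set, a 2199-gene disease list overlapping 152 targets,
#' 10 hubs, 17 isolates, 3 dual-herb key targets and k = 3 clusters.
#'
#' @param seed master seed; all randomness flows from it.
#' @param outDir if non-NULL, write all input files plus `truth.json` here.
#' @param nPresc,nHerbs,pairProb,bgProb see [genPrescriptions()].
#' @param nEH,nCS,nShared,failFraction see [genCompounds()].
#' @param nTargets,nCSTargets,nDualHerbTargets,nestedSubset see
#'   [genCTEdges()].
#' @param overlapK,nExtraDisease see [genDiseaseSet()].
#' @param nHubs,hubAttach,bgDensity,nIsolates,scoreRange see [genPPI()].
#' @param termSize,nNoiseTerms see [genAnnotations()].
#' @param kClusters clusters for the planted-annotation step (default 3).
#' @return list with elements `prescriptions`, `compounds`, `ctEdges`,
#'   `diseaseGenes`, `ppiEdges`, `annotations`, `truth` and, when written,
#'   `files` (named vector of paths).
#' @export
genBundle <- function(seed = 1, outDir = NULL,
                      nPresc = 9, nHerbs = 17, pairProb = 0.8, bgProb = 0.25,
                      nEH = 15, nCS = 7, nShared = 2, failFraction = 0,
                      nTargets = 223, nCSTargets = 31, nDualHerbTargets = 3,
                      nestedSubset = TRUE, overlapK = 152,
                      nExtraDisease = 2047, nHubs = 10, hubAttach = 0.6,
                      bgDensity = 0.05, nIsolates = 17,
                      scoreRange = c(0.15, 0.99), termSize = 5,
                      nNoiseTerms = 15, kClusters = 3) {
    ss <- vapply(1:7, function(i) .subSeed(seed, i), integer(1))
    pres <- genPrescriptions(nPresc, nHerbs, pairProb, bgProb, seed = ss[1])
    cmp <- genCompounds(nEH, nCS, nShared, failFraction = failFraction,
                        seed = ss[2])
    passing <- filterCompounds(cmp$compounds)
    ct <- genCTEdges(passing, nTargets, nCSTargets,
                     nDualHerbTargets = nDualHerbTargets,
                     nestedSubset = nestedSubset, seed = ss[3])
    dis <- genDiseaseSet(ct$targets, overlapK, nExtraDisease,
                         include = ct$dualTargets,
                         exclude = setdiff(ct$csTargets, ct$dualTargets),
                         seed = ss[4])
    hubPool <- setdiff(dis$overlap, ct$dualTargets)
    hubs <- .withSeed(ss[5], c(ct$dualTargets,
                               sample(hubPool, nHubs - nDualHerbTargets)))
    isolates <- .withSeed(.subSeed(seed, 8),
                          sample(setdiff(dis$overlap, hubs), nIsolates))
    ppi <- genPPI(dis$overlap, nHubs, hubAttach, bgDensity, nIsolates,
                  scoreRange, hubs = hubs, isolates = isolates, seed = ss[6])
    # plant the enriched term inside a k-means cluster of the key subnetwork
    net <- buildPPIGraph(ppi$edges, dis$overlap, 0.4)
    pruned <- removeIsolates(net)
    keys <- screenKeyTargets(centralityMetrics(pruned$network))
    clusters <- spectralKmeans(inducedSubgraph(pruned$network, keys),
                               k = kClusters, seed = ss[7])
    active <- setdiff(dis$overlap, ppi$isolates)
    ann <- genAnnotations(clusters, active, termSize, nNoiseTerms,
                          seed = ss[7])
    truth <- new("SyntheticTruth", plantedPair = pres$plantedPair,
                 plantedHubs = ppi$hubs, plantedIsolates = ppi$isolates,
                 plantedSharedTargets = ct$dualTargets,
                 plantedEnrichedTerm = ann$plantedTerm,
                 nestedSubset = nestedSubset,
                 params = list(nPresc = nPresc, nHerbs = nHerbs,
                               pairProb = pairProb, bgProb = bgProb,
                               nEH = nEH, nCS = nCS, nShared = nShared,
                               failFraction = failFraction,
                               nTargets = nTargets, nCSTargets = nCSTargets,
                               nDualHerbTargets = nDualHerbTargets,
                               overlapK = overlapK,
                               nExtraDisease = nExtraDisease, nHubs = nHubs,
                               hubAttach = hubAttach, bgDensity = bgDensity,
                               nIsolates = nIsolates,
                               scoreRange = scoreRange, termSize = termSize,
                               nNoiseTerms = nNoiseTerms,
                               kClusters = kClusters, subSeeds = ss,
                               csTargets = ct$csTargets,
                               diseaseOverlap = dis$overlap,
                               decoys = cmp$decoys),
                 seed = seed)
    out <- list(prescriptions = pres$prescriptions,
                compounds = cmp$compounds, ctEdges = ct$edges,
                diseaseGenes = dis$genes, ppiEdges = ppi$edges,
                annotations = ann$db, truth = truth)
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        f <- c(prescriptions = file.path(outDir, "prescriptions.tsv"),
               compounds = file.path(outDir, "compounds.tsv"),
               ctEdges = file.path(outDir, "ct_edges.tsv"),
               disease = file.path(outDir, "disease_genes.txt"),
               ppi = file.path(outDir, "ppi_edges.tsv"),
               annotations = file.path(outDir, "annotations.gmt"),
               truth = file.path(outDir, "truth.json"))
        long <- data.frame(
            prescription = rep(names(pres$prescriptions),
                               lengths(pres$prescriptions)),
            herb = unlist(pres$prescriptions))
        utils::write.table(long, f["prescriptions"], sep = "\t",
                           quote = FALSE, row.names = FALSE)
        writeCompoundTable(cmp$compounds, f["compounds"])
        utils::write.table(ct$edges, f["ctEdges"], sep = "\t", quote = FALSE,
                           row.names = FALSE)
        writeLines(dis$genes, f["disease"])
        string <- data.frame(protein1 = ppi$edges$a, protein2 = ppi$edges$b,
                             combined_score = as.integer(
                                 round(ppi$edges$score * 1000)))
        utils::write.table(string, f["ppi"], sep = "\t", quote = FALSE,
                           row.names = FALSE)
        writeGeneSets(ann$db, f["annotations"])
        jsonlite::write_json(
            list(plantedPair = truth@plantedPair,
                 plantedHubs = truth@plantedHubs,
                 plantedIsolates = truth@plantedIsolates,
                 plantedSharedTargets = truth@plantedSharedTargets,
                 plantedEnrichedTerm = truth@plantedEnrichedTerm,
                 nestedSubset = truth@nestedSubset, seed = truth@seed,
                 params = truth@params),
            f["truth"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
        out$files <- f
    }
    out
}
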