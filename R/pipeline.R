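#' Assemble a pipeline configuration
#'
#' Collects every input path and tunable of the end-to-end analysis with the
#' conventional defaults: ADME cutoffs OB >= 30 percent and DL >= 0.18, PPI
#' inclusion score 0.4, disease-set combination by intersection, k = 3
#' key-target clusters, top 20 enriched terms per category, per-category BH
#' adjustment. The full configuration is serialized into the run report.
#'
#' @param prescriptions path to a prescriptions table
#'   (see [readPrescriptions()]).
#' @param compounds path to a compound table (see [readCompoundTable()]).
#' @param ctEdges path to a compound-target edge TSV (columns `compound`,
#'   `target`).
#' @param diseaseGenes character vector of 1 or 2 disease gene-list paths;
#'   two lists are combined with `diseaseCombineMode`.
#' @param ppiEdges path to a scored PPI edge TSV (see [readPPIEdges()]).
#' @param geneSets path to a GMT annotation file (see [readGeneSets()]).
#' @param outDir output directory for all artifacts.
#' @param obMin,dlMin ADME thresholds (defaults 30, 0.18).
#' @param ppiMinScore PPI inclusion threshold (default 0.4).
#' @param diseaseCombineMode `"intersection"` (default) or `"union"`.
#' @param kClusters number of key-target clusters (default 3).
#' @param topNTerms enriched terms reported per category (default 20).
#' @param bhScope `"per-category"` (default) or `"global"`.
#' @param seed seed for the clustering restarts (default 1).
#' @return a named list of class `pipeline_config`.
#' @export
pipelineConfig <- function(prescriptions, compounds, ctEdges, diseaseGenes,
                           ppiEdges, geneSets, outDir,
                           obMin = 30, dlMin = 0.18, ppiMinScore = 0.4,
                           diseaseCombineMode = "intersection",
                           kClusters = 3, topNTerms = 20,
                           bhScope = "per-category", seed = 1) {
    stopifnot(obMin >= 0, dlMin >= 0, dlMin <= 1,
              ppiMinScore >= 0, ppiMinScore <= 1, kClusters >= 2,
              topNTerms >= 1, length(diseaseGenes) %in% c(1, 2))
    structure(list(prescriptions = prescriptions, compounds = compounds,
                   ctEdges = ctEdges, diseaseGenes = diseaseGenes,
                   ppiEdges = ppiEdges, geneSets = geneSets,
                   outDir = outDir, obMin = obMin, dlMin = dlMin,
                   ppiMinScore = ppiMinScore,
                   diseaseCombineMode = diseaseCombineMode,
                   kClusters = kClusters, topNTerms = topNTerms,
                   bhScope = bhScope, seed = seed),
              class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipelineConfig()]; relative input paths are resolved against the YAML
#'   file's directory.
#' @return a `pipeline_config`.
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    base <- dirname(normalizePath(path))
    resolve <- function(p) ifelse(startsWith(p, "/"), p, file.path(base, p))
    for (k in c("prescriptions", "compounds", "ctEdges", "ppiEdges",
                "geneSets"))
        y[[k]] <- resolve(y[[k]])
    y$diseaseGenes <- resolve(unlist(y$diseaseGenes))
    do.call(pipelineConfig, y)
}

.stage <- function(name, expr) {
    message(sprintf("[%s] running", name))
    tryCatch(expr, error = function(e)
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE))
}

#' Run the full network-pharmacology pipeline
#'
#' Executes all stages in order — herb co-prescription network, ADME
#' compound screen, herb/disease target-set algebra, scored PPI
#' construction with isolate removal and dual-criterion key-target
#' screening, key-subnetwork clustering and over-representation analysis,
#' and compound-target network assembly — writing every intermediate
#' artifact plus a JSON `report.json` of all counts to the configured
#' output directory. The report contains no timestamps, so identical
#' configurations yield byte-identical reports.
#'
#' Screening follows the two-pass convention: key targets are selected with
#' centrality measured on the full isolate-free network, then degree and
#' betweenness are recomputed inside the induced key-target subnetwork for
#' reporting (the form in which published key-target tables are printed,
#' where the degree column sums to twice the subnetwork edge count).
#'
#' @param config a `pipeline_config` from [pipelineConfig()] or
#'   [readPipelineConfig()], or a path to a YAML config.
#' @return the report, invisibly (a named list, also written to
#'   `outDir/report.json`).
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- readPipelineConfig(config)
    stopifnot(inherits(config, "pipeline_config"))
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    art <- function(f) file.path(config$outDir, f)

    ## herb co-prescription network
    herbnet <- .stage("herbnet", {
        presc <- readPrescriptions(config$prescriptions)
        inc <- buildIncidence(presc)
        co <- projectComembership(inc)
        jac <- jaccardMatrix(inc)
        pear <- suppressWarnings(pearsonMatrix(inc))
        g <- herbNetwork(co, jac)
        utils::write.table(incidenceMatrix(inc), art("incidence.tsv"),
                           sep = "\t", quote = FALSE)
        utils::write.table(co, art("cooccurrence.tsv"), sep = "\t",
                           quote = FALSE)
        utils::write.table(round(jac, 6), art("jaccard.tsv"), sep = "\t",
                           quote = FALSE)
        ord <- orderForHeatmap(pear)
        utils::write.table(round(pear[ord, ord], 6),
                           art("pearson_clustered.tsv"), sep = "\t",
                           quote = FALSE)
        writeNetwork(g, art("herb_network.graphml"), "graphml")
        writeNetwork(g, art("herb_network.sif"), "sif")
        codiag <- co; diag(codiag) <- 0L
        top <- which(codiag == max(codiag), arr.ind = TRUE)[1, ]
        list(inc = inc, g = g,
             topPair = sort(rownames(co)[c(top[1], top[2])]),
             topPairCount = max(codiag))
    })

    ## ADME screen and source-herb partition
    adme <- .stage("adme", {
        tab <- readCompoundTable(config$compounds)
        passing <- filterCompounds(tab, config$obMin, config$dlMin)
        part <- partitionBySource(passing)
        writeCompoundTable(passing, art("compounds_filtered.tsv"))
        writeReport(as.list(part$counts), art("venn_compounds.json"))
        list(tab = tab, passing = passing, part = part)
    })

    ## target sets and disease overlap
    targets <- .stage("targets", {
        edges <- utils::read.table(config$ctEdges, header = TRUE,
                                   sep = "\t", stringsAsFactors = FALSE)
        herbs <- sort(unique(unlist(adme$passing$herbs)))
        unions <- lapply(herbs, herbTargetUnion, compounds = adme$passing,
                         edges = edges)
        names(unions) <- herbs
        allTargets <- sort(unique(unlist(unions)))
        disease <- readGeneList(config$diseaseGenes[1])
        if (length(config$diseaseGenes) == 2)
            disease <- combineDiseaseSets(
                disease, readGeneList(config$diseaseGenes[2]),
                config$diseaseCombineMode)
        overlap <- overlapWithDisease(allTargets, disease)
        for (h in herbs)
            writeLines(unions[[h]], art(sprintf("targets_%s.txt", h)))
        writeLines(overlap, art("targets_disease_overlap.txt"))
        list(edges = edges, unions = unions, allTargets = allTargets,
             disease = disease, overlap = overlap)
    })

    ## PPI topology and key-target screening (two-pass)
    ppi <- .stage("ppi", {
        raw <- readPPIEdges(config$ppiEdges)
        net <- buildPPIGraph(raw, targets$overlap, config$ppiMinScore)
        pruned <- removeIsolates(net)
        cm <- centralityMetrics(pruned$network)
        keys <- screenKeyTargets(cm)
        sub <- inducedSubgraph(pruned$network, keys)
        cmSub <- centralityMetrics(sub)
        utils::write.table(cm, art("centrality_full.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        utils::write.table(cmSub, art("centrality_subnetwork.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        writeLines(keys, art("key_targets.txt"))
        writeNetwork(ppiGraph(sub), art("key_subnetwork.graphml"), "graphml")
        writeNetwork(ppiGraph(sub), art("key_subnetwork.sif"), "sif",
                     interaction = "pp")
        list(net = net, pruned = pruned$network, removed = pruned$removed,
             cm = cm, keys = keys, sub = sub, cmSub = cmSub)
    })

    ## clustering and enrichment of key targets
    enrich <- .stage("enrich", {
        clusters <- spectralKmeans(ppi$sub, k = config$kClusters,
                                   seed = config$seed)
        db <- readGeneSets(config$geneSets)
        rows <- hypergeomEnrich(ppi$keys, db, bhScope = config$bhScope)
        top <- topTerms(rows, config$topNTerms, byCategory = TRUE)
        utils::write.table(
            data.frame(gene = names(clusters), cluster = unname(clusters)),
            art("clusters.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
        utils::write.table(rows, art("enrichment.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        utils::write.table(bubbleData(top), art("bubble_data.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        list(clusters = clusters, rows = rows, top = top)
    })

    ## compound-target network
    ctnet <- .stage("ctnet", {
        net <- assembleCTNetwork(adme$passing, targets$edges, ppi$keys,
                                 enrich$clusters)
        shared <- sharedKeyTargets(net)
        writeNetwork(ctGraph(net), art("ct_network.graphml"), "graphml")
        writeNetwork(ctGraph(net), art("ct_network.sif"), "sif",
                     interaction = "ct")
        writeLines(shared, art("shared_key_targets.txt"))
        list(net = net, shared = shared)
    })

    report <- list(
        config = unclass(config),
        herbnet = list(
            n_herbs = nrow(incidenceMatrix(herbnet$inc)),
            n_prescriptions = ncol(incidenceMatrix(herbnet$inc)),
            top_cooccurring_pair = herbnet$topPair,
            top_cooccurrence_count = herbnet$topPairCount),
        adme = list(
            compounds_total = nrow(adme$tab),
            compounds_retained = nrow(adme$passing),
            venn_blocks = as.list(adme$part$counts)),
        targets = list(
            per_herb = lapply(targets$unions, length),
            union_all = length(targets$allTargets),
            disease_genes = length(targets$disease),
            disease_overlap = length(targets$overlap)),
        ppi = list(
            nodes_before = igraph::gorder(ppiGraph(ppi$net)),
            isolates_removed = length(ppi$removed),
            nodes_after = igraph::gorder(ppiGraph(ppi$pruned)),
            edges = igraph::gsize(ppiGraph(ppi$pruned)),
            key_targets = length(ppi$keys),
            subnetwork_edges = igraph::gsize(ppiGraph(ppi$sub)),
            subnetwork_degree_sum = sum(ppi$cmSub$degree)),
        cluster_enrich = list(
            k = config$kClusters,
            cluster_sizes = as.list(table(enrich$clusters)),
            terms_tested = nrow(enrich$rows),
            top_term = if (nrow(enrich$rows)) enrich$rows$term_id[1]
                       else NA,
            min_p = if (nrow(enrich$rows)) enrich$rows$p[1] else NA),
        ct_network = list(
            compounds = sum(igraph::V(ctGraph(ctnet$net))$layer ==
                                "compound"),
            targets = sum(igraph::V(ctGraph(ctnet$net))$layer == "target"),
            nodes = igraph::gorder(ctGraph(ctnet$net)),
            edges = igraph::gsize(ctGraph(ctnet$net)),
            compounds_dropped = length(droppedCompounds(ctnet$net)),
            shared_key_targets = ctnet$shared))
    writeReport(report, art("report.json"))
    invisible(report)
}
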