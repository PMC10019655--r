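#' Read a TCMSP-style compound table
#'
#' Parses a CSV/TSV table of candidate herbal compounds with ADME descriptors.
#' Required header columns: `name`, `pubchem_cid`, `mw`, `ob`, `dl`, `herbs`
#' (semicolon-joined source-herb codes). Oral bioavailability (`ob`) is a
#' percentage; drug-likeness (`dl`) is unitless in `[0, 1]`.
#'
#' @param path path to a UTF-8 delimited file with a header row; the field
#'   separator (tab or comma) is sniffed from the header line.
#' @return a data.frame with columns `name`, `pubchem_cid` (numeric), `mw`,
#'   `ob`, `dl` and a list-column `herbs` of source-herb code vectors.
#' @examples
#' tab <- readCompoundTable(system.file("extdata", "eh_cs_compounds.tsv",
#'                                      package = "HerbNetPharm"))
#' nrow(tab)  # 24
#' @export
readCompoundTable <- function(path) {
    sep <- .sniffSep(path)
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, quote = "\"",
                            comment.char = "", check.names = TRUE)
    need <- c("name", "pubchem_cid", "mw", "ob", "dl", "herbs")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop(sprintf("compound table is missing column(s): %s",
                     paste(miss, collapse = ", ")))
    if (nrow(df) == 0)
        return(data.frame(name = character(), pubchem_cid = numeric(),
                          mw = numeric(), ob = numeric(), dl = numeric(),
                          herbs = I(list())))
    for (col in c("pubchem_cid", "mw", "ob", "dl")) {
        v <- suppressWarnings(as.numeric(df[[col]]))
        bad <- which(is.na(v) & !is.na(df[[col]]))
        if (length(bad))
            stop(sprintf("non-numeric '%s' at data line %d: '%s'",
                         col, bad[1] + 1L, df[[col]][bad[1]]))
        df[[col]] <- v
    }
    herbs <- .splitHerbs(df$herbs)
    if (any(lengths(herbs) == 0))
        stop(sprintf("compound without source herb at data line %d",
                     which(lengths(herbs) == 0)[1] + 1L))
    if (anyDuplicated(df$pubchem_cid))
        stop(sprintf("duplicate pubchem_cid: %s",
                     df$pubchem_cid[anyDuplicated(df$pubchem_cid)][1]))
    if (any(df$ob < 0)) stop("oral bioavailability must be >= 0")
    if (any(df$dl < 0 | df$dl > 1)) stop("drug-likeness must lie in [0, 1]")
    out <- data.frame(name = as.character(df$name),
                      pubchem_cid = df$pubchem_cid, mw = df$mw,
                      ob = df$ob, dl = df$dl, stringsAsFactors = FALSE)
    out$herbs <- herbs
    out
}

#' Write a compound table
#'
#' Inverse of [readCompoundTable()]: the `herbs` list-column is re-joined with
#' semicolons. `readCompoundTable(writeCompoundTable(x, f))` reproduces `x`.
#'
#' @param records compound data.frame as returned by [readCompoundTable()].
#' @param path output path; tab-separated.
#' @return `path`, invisibly.
#' @export
writeCompoundTable <- function(records, path) {
    df <- records
    df$herbs <- vapply(df$herbs, paste, character(1), collapse = ";")
    utils::write.table(df[, c("name", "pubchem_cid", "mw", "ob", "dl",
                              "herbs")],
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a scored PPI edge list (STRING export style)
#'
#' Reads a tab-separated edge table with two gene-symbol columns and a
#' combined confidence score, normalizes scores to the unit scale, uppercases
#' gene symbols, drops self-loops (with a message reporting how many) and
#' collapses duplicate unordered pairs keeping the maximum score.
#'
#' STRING exports ship integer scores on a 0-1000 scale while the
#' conventional inclusion threshold (0.4) is quoted on the unit scale;
#' `scoreScale = "auto"` therefore divides by 1000 whenever any score
#' exceeds 1.
#'
#' @param path TSV with a header; the first two columns are interpreted as
#'   gene symbols, the score is taken from a column named `combined_score` or
#'   `score` (else the third column).
#' @param scoreScale `"auto"` (default), `"unit"` (scores already in
#'   `[0, 1]`) or `"thousand"` (divide by 1000).
#' @return data.frame with columns `a`, `b`, `score`; one row per unordered
#'   pair, scores in `[0, 1]`.
#' @export
readPPIEdges <- function(path, scoreScale = c("auto", "unit", "thousand")) {
    scoreScale <- match.arg(scoreScale)
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, quote = "\"",
                            comment.char = "")
    if (ncol(df) < 3) stop("PPI edge table needs two symbol columns and a score")
    scol <- intersect(c("combined_score", "score"), names(df))
    scol <- if (length(scol)) scol[1] else names(df)[3]
    edges <- data.frame(a = toupper(trimws(as.character(df[[1]]))),
                        b = toupper(trimws(as.character(df[[2]]))),
                        score = suppressWarnings(as.numeric(df[[scol]])),
                        stringsAsFactors = FALSE)
    if (anyNA(edges$score)) stop("non-numeric interaction score")
    if (scoreScale == "auto")
        scoreScale <- if (any(edges$score > 1)) "thousand" else "unit"
    if (scoreScale == "thousand") edges$score <- edges$score / 1000
    if (any(edges$score < 0 | edges$score > 1))
        stop("interaction scores outside [0, 1] after normalization")
    loops <- edges$a == edges$b
    if (any(loops)) {
        message(sprintf("dropped %d self-loop(s)", sum(loops)))
        edges <- edges[!loops, , drop = FALSE]
    }
    if (nrow(edges)) {
        swap <- edges$a > edges$b
        tmp <- edges$a[swap]; edges$a[swap] <- edges$b[swap]
        edges$b[swap] <- tmp
        key <- paste(edges$a, edges$b, sep = "\r")
        score <- vapply(split(edges$score, key), max, numeric(1))
        parts <- strsplit(names(score), "\r", fixed = TRUE)
        edges <- data.frame(a = vapply(parts, `[`, character(1), 1L),
                            b = vapply(parts, `[`, character(1), 2L),
                            score = unname(score), stringsAsFactors = FALSE)
        edges <- edges[order(edges$a, edges$b), , drop = FALSE]
        rownames(edges) <- NULL
    }
    edges
}

#' Construct a gene-set collection
#'
#' @param ids unique term identifiers.
#' @param names human-readable term names (defaults to `ids`).
#' @param categories per-term category tag in
#'   `{"KEGG","BP","CC","MF","other"}` (default `"other"`).
#' @param genes list of member gene-symbol vectors; uppercased and
#'   deduplicated on construction.
#' @return a [GeneSetDb-class].
#' @export
GeneSetDb <- function(ids, genes, names = ids,
                      categories = rep("other", length(ids))) {
    new("GeneSetDb", ids = as.character(ids), names = as.character(names),
        categories = as.character(categories),
        genes = lapply(genes, function(g) unique(.normSymbols(g))))
}

#' Read gene sets from a GMT file
#'
#' GMT lines are `term-id TAB description TAB gene TAB gene ...`. The
#' description field may carry a category prefix written as
#' `"CATEGORY|term name"` with CATEGORY one of KEGG/BP/CC/MF (the convention
#' used by [writeGeneSets()]); otherwise the category is `"other"`. Terms
#' with an empty member list are skipped with a warning.
#'
#' @param path GMT file path.
#' @return a [GeneSetDb-class].
#' @export
readGeneSets <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- lengths(fields) < 3
    if (any(short)) {
        warning(sprintf("skipped %d term(s) with empty member list",
                        sum(short)))
        fields <- fields[!short]
    }
    ids <- vapply(fields, `[`, character(1), 1L)
    desc <- vapply(fields, `[`, character(1), 2L)
    cats <- rep("other", length(ids))
    nm <- desc
    pref <- regmatches(desc, regexpr("^(KEGG|BP|CC|MF)\\|", desc))
    has <- lengths(regmatches(desc, gregexpr("^(KEGG|BP|CC|MF)\\|", desc))) > 0
    cats[has] <- sub("\\|$", "", pref)
    nm[has] <- sub("^(KEGG|BP|CC|MF)\\|", "", desc[has])
    genes <- lapply(fields, function(f) f[-(1:2)])
    GeneSetDb(ids, genes, names = nm, categories = cats)
}

#' Write gene sets to a GMT file
#'
#' The category tag is encoded in the description field as
#' `"CATEGORY|term name"` so that [readGeneSets()] round-trips losslessly.
#'
#' @param db a [GeneSetDb-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneSets <- function(db, path) {
    desc <- ifelse(db@categories == "other", db@names,
                   paste0(db@categories, "|", db@names))
    lines <- vapply(seq_along(db@ids), function(i)
        paste(c(db@ids[i], desc[i], db@genes[[i]]), collapse = "\t"),
        character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read a plain gene list (one symbol per line)
#'
#' @param path text file, one gene symbol per line; blank lines and `#`
#'   comments ignored.
#' @return character vector of unique uppercase symbols.
#' @export
readGeneList <- function(path) {
    x <- readLines(path)
    x <- trimws(x)
    x <- x[nzchar(x) & !startsWith(x, "#")]
    unique(.normSymbols(x))
}

#' Export a graph for Cytoscape
#'
#' Writes an igraph in one of three formats: SIF (`A <label> B` lines, one
#' per edge; label `"pp"` for protein-protein and `"ct"` for compound-target
#' edges), GraphML (full attribute round-trip via igraph) or a plain edge
#' TSV including edge attributes.
#'
#' @param graph an igraph.
#' @param path output path.
#' @param format `"sif"`, `"graphml"` or `"edge-tsv"`.
#' @param interaction SIF interaction label (default `"pp"`).
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(graph, path, format = c("sif", "graphml", "edge-tsv"),
                         interaction = "pp") {
    format <- match.arg(format)
    if (format == "graphml") {
        igraph::write_graph(graph, path, format = "graphml")
    } else {
        el <- igraph::as_edgelist(graph, names = TRUE)
        if (format == "sif") {
            writeLines(if (nrow(el)) paste(el[, 1], interaction, el[, 2])
                       else character(0), path)
        } else {
            df <- data.frame(from = el[, 1], to = el[, 2],
                             stringsAsFactors = FALSE)
            for (at in igraph::edge_attr_names(graph))
                df[[at]] <- igraph::edge_attr(graph, at)
            utils::write.table(df, path, sep = "\t", quote = FALSE,
                               row.names = FALSE)
        }
    }
    invisible(path)
}

#' Read a GraphML network written by [writeNetwork()]
#'
#' @param path GraphML file path.
#' @return an igraph.
#' @export
readNetworkGraphml <- function(path)
    igraph::read_graph(path, format = "graphml")

#' Write a JSON results report
#'
#' Scalars are unboxed and numbers written at full precision so that two runs
#' with identical inputs produce byte-identical reports.
#'
#' @param results a named list of counts/settings/tables.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeReport <- function(results, path) {
    jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' Read prescriptions from a long-format table or incidence matrix
#'
#' Accepts either a long-format delimited table with columns `prescription`
#' and `herb` (one row per membership) or, when those columns are absent, a
#' binary incidence matrix with herb codes in the first column and one
#' column per prescription.
#'
#' @param path delimited text file (separator sniffed).
#' @return named list: prescription id -> character vector of herb codes.
#' @export
readPrescriptions <- function(path) {
    sep <- .sniffSep(path)
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE)
    if (all(c("prescription", "herb") %in% names(df)))
        return(lapply(split(df$herb, df$prescription), unique))
    herbs <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    lapply(stats::setNames(seq_len(ncol(m)), colnames(m)),
           function(j) herbs[m[, j] == 1])
}
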