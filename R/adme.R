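#' ADME screen: oral bioavailability and drug-likeness filter
#'
#' Retains candidate compounds satisfying both ADME criteria, inclusively:
#' `ob >= obMin` (oral bioavailability, percent) and `dl >= dlMin`
#' (drug-likeness). Defaults are the conventional TCMSP screening cutoffs
#' OB >= 30 percent and DL >= 0.18. Row order is preserved, so the filter is
#' a pure subset operation and monotone in both thresholds.
#'
#' @param records compound data.frame from [readCompoundTable()] or
#'   [genCompounds()].
#' @param obMin minimum oral bioavailability in percent (default 30).
#' @param dlMin minimum drug-likeness (default 0.18).
#' @return the retained subset of `records`.
#' @examples
#' tab <- readCompoundTable(system.file("extdata", "eh_cs_compounds.tsv",
#'                                      package = "HerbNetPharm"))
#' nrow(filterCompounds(tab))  # all 24 pass at the defaults
#' @export
filterCompounds <- function(records, obMin = 30, dlMin = 0.18) {
    stopifnot(is.finite(obMin), is.finite(dlMin))
    keep <- records$ob >= obMin & records$dl >= dlMin
    out <- records[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Partition compounds by source herb (Venn blocks)
#'
#' Assigns each compound to exactly one block keyed by its full set of
#' source herbs: single-herb blocks are "exclusive", multi-herb blocks are
#' "shared" (keys join the sorted codes with `&`, e.g. `"CS&EH"`). Compounds
#' listed once per herb under the same PubChem CID are merged into one record
#' attributed to all of its herbs before partitioning.
#'
#' @param records compound data.frame (typically after [filterCompounds()]).
#' @return object of class `venn_partition`: a list with `blocks` (named
#'   list of pubchem_cid vectors), `exclusive`/`shared` (the same blocks
#'   split by key arity) and `counts` (named integer vector).
#' @examples
#' tab <- readCompoundTable(system.file("extdata", "eh_cs_compounds.tsv",
#'                                      package = "HerbNetPharm"))
#' partitionBySource(filterCompounds(tab))$counts  # CS 7, CS&EH 2, EH 15
#' @export
partitionBySource <- function(records) {
    if (any(lengths(records$herbs) == 0))
        stop("every compound needs at least one source herb")
    cid <- records$pubchem_cid
    herbs <- records$herbs
    if (anyDuplicated(cid)) {  # merge duplicate CIDs across herbs
        herbs <- lapply(split(herbs, cid), function(h) unique(unlist(h)))
        cid <- as.numeric(names(herbs))
    }
    blocks <- .partitionByKey(cid, herbs)
    arity <- vapply(strsplit(names(blocks), "&", fixed = TRUE), length,
                    integer(1))
    structure(list(blocks = blocks,
                   exclusive = blocks[arity == 1],
                   shared = blocks[arity > 1],
                   counts = vapply(blocks, length, integer(1))),
              class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
    cat("Venn partition:", sum(x$counts), "items in", length(x$blocks),
        "block(s)\n")
    print(x$counts)
    invisible(x)
}
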