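#' Accessors for HerbNetPharm classes
#'
#' Small accessor generics: `incidenceMatrix` returns the binary matrix of a
#' [HerbIncidence-class], `herbCodes` and `prescriptionIds` its dimnames;
#' `ppiGraph` and `minScore` unwrap a [PPINetwork-class]; `ctGraph` and
#' `droppedCompounds` unwrap a [CTNetwork-class]; `geneSets`, `setIds` and
#' `setCategories` read a [GeneSetDb-class]; `truthParams` the parameter list
#' of a [SyntheticTruth-class].
#'
#' @param x an object of the matching class.
#' @return the slot contents (matrix, igraph, character vector or list).
#' @name accessors
#' @examples
#' inc <- buildIncidence(list(P1 = c("EH", "CS"), P2 = c("CS", "GR")))
#' herbCodes(inc)
#' incidenceMatrix(inc)
NULL

#' @rdname accessors
#' @export
setGeneric("incidenceMatrix", function(x) standardGeneric("incidenceMatrix"))
#' @rdname accessors
#' @export
setGeneric("herbCodes", function(x) standardGeneric("herbCodes"))
#' @rdname accessors
#' @export
setGeneric("prescriptionIds", function(x) standardGeneric("prescriptionIds"))
#' @rdname accessors
#' @export
setGeneric("ppiGraph", function(x) standardGeneric("ppiGraph"))
#' @rdname accessors
#' @export
setGeneric("minScore", function(x) standardGeneric("minScore"))
#' @rdname accessors
#' @export
setGeneric("ctGraph", function(x) standardGeneric("ctGraph"))
#' @rdname accessors
#' @export
setGeneric("droppedCompounds", function(x) standardGeneric("droppedCompounds"))
#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @rdname accessors
#' @export
setGeneric("setIds", function(x) standardGeneric("setIds"))
#' @rdname accessors
#' @export
setGeneric("setCategories", function(x) standardGeneric("setCategories"))
#' @rdname accessors
#' @export
setGeneric("truthParams", function(x) standardGeneric("truthParams"))

#' @rdname accessors
setMethod("incidenceMatrix", "HerbIncidence", function(x) x@mat)
#' @rdname accessors
setMethod("herbCodes", "HerbIncidence", function(x) rownames(x@mat))
#' @rdname accessors
setMethod("prescriptionIds", "HerbIncidence", function(x) colnames(x@mat))
#' @rdname accessors
setMethod("ppiGraph", "PPINetwork", function(x) x@graph)
#' @rdname accessors
setMethod("minScore", "PPINetwork", function(x) x@minScore)
#' @rdname accessors
setMethod("ctGraph", "CTNetwork", function(x) x@graph)
#' @rdname accessors
setMethod("droppedCompounds", "CTNetwork", function(x) x@dropped)
#' @rdname accessors
setMethod("geneSets", "GeneSetDb",
          function(x) stats::setNames(x@genes, x@ids))
#' @rdname accessors
setMethod("setIds", "GeneSetDb", function(x) x@ids)
#' @rdname accessors
setMethod("setCategories", "GeneSetDb",
          function(x) stats::setNames(x@categories, x@ids))
#' @rdname accessors
setMethod("truthParams", "SyntheticTruth", function(x) x@params)

#' @describeIn accessors number of gene sets in the collection.
#' @export
setMethod("length", "GeneSetDb", function(x) length(x@ids))
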