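#' Extract the logical presence assay
#' @param x a \code{\linkS4class{PresenceMatrix}}.
#' @return logical matrix, families as rows, genomes as columns.
#' @export
setGeneric("presence", function(x) standardGeneric("presence"))

#' @rdname presence
setMethod("presence", "PresenceMatrix", function(x) {
  SummarizedExperiment::assay(x, "presence")
})

#' Family identifiers (row labels) of a presence matrix
#' @param x a \code{\linkS4class{PresenceMatrix}}.
#' @export
setGeneric("familyIDs", function(x) standardGeneric("familyIDs"))

#' @rdname familyIDs
setMethod("familyIDs", "PresenceMatrix", function(x) rownames(x))

#' Genome identifiers (column labels) of a presence matrix
#' @param x a \code{\linkS4class{PresenceMatrix}}.
#' @export
setGeneric("genomeIDs", function(x) standardGeneric("genomeIDs"))

#' @rdname genomeIDs
setMethod("genomeIDs", "PresenceMatrix", function(x) colnames(x))

#' E-value threshold recorded when the matrix was built
#' @param x a \code{\linkS4class{PresenceMatrix}}.
#' @export
setGeneric("evalueThreshold", function(x) standardGeneric("evalueThreshold"))

#' @rdname evalueThreshold
setMethod("evalueThreshold", "PresenceMatrix", function(x) {
  S4Vectors::metadata(x)$evalue_threshold
})

#' Per-module family sets
#' @param x a \code{\linkS4class{ModuleSet}}.
#' @return named list of character vectors.
#' @export
setGeneric("moduleFamilies", function(x) standardGeneric("moduleFamilies"))

#' @rdname moduleFamilies
setMethod("moduleFamilies", "ModuleSet", function(x) x@families)

#' Per-module statistics table
#' @param x a \code{\linkS4class{ModuleSet}}.
#' @return data.frame with one row per module.
#' @export
setGeneric("moduleTable", function(x) standardGeneric("moduleTable"))

#' @rdname moduleTable
setMethod("moduleTable", "ModuleSet", function(x) x@table)

#' Residual clusters below the minimum module size
#' @param x a \code{\linkS4class{ModuleSet}}.
#' @return named list of character vectors.
#' @export
setGeneric("moduleResiduals", function(x) standardGeneric("moduleResiduals"))

#' @rdname moduleResiduals
setMethod("moduleResiduals", "ModuleSet", function(x) x@residuals)

#' Retained (top-carrying) genomes per module under the median-genome rule
#' @param x a \code{\linkS4class{ModuleSet}}.
#' @return named list of character vectors.
#' @export
setGeneric("retainedGenomes", function(x) standardGeneric("retainedGenomes"))

#' @rdname retainedGenomes
setMethod("retainedGenomes", "ModuleSet", function(x) x@retained)
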