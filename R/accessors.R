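#' Antibody-capture accessors
#'
#' Convenience accessors for the \code{"AntibodyCapture"} alternative
#' experiment of an \linkS4class{InciteExperiment}.
#'
#' @param x an \code{InciteExperiment}.
#' @return \code{adtCounts} returns the full antibodies x nuclei count matrix;
#'   \code{targetCounts}, \code{normalizerCounts} and \code{hashtagCounts}
#'   return the rows of the corresponding role; \code{antibodyRoles} the named
#'   role vector; \code{targetNames}, \code{normalizerName} and
#'   \code{hashtagNames} the antibody names by role.
#' @name adt-accessors
NULL

#' @rdname adt-accessors
#' @export
setGeneric("adtCounts", function(x) standardGeneric("adtCounts"))

#' @rdname adt-accessors
#' @export
setMethod("adtCounts", "InciteExperiment", function(x) {
  assay(altExp(x, "AntibodyCapture"), "counts")
})

#' @rdname adt-accessors
#' @export
setGeneric("antibodyRoles", function(x) standardGeneric("antibodyRoles"))

#' @rdname adt-accessors
#' @export
setMethod("antibodyRoles", "InciteExperiment", function(x) {
  ae <- altExp(x, "AntibodyCapture")
  stats::setNames(rowData(ae)$role, rownames(ae))
})

#' @rdname adt-accessors
#' @export
setGeneric("targetCounts", function(x) standardGeneric("targetCounts"))

#' @rdname adt-accessors
#' @export
setMethod("targetCounts", "InciteExperiment", function(x) {
  adtCounts(x)[antibodyRoles(x) == "target", , drop = FALSE]
})

#' @rdname adt-accessors
#' @export
setGeneric("normalizerCounts", function(x) standardGeneric("normalizerCounts"))

#' @rdname adt-accessors
#' @export
setMethod("normalizerCounts", "InciteExperiment", function(x) {
  adtCounts(x)[antibodyRoles(x) == "normalizer", , drop = TRUE]
})

#' @rdname adt-accessors
#' @export
setGeneric("hashtagCounts", function(x) standardGeneric("hashtagCounts"))

#' @rdname adt-accessors
#' @export
setMethod("hashtagCounts", "InciteExperiment", function(x) {
  adtCounts(x)[antibodyRoles(x) == "hashtag", , drop = FALSE]
})

#' @rdname adt-accessors
#' @export
targetNames <- function(x) names(which(antibodyRoles(x) == "target"))

#' @rdname adt-accessors
#' @export
normalizerName <- function(x) names(which(antibodyRoles(x) == "normalizer"))

#' @rdname adt-accessors
#' @export
hashtagNames <- function(x) names(which(antibodyRoles(x) == "hashtag"))

#' Ground-truth gene programs of a synthetic cohort
#'
#' @param x an \code{InciteExperiment} produced by \code{\link{generateCohort}}.
#' @return Named list of gene-name vectors (cell-type markers, NF-kB targets,
#'   Wnt targets, DAM and homeostatic microglial markers).
#' @export
geneMarkers <- function(x) metadata(x)$gene_programs
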