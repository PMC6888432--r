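#' Accessors for pipeline containers
#'
#' Small accessor layer so downstream code never touches slots directly.
#'
#' @param x an object
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))

#' @rdname accessors
#' @export
setGeneric("referenceId", function(x) standardGeneric("referenceId"))

#' @rdname accessors
#' @export
setGeneric("alignmentWidth", function(x) standardGeneric("alignmentWidth"))

#' @rdname accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname accessors
#' @export
setGeneric("siteRates", function(x) standardGeneric("siteRates"))

#' @rdname accessors
#' @export
setGeneric("zScores", function(x) standardGeneric("zScores"))

#' @rdname accessors
#' @export
setGeneric("noDataColumns", function(x) standardGeneric("noDataColumns"))

#' @rdname accessors
#' @export
setGeneric("gammaShape", function(x) standardGeneric("gammaShape"))

#' @rdname accessors
#' @export
setGeneric("profileMatrix", function(x) standardGeneric("profileMatrix"))

#' @rdname accessors
#' @export
setGeneric("taxonomyGroups", function(x) standardGeneric("taxonomyGroups"))

#' @rdname accessors
#' @export
setGeneric("clusterAssignment", function(x) standardGeneric("clusterAssignment"))

#' @rdname accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname accessors
setMethod("taxa", "MultipleAlignment", function(x) names(x@seqs))

#' @rdname accessors
setMethod("referenceId", "MultipleAlignment", function(x) x@referenceId)

#' @rdname accessors
setMethod("alignmentWidth", "MultipleAlignment",
          function(x) nchar(x@seqs[[1L]]))

#' @rdname accessors
setMethod("sequences", "MultipleAlignment", function(x) x@seqs)

#' @rdname accessors
setMethod("scores", "AnnotationTrack", function(x) x@scores)

#' @rdname accessors
setMethod("scores", "DisorderMatrix", function(x) x@scores)

#' @rdname accessors
setMethod("siteRates", "SiteRateResult", function(x) x@rate)

#' @rdname accessors
setMethod("zScores", "SiteRateResult", function(x) x@z)

#' @rdname accessors
setMethod("noDataColumns", "SiteRateResult", function(x) x@noData)

#' @rdname accessors
setMethod("gammaShape", "SiteRateResult", function(x) x@alpha)

#' @rdname accessors
setMethod("profileMatrix", "PhyloProfile", function(x) x@mat)

#' @rdname accessors
setMethod("taxonomyGroups", "PhyloProfile", function(x) x@groups)

#' @rdname accessors
setMethod("clusterAssignment", "ProfileClusters", function(x) x@assignment)

#' @rdname accessors
setMethod("classLabels", "ProfileClusters", function(x) x@classLabels)

setMethod("show", "MultipleAlignment", function(object) {
  cat(sprintf("MultipleAlignment: %d sequences x %d columns (reference: %s)\n",
              length(object@seqs), alignmentWidth(object),
              object@referenceId))
})

setMethod("show", "AnnotationTrack", function(object) {
  cat(sprintf("AnnotationTrack [%s] for %s: %d residues, scores in [%.2f, %.2f]\n",
              object@kind, object@sequenceId, length(object@scores),
              min(object@scores), max(object@scores)))
})

setMethod("show", "SiteRateResult", function(object) {
  cat(sprintf(
    "SiteRateResult: %d columns (%d no-data), alpha = %.4g, K = %d, logLik = %.2f\n",
    length(object@rate), sum(object@noData), object@alpha,
    object@nCategories, object@logLik))
})

setMethod("show", "DisorderMatrix", function(object) {
  cat(sprintf("DisorderMatrix: %d taxa x %d columns (%d masked cells)\n",
              nrow(object@scores), ncol(object@scores),
              sum(is.na(object@scores))))
})

setMethod("show", "PhyloProfile", function(object) {
  cat(sprintf("PhyloProfile: %d proteins x %d species; groups: %s\n",
              nrow(object@mat), ncol(object@mat),
              paste(names(object@groups), collapse = " < ")))
})

setMethod("show", "ProfileClusters", function(object) {
  tb <- table(object@assignment)
  cat(sprintf("ProfileClusters: k = %d (%s)\n", object@k,
              paste(sprintf("%s: %d", object@classLabels, as.integer(tb)),
                    collapse = ", ")))
})
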