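#' @rdname BerryExpressionSet-class
#' @param object,x a \code{BerryExpressionSet} or \code{ClusterResult}.
#' @export
setGeneric("rpkm", function(x) standardGeneric("rpkm"))

#' @rdname BerryExpressionSet-class
#' @export
setGeneric("uniqueReads", function(x) standardGeneric("uniqueReads"))

#' @rdname BerryExpressionSet-class
#' @export
setGeneric("allocatedReads", function(x) standardGeneric("allocatedReads"))

#' @rdname BerryExpressionSet-class
#' @export
setGeneric("totalMapped", function(x) standardGeneric("totalMapped"))

#' @rdname ClusterResult-class
#' @export
setGeneric("clusterAssignments", function(x) standardGeneric("clusterAssignments"))

#' @rdname ClusterResult-class
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @rdname ClusterResult-class
#' @export
setGeneric("timesFound", function(x) standardGeneric("timesFound"))

#' @rdname ClusterResult-class
#' @export
setGeneric("bestObjective", function(x) standardGeneric("bestObjective"))

#' @rdname ClusterResult-class
#' @export
setGeneric("archetypeLabels", function(x) standardGeneric("archetypeLabels"))

#' @rdname BerryExpressionSet-class
#' @export
setMethod("rpkm", "BerryExpressionSet", function(x)
  SummarizedExperiment::assay(x, "rpkm"))

#' @rdname BerryExpressionSet-class
#' @export
setMethod("uniqueReads", "BerryExpressionSet", function(x)
  SummarizedExperiment::assay(x, "uniqueReads"))

#' @rdname BerryExpressionSet-class
#' @export
setMethod("allocatedReads", "BerryExpressionSet", function(x)
  SummarizedExperiment::assay(x, "allocatedReads"))

#' @rdname BerryExpressionSet-class
#' @export
setMethod("totalMapped", "BerryExpressionSet", function(x)
  S4Vectors::metadata(x)$totalMapped)

#' @rdname ClusterResult-class
#' @export
setMethod("clusterAssignments", "ClusterResult", function(x) x@assignments)

#' @rdname ClusterResult-class
#' @export
setMethod("centroids", "ClusterResult", function(x) x@centroids)

#' @rdname ClusterResult-class
#' @export
setMethod("timesFound", "ClusterResult", function(x) x@timesFound)

#' @rdname ClusterResult-class
#' @export
setMethod("bestObjective", "ClusterResult", function(x) x@bestObjective)

#' @rdname ClusterResult-class
#' @export
setMethod("archetypeLabels", "ClusterResult", function(x) x@archetypeLabels)

#' @rdname ClusterResult-class
#' @export
setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult: k =", object@k, "over", length(object@assignments),
      "profiles\n")
  cat("  best objective:", format(object@bestObjective, digits = 8),
      "reached in", object@timesFound, "of", object@nRuns, "runs\n")
  sizes <- tabulate(object@assignments, nbins = object@k)
  cat("  cluster sizes:", paste(sizes, collapse = ", "), "\n")
  if (length(object@archetypeLabels))
    cat("  archetypes:",
        paste(unique(object@archetypeLabels), collapse = ", "), "\n")
})

#' @rdname NormalizedProfiles-class
#' @param object a \code{NormalizedProfiles}.
#' @export
setMethod("show", "NormalizedProfiles", function(object) {
  tab <- table(factor(object@reasons,
                      levels = c("kept", "all_low", "low_range")))
  cat("NormalizedProfiles:", nrow(object@normalized), "kept of",
      length(object@reasons), "transcripts\n")
  cat("  filtered:", tab[["all_low"]], "all_low,",
      tab[["low_range"]], "low_range\n")
})
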