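#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats cor p.adjust phyper quantile rbinom rlnorm rmultinom
#'   rnorm rpois runif qnorm setNames
#' @importFrom utils head write.table read.delim
NULL

#' BerryExpressionSet: stage-wise transcript expression container
#'
#' An extension of \linkS4class{SummarizedExperiment} holding the three
#' quantities the quantification stage produces per transcript and
#' developmental stage: \code{rpkm} (Reads Per Kilobase of transcript per
#' Million mapped reads), \code{uniqueReads} (reads whose single accepted
#' alignment names this transcript) and \code{allocatedReads} (unique reads
#' plus the proportional share of multi-mapped reads). Transcript length
#' lives in \code{rowData(x)$length}; per-stage totals of allocated reads
#' (the RPKM denominator) in \code{metadata(x)$totalMapped}.
#'
#' @slot .Data inherited SummarizedExperiment representation.
#' @seealso [quantifyStages()], [rpkm()], [uniqueReads()], [allocatedReads()]
#' @export
setClass("BerryExpressionSet", contains = "SummarizedExperiment")

setValidity("BerryExpressionSet", function(object) {
  msg <- character()
  need <- c("rpkm", "uniqueReads", "allocatedReads")
  have <- SummarizedExperiment::assayNames(object)
  if (!all(need %in% have))
    msg <- c(msg, paste0("assays must include: ", paste(need, collapse = ", ")))
  else {
    if (any(SummarizedExperiment::assay(object, "rpkm") < 0))
      msg <- c(msg, "rpkm must be nonnegative")
    if (any(SummarizedExperiment::assay(object, "allocatedReads") <
            SummarizedExperiment::assay(object, "uniqueReads") - 1e-9))
      msg <- c(msg, "allocatedReads must be >= uniqueReads")
  }
  if (is.null(SummarizedExperiment::rowData(object)$length))
    msg <- c(msg, "rowData must carry transcript 'length'")
  tm <- S4Vectors::metadata(object)$totalMapped
  if (is.null(tm) || length(tm) != ncol(object))
    msg <- c(msg, "metadata$totalMapped must have one entry per stage")
  if (length(msg)) msg else TRUE
})

#' Construct a BerryExpressionSet
#'
#' @param rpkm,uniqueReads,allocatedReads numeric matrices, transcripts x
#'   stages, with identical dimnames.
#' @param lengths named numeric vector of transcript lengths (bp).
#' @param totalMapped per-stage totals of allocated reads used as the RPKM
#'   denominator.
#' @param rowData optional extra per-transcript annotation (data.frame).
#' @return A [BerryExpressionSet-class] object.
#' @export
BerryExpressionSet <- function(rpkm, uniqueReads, allocatedReads, lengths,
                               totalMapped, rowData = NULL) {
  stopifnot(identical(dim(rpkm), dim(uniqueReads)),
            identical(dim(rpkm), dim(allocatedReads)))
  rd <- S4Vectors::DataFrame(length = as.numeric(lengths[rownames(rpkm)]))
  if (!is.null(rowData))
    rd <- cbind(rd, S4Vectors::DataFrame(rowData))
  rownames(rd) <- rownames(rpkm)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(rpkm = rpkm, uniqueReads = uniqueReads,
                  allocatedReads = allocatedReads),
    rowData = rd,
    colData = S4Vectors::DataFrame(stage = colnames(rpkm),
                                   row.names = colnames(rpkm)))
  S4Vectors::metadata(se)$totalMapped <- totalMapped
  new("BerryExpressionSet", se)
}

#' ClusterResult: stability-checked k-means clustering of expression profiles
#'
#' Holds the best-objective solution over repeated random restarts of
#' Lloyd's k-means on normalized 4-stage profiles, together with the
#' stability record (how many restarts reached that objective) and optional
#' archetype labels per cluster.
#'
#' @slot k number of clusters.
#' @slot assignments named integer vector, transcript -> cluster in 1..k.
#' @slot centroids k x 4 numeric matrix of cluster means.
#' @slot nRuns number of random restarts performed.
#' @slot bestObjective total within-cluster sum of squared Euclidean
#'   distances of the reported solution.
#' @slot timesFound number of restarts whose final objective matched the
#'   best one (relative tolerance 1e-8).
#' @slot archetypeLabels character per cluster: an archetype name or
#'   "unlabeled"; empty until [labelArchetypes()] is applied.
#' @seealso [kmeansStable()], [labelArchetypes()]
#' @export
setClass("ClusterResult",
  representation(k = "integer", assignments = "integer",
                 centroids = "matrix", nRuns = "integer",
                 bestObjective = "numeric", timesFound = "integer",
                 archetypeLabels = "character"))

setValidity("ClusterResult", function(object) {
  msg <- character()
  if (length(object@assignments) &&
      (min(object@assignments) < 1L || max(object@assignments) > object@k))
    msg <- c(msg, "assignments must lie in 1..k")
  if (object@timesFound < 1L) msg <- c(msg, "timesFound must be >= 1")
  if (nrow(object@centroids) != object@k)
    msg <- c(msg, "centroids must have k rows")
  if (length(msg)) msg else TRUE
})

#' NormalizedProfiles: scale-and-centred 4-stage expression profiles
#'
#' Result of the pre-clustering normalization: rows scaled to unit sum of
#' squares, then centred to zero mean, with low-expression and low-range
#' rows filtered out. \code{scaled} holds the pre-centring values whose
#' sum of squares is exactly 1; \code{normalized} the centred values that
#' clustering consumes (kept rows only).
#'
#' @slot normalized kept transcripts x 4 matrix of centred profiles.
#' @slot scaled same rows before centring (unit sum of squares).
#' @slot scaleFactors per-kept-row multiplier 1/sqrt(sum(x^2)).
#' @slot reasons per-input-row filter outcome: "kept", "all_low" (all four
#'   RPKM below the detection floor) or "low_range" (normalized
#'   max - min below the range threshold).
#' @seealso [normalizeProfiles()]
#' @export
setClass("NormalizedProfiles",
  representation(normalized = "matrix", scaled = "matrix",
                 scaleFactors = "numeric", reasons = "character"))
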