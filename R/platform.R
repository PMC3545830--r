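#' Build matched probeset-transcript pairs for cross-platform comparison
#'
#' Applies the probeset eligibility rules: cross-hybridizing probesets
#' (suffix classes _s, _x, _a) are removed, as are probesets whose EST
#' match to the transcript catalog has an e-value above zero; probesets
#' referencing transcripts absent from the expression matrix are dropped
#' with a warning. When several eligible probesets match one transcript,
#' the probeset whose 4-stage intensity pattern has the highest Spearman
#' correlation with the transcript's log2(RPKM + 1) pattern is kept (ties
#' break to the first probeset id in sort order).
#'
#' @param probesets data.frame from [generateProbesets()] or equivalent:
#'   probeset_id, suffix_class, transcript_id, evalue, and one intensity
#'   column per stage (log2 scale unless \code{log2Transform = TRUE}).
#' @param x a [BerryExpressionSet-class] or RPKM matrix.
#' @param log2Transform set TRUE when intensities arrive on a linear
#'   scale.
#' @return data.frame with transcript_id, probeset_id, then
#'   \code{intensity.<stage>} and \code{logrpkm.<stage>} columns.
#' @export
buildMatchedPairs <- function(probesets, x, log2Transform = FALSE) {
  if (is(x, "BerryExpressionSet")) x <- rpkm(x)
  stages <- colnames(x)
  ok <- !(probesets$suffix_class %in% c("_s", "_x", "_a")) &
    probesets$evalue == 0
  ps <- probesets[ok, , drop = FALSE]
  unknown <- !(ps$transcript_id %in% rownames(x))
  if (any(unknown)) {
    warning(sum(unknown), " probeset(s) reference transcripts absent",
            " from the expression matrix and were dropped")
    ps <- ps[!unknown, , drop = FALSE]
  }
  I <- as.matrix(ps[, stages, drop = FALSE])
  if (log2Transform) I <- log2(I)
  R <- log2(x[ps$transcript_id, , drop = FALSE] + 1)
  # best-correlating probeset per transcript
  ord <- order(ps$transcript_id, ps$probeset_id)
  ps <- ps[ord, , drop = FALSE]; I <- I[ord, , drop = FALSE]
  R <- R[ord, , drop = FALSE]
  rho <- vapply(seq_len(nrow(ps)), function(i)
    suppressWarnings(cor(I[i, ], R[i, ], method = "spearman")),
    numeric(1))
  rho[is.na(rho)] <- -Inf
  keep <- unlist(lapply(split(seq_len(nrow(ps)), ps$transcript_id),
                        function(ii) ii[which.max(rho[ii])]),
                 use.names = FALSE)
  out <- data.frame(transcript_id = ps$transcript_id[keep],
                    probeset_id = ps$probeset_id[keep],
                    stringsAsFactors = FALSE)
  Io <- I[keep, , drop = FALSE]; Ro <- R[keep, , drop = FALSE]
  colnames(Io) <- paste0("intensity.", stages)
  colnames(Ro) <- paste0("logrpkm.", stages)
  cbind(out, Io, Ro)
}

.pairMatrices <- function(pairs) {
  list(I = as.matrix(pairs[, grep("^intensity\\.", colnames(pairs)),
                           drop = FALSE]),
       R = as.matrix(pairs[, grep("^logrpkm\\.", colnames(pairs)),
                           drop = FALSE]))
}

#' Flag pairs as expressed on each platform
#'
#' A pair is expressed on the array side when its mean log2 intensity
#' across stages is at least the \code{intensityPercentile} threshold
#' recomputed from the supplied data (default the 25th percentile — the
#' printed normalised-intensity value of 4.0 is array-specific and never
#' hard-coded), and expressed on the RNA-Seq side when its mean RPKM is
#' at least \code{rpkmFloor} (default 0.5). Boundary values are included.
#'
#' @param pairs output of [buildMatchedPairs()].
#' @param intensityPercentile percentile defining the intensity floor.
#' @param rpkmFloor RNA-Seq expression floor (RPKM units).
#' @return \code{pairs} with logical columns expressed_intensity and
#'   expressed_rnaseq; the intensity threshold is attached as attribute
#'   \code{"intensityThreshold"}.
#' @export
applyExpressionFloors <- function(pairs, intensityPercentile = 0.25,
                                  rpkmFloor = 0.5) {
  m <- .pairMatrices(pairs)
  meanI <- rowMeans(m$I)
  thr <- unname(quantile(meanI, intensityPercentile))
  meanRPKM <- rowMeans(2^m$R - 1)
  pairs$expressed_intensity <- meanI >= thr
  pairs$expressed_rnaseq <- meanRPKM >= rpkmFloor
  attr(pairs, "intensityThreshold") <- thr
  pairs
}

#' Per-stage global Spearman correlation between platforms
#'
#' Computes, per developmental stage, the Spearman rank correlation
#' (average ranks on ties) between log2 intensity and log2(RPKM + 1) over
#' the retained pairs, and their arithmetic mean across the four stages.
#'
#' @param pairs matched pairs; if expression flags are present and
#'   \code{expressedOnly} is TRUE, only pairs expressed on both platforms
#'   enter the correlation.
#' @param expressedOnly restrict to doubly-expressed pairs.
#' @return list(perStage = named numeric, mean = numeric).
#' @export
globalStageCorrelation <- function(pairs, expressedOnly = TRUE) {
  if (expressedOnly && "expressed_intensity" %in% colnames(pairs))
    pairs <- pairs[pairs$expressed_intensity & pairs$expressed_rnaseq, ,
                   drop = FALSE]
  if (nrow(pairs) < 3)
    stop("fewer than 3 retained pairs; cannot estimate correlation")
  m <- .pairMatrices(pairs)
  stages <- sub("^intensity\\.", "", colnames(m$I))
  rho <- vapply(seq_along(stages), function(s)
    cor(m$I[, s], m$R[, s], method = "spearman"), numeric(1))
  names(rho) <- stages
  list(perStage = rho, mean = mean(rho))
}

#' Per-transcript pattern correlation and histogram bins
#'
#' For each retained pair, the Spearman correlation between the 4-stage
#' intensity pattern and the 4-stage log2(RPKM + 1) pattern; counts are
#' reported per threshold bin (default bins bounded at 0.9, 0.6, 0.3, 0,
#' -0.3, -0.6, -0.9, each bin closed at its upper bound except the top
#' bin which includes 1). A pattern constant on either platform has no
#' defined rank correlation and is counted in a reserved "undefined" bin.
#'
#' @param pairs matched pairs (see [globalStageCorrelation()]).
#' @param thresholds decreasing bin boundaries within (-1, 1).
#' @param expressedOnly restrict to doubly-expressed pairs.
#' @return list(rho = named per-transcript correlations (NA when
#'   undefined), counts = named integer vector per bin plus "undefined",
#'   fraction_ge_0.9, fraction_ge_0.6).
#' @export
patternCorrelationHistogram <- function(pairs,
    thresholds = c(0.9, 0.6, 0.3, 0, -0.3, -0.6, -0.9),
    expressedOnly = TRUE) {
  if (expressedOnly && "expressed_intensity" %in% colnames(pairs))
    pairs <- pairs[pairs$expressed_intensity & pairs$expressed_rnaseq, ,
                   drop = FALSE]
  m <- .pairMatrices(pairs)
  rho <- vapply(seq_len(nrow(pairs)), function(i) {
    if (stats::sd(m$I[i, ]) == 0 || stats::sd(m$R[i, ]) == 0)
      return(NA_real_)
    cor(m$I[i, ], m$R[i, ], method = "spearman")
  }, numeric(1))
  names(rho) <- pairs$transcript_id
  br <- c(1, sort(thresholds, decreasing = TRUE), -1)
  labs <- c(paste0(">=", br[2]),
            paste0("[", br[-c(1, 2)], ",", br[-c(1, length(br))], ")"))
  bin <- cut(rho, breaks = rev(br), right = FALSE,
             include.lowest = TRUE, labels = rev(labs))
  counts <- table(factor(bin, levels = labs))
  counts <- c(as.integer(counts),
              undefined = sum(is.na(rho)))
  names(counts)[seq_along(labs)] <- labs
  list(rho = rho, counts = counts,
       fraction_ge_0.9 = mean(rho >= 0.9, na.rm = TRUE),
       fraction_ge_0.6 = mean(rho >= 0.6, na.rm = TRUE))
}
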