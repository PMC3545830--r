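#' Floored fold change between two RPKM values
#'
#' Both numerator and denominator are clamped upwards to \code{floor}
#' (default 0.1 RPKM) before taking the ratio, so that values approaching
#' zero cannot produce unrealistically large fold changes: the pair
#' (1.00, 0.02) is a 10-fold increase, not a 50-fold one.
#'
#' @param a,b nonnegative RPKM values (vectorized).
#' @param floor low-expression floor (default 0.1).
#' @return \code{pmax(a, floor) / pmax(b, floor)}.
#' @export
#' @examples
#' flooredFoldChange(1.00, 0.02)  # 10
flooredFoldChange <- function(a, b, floor = 0.1) {
  if (any(a < 0) || any(b < 0)) stop("RPKM values must be nonnegative")
  pmax(a, floor) / pmax(b, floor)
}

.foldBin <- function(f, minFold = 3) {
  out <- rep("none", length(f))
  out[f >= minFold] <- "3-10"
  out[f >= 10] <- "10-50"
  out[f >= 50] <- ">50"
  out
}

.stageCallNames <- c("young", "early_veraison", "late_veraison", "ripe")

#' Stage-specific up-regulation calls
#'
#' For each transcript, computes the floored fold change of every stage
#' against each of the other three; the transcript is called specific to
#' stage s iff the minimum of its three folds against the other stages is
#' at least \code{minFold} (default 3). At most one stage can satisfy this
#' (mutually exclusive by construction). The fold magnitude binned is the
#' conservative minimum versus all other stages, into [3, 10), [10, 50)
#' and [50, Inf).
#'
#' @param x a [BerryExpressionSet-class] or an RPKM matrix with the four
#'   stages as columns (EL31, EL35, EL36, EL38 order).
#' @param minFold call threshold, inclusive (default 3).
#' @param floor fold-change floor passed to [flooredFoldChange()].
#' @return data.frame: transcript_id, call (young / early_veraison /
#'   late_veraison / ripe / none), min_fold_vs_others, bin.
#' @export
#' @examples
#' m <- matrix(c(125.18, 0.51, 0.76, 0.35), 1,
#'             dimnames = list("t", berryStages()))
#' stageSpecificCalls(m)  # young, bin >50
stageSpecificCalls <- function(x, minFold = 3, floor = 0.1) {
  if (is(x, "BerryExpressionSet")) x <- rpkm(x)
  if (ncol(x) != 4L) stop("exactly 4 stages required")
  f <- pmax(x, floor)
  n <- nrow(x)
  call <- rep("none", n)
  minfold <- numeric(n)
  for (s in 1:4) {
    others <- setdiff(1:4, s)
    folds <- f[, s] / f[, others, drop = FALSE]
    mf <- do.call(pmin, as.data.frame(folds))
    hit <- mf >= minFold
    call[hit] <- .stageCallNames[s]
    minfold[hit] <- mf[hit]
  }
  data.frame(transcript_id = rownames(x), call = call,
             min_fold_vs_others = minfold,
             bin = ifelse(call == "none", "none", .foldBin(minfold, minFold)),
             stringsAsFactors = FALSE)
}

#' Joint veraison up-regulation calls
#'
#' Flags transcripts specifically up-regulated at both veraison
#' time-points: the floored fold changes of EL35 versus EL31, EL35 versus
#' EL38, EL36 versus EL31 and EL36 versus EL38 must all be at least
#' \code{minFold} (inclusive). The binned magnitude is the minimum of the
#' four folds.
#'
#' @inheritParams stageSpecificCalls
#' @return data.frame: transcript_id, flagged (logical), min_fold, bin.
#' @export
veraisonCalls <- function(x, minFold = 3, floor = 0.1) {
  if (is(x, "BerryExpressionSet")) x <- rpkm(x)
  if (ncol(x) != 4L) stop("exactly 4 stages required")
  f <- pmax(x, floor)
  folds <- cbind(f[, 2] / f[, 1], f[, 2] / f[, 4],
                 f[, 3] / f[, 1], f[, 3] / f[, 4])
  mf <- do.call(pmin, as.data.frame(folds))
  flagged <- mf >= minFold
  data.frame(transcript_id = rownames(x), flagged = flagged,
             min_fold = mf,
             bin = ifelse(flagged, .foldBin(mf, minFold), "none"),
             stringsAsFactors = FALSE)
}
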