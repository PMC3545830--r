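#' Scale-and-centre normalization of 4-stage profiles
#'
#' Prepares RPKM profiles for clustering in three steps, in this order:
#' (1) rows with all four RPKM below \code{rpkmFloor} are discarded
#' ("all_low"); (2) each remaining row is multiplied by a scale factor
#' such that the sum of squares of its four values is exactly 1, then
#' centred to mean zero by subtracting the row mean (centring breaks the
#' unit sum of squares, which therefore holds for the \code{scaled} slot);
#' (3) rows whose normalized max minus min is below \code{minRange} are
#' discarded ("low_range"). Scaling and centring are amplitude-invariant,
#' so transcripts sharing a shape land on the same normalized point
#' regardless of expression level.
#'
#' @param x a [BerryExpressionSet-class] or RPKM matrix (4 columns).
#' @param rpkmFloor all-stage discard threshold (default 0.5).
#' @param minRange minimum normalized range to keep (default 0.5).
#' @param rangeOn compute the range filter on the "centered" values
#'   (default; centring only shifts, so this equals the scaled range) or
#'   on the "raw" RPKM row.
#' @return A [NormalizedProfiles-class].
#' @export
#' @examples
#' normalizeProfiles(matrix(c(3, 0, 0, 0), 1,
#'                   dimnames = list("t", berryStages())))
normalizeProfiles <- function(x, rpkmFloor = 0.5, minRange = 0.5,
                              rangeOn = c("centered", "raw")) {
  rangeOn <- match.arg(rangeOn)
  if (is(x, "BerryExpressionSet")) x <- rpkm(x)
  if (ncol(x) != 4L) stop("exactly 4 stages required")
  if (is.null(rownames(x))) rownames(x) <- seq_len(nrow(x))
  reasons <- setNames(rep("kept", nrow(x)), rownames(x))
  all_low <- apply(x, 1, max) < rpkmFloor
  reasons[all_low] <- "all_low"
  surv <- x[!all_low, , drop = FALSE]
  ss <- sqrt(rowSums(surv^2))
  if (any(ss == 0))
    stop("zero row survived the all-low filter; inputs must be nonnegative")
  sf <- 1 / ss
  scaled <- surv * sf
  centered <- scaled - rowMeans(scaled)
  rng <- if (rangeOn == "centered")
    apply(centered, 1, function(r) diff(range(r)))
  else apply(surv, 1, function(r) diff(range(r)))
  low_range <- rng < minRange
  reasons[rownames(surv)[low_range]] <- "low_range"
  new("NormalizedProfiles",
      normalized = centered[!low_range, , drop = FALSE],
      scaled = scaled[!low_range, , drop = FALSE],
      scaleFactors = sf[!low_range],
      reasons = reasons)
}

# squared Euclidean distances between rows of X (n x d) and C (k x d)
.dist2 <- function(X, C) {
  outer(rowSums(X^2), rep(1, nrow(C))) +
    outer(rep(1, nrow(X)), rowSums(C^2)) - 2 * X %*% t(C)
}

# one Lloyd run from given initial centers; returns assignment, objective
# and the per-iteration objective trace (non-increasing by construction)
.lloyd <- function(X, C, maxIter = 100L) {
  n <- nrow(X)
  assign_prev <- integer(n)
  trace <- numeric(0)
  for (it in seq_len(maxIter)) {
    D <- .dist2(X, C)
    a <- max.col(-D, ties.method = "first")
    for (j in seq_len(nrow(C))) {
      idx <- a == j
      if (!any(idx)) {
        # empty cluster: re-seed with the point farthest from its centroid
        far <- which.max(D[cbind(seq_len(n), a)])
        C[j, ] <- X[far, ]
        a[far] <- j
      } else C[j, ] <- colMeans(X[idx, , drop = FALSE])
    }
    trace <- c(trace, sum((X - C[a, , drop = FALSE])^2))
    if (identical(a, assign_prev)) break
    assign_prev <- a
  }
  # final centroids as cluster means, objective = within-cluster SS
  for (j in seq_len(nrow(C))) {
    idx <- a == j
    if (any(idx)) C[j, ] <- colMeans(X[idx, , drop = FALSE])
  }
  obj <- sum((X - C[a, , drop = FALSE])^2)
  list(assign = a, centers = C, objective = obj, trace = trace)
}

#' k-means with a run-stability criterion
#'
#' Runs Lloyd's k-means \code{nRuns} times, each from a fresh uniform
#' random draw of k distinct profiles as initial centres, and reports the
#' solution with the lowest within-cluster sum of squared Euclidean
#' distances together with the number of runs that reached the same
#' objective (relative tolerance 1e-8) — the "result found N times"
#' stability record. A warning (not an error) is raised when the best
#' solution was found fewer than \code{requiredRepeats} times.
#'
#' @param profiles a [NormalizedProfiles-class] or a numeric matrix of
#'   profiles in rows.
#' @param k number of clusters (default 20).
#' @param nRuns random restarts (default 1000).
#' @param requiredRepeats stability requirement on the reported solution
#'   (default 3).
#' @param seed optional integer seed for reproducible restarts.
#' @param maxIter Lloyd iteration cap per run.
#' @return A [ClusterResult-class].
#' @export
kmeansStable <- function(profiles, k = 20L, nRuns = 1000L,
                         requiredRepeats = 3L, seed = NULL,
                         maxIter = 100L) {
  X <- if (is(profiles, "NormalizedProfiles")) profiles@normalized
       else as.matrix(profiles)
  n <- nrow(X)
  if (n < k)
    stop("fewer profiles (", n, ") than clusters (", k, ")")
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  objectives <- numeric(nRuns)
  for (r in seq_len(nRuns)) {
    C0 <- X[sample.int(n, k), , drop = FALSE]
    fit <- .lloyd(X, C0, maxIter = maxIter)
    objectives[r] <- fit$objective
    if (is.null(best) || fit$objective < best$objective -
        1e-8 * max(1, abs(best$objective)))
      best <- fit
  }
  tol <- 1e-8 * max(1, abs(best$objective))
  found <- sum(abs(objectives - best$objective) <= tol)
  if (found < requiredRepeats)
    warning("best clustering found only ", found, " of ", nRuns,
            " runs (required ", requiredRepeats, ")")
  res <- new("ClusterResult", k = as.integer(k),
             assignments = setNames(as.integer(best$assign), rownames(X)),
             centroids = best$centers, nRuns = as.integer(nRuns),
             bestObjective = best$objective, timesFound = as.integer(found),
             archetypeLabels = character(0))
  res
}

#' Label cluster centroids with archetype names
#'
#' Each centroid is compared with every template (normalized by the same
#' scale-and-centre procedure as the profiles) by Pearson correlation and
#' receives the best-correlating template's name if that correlation is at
#' least \code{minCor} (default 0.8), otherwise "unlabeled". Exact ties
#' break deterministically to the alphabetically first template name;
#' labels need not be unique across clusters.
#'
#' @param result a [ClusterResult-class].
#' @param templates named list of nonnegative 4-vectors (default
#'   [berryArchetypes()]).
#' @param minCor label acceptance threshold.
#' @return The result with \code{archetypeLabels(result)} filled.
#' @export
labelArchetypes <- function(result, templates = berryArchetypes(),
                            minCor = 0.8) {
  if (!length(templates)) stop("template set must be non-empty")
  templates <- templates[order(names(templates))]
  Tm <- t(vapply(templates, function(v) {
    s <- v / sqrt(sum(v^2)); s - mean(s)
  }, numeric(4)))
  labels <- vapply(seq_len(result@k), function(j) {
    ce <- result@centroids[j, ]
    if (stats::sd(ce) == 0) return("unlabeled")
    cc <- apply(Tm, 1, function(t) cor(ce, t))
    i <- which.max(cc)  # ties: first in alphabetical template order
    if (cc[i] >= minCor) rownames(Tm)[i] else "unlabeled"
  }, character(1))
  result@archetypeLabels <- labels
  result
}
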