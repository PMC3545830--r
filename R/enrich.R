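#' Hypergeometric GO term enrichment of one cluster
#'
#' For every GO term annotated to at least one transcript of the cluster,
#' computes the upper-tail hypergeometric probability of observing at
#' least the cluster's count among \code{n_cluster} draws from a
#' background of \code{N_bg} transcripts of which \code{K_bg} carry the
#' term (one-sided enrichment; equivalently Fisher's exact test on the
#' enrichment side), then adjusts across all tested terms of the cluster
#' with Benjamini-Hochberg.
#'
#' @param clusterTranscripts character vector of transcript ids in the
#'   cluster (must all be in \code{background}).
#' @param background character vector: the whole-catalog transcript
#'   universe.
#' @param annotation data.frame with columns transcript_id, term_id.
#' @param clusterId optional label recorded in the result.
#' @return data.frame: cluster_id, term_id, k_in, n_cluster, K_bg, N_bg,
#'   p_value, fdr — ordered by p-value.
#' @export
enrichCluster <- function(clusterTranscripts, background, annotation,
                          clusterId = NA) {
  extra <- setdiff(clusterTranscripts, background)
  if (length(extra))
    stop("cluster transcripts absent from background, e.g. ", extra[1])
  N <- length(background)
  n <- length(clusterTranscripts)
  ann <- annotation[annotation$transcript_id %in% background, , drop = FALSE]
  K_all <- table(ann$term_id)
  in_cl <- ann[ann$transcript_id %in% clusterTranscripts, , drop = FALSE]
  k_all <- table(in_cl$term_id)
  terms <- names(k_all)
  if (!length(terms))
    return(data.frame(cluster_id = character(0), term_id = character(0),
                      k_in = integer(0), n_cluster = integer(0),
                      K_bg = integer(0), N_bg = integer(0),
                      p_value = numeric(0), fdr = numeric(0)))
  k <- as.integer(k_all[terms])
  K <- as.integer(K_all[terms])
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  fdr <- p.adjust(p, method = "BH")
  out <- data.frame(cluster_id = clusterId, term_id = terms,
                    k_in = k, n_cluster = n, K_bg = K, N_bg = N,
                    p_value = p, fdr = fdr, stringsAsFactors = FALSE)
  out[order(out$p_value, out$term_id), , drop = FALSE]
}

#' Enrichment of every cluster in a ClusterResult
#'
#' @param result a [ClusterResult-class] (or a named cluster-assignment
#'   vector).
#' @param background,annotation as in [enrichCluster()].
#' @return Row-bound [enrichCluster()] results with cluster_id set.
#' @export
enrichClusters <- function(result, background, annotation) {
  a <- if (is(result, "ClusterResult")) clusterAssignments(result) else result
  do.call(rbind, lapply(sort(unique(a)), function(j)
    enrichCluster(names(a)[a == j], background, annotation, clusterId = j)))
}

#' Aggregate enriched terms into group-significance scores
#'
#' Keeps terms with FDR at most \code{fdrCutoff} (default 0.05), maps each
#' to its biological-process group, and scores every group as the sum over
#' member terms of \code{100 * (-log10 FDR)}: a single enriched term at
#' FDR 0.01 gives 200, at FDR 1e-10 gives 1000. FDR values underflowing
#' to zero are clamped to 1e-300 before the logarithm. Terms without a
#' group mapping are reported under the reserved group "ungrouped".
#'
#' @param termResults data.frame from [enrichCluster()] /
#'   [enrichClusters()] (needs term_id and fdr; cluster_id honoured when
#'   present).
#' @param termGroups data.frame with columns term_id, group_id.
#' @param fdrCutoff inclusion threshold (inclusive).
#' @return data.frame: (cluster_id,) group_id, n_subterms, value,
#'   member_terms (";"-separated), ordered by decreasing value.
#' @export
#' @examples
#' tr <- data.frame(term_id = "GO:1", fdr = 0.01)
#' summarizeGroups(tr, data.frame(term_id = "GO:1", group_id = "g"))$value
summarizeGroups <- function(termResults, termGroups, fdrCutoff = 0.05) {
  keep <- termResults[termResults$fdr <= fdrCutoff, , drop = FALSE]
  if (!nrow(keep))
    return(data.frame(group_id = character(0), n_subterms = integer(0),
                      value = numeric(0), member_terms = character(0)))
  g <- termGroups$group_id[match(keep$term_id, termGroups$term_id)]
  g[is.na(g)] <- "ungrouped"
  keep$group_id <- g
  keep$score <- 100 * (-log10(pmax(keep$fdr, 1e-300)))
  byCluster <- "cluster_id" %in% colnames(keep) && !all(is.na(keep$cluster_id))
  key <- if (byCluster) interaction(keep$cluster_id, keep$group_id, drop = TRUE)
         else keep$group_id
  rows <- lapply(split(keep, key), function(d) {
    out <- data.frame(group_id = d$group_id[1],
                      n_subterms = nrow(d),
                      value = sum(d$score),
                      member_terms = paste(sort(d$term_id), collapse = ";"),
                      stringsAsFactors = FALSE)
    if (byCluster) out <- cbind(cluster_id = d$cluster_id[1], out)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(-out$value), , drop = FALSE]
}
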