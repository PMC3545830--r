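#' Pipeline configuration
#'
#' Collects every tunable constant of the analysis in one audited place.
#' Defaults are the thresholds used throughout berry-development RNA-Seq
#' analysis at this design: detection floor 0.5 RPKM with 5 unique reads,
#' fold floor 0.1 RPKM, 3-fold call threshold, k = 20 clusters over 1000
#' restarts with a 3-repeat stability requirement, FDR cutoff 0.05, and a
#' cross-platform RPKM floor of 0.5.
#'
#' @param nTranscripts,nGoTerms,archetypeFractions,noiseSd,platformRho
#'   synthetic catalog parameters (see [generateCatalog()]).
#' @param readsPerStage,multimapRate,qcFailRate alignment simulation
#'   parameters (see [generateAlignments()]).
#' @param crosshybFraction probeset simulation parameter.
#' @param minReadLength,maxAmbiguous read QC thresholds.
#' @param minIdentity,minAlignedFraction alignment acceptance thresholds.
#' @param rpkmFloor,minUnique detection thresholds.
#' @param foldFloor,minFold fold-change parameters.
#' @param k,nRuns,requiredRepeats clustering parameters.
#' @param fdrCutoff enrichment inclusion threshold.
#' @param seed master seed for the run.
#' @param outDir output directory.
#' @return A validated list of class "BerryConfig".
#' @export
berryConfig <- function(nTranscripts = 2000L, nGoTerms = 200L,
                        archetypeFractions = defaultArchetypeFractions(),
                        noiseSd = 0.05, platformRho = 0.7,
                        readsPerStage = 50000L, multimapRate = 0.15,
                        qcFailRate = 0.08, crosshybFraction = 0.15,
                        minReadLength = 60L, maxAmbiguous = 2L,
                        minIdentity = 0.98, minAlignedFraction = 0.5,
                        rpkmFloor = 0.5, minUnique = 5L,
                        foldFloor = 0.1, minFold = 3,
                        k = 20L, nRuns = 1000L, requiredRepeats = 3L,
                        fdrCutoff = 0.05, seed = 1L,
                        outDir = tempfile("berryseq_run_")) {
  cfg <- as.list(environment())
  pos <- c("minReadLength", "minIdentity", "minAlignedFraction",
           "rpkmFloor", "minUnique", "foldFloor", "minFold", "k",
           "nRuns", "requiredRepeats", "fdrCutoff")
  bad <- pos[vapply(pos, function(p) cfg[[p]] <= 0, logical(1))]
  if (length(bad))
    stop("thresholds must be positive: ", paste(bad, collapse = ", "))
  structure(cfg, class = "BerryConfig")
}

#' Run the full synthetic pipeline
#'
#' Executes simulate, quantify, classify, cluster, enrich and compare in
#' sequence, writes every stage's tabular output under
#' \code{config$outDir}, and returns a machine-readable manifest: the
#' output paths plus summary statistics (abundance-bin counts, per-stage
#' stage-specific call counts, veraison call count, cluster sizes and
#' stability, top group scores, and the cross-platform correlation
#' summary).
#'
#' @param config a [berryConfig()].
#' @param verbose log stage progress with [message()].
#' @return The manifest (list with elements files, summary, config,
#'   seed); the summary is also written as JSON next to the tables.
#' @export
runPipeline <- function(config = berryConfig(), verbose = TRUE) {
  if (!inherits(config, "BerryConfig")) stop("config must be a BerryConfig")
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(config$outDir))
    stop("cannot create output directory ", config$outDir)
  say <- function(...) if (verbose)
    message(format(Sys.time(), "%H:%M:%S"), " | ", ...)
  fp <- function(f) file.path(config$outDir, f)
  files <- list()

  say("simulate: catalog of ", config$nTranscripts, " transcripts")
  gen <- generateCatalog(config$nTranscripts, config$nGoTerms,
                         config$archetypeFractions, config$noiseSd,
                         platformRho = config$platformRho,
                         seed = config$seed)
  sim <- generateAlignments(gen$truth, gen$catalog, config$readsPerStage,
                            config$multimapRate, config$qcFailRate,
                            seed = config$seed + 1L)
  probes <- generateProbesets(gen$truth, gen$catalog,
                              config$crosshybFraction, seed = config$seed + 2L)
  writeCatalogFasta(gen$catalog, fp("catalog.fasta"), fp("catalog.tsv"),
                    seed = config$seed)
  writeBerryTable(sim$reads, fp("reads.tsv"))
  writeBerryTable(sim$alignments, fp("alignments.tsv"))
  writeBerryTable(probes, fp("probesets.tsv"))
  writeBerryTable(gen$annotation, fp("annotation.tsv"))
  writeBerryTable(gen$termGroups, fp("term_groups.tsv"))
  files[c("catalog_fasta", "catalog", "reads", "alignments", "probesets",
          "annotation", "term_groups")] <-
    lapply(c("catalog.fasta", "catalog.tsv", "reads.tsv", "alignments.tsv",
             "probesets.tsv", "annotation.tsv", "term_groups.tsv"), fp)

  say("quantify: ", nrow(sim$reads), " reads")
  se <- quantifyStages(sim$reads, sim$alignments, gen$catalog,
                       config$minReadLength, config$maxAmbiguous,
                       config$minIdentity, config$minAlignedFraction)
  expr <- data.frame(transcript_id = rownames(rpkm(se)), rpkm(se),
                     check.names = FALSE)
  writeBerryTable(expr, fp("rpkm.tsv"))
  files$rpkm <- fp("rpkm.tsv")
  bins <- abundanceBins(se, rpkmFloor = config$rpkmFloor,
                        minUnique = config$minUnique)

  say("diffexpr: stage-specific calls")
  calls <- stageSpecificCalls(se, config$minFold, config$foldFloor)
  ver <- veraisonCalls(se, config$minFold, config$foldFloor)
  writeBerryTable(calls, fp("stage_calls.tsv"))
  writeBerryTable(ver, fp("veraison_calls.tsv"))
  files$stage_calls <- fp("stage_calls.tsv")
  files$veraison_calls <- fp("veraison_calls.tsv")

  say("cluster: k = ", config$k, ", ", config$nRuns, " runs")
  prof <- normalizeProfiles(se, rpkmFloor = config$rpkmFloor)
  res <- kmeansStable(prof, k = config$k, nRuns = config$nRuns,
                      requiredRepeats = config$requiredRepeats,
                      seed = config$seed + 3L)
  res <- labelArchetypes(res)
  asg <- clusterAssignments(res)
  writeBerryTable(data.frame(transcript_id = names(asg), cluster = asg,
                             archetype = archetypeLabels(res)[asg],
                             stringsAsFactors = FALSE),
                  fp("clusters.tsv"))
  files$clusters <- fp("clusters.tsv")

  say("enrich: GO terms per cluster")
  enr <- enrichClusters(res, gen$catalog$transcript_id, gen$annotation)
  groups <- summarizeGroups(enr, gen$termGroups, config$fdrCutoff)
  writeBerryTable(enr, fp("enrichment.tsv"))
  writeBerryTable(groups, fp("group_scores.tsv"))
  files$enrichment <- fp("enrichment.tsv")
  files$group_scores <- fp("group_scores.tsv")

  say("compare: cross-platform correlation")
  pairs <- buildMatchedPairs(probes, se)
  pairs <- applyExpressionFloors(pairs, rpkmFloor = config$rpkmFloor)
  gc_ <- globalStageCorrelation(pairs)
  hist_ <- patternCorrelationHistogram(pairs)
  writeBerryTable(pairs, fp("matched_pairs.tsv"))
  files$matched_pairs <- fp("matched_pairs.tsv")

  summary <- list(
    total_reads = nrow(sim$reads),
    abundance_bins = as.data.frame.matrix(as.data.frame(bins)),
    detected = attr(bins, "detected"),
    stage_call_counts = table(calls$call),
    veraison_flagged = sum(ver$flagged),
    profiles_kept = nrow(prof@normalized),
    cluster_sizes = tabulate(asg, config$k),
    times_found = timesFound(res),
    top_group_scores = head(groups, 10),
    correlation = list(per_stage = gc_$perStage, mean = gc_$mean,
                       pattern_counts = hist_$counts))
  jsonlite::write_json(summary, fp("summary.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  files$summary <- fp("summary.json")
  say("done: outputs in ", config$outDir)
  manifest <- list(files = files, summary = summary, config = config,
                   seed = config$seed)
  invisible(manifest)
}
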