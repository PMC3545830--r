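#' Default archetype fractions for synthetic catalogs
#'
#' Each of the ten archetypes receives 5\% of the catalog, leaving half the
#' transcripts flat, which mirrors the rough proportion of developmentally
#' regulated transcripts surviving the range filter in a berry time course.
#'
#' @return Named numeric vector summing to 0.5.
#' @export
defaultArchetypeFractions <- function()
  setNames(rep(0.05, 10L), names(berryArchetypes()))

#' Generate a synthetic transcript catalog with known ground truth
#'
#' Builds a catalog of transcripts whose 4-stage expression follows one of
#' the ten named archetype shapes (see [berryArchetypes()]) or a flat
#' background profile, together with GO annotation carrying planted
#' enrichment, probeset links for the cross-platform comparison, and the
#' full ground truth needed for parameter-recovery tests.
#'
#' Per-transcript true RPKM is \code{amplitude * template * exp(noise)}
#' with log-normal amplitudes (meanlog log(20), sdlog 1) and multiplicative
#' log-normal noise of standard deviation \code{noiseSd} per stage. For
#' each archetype one GO term is planted into 50\% of its members (at
#' least 5) and into \code{backgroundTermRate} of all other transcripts;
#' every transcript additionally draws Poisson(2) background terms. Terms
#' are partitioned into groups of five to emulate a term-to-process map.
#'
#' @param nTranscripts number of transcripts (>= 50).
#' @param nGoTerms size of the GO term pool.
#' @param archetypeFractions named fractions per archetype; must sum to at
#'   most 1, the remainder is flat background.
#' @param noiseSd standard deviation of per-stage log-normal expression
#'   noise (default 0.05).
#' @param probesetCoverage fraction of transcripts linked to a probeset.
#' @param backgroundTermRate rate at which a planted term appears outside
#'   its archetype.
#' @param platformRho target Spearman correlation between probeset
#'   intensity and log2(RPKM + 1), recorded in the truth and used by
#'   [generateProbesets()].
#' @param seed integer seed; identical seeds give identical output.
#' @return List with elements \code{catalog} (data.frame: transcript_id,
#'   length, go_terms (";"-separated), probeset_id, archetype),
#'   \code{annotation} (long data.frame transcript_id/term_id),
#'   \code{termGroups} (data.frame term_id/group_id) and \code{truth}
#'   (list: true_rpkm matrix, archetype_assignments, enriched_terms,
#'   platform_rho, noise_sd).
#' @export
#' @examples
#' cat1 <- generateCatalog(100, seed = 1)
#' table(cat1$catalog$archetype)
generateCatalog <- function(nTranscripts, nGoTerms = 200L,
                            archetypeFractions = defaultArchetypeFractions(),
                            noiseSd = 0.05, probesetCoverage = 0.85,
                            backgroundTermRate = 0.05, platformRho = 0.7,
                            seed = 1L) {
  if (nTranscripts < 50L)
    stop("nTranscripts must be at least 50")
  if (length(archetypeFractions) &&
      is.null(names(archetypeFractions)))
    stop("archetypeFractions must be named")
  unknown <- setdiff(names(archetypeFractions), names(berryArchetypes()))
  if (length(unknown))
    stop("unknown archetypes: ", paste(unknown, collapse = ", "))
  if (sum(archetypeFractions) > 1 + 1e-12)
    stop("archetypeFractions must sum to at most 1")
  set.seed(seed)

  ids <- sprintf("TX_%05d", seq_len(nTranscripts))
  lengths <- as.integer(
    pmin(pmax(round(rlnorm(nTranscripts, log(1500), 0.4)), 300), 8000))

  counts <- floor(nTranscripts * archetypeFractions)
  arch <- rep("flat", nTranscripts)
  pos <- 1L
  for (a in names(counts)) {
    if (counts[[a]] > 0L) {
      arch[pos:(pos + counts[[a]] - 1L)] <- a
      pos <- pos + counts[[a]]
    }
  }

  templates <- berryArchetypes()
  stages <- berryStages()
  amp <- rlnorm(nTranscripts, log(20), 1)
  base <- t(vapply(arch, function(a) {
    if (a == "flat") rep(1, 4) else templates[[a]]
  }, numeric(4)))
  noise <- matrix(exp(rnorm(4L * nTranscripts, 0, noiseSd)),
                  nrow = nTranscripts)
  true_rpkm <- amp * base * noise
  dimnames(true_rpkm) <- list(ids, stages)

  terms <- sprintf("GO:%07d", seq_len(nGoTerms))
  planted_names <- as.character(names(counts)[counts > 0L])
  if (length(planted_names) > nGoTerms)
    stop("nGoTerms too small for the number of planted archetypes")
  planted <- setNames(terms[seq_along(planted_names)], planted_names)

  ann_t <- vector("list", 3L)
  # planted terms: >= 5 members of the archetype, plus background leakage
  planted_rows <- lapply(planted_names, function(a) {
    members <- ids[arch == a]
    n_in <- max(5L, round(0.5 * length(members)))
    n_in <- min(n_in, length(members))
    inside <- sample(members, n_in)
    outside <- ids[arch != a]
    leak <- outside[runif(length(outside)) < backgroundTermRate]
    data.frame(transcript_id = c(inside, leak),
               term_id = planted[[a]], stringsAsFactors = FALSE)
  })
  # background annotation: Poisson(2) terms per transcript from the rest
  bg_pool <- setdiff(terms, planted)
  n_bg <- rpois(nTranscripts, 2)
  bg_rows <- data.frame(
    transcript_id = rep(ids, n_bg),
    term_id = sample(bg_pool, sum(n_bg), replace = TRUE),
    stringsAsFactors = FALSE)
  annotation <- unique(rbind(do.call(rbind, planted_rows), bg_rows))
  rownames(annotation) <- NULL

  # term -> group map: each planted term gets its own process; background
  # terms are chunked into groups of five
  grp_bg <- paste0("process_", sprintf("%03d",
                   ceiling(seq_along(bg_pool) / 5)))
  termGroups <- rbind(
    data.frame(term_id = unname(planted),
               group_id = sprintf("process_%s", planted_names),
               stringsAsFactors = FALSE),
    data.frame(term_id = bg_pool, group_id = grp_bg,
               stringsAsFactors = FALSE))

  probeset_id <- rep(NA_character_, nTranscripts)
  has_ps <- runif(nTranscripts) < probesetCoverage
  probeset_id[has_ps] <- sprintf("PS_%05d_at", which(has_ps))

  go_collapsed <- vapply(split(annotation$term_id, annotation$transcript_id),
                         paste, character(1), collapse = ";")
  catalog <- data.frame(
    transcript_id = ids, length = lengths,
    go_terms = unname(go_collapsed[ids]),
    probeset_id = probeset_id, archetype = arch,
    stringsAsFactors = FALSE)
  catalog$go_terms[is.na(catalog$go_terms)] <- ""

  truth <- list(true_rpkm = true_rpkm,
                archetype_assignments = setNames(arch, ids),
                enriched_terms = as.list(planted),
                platform_rho = platformRho,
                noise_sd = noiseSd)
  flat <- true_rpkm[arch == "flat", , drop = FALSE]
  if (nrow(flat) &&
      any(apply(flat, 1, max) / apply(flat, 1, min) >= 3))
    stop("internal: flat profiles must stay within a 3-fold range")
  list(catalog = catalog, annotation = annotation,
       termGroups = termGroups, truth = truth)
}

#' Generate stage-structured reads and alignment candidates
#'
#' Draws reads per stage with expected counts proportional to
#' \code{true_rpkm * length} (multinomial sampling at fixed stage depth)
#' and emits one alignment candidate per read, or 2-4 candidates within a
#' randomly partnered homology group for a \code{multimapRate} fraction of
#' reads. A \code{qcFailRate} fraction of reads violates the read QC rule
#' (trimmed length below 60 nt or more than two ambiguous bases) and a
#' \code{lowQualRate} fraction carries candidates failing the alignment
#' acceptance rule (identity <= 0.98 or aligned fraction <= 0.5), so that
#' downstream filters are exercised.
#'
#' @param truth,catalog output of [generateCatalog()].
#' @param readsPerStage reads drawn per stage (default 50000).
#' @param multimapRate fraction of reads given multiple candidates
#'   (default 0.15: in deep berry data roughly 85\% of accepted reads map
#'   to a single location).
#' @param qcFailRate fraction of reads failing read QC (default 0.08).
#' @param lowQualRate fraction of reads whose candidates fail the
#'   alignment quality thresholds.
#' @param readLength nominal read length before end-trimming (4 nt total).
#' @param seed integer seed.
#' @return List with \code{reads} (data.frame: read_id, length_after_trim,
#'   ambiguous_count, stage) and \code{alignments} (data.frame: read_id,
#'   transcript_id, percent_identity, aligned_fraction).
#' @export
generateAlignments <- function(truth, catalog, readsPerStage = 50000L,
                               multimapRate = 0.15, qcFailRate = 0.08,
                               lowQualRate = 0.02, readLength = 100L,
                               seed = 1L) {
  if (is.null(catalog) || nrow(catalog) == 0L)
    stop("catalog must be non-empty")
  for (r in c(multimapRate, qcFailRate, lowQualRate))
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  set.seed(seed)

  ids <- catalog$transcript_id
  stages <- colnames(truth$true_rpkm)
  trimmed <- readLength - 4L

  # homology groups of size 2-4 covering the catalog
  perm <- sample(ids)
  sizes <- integer(0)
  left <- length(ids)
  while (left > 0L) {
    s <- min(sample(2:4, 1L), left)
    sizes <- c(sizes, s)
    left <- left - s
  }
  group_of <- setNames(rep(seq_along(sizes), sizes), perm)
  members <- split(perm, group_of[perm])

  all_reads <- vector("list", length(stages))
  all_aln <- vector("list", length(stages))
  for (si in seq_along(stages)) {
    s <- stages[si]
    w <- truth$true_rpkm[ids, s] * catalog$length
    n_per_tx <- as.integer(rmultinom(1L, readsPerStage, w / sum(w)))
    src <- rep(ids, n_per_tx)
    n <- length(src)
    rid <- sprintf("%s_r%06d", s, seq_len(n))

    len <- rep(trimmed, n)
    amb <- integer(n)
    fail <- runif(n) < qcFailRate
    short <- fail & runif(n) < 0.5
    len[short] <- sample(30:59, sum(short), replace = TRUE)
    ambig <- fail & !short
    amb[ambig] <- sample(3:5, sum(ambig), replace = TRUE)

    multi <- runif(n) < multimapRate
    # single-candidate reads
    one <- data.frame(read_id = rid[!multi], transcript_id = src[!multi],
                      stringsAsFactors = FALSE)
    # multi-candidate reads: sample 2-4 partners from the homology group
    mm_idx <- which(multi)
    mm <- lapply(mm_idx, function(i) {
      grp <- members[[group_of[[src[i]]]]]
      m <- min(sample(2:4, 1L), length(grp))
      if (m < 2L) return(src[i])  # singleton group: falls back to unique
      c(src[i], sample(setdiff(grp, src[i]), m - 1L))
    })
    mm_df <- data.frame(
      read_id = rep(rid[mm_idx], lengths(mm)),
      transcript_id = unlist(mm, use.names = FALSE),
      stringsAsFactors = FALSE)
    aln <- rbind(one, mm_df)
    na <- nrow(aln)
    aln$percent_identity <- runif(na, 0.985, 1.0)
    aln$aligned_fraction <- runif(na, 0.55, 1.0)

    low <- rid[runif(n) < lowQualRate]
    bad <- aln$read_id %in% low
    flip <- runif(sum(bad)) < 0.5
    aln$percent_identity[bad][flip] <- runif(sum(flip), 0.90, 0.98)
    aln$aligned_fraction[bad][!flip] <- runif(sum(!flip), 0.10, 0.50)

    all_reads[[si]] <- data.frame(
      read_id = rid, length_after_trim = len, ambiguous_count = amb,
      stage = s, stringsAsFactors = FALSE)
    all_aln[[si]] <- aln
  }
  reads <- do.call(rbind, all_reads)
  alignments <- do.call(rbind, all_aln)
  rownames(reads) <- rownames(alignments) <- NULL
  list(reads = reads, alignments = alignments)
}

#' Generate microarray-style probeset intensities
#'
#' Produces one intensity row (log2 RMA-like scale) per probeset-linked
#' transcript. With an explicit \code{noiseSd} the intensity is an affine
#' function of log2(true RPKM + 1) plus Gaussian noise. With
#' \code{noiseSd = NULL} intensities are built on per-stage normal scores
#' of log2(RPKM + 1) through a Gaussian copula calibrated so the expected
#' Spearman correlation per stage equals \code{truth$platform_rho}
#' (Pearson latent correlation r = 2 sin(pi * rho / 6)).
#'
#' A \code{crosshybFraction} of probesets is flagged with a
#' cross-hybridization suffix (_s, _x, _a), a small fraction carries a
#' nonzero BLAST e-value, and \code{duplicateFraction} of transcripts get
#' a second, noisier probeset — all to exercise the matched-pair filters.
#'
#' @param truth,catalog output of [generateCatalog()].
#' @param crosshybFraction fraction of probesets flagged as
#'   cross-hybridizing.
#' @param noiseSd Gaussian noise SD for the affine mode, or NULL for the
#'   copula mode targeting \code{truth$platform_rho}.
#' @param evalueFraction fraction of probesets with e-value > 0.
#' @param duplicateFraction fraction of linked transcripts receiving a
#'   second probeset.
#' @param seed integer seed.
#' @return data.frame: probeset_id, suffix_class ("" or one of
#'   "_s"/"_x"/"_a"), transcript_id, evalue, and one log2-intensity column
#'   per stage.
#' @export
generateProbesets <- function(truth, catalog, crosshybFraction = 0.15,
                              noiseSd = NULL, evalueFraction = 0.05,
                              duplicateFraction = 0.05, seed = 1L) {
  if (crosshybFraction < 0 || crosshybFraction > 1)
    stop("crosshybFraction must lie in [0, 1]")
  if (!is.null(noiseSd) && noiseSd < 0)
    stop("noiseSd must be nonnegative")
  set.seed(seed)

  linked <- catalog[!is.na(catalog$probeset_id), , drop = FALSE]
  if (nrow(linked) == 0L) stop("catalog has no probeset-linked transcripts")
  stages <- colnames(truth$true_rpkm)
  logr <- log2(truth$true_rpkm[linked$transcript_id, , drop = FALSE] + 1)
  n <- nrow(linked)

  intensity_for <- function(extraSd = 0) {
    if (is.null(noiseSd)) {
      r <- 2 * sin(pi * truth$platform_rho / 6)
      z <- apply(logr, 2, function(x)
        qnorm((rank(x, ties.method = "average") - 0.5) / length(x)))
      lat <- r * z + sqrt(1 - r^2) *
        matrix(rnorm(n * length(stages)), n)
      out <- 7 + 1.5 * lat
    } else {
      out <- 2 + logr + matrix(rnorm(n * length(stages), 0, noiseSd), n)
    }
    if (extraSd > 0)
      out <- out + matrix(rnorm(n * length(stages), 0, extraSd), n)
    colnames(out) <- stages
    out
  }

  base <- data.frame(probeset_id = linked$probeset_id,
                     suffix_class = "",
                     transcript_id = linked$transcript_id,
                     evalue = 0, stringsAsFactors = FALSE)
  xh <- runif(n) < crosshybFraction
  base$suffix_class[xh] <- sample(c("_s", "_x", "_a"), sum(xh), replace = TRUE)
  ev <- runif(n) < evalueFraction
  base$evalue[ev] <- 10^runif(sum(ev), -30, -5)
  tab <- cbind(base, intensity_for())

  dup <- runif(n) < duplicateFraction
  if (any(dup)) {
    d <- base[dup, , drop = FALSE]
    d$probeset_id <- sub("_at$", "_b_at", d$probeset_id)
    d$suffix_class <- ""
    d$evalue <- 0
    dI <- intensity_for(extraSd = 1.5)[dup, , drop = FALSE]
    tab <- rbind(tab, cbind(d, dI))
  }
  rownames(tab) <- NULL
  tab
}
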