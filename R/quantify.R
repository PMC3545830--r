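#' Filter reads on trimmed length and ambiguous-base count
#'
#' A read is kept iff its post-trim length is at least \code{minLength}
#' nucleotides and it carries at most \code{maxAmbiguous} ambiguous bases.
#' Input order is preserved.
#'
#' @param reads data.frame with columns read_id, length_after_trim,
#'   ambiguous_count (and optionally stage).
#' @param minLength minimum trimmed length (default 60 nt).
#' @param maxAmbiguous maximum ambiguous bases (default 2).
#' @return The kept subset of \code{reads}.
#' @export
#' @examples
#' r <- data.frame(read_id = c("a", "b"), length_after_trim = c(59, 100),
#'                 ambiguous_count = c(0, 2))
#' filterReads(r)$read_id  # "b"
filterReads <- function(reads, minLength = 60L, maxAmbiguous = 2L) {
  if (minLength <= 0 || maxAmbiguous < 0)
    stop("minLength must be positive and maxAmbiguous nonnegative")
  keep <- reads$length_after_trim >= minLength &
    reads$ambiguous_count <= maxAmbiguous
  reads[keep, , drop = FALSE]
}

#' Filter alignment candidates on identity and aligned fraction
#'
#' A candidate is accepted iff strictly more than \code{minIdentity} of
#' the aligned bases are identical and strictly more than
#' \code{minAlignedFraction} of the read aligned contiguously (both
#' strict, matching the "greater than" acceptance rule).
#'
#' @param candidates data.frame with columns read_id, transcript_id,
#'   percent_identity, aligned_fraction.
#' @param minIdentity identity threshold, exclusive (default 0.98).
#' @param minAlignedFraction aligned-fraction threshold, exclusive
#'   (default 0.5).
#' @param reads optional data.frame of QC-passing reads; if supplied,
#'   candidates referencing reads absent from it raise an error.
#' @return The accepted subset of \code{candidates}.
#' @export
filterAlignments <- function(candidates, minIdentity = 0.98,
                             minAlignedFraction = 0.5, reads = NULL) {
  if (!is.null(reads)) {
    missing <- setdiff(candidates$read_id, reads$read_id)
    if (length(missing))
      stop("candidates reference ", length(missing),
           " read(s) absent from the read table, e.g. ", missing[1])
  }
  keep <- candidates$percent_identity > minIdentity &
    candidates$aligned_fraction > minAlignedFraction
  candidates[keep, , drop = FALSE]
}

#' Two-pass proportional allocation of reads to transcripts
#'
#' Pass one counts reads with exactly one accepted candidate as unique
#' reads of that transcript. Pass two distributes every multi-candidate
#' read across its candidate transcripts with weights proportional to the
#' unique-read counts frozen in pass one; if all candidates of a read have
#' zero unique reads the read is split equally (the proportional rule is
#' undefined at 0/0 and an equal split preserves conservation). Allocation
#' is single-pass, not iterative: unique counts are not updated as
#' multi-mapped mass is assigned.
#'
#' The total allocated mass equals the number of reads contributing at
#' least one accepted candidate.
#'
#' @param candidates accepted candidates of one stage (data.frame with
#'   read_id, transcript_id).
#' @param transcriptIds optional full transcript universe; transcripts
#'   without reads appear with zero counts.
#' @return data.frame: transcript_id, unique_reads (integer),
#'   allocated_reads (numeric).
#' @export
#' @examples
#' cand <- data.frame(
#'   read_id = c(sprintf("u%d", 1:10), "m", "m"),
#'   transcript_id = c(rep("A", 8), rep("B", 2), "A", "B"))
#' allocateReads(cand)  # A: 8 unique, 8.8 allocated; B: 2, 2.2
allocateReads <- function(candidates, transcriptIds = NULL) {
  tx <- if (is.null(transcriptIds)) sort(unique(candidates$transcript_id))
        else transcriptIds
  u <- setNames(numeric(length(tx)), tx)
  alloc <- u
  if (nrow(candidates)) {
    rid <- match(candidates$read_id, unique(candidates$read_id))
    ncand <- tabulate(rid)[rid]
    uni <- candidates[ncand == 1L, , drop = FALSE]
    ucount <- table(factor(uni$transcript_id, levels = tx))
    u[] <- as.numeric(ucount)
    alloc <- u
    multi <- candidates[ncand > 1L, , drop = FALSE]
    if (nrow(multi)) {
      w <- u[multi$transcript_id]
      mrid <- match(multi$read_id, unique(multi$read_id))
      totw <- rowsum(w, mrid)[, 1]
      m <- tabulate(mrid)
      share <- ifelse(totw[mrid] > 0, w / totw[mrid], 1 / m[mrid])
      sh <- rowsum(share, multi$transcript_id)
      add <- setNames(numeric(length(tx)), tx)
      add[rownames(sh)] <- sh[, 1]
      alloc <- u + add
    }
  }
  data.frame(transcript_id = tx, unique_reads = as.integer(u),
             allocated_reads = unname(alloc), stringsAsFactors = FALSE)
}

#' RPKM from allocated counts
#'
#' \code{rpkm = allocated / ((length / 1000) * (totalMapped / 1e6))}.
#' Fractional allocated counts are carried through unrounded.
#'
#' @param counts data.frame from [allocateReads()].
#' @param lengths named vector of transcript lengths (bp).
#' @param totalMapped RPKM denominator; defaults to the sum of allocated
#'   reads (fractional totals). Pass \code{round(sum(...))} for integer
#'   totals if preferred.
#' @return Named numeric vector of RPKM, one entry per counts row.
#' @export
#' @examples
#' computeRPKM(data.frame(transcript_id = "t", unique_reads = 20L,
#'                        allocated_reads = 20),
#'             c(t = 1000), totalMapped = 40e6)  # 0.5
computeRPKM <- function(counts, lengths, totalMapped = NULL) {
  if (is.null(totalMapped)) totalMapped <- sum(counts$allocated_reads)
  if (totalMapped <= 0) stop("totalMapped must be positive")
  len <- lengths[counts$transcript_id]
  if (any(is.na(len)))
    stop("length missing for some counted transcripts")
  setNames(counts$allocated_reads / ((len / 1000) * (totalMapped / 1e6)),
           counts$transcript_id)
}

#' Expected mean per-base coverage implied by an RPKM value
#'
#' \code{coverage = rpkm * mappedMillions * readLength / 1000}: an RPKM of
#' 0.5 at 40 million mapped 100 nt reads corresponds to a mean coverage of
#' 2 (about 2000 nt of read sequence on a 1000 bp transcript).
#'
#' @param rpkm RPKM value (>= 0).
#' @param length transcript length in bp (positive; the mean coverage is
#'   length-free but the argument documents the worked setting).
#' @param readLength read length in nt (positive).
#' @param mappedMillions mapped reads in millions (positive).
#' @return Mean per-base coverage.
#' @export
#' @examples
#' expectedCoverage(0.5, 1000, 100, 40)  # 2
expectedCoverage <- function(rpkm, length, readLength, mappedMillions) {
  if (any(rpkm < 0)) stop("rpkm must be nonnegative")
  if (length <= 0 || readLength <= 0 || mappedMillions <= 0)
    stop("length, readLength and mappedMillions must be positive")
  rpkm * mappedMillions * readLength / 1000
}

#' Quantify all stages into a BerryExpressionSet
#'
#' Runs the full counting stage per developmental stage: read QC filter,
#' alignment acceptance filter, two-pass proportional allocation, and
#' RPKM. The RPKM denominator is the per-stage total of allocated reads
#' (fractional by default; set \code{integerTotals = TRUE} to round).
#'
#' @param reads read table (read_id, length_after_trim, ambiguous_count,
#'   stage).
#' @param alignments candidate table (read_id, transcript_id,
#'   percent_identity, aligned_fraction).
#' @param catalog catalog data.frame with transcript_id and length (extra
#'   columns are kept as rowData).
#' @param minLength,maxAmbiguous read QC thresholds.
#' @param minIdentity,minAlignedFraction alignment acceptance thresholds.
#' @param integerTotals use rounded totals in the RPKM denominator.
#' @return A [BerryExpressionSet-class].
#' @export
quantifyStages <- function(reads, alignments, catalog,
                           minLength = 60L, maxAmbiguous = 2L,
                           minIdentity = 0.98, minAlignedFraction = 0.5,
                           integerTotals = FALSE) {
  stages <- unique(reads$stage)
  tx <- catalog$transcript_id
  lengths <- setNames(catalog$length, tx)
  kept <- filterReads(reads, minLength, maxAmbiguous)
  rpkmM <- uM <- aM <- matrix(0, length(tx), length(stages),
                              dimnames = list(tx, stages))
  tot <- setNames(numeric(length(stages)), stages)
  for (s in stages) {
    sreads <- kept[kept$stage == s, , drop = FALSE]
    cand <- alignments[alignments$read_id %in% sreads$read_id, , drop = FALSE]
    acc <- filterAlignments(cand, minIdentity, minAlignedFraction,
                            reads = sreads)
    cnt <- allocateReads(acc, transcriptIds = tx)
    tm <- sum(cnt$allocated_reads)
    if (integerTotals) tm <- round(tm)
    tot[s] <- tm
    uM[, s] <- cnt$unique_reads
    aM[, s] <- cnt$allocated_reads
    if (tm > 0) rpkmM[, s] <- computeRPKM(cnt, lengths, totalMapped = tm)
  }
  extra <- catalog[, setdiff(colnames(catalog),
                             c("transcript_id", "length")), drop = FALSE]
  rownames(extra) <- tx
  BerryExpressionSet(rpkmM, uM, aM, lengths, tot, rowData = extra)
}

#' Detection calls per transcript and stage
#'
#' A transcript is detected in a stage iff its RPKM is at least
#' \code{rpkmFloor} (default 0.5) or, below that floor, at least
#' \code{minUnique} uniquely matched reads support it (default 5).
#'
#' @param x a [BerryExpressionSet-class], or an RPKM matrix.
#' @param uniqueReads unique-read matrix when \code{x} is a matrix.
#' @param rpkmFloor,minUnique detection thresholds.
#' @return Logical matrix, transcripts x stages.
#' @export
detectExpressed <- function(x, uniqueReads = NULL, rpkmFloor = 0.5,
                            minUnique = 5L) {
  if (is(x, "BerryExpressionSet")) {
    uniqueReads <- uniqueReads(x)
    x <- rpkm(x)
  }
  x >= rpkmFloor | uniqueReads >= minUnique
}

#' Abundance bins per stage
#'
#' Counts detected transcripts per stage in four abundance classes:
#' RPKM strictly above 200; 10 to 200 inclusive; 0.5 up to (excluding) 10;
#' and below 0.5 but detected through at least \code{minUnique} unique
#' reads. Every detected transcript falls in exactly one bin, so the
#' column sums equal the per-stage detected totals.
#'
#' @inheritParams detectExpressed
#' @return Integer matrix, 4 bins x stages, with a "detected" total row
#'   attached as attribute \code{"detected"}.
#' @export
abundanceBins <- function(x, uniqueReads = NULL, rpkmFloor = 0.5,
                          minUnique = 5L) {
  if (is(x, "BerryExpressionSet")) {
    uniqueReads <- uniqueReads(x)
    x <- rpkm(x)
  }
  det <- x >= rpkmFloor | uniqueReads >= minUnique
  bins <- rbind(
    `>200`          = colSums(x > 200),
    `10-200`        = colSums(x >= 10 & x <= 200),
    `0.5-10`        = colSums(x >= rpkmFloor & x < 10),
    `<0.5, unique>=5` = colSums(x < rpkmFloor & uniqueReads >= minUnique))
  storage.mode(bins) <- "integer"
  attr(bins, "detected") <- colSums(det)
  bins
}
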