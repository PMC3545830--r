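#' Write a transcript catalog as FASTA plus annotation table
#'
#' Emits one random DNA sequence of the declared length per transcript
#' (sequence content is a placeholder: the pipeline consumes alignment
#' candidates, not raw sequence) and the annotation as a tab-separated
#' table with the documented columns transcript_id, length, go_terms,
#' probeset_id, archetype.
#'
#' @param catalog catalog data.frame from [generateCatalog()].
#' @param fastaPath,tablePath output paths.
#' @param seed seed for the placeholder sequences.
#' @return Invisibly, the two paths.
#' @export
writeCatalogFasta <- function(catalog, fastaPath, tablePath = NULL,
                              seed = 1L) {
  set.seed(seed)
  seqs <- vapply(catalog$length, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- catalog$transcript_id
  Biostrings::writeXStringSet(dna, fastaPath)
  if (!is.null(tablePath)) writeBerryTable(catalog, tablePath)
  invisible(c(fasta = fastaPath, table = tablePath))
}

#' Read a transcript catalog FASTA
#'
#' @param fastaPath path written by [writeCatalogFasta()].
#' @return data.frame with transcript_id and length derived from the
#'   sequences.
#' @export
readCatalogFasta <- function(fastaPath) {
  dna <- Biostrings::readDNAStringSet(fastaPath)
  data.frame(transcript_id = names(dna),
             length = Biostrings::width(dna),
             stringsAsFactors = FALSE)
}

#' Tab-separated table I/O with stable headers
#'
#' Thin wrappers fixing the conventions used by every tabular output of
#' the pipeline: tab separator, header row, no quoting, no row names.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return \code{readBerryTable} returns a data.frame.
#' @export
writeBerryTable <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBerryTable
#' @export
readBerryTable <- function(path)
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
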