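# Independent oracles, deliberately naive: plain loops and enumeration,
# sharing no code with the implementation they check.

# two-pass proportional allocation by direct looping over reads
bruteAllocate <- function(candidates, transcriptIds) {
  u <- setNames(numeric(length(transcriptIds)), transcriptIds)
  byRead <- split(candidates$transcript_id, candidates$read_id)
  for (tx in byRead) if (length(tx) == 1L) u[tx] <- u[tx] + 1
  alloc <- u
  for (tx in byRead) {
    if (length(tx) > 1L) {
      w <- u[tx]
      if (sum(w) == 0) w <- rep(1, length(tx))
      alloc[tx] <- alloc[tx] + w / sum(w)
    }
  }
  list(unique = u, allocated = alloc)
}

# P(X >= k) for hypergeometric by exhaustive enumeration of all C(N, n)
# draws of the cluster from the background
enumHyperUpperTail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% marked) >= k)
  mean(hits)
}

# Spearman rho of two 4-vectors from the rank-difference formula
spearmanByFormula <- function(x, y) {
  rx <- rank(x); ry <- rank(y); n <- length(x)
  1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
}

# random alignment-candidate instance with <= maxReads reads over a small
# transcript set, mixing unique and multi-candidate reads
randomAllocationInstance <- function(maxReads = 20L, nTx = 4L) {
  tx <- LETTERS[seq_len(nTx)]
  nReads <- sample(2:maxReads, 1L)
  rows <- lapply(seq_len(nReads), function(i) {
    m <- sample(c(1L, 1L, 1L, 2L, 3L), 1L)  # mostly unique
    data.frame(read_id = sprintf("r%02d", i),
               transcript_id = sample(tx, min(m, nTx)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# tiny 4-stage RPKM matrix with named rows
randomRpkmMatrix <- function(n, maxRpkm = 100) {
  m <- matrix(runif(4 * n, 0, maxRpkm), n,
              dimnames = list(sprintf("t%03d", seq_len(n)), berryStages()))
  m
}
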