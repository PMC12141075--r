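# Independent brute-force oracles. These deliberately avoid the dynamic
# programming (and the libraries) used by the implementation: alignments are
# enumerated path by path, LCS by subsequence enumeration, and NJ is checked
# against trees the test itself generated.

# Exhaustive global affine-gap alignment score: recursively enumerate every
# alignment (monotone path with M/I/D ops), scoring gaps as open + L * ext.
bruteGlobalScore <- function(a, b, mat, open, ext) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  best <- -Inf
  rec <- function(i, j, sc, last) {
    if (i > n && j > m) {
      if (sc > best) best <<- sc
      return(invisible(NULL))
    }
    if (i <= n && j <= m)
      rec(i + 1L, j + 1L, sc + mat[A[i], B[j]], "M")
    if (i <= n)
      rec(i + 1L, j, sc - ext - if (last == "I") 0 else open, "I")
    if (j <= m)
      rec(i, j + 1L, sc - ext - if (last == "D") 0 else open, "D")
  }
  rec(1L, 1L, 0, "M")
  best
}

# Exhaustive local affine-gap score: best over all alignments that start and
# end with an aligned column (gaps at local alignment ends cannot help when
# penalties are positive), floored at 0 (empty alignment).
bruteLocalScore <- function(a, b, mat, open, ext) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  best <- 0
  rec <- function(i, j, sc, last) {
    # i, j: next positions to consume
    if (i <= n && j <= m) {
      sc2 <- sc + mat[A[i], B[j]]
      if (sc2 > best) best <<- sc2  # alignment may end at this M column
      rec(i + 1L, j + 1L, sc2, "M")
    }
    if (i <= n) rec(i + 1L, j, sc - ext - if (last == "I") 0 else open, "I")
    if (j <= m) rec(i, j + 1L, sc - ext - if (last == "D") 0 else open, "D")
  }
  for (i0 in seq_len(n)) for (j0 in seq_len(m))
    rec(i0, j0, 0, "M")
  best
}

unitMatrix <- function(alphabet = c("A", "C", "G", "T"),
                       match = 1, mismatch = -1) {
  m <- matrix(mismatch, length(alphabet), length(alphabet),
              dimnames = list(alphabet, alphabet))
  diag(m) <- match
  m
}

randomSeq <- function(len, alphabet = c("A", "C", "G", "T"))
  paste(sample(alphabet, len, replace = TRUE), collapse = "")

# Brute-force orientation-aware LCS: enumerate all subsequences of the
# shorter token list and check each against the other by greedy scan.
bruteLCS <- function(groupsA, strandsA, groupsB, strandsB) {
  tokA <- paste(groupsA, strandsA)
  tokB <- paste(groupsB, strandsB)
  if (length(tokA) > length(tokB)) { tmp <- tokA; tokA <- tokB; tokB <- tmp }
  n <- length(tokA)
  best <- 0L
  isSubseq <- function(x, y) {
    j <- 1L
    for (t in x) {
      while (j <= length(y) && y[j] != t) j <- j + 1L
      if (j > length(y)) return(FALSE)
      j <- j + 1L
    }
    TRUE
  }
  for (mask in seq_len(2^n) - 1L) {
    pick <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(pick) <= best) next
    if (isSubseq(tokA[pick], tokB)) best <- length(pick)
  }
  best
}

# A random unrooted binary tree with positive branch lengths plus its exact
# (additive) leaf-to-leaf distance matrix.
randomAdditiveCase <- function(ntaxa) {
  tr <- ape::rtree(ntaxa, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 2)
  D <- ape::cophenetic.phylo(tr)
  list(tree = tr, D = D[tr$tip.label, tr$tip.label])
}
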