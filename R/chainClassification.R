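#' Pairwise p-distances between protein sequences
#'
#' Aligns every pair globally (affine gaps, BLOSUM62 by default) and
#' computes the p-distance: mismatched aligned columns over aligned columns,
#' gap columns excluded. Optionally Poisson-corrected
#' (d = -log(1 - p)).
#'
#' @param seqs named character vector of >= 3 amino-acid sequences.
#' @param correction "none" (p-distance, default) or "poisson".
#' @param substitutionMatrix,gapOpen,gapExtend passed to [alignProteins()]
#'   (global mode).
#' @return symmetric numeric matrix with zero diagonal, dimnames =
#'   sequence labels.
#' @export
pairwiseDistances <- function(seqs, correction = c("none", "poisson"),
                              substitutionMatrix = "BLOSUM62",
                              gapOpen = 11, gapExtend = 1) {
  correction <- match.arg(correction)
  n <- length(seqs)
  stopifnot(n >= 3L)
  labels <- names(seqs)
  mat <- resolveMatrix(substitutionMatrix)
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(sanitizeResidues(seqs[[i]], rownames(mat))),
      Biostrings::AAString(sanitizeResidues(seqs[[j]], rownames(mat))),
      substitutionMatrix = mat, gapOpening = gapOpen,
      gapExtension = gapExtend, type = "global")
    ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    both <- ap != "-" & as_ != "-"
    ncols <- sum(both)
    if (!ncols)
      stop("no aligned columns between '", labels[i], "' and '", labels[j], "'")
    p <- sum(ap[both] != as_[both]) / ncols
    d <- if (correction == "poisson") {
      if (p >= 1) stop("Poisson correction undefined at p = 1 for pair ",
                       labels[i], "/", labels[j])
      -log(1 - p)
    } else p
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (exact on additive matrices:
#' the unique generating tree is recovered, topology and branch lengths).
#' Negative branch-length estimates, which NJ can produce on non-additive
#' input, are clamped to zero with a message.
#'
#' @param D symmetric nonnegative matrix with zero diagonal and labelled
#'   dimnames.
#' @return an unrooted `phylo` tree (ape), serialisable with
#'   [ape::write.tree()].
#' @export
neighborJoining <- function(D) {
  if (!isSymmetric(unname(D), tol = 1e-12))
    stop("distance matrix must be symmetric")
  if (any(!is.finite(D))) stop("distance matrix has non-finite entries")
  if (nrow(D) < 3L) stop("need at least 3 taxa")
  tr <- ape::nj(stats::as.dist(D))
  if (any(tr$edge.length < 0)) {
    message("clamping ", sum(tr$edge.length < 0),
            " negative branch length(s) to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Assign duplicated chains to their progenitor type
#'
#' Each leaf labelled "query" is assigned the type (`alpha1_type` or
#' `alpha2_type`) of its nearest reference leaf by tree path length; exact
#' ties give "ambiguous". The result does not depend on the input leaf
#' order.
#'
#' @param tree a `phylo` tree whose tip labels cover `names(typeLabels)`.
#' @param typeLabels named character vector leaf -> one of "alpha1_type",
#'   "alpha2_type", "query".
#' @return named character vector query leaf -> assigned type.
#' @export
assignProgenitors <- function(tree, typeLabels) {
  stopifnot(all(names(typeLabels) %in% tree$tip.label))
  refs1 <- names(typeLabels)[typeLabels == "alpha1_type"]
  refs2 <- names(typeLabels)[typeLabels == "alpha2_type"]
  if (!length(refs1) || !length(refs2))
    stop("need at least one reference leaf of each type")
  queries <- names(typeLabels)[typeLabels == "query"]
  pd <- ape::cophenetic.phylo(tree)
  out <- vapply(queries, function(q) {
    d1 <- min(pd[q, refs1]); d2 <- min(pd[q, refs2])
    if (isTRUE(all.equal(d1, d2))) "ambiguous"
    else if (d1 < d2) "alpha1_type" else "alpha2_type"
  }, character(1))
  names(out) <- queries
  out
}
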