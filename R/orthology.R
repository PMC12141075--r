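#' Pairwise protein alignment with affine gap penalties
#'
#' Optimal affine-gap alignment of two amino-acid sequences:
#' Smith-Waterman for `mode = "local"`, Needleman-Wunsch (end gaps
#' penalised) for `mode = "global"`. A gap of length L costs
#' `gapOpen + L * gapExtend`, the BLAST convention. Residues not covered by
#' the substitution matrix are treated as "X". Identity is the fraction of
#' matching residues over aligned (gap-free) columns; the aligned fraction is
#' aligned columns over the shorter sequence length.
#'
#' @param a,b amino-acid sequences (single strings, non-empty).
#' @param substitutionMatrix a named square scoring matrix, or the name of a
#'   matrix shipped with Biostrings ("BLOSUM62" by default).
#' @param gapOpen,gapExtend non-negative gap penalties (defaults 11 and 1,
#'   the usual protein-search settings).
#' @param mode "local" or "global".
#' @return list with `score`, `identity`, `alignedFraction`, `mode`.
#' @export
alignProteins <- function(a, b, substitutionMatrix = "BLOSUM62",
                          gapOpen = 11, gapExtend = 1,
                          mode = c("local", "global")) {
  mode <- match.arg(mode)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  mat <- resolveMatrix(substitutionMatrix)
  a <- sanitizeResidues(a, rownames(mat))
  b <- sanitizeResidues(b, rownames(mat))
  type <- if (mode == "local") "local" else "global"
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = mat, gapOpening = gapOpen, gapExtension = gapExtend,
    type = type)
  sc <- Biostrings::score(pa)
  if (mode == "local" && sc <= 0)
    return(list(score = 0, identity = 0, alignedFraction = 0, mode = mode))
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  both <- ap != "-" & as_ != "-"
  ncols <- sum(both)
  ident <- if (ncols) sum(ap[both] == as_[both]) / ncols else 0
  list(score = sc, identity = ident,
       alignedFraction = ncols / min(nchar(a), nchar(b)), mode = mode)
}

# Accept either a matrix or the name of a Biostrings-shipped matrix.
resolveMatrix <- function(m) {
  if (is.matrix(m)) return(m)
  e <- new.env()
  utils::data(list = m, package = "Biostrings", envir = e)
  get(m, envir = e)
}

sanitizeResidues <- function(x, known) {
  ch <- strsplit(x, "")[[1]]
  ch[!ch %in% known] <- "X"
  paste(ch, collapse = "")
}

#' Reciprocal best hits between two proteomes
#'
#' Scores every protein of A against every protein of B by local affine-gap
#' alignment and reports the pairs that are each other's unique top hit,
#' subject to a minimum score and a minimum aligned fraction. Ties for the
#' top hit disqualify the gene and are recorded in the `ties` attribute of
#' the result. The output is independent of argument order (up to column
#' naming).
#'
#' @param proteomeA,proteomeB named character vectors gene -> protein.
#' @param minScore minimum alignment score (matrix units; default 50).
#' @param minAlignedFraction minimum aligned fraction (default 0.5).
#' @param substitutionMatrix,gapOpen,gapExtend passed to [alignProteins()].
#' @return data.frame with columns `geneA`, `geneB`, `score`; attribute
#'   `ties` lists genes dropped because of tied best hits.
#' @export
reciprocalBestHits <- function(proteomeA, proteomeB, minScore = 50,
                               minAlignedFraction = 0.5,
                               substitutionMatrix = "BLOSUM62",
                               gapOpen = 11, gapExtend = 1) {
  stopifnot(length(proteomeA) > 0, length(proteomeB) > 0)
  mat <- resolveMatrix(substitutionMatrix)
  pa <- vapply(proteomeA, sanitizeResidues, character(1), known = rownames(mat))
  pb <- vapply(proteomeB, sanitizeResidues, character(1), known = rownames(mat))
  setA <- Biostrings::AAStringSet(pa)
  # score matrix: one vectorised call per subject
  S <- matrix(NA_real_, length(pa), length(pb),
              dimnames = list(names(pa), names(pb)))
  for (j in seq_along(pb)) {
    S[, j] <- Biostrings::pairwiseAlignment(
      setA, Biostrings::AAString(pb[[j]]), substitutionMatrix = mat,
      gapOpening = gapOpen, gapExtension = gapExtend,
      type = "local", scoreOnly = TRUE)
  }
  S[S < 0] <- 0
  ties <- character(0)
  bestOf <- function(v) {
    m <- max(v)
    w <- which(v == m)
    if (length(w) != 1L) NA_integer_ else w
  }
  bestB <- apply(S, 1L, bestOf)  # for each A gene, its best B hit
  bestA <- apply(S, 2L, bestOf)  # for each B gene, its best A hit
  ties <- c(names(pa)[is.na(bestB)], names(pb)[is.na(bestA)])
  out <- list()
  for (i in seq_along(pa)) {
    j <- bestB[i]
    if (is.na(j)) next
    if (is.na(bestA[j]) || bestA[j] != i) next
    if (S[i, j] < minScore) next
    al <- alignProteins(pa[[i]], pb[[j]], substitutionMatrix = mat,
                        gapOpen = gapOpen, gapExtend = gapExtend,
                        mode = "local")
    if (al$alignedFraction < minAlignedFraction) next
    out[[length(out) + 1L]] <- data.frame(
      geneA = names(pa)[i], geneB = names(pb)[j], score = S[i, j],
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out)
    else data.frame(geneA = character(0), geneB = character(0),
                    score = numeric(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "ties") <- unique(ties)
  res
}

#' Build ortholog groups anchored on a reference proteome
#'
#' Star topology around one reference species: each reference gene names a
#' group, and the group members are the reference gene plus its reciprocal
#' best hit in each other species (absence allowed). RBH uniqueness
#' guarantees at most one member per species per group.
#'
#' @param rbhList named list, species id -> RBH data.frame from
#'   [reciprocalBestHits()] computed with the reference proteome as A.
#' @param referenceGenes character vector of reference gene names.
#' @param referenceSpecies id of the reference species.
#' @return data.frame with columns `group`, `species`, `gene`.
#' @export
buildOrthologGroups <- function(rbhList, referenceGenes, referenceSpecies) {
  rows <- data.frame(group = referenceGenes, species = referenceSpecies,
                     gene = referenceGenes, stringsAsFactors = FALSE)
  for (sp in names(rbhList)) {
    rbh <- rbhList[[sp]]
    if (!nrow(rbh)) next
    if (anyDuplicated(rbh$geneA) || anyDuplicated(rbh$geneB))
      stop("RBH table for ", sp, " violates uniqueness")
    keep <- rbh$geneA %in% referenceGenes
    if (!any(keep)) next
    rows <- rbind(rows, data.frame(group = rbh$geneA[keep], species = sp,
                                   gene = rbh$geneB[keep],
                                   stringsAsFactors = FALSE))
  }
  rows <- rows[order(rows$group, rows$species), ]
  rownames(rows) <- NULL
  rows
}
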