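#' Cut a flanking-gene window around an anchor pair
#'
#' Collects up to `flankN` genes on each side of a divergent anchor pair,
#' labels every gene with its ortholog group ("unassigned" when it has
#' none), and records strand and contig-end truncation.
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param anchorGenes character vector of the two anchor gene ids (adjacent
#'   genes of a detected pair).
#' @param flankN genes to take on each side (default 5).
#' @param groups named character vector gene id -> ortholog group for this
#'   species (genes absent from it are "unassigned").
#' @param anchorLabel label for the anchor family (e.g. "A34").
#' @return a [SyntenyBlock-class].
#' @export
extractWindow <- function(annotation, anchorGenes, flankN = 5L,
                          groups = character(0), anchorLabel = "anchor") {
  stopifnot(length(anchorGenes) == 2L, flankN >= 1L)
  ids <- geneIDs(annotation)
  pos <- match(anchorGenes, ids)
  if (anyNA(pos)) stop("anchor gene(s) not in annotation: ",
                       paste(anchorGenes[is.na(pos)], collapse = ","))
  g <- geneRanges(annotation)
  reg <- as.character(GenomicRanges::seqnames(g))[pos]
  if (reg[1] != reg[2] || abs(diff(pos)) != 1L)
    stop("anchor genes must be adjacent on one region")
  idx_reg <- which(as.character(GenomicRanges::seqnames(g)) == reg[1])
  lo <- min(pos); hi <- max(pos)
  left <- idx_reg[idx_reg < lo]
  right <- idx_reg[idx_reg > hi]
  truncL <- length(left) < flankN
  truncR <- length(right) < flankN
  take <- c(utils::tail(left, flankN), lo, hi, utils::head(right, flankN))
  grp <- groups[ids[take]]
  grp[is.na(grp)] <- "unassigned"
  entries <- data.frame(
    gene = ids[take],
    group = unname(grp),
    strand = as.character(GenomicRanges::strand(g))[take],
    isAnchor = take %in% pos,
    stringsAsFactors = FALSE)
  new("SyntenyBlock", speciesID = speciesID(annotation),
      anchor = anchorLabel, region = reg[1], entries = entries,
      truncatedLeft = truncL, truncatedRight = truncR)
}

# Longest common subsequence of two token sequences where a match requires
# equal group AND equal strand. Standard O(nm) DP.
lcsOriented <- function(groupsA, strandsA, groupsB, strandsB) {
  n <- length(groupsA); m <- length(groupsB)
  if (!n || !m) return(0L)
  prev <- integer(m + 1L)
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    for (j in seq_len(m)) {
      cur[j + 1L] <- if (groupsA[i] == groupsB[j] && strandsA[i] == strandsB[j])
        prev[j] + 1L else max(cur[j], prev[j + 1L])
    }
    prev <- cur
  }
  prev[m + 1L]
}

#' Compare two synteny blocks and call the event
#'
#' Blocks are compared on their assigned entries only ("unassigned" genes
#' are excluded from the Jaccard index and the collinearity runs, though they
#' still occupy window slots). The conservation Jaccard is shared groups
#' over the union of assigned groups. `collinearRun` is the
#' orientation-aware longest common subsequence (group and strand must both
#' match); `reversedRun` is the same against block b reversed with strands
#' flipped. Event rule, thresholds exposed as arguments:
#' `conserved` if collinearRun >= ceiling(minFrac * shorter assigned
#' length); else `inverted` if reversedRun > collinearRun and
#' reversedRun >= minInvRun; else `rearranged` if jaccard >= minJaccard;
#' else `translocated`.
#'
#' @param a,b [SyntenyBlock-class] objects labelled against the same group
#'   universe.
#' @param minFrac collinear fraction for "conserved" (default 0.6).
#' @param minInvRun minimum reversed run for "inverted" (default 3).
#' @param minJaccard Jaccard threshold separating "rearranged" from
#'   "translocated" (default 0.5).
#' @return list with `jaccard`, `collinearRun`, `reversedRun`, `event`.
#' @export
compareBlocks <- function(a, b, minFrac = 0.6, minInvRun = 3L,
                          minJaccard = 0.5) {
  ea <- blockEntries(a); eb <- blockEntries(b)
  ea <- ea[ea$group != "unassigned", , drop = FALSE]
  eb <- eb[eb$group != "unassigned", , drop = FALSE]
  if (!nrow(ea) || !nrow(eb)) {
    warning("empty (or fully unassigned) block; comparison indeterminate")
    return(list(jaccard = NA_real_, collinearRun = 0L, reversedRun = 0L,
                event = "indeterminate"))
  }
  shared <- intersect(unique(ea$group), unique(eb$group))
  uni <- union(unique(ea$group), unique(eb$group))
  jac <- length(shared) / length(uni)
  coll <- lcsOriented(ea$group, ea$strand, eb$group, eb$strand)
  flip <- c(`+` = "-", `-` = "+")
  revb_groups <- rev(eb$group)
  revb_strands <- unname(flip[rev(eb$strand)])
  revr <- lcsOriented(ea$group, ea$strand, revb_groups, revb_strands)
  minLen <- min(nrow(ea), nrow(eb))
  event <- if (coll >= ceiling(minFrac * minLen)) "conserved"
    else if (revr > coll && revr >= minInvRun) "inverted"
    else if (jac >= minJaccard) "rearranged"
    else "translocated"
  list(jaccard = jac, collinearRun = coll, reversedRun = as.integer(revr),
       event = event)
}

#' Call a precise deletion of an anchor pair in a query genome
#'
#' Given the reference window around an anchor pair and a query annotation
#' with ortholog-group labels, decides among: `anchor_present` (any query
#' gene anywhere matches the anchor groups); `precise_deletion` (anchor
#' absent genome-wide and at least one assigned flank group from each side
#' of the reference window occurs on one query region with at most
#' `maxGapGenes` unrelated genes between the innermost flank matches);
#' `deletion_with_insertion` (flanks joined but the gap exceeds
#' `maxGapGenes`); `indeterminate` otherwise (e.g. flanks split across
#' contigs).
#'
#' @param referenceBlock [SyntenyBlock-class] with assigned flanks on both
#'   sides of the anchor.
#' @param query a [GenomeAnnotation-class].
#' @param groups named character vector: query gene id -> ortholog group.
#' @param maxGapGenes maximum intervening genes for a precise call
#'   (default 3).
#' @return list with `status`, `joinedFlanks` (gene ids spanning the joined
#'   region, or character(0)), `intergenicGapGenes` (NA unless flanks
#'   joined).
#' @export
detectPreciseDeletion <- function(referenceBlock, query, groups,
                                  maxGapGenes = 3L) {
  e <- blockEntries(referenceBlock)
  anchorGroups <- e$group[e$isAnchor]
  anchorGroups <- setdiff(anchorGroups, "unassigned")
  ai <- which(e$isAnchor)
  leftGroups <- setdiff(e$group[seq_len(min(ai) - 1L)], "unassigned")
  rightGroups <- setdiff(e$group[seq(max(ai) + 1L, nrow(e))], "unassigned")
  if (!length(leftGroups) || !length(rightGroups))
    stop("reference block must have assigned flanks on both sides")
  ids <- geneIDs(query)
  qgrp <- groups[ids]
  qgrp[is.na(qgrp)] <- "unassigned"
  if (any(qgrp %in% anchorGroups))
    return(list(status = "anchor_present", joinedFlanks = character(0),
                intergenicGapGenes = NA_integer_))
  g <- geneRanges(query)
  regs <- as.character(GenomicRanges::seqnames(g))
  best <- NULL
  for (reg in unique(regs)) {
    sel <- which(regs == reg)
    lg <- sel[qgrp[sel] %in% leftGroups]
    rg <- sel[qgrp[sel] %in% rightGroups]
    if (!length(lg) || !length(rg)) next
    # innermost pair: minimal count of genes strictly between a left-group
    # match and a right-group match
    for (i in lg) for (j in rg) {
      gap <- abs(j - i) - 1L
      if (is.null(best) || gap < best$gap)
        best <- list(gap = gap, from = min(i, j), to = max(i, j), reg = reg)
    }
  }
  if (is.null(best))
    return(list(status = "indeterminate", joinedFlanks = character(0),
                intergenicGapGenes = NA_integer_))
  status <- if (best$gap <= maxGapGenes) "precise_deletion"
    else "deletion_with_insertion"
  list(status = status,
       joinedFlanks = ids[seq(best$from, best$to)],
       intergenicGapGenes = as.integer(best$gap))
}
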