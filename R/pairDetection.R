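#' Classify the arrangement of two adjacent genes
#'
#' Two genes on the same region are classified by the relative orientation
#' of their transcription units: `head_to_head` when the left gene is on "-"
#' and the right on "+" (5' ends facing across a shared intergenic region),
#' `tail_to_tail` when left is "+" and right "-", and `head_to_tail` when
#' both are on the same strand. Genes on different regions are `unlinked`.
#'
#' The TSS gap counts the bases strictly between the two transcription start
#' sites (gene bounds stand in for the TSS, see [tssPositions()]).
#' Overlapping genes get `overlap = TRUE` and gap 0.
#'
#' @param a,b single-range `GRanges` gene models (order along the chromosome
#'   is worked out internally).
#' @return list with `arrangement`, `tssGap` (NA when unlinked) and
#'   `overlap`.
#' @export
classifyArrangement <- function(a, b) {
  if (as.character(GenomicRanges::seqnames(a)) !=
      as.character(GenomicRanges::seqnames(b)))
    return(list(arrangement = "unlinked", tssGap = NA_integer_,
                overlap = FALSE))
  if (GenomicRanges::start(a) > GenomicRanges::start(b)) { tmp <- a; a <- b; b <- tmp }
  overlap <- GenomicRanges::start(b) <= GenomicRanges::end(a)
  sa <- as.character(GenomicRanges::strand(a))
  sb <- as.character(GenomicRanges::strand(b))
  arrangement <- if (sa == sb) "head_to_tail"
    else if (sa == "-" && sb == "+") "head_to_head"
    else "tail_to_tail"
  gap <- if (overlap) 0L else
    max(0L, abs(tssPositions(b) - tssPositions(a)) - 1L)
  list(arrangement = arrangement, tssGap = as.integer(gap), overlap = overlap)
}

#' Detect head-to-head (divergently transcribed) gene pairs
#'
#' Scans each region for adjacent genes in head-to-head arrangement with a
#' TSS gap at most `maxTssGap`. When a gene could pair with both neighbours,
#' pairs are chosen greedily by ascending TSS gap (ties by leftmost
#' coordinate) so that no gene is reported in two pairs. Only immediately
#' adjacent genes (no intervening gene model) can pair.
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param maxTssGap maximum TSS gap in bp (default 50 kb).
#' @return data.frame with columns `species`, `region`, `geneLeft`,
#'   `geneRight`, `arrangement`, `tssGap`, sorted by region then coordinate.
#' @export
detectDivergentPairs <- function(annotation, maxTssGap = 50000L) {
  stopifnot(maxTssGap > 0)
  g <- geneRanges(annotation)
  ids <- geneIDs(annotation)
  out <- list()
  for (reg in unique(as.character(GenomicRanges::seqnames(g)))) {
    idx <- which(as.character(GenomicRanges::seqnames(g)) == reg)
    if (length(idx) < 2L) next
    cand <- list()
    for (k in seq_len(length(idx) - 1L)) {
      i <- idx[k]; j <- idx[k + 1L]
      cl <- classifyArrangement(g[i], g[j])
      if (cl$arrangement == "head_to_head" && !cl$overlap &&
          cl$tssGap <= maxTssGap)
        cand[[length(cand) + 1L]] <- list(
          i = i, j = j, gap = cl$tssGap, left = GenomicRanges::start(g[i]))
    }
    if (!length(cand)) next
    ord <- order(vapply(cand, `[[`, numeric(1), "gap"),
                 vapply(cand, `[[`, numeric(1), "left"))
    used <- integer(0)
    for (c0 in cand[ord]) {
      if (c0$i %in% used || c0$j %in% used) next
      used <- c(used, c0$i, c0$j)
      out[[length(out) + 1L]] <- data.frame(
        species = speciesID(annotation), region = reg,
        geneLeft = ids[c0$i], geneRight = ids[c0$j],
        arrangement = "head_to_head", tssGap = c0$gap,
        start = GenomicRanges::start(g[c0$i]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(species = character(0), region = character(0),
                      geneLeft = character(0), geneRight = character(0),
                      arrangement = character(0), tssGap = integer(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$region, res$start), ]
  res$start <- NULL
  rownames(res) <- NULL
  res
}

#' Presence/absence of anchor gene-pair families across species
#'
#' For each species and each anchor family (two ortholog groups forming a
#' head-to-head pair, e.g. A12 = {COL4A1, COL4A2}), reports
#' `present_paired` when a detected divergent pair joins the two groups,
#' `present_unpaired` when at least one member group has a gene in the
#' species but no such pair exists (singleton / unlinked loci), and
#' `absent` otherwise. Species listed in `species` but missing from the
#' inputs get an all-`absent` row with a warning.
#'
#' @param pairs data.frame of detected pairs across species (rbind of
#'   [detectDivergentPairs()] outputs).
#' @param geneGroups data.frame with columns `species`, `gene`, `group`
#'   giving ortholog-group assignments.
#' @param anchorFamilies named list; each element a character vector of the
#'   two group ids of one pair family.
#' @param species optional character vector of all species to report.
#' @return data.frame, one row per species, one column per family.
#' @export
summarizePairPresence <- function(pairs, geneGroups, anchorFamilies,
                                  species = NULL) {
  if (is.null(species))
    species <- sort(unique(c(pairs$species, geneGroups$species)))
  res <- data.frame(species = species, stringsAsFactors = FALSE)
  for (fam in names(anchorFamilies)) {
    groups <- anchorFamilies[[fam]]
    stopifnot(length(groups) == 2L)
    status <- character(length(species))
    for (si in seq_along(species)) {
      sp <- species[si]
      gg <- geneGroups[geneGroups$species == sp & geneGroups$group %in% groups, ]
      if (!nrow(gg)) { status[si] <- "absent"; next }
      grp_of <- stats::setNames(gg$group, gg$gene)
      pp <- pairs[pairs$species == sp, , drop = FALSE]
      paired <- FALSE
      if (nrow(pp)) {
        gl <- grp_of[pp$geneLeft]; gr <- grp_of[pp$geneRight]
        paired <- any(!is.na(gl) & !is.na(gr) & gl != gr &
                        gl %in% groups & gr %in% groups)
      }
      status[si] <- if (paired) "present_paired" else "present_unpaired"
    }
    res[[fam]] <- status
  }
  noinfo <- !species %in% c(pairs$species, geneGroups$species)
  if (any(noinfo))
    warning("no annotation information for species: ",
            paste(species[noinfo], collapse = ", "),
            "; reported as absent")
  res
}
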