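#' Generate a collagen-like open reading frame
#'
#' Builds a chain with the canonical collagen IV layout: a collagenous
#' region of `nTriplets` Gly-X-Y triplets (optionally split by
#' interruptions), followed by an NC1-like C-terminal region. Defaults match
#' the canonical chain dimensions: ~1400 collagenous residues (470 triplets)
#' and a ~230-residue NC1 domain. X/Y positions and interruption/NC1
#' residues are drawn from the 18 residues other than Gly and Cys; the
#' requested numbers of cysteines are then planted at seeded-random X/Y
#' positions (collagenous) and NC1 positions. The CDS is a deterministic
#' reverse translation plus a TAA stop, so translating it reproduces the
#' protein exactly.
#'
#' @param nTriplets number of Gly-X-Y triplets (default 470).
#' @param interruptions NULL or data.frame with columns `position` (insert
#'   after this triplet) and `length` (residues). Runs between interruptions
#'   must keep at least `minRunTriplets` triplets.
#' @param nCysCollagenous cysteines planted at X/Y positions (default 4).
#' @param nCysNC1 cysteines planted in the NC1 region (default 12, the
#'   conserved disulfide set).
#' @param nc1Length NC1 length in residues (default 230).
#' @param seed RNG seed.
#' @param minRunTriplets run-length floor used to validate interruption
#'   placement (default 5, matching the parser default).
#' @return list with `cds`, `protein`, `segments` (the planted domain
#'   table, same layout as [parseCollagenDomains()]), and `xyPositions`
#'   (residue indices eligible for cysteine substitution).
#' @export
generateCollagenORF <- function(nTriplets = 470L, interruptions = NULL,
                                nCysCollagenous = 4L, nCysNC1 = 12L,
                                nc1Length = 230L, seed = 1L,
                                minRunTriplets = 5L) {
  stopifnot(nTriplets >= minRunTriplets, nc1Length >= 0L)
  if (!is.null(interruptions) && nrow(interruptions)) {
    interruptions <- interruptions[order(interruptions$position), , drop = FALSE]
    bnd <- c(0L, interruptions$position, nTriplets)
    if (any(diff(bnd) < minRunTriplets))
      stop("interruptions leave a Gly-X-Y run shorter than ", minRunTriplets,
           " triplets")
    if (any(interruptions$length < 1L))
      stop("interruption length must be >= 1")
  }
  withSeed(seed, {
    xy <- sample(AA_XY_POOL, 2L * nTriplets, replace = TRUE)
    triplets <- paste0("G", xy[seq(1L, 2L * nTriplets, 2L)],
                       xy[seq(2L, 2L * nTriplets, 2L)])
    # assemble collagenous region with interruptions, tracking segments
    segs <- list()
    pieces <- character(0)
    pos <- 0L
    lastCut <- 0L
    cuts <- if (is.null(interruptions)) integer(0) else interruptions$position
    lens <- if (is.null(interruptions)) integer(0) else interruptions$length
    for (k in seq_along(cuts)) {
      runTr <- triplets[seq(lastCut + 1L, cuts[k])]
      run <- paste(runTr, collapse = "")
      segs[[length(segs) + 1L]] <- data.frame(
        kind = "collagenous", start = pos + 1L, end = pos + nchar(run))
      pieces <- c(pieces, run); pos <- pos + nchar(run)
      intr <- paste(sample(AA_XY_POOL, lens[k], replace = TRUE), collapse = "")
      segs[[length(segs) + 1L]] <- data.frame(
        kind = "interruption", start = pos + 1L, end = pos + lens[k])
      pieces <- c(pieces, intr); pos <- pos + lens[k]
      lastCut <- cuts[k]
    }
    run <- paste(triplets[seq(lastCut + 1L, nTriplets)], collapse = "")
    segs[[length(segs) + 1L]] <- data.frame(
      kind = "collagenous", start = pos + 1L, end = pos + nchar(run))
    pieces <- c(pieces, run); pos <- pos + nchar(run)
    if (nc1Length > 0L) {
      nc1 <- paste(sample(AA_XY_POOL, nc1Length, replace = TRUE), collapse = "")
      segs[[length(segs) + 1L]] <- data.frame(
        kind = "cterm_nc1", start = pos + 1L, end = pos + nc1Length)
      pieces <- c(pieces, nc1)
    }
    protein <- paste(pieces, collapse = "")
    segments <- do.call(rbind, segs)
    ch <- strsplit(protein, "")[[1]]
    # X/Y residue indices (non-Gly positions inside collagenous segments)
    collSegs <- segments[segments$kind == "collagenous", , drop = FALSE]
    xyPositions <- integer(0)
    for (r in seq_len(nrow(collSegs))) {
      idx <- seq(collSegs$start[r], collSegs$end[r])
      xyPositions <- c(xyPositions, idx[(idx - collSegs$start[r]) %% 3L != 0L])
    }
    if (nCysCollagenous > length(xyPositions))
      stop("infeasible cysteine count: ", nCysCollagenous, " requested, ",
           length(xyPositions), " X/Y positions available")
    if (nCysCollagenous > 0L)
      ch[sample(xyPositions, nCysCollagenous)] <- "C"
    if (nc1Length > 0L && nCysNC1 > 0L) {
      if (nCysNC1 > nc1Length) stop("infeasible NC1 cysteine count")
      nc1Start <- segments$start[segments$kind == "cterm_nc1"]
      ch[nc1Start - 1L + sample(nc1Length, nCysNC1)] <- "C"
    }
    protein <- paste(ch, collapse = "")
    list(cds = reverseTranslate(protein), protein = protein,
         segments = segments, xyPositions = sort(xyPositions))
  })
}

#' Substitute symbols of a sequence at a fixed per-site rate
#'
#' Each unprotected position is substituted with probability `rate` by a
#' uniformly chosen *different* symbol from `alphabet`. Seeded and
#' deterministic; consumes no randomness when `rate` is 0.
#'
#' @param seq single character string.
#' @param rate substitution probability per site, in `[0,1]`.
#' @param seed RNG seed.
#' @param protect integer positions never substituted.
#' @param alphabet symbols to draw from (default DNA).
#' @return the mutated string.
#' @export
mutateSequence <- function(seq, rate, seed, protect = integer(0),
                           alphabet = c("A", "C", "G", "T")) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0 || !nchar(seq)) return(seq)
  withSeed(seed, {
    ch <- strsplit(seq, "")[[1]]
    hit <- which(stats::runif(length(ch)) < rate)
    hit <- setdiff(hit, protect)
    for (i in hit) {
      ch[i] <- sample(setdiff(alphabet, ch[i]), 1L)
    }
    paste(ch, collapse = "")
  })
}

# ---------------------------------------------------------------------------
# Clade simulation internals. The evolving state is a list:
#   regions: named list region -> list of gene entries
#   pairs:   named list pair label -> list(region, left, right)  (families)
# A gene entry: list(family, strand, protein, gapBefore, collagen,
#                    xyPositions, segments, pairLabel)
# ---------------------------------------------------------------------------

newFlankGene <- function(family, strand, seed, gapBefore) {
  prot <- withSeed(seed, {
    len <- sample(200:400, 1L)
    paste0("M", paste(sample(AA_STANDARD, len - 1L, replace = TRUE),
                      collapse = ""))
  })
  list(family = family, strand = strand, protein = prot,
       gapBefore = gapBefore, collagen = FALSE, xyPositions = integer(0),
       segments = NULL, pairLabel = NA_character_)
}

newChainGene <- function(family, strand, seed, gapBefore, pairLabel,
                         nTriplets, nCysCollagenous, nCysNC1, nc1Length,
                         interruptions = NULL) {
  orf <- generateCollagenORF(nTriplets = nTriplets,
                             interruptions = interruptions,
                             nCysCollagenous = nCysCollagenous,
                             nCysNC1 = nCysNC1, nc1Length = nc1Length,
                             seed = seed)
  list(family = family, strand = strand, protein = orf$protein,
       gapBefore = gapBefore, collagen = TRUE,
       xyPositions = orf$xyPositions, segments = orf$segments,
       pairLabel = pairLabel)
}

drawGap <- function(seed, lo = 1000, hi = 20000) {
  withSeed(seed, as.integer(round(exp(stats::runif(1, log(lo), log(hi))))))
}

drawPairGap <- function(seed) drawGap(seed, 100, 5000)

# Default root locus: the ancestral divergent pair (A12-like) plus 12
# single-copy flanking genes, named after the conserved neighbourhood of
# the mammalian COL4A1/COL4A2 locus.
makeRootLocus <- function(seed, chain = list()) {
  leftFams <- c("COQ5", "RAB20", "ING1", "CARS2", "ARHGEF7", "ANKRD10")
  rightFams <- c("IRS2", "MYO16", "UBAC2", "GPR18", "TM9SF2", "CLYBL")
  genes <- list()
  k <- 0L
  # flanks all on "+": no head-to-head adjacency can arise outside the
  # planted anchor pair, so pair truth is unambiguous
  for (f in leftFams) {
    k <- k + 1L
    genes[[k]] <- newFlankGene(f, "+",
                               deriveSeed(seed, paste0("root_", f)),
                               drawGap(deriveSeed(seed, paste0("gap_", f))))
  }
  genes[[k + 1L]] <- newChainGene(
    "COL4A2", "-", deriveSeed(seed, "root_COL4A2"),
    drawGap(deriveSeed(seed, "gap_COL4A2")), "A12",
    nTriplets = chain$nTriplets %||% 470L,
    nCysCollagenous = chain$nCysA12 %||% 2L,
    nCysNC1 = chain$nCysNC1 %||% 12L,
    nc1Length = chain$nc1Length %||% 230L,
    interruptions = chain$interruptions)
  genes[[k + 2L]] <- newChainGene(
    "COL4A1", "+", deriveSeed(seed, "root_COL4A1"),
    drawPairGap(deriveSeed(seed, "pairgap_A12")), "A12",
    nTriplets = chain$nTriplets %||% 470L,
    nCysCollagenous = chain$nCysA12 %||% 2L,
    nCysNC1 = chain$nCysNC1 %||% 12L,
    nc1Length = chain$nc1Length %||% 230L,
    interruptions = chain$interruptions)
  k <- k + 2L
  for (f in rightFams) {
    k <- k + 1L
    genes[[k]] <- newFlankGene(f, "+",
                               deriveSeed(seed, paste0("root_", f)),
                               drawGap(deriveSeed(seed, paste0("gap_", f))))
  }
  list(regions = list(chr1 = genes),
       pairs = list(A12 = list(region = "chr1", left = "COL4A2",
                               right = "COL4A1")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

findGeneByFamily <- function(state, family) {
  for (reg in names(state$regions)) {
    fams <- vapply(state$regions[[reg]], `[[`, character(1), "family")
    i <- match(family, fams)
    if (!is.na(i)) return(list(region = reg, index = i))
  }
  NULL
}

applyEvent <- function(state, ev, node, seed) {
  type <- ev$type
  if (type == "duplicate_pair") {
    pr <- state$pairs[[ev$source]]
    if (is.null(pr)) stop("event at '", node, "' references missing pair '",
                          ev$source, "'")
    newRegion <- paste0("chr", length(state$regions) + 1L)
    nFlank <- ev$nFlank %||% 10L
    flankLeft <- ev$flankLeft %||%
      paste0(ev$new, "FL", seq_len(ceiling(nFlank / 2)))
    flankRight <- ev$flankRight %||%
      paste0(ev$new, "FR", seq_len(floor(nFlank / 2)))
    srcLeft <- findGeneByFamily(state, ev$leftFrom %||% pr$left)
    srcRight <- findGeneByFamily(state, ev$rightFrom %||% pr$right)
    gl <- state$regions[[srcLeft$region]][[srcLeft$index]]
    gr <- state$regions[[srcRight$region]][[srcRight$index]]
    genes <- list()
    k <- 0L
    for (f in flankLeft) {
      k <- k + 1L
      genes[[k]] <- newFlankGene(f, "+",
                                 deriveSeed(seed, paste0(node, "_", f)),
                                 drawGap(deriveSeed(seed, paste0(node, "_gap_", f))))
    }
    newLeft <- gl; newLeft$family <- ev$left; newLeft$strand <- "-"
    newLeft$pairLabel <- ev$new
    newLeft$gapBefore <- drawGap(deriveSeed(seed, paste0(node, "_gapL")))
    newRight <- gr; newRight$family <- ev$right; newRight$strand <- "+"
    newRight$pairLabel <- ev$new
    newRight$gapBefore <- drawPairGap(deriveSeed(seed, paste0(node, "_pairgap")))
    # post-duplication divergence burst: the new copies race away from their
    # progenitors, so paralog distance exceeds ortholog distance. As for all
    # collagen-chain substitutions, Gly (triplet frame) and Cys (an
    # event-controlled quantity) positions are left untouched.
    burst <- ev$burst %||% 0.3
    for (nm in c("newLeft", "newRight")) {
      gene <- get(nm)
      ch <- strsplit(gene$protein, "")[[1]]
      gene$protein <- mutateSequence(
        gene$protein, burst,
        deriveSeed(seed, paste0(node, "_burst_", gene$family)),
        protect = which(ch %in% c("G", "C")),
        alphabet = setdiff(AA_STANDARD, c("G", "C")))
      assign(nm, gene)
    }
    genes[[k + 1L]] <- newLeft
    genes[[k + 2L]] <- newRight
    k <- k + 2L
    for (f in flankRight) {
      k <- k + 1L
      genes[[k]] <- newFlankGene(f, "+",
                                 deriveSeed(seed, paste0(node, "_", f)),
                                 drawGap(deriveSeed(seed, paste0(node, "_gap_", f))))
    }
    state$regions[[newRegion]] <- genes
    state$pairs[[ev$new]] <- list(region = newRegion, left = ev$left,
                                  right = ev$right)
  } else if (type == "invert_window") {
    pr <- state$pairs[[ev$anchor]]
    if (is.null(pr)) stop("event at '", node, "' references missing pair '",
                          ev$anchor, "'")
    genes <- state$regions[[pr$region]]
    fams <- vapply(genes, `[[`, character(1), "family")
    i <- match(pr$left, fams); j <- match(pr$right, fams)
    span <- ev$span %||% 5L
    lo <- max(1L, min(i, j) - span)
    hi <- min(length(genes), max(i, j) + span)
    win <- genes[seq(lo, hi)]
    gaps <- vapply(win, `[[`, numeric(1), "gapBefore")
    win <- rev(win)
    flip <- c(`+` = "-", `-` = "+")
    for (k in seq_along(win)) {
      win[[k]]$strand <- unname(flip[win[[k]]$strand])
      win[[k]]$gapBefore <- gaps[k]
    }
    genes[seq(lo, hi)] <- win
    state$regions[[pr$region]] <- genes
    # any pair wholly inside the window now has left and right swapped
    fams2 <- vapply(genes, `[[`, character(1), "family")
    for (lbl in names(state$pairs)) {
      p2 <- state$pairs[[lbl]]
      if (p2$region != pr$region) next
      li <- match(p2$left, fams2); ri <- match(p2$right, fams2)
      if (li >= lo && li <= hi && ri >= lo && ri <= hi && li > ri)
        state$pairs[[lbl]] <- list(region = p2$region, left = p2$right,
                                   right = p2$left)
    }
  } else if (type %in% c("delete_pair_precise", "delete_pair_with_insertion")) {
    pr <- state$pairs[[ev$anchor]]
    if (is.null(pr)) stop("event at '", node, "' references missing pair '",
                          ev$anchor, "'")
    genes <- state$regions[[pr$region]]
    fams <- vapply(genes, `[[`, character(1), "family")
    i <- match(pr$left, fams); j <- match(pr$right, fams)
    keepIdx <- setdiff(seq_along(genes), c(i, j))
    inserted <- list()
    if (type == "delete_pair_with_insertion") {
      n <- ev$nInserted %||% 1L
      for (q in seq_len(n)) {
        fam <- paste0("INS_", ev$anchor, "_", node, "_", q)
        inserted[[q]] <- newFlankGene(
          fam, "+",
          deriveSeed(seed, paste0(node, "_", fam)),
          drawGap(deriveSeed(seed, paste0(node, "_gap_", fam)), 200, 2000))
      }
    }
    at <- min(i, j) - 1L  # insert where the pair used to sit
    before <- genes[keepIdx[keepIdx <= at]]
    after <- genes[keepIdx[keepIdx > at]]
    state$regions[[pr$region]] <- c(before, inserted, after)
    state$pairs[[ev$anchor]] <- NULL
  } else if (type == "cys_gain") {
    pr <- state$pairs[[ev$pair]]
    if (is.null(pr)) stop("event at '", node, "' references missing pair '",
                          ev$pair, "'")
    delta <- ev$delta
    fams <- c(pr$left, pr$right)
    # distribute the pair-level gain across the two chains, alternating
    share <- c(ceiling(delta / 2), floor(delta / 2))
    for (q in 1:2) {
      loc <- findGeneByFamily(state, fams[q])
      gene <- state$regions[[loc$region]][[loc$index]]
      ch <- strsplit(gene$protein, "")[[1]]
      avail <- gene$xyPositions[ch[gene$xyPositions] != "C"]
      if (share[q] > length(avail))
        stop("infeasible cysteine gain at '", node, "'")
      pick <- withSeed(deriveSeed(seed, paste0(node, "_cys_", fams[q])),
                       sample(avail, share[q]))
      ch[pick] <- "C"
      gene$protein <- paste(ch, collapse = "")
      state$regions[[loc$region]][[loc$index]] <- gene
    }
  } else {
    stop("unknown event type: ", type)
  }
  state
}

mutateState <- function(state, perSite, node, seed) {
  if (perSite <= 0) return(state)
  for (reg in names(state$regions)) {
    for (k in seq_along(state$regions[[reg]])) {
      gene <- state$regions[[reg]][[k]]
      protect <- integer(0)
      alphabet <- AA_STANDARD
      if (gene$collagen) {
        # keep the triplet frame stable (Gly) and the cysteine complement
        # event-controlled (Cys): substitutions neither create nor destroy
        # either residue on collagen chains
        ch <- strsplit(gene$protein, "")[[1]]
        protect <- which(ch %in% c("G", "C"))
        alphabet <- setdiff(AA_STANDARD, c("G", "C"))
      } else {
        protect <- 1L  # keep the initiator Met
      }
      gene$protein <- mutateSequence(
        gene$protein, perSite,
        deriveSeed(seed, paste0(node, "_mut_", reg, "_", gene$family)),
        protect = protect, alphabet = alphabet)
      state$regions[[reg]][[k]] <- gene
    }
  }
  state
}

# Dry-run of the event book against the tree: verifies every event's anchor
# exists on its branch before any sequence is generated.
validateCladeSpec <- function(spec, tree) {
  labels <- c(tree$tip.label, tree$node.label)
  bad <- setdiff(names(spec$events %||% list()), labels)
  if (length(bad))
    stop("events reference unknown tree node(s): ", paste(bad, collapse = ","))
  pairSet <- new.env()
  assign("pairs", "A12", envir = pairSet)
  recurse <- function(node) {
    lab <- if (node <= length(tree$tip.label)) tree$tip.label[node]
      else tree$node.label[node - length(tree$tip.label)]
    for (ev in spec$events[[lab]] %||% list()) {
      pairs <- get("pairs", envir = pairSet)
      if (ev$type == "duplicate_pair") {
        if (!ev$source %in% pairs)
          stop("event at '", lab, "' references missing pair '", ev$source, "'")
        assign("pairs", c(pairs, ev$new), envir = pairSet)
      } else {
        anchor <- ev$anchor %||% ev$pair
        if (!anchor %in% pairs)
          stop("event at '", lab, "' references missing pair '", anchor, "'")
        if (startsWith(ev$type, "delete_pair"))
          assign("pairs", setdiff(pairs, anchor), envir = pairSet)
      }
    }
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    saved <- get("pairs", envir = pairSet)
    for (kid in kids) {
      assign("pairs", saved, envir = pairSet)
      recurse(kid)
    }
  }
  root <- length(tree$tip.label) + 1L
  recurse(root)
  invisible(TRUE)
}

#' Simulate a clade of annotated genomes with planted gene-pair events
#'
#' Evolves a root locus (a divergent A12-like collagen pair plus 12
#' single-copy flanking genes) down a labelled species tree, applying the
#' per-branch events of the spec (pair duplication, window inversion,
#' precise or insertion-bearing pair deletion, cysteine gain) and per-branch
#' point substitutions (protein-level, Gly positions of collagen chains
#' protected so the triplet frame is stable), and emits per-leaf genome
#' annotations plus a machine-readable truth table. Deterministic under the
#' spec seed.
#'
#' The spec is a list with fields: `newick` (tree text; internal nodes must
#' be labelled so events can be attached to branches via their child node),
#' `events` (named list node label -> list of event lists, each with a
#' `type` of `duplicate_pair`, `invert_window`, `delete_pair_precise`,
#' `delete_pair_with_insertion` or `cys_gain`), `habitats` (named character
#' leaf -> habitat class), `rate` (substitutions per site per unit branch
#' length, default 0.02), `chain` (optional overrides for chain dimensions),
#' and `seed`.
#'
#' @param spec the clade specification (see Details).
#' @return object of class `SimulatedClade`: list with `species` (named list
#'   leaf -> list(annotation, genome, proteome)), `truth` (per-species pair
#'   presence/arrangement, flank order, ortholog map, applied events,
#'   cysteine counts, habitat), and the echoed `spec`.
#' @export
simulateClade <- function(spec) {
  stopifnot(!is.null(spec$newick), !is.null(spec$seed))
  tree <- ape::read.tree(text = spec$newick)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(1, nrow(tree$edge))
  validateCladeSpec(spec, tree)
  rate <- spec$rate %||% 0.02
  seed <- spec$seed
  root <- makeRootLocus(deriveSeed(seed, "rootlocus"), spec$chain %||% list())
  ntip <- length(tree$tip.label)
  nodeLabel <- function(node) {
    if (node <= ntip) tree$tip.label[node]
    else tree$node.label[node - ntip]
  }
  leaves <- list()
  eventsApplied <- list()
  recurse <- function(node, state, applied) {
    lab <- nodeLabel(node)
    kids <- which(tree$edge[, 1L] == node)
    if (!length(kids)) {
      leaves[[lab]] <<- state
      eventsApplied[[lab]] <<- applied
      return(invisible(NULL))
    }
    for (e in kids) {
      kid <- tree$edge[e, 2L]
      klab <- nodeLabel(kid)
      kstate <- state
      kapplied <- applied
      for (ev in spec$events[[klab]] %||% list()) {
        kstate <- applyEvent(kstate, ev, klab, seed)
        kapplied <- c(kapplied, paste0(klab, ":", ev$type, ":",
                                       ev$new %||% ev$anchor %||% ev$pair))
      }
      kstate <- mutateState(kstate, rate * tree$edge.length[e], klab, seed)
      recurse(kid, kstate, kapplied)
    }
  }
  recurse(ntip + 1L, root, character(0))

  species <- list()
  truth <- list()
  for (sp in tree$tip.label) {
    emit <- emitSpecies(sp, leaves[[sp]])
    species[[sp]] <- emit$data
    truth[[sp]] <- c(emit$truth,
                     list(events = eventsApplied[[sp]],
                          habitat = (spec$habitats %||% character(0))[sp]))
  }
  structure(list(species = species, truth = truth, spec = spec),
            class = "SimulatedClade")
}

# Lay a genome state out on concrete coordinates and build the
# GenomeAnnotation / genome sequence / proteome plus per-species truth.
emitSpecies <- function(sp, state) {
  filler <- function(n) if (n <= 0L) "" else
    substr(strrep("ACGTTGCA", ceiling(n / 8)), 1L, n)
  regv <- character(0); startv <- integer(0); endv <- integer(0)
  strandv <- character(0); gidv <- character(0)
  genome <- character(0)
  orthoMap <- list()
  flankOrder <- list()
  cysRows <- list()
  for (reg in names(state$regions)) {
    genes <- state$regions[[reg]]
    seqParts <- character(0)
    pos <- 0L
    for (g in genes) {
      cds <- reverseTranslate(g$protein)
      len <- nchar(cds)
      gid <- paste0(sp, "_", g$family)
      startPos <- pos + g$gapBefore + 1L
      endPos <- startPos + len - 1L
      seqParts <- c(seqParts, filler(g$gapBefore),
                    if (g$strand == "-") reverseComplement(cds) else cds)
      pos <- endPos
      regv <- c(regv, reg); startv <- c(startv, startPos)
      endv <- c(endv, endPos); strandv <- c(strandv, g$strand)
      gidv <- c(gidv, gid)
      orthoMap[[length(orthoMap) + 1L]] <- data.frame(
        family = g$family, gene = gid, stringsAsFactors = FALSE)
      if (g$collagen) {
        dom <- g$segments
        prof <- countCysteines(g$protein, dom)
        cysRows[[length(cysRows) + 1L]] <- data.frame(
          family = g$family, pair = g$pairLabel,
          collagenousCys = unname(prof$counts["collagenous"]),
          nc1Cys = unname(prof$counts["cterm_nc1"]),
          total = prof$total, stringsAsFactors = FALSE)
      }
    }
    seqParts <- c(seqParts, filler(500L))
    genome[[reg]] <- paste(seqParts, collapse = "")
    flankOrder[[reg]] <- data.frame(
      family = vapply(genes, `[[`, character(1), "family"),
      strand = vapply(genes, `[[`, character(1), "strand"),
      pair = vapply(genes, function(g)
        if (is.na(g$pairLabel)) "" else g$pairLabel, character(1)),
      stringsAsFactors = FALSE)
  }
  gr <- GenomicRanges::GRanges(regv, IRanges::IRanges(startv, endv),
                               strand = strandv, gene_id = gidv)
  cds_list <- stats::setNames(
    lapply(seq_along(gr), function(i) {
      x <- gr[i]; S4Vectors::mcols(x) <- NULL; x
    }), gidv)
  ann <- GenomeAnnotation(sp, gr, GenomicRanges::GRangesList(cds_list))
  proteome <- stats::setNames(
    unlist(lapply(names(state$regions), function(reg)
      lapply(state$regions[[reg]], `[[`, "protein"))),
    unlist(lapply(names(state$regions), function(reg)
      vapply(state$regions[[reg]], function(g) paste0(sp, "_", g$family),
             character(1)))))
  pairsTruth <- if (length(state$pairs)) data.frame(
    label = names(state$pairs),
    region = vapply(state$pairs, `[[`, character(1), "region"),
    leftFamily = vapply(state$pairs, `[[`, character(1), "left"),
    rightFamily = vapply(state$pairs, `[[`, character(1), "right"),
    stringsAsFactors = FALSE)
  else data.frame(label = character(0), region = character(0),
                  leftFamily = character(0), rightFamily = character(0))
  rownames(pairsTruth) <- NULL
  list(data = list(annotation = ann, genome = genome, proteome = proteome),
       truth = list(pairs = pairsTruth,
                    orthologMap = do.call(rbind, orthoMap),
                    flankOrder = flankOrder,
                    cysteines = if (length(cysRows)) do.call(rbind, cysRows)
                      else NULL))
}

#' Write a simulated clade to disk as GFF3 + FASTA + truth JSON
#'
#' @param clade a `SimulatedClade` from [simulateClade()].
#' @param dir output directory (created if needed).
#' @return named list of per-species file paths, invisibly.
#' @export
writeClade <- function(clade, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  for (sp in names(clade$species)) {
    gff <- file.path(dir, paste0(sp, ".gff3"))
    fa <- file.path(dir, paste0(sp, ".fa"))
    writeGFF3(clade$species[[sp]]$annotation, gff)
    writeFasta(clade$species[[sp]]$genome, fa)
    out[[sp]] <- list(gff = gff, fasta = fa)
  }
  jsonlite::write_json(
    lapply(clade$truth, function(t) t[c("pairs", "events", "habitat")]),
    file.path(dir, "truth.json"), auto_unbox = TRUE, null = "null")
  invisible(out)
}
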