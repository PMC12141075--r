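#' Default pipeline configuration
#'
#' Returns the full set of stage thresholds with their defaults; every value
#' is echoed into the run log of [runPipeline()].
#'
#' @return named list of defaults.
#' @export
defaultConfig <- function() {
  list(
    maxTssGap = 50000L,          # bp, divergent-pair TSS gap ceiling
    flankN = 5L,                 # genes per side in synteny windows
    minScore = 50,               # RBH: minimum local alignment score
    minAlignedFraction = 0.5,    # RBH: minimum aligned fraction
    gapOpen = 11, gapExtend = 1, # affine gap penalties (BLOSUM62 units)
    minFrac = 0.6,               # collinear fraction for "conserved"
    minInvRun = 3L,              # reversed run floor for "inverted"
    minJaccard = 0.5,            # Jaccard floor for "rearranged"
    maxGapGenes = 3L,            # precise-deletion gap ceiling
    minRunTriplets = 5L,         # collagen parser
    maxInterruption = 30L,       # collagen parser
    nPerm = 999L,                # habitat permutation count
    seed = 1L
  )
}

#' Run the full gene-pair comparative pipeline
#'
#' Orchestrates the stages in dependency order: load annotations and
#' proteomes; reciprocal-best-hit orthology against the reference species;
#' divergent-pair detection; pair-family presence/absence; microsynteny
#' window comparison (conservation / inversion / rearrangement calls) and
#' precise-deletion calls for species lacking an anchor; NC1-domain distance
#' tree with progenitor assignment of duplicated chains; per-chain cysteine
#' census and, when habitats are supplied, the salinity permutation test.
#' Per-species stage failures degrade to warnings; only configuration or
#' reference errors are fatal.
#'
#' @param config list with entries:
#'   * `clade`: a `SimulatedClade` (in-memory inputs), OR `species`: named
#'     list species -> list(gff=, fasta=) file paths;
#'   * `reference`: reference species id (fatal if missing);
#'   * `anchorFamilies`: named list, pair label -> the two reference gene
#'     ids of the family, odd (alpha1-type) chain first;
#'   * `habitats`: optional named character species -> habitat;
#'   * `cysteinePair`: pair label whose totals feed the habitat test
#'     (default "A34");
#'   * plus any overrides of [defaultConfig()].
#' @return a report bundle: list with `presence`, `pairs`, `orthologs`,
#'   `syntenyEvents`, `deletionCalls`, `treeNewick`, `progenitors`,
#'   `cysteineProfiles`, `habitatTest`, `log`.
#' @export
runPipeline <- function(config) {
  cfg <- utils::modifyList(defaultConfig(), config)
  if (is.null(cfg$reference)) stop("config error: no reference species")
  if (!is.null(cfg$flankN) && cfg$flankN < 1L)
    stop("config error: flankN must be >= 1")
  if (cfg$maxTssGap <= 0) stop("config error: maxTssGap must be > 0")

  # ---- inputs -------------------------------------------------------------
  if (!is.null(cfg$clade)) {
    data <- cfg$clade$species
  } else if (!is.null(cfg$species)) {
    data <- lapply(names(cfg$species), function(sp) {
      ann <- readGFF3(cfg$species[[sp]]$gff, speciesID = sp)
      gen <- readFasta(cfg$species[[sp]]$fasta)
      list(annotation = ann, genome = gen,
           proteome = extractProteome(ann, gen))
    })
    names(data) <- names(cfg$species)
  } else stop("config error: provide 'clade' or 'species'")
  allSpecies <- names(data)
  if (!cfg$reference %in% allSpecies)
    stop("config error: reference species '", cfg$reference,
         "' not among inputs")
  if (length(allSpecies) < 3L)
    stop("config error: need at least 3 species")
  ref <- cfg$reference
  if (is.null(cfg$anchorFamilies))
    stop("config error: anchorFamilies required")

  # ---- orthology (star topology around the reference) --------------------
  rbhList <- list()
  for (sp in setdiff(allSpecies, ref)) {
    rbhList[[sp]] <- tryCatch(
      reciprocalBestHits(data[[ref]]$proteome, data[[sp]]$proteome,
                         minScore = cfg$minScore,
                         minAlignedFraction = cfg$minAlignedFraction,
                         gapOpen = cfg$gapOpen, gapExtend = cfg$gapExtend),
      error = function(e) {
        warning("orthology failed for ", sp, ": ", conditionMessage(e))
        data.frame(geneA = character(0), geneB = character(0),
                   score = numeric(0))
      })
  }
  orthologs <- buildOrthologGroups(rbhList, names(data[[ref]]$proteome), ref)
  geneGroups <- orthologs[, c("species", "gene", "group")]

  # ---- divergent pairs ----------------------------------------------------
  pairs <- do.call(rbind, lapply(allSpecies, function(sp)
    detectDivergentPairs(data[[sp]]$annotation, maxTssGap = cfg$maxTssGap)))

  presence <- summarizePairPresence(pairs, geneGroups, cfg$anchorFamilies,
                                    species = allSpecies)

  # ---- microsynteny -------------------------------------------------------
  groupsOf <- function(sp) {
    gg <- geneGroups[geneGroups$species == sp, ]
    stats::setNames(gg$group, gg$gene)
  }
  familyPairOf <- function(sp, fam) {
    # the detected pair of species sp whose genes map to family fam's groups
    grp <- groupsOf(sp)
    pp <- pairs[pairs$species == sp, , drop = FALSE]
    for (r in seq_len(nrow(pp))) {
      gl <- grp[pp$geneLeft[r]]; gr <- grp[pp$geneRight[r]]
      if (!is.na(gl) && !is.na(gr) && gl != gr &&
          all(c(gl, gr) %in% cfg$anchorFamilies[[fam]]))
        return(c(pp$geneLeft[r], pp$geneRight[r]))
    }
    NULL
  }
  synRows <- list()
  delRows <- list()
  for (fam in names(cfg$anchorFamilies)) {
    refAnchor <- familyPairOf(ref, fam)
    if (is.null(refAnchor)) {
      warning("reference species lacks a detected pair for family ", fam)
      next
    }
    refBlock <- extractWindow(data[[ref]]$annotation, refAnchor,
                              flankN = cfg$flankN, groups = groupsOf(ref),
                              anchorLabel = fam)
    for (sp in setdiff(allSpecies, ref)) {
      res <- tryCatch({
        anchor <- familyPairOf(sp, fam)
        if (!is.null(anchor)) {
          blk <- extractWindow(data[[sp]]$annotation, anchor,
                               flankN = cfg$flankN, groups = groupsOf(sp),
                               anchorLabel = fam)
          cmp <- compareBlocks(refBlock, blk, minFrac = cfg$minFrac,
                               minInvRun = cfg$minInvRun,
                               minJaccard = cfg$minJaccard)
          synRows[[length(synRows) + 1L]] <- data.frame(
            speciesA = ref, speciesB = sp, anchor = fam,
            jaccard = cmp$jaccard, collinearRun = cmp$collinearRun,
            reversedRun = cmp$reversedRun, event = cmp$event,
            stringsAsFactors = FALSE)
        } else {
          dc <- detectPreciseDeletion(refBlock, data[[sp]]$annotation,
                                      groupsOf(sp),
                                      maxGapGenes = cfg$maxGapGenes)
          delRows[[length(delRows) + 1L]] <- data.frame(
            species = sp, anchor = fam, status = dc$status,
            intergenicGapGenes = dc$intergenicGapGenes,
            stringsAsFactors = FALSE)
        }
        NULL
      }, error = function(e) {
        warning("synteny stage failed for ", sp, "/", fam, ": ",
                conditionMessage(e))
        NULL
      })
    }
  }
  syntenyEvents <- if (length(synRows)) do.call(rbind, synRows) else
    data.frame(speciesA = character(0), speciesB = character(0),
               anchor = character(0), jaccard = numeric(0),
               collinearRun = integer(0), reversedRun = integer(0),
               event = character(0))
  deletionCalls <- if (length(delRows)) do.call(rbind, delRows) else
    data.frame(species = character(0), anchor = character(0),
               status = character(0), intergenicGapGenes = integer(0))

  # ---- progenitor assignment from NC1 domains -----------------------------
  chainGroups <- unlist(cfg$anchorFamilies, use.names = FALSE)
  chains <- orthologs[orthologs$group %in% chainGroups, , drop = FALSE]
  prog <- tryCatch({
    seqs <- character(0)
    types <- character(0)
    basePair <- names(cfg$anchorFamilies)[1L]
    alpha1Ref <- cfg$anchorFamilies[[basePair]][1L]
    alpha2Ref <- cfg$anchorFamilies[[basePair]][2L]
    for (r in seq_len(nrow(chains))) {
      sp <- chains$species[r]; gid <- chains$gene[r]
      nc1 <- nc1Domain(data[[sp]]$proteome[[gid]],
                       minRunTriplets = cfg$minRunTriplets,
                       maxInterruption = cfg$maxInterruption)
      if (!nzchar(nc1)) next
      seqs[[gid]] <- nc1
      types[[gid]] <-
        if (sp == ref && gid == alpha1Ref) "alpha1_type"
        else if (sp == ref && gid == alpha2Ref) "alpha2_type"
        else "query"
    }
    if (length(seqs) >= 3L) {
      D <- pairwiseDistances(seqs, gapOpen = cfg$gapOpen,
                             gapExtend = cfg$gapExtend)
      tr <- neighborJoining(D)
      assign <- assignProgenitors(tr, types)
      list(newick = ape::write.tree(tr),
           table = data.frame(
             gene = names(assign),
             species = chains$species[match(names(assign), chains$gene)],
             group = chains$group[match(names(assign), chains$gene)],
             progenitor = unname(assign), stringsAsFactors = FALSE))
    } else NULL
  }, error = function(e) {
    warning("progenitor stage failed: ", conditionMessage(e))
    NULL
  })
  treeNewick <- prog$newick
  progenitors <- prog$table

  # ---- cysteine census ----------------------------------------------------
  cysRows <- list()
  for (sp in allSpecies) {
    grp <- groupsOf(sp)
    for (fam in names(cfg$anchorFamilies)) {
      members <- names(grp)[grp %in% cfg$anchorFamilies[[fam]]]
      if (length(members) != 2L) next
      tryCatch({
        tot <- 0L; coll <- 0L; nc1 <- 0L
        for (gid in members) {
          p <- data[[sp]]$proteome[[gid]]
          dom <- parseCollagenDomains(p, cfg$minRunTriplets,
                                      cfg$maxInterruption)
          prof <- countCysteines(p, dom)
          tot <- tot + prof$total
          coll <- coll + prof$counts["collagenous"]
          nc1 <- nc1 + prof$counts["cterm_nc1"]
        }
        cysRows[[length(cysRows) + 1L]] <- data.frame(
          species = sp, pair = fam, collagenousCys = unname(coll),
          nc1Cys = unname(nc1), total = tot,
          habitat = if (!is.null(cfg$habitats)) cfg$habitats[[sp]] %||%
            NA_character_ else NA_character_,
          stringsAsFactors = FALSE)
      }, error = function(e)
        warning("cysteine stage failed for ", sp, "/", fam, ": ",
                conditionMessage(e)))
    }
  }
  cysteineProfiles <- if (length(cysRows)) do.call(rbind, cysRows) else NULL

  habitatTest <- NULL
  if (!is.null(cfg$habitats) && !is.null(cysteineProfiles)) {
    pairLab <- cfg$cysteinePair %||% "A34"
    sub <- cysteineProfiles[cysteineProfiles$pair == pairLab &
                              !is.na(cysteineProfiles$habitat), , drop = FALSE]
    habitatTest <- tryCatch(
      habitatPermutationTest(
        stats::setNames(sub$total, sub$species),
        stats::setNames(sub$habitat, sub$species),
        nPerm = cfg$nPerm,
        seed = deriveSeed(cfg$seed, "habitat_test")),
      error = function(e) {
        warning("habitat test skipped: ", conditionMessage(e))
        NULL
      })
  }

  log <- cfg[c("maxTssGap", "flankN", "minScore", "minAlignedFraction",
               "gapOpen", "gapExtend", "minFrac", "minInvRun", "minJaccard",
               "maxGapGenes", "minRunTriplets", "maxInterruption", "nPerm",
               "seed")]
  log$reference <- ref
  log$species <- allSpecies

  bundle <- list(presence = presence, pairs = pairs, orthologs = orthologs,
                 syntenyEvents = syntenyEvents, deletionCalls = deletionCalls,
                 treeNewick = treeNewick, progenitors = progenitors,
                 cysteineProfiles = cysteineProfiles,
                 habitatTest = habitatTest, log = log)
  if (!is.null(cfg$outDir)) writeReportBundle(bundle, cfg$outDir)
  bundle
}

#' Write a report bundle to a directory as TSV/JSON files
#'
#' @param bundle output of [runPipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeReportBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(df, name) {
    if (!is.null(df) && nrow(df))
      utils::write.table(df, file.path(dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  wtsv(bundle$presence, "presence.tsv")
  wtsv(bundle$pairs, "pairs.tsv")
  wtsv(bundle$orthologs, "orthologs.tsv")
  wtsv(bundle$syntenyEvents, "synteny_events.tsv")
  wtsv(bundle$deletionCalls, "deletion_calls.tsv")
  wtsv(bundle$progenitors, "progenitors.tsv")
  wtsv(bundle$cysteineProfiles, "cysteine_profiles.tsv")
  if (!is.null(bundle$treeNewick))
    writeLines(bundle$treeNewick, file.path(dir, "nc1_tree.nwk"))
  jsonlite::write_json(
    list(log = bundle$log, habitatTest = bundle$habitatTest),
    file.path(dir, "run_log.json"), auto_unbox = TRUE, null = "null",
    digits = NA)
  invisible(dir)
}

#' Clade spec replaying the inferred duplication history of the pair family
#'
#' A ready-made [simulateClade()] spec encoding the inferred scenario: the
#' ancestral A12 pair duplicates into A34 on the branch to the vertebrate
#' ancestor (so cyclostomes carry A12 + A34), duplicates again into A56 on
#' the gnathostome branch, and A34 is precisely deleted on the amphibian
#' branch. The odd chain of each derived pair descends from the alpha1-like
#' chain and the even chain from the alpha2-like chain. Includes a basal
#' deuterostome outgroup carrying only A12.
#'
#' @param seed RNG seed for the simulation.
#' @param rate substitutions per site per unit branch length (default 0.02).
#' @param chain optional chain-dimension overrides (see [simulateClade()]).
#' @return a clade spec list.
#' @export
col4ScenarioSpec <- function(seed = 1L, rate = 0.02, chain = NULL) {
  list(
    newick = paste0(
      "(amphioxus:2,((hagfish:1,lamprey:1)cyclostomes:1,",
      "(shark:1.5,(caecilian:1,(mouse:0.5,lizard:0.5)amniotes:0.5)",
      "tetrapods:0.5)gnathostomes:0.5)vertebrates:1)root;"),
    events = list(
      vertebrates = list(
        list(
          type = "duplicate_pair", source = "A12", new = "A34",
          left = "COL4A3", right = "COL4A4",
          leftFrom = "COL4A1", rightFrom = "COL4A2",
          flankLeft = c("SLC19A3", "AGFG1", "COPS8", "MRPL44", "MFF"),
          flankRight = c("RHBDD1", "IRS1", "NYAP2", "SPHKAP", "PID1")),
        # the derived pair gains triple-helical cysteines, the crosslinking
        # adaptation that distinguishes the alpha345 scaffold
        list(type = "cys_gain", pair = "A34", delta = 16L)),
      gnathostomes = list(list(
        type = "duplicate_pair", source = "A12", new = "A56",
        left = "COL4A5", right = "COL4A6",
        leftFrom = "COL4A1", rightFrom = "COL4A2",
        flankLeft = c("TMEM164", "AMMECR1", "SASH3", "ZDHHC9", "UTP14A"),
        flankRight = c("IRS4", "GUCY2F", "NXT2", "KCNE1B", "ACSL4"))),
      caecilian = list(list(type = "delete_pair_precise", anchor = "A34"))),
    habitats = c(amphioxus = "marine", hagfish = "marine",
                 lamprey = "freshwater", shark = "estuarine",
                 caecilian = "terrestrial", mouse = "terrestrial",
                 lizard = "terrestrial"),
    rate = rate,
    chain = chain,
    seed = as.integer(seed)
  )
}
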