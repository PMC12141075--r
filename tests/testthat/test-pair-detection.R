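grOf <- function(start, end, strand, region = "chr1")
  GenomicRanges::GRanges(region, IRanges::IRanges(start, end), strand = strand)

test_that("arrangement classification covers the four orientations", {
  hh <- classifyArrangement(grOf(1, 100, "-"), grOf(151, 250, "+"))
  expect_equal(hh$arrangement, "head_to_head")
  expect_equal(hh$tssGap, 50L)  # bases strictly between the two TSSs
  expect_equal(classifyArrangement(grOf(1, 100, "+"),
                                   grOf(151, 250, "+"))$arrangement,
               "head_to_tail")
  expect_equal(classifyArrangement(grOf(1, 100, "+"),
                                   grOf(151, 250, "-"))$arrangement,
               "tail_to_tail")
  un <- classifyArrangement(grOf(1, 100, "-"),
                            grOf(151, 250, "+", region = "chr2"))
  expect_equal(un$arrangement, "unlinked")
  expect_true(is.na(un$tssGap))
  ov <- classifyArrangement(grOf(1, 100, "-"), grOf(80, 250, "+"))
  expect_true(ov$overlap)
  expect_equal(ov$tssGap, 0L)
  # argument order does not matter
  hh2 <- classifyArrangement(grOf(151, 250, "+"), grOf(1, 100, "-"))
  expect_equal(hh2$arrangement, "head_to_head")
})

test_that("a tandem same-strand array yields no divergent pairs", {
  ann <- makeAnn("sp", "chr1", c(1, 201, 401, 601), c(100, 300, 500, 700),
                 rep("+", 4), paste0("g", 1:4))
  expect_equal(nrow(detectDivergentPairs(ann)), 0L)
})

test_that("each gene joins at most one pair and gap ceiling is honoured", {
  ann <- makeAnn("sp", "chr1", c(1, 201, 401), c(100, 300, 500),
                 c("-", "+", "-"), paste0("g", 1:3))
  p <- detectDivergentPairs(ann)
  expect_equal(nrow(p), 1L)
  expect_equal(p$geneLeft, "g1")
  expect_equal(p$geneRight, "g2")
  # gap ceiling excludes the pair entirely
  expect_equal(nrow(detectDivergentPairs(ann, maxTssGap = 50L)), 0L)
})

test_that("detection is invariant under translation and mirror reflection", {
  ann <- makeAnn("sp", "chr1",
                 c(1, 501, 1001, 2001, 3001), c(400, 900, 1800, 2800, 3700),
                 c("+", "-", "+", "-", "+"), paste0("g", 1:5))
  base <- detectDivergentPairs(ann)
  # translation by a constant offset
  g <- geneRanges(ann)
  annT <- makeAnn("sp", "chr1", GenomicRanges::start(g) + 10000L,
                  GenomicRanges::end(g) + 10000L,
                  as.character(GenomicRanges::strand(g)), geneIDs(ann))
  shifted <- detectDivergentPairs(annT)
  expect_equal(shifted[c("geneLeft", "geneRight", "tssGap")],
               base[c("geneLeft", "geneRight", "tssGap")])
  # mirror: reflect coordinates and flip strands; head-to-head adjacencies
  # must map onto head-to-head adjacencies with the same gaps
  L <- 5000L
  flip <- c(`+` = "-", `-` = "+")
  annM <- makeAnn("sp", "chr1", L - GenomicRanges::end(g),
                  L - GenomicRanges::start(g),
                  unname(flip[as.character(GenomicRanges::strand(g))]),
                  geneIDs(ann))
  mirrored <- detectDivergentPairs(annM)
  expect_equal(nrow(mirrored), nrow(base))
  expect_equal(sort(mirrored$tssGap), sort(base$tssGap))
  expect_setequal(c(mirrored$geneLeft, mirrored$geneRight),
                  c(base$geneLeft, base$geneRight))
})

test_that("planted divergent pairs are recovered exactly on simulated clades", {
  for (seed in 1:4) {
    clade <- simulateClade(recoveryCladeSpec(seed))
    for (sp in names(clade$species)) {
      det <- detectDivergentPairs(clade$species[[sp]]$annotation)
      truth <- clade$truth[[sp]]$pairs
      expect_equal(nrow(det), nrow(truth))
      expect_setequal(det$geneLeft, paste0(sp, "_", truth$leftFamily))
      expect_setequal(det$geneRight, paste0(sp, "_", truth$rightFamily))
      # every reported pair satisfies the head-to-head predicate
      expect_true(all(det$arrangement == "head_to_head"))
      expect_false(any(duplicated(c(det$geneLeft, det$geneRight))))
    }
  }
})

test_that("presence summary distinguishes paired, unpaired and absent", {
  pairs <- data.frame(species = "sp1", region = "chr1",
                      geneLeft = "sp1_a2", geneRight = "sp1_a1",
                      arrangement = "head_to_head", tssGap = 500L,
                      stringsAsFactors = FALSE)
  geneGroups <- data.frame(
    species = c("sp1", "sp1", "sp2", "sp2"),
    gene = c("sp1_a1", "sp1_a2", "sp2_x", "sp2_y"),
    group = c("COL4A1", "COL4A2", "COL4A1", "COL4A2"),
    stringsAsFactors = FALSE)
  fams <- list(A12 = c("COL4A1", "COL4A2"), A34 = c("COL4A3", "COL4A4"))
  expect_warning(
    tab <- summarizePairPresence(pairs, geneGroups, fams,
                                 species = c("sp1", "sp2", "sp3")),
    "sp3")
  expect_equal(tab$A12[tab$species == "sp1"], "present_paired")
  # sp2 has both genes but no detected pair: singleton/unlinked loci
  expect_equal(tab$A12[tab$species == "sp2"], "present_unpaired")
  expect_equal(tab$A12[tab$species == "sp3"], "absent")
  expect_true(all(tab$A34 == "absent"))
})
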