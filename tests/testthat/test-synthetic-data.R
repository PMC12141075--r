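test_that("collagen ORFs have the requested composition", {
  orf <- generateCollagenORF(nTriplets = 10, nCysCollagenous = 2,
                             nCysNC1 = 3, nc1Length = 40, seed = 2)
  expect_equal(nchar(orf$protein), 30L + 40L)
  ch <- strsplit(orf$protein, "")[[1]]
  expect_equal(sum(ch[1:30] == "C"), 2L)
  expect_equal(sum(ch[31:70] == "C"), 3L)
  # every collagenous triplet starts with Gly
  expect_true(all(ch[seq(1, 28, 3)] == "G"))
  # the CDS translates back to the protein
  expect_equal(
    sub("\\*$", "", as.character(
      Biostrings::translate(Biostrings::DNAString(orf$cds)))),
    orf$protein)
  # determinism and seed sensitivity
  expect_identical(orf,
                   generateCollagenORF(nTriplets = 10, nCysCollagenous = 2,
                                       nCysNC1 = 3, nc1Length = 40, seed = 2))
  expect_false(identical(orf$protein,
                         generateCollagenORF(nTriplets = 10,
                                             nCysCollagenous = 2,
                                             nCysNC1 = 3, nc1Length = 40,
                                             seed = 3)$protein))
})

test_that("generator and parser agree on planted domain boundaries", {
  for (seed in 1:5) {
    orf <- generateCollagenORF(
      nTriplets = 40, nCysCollagenous = 6, nCysNC1 = 5, nc1Length = 80,
      interruptions = data.frame(position = c(15, 30), length = c(6, 12)),
      seed = seed)
    dom <- parseCollagenDomains(orf$protein)
    expect_equal(dom, orf$segments, ignore_attr = TRUE)
  }
})

test_that("infeasible cysteine requests are rejected", {
  expect_error(generateCollagenORF(nTriplets = 5, nCysCollagenous = 11,
                                   nc1Length = 10, seed = 1),
               "infeasible")
  expect_error(
    generateCollagenORF(nTriplets = 12, seed = 1,
                        interruptions = data.frame(position = 2, length = 5)),
    "shorter")
})

test_that("sequence mutation honours rate, protection and determinism", {
  s <- strrep("ACGT", 2500)
  expect_identical(mutateSequence(s, 0, seed = 1), s)
  m1 <- mutateSequence(s, 1, seed = 1)
  expect_false(any(strsplit(m1, "")[[1]] == strsplit(s, "")[[1]]))
  m <- mutateSequence(s, 0.1, seed = 7)
  frac <- mean(strsplit(m, "")[[1]] != strsplit(s, "")[[1]])
  expect_lt(abs(frac - 0.1), 0.01)  # ~3 binomial sd at n = 10,000
  mp <- mutateSequence(s, 1, seed = 2, protect = 1:100)
  expect_equal(substr(mp, 1, 100), substr(s, 1, 100))
  expect_identical(mutateSequence(s, 0.3, seed = 9),
                   mutateSequence(s, 0.3, seed = 9))
})

test_that("zero-rate, zero-event clades leave all species identical", {
  spec <- list(newick = "((a:1,b:1)ab:1,c:2)root;", events = list(),
               rate = 0, chain = list(nTriplets = 10L, nc1Length = 20L,
                                      nCysNC1 = 2L), seed = 11)
  clade <- simulateClade(spec)
  pa <- clade$species$a$proteome
  expect_identical(unname(pa), unname(clade$species$b$proteome))
  expect_identical(unname(pa), unname(clade$species$c$proteome))
  # identical spec implies identical output
  clade2 <- simulateClade(spec)
  expect_identical(clade$species$a$genome, clade2$species$a$genome)
  expect_identical(clade$truth, clade2$truth)
})

test_that("events referencing missing anchors fail before generation", {
  spec <- recoveryCladeSpec(1)
  spec$events$s3 <- list(list(type = "delete_pair_precise", anchor = "A56"))
  expect_error(simulateClade(spec), "missing pair 'A56'")
  spec2 <- recoveryCladeSpec(1)
  spec2$events$zz <- list(list(type = "invert_window", anchor = "A12"))
  expect_error(simulateClade(spec2), "unknown tree node")
})

test_that("emitted files round-trip through the annotation readers", {
  clade <- simulateClade(recoveryCladeSpec(3))
  dir <- tempfile()
  paths <- writeClade(clade, dir)
  expect_true(file.exists(file.path(dir, "truth.json")))
  for (sp in c("s1", "s2")) {
    ann <- readGFF3(paths[[sp]]$gff, speciesID = sp)
    genome <- readFasta(paths[[sp]]$fasta)
    mem <- clade$species[[sp]]$annotation
    expect_equal(geneIDs(ann), geneIDs(mem))
    expect_equal(GenomicRanges::start(geneRanges(ann)),
                 GenomicRanges::start(geneRanges(mem)))
    expect_equal(as.character(GenomicRanges::strand(geneRanges(ann))),
                 as.character(GenomicRanges::strand(geneRanges(mem))))
    # translations reproduce the truth proteome exactly
    prots <- extractProteome(ann, genome)
    expect_identical(prots[names(clade$species[[sp]]$proteome)],
                     clade$species[[sp]]$proteome)
  }
})

test_that("precise deletion leaves the innermost flanks adjacent", {
  clade <- simulateClade(recoveryCladeSpec(5))
  # s2 deleted A34: its chr2 must contain the A34 flanks with no chain genes
  fams_s1 <- clade$truth$s1$flankOrder$chr2$family
  fams_s2 <- clade$truth$s2$flankOrder$chr2$family
  expect_true(all(c("COL4A3", "COL4A4") %in% fams_s1))
  expect_false(any(c("COL4A3", "COL4A4") %in% fams_s2))
  expect_equal(setdiff(fams_s1, fams_s2), c("COL4A3", "COL4A4"))
  # order of the surviving flanks is unchanged
  expect_equal(fams_s2, setdiff(fams_s1, c("COL4A3", "COL4A4")))
  # and the emitted annotation has the innermost flanks adjacent
  ids <- geneIDs(clade$species$s2$annotation)
  i <- match("s2_A34FL5", ids)  # innermost left flank
  j <- match("s2_A34FR1", ids)  # innermost right flank
  expect_equal(j, i + 1L)
})
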