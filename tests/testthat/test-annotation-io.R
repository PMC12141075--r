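test_that("GFF3 genes are read with native 1-based closed coordinates", {
  f <- writeTempGFF3(c(
    "chr1\tsrc\tgene\t100\t200\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t100\t200\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\tsrc\tCDS\t100\t200\t.\t+\t0\tID=g1.c1;Parent=g1.t1"))
  ann <- readGFF3(f, speciesID = "sp")
  expect_equal(length(geneRanges(ann)), 1L)
  expect_equal(GenomicRanges::start(geneRanges(ann)), 100L)
  expect_equal(GenomicRanges::end(geneRanges(ann)), 200L)
  expect_equal(geneIDs(ann), "g1")
})

test_that("an empty GFF3 yields an empty annotation", {
  f <- tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", f)
  ann <- readGFF3(f, speciesID = "sp")
  expect_equal(length(geneRanges(ann)), 0L)
})

test_that("CDS segments come back in transcription (5'->3') order", {
  f <- writeTempGFF3(c(
    "chr1\tsrc\tgene\t10\t33\t.\t-\t.\tID=g1",
    "chr1\tsrc\tmRNA\t10\t33\t.\t-\t.\tID=g1.t1;Parent=g1",
    "chr1\tsrc\tCDS\t10\t18\t.\t-\t0\tID=c1;Parent=g1.t1",
    "chr1\tsrc\tCDS\t25\t33\t.\t-\t0\tID=c2;Parent=g1.t1"))
  ann <- readGFF3(f, speciesID = "sp")
  segs <- cdsSegments(ann, "g1")
  # minus strand: the 25..33 segment is 5'-most
  expect_equal(GenomicRanges::start(segs), c(25L, 10L))
  expect_equal(GenomicRanges::end(segs), c(33L, 18L))
})

test_that("multi-transcript genes keep the longest CDS, ties lexicographic", {
  f <- writeTempGFF3(c(
    "chr1\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t1\t100\t.\t+\t.\tID=g1.tB;Parent=g1",
    "chr1\tsrc\tCDS\t1\t30\t.\t+\t0\tID=cB;Parent=g1.tB",
    "chr1\tsrc\tmRNA\t1\t100\t.\t+\t.\tID=g1.tA;Parent=g1",
    "chr1\tsrc\tCDS\t1\t60\t.\t+\t0\tID=cA;Parent=g1.tA"))
  ann <- readGFF3(f, speciesID = "sp")
  expect_equal(GenomicRanges::end(cdsSegments(ann, "g1")), 60L)
})

test_that("malformed GFF3 lines raise informative errors", {
  f <- writeTempGFF3("chr1\tsrc\tgene\t100\t200\t.\t+")  # 7 columns
  expect_error(readGFF3(f), "line 2")
  f2 <- writeTempGFF3("chr1\tsrc\tgene\t200\t100\t.\t+\t.\tID=g1")
  expect_error(readGFF3(f2), "end < start")
  f3 <- writeTempGFF3(c(
    "chr1\tsrc\tgene\t1\t9\t.\t+\t.\tID=g1",
    "chr1\tsrc\tCDS\t1\t9\t.\t+\t0\tID=c1;Parent=nosuch"))
  expect_error(readGFF3(f3), "linkage")
})

test_that("FASTA reading takes first-token ids and uppercases", {
  expect_equal(readFasta(writeTempFasta(c(">a", "ACGT"))), c(a = "ACGT"))
  expect_equal(readFasta(writeTempFasta(c(">a desc", "ac", "gt"))),
               c(a = "ACGT"))
  expect_error(readFasta(writeTempFasta(c(">a", "AC", ">a", "GT"))),
               "duplicate")
  expect_error(readFasta(writeTempFasta(c(">a", "", ">b", "ACGT"))), "empty")
})

test_that("FASTA round-trips through write/read", {
  seqs <- c(g1 = paste(rep("ACGTA", 30), collapse = ""), g2 = "TTTT")
  f <- tempfile(fileext = ".fa")
  writeFasta(seqs, f)
  expect_equal(readFasta(f), seqs)
})

test_that("protein extraction splices, reverse-complements and translates", {
  ann <- makeAnn("sp", "chr1", 1, 9, "+", "g1")
  expect_equal(extractProtein(ann, c(chr1 = "ATGGGTTGA"), "g1"), "MG")
  # minus strand: genomic TCACCCCAT reverse-complements to ATGGGGTGA -> "MG"
  annm <- makeAnn("sp", "chr1", 1, 9, "-", "g1")
  expect_equal(extractProtein(annm, c(chr1 = "TCACCCCAT"), "g1"), "MG")
})

test_that("frame and internal-stop problems are reported", {
  ann <- makeAnn("sp", "chr1", 1, 8, "+", "g1")
  expect_error(extractProtein(ann, c(chr1 = "ATGGGTTG"), "g1"), "frame")
  ann2 <- makeAnn("sp", "chr1", 1, 12, "+", "g1")
  expect_warning(
    p <- extractProtein(ann2, c(chr1 = "ATGTAAGGTTGA"), "g1"),
    "internal stop")
  expect_equal(p, "M")
})

test_that("translated length satisfies 3 * protein == CDS length - 3", {
  orf <- generateCollagenORF(nTriplets = 12, nCysCollagenous = 2,
                             nCysNC1 = 3, nc1Length = 30, seed = 5)
  ann <- makeAnn("sp", "chr1", 1, nchar(orf$cds), "+", "g1")
  p <- extractProtein(ann, c(chr1 = orf$cds), "g1")
  expect_equal(3L * nchar(p), nchar(orf$cds) - 3L)
})

test_that("GFF3 writing round-trips coordinates, strands and gene order", {
  clade <- simulateClade(list(
    newick = "(a:1,b:1)root;", events = list(), rate = 0,
    chain = list(nTriplets = 10L, nc1Length = 20L, nCysNC1 = 2L), seed = 3))
  ann <- clade$species$a$annotation
  f <- tempfile(fileext = ".gff3")
  writeGFF3(ann, f)
  back <- readGFF3(f, speciesID = "a")
  expect_equal(geneIDs(back), geneIDs(ann))
  expect_equal(GenomicRanges::start(geneRanges(back)),
               GenomicRanges::start(geneRanges(ann)))
  expect_equal(GenomicRanges::end(geneRanges(back)),
               GenomicRanges::end(geneRanges(ann)))
  expect_equal(as.character(GenomicRanges::strand(geneRanges(back))),
               as.character(GenomicRanges::strand(geneRanges(ann))))
  # stable under re-read
  f2 <- tempfile(fileext = ".gff3")
  writeGFF3(back, f2)
  back2 <- readGFF3(f2, speciesID = "a")
  expect_equal(geneRanges(back2), geneRanges(back))
})
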