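test_that("windows are cut around the anchor with truncation flags", {
  n <- 12L
  ann <- makeAnn("sp", "chr1", seq(1, by = 1000, length.out = n),
                 seq(500, by = 1000, length.out = n),
                 c(rep("+", 5), "-", "+", rep("+", 5)),
                 paste0("g", 1:n))
  groups <- stats::setNames(paste0("G", 1:n), paste0("g", 1:n))
  blk <- extractWindow(ann, c("g6", "g7"), flankN = 5, groups = groups,
                       anchorLabel = "A12")
  e <- blockEntries(blk)
  expect_equal(nrow(e), 12L)
  expect_equal(e$gene[e$isAnchor], c("g6", "g7"))
  expect_false(blockTruncated(blk))
  # anchor 2 genes from the contig start: left side truncated
  ann2 <- makeAnn("sp", "chr1", seq(1, by = 1000, length.out = 8),
                  seq(500, by = 1000, length.out = 8),
                  c("+", "+", "-", "+", rep("+", 4)), paste0("g", 1:8))
  blk2 <- extractWindow(ann2, c("g3", "g4"), flankN = 5,
                        groups = stats::setNames(paste0("G", 1:8),
                                                 paste0("g", 1:8)))
  expect_true(blk2@truncatedLeft)
  expect_equal(nrow(blockEntries(blk2)), 8L)
  expect_error(extractWindow(ann, c("g2", "g7"), groups = groups),
               "adjacent")
})

test_that("the canonical A34 window lists its groups in order", {
  fams <- c("MRPL44", "MFF", "COL4A3", "COL4A4", "RHBDD1", "IRS1")
  ann <- makeAnn("sp", "chr2", seq(1, by = 2000, length.out = 6),
                 seq(900, by = 2000, length.out = 6),
                 c("+", "+", "-", "+", "+", "+"),
                 paste0("sp_", fams))
  groups <- stats::setNames(fams, paste0("sp_", fams))
  blk <- extractWindow(ann, c("sp_COL4A3", "sp_COL4A4"), flankN = 2,
                       groups = groups, anchorLabel = "A34")
  expect_equal(blockEntries(blk)$group, fams)
})

test_that("identical blocks are conserved; mirrored blocks are inverted", {
  g <- paste0("G", 1:11)
  s <- rep(c("+", "-"), length.out = 11)
  a <- makeBlock(g, s)
  same <- compareBlocks(a, a)
  expect_equal(same$jaccard, 1)
  expect_equal(same$collinearRun, 11L)
  expect_equal(same$event, "conserved")
  flip <- c(`+` = "-", `-` = "+")
  b <- makeBlock(rev(g), unname(flip[rev(s)]))
  inv <- compareBlocks(a, b)
  expect_equal(inv$reversedRun, 11L)
  expect_equal(inv$event, "inverted")
  # involution: inverting the inverted block restores conservation
  c2 <- makeBlock(rev(rev(g)), unname(flip[unname(flip[rev(rev(s))])]))
  expect_equal(compareBlocks(a, c2)$event, "conserved")
})

test_that("a single gene loss keeps a long collinear run", {
  a <- makeBlock(paste0("G", 1:5), rep("+", 5))
  b <- makeBlock(paste0("G", c(1, 2, 4, 5)), rep("+", 4))
  cmp <- compareBlocks(a, b)
  expect_equal(cmp$collinearRun, 4L)
  expect_equal(cmp$collinearRun,
               bruteLCS(paste0("G", 1:5), rep("+", 5),
                        paste0("G", c(1, 2, 4, 5)), rep("+", 4)))
})

test_that("collinear and reversed runs match brute-force LCS enumeration", {
  set.seed(5)
  flip <- c(`+` = "-", `-` = "+")
  for (k in 1:30) {
    na <- sample(2:8, 1); nb <- sample(2:8, 1)
    ga <- paste0("G", sample(1:6, na, replace = TRUE))
    gb <- paste0("G", sample(1:6, nb, replace = TRUE))
    sa <- sample(c("+", "-"), na, replace = TRUE)
    sb <- sample(c("+", "-"), nb, replace = TRUE)
    cmp <- compareBlocks(makeBlock(ga, sa), makeBlock(gb, sb))
    expect_equal(cmp$collinearRun, bruteLCS(ga, sa, gb, sb))
    expect_equal(cmp$reversedRun,
                 bruteLCS(ga, sa, rev(gb), unname(flip[rev(sb)])))
  }
})

test_that("unassigned genes are excluded from Jaccard and runs", {
  a <- makeBlock(c("G1", "unassigned", "G2", "G3"), rep("+", 4))
  b <- makeBlock(c("G1", "G2", "unassigned", "G3"), rep("+", 4))
  cmp <- compareBlocks(a, b)
  expect_equal(cmp$jaccard, 1)
  expect_equal(cmp$collinearRun, 3L)
  allun <- makeBlock(c("unassigned", "unassigned"), c("+", "+"))
  expect_warning(ind <- compareBlocks(a, allun), "indeterminate")
  expect_equal(ind$event, "indeterminate")
})

test_that("precise deletions are separated from insertions and presence", {
  # reference window: L2 L1 | A_left A_right | R1 R2
  ref <- makeBlock(c("L2", "L1", "AL", "AR", "R1", "R2"), rep("+", 6),
                   isAnchor = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE))
  mkQuery <- function(fams) {
    makeAnn("q", "chr1", seq(1, by = 1000, length.out = length(fams)),
            seq(500, by = 1000, length.out = length(fams)),
            rep("+", length(fams)), paste0("q_", seq_along(fams)))
  }
  grpOf <- function(fams) stats::setNames(fams, paste0("q_", seq_along(fams)))

  # flanks joined directly: precise deletion with gap 0
  q0 <- mkQuery(c("L2", "L1", "R1", "R2"))
  d0 <- detectPreciseDeletion(ref, q0, grpOf(c("L2", "L1", "R1", "R2")))
  expect_equal(d0$status, "precise_deletion")
  expect_equal(d0$intergenicGapGenes, 0L)
  # one novel gene in the gap still counts as precise when allowed
  q1 <- mkQuery(c("L2", "L1", "novel", "R1", "R2"))
  d1 <- detectPreciseDeletion(ref, q1,
                              grpOf(c("L2", "L1", "unassigned", "R1", "R2")),
                              maxGapGenes = 1L)
  expect_equal(d1$status, "precise_deletion")
  expect_equal(d1$intergenicGapGenes, 1L)
  # a large insertion exceeds the gap ceiling
  q5 <- mkQuery(c("L1", paste0("x", 1:5), "R1"))
  d5 <- detectPreciseDeletion(
    ref, q5, grpOf(c("L1", rep("unassigned", 5), "R1")), maxGapGenes = 3L)
  expect_equal(d5$status, "deletion_with_insertion")
  # anchor retained anywhere blocks the deletion call
  qa <- mkQuery(c("L1", "AL", "AR", "R1"))
  expect_equal(detectPreciseDeletion(ref, qa,
                                     grpOf(c("L1", "AL", "AR", "R1")))$status,
               "anchor_present")
  # flanks split across contigs: indeterminate
  qs <- makeAnn("q", c("c1", "c2"), c(1, 1), c(500, 500), c("+", "+"),
                c("q_1", "q_2"))
  expect_equal(detectPreciseDeletion(ref, qs,
                                     stats::setNames(c("L1", "R1"),
                                                     c("q_1", "q_2")))$status,
               "indeterminate")
})
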