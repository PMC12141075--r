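# Fixture builders: all test inputs are constructed in code.

# Build a GenomeAnnotation from parallel vectors; CDS defaults to the whole
# gene body (single segment).
makeAnn <- function(species, region, start, end, strand, gene,
                    cds = NULL) {
  gr <- GenomicRanges::GRanges(region, IRanges::IRanges(start, end),
                               strand = strand, gene_id = gene)
  if (is.null(cds)) {
    cds <- stats::setNames(lapply(seq_along(gr), function(i) {
      x <- gr[i]; S4Vectors::mcols(x) <- NULL; x
    }), gene)
  }
  GenomeAnnotation(species, gr, GenomicRanges::GRangesList(cds))
}

writeTempGFF3 <- function(lines) {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), f)
  f
}

writeTempFasta <- function(text) {
  f <- tempfile(fileext = ".fa")
  writeLines(text, f)
  f
}

# A SyntenyBlock straight from vectors (all non-anchor unless flagged).
makeBlock <- function(groups, strands, isAnchor = rep(FALSE, length(groups)),
                      species = "sp", anchor = "A", region = "chr1",
                      genes = paste0("g", seq_along(groups))) {
  new("SyntenyBlock", speciesID = species, anchor = anchor, region = region,
      entries = data.frame(gene = genes, group = groups, strand = strands,
                           isAnchor = isAnchor, stringsAsFactors = FALSE),
      truncatedLeft = FALSE, truncatedRight = FALSE)
}

# Small clade spec used for event-recovery experiments: a four-species tree
# where one inner branch duplicates A12 into A34, one leaf inverts the A12
# window, one leaf precisely deletes A34, and the others retain everything.
recoveryCladeSpec <- function(seed, rate = 0.03) {
  list(
    newick = "((s1:1,s2:1)n1:1,(s3:1,s4:1)n2:1)root;",
    events = list(
      n1 = list(list(type = "duplicate_pair", source = "A12", new = "A34",
                     left = "COL4A3", right = "COL4A4",
                     leftFrom = "COL4A1", rightFrom = "COL4A2")),
      s1 = list(list(type = "invert_window", anchor = "A12", span = 99L)),
      s2 = list(list(type = "delete_pair_precise", anchor = "A34"))),
    rate = rate,
    chain = list(nTriplets = 40L, nc1Length = 60L, nCysNC1 = 4L),
    seed = as.integer(seed)
  )
}

# Per-species gene -> family map from a clade's truth table ("true" ortholog
# groups, independent of the RBH machinery).
truthGroups <- function(clade, sp) {
  om <- clade$truth[[sp]]$orthologMap
  stats::setNames(om$family, om$gene)
}

# The planted pair genes of a species, as (left, right) gene ids.
truthPairGenes <- function(clade, sp, label) {
  tp <- clade$truth[[sp]]$pairs
  row <- tp[tp$label == label, ]
  if (!nrow(row)) return(NULL)
  c(paste0(sp, "_", row$leftFamily), paste0(sp, "_", row$rightFamily))
}
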