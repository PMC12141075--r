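#' Read a GFF3 genome annotation into a GenomeAnnotation
#'
#' Reads gene / mRNA / CDS features from a GFF3 file (1-based, closed
#' intervals, the native convention of both GFF3 and GRanges) and assembles
#' one gene model per gene. When a gene has several mRNAs, the transcript
#' with the longest total CDS is kept (ties broken by lexicographically
#' smallest transcript ID). CDS features may be attached to an mRNA or
#' directly to a gene.
#'
#' @param path path to a GFF3 file.
#' @param speciesID species identifier; defaults to the file name without
#'   extension.
#' @param assembly assembly name recorded in the annotation.
#' @return A [GenomeAnnotation-class].
#' @export
readGFF3 <- function(path, speciesID = NULL, assembly = "") {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(speciesID))
    speciesID <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  for (i in body) {
    nf <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (nf != 9L)
      stop("GFF3 parse error at line ", i, ": expected 9 tab-separated ",
           "columns, found ", nf)
  }
  if (!length(body)) {
    return(GenomeAnnotation(speciesID, GenomicRanges::GRanges(),
                            assembly = assembly))
  }
  # coordinate sanity before handing to the importer
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e) || e < s)
      stop("GFF3 coordinate error at line ", i, ": end < start or non-numeric")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  mrnas <- gr[type == "mRNA"]
  cdss <- gr[type == "CDS"]
  if (!length(genes))
    return(GenomeAnnotation(speciesID, GenomicRanges::GRanges(),
                            assembly = assembly))
  gene_ids <- as.character(genes$ID)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ID in GFF3: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ","))
  S4Vectors::mcols(genes) <- S4Vectors::DataFrame(gene_id = gene_ids)

  firstParent <- function(x) {
    p <- x$Parent
    vapply(seq_along(x), function(i) {
      pi <- p[[i]]
      if (length(pi)) pi[[1]] else NA_character_
    }, character(1))
  }
  mrna_parent <- if (length(mrnas)) firstParent(mrnas) else character(0)
  mrna_id <- if (length(mrnas)) as.character(mrnas$ID) else character(0)
  cds_parent <- if (length(cdss)) firstParent(cdss) else character(0)
  if (length(cdss) && anyNA(cds_parent))
    stop("CDS linkage error: CDS feature without a Parent attribute")
  unknown <- setdiff(cds_parent, c(mrna_id, gene_ids))
  if (length(unknown))
    stop("CDS linkage error: Parent '", unknown[1],
         "' matches no gene or mRNA")

  cds_list <- list()
  for (k in seq_along(gene_ids)) {
    gid <- gene_ids[k]
    # candidate transcripts of this gene, plus the gene itself for
    # annotations that attach CDS straight to the gene
    tx <- mrna_id[mrna_parent %in% gid]
    cand <- c(tx, gid)
    seg_sets <- lapply(cand, function(p) cdss[cds_parent == p])
    tot <- vapply(seg_sets, function(s) sum(GenomicRanges::width(s)), numeric(1))
    if (all(tot == 0)) next
    best <- which(tot == max(tot))
    if (length(best) > 1L) best <- best[order(cand[best])][1L]
    segs <- seg_sets[[best]]
    segs <- segs[order(GenomicRanges::start(segs))]
    S4Vectors::mcols(segs) <- NULL
    cds_list[[gid]] <- segs
  }
  GenomeAnnotation(speciesID, genes,
                   GenomicRanges::GRangesList(cds_list), assembly = assembly)
}

#' Write a GenomeAnnotation to GFF3
#'
#' Emits gene, mRNA and CDS features; coordinates and strands round-trip
#' exactly through [readGFF3()].
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGFF3 <- function(annotation, path) {
  g <- geneRanges(annotation)
  feats <- GenomicRanges::GRanges()
  if (length(g)) {
    ids <- geneIDs(annotation)
    rows <- list()
    for (k in seq_along(g)) {
      gid <- ids[k]
      gene <- g[k]
      S4Vectors::mcols(gene) <- S4Vectors::DataFrame(
        source = "pairsynt", type = "gene", ID = gid, Parent = NA_character_)
      rows[[length(rows) + 1L]] <- gene
      if (gid %in% names(annotation@cds)) {
        segs <- annotation@cds[[gid]]
        tid <- paste0(gid, ".t1")
        tx <- gene
        S4Vectors::mcols(tx) <- S4Vectors::DataFrame(
          source = "pairsynt", type = "mRNA", ID = tid, Parent = gid)
        rows[[length(rows) + 1L]] <- tx
        # phase: residues of the previous codon carried into each segment,
        # accumulated in transcription order
        tsegs <- cdsSegments(annotation, gid)
        cum <- c(0L, cumsum(GenomicRanges::width(tsegs)))
        phase <- stats::setNames(
          (3L - cum[seq_along(tsegs)] %% 3L) %% 3L,
          paste(GenomicRanges::start(tsegs), GenomicRanges::end(tsegs)))
        for (j in seq_along(segs)) {
          cj <- segs[j]
          key <- paste(GenomicRanges::start(cj), GenomicRanges::end(cj))
          S4Vectors::mcols(cj) <- S4Vectors::DataFrame(
            source = "pairsynt", type = "CDS",
            ID = paste0(gid, ".c", j), Parent = tid,
            phase = unname(phase[key]))
          rows[[length(rows) + 1L]] <- cj
        }
      }
    }
    feats <- do.call(c, rows)
  }
  rtracklayer::export(feats, path, format = "gff3")
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' Identifiers are the first whitespace-delimited token of each header;
#' sequences are uppercased. Duplicate identifiers and empty records are
#' errors.
#'
#' @param path path to a FASTA file (nucleotide or amino acid).
#' @return named character vector of sequences.
#' @export
readFasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate sequence identifier: ",
         paste(unique(ids[duplicated(ids)]), collapse = ","))
  seqs <- toupper(as.character(ss))
  if (any(!nzchar(seqs)))
    stop("empty sequence record: ", paste(ids[!nzchar(seqs)], collapse = ","))
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA (wrapped at 60 columns)
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 60L)
  invisible(path)
}

#' Transcription start site of each gene
#'
#' The gene's 5'-most coordinate in transcription orientation: `start` for
#' "+" genes, `end` for "-" genes. Gene bounds stand in for an annotated
#' TSS, the reproducible proxy when UTRs are not annotated.
#'
#' @param genes `GRanges` of gene bodies.
#' @return integer vector of TSS positions.
#' @export
tssPositions <- function(genes) {
  ifelse(as.character(GenomicRanges::strand(genes)) == "+",
         GenomicRanges::start(genes), GenomicRanges::end(genes))
}

#' Extract and translate the protein of one gene
#'
#' CDS segments are spliced in transcription order (reverse-complemented for
#' "-" genes) and translated with the standard genetic code. A terminal stop
#' is removed; an internal stop raises a warning and truncates the
#' translation at the stop.
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param genome named character vector of region sequences (from
#'   [readFasta()]).
#' @param geneID gene to translate.
#' @return single character string, the amino-acid sequence.
#' @export
extractProtein <- function(annotation, genome, geneID) {
  segs <- cdsSegments(annotation, geneID)
  if (!length(segs)) stop("gene has no CDS: ", geneID)
  reg <- as.character(GenomicRanges::seqnames(segs))[1]
  if (!reg %in% names(genome))
    stop("region '", reg, "' not present in genome sequences")
  regseq <- genome[[reg]]
  if (max(GenomicRanges::end(segs)) > nchar(regseq))
    stop("CDS of ", geneID, " extends beyond region '", reg, "'")
  st <- as.character(GenomicRanges::strand(
    geneRanges(annotation)[match(geneID, geneIDs(annotation))]))
  pieces <- vapply(seq_along(segs), function(j) {
    s <- substr(regseq, GenomicRanges::start(segs)[j],
                GenomicRanges::end(segs)[j])
    if (st == "-") reverseComplement(s) else s
  }, character(1))
  cds <- paste(pieces, collapse = "")
  if (nchar(cds) %% 3L != 0L)
    stop("frame error: CDS length of ", geneID, " (", nchar(cds),
         ") is not divisible by 3")
  aa <- translateCDS(cds)
  if (substr(aa, nchar(aa), nchar(aa)) == "*")
    aa <- substr(aa, 1L, nchar(aa) - 1L)
  if (grepl("*", aa, fixed = TRUE)) {
    warning("internal stop codon in ", geneID, "; translation truncated")
    aa <- sub("\\*.*$", "", aa)
  }
  aa
}

#' Proteome of a species: every translatable gene
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param genome named character vector of region sequences.
#' @return named character vector gene id -> protein.
#' @export
extractProteome <- function(annotation, genome) {
  ids <- intersect(geneIDs(annotation), names(annotation@cds))
  prots <- vapply(ids, function(g) extractProtein(annotation, genome, g),
                  character(1))
  names(prots) <- ids
  prots
}
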