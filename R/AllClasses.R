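#' @import methods
#' @importFrom GenomicRanges GRanges start end strand seqnames
#' @importFrom S4Vectors mcols mcols<-
#' @importClassesFrom GenomicRanges GRanges GRangesList
NULL

#' GenomeAnnotation: ordered gene models for one species
#'
#' Container for the gene models of one species: a `GRanges` of gene bodies
#' (one range per gene, metadata column `gene_id`) plus a `GRangesList` of
#' CDS segments named by gene id. Genes are kept sorted by region and start
#' coordinate; gene ids are unique within a species. Coordinates follow the
#' Bioconductor convention (1-based, closed intervals), matching GFF3.
#'
#' @slot speciesID single character, species identifier.
#' @slot assembly single character, assembly name (may be "").
#' @slot genes `GRanges` of gene bodies with a `gene_id` metadata column,
#'   sorted by seqnames then start.
#' @slot cds `GRangesList` named by gene id; each element holds the CDS
#'   segments of the selected transcript of that gene, in genomic order.
#'
#' @exportClass GenomeAnnotation
setClass("GenomeAnnotation",
  representation(
    speciesID = "character",
    assembly = "character",
    genes = "GRanges",
    cds = "GRangesList"
  )
)

setValidity("GenomeAnnotation", function(object) {
  msgs <- character(0)
  if (length(object@speciesID) != 1L || is.na(object@speciesID))
    msgs <- c(msgs, "speciesID must be a single non-NA string")
  g <- object@genes
  if (length(g)) {
    ids <- mcols(g)$gene_id
    if (is.null(ids)) {
      msgs <- c(msgs, "genes must carry a gene_id metadata column")
    } else {
      if (anyDuplicated(ids))
        msgs <- c(msgs, "gene ids must be unique within a species")
      bad <- !names(object@cds) %in% ids
      if (any(bad))
        msgs <- c(msgs, "cds list contains entries for unknown gene ids")
    }
    if (!all(as.character(strand(g)) %in% c("+", "-")))
      msgs <- c(msgs, "gene strand must be '+' or '-'")
    # sorted by region then start
    sp <- split(start(g), as.character(seqnames(g)))
    if (!all(vapply(sp, function(x) !is.unsorted(x), logical(1))))
      msgs <- c(msgs, "genes must be sorted by start within each region")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenomeAnnotation
#'
#' @param speciesID species identifier.
#' @param genes `GRanges` with `gene_id` metadata column.
#' @param cds `GRangesList` named by gene id (CDS segments per gene).
#' @param assembly assembly name.
#' @return A [GenomeAnnotation-class] object (genes re-sorted by region and
#'   start).
#' @export
GenomeAnnotation <- function(speciesID, genes, cds = GenomicRanges::GRangesList(),
                             assembly = "") {
  if (length(genes)) {
    o <- order(as.character(GenomicRanges::seqnames(genes)),
               GenomicRanges::start(genes))
    genes <- genes[o]
  }
  if (is(cds, "list")) cds <- GenomicRanges::GRangesList(cds)
  new("GenomeAnnotation", speciesID = as.character(speciesID),
      assembly = as.character(assembly), genes = genes, cds = cds)
}

#' @describeIn GenomeAnnotation-class species identifier
#' @param x a `GenomeAnnotation`
#' @export
speciesID <- function(x) x@speciesID

#' @describeIn GenomeAnnotation-class assembly name
#' @export
assemblyName <- function(x) x@assembly

#' @describeIn GenomeAnnotation-class `GRanges` of gene bodies
#' @export
geneRanges <- function(x) x@genes

#' @describeIn GenomeAnnotation-class gene ids in coordinate order
#' @export
geneIDs <- function(x) as.character(mcols(x@genes)$gene_id)

#' CDS segments of one gene, in transcription (5' to 3') order
#'
#' Segments are returned ordered so the first element is 5'-most in the
#' transcript: ascending genomic start for "+" genes, descending for "-".
#'
#' @param x a `GenomeAnnotation`
#' @param geneID gene identifier
#' @return `GRanges` of CDS segments in transcription order.
#' @export
cdsSegments <- function(x, geneID) {
  if (!geneID %in% geneIDs(x))
    stop("unknown gene id: ", geneID)
  if (!geneID %in% names(x@cds))
    return(GenomicRanges::GRanges())
  segs <- x@cds[[geneID]]
  st <- as.character(strand(x@genes[match(geneID, geneIDs(x))]))
  segs <- segs[order(GenomicRanges::start(segs))]
  if (st == "-") segs <- rev(segs)
  segs
}

setMethod("show", "GenomeAnnotation", function(object) {
  nreg <- length(unique(as.character(seqnames(object@genes))))
  cat("GenomeAnnotation for species '", object@speciesID, "'\n", sep = "")
  if (nzchar(object@assembly))
    cat("  assembly: ", object@assembly, "\n", sep = "")
  cat("  ", length(object@genes), " gene(s) on ", nreg, " region(s); ",
      length(object@cds), " with CDS\n", sep = "")
})

#' SyntenyBlock: a flanking-gene window around an anchor gene pair
#'
#' Ordered window of gene models centred on a divergent anchor pair, each
#' entry labelled with its ortholog group (or "unassigned") and strand.
#' Entries are in chromosome coordinate order; anchor members are flagged.
#'
#' @slot speciesID species the window was cut from.
#' @slot anchor label of the anchor pair family (e.g. "A12").
#' @slot region region (chromosome/contig) id.
#' @slot entries data.frame with columns `gene`, `group`, `strand`,
#'   `isAnchor`, in coordinate order.
#' @slot truncatedLeft,truncatedRight TRUE when the window hit a contig end
#'   before collecting the requested number of flanking genes.
#'
#' @exportClass SyntenyBlock
setClass("SyntenyBlock",
  representation(
    speciesID = "character",
    anchor = "character",
    region = "character",
    entries = "data.frame",
    truncatedLeft = "logical",
    truncatedRight = "logical"
  )
)

setValidity("SyntenyBlock", function(object) {
  need <- c("gene", "group", "strand", "isAnchor")
  if (!all(need %in% names(object@entries)))
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  if (!all(object@entries$strand %in% c("+", "-")))
    return("entry strand must be '+' or '-'")
  TRUE
})

setMethod("show", "SyntenyBlock", function(object) {
  e <- object@entries
  lab <- ifelse(e$isAnchor, paste0("[", e$group, "]"), e$group)
  lab <- paste0(lab, "(", e$strand, ")")
  cat("SyntenyBlock ", object@speciesID, " / ", object@region,
      " anchor=", object@anchor, "\n  ", sep = "")
  if (object@truncatedLeft) cat("} ")
  cat(paste(lab, collapse = " "))
  if (object@truncatedRight) cat(" {")
  cat("\n")
})

#' @describeIn SyntenyBlock-class window entries as a data.frame
#' @param x a `SyntenyBlock`
#' @export
blockEntries <- function(x) x@entries

#' @describeIn SyntenyBlock-class TRUE if either side hit a contig end
#' @export
blockTruncated <- function(x) x@truncatedLeft || x@truncatedRight
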