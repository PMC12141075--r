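#' Parse collagen-chain domain architecture
#'
#' Segments a chain into the canonical collagen IV layout: an N-terminal
#' region (7S side), a collagenous region of Gly-X-Y triplet runs with
#' interruptions, and a C-terminal noncollagenous (NC1) region. Maximal runs
#' of consecutive triplets starting with Gly, of at least `minRunTriplets`
#' triplets, qualify as collagenous; qualifying runs separated by at most
#' `maxInterruption` residues are merged, the residues between them labelled
#' interruptions. When merging leaves more than one run cluster, the cluster
#' with the most triplets defines the collagenous region (ties go to the
#' leftmost) and the rest is absorbed into the terminal segments. Segments
#' tile the protein exactly. Positions are 1-based closed on the protein.
#'
#' @param protein amino-acid sequence (single string).
#' @param minRunTriplets minimum triplets for a qualifying run (default 5).
#' @param maxInterruption maximum residues between merged runs (default 30).
#' @return data.frame with columns `kind` (one of `nterm_7s_region`,
#'   `collagenous`, `interruption`, `cterm_nc1`), `start`, `end`. When no
#'   run qualifies the whole protein is `cterm_nc1` with a warning.
#' @export
parseCollagenDomains <- function(protein, minRunTriplets = 5L,
                                 maxInterruption = 30L) {
  n <- nchar(protein)
  ch <- strsplit(protein, "")[[1]]
  runs <- list()  # each: c(start, end) in residues, triplet-aligned
  i <- 1L
  while (i <= n - 2L) {
    if (ch[i] == "G") {
      k <- 0L
      while (i + 3L * k + 2L <= n && ch[i + 3L * k] == "G") k <- k + 1L
      if (k >= minRunTriplets) {
        runs[[length(runs) + 1L]] <- c(i, i + 3L * k - 1L, k)
        i <- i + 3L * k
        next
      }
    }
    i <- i + 1L
  }
  if (!length(runs)) {
    warning("non-collagenous chain: no Gly-X-Y run of >= ", minRunTriplets,
            " triplets")
    return(data.frame(kind = "cterm_nc1", start = 1L, end = n,
                      stringsAsFactors = FALSE))
  }
  runs <- do.call(rbind, runs)
  # cluster runs across small gaps
  cl <- cumsum(c(1L, (runs[-1L, 1L] - runs[-nrow(runs), 2L] - 1L) >
                   maxInterruption))
  best <- which.max(tapply(runs[, 3L], cl, sum))  # ties -> leftmost
  keep <- runs[cl == as.integer(names(best)), , drop = FALSE]
  segs <- list()
  addSeg <- function(kind, s, e) {
    if (e >= s)
      segs[[length(segs) + 1L]] <<- data.frame(
        kind = kind, start = s, end = e, stringsAsFactors = FALSE)
  }
  addSeg("nterm_7s_region", 1L, keep[1L, 1L] - 1L)
  for (r in seq_len(nrow(keep))) {
    addSeg("collagenous", keep[r, 1L], keep[r, 2L])
    if (r < nrow(keep))
      addSeg("interruption", keep[r, 2L] + 1L, keep[r + 1L, 1L] - 1L)
  }
  addSeg("cterm_nc1", keep[nrow(keep), 2L] + 1L, n)
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Extract the NC1 (C-terminal noncollagenous) domain of a chain
#'
#' @param protein amino-acid sequence.
#' @param ... passed to [parseCollagenDomains()].
#' @return the NC1 substring ("" if the parse leaves no C-terminal segment).
#' @export
nc1Domain <- function(protein, ...) {
  dom <- parseCollagenDomains(protein, ...)
  nc1 <- dom[dom$kind == "cterm_nc1", , drop = FALSE]
  if (!nrow(nc1)) return("")
  substr(protein, nc1$start[1], nc1$end[1])
}

#' Census cysteines per domain of one chain
#'
#' Counts "C" residues in each domain kind and records the normalized
#' positions (in `[0,1]`) of collagenous-region cysteines, measured across
#' the span from the first to the last collagenous segment.
#'
#' @param protein amino-acid sequence.
#' @param domains domain table from [parseCollagenDomains()].
#' @return list with `counts` (named by domain kind, all four kinds
#'   present), `total`, and `positions` (sorted ascending; empty when the
#'   collagenous region has no cysteine).
#' @export
countCysteines <- function(protein, domains) {
  ch <- strsplit(protein, "")[[1]]
  if (sum(domains$end - domains$start + 1L) != length(ch))
    stop("domain segments do not tile the protein")
  kinds <- c("nterm_7s_region", "collagenous", "interruption", "cterm_nc1")
  counts <- stats::setNames(integer(4L), kinds)
  for (r in seq_len(nrow(domains))) {
    k <- domains$kind[r]
    counts[k] <- counts[k] +
      sum(ch[seq(domains$start[r], domains$end[r])] == "C")
  }
  positions <- numeric(0)
  coll <- domains[domains$kind == "collagenous", , drop = FALSE]
  if (nrow(coll)) {
    s0 <- min(coll$start); e0 <- max(coll$end)
    cpos <- integer(0)
    for (r in seq_len(nrow(coll)))
      cpos <- c(cpos, seq(coll$start[r], coll$end[r])[
        ch[seq(coll$start[r], coll$end[r])] == "C"])
    if (length(cpos))
      positions <- sort(if (e0 > s0) (cpos - s0) / (e0 - s0)
                        else rep(0, length(cpos)))
  }
  list(counts = counts, total = sum(counts), positions = positions)
}

#' Positional density of collagenous cysteines
#'
#' Bins normalized cysteine positions over `[0,1]` and reports the fraction
#' falling in the C-terminal half (position >= 0.5).
#'
#' @param positions numeric vector of normalized positions (pooled over
#'   profiles), each in `[0,1]`.
#' @param nBins number of equal-width bins (default 20).
#' @return list with `binCounts` (length `nBins`) and `cTerminalFraction`
#'   (NA when there are no positions).
#' @export
positionalDensity <- function(positions, nBins = 20L) {
  stopifnot(nBins >= 1L)
  if (!length(positions))
    return(list(binCounts = integer(nBins), cTerminalFraction = NA_real_))
  stopifnot(all(positions >= 0 & positions <= 1))
  br <- seq(0, 1, length.out = nBins + 1L)
  binCounts <- as.integer(table(cut(positions, br, include.lowest = TRUE)))
  list(binCounts = binCounts,
       cTerminalFraction = mean(positions >= 0.5))
}

#' Permutation test of cysteine content against habitat salinity
#'
#' Tests whether freshwater species carry more cysteines than the pooled
#' non-freshwater (estuarine/marine/terrestrial) species. The observed
#' statistic is the freshwater mean minus the pooled non-freshwater mean
#' (one-sided, matching the direction of interest); habitat labels are
#' permuted across species and
#' p = (1 + #\{permuted >= observed\}) / (nPerm + 1). A two-sided variant
#' uses the absolute statistic.
#'
#' @param values named numeric vector: species -> per-pair cysteine total.
#' @param habitats named character vector: species -> habitat, from
#'   \{freshwater, estuarine, marine, terrestrial\}.
#' @param nPerm number of permutations (default 999).
#' @param seed RNG seed, recorded in the result.
#' @param alternative "greater" (default, freshwater > others) or
#'   "two.sided". Ignored for the Kruskal-Wallis statistic, which is
#'   inherently omnibus.
#' @param statistic "mean_shift" (default; freshwater mean minus pooled
#'   non-freshwater mean) or "kruskal" (Kruskal-Wallis rank statistic over
#'   all habitat classes, permutation-calibrated).
#' @return list with `groupMeans`, `observed`, `pValue`, `nPerm`, `seed`.
#' @export
habitatPermutationTest <- function(values, habitats, nPerm = 999L, seed = 1L,
                                   alternative = c("greater", "two.sided"),
                                   statistic = c("mean_shift", "kruskal")) {
  alternative <- match.arg(alternative)
  statistic <- match.arg(statistic)
  habitats <- habitats[names(values)]
  allowed <- c("freshwater", "estuarine", "marine", "terrestrial")
  if (anyNA(habitats) || !all(habitats %in% allowed))
    stop("every species needs a habitat from: ",
         paste(allowed, collapse = ", "))
  sizes <- table(habitats)
  if (length(sizes) < 2L || any(sizes < 2L))
    stop("need >= 2 habitat classes with >= 2 species each; sizes: ",
         paste(names(sizes), sizes, sep = "=", collapse = ", "))
  isFW <- habitats == "freshwater"
  if (!any(isFW) || all(isFW))
    stop("need both freshwater and non-freshwater species")
  if (statistic == "kruskal") {
    statFun <- function(lab) {
      s <- unname(stats::kruskal.test(values, factor(lab))$statistic)
      if (is.nan(s)) 0 else s  # all-tied data carry no group signal
    }
    obs <- statFun(habitats)
    perm <- withSeed(seed, {
      vapply(seq_len(nPerm), function(k) statFun(sample(habitats)),
             numeric(1))
    })
    p <- (1 + sum(perm >= obs)) / (nPerm + 1)
  } else {
    statFun <- function(fw) mean(values[fw]) - mean(values[!fw])
    obs <- statFun(isFW)
    nFW <- sum(isFW)
    perm <- withSeed(seed, {
      vapply(seq_len(nPerm), function(k) {
        fw <- logical(length(values))
        fw[sample.int(length(values), nFW)] <- TRUE
        statFun(fw)
      }, numeric(1))
    })
    p <- if (alternative == "greater") (1 + sum(perm >= obs)) / (nPerm + 1)
      else (1 + sum(abs(perm) >= abs(obs))) / (nPerm + 1)
  }
  list(groupMeans = tapply(values, habitats, mean),
       observed = obs, pValue = p, nPerm = as.integer(nPerm),
       seed = as.integer(seed), alternative = alternative,
       statistic = statistic)
}
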