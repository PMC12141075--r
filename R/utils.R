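# Internal helpers shared across modules.

# The 20 standard amino acids (no ambiguity codes).
AA_STANDARD <- c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V")

# Residues used for collagen X/Y positions, interruptions and NC1 filler:
# the 20 standard amino acids minus Gly (so triplet structure is stable by
# construction) and minus Cys (cysteines are planted deliberately).
AA_XY_POOL <- c("A","R","N","D","Q","E","H","I",
                "L","K","M","F","P","S","T","W","Y","V")

# One representative codon per amino acid, used by the reverse translator.
CODON_OF <- c(A="GCT", R="CGT", N="AAT", D="GAT", C="TGT", Q="CAA", E="GAA",
              G="GGT", H="CAT", I="ATT", L="CTG", K="AAA", M="ATG", F="TTT",
              P="CCT", S="TCT", T="ACT", W="TGG", Y="TAT", V="GTT")

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
withSeed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stage-specific seed from a master seed and a salt string,
# keeping the result a valid 32-bit integer.
deriveSeed <- function(seed, salt) {
  h <- sum(utf8ToInt(salt) * seq_along(utf8ToInt(salt)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# Reverse-translate a protein using fixed representative codons; appends a
# TAA stop. Deterministic by construction.
reverseTranslate <- function(protein, stop_codon = "TAA") {
  aa <- strsplit(protein, "")[[1]]
  bad <- setdiff(aa, names(CODON_OF))
  if (length(bad))
    stop("cannot reverse-translate residue(s): ", paste(unique(bad), collapse = ","))
  paste0(paste(CODON_OF[aa], collapse = ""), stop_codon)
}

reverseComplement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Translate a CDS (sense strand) with the standard code; returns the raw
# translation including any '*' characters.
translateCDS <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     if.fuzzy.codon = "solve"))
}
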