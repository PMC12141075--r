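---
title: "Methods: divergent gene-pair microsynteny and collagen IV chain evolution"
author: "pairsynt"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: divergent gene-pair microsynteny and collagen IV chain evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the models, decision rules and numerical choices
behind each pipeline stage, in enough detail that a reader can judge what a
passing test suite does and does not establish.

# Coordinates and gene models

All coordinates are 1-based, closed intervals — the native convention of
both GFF3 and the GRanges containers the package is built on — so GFF3 I/O
involves no coordinate conversion and all interval arithmetic is delegated
to IRanges. A `GenomeAnnotation` holds one gene model per gene: when an
annotation offers several mRNAs, the transcript with the longest total CDS
is kept, ties broken by lexicographically smallest transcript ID
(a determinism requirement; annotations rarely mark a canonical transcript).
The transcription start site of a gene is taken as its 5′-most gene-body
coordinate (`start` on "+", `end` on "−"). Annotated UTRs would place the
true TSS further out, but gene bounds are the proxy that every annotation
provides, and a divergent pair's TSS gap is dominated by the intergenic
distance in any case. Only the standard genetic code is supported.

# Divergent-pair detection

Two adjacent genes form a `head_to_head` (divergent) arrangement when the
chromosomally left gene lies on "−" and the right on "+", so their 5′ ends
face each other across a shared intergenic region. The TSS gap counts the
bases strictly between the two TSS positions; overlapping genes are flagged
and given gap 0. Only immediately adjacent genes can pair: every known
divergent pair of the collagen IV family is immediately adjacent, and the
adjacency restriction prevents spurious long-range pairings. When several
candidate pairs would share a gene (possible only across distinct
adjacencies), pairs are accepted greedily by ascending TSS gap with ties
broken by leftmost coordinate, so no gene is reported twice and the result
is deterministic.

The TSS-gap ceiling defaults to `maxTssGap = 50000` bp. The family's real
pairs sit within a few kilobases of each other, so 50 kb is generous, but
no authoritative numeric cutoff exists for calling a "gene pair"; the value
is configurable and echoed in every run log.

Per-species presence of a pair family is summarised as `present_paired`
(a detected divergent pair joins the family's two ortholog groups),
`present_unpaired` (member genes exist but not as a divergent pair —
singleton or unlinked loci, the nematode configuration), or `absent`.

# Orthology by reciprocal best hits

Cross-species gene naming is anchored on one reference proteome, star
topology: each reference gene names a group and collects at most one gene
per other species, its reciprocal best hit (RBH). Pairwise protein scores
are optimal affine-gap local alignments (Smith–Waterman) under BLOSUM62
with gap open 11 and extension 1 — the customary protein-search settings —
where a gap of length $L$ costs $11 + L$. A pair is reported only when each
member is the other's *unique* top hit with score ≥ 50 matrix units and
aligned fraction ≥ 0.5 (aligned columns over the shorter sequence). Ties
for a top hit disqualify the gene and are logged rather than resolved
arbitrarily: a tie means the data cannot distinguish paralogs, and a wrong
resolution would corrupt every downstream stage. The score and coverage
thresholds replace a database-size-dependent E-value cutoff, which is not
meaningful for the small proteomes the pipeline compares; both are
configurable and logged. Genes in multi-copy families that lose the RBH
tie-break remain unassigned and surface as "unassigned paralog candidates"
in the window labels.

# Microsynteny windows and event calls

A synteny block is the anchor pair plus up to `flankN = 5` genes on each
side, each labelled with its ortholog group or `"unassigned"`, with strand.
Five flanking genes is the scale on which the family's neighbourhoods are
conserved in practice; windows truncated by contig ends carry a truncation
flag rather than failing (fragmented assemblies are the norm for large
genomes).

Two blocks are compared on their assigned entries only — unassigned genes
(low-confidence annotations, lineage-specific insertions) keep their window
slots for gap counting but carry no evidence about conservation:

* `jaccard` — shared groups over the union of assigned groups;
* `collinearRun` — the longest common subsequence of (group, strand)
  tokens, so a flank matches only when both its identity and its relative
  orientation match;
* `reversedRun` — the same statistic against the second block reversed
  with strands flipped.

The event call applies thresholds in a fixed order: `conserved` when
`collinearRun ≥ ceiling(0.6 × shorter assigned length)`; else `inverted`
when `reversedRun > collinearRun` and `reversedRun ≥ 3`; else `rearranged`
when `jaccard ≥ 0.5`; else `translocated`. These cutoffs (0.6, 3, 0.5)
formalise calls that are conventionally made by eye; no published numeric
criterion exists for a "conserved core", so all three are exposed as
configuration and echoed into every report.

A deletion call for an anchor pair proceeds genome-wide: if any query gene
maps to the anchor groups the status is `anchor_present`. Otherwise the
caller looks for one region carrying at least one assigned flank group from
each side of the reference window and counts the genes strictly between the
innermost matches: at most `maxGapGenes = 3` unrelated genes is a
`precise_deletion` (the amphibian configuration, including a lineage that
slipped a single novel gene into the joint), more is
`deletion_with_insertion`; flanks split across contigs are `indeterminate`.

# Chain classification

Chain relationships are computed from the C-terminal noncollagenous (NC1)
domain by default: it is compact (~230 residues), alignable without the
ambiguity of the long interrupted Gly-X-Y region, and sufficient to
separate the α1-descended from the α2-descended chains; full-chain mode is
available. Distances are p-distances (mismatched aligned columns over
aligned columns, gap columns excluded) from global affine-gap alignments —
chosen over model-corrected distances to avoid a model-choice degree of
freedom at the short divergences involved; a Poisson correction
(`-log(1 - p)`) is available behind a flag.

Trees are built by neighbor joining, which recovers the unique generating
tree exactly (topology and branch lengths) whenever the input matrix is
additive; negative branch-length estimates, which NJ can produce on
non-additive input, are clamped to zero with a message. Each query chain is
assigned the type of its nearest reference leaf by tree path length, exact
ties giving `ambiguous` rather than a coin flip.

# Cysteine analysis

The domain parser scans for maximal runs of consecutive Gly-led triplets.
Runs of at least `minRunTriplets = 5` qualify as collagenous; qualifying
runs separated by at most `maxInterruption = 30` residues are merged, the
residues between them labelled interruptions. The run floor keeps
spuriously Gly-rich stretches of globular sequence out of the collagenous
region, and 30 residues comfortably covers the natural interruptions of
collagen IV chains. When merging still leaves more than one run cluster,
the cluster with the most triplets defines the collagenous region (ties go
leftmost) and the remainder is absorbed into the terminal segments — the
four-kind segmentation (N-terminal region, collagenous, interruption, NC1)
must tile the protein exactly, and this rule makes the degenerate case
deterministic. A chain with no qualifying run is labelled entirely NC1 with
a "non-collagenous chain" warning.

Cysteines are counted per domain kind at the residue level (codon and
residue counts coincide under the standard code). Collagenous cysteine
positions are normalised to $[0,1]$ across the span from the first to the
last collagenous segment, and the positional density reports the fraction
in the C-terminal half. NC1 cysteines are counted but reported separately
throughout: they form the conserved intradomain disulfides and carry no
signal about interprotomer crosslinking.

The habitat association test is a label-permutation test, declared rather
than reconstructed (the original analysis names no test): the statistic is
the freshwater mean minus the pooled non-freshwater mean of per-pair
cysteine totals, one-sided in the direction of the biological claim
(freshwater > other), with
$p = (1 + \#\{\text{permuted} \ge \text{observed}\}) / (n_{perm} + 1)$,
`nPerm = 999` by default, seeded so identical seeds give identical
p-values. A two-sided variant is available. Classes with fewer than two
species abort with the class sizes listed.

# The synthetic-clade generator

The simulator exists so every stage can be exercised against planted ground
truth. Its defaults encode the canonical chain dimensions: 470 Gly-X-Y
triplets (~1400 collagenous residues) and a 230-residue NC1 domain, with 12
NC1 cysteines per chain as the conserved disulfide set and 2 collagenous
cysteines per ancestral chain. The root locus is one divergent A12-like
pair plus 12 single-copy flanking genes named after the conserved
neighbourhood of the mammalian locus; intergenic spacers are drawn
log-uniformly from 1–20 kb and the divergent pair's TSS gap from 0.1–5 kb,
once, at locus creation, so they are inherited identically down the tree.

Evolution proceeds in preorder down a labelled species tree. Per-branch
events: `duplicate_pair` copies the pair's chains to a new region flanked
by newly created single-copy families; `invert_window` reverses a gene
window around a pair, flipping strands; `delete_pair_precise` removes the
two pair genes leaving the flanks adjacent; `delete_pair_with_insertion`
additionally inserts novel single-exon genes; `cys_gain` converts a chosen
number of X/Y positions of a pair's chains to cysteine. Point substitutions
are applied per branch at `rate × branch length` per site, at the protein
level, with codons rebuilt deterministically — substitution-only evolution
keeps alignment oracles exact while still exercising the RBH machinery.

Three deliberate idealisations, and what they mean for interpreting green
tests:

* **Flanking genes all sit on the "+" strand**, so the planted divergent
  pairs are the only head-to-head adjacencies and pair truth is
  unambiguous. Real genomes mix orientations; zero false positives on
  simulated clades therefore certifies the detector's logic, not its
  behaviour on genuinely divergent non-family promoter pairs, which it
  would (correctly) also report.
* **Duplications apply a divergence burst** (0.3 substitutions/site on the
  new copies, in addition to subsequent branch substitutions). Without it,
  a duplicate and its progenitor would be equidistant from every outgroup
  ortholog and reference-anchored naming would be ill-posed — mirroring the
  reality that the chain pairs are deeply diverged from one another while
  orthologs remain close.
* **Substitutions on collagen chains never create or destroy Gly or Cys**
  (both positions are protected and excluded from the replacement
  alphabet). Gly protection keeps the triplet frame — and hence the planted
  domain boundaries — stable; Cys protection makes cysteine content an
  event-controlled quantity, so a planted gain of Δ is recovered as exactly
  Δ. Real chains accumulate and lose cysteines by ordinary substitution;
  the habitat-test power measured on generator output is therefore power
  against a clean shift plus the generator's species-level jitter, not
  against full mutational noise.

The generator does not model indels, codon-level substitution processes,
rate heterogeneity, whole-genome duplication, or assembly artefacts beyond
contig truncation flags.

# Pipeline orchestration and problem sizes

`runPipeline()` validates its configuration before any computation (a
missing reference species or an out-of-range threshold is fatal), then runs
the stages in dependency order. Per-species stage failures degrade to
warnings so that one fragmented assembly does not abort a multi-species
run. All thresholds that influence an event call are echoed into the run
log; stage seeds are derived from the single top-level seed by a salted
hash, so identical configurations give identical report bundles.

Problem sizes used by the shipped experiments: the 50-clade event-recovery
experiment uses four-species clades with 40-triplet chains — pair,
inversion and deletion calls are functions of gene order, not chain length,
so the smaller chains change nothing about what is being tested; the
duplication-scenario replay and all cysteine/domain experiments use the
full-size 470-triplet chains. The alignment oracle enumerates every
alignment path, which is feasible to length 8 for global alignments and
length 6 for local ones (the local oracle additionally ranges over all
start points); sampled pairs cover those length ranges.

# Known limitations

* Reference-anchored RBH naming cannot separate paralogs that are
  genuinely equidistant from the reference; such genes are deliberately
  left unassigned. The paralog-adjacency context that can disambiguate
  them (which IRS-family neighbour a pair sits next to) is reported by the
  synteny stage as separate evidence, not merged into the naming.
* Event thresholds formalise by-eye judgements; on real, noisier
  neighbourhoods the `rearranged`/`translocated` boundary in particular is
  sensitive to the Jaccard cutoff.
* p-distance trees are appropriate at the divergences simulated here;
  deep-metazoan full-chain comparisons would need model-corrected
  distances and alignment curation beyond this package's scope.
* The permutation test treats species as exchangeable under the null;
  it does not correct for phylogenetic non-independence.
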