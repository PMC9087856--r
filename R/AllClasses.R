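#' @import methods
#' @importFrom Biostrings DNAStringSet AAStringSet width
#' @importFrom GenomicRanges GRanges seqnames start end strand
#' @importFrom S4Vectors mcols
NULL

.REGION_KINDS <- c("WGS", "rmWGS", "CDS", "intron", "repeat", "protein")
.LIFESTYLES <- c("symbiotic", "free-living", "opportunistic", "unknown")
.FEATURE_KINDS <- c("gene", "exon", "CDS", "intron", "repeat")

#' GenomeRecord: one annotated genome assembly
#'
#' Container for a single genome: its scaffolds as a
#' [Biostrings::DNAStringSet], organism metadata (species, isolate,
#' lifestyle) and a feature index as a [GenomicRanges::GRanges] whose
#' `type` metadata column holds the feature kind (`gene`, `exon`, `CDS`,
#' `intron` or `repeat`). Feature metadata columns used downstream are
#' `transcript_id` (CDS/intron/exon grouping), `gene_id`, `gene_status`
#' (`known`/`dark`), `repeat_type`, `repeat_class` and `kimura_divergence`
#' (percent divergence of a repeat copy from its family consensus).
#'
#' @slot genomeId single character, unique label for the genome.
#' @slot species species name.
#' @slot isolate isolate label.
#' @slot lifestyle one of `symbiotic`, `free-living`, `opportunistic`,
#'   `unknown`.
#' @slot scaffolds `DNAStringSet`, named, non-empty sequences.
#' @slot features `GRanges` of annotated features on the scaffolds.
#'
#' @export
setClass("GenomeRecord",
  representation(
    genomeId = "character",
    species = "character",
    isolate = "character",
    lifestyle = "character",
    scaffolds = "DNAStringSet",
    features = "GRanges"
  )
)

setValidity("GenomeRecord", function(object) {
  msg <- character()
  if (length(object@genomeId) != 1L || !nzchar(object@genomeId))
    msg <- c(msg, "genomeId must be a single non-empty string")
  if (!object@lifestyle %in% .LIFESTYLES)
    msg <- c(msg, sprintf("lifestyle must be one of: %s",
                          paste(.LIFESTYLES, collapse = ", ")))
  nm <- names(object@scaffolds)
  if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
    msg <- c(msg, "scaffolds must have unique non-empty names")
  if (length(object@scaffolds) && any(width(object@scaffolds) == 0L))
    msg <- c(msg, "scaffold sequences must be non-empty")
  ft <- object@features
  if (length(ft)) {
    if (is.null(ft$type) || !all(ft$type %in% .FEATURE_KINDS))
      msg <- c(msg, "features$type must be gene/exon/CDS/intron/repeat")
    bad <- !as.character(seqnames(ft)) %in% nm
    if (any(bad))
      msg <- c(msg, sprintf("feature on unknown scaffold: %s",
                            paste(unique(as.character(seqnames(ft))[bad]),
                                  collapse = ", ")))
    else {
      lens <- setNames(width(object@scaffolds), nm)
      if (any(end(ft) > lens[as.character(seqnames(ft))]) ||
          any(start(ft) < 1L))
        msg <- c(msg, "feature interval outside scaffold bounds")
    }
    stranded <- ft$type %in% c("gene", "exon", "CDS", "intron")
    if (any(stranded & !as.character(strand(ft)) %in% c("+", "-")))
      msg <- c(msg, "gene/exon/CDS/intron features must be stranded (+/-)")
  }
  if (length(msg)) msg else TRUE
})

#' RegionSet: curated sequences of one region kind for one genome
#'
#' Holds one of the six region-specific sequence sets the pipeline
#' analyses: `WGS` (whole assembly), `rmWGS` (repeat-masked assembly),
#' `CDS`, `intron`, `repeat` (nucleotide), or `protein` (amino-acid).
#'
#' @slot genomeId genome label.
#' @slot regionKind one of `WGS`, `rmWGS`, `CDS`, `intron`, `repeat`,
#'   `protein`.
#' @slot sequences an `XStringSet` (`DNAStringSet` for nucleotide kinds,
#'   `AAStringSet` for `protein`).
#'
#' @export
setClass("RegionSet",
  representation(
    genomeId = "character",
    regionKind = "character",
    sequences = "XStringSet"
  )
)

setValidity("RegionSet", function(object) {
  msg <- character()
  if (!object@regionKind %in% .REGION_KINDS)
    msg <- c(msg, sprintf("regionKind must be one of: %s",
                          paste(.REGION_KINDS, collapse = ", ")))
  isProt <- identical(object@regionKind, "protein")
  if (isProt && !is(object@sequences, "AAStringSet"))
    msg <- c(msg, "protein region must use AAStringSet")
  if (!isProt && !is(object@sequences, "DNAStringSet"))
    msg <- c(msg, "nucleotide regions must use DNAStringSet")
  if (length(msg)) msg else TRUE
})

#' KmerProfile: k-mer counts for one genome/region
#'
#' A multiset of words of fixed length `k` with their occurrence counts.
#' Summary statistics follow the usual conventions: `T` (total counted
#' windows) is the sum of multiplicities, `D` (distinct) the number of
#' different words, and `U` (unique) the number of words seen exactly
#' once.
#'
#' @slot genomeId genome label.
#' @slot regionKind region the words were counted from.
#' @slot k word length.
#' @slot alphabet `"nucleotide"` or `"protein"`.
#' @slot canonical whether each word was replaced by the lexicographic
#'   minimum of itself and its reverse complement (nucleotide only).
#' @slot counts named integer vector, word -> multiplicity.
#'
#' @export
setClass("KmerProfile",
  representation(
    genomeId = "character",
    regionKind = "character",
    k = "integer",
    alphabet = "character",
    canonical = "logical",
    counts = "integer"
  )
)

setValidity("KmerProfile", function(object) {
  msg <- character()
  if (length(object@k) != 1L || object@k < 1L)
    msg <- c(msg, "k must be a single integer >= 1")
  if (!object@alphabet %in% c("nucleotide", "protein"))
    msg <- c(msg, "alphabet must be 'nucleotide' or 'protein'")
  cnt <- object@counts
  if (length(cnt)) {
    if (is.null(names(cnt)) || anyDuplicated(names(cnt)))
      msg <- c(msg, "counts must be uniquely named by word")
    else if (any(nchar(names(cnt)) != object@k))
      msg <- c(msg, "all words must have length k")
    if (any(cnt < 1L)) msg <- c(msg, "counts must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' KmerDistanceMatrix: pairwise D2S dissimilarities between genomes
#'
#' Symmetric labelled matrix of distances `d` in `[0, 10]` with zero
#' diagonal, as produced by [distanceMatrix()]. The bounded range makes
#' the similarity `S = 10 - d` span exactly the `[0, 10]` threshold
#' slider used by the relatedness network.
#'
#' @slot d symmetric numeric matrix with dimnames = genome labels.
#' @slot regionKind region the underlying k-mers came from.
#' @slot k word length used.
#'
#' @export
setClass("KmerDistanceMatrix",
  representation(d = "matrix", regionKind = "character", k = "integer")
)

setValidity("KmerDistanceMatrix", function(object) {
  d <- object@d
  msg <- character()
  if (nrow(d) != ncol(d)) msg <- c(msg, "matrix must be square")
  if (is.null(rownames(d)) || anyDuplicated(rownames(d)) ||
      !identical(rownames(d), colnames(d)))
    msg <- c(msg, "matrix must have identical unique row/col labels")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12)))
    msg <- c(msg, "matrix must be symmetric")
  if (any(abs(diag(d)) > 0)) msg <- c(msg, "diagonal must be zero")
  if (any(d < 0) || any(d > 10)) msg <- c(msg, "distances must lie in [0, 10]")
  if (length(msg)) msg else TRUE
})

#' RelatednessNetwork: thresholded genome-relatedness graph
#'
#' Complete weighted graph over genomes where each pair carries the
#' similarity `S = 10 - d`. Edges are filtered dynamically by a display
#' threshold `t`: only pairs with `S >= t` are connected.
#'
#' @slot nodes data.frame with columns `id`, `species`, `lifestyle`,
#'   `group` (display colour group).
#' @slot edges data.frame with columns `from`, `to`, `S` — every
#'   unordered genome pair exactly once.
#'
#' @export
setClass("RelatednessNetwork",
  representation(nodes = "data.frame", edges = "data.frame")
)

setValidity("RelatednessNetwork", function(object) {
  msg <- character()
  if (!all(c("id", "species", "lifestyle", "group") %in%
           names(object@nodes)))
    msg <- c(msg, "nodes needs columns id, species, lifestyle, group")
  if (!all(c("from", "to", "S") %in% names(object@edges)))
    msg <- c(msg, "edges needs columns from, to, S")
  else {
    e <- object@edges
    if (nrow(e)) {
      if (!all(c(e$from, e$to) %in% object@nodes$id))
        msg <- c(msg, "edge references unknown node")
      if (any(e$from == e$to)) msg <- c(msg, "self-edges are not allowed")
      if (any(e$S < 0 | e$S > 10)) msg <- c(msg, "S must lie in [0, 10]")
    }
  }
  if (anyDuplicated(object@nodes$id)) msg <- c(msg, "node ids must be unique")
  if (length(msg)) msg else TRUE
})
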