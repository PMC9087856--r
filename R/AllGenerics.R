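#' @include AllClasses.R
NULL

#' Accessors for kmerphylo classes
#'
#' `genomeId()`, `regionKind()`, `scaffolds()`, `genomeFeatures()`,
#' `regionSequences()`, `totalBases()`, `kmerCounts()`, `kmerK()`,
#' `totalKmers()` (T), `distinctKmers()` (D), `uniqueKmers()` (U),
#' `distances()`, `networkNodes()` and `networkEdges()` read the
#' corresponding component without touching slots directly.
#'
#' @param x an object of the documented class.
#' @return the component named by the accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))
#' @rdname accessors
#' @export
setGeneric("regionKind", function(x) standardGeneric("regionKind"))
#' @rdname accessors
#' @export
setGeneric("scaffolds", function(x) standardGeneric("scaffolds"))
#' @rdname accessors
#' @export
setGeneric("genomeFeatures", function(x) standardGeneric("genomeFeatures"))
#' @rdname accessors
#' @export
setGeneric("regionSequences", function(x) standardGeneric("regionSequences"))
#' @rdname accessors
#' @export
setGeneric("totalBases", function(x) standardGeneric("totalBases"))
#' @rdname accessors
#' @export
setGeneric("kmerCounts", function(x) standardGeneric("kmerCounts"))
#' @rdname accessors
#' @export
setGeneric("kmerK", function(x) standardGeneric("kmerK"))
#' @rdname accessors
#' @export
setGeneric("totalKmers", function(x) standardGeneric("totalKmers"))
#' @rdname accessors
#' @export
setGeneric("distinctKmers", function(x) standardGeneric("distinctKmers"))
#' @rdname accessors
#' @export
setGeneric("uniqueKmers", function(x) standardGeneric("uniqueKmers"))
#' @rdname accessors
#' @export
setGeneric("distances", function(x) standardGeneric("distances"))
#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname accessors
setMethod("genomeId", "GenomeRecord", function(x) x@genomeId)
#' @rdname accessors
setMethod("genomeId", "RegionSet", function(x) x@genomeId)
#' @rdname accessors
setMethod("genomeId", "KmerProfile", function(x) x@genomeId)
#' @rdname accessors
setMethod("regionKind", "RegionSet", function(x) x@regionKind)
#' @rdname accessors
setMethod("regionKind", "KmerProfile", function(x) x@regionKind)
#' @rdname accessors
setMethod("regionKind", "KmerDistanceMatrix", function(x) x@regionKind)
#' @rdname accessors
setMethod("scaffolds", "GenomeRecord", function(x) x@scaffolds)
#' @rdname accessors
setMethod("genomeFeatures", "GenomeRecord", function(x) x@features)
#' @rdname accessors
setMethod("regionSequences", "RegionSet", function(x) x@sequences)
#' @rdname accessors
setMethod("totalBases", "RegionSet",
          function(x) sum(Biostrings::width(x@sequences)))
#' @rdname accessors
setMethod("kmerCounts", "KmerProfile", function(x) x@counts)
#' @rdname accessors
setMethod("kmerK", "KmerProfile", function(x) x@k)
#' @rdname accessors
setMethod("kmerK", "KmerDistanceMatrix", function(x) x@k)
#' @rdname accessors
setMethod("totalKmers", "KmerProfile", function(x) sum(x@counts))
#' @rdname accessors
setMethod("distinctKmers", "KmerProfile", function(x) length(x@counts))
#' @rdname accessors
setMethod("uniqueKmers", "KmerProfile", function(x) sum(x@counts == 1L))
#' @rdname accessors
setMethod("distances", "KmerDistanceMatrix", function(x) x@d)
#' @rdname accessors
setMethod("networkNodes", "RelatednessNetwork", function(x) x@nodes)
#' @rdname accessors
setMethod("networkEdges", "RelatednessNetwork", function(x) x@edges)

setMethod("show", "GenomeRecord", function(object) {
  cat(sprintf(
    "GenomeRecord '%s' (%s, isolate %s, %s)\n  %d scaffold(s), %s bp; %d feature(s)\n",
    object@genomeId, object@species, object@isolate, object@lifestyle,
    length(object@scaffolds),
    format(sum(Biostrings::width(object@scaffolds)), big.mark = ","),
    length(object@features)))
})

setMethod("show", "RegionSet", function(object) {
  cat(sprintf("RegionSet '%s' [%s]: %d sequence(s), %s bases\n",
              object@genomeId, object@regionKind,
              length(object@sequences),
              format(totalBases(object), big.mark = ",")))
})

setMethod("show", "KmerProfile", function(object) {
  cat(sprintf(
    "KmerProfile '%s' [%s] k=%d (%s%s): T=%d, D=%d, U=%d\n",
    object@genomeId, object@regionKind, object@k, object@alphabet,
    if (object@canonical) ", canonical" else "",
    totalKmers(object), distinctKmers(object), uniqueKmers(object)))
})

setMethod("show", "KmerDistanceMatrix", function(object) {
  cat(sprintf("KmerDistanceMatrix [%s, k=%d]: %d genomes, d in [%.3f, %.3f]\n",
              object@regionKind, object@k, nrow(object@d),
              min(object@d[upper.tri(object@d)]),
              max(object@d[upper.tri(object@d)])))
})

setMethod("show", "RelatednessNetwork", function(object) {
  cat(sprintf("RelatednessNetwork: %d nodes, %d weighted pairs (S = 10 - d)\n",
              nrow(object@nodes), nrow(object@edges)))
})
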