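#' Read a FASTA file
#'
#' Reads nucleotide or protein FASTA. Sequence ids are the first
#' whitespace-delimited token of each header and sequences are
#' case-normalised to upper case. Malformed input (sequence data before
#' any header) is rejected with the offending line number rather than
#' silently repaired; an empty file yields an empty set.
#'
#' @param path file path (plain or gzip-compressed FASTA).
#' @param alphabet `"DNA"` or `"AA"`.
#' @return a named [Biostrings::DNAStringSet] or [Biostrings::AAStringSet].
#' @export
readFasta <- function(path, alphabet = c("DNA", "AA")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) .stopf("FASTA file not found: %s", path)
  con <- gzfile(path, "rt")
  lines <- readLines(con, warn = FALSE)
  close(con)
  nonblank <- which(nzchar(trimws(lines)))
  empty <- if (alphabet == "DNA") Biostrings::DNAStringSet()
           else Biostrings::AAStringSet()
  if (!length(nonblank)) return(empty)
  if (!startsWith(trimws(lines[nonblank[1L]]), ">"))
    .stopf("malformed FASTA: sequence before header at line %d",
           nonblank[1L])
  raw <- Biostrings::readBStringSet(path)
  if (!length(raw)) return(empty)
  ids <- vapply(strsplit(names(raw), "[[:space:]]+"), `[`, "", 1L)
  seqs <- toupper(as.character(raw))
  out <- if (alphabet == "DNA") Biostrings::DNAStringSet(seqs)
         else Biostrings::AAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param x a named `XStringSet` or [RegionSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path) {
  if (is(x, "RegionSet")) x <- regionSequences(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read GFF3 feature annotations
#'
#' Imports GFF3 (1-based inclusive coordinates, the native [GRanges]
#' convention) and validates it as a feature index: feature kinds are
#' mapped onto `gene`, `exon`, `CDS`, `intron`, `repeat`
#' (`repeat_region` is accepted as a synonym of `repeat`), stranded
#' kinds must carry `+` or `-`, and every interval must fall inside its
#' scaffold when scaffold lengths are supplied. Out-of-bounds or
#' malformed records raise an error rather than being repaired.
#'
#' @param path GFF3 file.
#' @param scaffoldLengths optional named integer vector of scaffold
#'   lengths used for bounds validation.
#' @return a [GenomicRanges::GRanges] with a `type` metadata column plus
#'   any GFF3 attributes (e.g. `transcript_id`, `repeat_type`,
#'   `repeat_class`, `kimura_divergence`, `gene_status`).
#' @export
readGff3Features <- function(path, scaffoldLengths = NULL) {
  if (!file.exists(path)) .stopf("GFF3 file not found: %s", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) .stopf("GFF3 parse error in %s: %s",
                                            path, conditionMessage(e)))
  type <- as.character(gr$type)
  type[type == "repeat_region"] <- "repeat"
  keep <- type %in% .FEATURE_KINDS
  gr <- gr[keep]
  gr$type <- type[keep]
  if (!is.null(gr$kimura_divergence))
    gr$kimura_divergence <- as.numeric(gr$kimura_divergence)
  stranded <- gr$type %in% c("gene", "exon", "CDS", "intron")
  if (any(stranded & !as.character(strand(gr)) %in% c("+", "-")))
    .stopf("stranded feature (gene/exon/CDS/intron) without +/- strand in %s",
           path)
  if (!is.null(scaffoldLengths)) {
    sc <- as.character(seqnames(gr))
    unknown <- !sc %in% names(scaffoldLengths)
    if (any(unknown))
      .stopf("feature on unknown scaffold: %s",
             paste(unique(sc[unknown]), collapse = ", "))
    if (any(start(gr) < 1L) || any(end(gr) > scaffoldLengths[sc]))
      .stopf("feature interval outside scaffold bounds in %s", path)
  }
  gr
}

#' Write a feature index to GFF3
#'
#' @param features `GRanges` with a `type` column as produced by
#'   [readGff3Features()] or the simulator.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGff3Features <- function(features, path) {
  rtracklayer::export(features, path, format = "gff3")
  invisible(path)
}

#' Read a RepeatMasker-style repeat table
#'
#' Accepts a tab-separated table of repeat annotations with columns
#' `scaffold`, `start`, `end` (1-based inclusive), `strand` (`+`, `-` or
#' RepeatMasker's `C` for complement), `repeat_type`, `repeat_class` and
#' optionally `kimura_divergence` (percent), and maps it to the same
#' `GRanges` feature representation as GFF3 repeats.
#'
#' @param path tab-separated file with a header line.
#' @param scaffoldLengths optional named lengths for bounds validation.
#' @return `GRanges` with `type = "repeat"`.
#' @export
readRepeatTable <- function(path, scaffoldLengths = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("scaffold", "start", "end", "strand", "repeat_type",
            "repeat_class")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    .stopf("repeat table %s lacks column(s): %s", path,
           paste(miss, collapse = ", "))
  if (any(tab$end < tab$start))
    .stopf("repeat table %s has end < start", path)
  strand <- ifelse(tab$strand == "C", "-", tab$strand)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$scaffold,
    ranges = IRanges::IRanges(tab$start, tab$end),
    strand = strand)
  gr$type <- "repeat"
  gr$repeat_type <- tab$repeat_type
  gr$repeat_class <- tab$repeat_class
  if ("kimura_divergence" %in% names(tab))
    gr$kimura_divergence <- as.numeric(tab$kimura_divergence)
  if (!is.null(scaffoldLengths)) {
    sc <- as.character(seqnames(gr))
    if (any(!sc %in% names(scaffoldLengths)))
      .stopf("repeat on unknown scaffold in %s", path)
    if (any(end(gr) > scaffoldLengths[sc]))
      .stopf("repeat interval outside scaffold bounds in %s", path)
  }
  gr
}

#' Read a genome metadata table
#'
#' Tab-separated table with columns `genome_id`, `species`, `isolate`,
#' `lifestyle`.
#'
#' @param path file path.
#' @return data.frame with those four columns.
#' @export
readMetadataTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", "species", "isolate", "lifestyle")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    .stopf("metadata table lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$genome_id))
    .stopf("duplicate genome_id in metadata table")
  tab[need]
}

#' Construct a GenomeRecord
#'
#' @param genomeId unique genome label.
#' @param scaffolds named `DNAStringSet` (or named character vector).
#' @param features `GRanges` feature index (may be empty).
#' @param species,isolate,lifestyle organism metadata.
#' @return a [GenomeRecord-class].
#' @export
GenomeRecord <- function(genomeId, scaffolds,
                         features = GenomicRanges::GRanges(),
                         species = "", isolate = "",
                         lifestyle = "unknown") {
  if (is.character(scaffolds))
    scaffolds <- Biostrings::DNAStringSet(scaffolds)
  if (length(features) && is.null(features$type))
    .stopf("features must carry a 'type' metadata column")
  new("GenomeRecord", genomeId = genomeId, species = species,
      isolate = isolate, lifestyle = lifestyle,
      scaffolds = scaffolds, features = features)
}
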