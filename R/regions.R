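## Region curation: the six per-genome sequence sets analysed by the
## pipeline (WGS, rmWGS, CDS, introns, repeats, proteins).

.extractRanges <- function(scaffolds, gr) {
  if (!length(gr)) return(Biostrings::DNAStringSet())
  sc <- as.character(seqnames(gr))
  seqs <- Biostrings::DNAStringSet(lapply(seq_along(gr), function(i) {
    Biostrings::subseq(scaffolds[[sc[i]]], start(gr)[i], end(gr)[i])
  }))
  names(seqs) <- sprintf("%s:%d-%d", sc, start(gr), end(gr))
  seqs
}

.mergedRepeats <- function(genome, features) {
  rep <- features[features$type == "repeat"]
  GenomicRanges::reduce(rep, ignore.strand = TRUE)
}

#' Whole-genome region set
#'
#' @param genome a [GenomeRecord-class].
#' @return a [RegionSet-class] of kind `WGS` containing every scaffold.
#' @export
extractWGS <- function(genome) {
  new("RegionSet", genomeId = genomeId(genome), regionKind = "WGS",
      sequences = scaffolds(genome))
}

#' Repeat-masked whole-genome sequences (rmWGS)
#'
#' Deletes annotated repeats from the assembly and keeps the remaining
#' fragments. Overlapping repeat intervals are merged before deletion;
#' each scaffold is *split* at the deleted spans (flanks are never
#' concatenated, so no chimeric junction words can arise) and fragments
#' shorter than `minLen` are then discarded. Before that length filter,
#' rmWGS bases plus merged repeat bases account exactly for the whole
#' assembly.
#'
#' @param genome a [GenomeRecord-class].
#' @param features feature index to use (defaults to the genome's own).
#' @param minLen minimum fragment length retained, default 1000 bases.
#' @return a [RegionSet-class] of kind `rmWGS`.
#' @export
extractRmWGS <- function(genome, features = genomeFeatures(genome),
                         minLen = 1000L) {
  sc <- scaffolds(genome)
  merged <- .mergedRepeats(genome, features)
  lens <- setNames(Biostrings::width(sc), names(sc))
  if (length(merged)) {
    scn <- as.character(seqnames(merged))
    if (any(!scn %in% names(sc)) || any(end(merged) > lens[scn]))
      .stopf("repeat interval exceeds scaffold bounds")
  }
  whole <- GenomicRanges::GRanges(names(sc), IRanges::IRanges(1L, lens))
  GenomeInfoDb::seqlevels(whole) <- names(sc)
  merged <- GenomicRanges::GRanges(
    factor(as.character(seqnames(merged)), levels = names(sc)),
    IRanges::ranges(merged))
  frag <- GenomicRanges::setdiff(whole, merged, ignore.strand = TRUE)
  frag <- frag[Biostrings::width(frag) >= minLen]
  new("RegionSet", genomeId = genomeId(genome), regionKind = "rmWGS",
      sequences = .extractRanges(sc, frag))
}

## Group stranded sub-features (CDS or exon) into per-transcript
## GRangesLists, preferring transcript_id, then gene_id, else one group
## per interval.
.transcriptGroups <- function(gr) {
  key <- if (!is.null(gr$transcript_id)) gr$transcript_id
         else if (!is.null(gr$gene_id)) gr$gene_id
         else sprintf("feature_%06d", seq_along(gr))
  split(gr, key)
}

#' Strand-specific coding sequences
#'
#' Per transcript, CDS segments are concatenated in genomic order and
#' reverse-complemented as a unit for minus-strand transcripts, yielding
#' the sense-strand coding sequence. Where a gene carries several
#' transcripts, the transcript with the longest total CDS is used, so no
#' coding k-mer is counted twice.
#'
#' @inheritParams extractRmWGS
#' @return a [RegionSet-class] of kind `CDS`, one sequence per
#'   transcript, named by transcript.
#' @export
extractCDS <- function(genome, features = genomeFeatures(genome)) {
  cds <- features[features$type == "CDS"]
  groups <- .transcriptGroups(cds)
  sc <- scaffolds(genome)
  # longest-CDS transcript per gene
  if (length(groups) && !is.null(cds$gene_id) &&
      !is.null(cds$transcript_id)) {
    geneOf <- vapply(groups, function(g) g$gene_id[1L], "")
    lenOf <- vapply(groups, function(g) sum(Biostrings::width(g)), 0)
    keep <- unlist(lapply(split(seq_along(groups), geneOf), function(i) {
      i[which.max(lenOf[i])]
    }), use.names = FALSE)
    groups <- groups[sort(keep)]
  }
  seqs <- lapply(groups, function(g) {
    str <- unique(as.character(strand(g)))
    if (length(str) != 1L)
      .stopf("mixed strands within one transcript (%s)",
             paste(str, collapse = "/"))
    g <- g[order(start(g))]
    s <- do.call(Biostrings::xscat,
                 as.list(.extractRanges(sc, g)))
    if (str == "-") s <- Biostrings::reverseComplement(s)
    s
  })
  out <- if (length(seqs)) Biostrings::DNAStringSet(seqs)
         else Biostrings::DNAStringSet()
  names(out) <- names(groups)
  new("RegionSet", genomeId = genomeId(genome), regionKind = "CDS",
      sequences = out)
}

#' Strand-specific intronic sequences
#'
#' Uses annotated `intron` features when present; otherwise introns are
#' derived as the gaps between consecutive exons of each transcript.
#' Each intron is emitted individually on its gene's sense strand
#' (reverse-complemented for minus-strand genes). Overlapping exons
#' within a transcript (a negative gap) are rejected.
#'
#' @inheritParams extractRmWGS
#' @return a [RegionSet-class] of kind `intron`.
#' @export
extractIntrons <- function(genome, features = genomeFeatures(genome)) {
  sc <- scaffolds(genome)
  intr <- features[features$type == "intron"]
  if (!length(intr)) {
    ex <- features[features$type == "exon"]
    if (!length(ex)) ex <- features[features$type == "CDS"]
    groups <- .transcriptGroups(ex)
    pieces <- lapply(names(groups), function(tx) {
      g <- groups[[tx]]
      if (length(g) < 2L) return(NULL)
      str <- unique(as.character(strand(g)))
      if (length(str) != 1L)
        .stopf("mixed strands within one transcript")
      g <- g[order(start(g))]
      s0 <- end(g)[-length(g)] + 1L
      e0 <- start(g)[-1L] - 1L
      if (any(e0 < s0 - 1L))
        .stopf("overlapping exons in transcript %s", tx)
      keep <- e0 >= s0
      if (!any(keep)) return(NULL)
      GenomicRanges::GRanges(as.character(seqnames(g))[1L],
                             IRanges::IRanges(s0[keep], e0[keep]),
                             strand = str,
                             transcript_id = tx)
    })
    pieces <- pieces[!vapply(pieces, is.null, TRUE)]
    intr <- if (length(pieces)) do.call(c, pieces)
            else GenomicRanges::GRanges()
  }
  if (!length(intr))
    return(new("RegionSet", genomeId = genomeId(genome),
               regionKind = "intron",
               sequences = Biostrings::DNAStringSet()))
  seqs <- .extractRanges(sc, intr)
  minus <- as.character(strand(intr)) == "-"
  if (any(minus))
    seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
  new("RegionSet", genomeId = genomeId(genome), regionKind = "intron",
      sequences = seqs)
}

#' Annotated repeat sequences
#'
#' One sequence per annotated repeat interval, merged where intervals
#' overlap, in forward-strand orientation.
#'
#' @inheritParams extractRmWGS
#' @return a [RegionSet-class] of kind `repeat`.
#' @export
extractRepeats <- function(genome, features = genomeFeatures(genome)) {
  merged <- .mergedRepeats(genome, features)
  new("RegionSet", genomeId = genomeId(genome), regionKind = "repeat",
      sequences = .extractRanges(scaffolds(genome), merged))
}

#' Translate coding sequences to proteins
#'
#' Standard genetic code. A trailing partial codon is dropped with a
#' warning; empty sequences are skipped with a warning. The terminal
#' stop is removed; internal stops are retained as `*` and flagged with
#' a warning naming the affected sequences.
#'
#' @param cds a [RegionSet-class] of kind `CDS` (or a `DNAStringSet`).
#' @param genomeId genome label for the result when `cds` is a raw set.
#' @return a [RegionSet-class] of kind `protein`.
#' @export
translateCDS <- function(cds, genomeId = NULL) {
  if (is(cds, "RegionSet")) {
    genomeId <- genomeId(cds)
    cds <- regionSequences(cds)
  }
  if (is.null(genomeId)) genomeId <- ""
  w <- Biostrings::width(cds)
  if (any(w == 0L)) {
    .warnf("skipping %d empty CDS", sum(w == 0L))
    cds <- cds[w > 0L]
    w <- w[w > 0L]
  }
  if (any(w %% 3L != 0L)) {
    .warnf("%d CDS not divisible by 3; trailing remainder dropped",
           sum(w %% 3L != 0L))
    cds <- Biostrings::subseq(cds, 1L, w - (w %% 3L))
  }
  prot <- Biostrings::translate(cds, if.fuzzy.codon = "X",
                                no.init.codon = TRUE)
  pc <- as.character(prot)
  pc <- sub("\\*$", "", pc)
  internal <- grepl("\\*", pc)
  if (any(internal))
    .warnf("internal stop codon(s) in: %s",
           paste(names(cds)[internal], collapse = ", "))
  out <- Biostrings::AAStringSet(pc)
  names(out) <- names(cds)
  new("RegionSet", genomeId = genomeId, regionKind = "protein",
      sequences = out)
}

#' G+C content of a nucleotide region set
#'
#' `(G + C) / (A + C + G + T)`; ambiguity codes are excluded from both
#' numerator and denominator.
#'
#' @param region a [RegionSet-class] (nucleotide) or `DNAStringSet`.
#' @return fraction in `[0, 1]`.
#' @export
gcContent <- function(region) {
  seqs <- if (is(region, "RegionSet")) regionSequences(region) else region
  if (is(seqs, "AAStringSet")) .stopf("gcContent needs nucleotide sequences")
  lf <- colSums(Biostrings::letterFrequency(seqs, .NUC))
  tot <- sum(lf)
  if (tot == 0) .stopf("no unambiguous bases in region set")
  unname((lf["G"] + lf["C"]) / tot)
}

#' Per-genome region-size report
#'
#' Tabulates sequence counts and total bases per genome and region kind,
#' the summary used to verify that rmWGS plus repeats account for the
#' whole assembly.
#'
#' @param regionSets list of [RegionSet-class] objects.
#' @param path optional path to write the table as TSV.
#' @return data.frame with columns `genome_id`, `region_kind`,
#'   `n_sequences`, `total_bases`.
#' @export
regionSizeReport <- function(regionSets, path = NULL) {
  df <- do.call(rbind, lapply(regionSets, function(rs) {
    data.frame(genome_id = genomeId(rs), region_kind = regionKind(rs),
               n_sequences = length(regionSequences(rs)),
               total_bases = totalBases(rs),
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  df
}
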