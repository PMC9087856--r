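## Exact location of core k-mers on a reference genome and strand-aware
## classification against annotated features.

#' Locate k-mers exactly on a reference genome
#'
#' Reports every exact occurrence of each word on either strand of the
#' reference: a `+` hit means the word matches the forward strand at
#' `[start, start + k - 1]` (1-based), a `-` hit means the word's
#' reverse complement does. Since k-mers are exact words, exact
#' two-strand substring search replaces alignment-based placement
#' without loss. Words absent from the reference simply yield no hits.
#'
#' @param words character vector of k-mers (one common length, A/C/G/T).
#' @param genome a [GenomeRecord-class] (or named `DNAStringSet`).
#' @return data.frame with columns `word`, `scaffold`, `start` (1-based),
#'   `end`, `strand`; zero rows if nothing matches.
#' @export
locateKmers <- function(words, genome) {
  seqs <- if (is(genome, "GenomeRecord")) scaffolds(genome) else genome
  k <- unique(nchar(words))
  if (length(k) != 1L) .stopf("words must share one length")
  empty <- data.frame(word = character(), scaffold = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  if (!length(words)) return(empty)
  fwd <- Biostrings::PDict(Biostrings::DNAStringSet(words))
  rev <- Biostrings::PDict(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(words)))
  rows <- list()
  for (sc in names(seqs)) {
    subj <- seqs[[sc]]
    for (mode in c("+", "-")) {
      m <- Biostrings::matchPDict(if (mode == "+") fwd else rev, subj)
      st <- Biostrings::startIndex(m)
      hit <- which(lengths(st) > 0L)
      for (i in hit) {
        rows[[length(rows) + 1L]] <- data.frame(
          word = words[i], scaffold = sc, start = st[[i]],
          end = st[[i]] + k - 1L, strand = mode,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$word, out$scaffold, out$start, out$strand,
            method = "radix"), , drop = FALSE]
}

#' Write k-mer hits as BED
#'
#' Six-column BED (0-based half-open) with the word as the name field.
#'
#' @param hits data.frame from [locateKmers()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeKmerHitsBed <- function(hits, path) {
  bed <- data.frame(hits$scaffold, hits$start - 1L, hits$end,
                    hits$word, 0L, hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Classify k-mer hits against annotated features
#'
#' A hit overlaps a feature when their intervals intersect by at least
#' one base and — under `strandSpecific` — their strands are compatible
#' (a `-` hit over a `-` feature counts; features annotated `*` match
#' either strand). A word's flags are the union over all of its hits:
#' `repeat` from repeat features, `known_gene` / `dark_gene` from gene
#' spans (inclusive of introns and exons) split by the gene's
#' `gene_status` attribute; `unclassified` is true iff no flag is set.
#'
#' @param hits data.frame from [locateKmers()].
#' @param features `GRanges` feature index of the same reference.
#' @param strandSpecific require strand compatibility (default `TRUE`).
#' @return data.frame with columns `word`, `repeat`, `known_gene`,
#'   `dark_gene`, `unclassified` — one row per word with >= 1 hit.
#' @export
classifyHits <- function(hits, features, strandSpecific = TRUE) {
  words <- unique(hits$word)
  out <- data.frame(word = words, `repeat` = FALSE, known_gene = FALSE,
                    dark_gene = FALSE, unclassified = TRUE,
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (!nrow(hits)) return(out[0L, ])
  hitGR <- GenomicRanges::GRanges(hits$scaffold,
                                  IRanges::IRanges(hits$start, hits$end),
                                  strand = hits$strand)
  flag <- function(feat) {
    if (!length(feat)) return(character())
    ov <- GenomicRanges::findOverlaps(hitGR, feat, minoverlap = 1L,
                                      ignore.strand = !strandSpecific)
    unique(hits$word[S4Vectors::queryHits(ov)])
  }
  reps <- features[features$type == "repeat"]
  genes <- features[features$type == "gene"]
  status <- if (length(genes)) {
    s <- genes$gene_status
    if (is.null(s)) rep("known", length(genes)) else ifelse(is.na(s), "known", s)
  } else character()
  out$`repeat` <- out$word %in% flag(reps)
  out$known_gene <- out$word %in% flag(genes[status == "known"])
  out$dark_gene <- out$word %in% flag(genes[status == "dark"])
  out$unclassified <- !(out$`repeat` | out$known_gene | out$dark_gene)
  out
}

#' Venn-cell counts of core k-mer classifications
#'
#' Partitions classified words into the mutually exclusive cells of the
#' repeat / known-gene / dark-gene Venn diagram (cells always sum to
#' the number of classified words) and reports the aggregate count of
#' words inside at least one annotated feature. When the full word set
#' is supplied, words with no hit anywhere on the reference are tallied
#' separately as `absent_from_reference` — distinct from `unclassified`
#' (located, but in unannotated sequence).
#'
#' @param classifications data.frame from [classifyHits()].
#' @param allWords optional character vector of the complete word set.
#' @return list with `cells` (named integer vector), `n_classified`,
#'   `in_any_feature`, `absent_from_reference`.
#' @export
vennCounts <- function(classifications, allWords = NULL) {
  cl <- classifications
  cellNames <- c("repeat_only", "known_only", "dark_only",
                 "repeat_known", "repeat_dark", "known_dark",
                 "repeat_known_dark", "unclassified")
  cells <- setNames(integer(length(cellNames)), cellNames)
  if (nrow(cl)) {
    key <- paste0(ifelse(cl$`repeat`, "R", ""),
                  ifelse(cl$known_gene, "K", ""),
                  ifelse(cl$dark_gene, "D", ""))
    map <- c(R = "repeat_only", K = "known_only", D = "dark_only",
             RK = "repeat_known", RD = "repeat_dark", KD = "known_dark",
             RKD = "repeat_known_dark")
    cell <- ifelse(key == "", "unclassified", map[key])
    tab <- table(cell)
    cells[names(tab)] <- as.integer(tab)
  }
  absent <- if (is.null(allWords)) NA_integer_
            else length(setdiff(allWords, cl$word))
  list(cells = cells,
       n_classified = nrow(cl),
       in_any_feature = nrow(cl) - cells[["unclassified"]],
       absent_from_reference = absent)
}
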