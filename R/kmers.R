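## k-mer counting and the word-length optimisation sweep.

.alphabetOf <- function(seqs) {
  if (is(seqs, "AAStringSet")) "protein" else "nucleotide"
}

.badWindowPattern <- function(alphabet) {
  if (alphabet == "nucleotide") "[^ACGT]"
  else paste0("[^", paste(.AA20, collapse = ""), "]")
}

#' Count k-mers in a region set
#'
#' Slides a window of length `k` along every sequence. Windows
#' containing any out-of-alphabet symbol (e.g. `N`) are skipped and
#' words never span sequence boundaries. With `canonical = TRUE`
#' (nucleotide only) each word is replaced by the lexicographic minimum
#' of itself and its reverse complement, the conventional strand-merged
#' counting mode; the default is strand-as-given, appropriate for the
#' strand-specific CDS and intron sets.
#'
#' @param region a [RegionSet-class] (or a bare `XStringSet`).
#' @param k word length, `>= 1`.
#' @param canonical merge each word with its reverse complement.
#' @return a [KmerProfile-class]. If `k` exceeds every sequence length
#'   the profile is empty (`T = 0`) and a warning is raised.
#' @export
countKmers <- function(region, k, canonical = FALSE) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L) .stopf("k must be >= 1")
  gid <- ""; kind <- "WGS"
  if (is(region, "RegionSet")) {
    gid <- genomeId(region); kind <- regionKind(region)
    seqs <- regionSequences(region)
  } else seqs <- region
  alphabet <- .alphabetOf(seqs)
  if (canonical && alphabet != "nucleotide")
    .stopf("canonical counting is defined for nucleotide words only")
  chars <- as.character(seqs)
  chars <- chars[nchar(chars) >= k]
  if (!length(chars)) {
    .warnf("k = %d exceeds every sequence length; empty profile", k)
    return(new("KmerProfile", genomeId = gid, regionKind = kind,
               k = k, alphabet = alphabet, canonical = canonical,
               counts = setNames(integer(), character())))
  }
  bad <- .badWindowPattern(alphabet)
  words <- unlist(lapply(chars, function(s) {
    n <- nchar(s)
    w <- substring(s, 1:(n - k + 1L), k:n)
    w[!grepl(bad, w)]
  }), use.names = FALSE)
  if (canonical && length(words)) {
    rc <- .revcompChar(words)
    words <- ifelse(words <= rc, words, rc)
  }
  tab <- table(words)
  counts <- setNames(as.integer(tab), names(tab))
  counts <- counts[order(names(counts), method = "radix")]
  new("KmerProfile", genomeId = gid, regionKind = kind, k = k,
      alphabet = alphabet, canonical = canonical, counts = counts)
}

#' Distinct and unique k-mer proportions
#'
#' For a profile with `T` counted windows, `D` distinct words and `U`
#' words of multiplicity one, returns `prop_distinct = D/T` and
#' `prop_unique = U/D` — the two word-diversity summaries whose joint
#' maximisation guides the choice of `k`.
#'
#' @param profile a [KmerProfile-class] with `T > 0`.
#' @return named numeric vector `c(prop_distinct, prop_unique)`.
#' @export
kmerStats <- function(profile) {
  T <- totalKmers(profile)
  if (T == 0L) .stopf("empty profile (T = 0): proportions undefined")
  D <- distinctKmers(profile)
  c(prop_distinct = D / T, prop_unique = uniqueKmers(profile) / D)
}

#' Sweep word lengths across genomes
#'
#' Counts k-mers at every `k` in `grid` for each genome's region set and
#' tabulates the distinct/unique proportions; [selectOptimalK()] then
#' picks the representative `k`. A genome failing at some `k` is
#' reported with a warning and skipped while the others continue.
#'
#' @param regionSets named list of [RegionSet-class], one per genome.
#' @param grid strictly increasing integer vector of `k` values; the
#'   standard nucleotide grid is `seq(11, 25, 2)`, repeats escalate to
#'   `seq(11, 51, 2)`, proteins use `c(3, 5, 7, 9)`.
#' @param canonical passed to [countKmers()].
#' @param distinctnessFloor passed to [selectOptimalK()].
#' @return an object of class `KSweepResult`: list with `regionKind`,
#'   `grid`, `table` (genome_id, k, prop_distinct, prop_unique) and
#'   `chosen_k`.
#' @export
sweepK <- function(regionSets, grid, canonical = FALSE,
                   distinctnessFloor = 0.5) {
  grid <- as.integer(grid)
  if (!length(grid) || is.unsorted(grid, strictly = TRUE))
    .stopf("grid must be a strictly increasing set of k values")
  if (!length(regionSets)) .stopf("no genomes supplied")
  rows <- list()
  for (rs in regionSets) {
    for (k in grid) {
      st <- tryCatch(kmerStats(countKmers(rs, k, canonical)),
                     error = function(e) {
                       .warnf("sweep skipped %s at k=%d: %s",
                              genomeId(rs), k, conditionMessage(e))
                       c(prop_distinct = NA_real_, prop_unique = NA_real_)
                     })
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = genomeId(rs), k = k,
        prop_distinct = st[["prop_distinct"]],
        prop_unique = st[["prop_unique"]],
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  res <- structure(list(regionKind = regionKind(regionSets[[1L]]),
                        grid = grid, table = tab, chosen_k = NA_integer_),
                   class = "KSweepResult")
  res$chosen_k <- selectOptimalK(res, distinctnessFloor)
  res
}

#' Choose the representative k from a sweep
#'
#' Among grid values whose mean `prop_distinct` across genomes reaches
#' `distinctnessFloor`, returns the `k` maximising the mean of
#' `(prop_distinct + prop_unique) / 2`, breaking ties toward the
#' smallest `k`. When no value passes the floor — short words are not
#' sufficiently distinct, as happens for repeat sets — the largest grid
#' `k` is returned with a warning.
#'
#' @param sweep a `KSweepResult` from [sweepK()].
#' @param distinctnessFloor minimum acceptable mean `prop_distinct`,
#'   default 0.5.
#' @return the selected integer `k`.
#' @export
selectOptimalK <- function(sweep, distinctnessFloor = 0.5) {
  tab <- sweep$table
  if (is.null(tab) || !nrow(tab)) .stopf("empty sweep")
  byK <- split(tab, tab$k)
  ks <- as.integer(names(byK))
  meanPD <- vapply(byK, function(x) mean(x$prop_distinct, na.rm = TRUE), 0)
  score <- vapply(byK,
                  function(x) mean((x$prop_distinct + x$prop_unique) / 2,
                                   na.rm = TRUE), 0)
  ok <- which(meanPD >= distinctnessFloor)
  if (!length(ok)) {
    .warnf("no k reaches mean prop_distinct >= %.2f; returning largest k = %d",
           distinctnessFloor, max(ks))
    return(max(ks))
  }
  best <- ok[score[ok] == max(score[ok])]
  ks[min(best)]
}

#' @export
print.KSweepResult <- function(x, ...) {
  cat(sprintf("KSweepResult [%s]: %d genomes x %d k values; chosen k = %d\n",
              x$regionKind, length(unique(x$table$genome_id)),
              length(x$grid), x$chosen_k))
  invisible(x)
}

#' Write / read a k-mer dump
#'
#' Tab-separated `word<TAB>count` interchange format (one word per
#' line), as emitted by standard k-mer counters' dump commands.
#'
#' @param profile a [KmerProfile-class].
#' @param path file path.
#' @return `writeKmerDump`: `path` invisibly; `readKmerDump`: a
#'   [KmerProfile-class].
#' @export
writeKmerDump <- function(profile, path) {
  cnt <- kmerCounts(profile)
  writeLines(paste(names(cnt), cnt, sep = "\t"), path)
  invisible(path)
}

#' @rdname writeKmerDump
#' @param genomeId,regionKind,alphabet,canonical profile metadata to
#'   attach on read.
#' @export
readKmerDump <- function(path, genomeId = "", regionKind = "WGS",
                         alphabet = c("nucleotide", "protein"),
                         canonical = FALSE) {
  alphabet <- match.arg(alphabet)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(new("KmerProfile", genomeId = genomeId,
               regionKind = regionKind, k = 1L, alphabet = alphabet,
               canonical = canonical,
               counts = setNames(integer(), character())))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  words <- vapply(parts, `[`, "", 1L)
  counts <- as.integer(vapply(parts, `[`, "", 2L))
  if (anyDuplicated(words)) .stopf("duplicate words in dump %s", path)
  ord <- order(words, method = "radix")
  new("KmerProfile", genomeId = genomeId, regionKind = regionKind,
      k = nchar(words[1L]), alphabet = alphabet, canonical = canonical,
      counts = setNames(counts[ord], words[ord]))
}
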