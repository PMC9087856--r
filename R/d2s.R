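## The D2S statistic and its transformation into the pairwise distance
## matrix used for tree and network inference.

#' Zero-order background model of a region set
#'
#' Letter frequencies over the unambiguous alphabet (A/C/G/T for
#' nucleotide sets, the 20 standard amino acids for proteins), estimated
#' per genome per region. These are the independent-letter null
#' probabilities from which each word's expected count is derived when
#' centring the D2S terms.
#'
#' @param region a [RegionSet-class] or `XStringSet`.
#' @return object of class `BackgroundModel`: list with `genomeId`,
#'   `alphabet` and `frequencies` (named, summing to 1).
#' @export
letterFrequencies <- function(region) {
  gid <- ""
  seqs <- region
  if (is(region, "RegionSet")) {
    gid <- genomeId(region)
    seqs <- regionSequences(region)
  }
  alphabet <- .alphabetOf(seqs)
  letters <- if (alphabet == "nucleotide") .NUC else .AA20
  lf <- colSums(Biostrings::letterFrequency(seqs, letters))
  tot <- sum(lf)
  if (tot == 0) .stopf("no unambiguous letters in region set")
  structure(list(genomeId = gid, alphabet = alphabet,
                 frequencies = lf / tot),
            class = "BackgroundModel")
}

#' @export
print.BackgroundModel <- function(x, ...) {
  cat(sprintf("BackgroundModel '%s' (%s): %s\n", x$genomeId, x$alphabet,
              paste(sprintf("%s=%.3f", names(x$frequencies),
                            x$frequencies), collapse = " ")))
  invisible(x)
}

## Per-profile precomputation shared by d2sStatistic/distanceMatrix:
## word list, counts, letter-composition matrix, frequencies, T.
.d2sPrep <- function(profile, bg) {
  letters <- if (profile@alphabet == "nucleotide") .NUC else .AA20
  words <- names(kmerCounts(profile))
  comp <- if (length(words)) {
    ss <- if (profile@alphabet == "nucleotide")
      Biostrings::DNAStringSet(words) else Biostrings::AAStringSet(words)
    Biostrings::letterFrequency(ss, letters)
  } else matrix(0, 0L, length(letters), dimnames = list(NULL, letters))
  f <- bg$frequencies[letters]
  list(words = words, counts = as.numeric(kmerCounts(profile)),
       comp = comp, f = as.numeric(f), T = totalKmers(profile),
       k = kmerK(profile), alphabet = profile@alphabet)
}

## Word probabilities under an independent-letter model, given the
## letter-composition matrix of the words.
.wordProbs <- function(comp, f) {
  logf <- log(f)
  finite <- is.finite(logf)
  lp <- as.vector(comp[, finite, drop = FALSE] %*% logf[finite])
  p <- exp(lp)
  if (any(!finite)) {
    zero <- rowSums(comp[, !finite, drop = FALSE]) > 0
    p[zero] <- 0
  }
  p
}

.d2sFromPrep <- function(pa, pb) {
  newB <- !(pb$words %in% pa$words)
  words <- c(pa$words, pb$words[newB])
  comp <- rbind(pa$comp, pb$comp[newB, , drop = FALSE])
  X <- c(pa$counts, numeric(sum(newB)))
  Y <- numeric(length(words))
  Y[match(pb$words, words)] <- pb$counts
  EX <- pa$T * .wordProbs(comp, pa$f)
  EY <- pb$T * .wordProbs(comp, pb$f)
  Xc <- X - EX
  Yc <- Y - EY
  keep <- !(Xc == 0 & Yc == 0)
  sum(Xc[keep] * Yc[keep] / sqrt(Xc[keep]^2 + Yc[keep]^2))
}

#' D2S similarity statistic between two k-mer profiles
#'
#' Over the word set observed in at least one of the two profiles, each
#' word's observed count is centred by its expected count under that
#' genome's own zero-order background model (`E = T * p_w`, with `p_w`
#' the product of letter probabilities), and the centred counts are
#' accumulated as `sum(Xc * Yc / sqrt(Xc^2 + Yc^2))`. Terms with both
#' centred counts exactly zero are skipped. The statistic is symmetric
#' in its arguments. Restricting the sum to observed words (rather than
#' the full `4^k` lattice) is what makes large `k` tractable; the
#' deviation is negligible because unobserved words have near-zero
#' expectations.
#'
#' @param profileA,profileB [KmerProfile-class] objects at the same `k`
#'   and alphabet.
#' @param bgA,bgB their `BackgroundModel`s from [letterFrequencies()].
#' @return the D2S value (numeric scalar).
#' @export
d2sStatistic <- function(profileA, profileB, bgA, bgB) {
  if (kmerK(profileA) != kmerK(profileB))
    .stopf("k mismatch: %d vs %d", kmerK(profileA), kmerK(profileB))
  if (!identical(profileA@alphabet, profileB@alphabet))
    .stopf("alphabet mismatch")
  if (!distinctKmers(profileA) || !distinctKmers(profileB))
    .stopf("empty profile in D2S")
  .d2sFromPrep(.d2sPrep(profileA, bgA), .d2sPrep(profileB, bgB))
}

#' Transform D2S similarities into a bounded distance
#'
#' Normalises the cross-similarity geometrically by the
#' self-similarities, `a = D2S(A,B) / sqrt(D2S(A,A) * D2S(B,B))`, and
#' maps it to `d = -ln(a)`, clamped to `[0, 10]`; a non-positive `a`
#' maps to the maximal distance 10. The clamp makes the similarity
#' `S = 10 - d` span exactly the network threshold range `[0, 10]`.
#'
#' @param d2sAB cross D2S value.
#' @param d2sAA,d2sBB self D2S values (must be positive).
#' @return distance in `[0, 10]`.
#' @export
d2sToDistance <- function(d2sAB, d2sAA, d2sBB) {
  if (!(d2sAA > 0) || !(d2sBB > 0))
    .stopf("non-positive self-similarity (%.4g, %.4g)", d2sAA, d2sBB)
  a <- d2sAB / sqrt(d2sAA * d2sBB)
  if (a <= 0) return(10)
  min(10, max(0, -log(a)))
}

#' Pairwise D2S distance matrix over a genome collection
#'
#' Computes the D2S statistic for every genome pair (and each genome
#' against itself), transforms each pair through [d2sToDistance()], and
#' assembles the labelled symmetric matrix used for neighbour-joining
#' inference and the relatedness network.
#'
#' @param profiles named list of [KmerProfile-class] (>= 3 genomes,
#'   consistent `k`/alphabet); names are the genome labels.
#' @param backgrounds named list of `BackgroundModel`s aligned with
#'   `profiles`; when `NULL`, `regionSets` must be given and the models
#'   are estimated from them.
#' @param regionSets optional named list of [RegionSet-class] used to
#'   derive `backgrounds`.
#' @return a [KmerDistanceMatrix-class].
#' @export
distanceMatrix <- function(profiles, backgrounds = NULL,
                           regionSets = NULL) {
  n <- length(profiles)
  if (n < 3L) .stopf("distance matrix needs >= 3 genomes")
  labels <- names(profiles)
  if (is.null(labels) || anyDuplicated(labels))
    .stopf("profiles must be uniquely named by genome")
  if (is.null(backgrounds)) {
    if (is.null(regionSets))
      .stopf("supply backgrounds or regionSets")
    backgrounds <- lapply(regionSets[labels], letterFrequencies)
    names(backgrounds) <- labels
  }
  ks <- vapply(profiles, kmerK, 0L)
  if (length(unique(ks)) != 1L) .stopf("profiles disagree on k")
  preps <- lapply(labels, function(g)
    .d2sPrep(profiles[[g]], backgrounds[[g]]))
  names(preps) <- labels
  selfs <- vapply(preps, function(p) .d2sFromPrep(p, p), 0)
  bad <- selfs <= 0
  if (any(bad))
    .stopf("non-positive self-similarity for: %s",
           paste(labels[bad], collapse = ", "))
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ab <- tryCatch(.d2sFromPrep(preps[[i]], preps[[j]]),
                   error = function(e)
                     .stopf("D2S failed for pair (%s, %s): %s",
                            labels[i], labels[j], conditionMessage(e)))
    d[i, j] <- d[j, i] <- d2sToDistance(ab, selfs[i], selfs[j])
  }
  new("KmerDistanceMatrix", d = d,
      regionKind = regionKind(profiles[[1L]]), k = ks[[1L]])
}
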