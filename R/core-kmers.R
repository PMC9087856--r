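## Core k-mers: words present in every genome of a target group, and
## per-node shared-k-mer annotation of a tree.

#' Core k-mers of a genome group
#'
#' The words present (multiplicity >= 1) in every member of the group.
#' Two equivalent constructions are provided: `"intersection"` (n-way
#' intersection of the members' distinct-word sets) and `"pairwise"`
#' (shared words of every pair, then the overlap of all pairwise sets,
#' the dump-file procedure); they are provably identical and both kept
#' so tests can compare them. Membership is presence-based — no minimum
#' multiplicity. Strand handling follows the profiles' counting mode:
#' with strand-as-given counting a word and its reverse complement are
#' distinct words.
#'
#' @param profiles named list of [KmerProfile-class] at a common `k`.
#' @param group genome labels forming the target group (default: all).
#' @param method `"intersection"` or `"pairwise"`.
#' @return object of class `CoreKmerSet`: list with `group` (labels),
#'   `k` and `words` (character vector, sorted).
#' @export
coreKmers <- function(profiles, group = names(profiles),
                      method = c("intersection", "pairwise")) {
  method <- match.arg(method)
  if (!length(group)) .stopf("empty group")
  miss <- setdiff(group, names(profiles))
  if (length(miss))
    .stopf("no profile for: %s", paste(miss, collapse = ", "))
  prof <- profiles[group]
  ks <- vapply(prof, kmerK, 0L)
  if (length(unique(ks)) != 1L)
    .stopf("profiles disagree on k: %s", paste(unique(ks), collapse = ", "))
  wordSets <- lapply(prof, function(p) names(kmerCounts(p)))
  words <- if (method == "intersection" || length(wordSets) == 1L) {
    Reduce(intersect, wordSets)
  } else {
    pairSets <- list()
    for (i in seq_len(length(wordSets) - 1L))
      for (j in (i + 1L):length(wordSets))
        pairSets[[length(pairSets) + 1L]] <-
          intersect(wordSets[[i]], wordSets[[j]])
    Reduce(intersect, pairSets)
  }
  structure(list(group = group, k = ks[[1L]],
                 words = sort(words, method = "radix")),
            class = "CoreKmerSet")
}

#' @export
print.CoreKmerSet <- function(x, ...) {
  cat(sprintf("CoreKmerSet: %d core %d-mers across %d genomes\n",
              length(x$words), x$k, length(x$group)))
  invisible(x)
}

#' Write a core k-mer word list
#'
#' One k-mer per line.
#'
#' @param core a `CoreKmerSet` (or character vector of words).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeKmerList <- function(core, path) {
  words <- if (inherits(core, "CoreKmerSet")) core$words else core
  writeLines(words, path)
  invisible(path)
}

#' Shared-k-mer counts for every internal tree node
#'
#' For each internal node of the (rooted) tree, the number of core
#' k-mers shared by all genomes encompassed by that node. Counts are
#' anti-monotone from the leaves toward the root: a parent can never
#' share more words than either child clade.
#'
#' @param tree a rooted [ape::phylo] whose tips are genome labels.
#' @param profiles named list of [KmerProfile-class] covering every tip.
#' @return named integer vector indexed by internal node number
#'   (as in `tree$edge`), with an attribute `"tips"` listing each
#'   node's leaf set.
#' @export
perNodeCoreCounts <- function(tree, profiles) {
  miss <- setdiff(tree$tip.label, names(profiles))
  if (length(miss))
    .stopf("missing profile for leaf: %s", paste(miss, collapse = ", "))
  ntip <- length(tree$tip.label)
  sets <- .cladeSets(tree)
  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  counts <- vapply(nodes, function(v)
    length(coreKmers(profiles, group = sets[[v]])$words), 0L)
  names(counts) <- nodes
  attr(counts, "tips") <- setNames(sets[nodes], nodes)
  counts
}

#' Annotate a tree's internal nodes with shared-k-mer counts
#'
#' Writes the per-node counts into the tree's internal node labels so
#' the annotated Newick carries them.
#'
#' @inheritParams perNodeCoreCounts
#' @return the [ape::phylo] with `node.label` set to the counts.
#' @export
annotateCoreCounts <- function(tree, profiles) {
  counts <- perNodeCoreCounts(tree, profiles)
  tree$node.label <- as.character(counts)
  tree
}
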