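## Neighbour-joining inference, outgroup rooting, species-aware
## collapsing and the normalised Robinson-Foulds comparison.

.asDistMatrix <- function(x) {
  d <- if (is(x, "KmerDistanceMatrix")) distances(x) else as.matrix(x)
  if (nrow(d) != ncol(d) || is.null(rownames(d)))
    .stopf("need a square labelled distance matrix")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    .stopf("distance matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-12))
    .stopf("distance matrix has a non-zero diagonal")
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Classical Saitou-Nei agglomeration: at each step the pair minimising
#' the Q-criterion `(n-2) d(i,j) - r_i - r_j` is joined, with branch
#' lengths `b_i = d(i,j)/2 + (r_i - r_j) / (2(n-2))`. On an additive
#' matrix the true topology and branch lengths are recovered exactly.
#' When several pairs tie on Q (within 1e-12 relative), the pair whose
#' representative labels (the lexicographically smallest leaf in each
#' cluster) sort first is joined, making the output deterministic across
#' platforms. Negative branch lengths are retained — downstream use is
#' topology-only — but reported via a message.
#'
#' @param x a [KmerDistanceMatrix-class] or labelled symmetric numeric
#'   matrix with zero diagonal and at least 3 taxa.
#' @return an unrooted [ape::phylo] tree over all labels.
#' @export
neighborJoining <- function(x) {
  d <- .asDistMatrix(x)
  n <- nrow(d)
  if (n < 3L) .stopf("neighbour joining needs >= 3 taxa")
  fmt <- function(v) sprintf("%.15g", v)
  nodes <- rownames(d)
  reps <- rownames(d)
  anyNeg <- FALSE
  while (n > 3L) {
    r <- rowSums(d)
    Q <- (n - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    tol <- 1e-12 * max(1, abs(qmin))
    cand <- which(Q <= qmin + tol, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    key <- paste(pmin(reps[cand[, 1L]], reps[cand[, 2L]]),
                 pmax(reps[cand[, 1L]], reps[cand[, 2L]]), sep = "\r")
    pick <- cand[order(key, method = "radix")[1L], ]
    i <- pick[[1L]]; j <- pick[[2L]]
    bi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    bj <- d[i, j] - bi
    if (bi < 0 || bj < 0) anyNeg <- TRUE
    newNode <- sprintf("(%s:%s,%s:%s)", nodes[i], fmt(bi),
                       nodes[j], fmt(bj))
    newRep <- min(reps[i], reps[j])
    dNew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dNew[keep]),
               c(dNew[keep], 0))
    nodes <- c(nodes[keep], newNode)
    reps <- c(reps[keep], newRep)
    rownames(d) <- colnames(d) <- reps
    n <- n - 1L
  }
  b <- c((d[1, 2] + d[1, 3] - d[2, 3]) / 2,
         (d[1, 2] + d[2, 3] - d[1, 3]) / 2,
         (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  if (any(b < 0)) anyNeg <- TRUE
  if (anyNeg)
    message("neighborJoining: negative branch length(s) retained")
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", nodes[1L], fmt(b[1L]),
                 nodes[2L], fmt(b[2L]), nodes[3L], fmt(b[3L]))
  readNewick(nwk)
}

## Leaf set below every node, indexed by node number.
.cladeSets <- function(tr) {
  ntip <- length(tr$tip.label)
  sets <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tr$tip.label[i]
  po <- ape::reorder.phylo(tr, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

## Non-trivial bipartitions of the (unrooted) tree as canonical keys.
## Canonical side: the side NOT containing the reference leaf (the
## lexicographically smallest label), sorted; trivial splits excluded.
.bipartitionKeys <- function(tree, refLeaf = NULL) {
  tr <- ape::unroot(tree)
  ntip <- length(tr$tip.label)
  if (is.null(refLeaf)) refLeaf <- min(tr$tip.label)
  sets <- .cladeSets(tr)
  internalChild <- tr$edge[, 2L] > ntip
  keys <- character()
  for (ch in tr$edge[internalChild, 2L]) {
    side <- sets[[ch]]
    if (refLeaf %in% side) side <- setdiff(tr$tip.label, side)
    if (length(side) <= 1L || length(side) >= ntip - 1L) next
    keys <- c(keys, paste(sort(side), collapse = "\r"))
  }
  unique(keys)
}

#' Root a tree with an outgroup
#'
#' Requires the outgroup labels to form a clade of the unrooted tree
#' (always true for a single leaf); otherwise an error lists the labels
#' that intrude into the smallest clade containing the outgroup.
#'
#' @param tree an [ape::phylo].
#' @param outgroupLabels character vector of leaf labels.
#' @return a rooted [ape::phylo] with the outgroup on one side of the
#'   root edge.
#' @export
rootWithOutgroup <- function(tree, outgroupLabels) {
  tips <- tree$tip.label
  miss <- setdiff(outgroupLabels, tips)
  if (length(miss))
    .stopf("outgroup label(s) not in tree: %s", paste(miss, collapse = ", "))
  if (length(outgroupLabels) >= length(tips))
    .stopf("outgroup cannot contain every leaf")
  if (length(outgroupLabels) > 1L) {
    tr <- ape::unroot(tree)
    sets <- .cladeSets(tr)
    og <- sort(outgroupLabels)
    sides <- lapply(sets, sort)
    ok <- any(vapply(sides, identical, TRUE, y = og)) ||
      any(vapply(sides, identical, TRUE,
                 y = sort(setdiff(tips, outgroupLabels))))
    if (!ok) {
      holding <- sides[vapply(sides, function(s) all(og %in% s), TRUE)]
      smallest <- holding[[which.min(lengths(holding))]]
      .stopf("outgroup is not monophyletic; smallest containing clade also holds: %s",
             paste(setdiff(smallest, og), collapse = ", "))
    }
  }
  ape::root(tree, outgroup = outgroupLabels, resolve.root = TRUE)
}

## Species-to-leaf bookkeeping: returns list(species -> leaf labels).
.speciesLeaves <- function(tips, speciesMap) {
  sp <- ifelse(tips %in% names(speciesMap), speciesMap[tips], tips)
  split(tips, sp)
}

.isCladeOf <- function(tree, leaves) {
  tips <- tree$tip.label
  if (length(leaves) == length(tips)) return(TRUE)
  tr <- ape::unroot(tree)
  sets <- lapply(.cladeSets(tr), sort)
  tgt <- sort(leaves)
  any(vapply(sets, identical, TRUE, y = tgt)) ||
    any(vapply(sets, identical, TRUE, y = sort(setdiff(tips, leaves))))
}

## Collapse, given the set of species allowed to collapse (those
## monophyletic in every tree being compared).
.collapseWith <- function(tree, speciesMap, collapsible) {
  for (sp in names(collapsible)) {
    leaves <- collapsible[[sp]]
    if (length(leaves) > 1L)
      tree <- ape::drop.tip(tree, leaves[-1L])
    tree$tip.label[tree$tip.label == leaves[1L]] <- sp
  }
  tree
}

#' Collapse same-species isolates into species-level leaves
#'
#' Every maximal clade whose leaves all belong to one species is
#' replaced by a single leaf labelled with the species name; a species
#' with one isolate is simply relabelled. Species whose isolates are
#' *not* monophyletic keep their isolate-level leaves unchanged, so
#' the leaf set stays comparable between trees. Leaves absent from the
#' map are treated as their own species, which makes the operation
#' idempotent.
#'
#' @param tree an [ape::phylo].
#' @param speciesMap named character vector, leaf label -> species name.
#' @return the collapsed [ape::phylo].
#' @export
collapseSpecies <- function(tree, speciesMap) {
  bySp <- .speciesLeaves(tree$tip.label, speciesMap)
  mono <- vapply(bySp, function(lv)
    length(lv) == 1L || .isCladeOf(tree, lv), TRUE)
  .collapseWith(tree, speciesMap, bySp[mono])
}

#' Normalised Robinson-Foulds distance between two trees
#'
#' The symmetric difference of the two trees' non-trivial bipartition
#' sets, divided by the maximum possible distance `2(N - 3)` for `N`
#' post-collapse leaves, so identical topologies score 0 and trees
#' sharing no bipartition score 1. When a `speciesMap` is supplied the
#' branching order of same-species isolates is first discounted: species
#' monophyletic in *both* trees are collapsed to one species-level leaf
#' in both; non-monophyletic species keep their isolate leaves in both.
#' Multifurcating trees are accepted; the normalisation still uses
#' `2(N - 3)`.
#'
#' @param tree1,tree2 [ape::phylo] trees over the same leaf set (after
#'   collapsing).
#' @param speciesMap optional named character vector, leaf -> species.
#' @return normalised RF distance in `[0, 1]`.
#' @export
normalizedRF <- function(tree1, tree2, speciesMap = NULL) {
  if (!is.null(speciesMap)) {
    by1 <- .speciesLeaves(tree1$tip.label, speciesMap)
    by2 <- .speciesLeaves(tree2$tip.label, speciesMap)
    shared <- intersect(names(by1), names(by2))
    collapsible <- by1[shared[vapply(shared, function(sp) {
      setequal(by1[[sp]], by2[[sp]]) &&
        (length(by1[[sp]]) == 1L ||
           (.isCladeOf(tree1, by1[[sp]]) && .isCladeOf(tree2, by2[[sp]])))
    }, TRUE)]]
    tree1 <- .collapseWith(tree1, speciesMap, collapsible)
    tree2 <- .collapseWith(tree2, speciesMap, collapsible)
  }
  t1 <- sort(tree1$tip.label)
  t2 <- sort(tree2$tip.label)
  if (!identical(t1, t2))
    .stopf("leaf sets differ after collapsing: only in tree1 [%s]; only in tree2 [%s]",
           paste(setdiff(t1, t2), collapse = ", "),
           paste(setdiff(t2, t1), collapse = ", "))
  N <- length(t1)
  ref <- min(t1)
  b1 <- .bipartitionKeys(tree1, ref)
  b2 <- .bipartitionKeys(tree2, ref)
  raw <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  denom <- 2 * (N - 3)
  if (denom <= 0) return(0)
  raw / denom
}
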