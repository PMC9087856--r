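#' Read and write Newick trees
#'
#' Thin validated wrappers around [ape::read.tree()] /
#' [ape::write.tree()]. Reading rejects unparseable strings and trees
#' with duplicated leaf labels; writing preserves branch lengths at full
#' printed precision so that a write/read round trip is
#' topology-identical (Robinson-Foulds distance 0) with equal lengths.
#'
#' @param text a Newick string, or `NULL` if `path` is given.
#' @param path optionally, a file to read from / write to.
#' @return `readNewick`: an [ape::phylo]; `writeNewick`: the Newick
#'   string (invisibly returns `path` when writing to a file).
#' @export
readNewick <- function(text = NULL, path = NULL) {
  tr <- tryCatch(
    if (is.null(text)) ape::read.tree(file = path)
    else ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr))
    .stopf("Newick parse error%s",
           if (is.null(path)) "" else paste0(" in ", path))
  if (anyDuplicated(tr$tip.label))
    .stopf("duplicate leaf labels in Newick tree: %s",
           paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
                 collapse = ", "))
  tr
}

#' @rdname readNewick
#' @param tree an [ape::phylo] object.
#' @export
writeNewick <- function(tree, path = NULL) {
  if (is.null(path)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write / read a square PHYLIP distance matrix
#'
#' Serialises a [KmerDistanceMatrix-class] (or plain labelled symmetric
#' matrix) in square (full) PHYLIP format: a first line with the number
#' of taxa, then one row per taxon starting with its label. Values are
#' written at full double precision (17 significant digits), so a
#' write/read round trip is exact. Square rather than lower-triangular
#' format avoids the triangular-dialect ambiguity.
#'
#' @param x a `KmerDistanceMatrix` or symmetric matrix with dimnames.
#' @param path output file.
#' @return `writePhylipDistance`: `path` invisibly;
#'   `readPhylipDistance`: a labelled symmetric matrix.
#' @export
writePhylipDistance <- function(x, path) {
  d <- if (is(x, "KmerDistanceMatrix")) distances(x) else x
  lab <- rownames(d)
  lines <- c(sprintf("%5d", nrow(d)),
             vapply(seq_len(nrow(d)), function(i) {
               paste(c(lab[i],
                       sprintf("%.17g", d[i, ])), collapse = "  ")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writePhylipDistance
#' @export
readPhylipDistance <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1L]))
  if (is.na(n) || length(lines) < n + 1L)
    .stopf("malformed PHYLIP distance file: %s", path)
  rows <- strsplit(trimws(lines[2:(n + 1L)]), "[[:space:]]+")
  lab <- vapply(rows, `[`, "", 1L)
  d <- t(vapply(rows, function(r) as.numeric(r[-1L]), numeric(n)))
  dimnames(d) <- list(lab, lab)
  if (!isTRUE(all.equal(d, t(d))))
    .stopf("PHYLIP matrix in %s is not symmetric", path)
  d
}
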