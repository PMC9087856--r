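## Thresholded genome-relatedness network built from the distance
## matrix: S = 10 - d per pair, with a display threshold t in [0, 10].

#' Build the genome-relatedness network
#'
#' Converts every pairwise distance into the similarity `S = 10 - d`
#' and stores the complete weighted graph; [thresholdView()] filters it
#' dynamically. Distances outside `[0, 10]` violate the transform's
#' contract and are rejected.
#'
#' @param x a [KmerDistanceMatrix-class] or labelled symmetric matrix
#'   with distances in `[0, 10]`.
#' @param metadata optional data.frame (`genome_id`, `species`,
#'   `isolate`, `lifestyle`) used to annotate nodes; the display colour
#'   group is the species name.
#' @return a [RelatednessNetwork-class].
#' @export
buildNetwork <- function(x, metadata = NULL) {
  d <- .asDistMatrix(x)
  if (any(d < 0) || any(d > 10))
    .stopf("distances outside [0, 10]: cannot form S = 10 - d")
  ids <- rownames(d)
  nodes <- data.frame(id = ids, species = ids,
                      lifestyle = "unknown", group = ids,
                      stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    m <- match(ids, metadata$genome_id)
    ok <- !is.na(m)
    nodes$species[ok] <- metadata$species[m[ok]]
    nodes$lifestyle[ok] <- metadata$lifestyle[m[ok]]
    nodes$group[ok] <- metadata$species[m[ok]]
  }
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  edges <- data.frame(from = ids[pairs[, 1L]], to = ids[pairs[, 2L]],
                      S = 10 - d[pairs], stringsAsFactors = FALSE)
  new("RelatednessNetwork", nodes = nodes, edges = edges)
}

#' Edges visible at a display threshold
#'
#' Returns the edges with `S >= t` (closed comparison). Views are
#' nested: a higher threshold always yields a subset.
#'
#' @param network a [RelatednessNetwork-class].
#' @param t threshold in `[0, 10]`.
#' @return data.frame of edges (`from`, `to`, `S`).
#' @export
thresholdView <- function(network, t) {
  if (length(t) != 1L || is.na(t) || t < 0 || t > 10)
    .stopf("threshold t must lie in [0, 10]")
  e <- networkEdges(network)
  e[e$S >= t, , drop = FALSE]
}

#' Connected components of a thresholded network
#'
#' @param network a [RelatednessNetwork-class].
#' @param t threshold in `[0, 10]`.
#' @return list of character vectors, one per component (singletons
#'   included), ordered by their smallest member.
#' @export
connectedComponents <- function(network, t) {
  e <- thresholdView(network, t)
  ids <- networkNodes(network)$id
  g <- igraph::graph_from_data_frame(e[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = data.frame(name = ids))
  mem <- igraph::components(g)$membership
  comps <- split(names(mem), mem)
  names(comps) <- NULL
  comps[order(vapply(comps, min, ""))]
}

#' Threshold breakpoints of the component structure
#'
#' Sweeps `t` from 0 to 10 and reports every threshold at which the
#' partition into connected components changes (these are the values
#' just above an edge's `S`, since views use the closed comparison
#' `S >= t`), making the interactive threshold exploration scriptable.
#'
#' @param network a [RelatednessNetwork-class].
#' @return data.frame with columns `t` and `n_components`, one row per
#'   distinct component structure, starting at `t = 0`.
#' @export
networkBreakpoints <- function(network) {
  svals <- sort(unique(networkEdges(network)$S))
  eps <- 1e-9
  cand <- sort(unique(c(0, svals, svals + eps, 10)))
  cand <- cand[cand >= 0 & cand <= 10]
  sig <- ""
  rows <- list()
  for (t in cand) {
    comps <- connectedComponents(network, t)
    s <- paste(vapply(comps, paste, "", collapse = ","), collapse = ";")
    if (!identical(s, sig)) {
      rows[[length(rows) + 1L]] <- data.frame(t = t,
                                              n_components = length(comps))
      sig <- s
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a relatedness network as D3-style JSON
#'
#' Writes an object with a `nodes` array (`id`, `species`, `lifestyle`,
#' `group`) and a `links` array (`source`, `target`, `value` = S).
#' All edges are exported with their S values so a rendering layer can
#' re-threshold dynamically; `links` is present (empty) even with no
#' edges.
#'
#' @param network a [RelatednessNetwork-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeNetworkJSON <- function(network, path) {
  nodes <- networkNodes(network)
  e <- networkEdges(network)
  if (nrow(e) && !all(c(e$from, e$to) %in% nodes$id))
    .stopf("network link references unknown node")
  obj <- list(
    nodes = lapply(seq_len(nrow(nodes)), function(i)
      list(id = nodes$id[i], species = nodes$species[i],
           lifestyle = nodes$lifestyle[i], group = nodes$group[i])),
    links = lapply(seq_len(nrow(e)), function(i)
      list(source = e$from[i], target = e$to[i], value = e$S[i])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
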