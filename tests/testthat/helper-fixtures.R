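# Shared fixture builders and independent oracles.

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# A little annotated genome: one 3 kb scaffold, two genes (one per
# strand, two exons each), two repeats (one overlapping pair).
tinyGenome <- function(seed = 1) {
  set.seed(seed)
  seq <- randomDna(3000)
  gr <- GenomicRanges::GRanges(
    "sc1",
    IRanges::IRanges(
      start = c(101, 101, 231, 201, 501, 501, 631, 601, 1001, 1501, 1601),
      end   = c(330, 200, 330, 230, 730, 600, 730, 630, 1200, 1650, 1800)),
    strand = c("+", "+", "+", "+", "-", "-", "-", "-", "*", "*", "*"))
  gr$type <- c("gene", "CDS", "CDS", "intron",
               "gene", "CDS", "CDS", "intron",
               "repeat", "repeat", "repeat")
  gr$gene_id <- c("g1", "g1", "g1", "g1", "g2", "g2", "g2", "g2",
                  NA, NA, NA)
  gr$transcript_id <- c(NA, "g1.t1", "g1.t1", "g1.t1",
                        NA, "g2.t1", "g2.t1", "g2.t1", NA, NA, NA)
  gr$gene_status <- c("known", NA, NA, NA, "dark", NA, NA, NA, NA, NA, NA)
  gr$repeat_type <- c(rep(NA, 8), "Gypsy-7", "hAT-3", "hAT-3")
  gr$repeat_class <- c(rep(NA, 8), "LTR", "DNA", "DNA")
  gr$kimura_divergence <- c(rep(NA_real_, 8), 12.5, 20, 25)
  GenomeRecord("tiny", c(sc1 = seq), features = gr,
               species = "T. parva", isolate = "t1",
               lifestyle = "symbiotic")
}

# Independent sliding-window k-mer counter (explicit loop, no reuse of
# package internals).
oracleKmerCounts <- function(seqs, k) {
  env <- new.env()
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1L)) {
      w <- substr(s, i, i + k - 1L)
      if (grepl("[^ACGT]", w)) next
      env[[w]] <- (if (is.null(env[[w]])) 0L else env[[w]]) + 1L
    }
  }
  words <- sort(ls(env))
  setNames(vapply(words, function(w) env[[w]], 0L), words)
}

# Independent exhaustive D2S (explicit per-word loop).
oracleD2S <- function(sa, sb, k) {
  wins <- function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    w <- substring(s, 1:(n - k + 1L), k:n)
    w[!grepl("[^ACGT]", w)]
  }
  freqs <- function(s) {
    l <- strsplit(s, "")[[1]]
    l <- l[l %in% c("A", "C", "G", "T")]
    table(factor(l, levels = c("A", "C", "G", "T"))) / length(l)
  }
  fa <- freqs(sa); fb <- freqs(sb)
  wa <- wins(sa); wb <- wins(sb)
  total <- 0
  for (w in union(unique(wa), unique(wb))) {
    lets <- strsplit(w, "")[[1]]
    Xc <- sum(wa == w) - length(wa) * prod(fa[lets])
    Yc <- sum(wb == w) - length(wb) * prod(fb[lets])
    if (Xc == 0 && Yc == 0) next
    total <- total + Xc * Yc / sqrt(Xc^2 + Yc^2)
  }
  total
}

# Independent bipartition enumeration: remove each internal edge from
# the tree graph and read off the two leaf components (igraph, not the
# package's own clade machinery).
oracleBipartitions <- function(tree) {
  tr <- ape::unroot(tree)
  ntip <- length(tr$tip.label)
  g <- igraph::graph_from_edgelist(apply(tr$edge, 2, as.character),
                                   directed = FALSE)
  keys <- character()
  for (e in seq_len(nrow(tr$edge))) {
    child <- tr$edge[e, 2L]
    if (child <= ntip) next  # trivial split
    g2 <- igraph::delete_edges(
      g, igraph::get_edge_ids(g, as.character(tr$edge[e, ])))
    mem <- igraph::components(g2)$membership
    vnames <- as.integer(names(mem))
    tipsIn <- vnames[mem == mem[[as.character(child)]] & vnames <= ntip]
    side <- sort(tr$tip.label[tipsIn])
    if (min(tr$tip.label) %in% side)
      side <- sort(setdiff(tr$tip.label, side))
    if (length(side) <= 1L || length(side) >= ntip - 1L) next
    keys <- c(keys, paste(side, collapse = "\r"))
  }
  unique(keys)
}

oracleNormalizedRF <- function(t1, t2) {
  b1 <- oracleBipartitions(t1)
  b2 <- oracleBipartitions(t2)
  raw <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  raw / (2 * (length(t1$tip.label) - 3))
}

# Small simulated dataset reused by heavier tests (built once per run).
smallSimConfig <- function(seed = 1) {
  simulationConfig(seed = seed, backboneLength = 9000L, geneCount = 4L,
                   familyCount = 6L)
}
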