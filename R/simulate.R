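## Synthetic annotated genome collections with the statistical structure
## the pipeline assumes: a species tree with isolate pairs and an
## outgroup, Jukes-Cantor substitution along branches, a gene model,
## repeat families with per-family Kimura divergence and
## group-differential abundance, and planted clade-conserved elements.

.CODE2CHAR <- c(65L, 67L, 71L, 84L)  # A C G T

.stringToCodes <- function(s) {
  v <- utf8ToInt(s)
  code <- integer(length(v))
  code[v == 65L] <- 1L; code[v == 67L] <- 2L
  code[v == 71L] <- 3L; code[v == 84L] <- 4L
  code
}

.codesToString <- function(code) intToUtf8(.CODE2CHAR[code])

.randomCodes <- function(n) sample.int(4L, n, replace = TRUE)

#' Jukes-Cantor substitution along a branch
#'
#' Mutates a nucleotide sequence under the Jukes-Cantor model for a
#' branch of length `d` substitutions/site: each site differs from its
#' ancestor with probability `p = 3/4 (1 - exp(-4 d / 3))`, the exact
#' JC transition probability, substituting uniformly to one of the
#' three other bases. Composing branches therefore composes exactly.
#'
#' @param seq a character string over A/C/G/T (or a `DNAString`).
#' @param d branch length in expected substitutions per site, `>= 0`.
#' @return the mutated sequence as a character string.
#' @export
jcEvolve <- function(seq, d) {
  if (d < 0) .stopf("branch length must be >= 0")
  codes <- .stringToCodes(as.character(seq))
  .codesToString(.jcMutate(codes, d))
}

.jcMutate <- function(codes, d) {
  if (d == 0) return(codes)
  p <- 0.75 * (1 - exp(-4 * d / 3))
  n <- length(codes)
  hit <- which(stats::runif(n) < p)
  if (length(hit)) {
    off <- sample.int(3L, length(hit), replace = TRUE)
    codes[hit] <- ((codes[hit] - 1L + off) %% 4L) + 1L
  }
  codes
}

## Kimura two-parameter mutation: transitions (A<->G, C<->T) with
## per-site probability P, transversions with probability Q.
.k2pMutate <- function(codes, P, Q) {
  n <- length(codes)
  u <- stats::runif(n)
  ts <- which(u < P)
  tv <- which(u >= P & u < P + Q)
  tsPartner <- c(3L, 4L, 1L, 2L)
  tvA <- c(2L, 1L, 2L, 1L)
  tvB <- c(4L, 3L, 4L, 3L)
  if (length(ts)) codes[ts] <- tsPartner[codes[ts]]
  if (length(tv)) {
    pick <- stats::runif(length(tv)) < 0.5
    codes[tv] <- ifelse(pick, tvA[codes[tv]], tvB[codes[tv]])
  }
  codes
}

#' Kimura two-parameter distance
#'
#' `K = -1/2 ln[(1 - 2P - Q) sqrt(1 - 2Q)]` for transition proportion
#' `P` and transversion proportion `Q`; the divergence measure repeat
#' annotators report for a copy against its family consensus.
#'
#' @param P transition proportion.
#' @param Q transversion proportion.
#' @return the distance `K >= 0` (0 iff `P = Q = 0`).
#' @export
kimura2p <- function(P, Q) {
  if (P < 0 || Q < 0 || 1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0)
    .stopf("(P, Q) outside the Kimura-distance domain")
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}

## Invert K into (P, Q) at a fixed transition/transversion ratio R = P/Q.
.k2pRates <- function(K, R = 2) {
  if (K <= 0) return(c(P = 0, Q = 0))
  upper <- min(1 / (2 * R + 1), 0.5) - 1e-9
  f <- function(Q) kimura2p(R * Q, Q) - K
  Q <- stats::uniroot(f, c(1e-12, upper), tol = 1e-12)$root
  c(P = R * Q, Q = Q)
}

## Replace stop codons (TAA/TAG/TGA) in each gene's sense-strand CDS
## with a random sense codon; exon lengths are multiples of 3 so codons
## never straddle introns.
.sanitizeStops <- function(codes, layout) {
  # codes: T=4,A=1,G=3 -> stops are (4,1,1), (4,1,3), (4,3,1)
  isStop <- function(c1, c2, c3)
    (c1 == 4L & c2 == 1L & (c3 == 1L | c3 == 3L)) |
    (c1 == 4L & c2 == 3L & c3 == 1L)
  for (g in layout) {
    for (e in seq_along(g$exonStarts)) {
      idx <- g$exonStarts[e]:g$exonEnds[e]
      seg <- codes[idx]
      if (g$strand == "-") seg <- rev(5L - seg)
      starts <- seq(1L, length(seg), by = 3L)
      bad <- which(isStop(seg[starts], seg[starts + 1L], seg[starts + 2L]))
      for (b in bad) seg[starts[b] + 2L] <- 2L  # TAA->TAC etc.
      if (g$strand == "-") seg <- rev(5L - seg)
      codes[idx] <- seg
    }
  }
  codes
}

## Integer copy numbers whose total matches the summed base budget:
## floor division plus largest-remainder distribution, with at least
## one copy per family so every family is annotated in every genome.
.allocateCopies <- function(shareBases, unit) {
  frac <- shareBases / unit
  n <- floor(frac)
  total <- round(sum(frac))
  extra <- total - sum(n)
  if (extra > 0) {
    ord <- order(frac - n, decreasing = TRUE)
    n[ord[seq_len(extra)]] <- n[ord[seq_len(extra)]] + 1
  }
  setNames(pmax(1L, as.integer(n)), names(shareBases))
}

.defaultTaxa <- function() {
  data.frame(
    species = c("A1", "A2", "A3", "A4", "A5", "A6",
                "B1", "C1", "C2", "C3", "D1", "E1", "O1"),
    clade = c("A", "A", "A", "A", "A", "A",
              "B", "C", "C", "C", "D", "E", "O"),
    isolates = c(3L, 2L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 2L, 1L, 2L),
    lifestyle = c("symbiotic", "symbiotic", "symbiotic", "opportunistic",
                  "free-living", "free-living", "symbiotic", "symbiotic",
                  "symbiotic", "symbiotic", "symbiotic", "free-living",
                  "free-living"),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Assembles the full parameter set of the synthetic genome collection.
#' The defaults emulate the data regime of an 18-genome Suessiales-like
#' panel: 16 ingroup genomes in 5 clades (one clade of 9 with 7
#' symbiotic and 2 free-living members, several multi-isolate species)
#' plus a 2-isolate free-living outgroup; repeat content 20-40% of the
#' assembly in the ingroup and 69-70% in the outgroup; genic fraction
#' under 10%; planted conserved elements; and repeat families with
#' group-differential abundance and divergence.
#'
#' @param seed master seed; all randomness flows from it through named
#'   per-stage substreams.
#' @param backboneLength length (bp) of the non-repeat backbone shared
#'   by all genomes.
#' @param geneCount,exonsPerGene,exonLength,intronLength gene model;
#'   defaults keep the genic fraction under 10% of the assembly.
#' @param darkGeneFraction fraction of genes labelled `dark` (no
#'   functional annotation).
#' @param withinCladeBranch,betweenCladeBranch,terminalBranch,isolateBranch,outgroupStem
#'   branch lengths (substitutions/site): internal branches inside a
#'   clade and backbone branches separating clades are drawn uniformly
#'   from their respective ranges (clades are markedly more separated
#'   than species within a clade, matching genus-level structure);
#'   species terminals and isolate terminals are fixed; the outgroup
#'   attaches by a longer stem.
#' @param familyCount,consensusLength,familyKimuraRange repeat-family
#'   model: number of families, consensus length, and the range
#'   (percent) from which each family's target Kimura divergence is
#'   drawn.
#' @param repeatFractionIngroup,repeatFractionOutgroup target repeat
#'   fraction ranges of assembly length.
#' @param enrichedFamilies number of families whose copy number is
#'   multiplied by `enrichmentFold` in the symbiotic group.
#' @param conservedFamilies number of families whose copies are half as
#'   diverged in the symbiotic group.
#' @param enrichmentFold abundance fold-change of enriched families.
#' @param plantedElementLength length of each planted conserved element
#'   (copied verbatim, one present in every genome and one private to
#'   clade A).
#' @param tsTvRatio transition/transversion rate ratio for repeat-copy
#'   divergence.
#' @param taxa data.frame describing the taxon panel (`species`,
#'   `clade`, `isolates`, `lifestyle`); the default panel has 18
#'   genomes.
#' @return a named list of class `SimulationConfig`.
#' @export
simulationConfig <- function(seed = 1,
                             backboneLength = 45000L,
                             geneCount = 10L,
                             exonsPerGene = 3L,
                             exonLength = 99L,
                             intronLength = 80L,
                             darkGeneFraction = 0.3,
                             withinCladeBranch = c(0.002, 0.005),
                             betweenCladeBranch = c(0.035, 0.05),
                             terminalBranch = 0.01,
                             isolateBranch = 0.002,
                             outgroupStem = 0.06,
                             familyCount = 12L,
                             consensusLength = 300L,
                             familyKimuraRange = c(10, 35),
                             repeatFractionIngroup = c(0.2, 0.4),
                             repeatFractionOutgroup = c(0.69, 0.70),
                             enrichedFamilies = 3L,
                             conservedFamilies = 1L,
                             enrichmentFold = 2,
                             plantedElementLength = 150L,
                             tsTvRatio = 2,
                             taxa = .defaultTaxa()) {
  cfg <- as.list(environment())
  if (sum(taxa$isolates) < 4L) .stopf("need at least 4 genomes")
  if (any(c(cfg$darkGeneFraction) < 0 | c(cfg$darkGeneFraction) > 1))
    .stopf("fractions must lie in [0, 1]")
  if (any(unlist(cfg[c("withinCladeBranch", "betweenCladeBranch",
                       "terminalBranch", "isolateBranch",
                       "outgroupStem")]) < 0))
    .stopf("branch lengths must be >= 0")
  genic <- geneCount * (exonsPerGene * exonLength +
                          (exonsPerGene - 1L) * intronLength)
  if (genic >= backboneLength)
    .stopf("gene model does not fit in the backbone")
  structure(cfg, class = "SimulationConfig")
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat(sprintf(
    "SimulationConfig: %d genomes (%d species), backbone %d bp, %d repeat families\n",
    sum(x$taxa$isolates), nrow(x$taxa), x$backboneLength, x$familyCount))
  invisible(x)
}

.isolateIds <- function(taxa) {
  unlist(lapply(seq_len(nrow(taxa)), function(i)
    paste0(taxa$species[i], "_i", seq_len(taxa$isolates[i]))))
}

#' Simulate the true species/isolate tree
#'
#' Builds the binary tree over all genomes: a fixed clade skeleton
#' (five ingroup clades plus the outgroup pair under the default
#' panel), internal branch lengths drawn uniformly from the configured
#' range, species terminals and short isolate terminals fixed, and the
#' outgroup attached via a longer stem. Output is deterministic given
#' the seed (byte-identical Newick).
#'
#' @param config a `SimulationConfig`.
#' @return a rooted [ape::phylo] whose tips are genome ids.
#' @export
simulateTree <- function(config) {
  set.seed(.substreamSeed(config$seed, "tree"))
  tx <- config$taxa
  fmt <- function(v) sprintf("%.6f", v)
  ibW <- function() stats::runif(1, config$withinCladeBranch[1L],
                                 config$withinCladeBranch[2L])
  ibB <- function() stats::runif(1, config$betweenCladeBranch[1L],
                                 config$betweenCladeBranch[2L])
  tipOf <- function(sp, terminal = config$terminalBranch) {
    n <- tx$isolates[tx$species == sp]
    ids <- paste0(sp, "_i", seq_len(n))
    iso <- config$isolateBranch
    inner <- if (n == 1L) ids
    else if (n == 2L) sprintf("(%s:%s,%s:%s)", ids[1L], fmt(iso),
                              ids[2L], fmt(iso))
    else sprintf("((%s:%s,%s:%s):%s,%s:%s)", ids[1L], fmt(iso),
                 ids[2L], fmt(iso), fmt(iso), ids[3L], fmt(2 * iso))
    sprintf("%s:%s", inner, fmt(terminal))
  }
  node <- function(a, b, stem) sprintf("(%s,%s):%s", a, b, fmt(stem))
  nodeW <- function(a, b) node(a, b, ibW())
  # each clade's stem (the branch separating it from the other genera)
  # is drawn at between-clade depth; monotypic genera (B, D, E) carry
  # genus-depth terminal branches instead
  cladeA <- node(Reduce(nodeW, lapply(c("A1", "A2", "A3", "A4"), tipOf)),
                 nodeW(tipOf("A5"), tipOf("A6")), stem = ibB())
  cladeC <- node(nodeW(tipOf("C1"), tipOf("C2")), tipOf("C3"),
                 stem = ibB())
  ingroup <- node(cladeA,
                  node(node(tipOf("B1", terminal = ibB()), cladeC,
                            stem = ibB()),
                       node(tipOf("D1", terminal = ibB()),
                            tipOf("E1", terminal = ibB()),
                            stem = ibB()),
                       stem = ibB()),
                  stem = ibB())
  ogInner <- sub(sprintf(":%s$", fmt(config$terminalBranch)), "",
                 tipOf("O1"))
  nwk <- sprintf("(%s,%s:%s);", ingroup, ogInner,
                 fmt(config$outgroupStem))
  readNewick(nwk)
}

## Gene layout on the backbone: coordinates shared by all genomes.
.geneLayout <- function(config) {
  geneSpan <- config$exonsPerGene * config$exonLength +
    (config$exonsPerGene - 1L) * config$intronLength
  reserve <- 2000L + 400L * 2L  # tail kept gene-free for planted elements
  avail <- config$backboneLength - reserve
  gap <- (avail - config$geneCount * geneSpan) %/% (config$geneCount + 1L)
  if (gap < 1L) .stopf("genes do not fit in the backbone")
  lapply(seq_len(config$geneCount), function(i) {
    gStart <- gap * i + geneSpan * (i - 1L) + 1L
    exonStarts <- gStart +
      (seq_len(config$exonsPerGene) - 1L) *
      (config$exonLength + config$intronLength)
    list(gene_id = sprintf("gene%02d", i),
         start = gStart, end = gStart + geneSpan - 1L,
         strand = if (i %% 2L == 0L) "-" else "+",
         exonStarts = exonStarts,
         exonEnds = exonStarts + config$exonLength - 1L)
  })
}

.geneFeatures <- function(layout, darkGenes) {
  rows <- lapply(layout, function(g) {
    tx <- paste0(g$gene_id, ".t1")
    nEx <- length(g$exonStarts)
    status <- if (g$gene_id %in% darkGenes) "dark" else "known"
    gene <- data.frame(start = g$start, end = g$end, strand = g$strand,
                       type = "gene", gene_id = g$gene_id,
                       transcript_id = NA, gene_status = status)
    cds <- data.frame(start = g$exonStarts, end = g$exonEnds,
                      strand = g$strand, type = "CDS",
                      gene_id = g$gene_id, transcript_id = tx,
                      gene_status = NA)
    intr <- if (nEx > 1L)
      data.frame(start = g$exonEnds[-nEx] + 1L,
                 end = g$exonStarts[-1L] - 1L, strand = g$strand,
                 type = "intron", gene_id = g$gene_id,
                 transcript_id = tx, gene_status = NA)
    else NULL
    rbind(gene, cds, intr)
  })
  do.call(rbind, rows)
}

#' Evolve a genome collection along the tree
#'
#' Generates the root backbone (with genes at fixed coordinates), lets
#' it and each repeat-family consensus evolve down the tree under
#' Jukes-Cantor substitution (no indels, so gene coordinates lift
#' unchanged to every leaf), then assembles each leaf genome as its
#' evolved backbone followed by a repeat landscape: per family, a
#' genome-specific number of copies, each diverged from the leaf's
#' family consensus under a Kimura two-parameter process to the
#' family's target divergence, separated by short random spacers so
#' adjacent copies never merge. Copy numbers realise the configured
#' repeat fraction (higher in the outgroup) and the fold-change of
#' enriched families in the symbiotic group; conserved families get
#' half-divergence copies there. Planted conserved elements are written
#' verbatim into reserved backbone slots of their designated genomes
#' after mutation, so they are exactly shared.
#'
#' @param tree the true tree from [simulateTree()].
#' @param config the `SimulationConfig` used to build it.
#' @return an object of class `SimulatedDataset`: list with `tree`,
#'   `genomes` (named list of [GenomeRecord-class]), `metadata`
#'   (data.frame), `speciesMap` (leaf -> species) and `truth` (planted
#'   element sequences and carriers, enriched/conserved families,
#'   per-genome repeat fractions, enrichment groups).
#' @export
evolveGenomes <- function(tree, config) {
  set.seed(.substreamSeed(config$seed, "evolve"))
  tx <- config$taxa
  B <- config$backboneLength
  layout <- .geneLayout(config)
  nDark <- round(config$darkGeneFraction * config$geneCount)
  darkGenes <- sprintf("gene%02d", sample.int(config$geneCount, nDark))
  geneFeat <- .geneFeatures(layout, darkGenes)

  ## repeat families
  fams <- sprintf("rnd-%d_family-%d", seq_len(config$familyCount),
                  seq_len(config$familyCount))
  classes <- c("DNA", "LTR", "LINE", "SINE", "RC", "Unknown")
  famClass <- setNames(sample(classes, config$familyCount, replace = TRUE),
                       fams)
  famK <- setNames(stats::runif(config$familyCount,
                                config$familyKimuraRange[1L],
                                config$familyKimuraRange[2L]) / 100,
                   fams)
  enriched <- fams[seq_len(min(config$enrichedFamilies,
                               config$familyCount))]
  conserved <- if (config$conservedFamilies > 0L)
    fams[config$familyCount - seq_len(min(config$conservedFamilies,
                                          config$familyCount)) + 1L]
  else character()

  ## root sequences; root CDS codons are made stop-free on the sense
  ## strand so internal stops arise only from substitutions
  rootBackbone <- .sanitizeStops(.randomCodes(B), layout)
  rootFam <- lapply(fams, function(f) .randomCodes(config$consensusLength))
  names(rootFam) <- fams

  ## planted conserved elements live in the reserved gene-free tail
  elts <- list(
    core_all = list(pos = B - 2000L + 1L,
                    leaves = tree$tip.label),
    core_cladeA = list(pos = B - 2000L + 500L,
                       leaves = grep("^A", tree$tip.label, value = TRUE)))
  for (nm in names(elts))
    elts[[nm]]$codes <- .randomCodes(config$plantedElementLength)

  ## evolve backbone + family consensus down the tree (preorder)
  ntip <- length(tree$tip.label)
  nNode <- ntip + tree$Nnode
  backboneAt <- vector("list", nNode)
  famAt <- vector("list", nNode)
  root <- ntip + 1L
  backboneAt[[root]] <- rootBackbone
  famAt[[root]] <- rootFam
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  lens <- ape::reorder.phylo(tree, "cladewise")$edge.length
  for (e in seq_len(nrow(edges))) {
    p <- edges[e, 1L]; ch <- edges[e, 2L]; d <- lens[e]
    backboneAt[[ch]] <- .jcMutate(backboneAt[[p]], d)
    famAt[[ch]] <- lapply(famAt[[p]], .jcMutate, d = d)
  }

  ## per-leaf assembly
  leafIds <- tree$tip.label
  spOf <- sub("_i[0-9]+$", "", leafIds)
  lifeOf <- setNames(tx$lifestyle, tx$species)[spOf]
  cladeOf <- setNames(tx$clade, tx$species)[spOf]
  symbioticGroup <- leafIds[cladeOf == "A" &
                              lifeOf %in% c("symbiotic", "opportunistic")]
  freeLivingGroup <- leafIds[cladeOf == "A" & lifeOf == "free-living"]

  genomes <- list()
  repeatFraction <- setNames(numeric(length(leafIds)), leafIds)
  expectedRepeatBases <- setNames(numeric(length(leafIds)), leafIds)
  for (li in seq_along(leafIds)) {
    id <- leafIds[li]
    bb <- backboneAt[[li]]
    for (nm in names(elts)) {
      el <- elts[[nm]]
      if (id %in% el$leaves)
        bb[el$pos:(el$pos + length(el$codes) - 1L)] <- el$codes
    }
    isOut <- cladeOf[li] == "O"
    f <- if (isOut)
      stats::runif(1, config$repeatFractionOutgroup[1L],
                   config$repeatFractionOutgroup[2L])
    else stats::runif(1, config$repeatFractionIngroup[1L],
                      config$repeatFractionIngroup[2L])
    repeatFraction[id] <- f
    # solve repeats/(backbone + repeats + spacers) = f, with spacer
    # overhead ~mean(25:40)/consensusLength per copy
    overhead <- 32.5 / config$consensusLength
    repeatBases <- f * B / (1 - f * (1 + overhead))
    weight <- setNames(rep(1, length(fams)), fams)
    if (id %in% symbioticGroup)
      weight[enriched] <- weight[enriched] * config$enrichmentFold
    # divided by family count, not sum(weight): enrichment raises the
    # enriched families' genome share instead of renormalising it away
    share <- repeatBases * weight / length(fams)
    copies <- .allocateCopies(share, config$consensusLength)
    expectedRepeatBases[id] <- sum(copies) * config$consensusLength
    pieces <- list(.codesToString(bb))
    repRows <- list()
    offset <- B
    for (fam in fams) {
      Ktarget <- famK[[fam]]
      if (fam %in% conserved && id %in% symbioticGroup)
        Ktarget <- Ktarget / 2
      cons <- famAt[[li]][[fam]]
      for (cp in seq_len(copies[[fam]])) {
        spacerLen <- sample(25:40, 1L)
        spacer <- .codesToString(.randomCodes(spacerLen))
        Kcopy <- max(0.005, Ktarget * exp(stats::rnorm(1, 0, 0.1)))
        pq <- .k2pRates(Kcopy, config$tsTvRatio)
        copyCodes <- .k2pMutate(cons, pq[["P"]], pq[["Q"]])
        diffTs <- mean(copyCodes == c(3L, 4L, 1L, 2L)[cons])
        diffTv <- mean(copyCodes != cons) - diffTs
        Kreal <- tryCatch(100 * kimura2p(diffTs, diffTv),
                          error = function(e) NA_real_)
        cStart <- offset + spacerLen + 1L
        cEnd <- cStart + config$consensusLength - 1L
        repRows[[length(repRows) + 1L]] <- data.frame(
          start = cStart, end = cEnd, strand = "+", type = "repeat",
          repeat_type = fam, repeat_class = famClass[[fam]],
          kimura_divergence = Kreal, stringsAsFactors = FALSE)
        pieces[[length(pieces) + 1L]] <- paste0(spacer,
                                                .codesToString(copyCodes))
        offset <- cEnd
      }
    }
    seqStr <- paste(unlist(pieces), collapse = "")
    scName <- paste0(id, "_sc1")
    reps <- do.call(rbind, repRows)
    gr <- GenomicRanges::GRanges(
      seqnames = scName,
      ranges = IRanges::IRanges(
        c(geneFeat$start, reps$start), c(geneFeat$end, reps$end)),
      strand = c(geneFeat$strand, reps$strand))
    gr$type <- c(geneFeat$type, reps$type)
    # exon lengths are multiples of 3, so every CDS segment is phase 0
    gr$phase <- ifelse(gr$type == "CDS", 0L, NA_integer_)
    gr$gene_id <- c(geneFeat$gene_id, rep(NA, nrow(reps)))
    gr$transcript_id <- c(geneFeat$transcript_id, rep(NA, nrow(reps)))
    gr$gene_status <- c(geneFeat$gene_status, rep(NA, nrow(reps)))
    gr$repeat_type <- c(rep(NA, nrow(geneFeat)), reps$repeat_type)
    gr$repeat_class <- c(rep(NA, nrow(geneFeat)), reps$repeat_class)
    gr$kimura_divergence <- c(rep(NA_real_, nrow(geneFeat)),
                              reps$kimura_divergence)
    genomes[[id]] <- GenomeRecord(
      genomeId = id,
      scaffolds = setNames(Biostrings::DNAStringSet(seqStr), scName),
      features = gr,
      species = spOf[li],
      isolate = sub("^.*_", "", id),
      lifestyle = unname(lifeOf[li]))
  }

  metadata <- data.frame(genome_id = leafIds, species = spOf,
                         isolate = sub("^.*_", "", leafIds),
                         lifestyle = unname(lifeOf),
                         clade = unname(cladeOf),
                         stringsAsFactors = FALSE)
  truth <- list(
    plantedElements = lapply(elts, function(el)
      list(sequence = .codesToString(el$codes), position = el$pos,
           leaves = el$leaves)),
    enrichedFamilies = enriched,
    conservedFamilies = conserved,
    familyKimura = famK * 100,
    familyClass = famClass,
    repeatFraction = repeatFraction,
    expectedRepeatBases = expectedRepeatBases,
    darkGenes = darkGenes,
    enrichmentGroups = list(symbiotic = symbioticGroup,
                            freeLiving = freeLivingGroup))
  structure(list(tree = tree, genomes = genomes, metadata = metadata,
                 speciesMap = setNames(spOf, leafIds), truth = truth),
            class = "SimulatedDataset")
}

#' @export
print.SimulatedDataset <- function(x, ...) {
  cat(sprintf("SimulatedDataset: %d genomes, %d species, backbone-based assemblies\n",
              length(x$genomes), length(unique(x$metadata$species))))
  invisible(x)
}

#' Simulate a full annotated genome collection
#'
#' Convenience wrapper: [simulateTree()] then [evolveGenomes()].
#'
#' @param config a `SimulationConfig` (default configuration if a bare
#'   seed is given).
#' @return a `SimulatedDataset`.
#' @export
simulateDataset <- function(config = simulationConfig()) {
  if (is.numeric(config)) config <- simulationConfig(seed = config)
  evolveGenomes(simulateTree(config), config)
}

#' Write a simulated dataset to disk
#'
#' Emits per-genome FASTA and GFF3, the metadata table, the true tree
#' in Newick, and a truth-ledger TSV locating every planted structure.
#'
#' @param dataset a `SimulatedDataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulatedDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in dataset$genomes) {
    writeFasta(scaffolds(g), file.path(dir, paste0(genomeId(g), ".fasta")))
    writeGff3Features(genomeFeatures(g),
                      file.path(dir, paste0(genomeId(g), ".gff3")))
  }
  utils::write.table(dataset$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeNewick(dataset$tree, file.path(dir, "true_tree.nwk"))
  truth <- dataset$truth
  ledger <- rbind(
    do.call(rbind, lapply(names(truth$plantedElements), function(nm) {
      el <- truth$plantedElements[[nm]]
      data.frame(item = "planted_element", name = nm,
                 value = el$sequence,
                 detail = sprintf("pos=%d;leaves=%s", el$position,
                                  paste(el$leaves, collapse = ",")),
                 stringsAsFactors = FALSE)
    })),
    data.frame(item = "enriched_family", name = truth$enrichedFamilies,
               value = "", detail = "", stringsAsFactors = FALSE),
    data.frame(item = "conserved_family", name = truth$conservedFamilies,
               value = "", detail = "", stringsAsFactors = FALSE))
  utils::write.table(ledger, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Simulate per-genome repeat-type metric values
#'
#' Desk-scale generator for the enrichment screen: `nTypes` repeat
#' types measured in two genome groups, values drawn as
#' `Normal(mu_t, cv * mu_t)` with a common within-type standard
#' deviation across groups; the first `plantedTypes` types carry a
#' `fold`-change in group A. Baseline means are log-normal across
#' types. Used for type-I-error and power characterisation of
#' [enrichmentTest()].
#'
#' @param seed RNG seed.
#' @param nTypes number of repeat types.
#' @param nA,nB group sizes (defaults 7 and 2, the symbiotic vs
#'   free-living design).
#' @param plantedTypes number of types with a true effect.
#' @param fold effect size (mean ratio A/B) for planted types.
#' @param cv within-type coefficient of variation of the noise.
#' @param metric name of the value column to emit.
#' @return list with `table` (data.frame: `genome_id`, `repeat_type`,
#'   `repeat_class`, `proportion`, `kimura`), `groupA`, `groupB`,
#'   `plantedTypes`.
#' @export
simulateRepeatTypeValues <- function(seed, nTypes = 1000L, nA = 7L,
                                     nB = 2L, plantedTypes = 0L,
                                     fold = 2, cv = 0.2,
                                     metric = "proportion") {
  set.seed(.substreamSeed(seed, "repeat-values"))
  types <- sprintf("type%04d", seq_len(nTypes))
  classes <- sample(c("DNA", "LTR", "LINE", "SINE", "RC", "Satellite",
                      "Simple", "Unknown"), nTypes, replace = TRUE)
  baseMu <- stats::rlnorm(nTypes, meanlog = log(0.002), sdlog = 0.8)
  gA <- sprintf("symb%02d", seq_len(nA))
  gB <- sprintf("free%02d", seq_len(nB))
  planted <- types[seq_len(plantedTypes)]
  rows <- lapply(seq_len(nTypes), function(t) {
    muB <- baseMu[t]
    muA <- if (types[t] %in% planted) fold * muB else muB
    sdT <- cv * muB
    vals <- c(stats::rnorm(nA, muA, sdT), stats::rnorm(nB, muB, sdT))
    vals <- pmax(vals, 0)
    df <- data.frame(genome_id = c(gA, gB), repeat_type = types[t],
                     repeat_class = classes[t], proportion = NA_real_,
                     kimura = NA_real_, stringsAsFactors = FALSE)
    df[[metric]] <- vals
    df
  })
  list(table = do.call(rbind, rows), groupA = gA, groupB = gB,
       plantedTypes = planted)
}
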