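test_that("the simulated tree is deterministic, binary and correctly shaped", {
  cfg <- simulationConfig(seed = 5)
  tr <- simulateTree(cfg)
  expect_equal(ape::Ntip(tr), 18)
  expect_true(ape::is.binary(tr))
  expect_true(all(tr$edge.length >= 0))
  expect_identical(writeNewick(simulateTree(cfg)), writeNewick(tr))
  expect_false(identical(writeNewick(simulateTree(simulationConfig(seed = 6))),
                         writeNewick(tr)))
  # outgroup pair present as a clade
  expect_true(ape::is.monophyletic(tr, c("O1_i1", "O1_i2")))
  # isolate pairs attach as short-branch cherries
  expect_true(ape::is.monophyletic(tr, c("D1_i1", "D1_i2")))
})

test_that("Jukes-Cantor evolution recovers the input branch length", {
  set.seed(101)
  root <- randomDna(50000)
  leafA <- jcEvolve(root, 0.05)
  leafB <- jcEvolve(root, 0.05)
  phat <- mean(strsplit(leafA, "")[[1]] != strsplit(leafB, "")[[1]])
  dhat <- -3 / 4 * log(1 - 4 * phat / 3)
  expect_equal(dhat, 0.1, tolerance = 0.05)
  expect_identical(jcEvolve(root, 0), root)
})

test_that("Kimura distances follow the closed form and invert through simulation", {
  expect_equal(kimura2p(0, 0), 0)
  expect_equal(kimura2p(0.1, 0.05),
               -0.5 * log((1 - 0.2 - 0.05) * sqrt(1 - 0.1)))
  expect_error(kimura2p(0.5, 0.3), "domain")

  set.seed(102)
  cons <- kmerphylo:::.randomCodes(2000)
  for (K in c(0.1, 0.2, 0.3)) {
    pq <- kmerphylo:::.k2pRates(K, R = 2)
    expect_equal(kimura2p(pq[["P"]], pq[["Q"]]), K, tolerance = 1e-9)
    Khat <- vapply(1:8, function(r) {
      copy <- kmerphylo:::.k2pMutate(cons, pq[["P"]], pq[["Q"]])
      ts <- mean(copy == c(3L, 4L, 1L, 2L)[cons])
      tv <- mean(copy != cons) - ts
      kimura2p(ts, tv)
    }, 0)
    expect_equal(mean(Khat), K, tolerance = 0.05)
  }
})

test_that("evolved collections carry their planted truth", {
  cfg <- smallSimConfig(seed = 3)
  ds <- simulateDataset(cfg)
  expect_length(ds$genomes, 18)

  # planted elements: verbatim in carriers, absent elsewhere
  for (nm in names(ds$truth$plantedElements)) {
    el <- ds$truth$plantedElements[[nm]]
    for (id in names(ds$genomes)) {
      s <- as.character(scaffolds(ds$genomes[[id]])[[1]])
      expect_identical(grepl(el$sequence, s, fixed = TRUE),
                       id %in% el$leaves,
                       label = sprintf("%s in %s", nm, id))
    }
    # locatable at the recorded backbone coordinates
    carrier <- ds$genomes[[el$leaves[1]]]
    at <- substr(as.character(scaffolds(carrier)[[1]]), el$position,
                 el$position + nchar(el$sequence) - 1L)
    expect_identical(at, el$sequence)
  }

  # repeat landscape matches the recorded copy totals exactly
  for (id in c("A1_i1", "O1_i1")) {
    got <- totalBases(extractRepeats(ds$genomes[[id]]))
    expect_equal(got, ds$truth$expectedRepeatBases[[id]])
  }

  # realised repeat fraction approximates the planted target for
  # non-enriched genomes (outgroup has no enrichment applied)
  for (id in c("O1_i1", "O1_i2", "B1_i1")) {
    frac <- totalBases(extractRepeats(ds$genomes[[id]])) /
      totalBases(extractWGS(ds$genomes[[id]]))
    expect_lt(abs(frac - ds$truth$repeatFraction[[id]]), 0.02)
  }

  # per-family mean Kimura tracks the family targets
  tab <- repeatTypeTable(ds$genomes["O1_i1"])
  for (i in seq_len(nrow(tab))) {
    expect_equal(tab$kimura[i],
                 ds$truth$familyKimura[[tab$repeat_type[i]]],
                 tolerance = 0.2 * ds$truth$familyKimura[[tab$repeat_type[i]]])
  }

  # enriched families take up the designed share of the repeat
  # landscape: weight 2 against 1, so 2 nf / (nf + ne) relative to the
  # unenriched share
  tabAll <- repeatTypeTable(ds$genomes)
  enr <- ds$truth$enrichedFamilies
  shareOf <- function(id) {
    x <- tabAll[tabAll$genome_id == id, ]
    sum(x$proportion[x$repeat_type %in% enr]) / sum(x$proportion)
  }
  symb <- vapply(ds$truth$enrichmentGroups$symbiotic, shareOf, 0)
  free <- vapply(ds$truth$enrichmentGroups$freeLiving, shareOf, 0)
  nf <- cfg$familyCount; ne <- length(enr)
  expect_equal(mean(symb) / mean(free), 2 * nf / (nf + ne),
               tolerance = 0.2)
})

test_that("zero-length branches copy the backbone unchanged", {
  cfg <- smallSimConfig(seed = 4)
  cfg$withinCladeBranch <- c(0, 0)
  cfg$betweenCladeBranch <- c(0, 0)
  cfg$terminalBranch <- 0
  cfg$isolateBranch <- 0
  cfg$outgroupStem <- 0
  ds <- simulateDataset(cfg)
  B <- cfg$backboneLength
  bbOf <- function(id) substr(as.character(scaffolds(ds$genomes[[id]])[[1]]),
                              1, B)
  # same-clade genomes (both carry the clade-A element) are identical
  expect_identical(bbOf("A1_i1"), bbOf("A2_i1"))
  # non-A genomes are identical to each other too
  expect_identical(bbOf("B1_i1"), bbOf("C1_i1"))
})

test_that("datasets round trip to disk with annotations intact", {
  cfg <- smallSimConfig(seed = 7)
  ds <- simulateDataset(cfg)
  dir <- withr::local_tempdir()
  writeSimulatedDataset(ds, dir)
  expect_true(file.exists(file.path(dir, "A1_i1.fasta")))
  expect_true(file.exists(file.path(dir, "true_tree.nwk")))
  g <- ds$genomes[["A1_i1"]]
  fa <- readFasta(file.path(dir, "A1_i1.fasta"))
  expect_identical(as.character(fa), as.character(scaffolds(g)))
  lens <- setNames(Biostrings::width(scaffolds(g)), names(scaffolds(g)))
  gff <- readGff3Features(file.path(dir, "A1_i1.gff3"), lens)
  expect_equal(length(gff), length(genomeFeatures(g)))
  tr <- readNewick(path = file.path(dir, "true_tree.nwk"))
  expect_equal(normalizedRF(tr, ds$tree), 0)
  meta <- readMetadataTable(file.path(dir, "metadata.tsv"))
  expect_setequal(meta$genome_id, names(ds$genomes))
})

test_that("the same seed reproduces the same dataset", {
  a <- simulateDataset(smallSimConfig(seed = 9))
  b <- simulateDataset(smallSimConfig(seed = 9))
  expect_identical(as.character(scaffolds(a$genomes[["C2_i1"]])),
                   as.character(scaffolds(b$genomes[["C2_i1"]])))
  expect_identical(writeNewick(a$tree), writeNewick(b$tree))
})
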