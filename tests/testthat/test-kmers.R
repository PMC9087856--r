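test_that("k-mer counting handles multiplicity, ambiguity and boundaries", {
  p <- countKmers(Biostrings::DNAStringSet("AAAA"), 3)
  expect_equal(kmerCounts(p), c(AAA = 2L))
  expect_equal(totalKmers(p), 2L)
  expect_equal(distinctKmers(p), 1L)
  expect_equal(uniqueKmers(p), 0L)

  p2 <- countKmers(Biostrings::DNAStringSet("ACGNT"), 2)
  expect_equal(kmerCounts(p2), c(AC = 1L, CG = 1L))
  expect_equal(totalKmers(p2), 2L)

  # words never span sequence boundaries
  pSplit <- countKmers(Biostrings::DNAStringSet(c("ACG", "TAC")), 3)
  expect_setequal(names(kmerCounts(pSplit)), c("ACG", "TAC"))

  expect_warning(pBig <- countKmers(Biostrings::DNAStringSet("ACGT"), 10),
                 "exceeds every sequence")
  expect_equal(totalKmers(pBig), 0L)
  expect_error(countKmers(Biostrings::DNAStringSet("ACGT"), 0), "k must be")
})

test_that("random sequences match the independent sliding-window oracle", {
  set.seed(31)
  for (r in 1:5) {
    s <- randomDna(1000)
    # sprinkle some Ns
    s <- paste0(substr(s, 1, 400), "N", substr(s, 402, 1000))
    p <- countKmers(Biostrings::DNAStringSet(s), 5)
    expect_identical(kmerCounts(p), oracleKmerCounts(s, 5))
  }
})

test_that("canonical counting merges reverse complements", {
  p <- countKmers(Biostrings::DNAStringSet("ACGT"), 3, canonical = TRUE)
  # ACG -> min(ACG, CGT) = ACG ; CGT -> min(CGT, ACG) = ACG
  expect_equal(kmerCounts(p), c(ACG = 2L))
  set.seed(32)
  s <- Biostrings::DNAStringSet(randomDna(2000))
  expect_lte(distinctKmers(countKmers(s, 7, canonical = TRUE)),
             distinctKmers(countKmers(s, 7)))
  expect_error(countKmers(Biostrings::AAStringSet("MKV"), 2,
                          canonical = TRUE), "nucleotide")
})

test_that("profiles conserve totals and ignore sequence order", {
  set.seed(33)
  seqs <- vapply(1:5, function(i) randomDna(300), "")
  for (k in c(3, 9, 15)) {
    p <- countKmers(Biostrings::DNAStringSet(seqs), k)
    expect_identical(sum(kmerCounts(p)), totalKmers(p))
    pShuf <- countKmers(Biostrings::DNAStringSet(rev(seqs)), k)
    expect_identical(kmerCounts(p), kmerCounts(pShuf))
  }
})

test_that("k-mer proportions follow their definitions", {
  expect_equal(kmerStats(countKmers(Biostrings::DNAStringSet("AAAA"), 3)),
               c(prop_distinct = 0.5, prop_unique = 0))
  p <- countKmers(Biostrings::DNAStringSet("ACGTAC"), 4)  # all distinct
  expect_equal(unname(kmerStats(p)), c(1, 1))
  set.seed(34)
  p2 <- countKmers(Biostrings::DNAStringSet(randomDna(500)), 4)
  cnt <- kmerCounts(p2)
  expect_equal(kmerStats(p2),
               c(prop_distinct = length(cnt) / sum(cnt),
                 prop_unique = sum(cnt == 1) / length(cnt)))
  expect_error(kmerStats(suppressWarnings(
    countKmers(Biostrings::DNAStringSet("AC"), 5))), "T = 0")
})

test_that("the k sweep evaluates the full grid and proportions grow with k", {
  set.seed(35)
  rs <- setNames(lapply(1:2, function(i) {
    new("RegionSet", genomeId = paste0("g", i), regionKind = "WGS",
        sequences = Biostrings::DNAStringSet(
          paste(rep(randomDna(40), 12), collapse = "")))
  }), c("g1", "g2"))
  grid <- seq(11, 25, 2)
  # the repetitive fixture keeps distinctness below the floor, so the
  # chooser legitimately warns while escalating to the largest k
  sw <- suppressWarnings(sweepK(rs, grid))
  expect_equal(sw$grid, as.integer(grid))
  expect_equal(nrow(sw$table), 2 * 8)
  for (g in unique(sw$table$genome_id)) {
    pd <- sw$table$prop_distinct[sw$table$genome_id == g]
    expect_true(all(diff(pd) >= 0))
  }
  # per-k values match a direct recount
  for (i in seq_len(nrow(sw$table))) {
    row <- sw$table[i, ]
    st <- kmerStats(countKmers(rs[[row$genome_id]], row$k))
    expect_equal(row$prop_distinct, st[["prop_distinct"]])
    expect_equal(row$prop_unique, st[["prop_unique"]])
  }
})

test_that("optimal k maximises the mean proportions above the floor", {
  mkSweep <- function(tab, grid) {
    structure(list(regionKind = "WGS", grid = grid, table = tab,
                   chosen_k = NA), class = "KSweepResult")
  }
  tab <- data.frame(genome_id = "g1", k = c(11, 13, 15),
                    prop_distinct = c(0.6, 0.9, 0.8),
                    prop_unique = c(0.2, 0.8, 0.7))
  expect_equal(selectOptimalK(mkSweep(tab, c(11L, 13L, 15L))), 13)

  # nothing above the floor: escalate to the largest k with a warning
  tabLow <- transform(tab, prop_distinct = prop_distinct / 10)
  expect_warning(k <- selectOptimalK(mkSweep(tabLow, c(11L, 13L, 15L))),
                 "largest k")
  expect_equal(k, 15)

  # randomized sweeps against a brute-force argmax oracle
  set.seed(36)
  for (r in 1:20) {
    grid <- sort(sample(5:40, 4))
    tab <- expand.grid(genome_id = paste0("g", 1:3), k = grid)
    tab$prop_distinct <- runif(nrow(tab))
    tab$prop_unique <- runif(nrow(tab))
    got <- suppressWarnings(selectOptimalK(mkSweep(tab, grid)))
    mpd <- tapply(tab$prop_distinct, tab$k, mean)
    sc <- tapply((tab$prop_distinct + tab$prop_unique) / 2, tab$k, mean)
    ok <- names(mpd)[mpd >= 0.5]
    want <- if (!length(ok)) max(grid)
            else as.integer(ok[which.max(sc[ok])])
    expect_equal(got, want)
  }
})

test_that("k-mer dumps round trip through the tab-separated format", {
  set.seed(37)
  p <- countKmers(Biostrings::DNAStringSet(randomDna(400)), 6)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeKmerDump(p, f)
  back <- readKmerDump(f, genomeId = "g")
  expect_identical(kmerCounts(back), kmerCounts(p))
  expect_equal(kmerK(back), 6L)
})
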