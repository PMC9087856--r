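test_that("three-taxon neighbour joining uses the closed form", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighborJoining(d)
  expect_equal(ape::Ntip(tr), 3)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["a"]], (3 + 4 - 5) / 2)
  expect_equal(bl[["b"]], (3 + 5 - 4) / 2)
  expect_equal(bl[["c"]], (4 + 5 - 3) / 2)
})

test_that("NJ is exact on additive matrices (topology and lengths)", {
  nwk <- "(((a:1,b:2):3,c:4):1.5,(d:2.5,e:3.5):0.5);"
  t0 <- readNewick(nwk)
  d <- ape::cophenetic.phylo(t0)
  tr <- neighborJoining(d)
  expect_equal(normalizedRF(tr, t0), 0)
  expect_lt(max(abs(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)] - d)),
            1e-9)

  set.seed(51)
  for (r in 1:25) {
    n <- sample(5:12, 1)
    t0 <- ape::rtree(n, rooted = FALSE,
                     br = function(x) runif(x, 0.5, 3))
    d <- ape::cophenetic.phylo(t0)
    tr <- neighborJoining(d)
    expect_equal(normalizedRF(tr, t0), 0)
    expect_lt(max(abs(ape::cophenetic.phylo(tr)[rownames(d),
                                                colnames(d)] - d)), 1e-9)
  }
})

test_that("NJ agrees with an independent implementation on noisy matrices", {
  set.seed(52)
  for (r in 1:15) {
    t0 <- ape::rtree(6, rooted = FALSE, br = function(x) runif(x, 0.5, 2))
    d <- ape::cophenetic.phylo(t0)
    noise <- matrix(runif(36, 0, 0.05), 6)
    d <- d + (noise + t(noise)) / 2
    diag(d) <- 0
    expect_equal(normalizedRF(neighborJoining(d), ape::nj(d)), 0)
  }
})

test_that("NJ validates its input matrix", {
  d <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(neighborJoining(d), "not symmetric")
  d3 <- matrix(c(0.5, 1, 2, 1, 0, 3, 2, 3, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighborJoining(d3), "diagonal")
})

test_that("outgroup rooting requires a monophyletic outgroup", {
  tr <- readNewick("((P1:1,P2:1):1,((x:1,y:1):1,z:1):1);")
  rt <- rootWithOutgroup(ape::unroot(tr), c("P1", "P2"))
  expect_true(ape::is.rooted(rt))
  expect_true(ape::is.monophyletic(rt, c("P1", "P2")))

  # single-leaf outgroup always works
  expect_true(ape::is.rooted(rootWithOutgroup(ape::unroot(tr), "z")))

  # non-monophyletic outgroup is rejected with the intruding labels
  expect_error(rootWithOutgroup(ape::unroot(tr), c("P1", "x")),
               "not monophyletic")
  expect_error(rootWithOutgroup(tr, "missing"), "not in tree")

  # rooting then unrooting returns the original unrooted topology
  set.seed(53)
  for (r in 1:20) {
    t0 <- ape::rtree(8, rooted = FALSE)
    og <- sample(t0$tip.label, 1)
    expect_equal(normalizedRF(ape::unroot(rootWithOutgroup(t0, og)), t0), 0)
  }
})

test_that("species collapsing replaces monophyletic isolate clades", {
  tr <- readNewick("((Dt_A:1,Dt_B:1):1,(x:1,(y:1,z:1):1):1);")
  map <- c(Dt_A = "D. trenchii", Dt_B = "D. trenchii",
           x = "X sp.", y = "Y sp.", z = "Z sp.")
  col <- collapseSpecies(tr, map)
  expect_setequal(col$tip.label, c("D. trenchii", "X sp.", "Y sp.", "Z sp."))

  # single-isolate species are relabelled only
  expect_equal(ape::Ntip(col), 4)

  # idempotence
  expect_equal(normalizedRF(collapseSpecies(col, map), col), 0)

  # random trees with planted 2-isolate cherries: leaf count drops by
  # the number of collapsed clades
  set.seed(54)
  for (r in 1:10) {
    base <- ape::rtree(6, rooted = FALSE)
    base$tip.label <- paste0("sp", 1:6)
    nCol <- sample(1:3, 1)
    tr2 <- base
    for (i in seq_len(nCol)) {
      tr2 <- ape::bind.tree(
        tr2, readNewick(sprintf("(sp%d_a:0.1,sp%d_b:0.1):0.1;", i, i)),
        where = which(tr2$tip.label == paste0("sp", i)))
      tr2 <- ape::drop.tip(tr2, paste0("sp", i))
    }
    map2 <- setNames(sub("_[ab]$", "", tr2$tip.label), tr2$tip.label)
    col2 <- collapseSpecies(tr2, map2)
    expect_equal(ape::Ntip(col2), ape::Ntip(tr2) - nCol)
  }
})

test_that("non-monophyletic isolates keep their leaves in both trees", {
  t1 <- readNewick("((s1_a:1,s1_b:1):1,(s2:1,s3:1):1);")
  t2 <- readNewick("((s1_a:1,s2:1):1,(s1_b:1,s3:1):1);")  # s1 broken apart
  map <- c(s1_a = "s1", s1_b = "s1", s2 = "s2", s3 = "s3")
  rf <- normalizedRF(t1, t2, map)
  # collapsing must not have merged s1 in either tree: N stays 4
  expect_equal(rf, 1)  # 4-leaf trees with different splits share nothing
})

test_that("normalised RF follows its definition and the brute-force oracle", {
  t0 <- ape::rtree(18, rooted = FALSE)
  expect_equal(normalizedRF(t0, t0), 0)

  # two 6-leaf caterpillars sharing no non-trivial bipartitions
  t1 <- readNewick("(a,(b,(c,(d,(e,f)))));")
  t2 <- readNewick("(a,(d,(b,(f,(c,e)))));")
  expect_length(intersect(oracleBipartitions(t1), oracleBipartitions(t2)), 0)
  expect_equal(normalizedRF(t1, t2), 1)

  set.seed(55)
  for (r in 1:40) {
    ta <- ape::rtree(8, rooted = FALSE)
    tb <- ape::rtree(8, rooted = FALSE)
    tb$tip.label <- sample(ta$tip.label)
    expect_equal(normalizedRF(ta, tb), oracleNormalizedRF(ta, tb))
    expect_equal(normalizedRF(ta, tb), normalizedRF(tb, ta))
  }

  expect_error(normalizedRF(readNewick("((a,b),(c,d));"),
                            readNewick("((a,b),(c,e));")),
               "leaf sets differ")
})
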