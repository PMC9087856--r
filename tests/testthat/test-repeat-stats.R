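test_that("repeat-type tables summarise proportions and divergence", {
  g <- tinyGenome()
  tab <- repeatTypeTable(list(g))
  expect_setequal(tab$repeat_type, c("Gypsy-7", "hAT-3"))
  gy <- tab[tab$repeat_type == "Gypsy-7", ]
  expect_equal(gy$proportion, 200 / 3000)
  expect_equal(gy$kimura, 12.5)
  ha <- tab[tab$repeat_type == "hAT-3", ]
  expect_equal(ha$proportion, 300 / 3000)  # overlapping copies merged
  expect_equal(ha$kimura, 22.5)
})

test_that("shared repeat types require presence in every group member", {
  tab <- data.frame(
    genome_id = rep(c("g1", "g2", "g3"), each = 2),
    repeat_type = rep(c("tA", "tB"), 3),
    repeat_class = "DNA",
    proportion = c(0.1, 0.2, 0.1, 0, 0.1, 0.3),
    kimura = 10)
  expect_equal(sharedRepeatTypes(tab, c("g1", "g2", "g3")), "tA")
  expect_setequal(sharedRepeatTypes(tab, c("g1", "g3")), c("tA", "tB"))
  expect_error(sharedRepeatTypes(tab, character()), "empty group")

  # random presence matrix against a column-wise all() oracle
  set.seed(91)
  for (r in 1:10) {
    m <- matrix(runif(60) > 0.3, 6, 10,
                dimnames = list(paste0("g", 1:6), paste0("t", 1:10)))
    tabR <- do.call(rbind, lapply(rownames(m), function(g)
      data.frame(genome_id = g, repeat_type = colnames(m),
                 repeat_class = "DNA",
                 proportion = ifelse(m[g, ], 0.1, 0), kimura = 1)))
    expect_setequal(sharedRepeatTypes(tabR, rownames(m)),
                    colnames(m)[apply(m, 2, all)])
  }
})

mkTab <- function(valsA, valsB, type = "t1", cls = "DNA") {
  data.frame(
    genome_id = c(paste0("a", seq_along(valsA)), paste0("b", seq_along(valsB))),
    repeat_type = type, repeat_class = cls,
    proportion = c(valsA, valsB), kimura = c(valsA, valsB))
}

test_that("degenerate inputs are handled as specified", {
  tab <- mkTab(rep(0.2, 4), rep(0.2, 3))
  res <- enrichmentTest(tab, paste0("a", 1:4), paste0("b", 1:3),
                        metric = "proportion", types = "t1")
  expect_equal(res$raw_p, 1)
  expect_false(res$significant)
  expect_equal(res$reason, "identical values")

  tab2 <- mkTab(rep(0.2, 4), rep(0.4, 3))
  res2 <- enrichmentTest(tab2, paste0("a", 1:4), paste0("b", 1:3),
                         metric = "proportion", types = "t1")
  expect_true(is.na(res2$raw_p))
  expect_match(res2$reason, "zero within-group variance")
})

test_that("the decision tree traverses Shapiro, transform, Levene and the t-tests", {
  # heavily skewed values violate normality -> log transform
  set.seed(92)
  a <- exp(rnorm(7, 0, 2)); b <- exp(rnorm(7, 0, 2))
  res <- enrichmentTest(mkTab(a, b), paste0("a", 1:7), paste0("b", 1:7),
                        metric = "proportion", types = "t1")
  expect_lt(res$shapiro_p, 0.05)
  expect_equal(res$transform_applied, "log")

  # equal-variance normal fixture keeps Student's test, and Welch on the
  # same values agrees to numerical precision when variances are equal
  a2 <- c(1.0, 2.0, 3.0, 4.0)
  b2 <- c(2.5, 3.5, 4.5, 5.5)  # same spacing -> identical variance
  res2 <- enrichmentTest(mkTab(a2, b2), paste0("a", 1:4), paste0("b", 1:4),
                         metric = "proportion", types = "t1")
  expect_equal(res2$test_used, "student")
  welchP <- t.test(a2, b2, var.equal = FALSE)$p.value
  expect_equal(res2$raw_p, welchP, tolerance = 1e-9)

  # gross variance inequality routes to Welch
  set.seed(93)
  a3 <- rnorm(8, 10, 3); b3 <- rnorm(8, 10, 0.05)
  res3 <- enrichmentTest(mkTab(a3, b3), paste0("a", 1:8), paste0("b", 1:8),
                         metric = "proportion", types = "t1")
  expect_lt(res3$variance_test_p, 0.05)
  expect_equal(res3$test_used, "welch")
})

test_that("planted effects are detected in the 7-vs-2 design with correct direction", {
  sim <- simulateRepeatTypeValues(seed = 94, nTypes = 60, plantedTypes = 10,
                                  fold = 2)
  res <- enrichmentTest(sim$table, sim$groupA, sim$groupB,
                        metric = "proportion",
                        types = sort(unique(sim$table$repeat_type)))
  planted <- res$repeat_type %in% sim$plantedTypes
  expect_gte(mean(res$significant[planted]), 0.8)
  expect_true(all(res$direction[res$significant & planted] > 0))
  expect_lte(mean(res$significant[!planted]), 0.1)
})

test_that("adjusted p-values are a monotone step-up of the raw ones", {
  sim <- simulateRepeatTypeValues(seed = 95, nTypes = 80, plantedTypes = 8)
  res <- enrichmentTest(sim$table, sim$groupA, sim$groupB,
                        metric = "proportion",
                        types = sort(unique(sim$table$repeat_type)))
  ok <- !is.na(res$raw_p)
  expect_true(all(res$adjusted_p[ok] >= res$raw_p[ok] - 1e-12))
  expect_true(all(res$adjusted_p[ok] <= 1))
  ord <- order(res$raw_p[ok])
  expect_true(all(diff(res$adjusted_p[ok][ord]) >= -1e-12))
  # bonferroni is exposed as an alternative
  resB <- enrichmentTest(sim$table, sim$groupA, sim$groupB,
                         metric = "proportion", adjust = "bonferroni",
                         types = sort(unique(sim$table$repeat_type)))
  expect_true(all(resB$adjusted_p[ok] >= res$adjusted_p[ok] - 1e-12))
})

test_that("class summaries count each type once across metrics", {
  res <- data.frame(
    repeat_type = c(paste0("d", 1:5), paste0("l", 1:4), "both1", "both1"),
    repeat_class = c(rep("DNA", 5), rep("LTR", 4), "LTR", "LTR"),
    metric = c(rep("proportion", 9), "proportion", "kimura"),
    significant = TRUE)
  s <- summariseByClass(res)
  expect_equal(s$n_significant[s$repeat_class == "DNA"], 5)
  expect_equal(s$n_significant[s$repeat_class == "LTR"], 5)
  expect_equal(s$percent[s$repeat_class == "DNA"], 50)
  expect_equal(s$n_both[s$repeat_class == "LTR"], 1)

  none <- res; none$significant <- FALSE
  expect_equal(nrow(summariseByClass(none)), 0)

  # recount oracle on random flags
  set.seed(96)
  res$significant <- runif(nrow(res)) > 0.4
  s2 <- summariseByClass(res)
  sig <- unique(res$repeat_type[res$significant])
  expect_equal(sum(s2$n_significant), length(sig))
})
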