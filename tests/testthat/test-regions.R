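test_that("repeat-masked extraction splits at repeats and filters short fragments", {
  seq <- randomDna(3000)
  gr <- GenomicRanges::GRanges("sc1", IRanges::IRanges(1001, 1200))
  gr$type <- "repeat"
  g <- GenomeRecord("g", c(sc1 = seq), features = gr)
  rm <- extractRmWGS(g)
  expect_equal(sort(Biostrings::width(regionSequences(rm))), c(1000, 1800))
  # fragments are genuine splits, not flank joins
  expect_equal(as.character(regionSequences(rm)[[1]]), substr(seq, 1, 1000))

  seq2 <- randomDna(1500)
  gr2 <- GenomicRanges::GRanges("sc1", IRanges::IRanges(1, 600))
  gr2$type <- "repeat"
  g2 <- GenomeRecord("g2", c(sc1 = seq2), features = gr2)
  expect_length(regionSequences(extractRmWGS(g2)), 0)  # 900 bp < 1 kb
  expect_equal(totalBases(extractRmWGS(g2, minLen = 0)), 900)
})

test_that("rmWGS plus merged repeats account exactly for the assembly", {
  set.seed(21)
  for (r in 1:10) {
    nsc <- sample(1:3, 1)
    seqs <- setNames(vapply(seq_len(nsc),
                            function(i) randomDna(sample(2000:5000, 1)), ""),
                     paste0("sc", seq_len(nsc)))
    spec <- do.call(rbind, lapply(names(seqs), function(sc) {
      n <- sample(2:6, 1)
      data.frame(sc = sc,
                 st = sample(seq_len(nchar(seqs[[sc]]) - 400), n),
                 w = sample(50:400, n, replace = TRUE))
    }))
    reps <- GenomicRanges::GRanges(spec$sc,
                                   IRanges::IRanges(spec$st, width = spec$w))
    reps$type <- "repeat"
    g <- GenomeRecord("g", seqs, features = reps)
    wgs <- totalBases(extractWGS(g))
    expect_identical(totalBases(extractRmWGS(g, minLen = 0)) +
                       totalBases(extractRepeats(g)), wgs)
  }
})

test_that("CDS extraction is strand-specific and transcript-aware", {
  # plus strand, single segment
  g <- GenomeRecord("g", c(sc1 = "ATGAAATTTCCC"),
                    features = local({
                      gr <- GenomicRanges::GRanges("sc1", IRanges::IRanges(1, 6),
                                                   strand = "+")
                      gr$type <- "CDS"; gr$transcript_id <- "t1"; gr
                    }))
  expect_equal(as.character(regionSequences(extractCDS(g))[["t1"]]),
               "ATGAAA")

  # minus strand: sense strand is the reverse complement
  g2 <- GenomeRecord("g", c(sc1 = "TTTCAT"),
                     features = local({
                       gr <- GenomicRanges::GRanges("sc1", IRanges::IRanges(1, 6),
                                                    strand = "-")
                       gr$type <- "CDS"; gr$transcript_id <- "t1"; gr
                     }))
  expect_equal(as.character(regionSequences(extractCDS(g2))[["t1"]]),
               "ATGAAA")

  # two-exon CDS equals the independent concatenation oracle
  set.seed(22)
  seq <- randomDna(500)
  gr <- GenomicRanges::GRanges("sc1", IRanges::IRanges(c(11, 101), c(40, 160)),
                               strand = "-")
  gr$type <- "CDS"; gr$transcript_id <- "t1"
  g3 <- GenomeRecord("g", c(sc1 = seq), features = gr)
  oracle <- revcomp(paste0(substr(seq, 11, 40), substr(seq, 101, 160)))
  expect_equal(as.character(regionSequences(extractCDS(g3))[["t1"]]), oracle)

  # mixed strands in one transcript are rejected
  gr2 <- gr
  GenomicRanges::strand(gr2) <- c("+", "-")
  g4 <- GenomeRecord("g", c(sc1 = seq), features = gr2)
  expect_error(extractCDS(g4), "mixed strands")
})

test_that("introns come from annotation or exon gaps, on the sense strand", {
  seq <- randomDna(200)
  mkg <- function(strand) {
    gr <- GenomicRanges::GRanges("sc1", IRanges::IRanges(c(1, 21), c(10, 30)),
                                 strand = strand)
    gr$type <- "CDS"; gr$transcript_id <- "t1"
    GenomeRecord("g", c(sc1 = seq), features = gr)
  }
  expect_equal(as.character(regionSequences(extractIntrons(mkg("+")))[[1]]),
               substr(seq, 11, 20))
  expect_equal(as.character(regionSequences(extractIntrons(mkg("-")))[[1]]),
               revcomp(substr(seq, 11, 20)))

  # overlapping exons are a validation error
  grBad <- GenomicRanges::GRanges("sc1", IRanges::IRanges(c(1, 8), c(10, 30)),
                                  strand = "+")
  grBad$type <- "CDS"; grBad$transcript_id <- "t1"
  expect_error(extractIntrons(GenomeRecord("g", c(sc1 = seq),
                                           features = grBad)),
               "overlapping exons")

  # annotated introns and exon-gap derivation agree on the tiny genome
  g <- tinyGenome()
  withAnn <- sort(as.character(regionSequences(extractIntrons(g))))
  feats <- genomeFeatures(g)
  noAnn <- GenomeRecord("tiny2", scaffolds(g),
                        features = feats[feats$type != "intron"])
  expect_equal(sort(as.character(regionSequences(extractIntrons(noAnn)))),
               withAnn)
})

test_that("intron plus exon bases fill each gene span", {
  g <- tinyGenome()
  feats <- genomeFeatures(g)
  cdsB <- sum(Biostrings::width(feats[feats$type == "CDS"]))
  intB <- totalBases(extractIntrons(g))
  geneB <- sum(Biostrings::width(feats[feats$type == "gene"]))
  expect_identical(cdsB + intB, geneB)
})

test_that("repeat extraction merges overlapping intervals", {
  seq <- randomDna(100)
  gr <- GenomicRanges::GRanges("sc1", IRanges::IRanges(c(1, 6), c(10, 20)))
  gr$type <- "repeat"
  g <- GenomeRecord("g", c(sc1 = seq), features = gr)
  out <- regionSequences(extractRepeats(g))
  expect_length(out, 1)
  expect_equal(as.character(out[[1]]), substr(seq, 1, 20))
})

test_that("translation follows the standard code and flags anomalies", {
  tr <- function(s) {
    rs <- new("RegionSet", genomeId = "g", regionKind = "CDS",
              sequences = Biostrings::DNAStringSet(c(t1 = s)))
    as.character(regionSequences(translateCDS(rs)))[[1]]
  }
  expect_equal(tr("ATGAAATAA"), "MK")
  expect_warning(out <- tr("ATGTAAATG"), "internal stop")
  expect_equal(out, "M*M")
  expect_warning(tr("ATGAAAT"), "divisible by 3")

  # random CDS against an independent codon-table oracle
  set.seed(23)
  code <- Biostrings::GENETIC_CODE
  for (r in 1:100) {
    len <- 3 * sample(5:60, 1)
    s <- randomDna(len)
    codons <- substring(s, seq(1, len, 3), seq(3, len, 3))
    aa <- paste(code[codons], collapse = "")
    aa <- sub("\\*$", "", aa)
    expect_equal(suppressWarnings(tr(s)), aa)
  }
})

test_that("GC content counts unambiguous bases only", {
  rs <- function(s) Biostrings::DNAStringSet(s)
  expect_equal(gcContent(rs("GGCC")), 1)
  expect_equal(gcContent(rs("ATAT")), 0)
  expect_equal(gcContent(rs("GCNNAT")), 0.5)
  expect_error(gcContent(rs("NNNN")), "no unambiguous")
  set.seed(24)
  s <- randomDna(5000)
  l <- strsplit(s, "")[[1]]
  expect_equal(gcContent(rs(s)), mean(l %in% c("G", "C")))
})

test_that("extraction is invariant under reverse-complementing the genome", {
  g <- tinyGenome()
  L <- Biostrings::width(scaffolds(g))[[1]]
  feats <- genomeFeatures(g)
  rcFeats <- GenomicRanges::GRanges(
    "sc1",
    IRanges::IRanges(L - GenomicRanges::end(feats) + 1L,
                     L - GenomicRanges::start(feats) + 1L),
    strand = chartr("+-", "-+", as.character(GenomicRanges::strand(feats))))
  S4Vectors::mcols(rcFeats) <- S4Vectors::mcols(feats)
  gRC <- GenomeRecord("tinyRC",
                      c(sc1 = revcomp(as.character(scaffolds(g)[[1]]))),
                      features = rcFeats)
  for (extract in list(extractCDS, extractIntrons)) {
    expect_setequal(unname(as.character(regionSequences(extract(g)))),
                    unname(as.character(regionSequences(extract(gRC)))))
  }
})
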