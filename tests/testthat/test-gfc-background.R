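test_that("observed frequency follows t / (l_s - l_m + 1)", {
  expect_equal(observedFrequency(2, 20, 5), 0.125)
  expect_equal(observedFrequency(0, 20, 5), 0)
  expect_equal(observedFrequency(1, 5, 5), 1)
  expect_error(observedFrequency(1, 4, 5), "shorter")
})

test_that("background counts and placement totals are exact", {
  bg <- buildBackground(c(b = "ACGUACGU"), "ACGU", "cds")
  expect_equal(bg@counts$c, 2L)
  expect_equal(unname(bg@totals["4"]), 5)

  # absent motif counts zero
  bg0 <- buildBackground(c(b = "ACGUACGU"), "CCCC", "intron")
  expect_equal(bg0@counts$c, 0L)

  # sequences shorter than the motif contribute zero placements
  bg2 <- buildBackground(c(a = paste(rep("A", 10), collapse = ""),
                           b = "ACG"),
                         "AAAAA", "exon250")
  expect_equal(unname(bg2@totals["5"]), 6)

  expect_error(buildBackground(character(0), "ACGU", "cds"), "empty")
  expect_error(buildBackground(c(a = "ACGU"), "RCGU", "cds"), "concrete")
})

test_that("expected frequency divides count by the placement total", {
  set.seed(3)
  seqs <- c(s = randomSeq(105))
  bg <- buildBackground(seqs, "ACGUA", "cds")
  cTrue <- naiveCount(seqs[["s"]], "ACGUA")
  expect_equal(expectedFrequency(bg, "ACGUA"), cTrue / 101)
  expect_error(expectedFrequency(bg, "GGGG"), "not counted")
})

test_that("background construction agrees with a brute-force counter", {
  set.seed(17)
  for (rep in 1:10) {
    seqs <- setNames(vapply(1:3, function(i) randomSeq(sample(30:200, 1)),
                            character(1)), paste0("s", 1:3))
    motifs <- vapply(1:4, function(i) randomMotif(sample(4:6, 1)),
                     character(1))
    bg <- buildBackground(seqs, motifs, "intron")
    for (m in unique(rbpkit:::normalizeNucleotides(motifs))) {
      expect_equal(bg@counts$c[bg@counts$motif == m],
                   sum(vapply(seqs, naiveCount, integer(1), pattern = m)))
      lens <- nchar(seqs)
      expect_equal(unname(bg@totals[as.character(nchar(m))]),
                   sum(pmax(0, lens - nchar(m) + 1)))
    }
  }
})

test_that("log odds follow log2(Obs/Exp) with an NA sentinel at Exp = 0", {
  expect_equal(logOdds(0.1, 0.1), 0)
  expect_equal(logOdds(0.2, 0.1), 1)
  expect_equal(logOdds(0.125, 10 / 101), log(0.125 * 101 / 10) / log(2))
  expect_true(is.na(logOdds(0.1, 0)))
  expect_error(logOdds(0, 0.1), "positive")
})

test_that("a FASTA scored against itself as background has OR = 0", {
  tab <- MotifTable("CELF1", "UGUU", "Homo sapiens", "SELEX")
  seqs <- c(s = "AAUGUUAAUGUUACGCG")
  hits <- scanMotifs(seqs, tab)
  bgs <- lapply(c("exon250", "intron", "cds"), function(ctx)
    buildBackground(seqs, "UGUU", ctx, "Homo sapiens"))
  scored <- scoreHits(hits, seqs, bgs)
  expect_true(all(scored$exon250 == 0))
  expect_true(all(scored$intron == 0))
  expect_true(all(scored$cds == 0))
})

test_that("missing backgrounds and absent motifs yield NA sentinels", {
  tab <- toyMotifTable()
  seqs <- c(s = "AAUGUUAAUCUUCA")
  hits <- scanMotifs(seqs, tab)
  # background only for human, only two contexts carrying the motif
  bgs <- list(
    buildBackground(c(b = "UGUUAUGUUC"), "UGUU", "exon250", "Homo sapiens"),
    buildBackground(c(b = "CCCCCCCCCC"), "UGUU", "intron", "Homo sapiens"))
  scored <- scoreHits(hits, seqs, bgs)
  human <- scored[scored$gene_name == "CELF1", ]
  expect_true(all(!is.na(human$exon250)))
  expect_true(all(is.na(human$intron)))  # motif absent from that context
  expect_true(all(is.na(human$cds)))     # no cds background supplied
  mouse <- scored[scored$gene_name == "PTBP1", ]
  expect_true(all(is.na(mouse$exon250)))  # no mouse backgrounds at all
})

test_that("OR increases strictly with multiplicity at fixed background", {
  bg <- buildBackground(c(b = "UGUUAUGUUCAUGUU"), "UGUU", "cds", "h")
  expv <- expectedFrequency(bg, "UGUU")
  ors <- vapply(1:5, function(t)
    logOdds(observedFrequency(t, 50, 4), expv), numeric(1))
  expect_true(all(diff(ors) > 0))
})

test_that("planted enrichment is recovered exactly from truth counts", {
  fx <- genBackgroundPair(9, "AGGUA", tScan = 10, scanPositions = 100,
                          cContext = 10, contextPositions = 1000)
  tab <- MotifTable("X1", "AGGUA", "Homo sapiens", "SELEX")
  hits <- scanMotifs(fx$scan, tab)
  expect_equal(unique(hits$t), 10L)
  bgs <- lapply(c("exon250", "intron", "cds"), function(ctx)
    buildBackground(fx$context, "AGGUA", ctx, "Homo sapiens"))
  scored <- scoreHits(hits, fx$scan, bgs)
  expect_equal(unique(scored$cds), log2(10))
  expect_equal(unique(scored$cds), fx$truth$or)
})

test_that("background tables round-trip through TSV", {
  bg <- buildBackground(c(b = "ACGUACGUA"), c("ACGU", "CGUA"), "cds", "h")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeBackground(bg, path)
  back <- readBackground(path)[[1]]
  expect_equal(back@context, "cds")
  expect_equal(back@counts, bg@counts)
  expect_equal(back@totals, bg@totals)
  # the reloaded table scores identically
  expect_equal(expectedFrequency(back, "ACGU"),
               expectedFrequency(bg, "ACGU"))
})
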