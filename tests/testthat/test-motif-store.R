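test_that("gene-name normalization maps aliases to official names", {
  syn <- synonymTable("CUGBP1", "CELF1", "Homo sapiens")
  raw <- MotifTable("CUGBP1", "UGUU", "Homo sapiens", "SELEX")
  norm <- normalizeRecords(raw, syn)
  expect_equal(records(norm)$gene_name, "CELF1")
  expect_true("CUGBP1" %in% rbpkit:::splitSynonyms(records(norm)$synonyms)[[1]])

  # official names are fixed points
  already <- MotifTable("CELF1", "UGUU", "Homo sapiens", "SELEX")
  expect_equal(records(normalizeRecords(already, syn))$gene_name, "CELF1")

  # normalization is idempotent
  twice <- normalizeRecords(norm, syn)
  expect_identical(records(twice), records(norm))
})

test_that("normalization unifies the motif alphabet and warns on unknown organisms", {
  syn <- synonymTable("CUGBP1", "CELF1", "Homo sapiens")
  raw <- MotifTable("PTBP1", "acgt", "Mus musculus", "EMSA")
  expect_equal(records(raw)$motif, "ACGU")  # enforced at construction
  expect_warning(norm <- normalizeRecords(raw, syn), "Mus musculus")
  expect_equal(records(norm)$gene_name, "PTBP1")
})

test_that("distinct entries follow the three-clause rule", {
  # same motif bound by two different RBPs: two entries
  two <- MotifTable(gene_name = c("SRSF1", "RBM8A"), motif = "ACGCGCC",
                    organism = "Homo sapiens", experiment = "SELEX")
  expect_equal(length(distinctEntries(two)), 2L)

  # byte-identical records collapse to one
  dup <- MotifTable(gene_name = c("SRSF1", "SRSF1"), motif = "ACGCGCC",
                    organism = "Homo sapiens", experiment = "SELEX")
  expect_equal(length(distinctEntries(dup)), 1L)

  # same motif+RBP+experiment across organisms stays distinct
  orgs <- MotifTable(gene_name = "SRSF1", motif = "ACGCGCC",
                     organism = c("Homo sapiens", "Mus musculus"),
                     experiment = "SELEX")
  expect_equal(length(distinctEntries(orgs)), 2L)

  # different experiment stays distinct
  exps <- MotifTable(gene_name = "SRSF1", motif = "ACGCGCC",
                     organism = "Homo sapiens",
                     experiment = c("SELEX", "X-RAY"))
  expect_equal(length(distinctEntries(exps)), 2L)
})

test_that("distinctEntries is idempotent, order-stable and never grows", {
  tab <- toyMotifTable()
  big <- tab[c(1, 1, 2, 3, 1, 4, 5, 5)]
  once <- distinctEntries(big)
  expect_lte(length(once), length(big))
  expect_identical(records(distinctEntries(once)), records(once))
  # first occurrences survive in input order
  expect_identical(records(once)$gene_name,
                   records(tab)$gene_name)
})

test_that("query applies conjunctive criteria", {
  tab <- toyMotifTable()
  bySyn <- queryRecords(tab, synonym = "SFRS1")
  expect_true(all(records(bySyn)$gene_name == "SRSF1"))
  expect_equal(length(bySyn), 2L)

  byId <- queryRecords(tab, geneId = "ENSG00000136450")
  expect_true(all(records(byId)$gene_name == "SRSF1"))

  expect_equal(length(queryRecords(tab, organism = "no-such-organism")), 0L)

  # conjunction: organism AND length bound
  both <- queryRecords(tab, organism = "Homo sapiens", minLen = 6)
  expect_true(all(records(both)$organism == "Homo sapiens" &
                    records(both)$len >= 6))
  expect_equal(length(both), 3L)

  expect_error(queryRecords(tab, minLen = 8, maxLen = 4), "length bounds")
})

test_that("TSV round-trip preserves every field", {
  tab <- toyMotifTable()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeMotifRecords(tab, path)
  back <- readMotifRecords(path)
  expect_identical(records(back), records(tab))

  # header-only file gives an empty table
  empty <- tab[integer(0)]
  writeMotifRecords(empty, path)
  expect_equal(length(readMotifRecords(path)), 0L)
})

test_that("the bundled example table loads and is already distinct", {
  path <- system.file("extdata", "example_motifs.tsv", package = "rbpkit")
  tab <- readMotifRecords(path)
  expect_equal(length(tab), 6L)
  expect_equal(length(distinctEntries(tab)), 6L)
  expect_equal(length(queryRecords(tab, synonym = "SFRS1")), 2L)
})

test_that("TSV reading reports missing columns and malformed motifs", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_name\tmotif", "SRSF1\tACGCGCC"), path)
  expect_error(readMotifRecords(path), "organism")

  tab <- toyMotifTable()
  writeMotifRecords(tab, path)
  lines <- readLines(path)
  lines[3] <- sub("RCGUUC", "RXGUUC", lines[3])
  writeLines(lines, path)
  expect_error(readMotifRecords(path), "line 3")
})

test_that("record validity enforces motif length, alphabet and score range", {
  expect_error(MotifTable("X", "ACG", "h", "SELEX"), "length")
  expect_error(MotifTable("X", "ACGUACGUACGUA", "h", "SELEX"), "length")
  expect_error(MotifTable("X", "ACZU", "h", "SELEX"), "IUPAC")
  expect_error(MotifTable("X", "ACGU", "h", "SELEX", quality_score = 1.5),
               "quality_score")
})
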