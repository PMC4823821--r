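toyPath <- function(...) {
  path <- withr::local_tempfile(fileext = ".pdb",
                                .local_envir = parent.frame())
  genToyStructure(..., path = path)
  path
}

test_that("structures parse with chain classes, method and resolution", {
  p <- toyPath(c("A", "C", "G", "U", "A", "C"), 2.8)
  s <- readStructure(p)
  expect_equal(sort(s@chains$class), c("protein", "rna"))
  expect_equal(s@method, "X-ray")
  expect_equal(s@resolution, 2.0)
  expect_false(s@rnaAbsent)
  # RNA chain has 6 residues
  rna <- s@atoms[s@atoms$chain == "B", ]
  expect_equal(length(unique(rna$resno)), 6L)
})

test_that("NMR ensembles reduce to the first model", {
  path <- withr::local_tempfile(fileext = ".pdb")
  lines <- c("EXPDTA    SOLUTION NMR",
             "MODEL        1",
             "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
             "ATOM      2  O2'   A B   1       0.000   0.000   2.500  1.00  0.00           O",
             "ENDMDL",
             "MODEL        2",
             "ATOM      1  N   GLY A   1       9.000   0.000   0.000  1.00  0.00           N",
             "ATOM      2  O2'   A B   1       9.000   0.000   7.500  1.00  0.00           O",
             "ENDMDL", "END")
  writeLines(lines, path)
  s <- readStructure(path)
  expect_equal(nrow(s@atoms), 2L)
  expect_equal(s@method, "NMR")
  expect_true(is.na(s@resolution))
})

test_that("protein-only files parse and are flagged rna_absent", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("EXPDTA    X-RAY DIFFRACTION",
               "REMARK   2 RESOLUTION.    1.80 ANGSTROMS.",
               "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
               "END"), path)
  s <- readStructure(path)
  expect_true(s@rnaAbsent)
  expect_error(findContacts(s), "no RNA")
  expect_error(readStructure(file.path(tempdir(), "no-such-file.pdb")),
               "cannot read")
})

test_that("eligibility ties the resolution bound to X-ray only", {
  mk <- function(method, resolution) {
    p <- tempfile(fileext = ".pdb")
    on.exit(unlink(p))
    genToyStructure("ACGU", 2.8, method = method, resolution = resolution,
                    path = p)
    readStructure(p)
  }
  expect_true(isEligible(mk("X-RAY DIFFRACTION", 2.1)))
  expect_false(isEligible(mk("X-RAY DIFFRACTION", 4.1)))
  expect_false(isEligible(mk("X-RAY DIFFRACTION", 3.9)))  # strict bound
  expect_true(isEligible(mk("SOLUTION NMR", NA)))
  expect_true(isEligible(mk("ELECTRON MICROSCOPY", NA)))
  expect_warning(ok <- isEligible(mk("X-RAY DIFFRACTION", NA)),
                 "no resolution")
  expect_false(ok)
})

test_that("contact kinds follow the 3.0/3.9 Angstrom cutoffs", {
  # polar N...O pair at 2.9: hydrogen bond and vdW
  s <- readStructure(toyPath("ACGU", c(2.9, 5, 5, 5), kind = "polar"))
  ct <- findContacts(s)
  expect_setequal(ct$kind[ct$rna_resno == 1], c("hbond", "vdw"))
  expect_equal(unique(ct$min_distance[ct$rna_resno == 1]), 2.9)
  expect_equal(sort(unique(ct$rna_resno)), 1L)

  # carbon pair at 3.5: vdW only
  s2 <- readStructure(toyPath("ACGU", c(3.5, 5, 5, 5), kind = "carbon"))
  ct2 <- findContacts(s2)
  expect_equal(ct2$kind, "vdw")
  expect_equal(ct2$rna_resno, 1L)

  # nearest pair at 4.2: no contact of either kind
  s3 <- readStructure(toyPath("ACGU", 4.2, kind = "polar"))
  expect_equal(nrow(findContacts(s3)), 0L)

  # cutoffs are inclusive: exactly 3.0 / exactly 3.9 still qualify
  s4 <- readStructure(toyPath("ACGU", c(3.0, 5, 5, 5), kind = "polar"))
  expect_true("hbond" %in% findContacts(s4)$kind)
  s5 <- readStructure(toyPath("ACGU", c(3.9, 5, 5, 5), kind = "carbon"))
  expect_true("vdw" %in% findContacts(s5)$kind)
})

test_that("contact detection agrees with an all-pairs brute force", {
  set.seed(23)
  for (rep in 1:6) {
    n <- sample(4:8, 1)
    dists <- round(runif(n, 2.0, 5.0), 2)
    kind <- sample(c("polar", "carbon"), 1)
    s <- readStructure(toyPath(sample(c("A", "C", "G", "U"), n,
                                      replace = TRUE),
                               dists, kind = kind))
    got <- findContacts(s)[, c("rna_chain", "rna_resno", "kind")]
    got <- got[order(got$rna_chain, got$rna_resno, got$kind), ]
    want <- naiveContacts(s)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("shrinking the vdW cutoff never adds contacts", {
  set.seed(31)
  s <- readStructure(toyPath(c("A", "C", "G", "U", "A"),
                             round(runif(5, 3.0, 4.5), 2)))
  n <- vapply(c(4.5, 3.9, 3.5, 3.0),
              function(cut) nrow(findContacts(s, vdwCutoff = cut)),
              integer(1))
  expect_true(all(diff(n) <= 0))
})

test_that("binding sites need four or more contiguous contacted nucleotides", {
  # five contacted residues: one site, 5' -> 3' motif
  s <- readStructure(toyPath(c("A", "C", "G", "U", "A"), 2.8))
  sites <- callBindingSites(findContacts(s), s)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$motif, "ACGUA")
  expect_equal(c(sites$start, sites$end), c(1L, 5L))

  # three contacted residues: below threshold
  s3 <- readStructure(toyPath(c("A", "C", "G", "U", "A"),
                              c(2.8, 2.8, 2.8, 9, 9)))
  expect_equal(nrow(callBindingSites(findContacts(s3), s3)), 0L)

  # runs of 4 and 6 separated by an uncontacted nucleotide: two sites
  s46 <- readStructure(toyPath(rep("A", 11),
                               c(rep(2.8, 4), 9, rep(2.8, 6))))
  sites46 <- callBindingSites(findContacts(s46), s46)
  expect_equal(nrow(sites46), 2L)
  expect_equal(sites46$start, c(1L, 6L))
  expect_equal(sites46$end, c(4L, 11L))

  # vdW-only contacts support a site
  sv <- readStructure(toyPath(c("G", "G", "U", "U"), 3.5, kind = "carbon"))
  expect_equal(callBindingSites(findContacts(sv), sv)$motif, "GGUU")
})

test_that("site calling is independent of contact order", {
  s <- readStructure(toyPath(rep("C", 9), c(rep(2.8, 4), 9, rep(2.8, 4))))
  ct <- findContacts(s)
  a <- callBindingSites(ct, s)
  b <- callBindingSites(ct[sample(nrow(ct)), ], s)
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("ungapped alignment finds the minimal-mismatch offset", {
  expect_equal(ungappedMismatches("ACGU", "ACGU"),
               list(offset = 0, mismatches = 0))
  expect_equal(ungappedMismatches("ACGU", "ACGA")$mismatches, 1)
  expect_equal(ungappedMismatches("ACGU", "UACGU"),
               list(offset = 1, mismatches = 0))
  # IUPAC letters mismatch only when member sets are disjoint
  expect_equal(ungappedMismatches("ACGU", "RCGU")$mismatches, 0)
  expect_equal(ungappedMismatches("ACGU", "YCGU")$mismatches, 1)
  # ties resolve to the smallest offset
  expect_equal(ungappedMismatches("AAAA", "AAAAAA")$offset, 0)
  expect_error(ungappedMismatches("ACG", "ACGU"), "at least 4")
})

test_that("mismatch counts are symmetric and match brute force", {
  set.seed(77)
  for (i in 1:50) {
    a <- randomMotif(sample(4:9, 1))
    b <- randomMotif(sample(4:9, 1))
    got <- ungappedMismatches(a, b)
    expect_identical(got$mismatches, ungappedMismatches(b, a)$mismatches)
    # brute force over all offsets of the shorter along the longer
    sh <- if (nchar(a) <= nchar(b)) a else b
    lo <- if (nchar(a) <= nchar(b)) b else a
    best <- min(vapply(0:(nchar(lo) - nchar(sh)), function(off) {
      sum(vapply(seq_len(nchar(sh)), function(i)
        substr(sh, i, i) != substr(lo, i + off, i + off), logical(1)))
    }, numeric(1)))
    expect_equal(got$mismatches, best)
  }
})

test_that("extracted motifs classify into the mismatch bins", {
  ref <- c("ACGUA", "GGGGG")
  got <- validateMotifs(c("ACGUA", "ACGUC", "ACAUC", "UUUUU"), ref)
  expect_equal(got$class, c("0", "1", "2", ">2"))
  expect_equal(got$best_reference[1], "ACGUA")
})
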