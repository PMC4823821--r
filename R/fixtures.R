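# Deterministic synthetic-data generators. Every generator is a pure
# function of its arguments (including the seed): the Mersenne-Twister
# stream is local to the call, so outputs are byte-identical across runs
# and platforms and the caller's RNG state is untouched.

withLocalSeed <- function(seed, expr) {
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hasSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hasSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' Generate a random FASTA set with planted motifs
#'
#' Draws uniform random background sequences and overwrites them with the
#' requested motifs at non-overlapping random positions, recording every
#' planted position in a truth table. The scanner must recover at least the
#' truth offsets; chance matches in the random background are possible and
#' verifiable with a naive search.
#'
#' @param seed Integer seed; the same spec yields byte-identical output.
#' @param nSeq Number of sequences (default 3).
#' @param seqLen Length of each sequence in nt (default 200).
#' @param motifs Character vector of concrete motifs to plant (lengths
#'   4-12).
#' @param copies Integer vector, copies of each motif per sequence
#'   (recycled; default 1).
#' @param alphabet Background alphabet (default `A,C,G,U`); restrict it to
#'   make chance matches impossible.
#' @return A list with `sequences` (named character vector) and `truth`
#'   (`data.frame` with `sequence`, `offset`, `motif`).
#' @export
genPlantedFasta <- function(seed, nSeq = 3L, seqLen = 200L,
                            motifs = character(), copies = 1L,
                            alphabet = RNA_BASES) {
  motifs <- normalizeNucleotides(motifs)
  if (length(motifs)) {
    lens <- nchar(motifs)
    if (any(lens < 4L | lens > 12L)) stop("planted motifs must be 4-12 nt")
    if (any(lens > seqLen)) stop("planted motif longer than the sequence")
    if (any(grepl("[^ACGU]", motifs))) stop("planted motifs must be concrete")
  }
  copies <- rep_len(as.integer(copies), max(1L, length(motifs)))
  withLocalSeed(seed, {
    seqs <- character(nSeq)
    truth <- list()
    for (s in seq_len(nSeq)) {
      chars <- sample(alphabet, seqLen, replace = TRUE)
      taken <- logical(seqLen)
      for (mi in seq_along(motifs)) {
        m <- strsplit(motifs[mi], "", fixed = TRUE)[[1L]]
        lm <- length(m)
        for (cp in seq_len(copies[mi])) {
          free <- which(vapply(seq_len(seqLen - lm + 1L), function(p) {
            !any(taken[p:(p + lm - 1L)])
          }, logical(1L)))
          if (!length(free)) {
            stop("no room left to plant ", motifs[mi], " in sequence ", s)
          }
          p <- if (length(free) == 1L) free else sample(free, 1L)
          chars[p:(p + lm - 1L)] <- m
          taken[p:(p + lm - 1L)] <- TRUE
          truth[[length(truth) + 1L]] <- data.frame(
            sequence = paste0("seq", s), offset = p, motif = motifs[mi],
            stringsAsFactors = FALSE)
        }
      }
      seqs[s] <- paste(chars, collapse = "")
    }
    truth <- if (length(truth)) {
      tr <- do.call(rbind, truth)
      tr <- tr[order(tr$sequence, tr$offset), , drop = FALSE]
      rownames(tr) <- NULL
      tr
    } else {
      data.frame(sequence = character(), offset = integer(),
                 motif = character(), stringsAsFactors = FALSE)
    }
    list(sequences = stats::setNames(seqs, paste0("seq", seq_len(nSeq))),
         truth = truth)
  })
}

#' Generate a scan/background sequence pair with an exact enrichment ratio
#'
#' Builds two single-sequence sets in which a motif occurs with exactly
#' known densities: `tScan` occurrences among `scanPositions` possible
#' placements in the scan sequence, and `cContext` among `contextPositions`
#' in the background. Occurrence counts are exact by construction: copies of
#' the motif are separated by a filler nucleotide that does not occur in the
#' motif, so no spurious matches can arise, and the generator re-verifies
#' the counts by direct string search. The implied log2 odds ratio is
#' `log2((tScan / scanPositions) / (cContext / contextPositions))`.
#'
#' @param seed Integer seed (fixes the placement pattern).
#' @param motif Concrete motif using at most three distinct nucleotides (one
#'   letter must remain free for the filler).
#' @param tScan Planted occurrences in the scan sequence (>= 1).
#' @param scanPositions Number of possible placements in the scan sequence.
#' @param cContext Planted occurrences in the context sequence (>= 0).
#' @param contextPositions Number of possible placements in the context
#'   sequence.
#' @return A list with `scan`, `context` (named character vectors),
#'   `truth` (list with `t`, `c`, `scanPositions`, `contextPositions`,
#'   `or`).
#' @examples
#' fx <- genBackgroundPair(1, "AGGUA", tScan = 10, scanPositions = 100,
#'                         cContext = 10, contextPositions = 1000)
#' fx$truth$or  # log2(10)
#' @export
genBackgroundPair <- function(seed, motif, tScan, scanPositions,
                              cContext, contextPositions) {
  motif <- normalizeNucleotides(motif)
  lm <- nchar(motif)
  if (lm < 4L || lm > 12L) stop("motif must be 4-12 nt")
  used <- unique(strsplit(motif, "", fixed = TRUE)[[1L]])
  filler <- setdiff(RNA_BASES, used)
  if (!length(filler)) {
    stop("motif uses all four nucleotides; no filler letter is available")
  }
  filler <- filler[1L]
  buildSeq <- function(nCopies, nPositions) {
    len <- nPositions + lm - 1L
    if (nCopies * (lm + 1L) - 1L > len && nCopies > 0L) {
      stop("infeasible density: ", nCopies, " copies of a ", lm,
           "-nt motif do not fit in ", len, " nt with separators")
    }
    # place copies into slots of (motif + separator), padding with filler
    chars <- rep(filler, len)
    if (nCopies > 0L) {
      # deterministic even placement, then jitter by the seeded stream
      gaps <- len - nCopies * lm
      span <- gaps - nCopies + 1L  # slack beyond one separator per copy
      cuts <- if (span >= 1L) {
        sort(sample.int(span, nCopies, replace = TRUE) - 1L)
      } else rep(0L, nCopies)
      pos <- cuts + (seq_len(nCopies) - 1L) * (lm + 1L) + 1L
      for (p in pos) chars[p:(p + lm - 1L)] <- strsplit(motif, "",
                                                        fixed = TRUE)[[1L]]
    }
    paste(chars, collapse = "")
  }
  withLocalSeed(seed, {
    scanSeq <- buildSeq(as.integer(tScan), as.integer(scanPositions))
    ctxSeq <- buildSeq(as.integer(cContext), as.integer(contextPositions))
    countIn <- function(s) {
      # overlapping occurrences by direct window comparison
      lm <- nchar(motif)
      n <- nchar(s)
      if (n < lm) return(0L)
      sum(vapply(seq_len(n - lm + 1L),
                 function(p) substr(s, p, p + lm - 1L) == motif,
                 logical(1L)))
    }
    stopifnot(countIn(scanSeq) == tScan, countIn(ctxSeq) == cContext)
    or <- if (cContext > 0) {
      log2((tScan / scanPositions) / (cContext / contextPositions))
    } else NA_real_
    list(scan = c(scan = scanSeq), context = c(context = ctxSeq),
         truth = list(t = as.integer(tScan), c = as.integer(cContext),
                      scanPositions = as.integer(scanPositions),
                      contextPositions = as.integer(contextPositions),
                      or = or))
  })
}

# one PDB ATOM line
pdbAtomLine <- function(serial, name, resName, chain, resSeq, x, y, z,
                        element) {
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, resName, chain, resSeq, x, y, z, 1.00, 0.00, element)
}

#' Generate a toy protein-RNA complex in PDB format
#'
#' Writes a minimal coordinate file — EXPDTA, REMARK 2 resolution, ATOM and
#' TER records — containing a glycine protein chain A and an RNA chain B
#' whose residues sit at requested nearest-atom distances from the protein,
#' exercising the contact-detection and binding-site rules with exactly
#' known geometry. Residue `i` gets a protein atom at `(10 i, 0, 0)` and an
#' RNA atom at `(10 i, 0, d_i)`, so its nearest-atom distance is exactly
#' `d_i` and cross-residue pairs are at least 10 Angstrom apart.
#'
#' @param nucleotides The RNA chain 5' to 3': a character vector of single
#'   letters A/C/G/U, or one string to split.
#' @param distances Numeric vector of per-nucleotide nearest-atom distances
#'   in Angstrom (recycled); each must be >= 1 (closer atoms would clash).
#' @param kind `"polar"` places N (protein) / O2' (RNA) atom pairs, so the
#'   distance drives both the hydrogen-bond and the van der Waals test;
#'   `"carbon"` places CA / C4' pairs, so only the van der Waals test can
#'   fire.
#' @param method Experimental method for EXPDTA (default `"X-RAY
#'   DIFFRACTION"`).
#' @param resolution Resolution written to REMARK 2 (default 2.0; `NA`
#'   omits the record).
#' @param path Optional output path; when given the lines are written there.
#' @return Invisibly, a list with `lines` (the PDB text), `path` (or
#'   `NULL`), and `truth` (`data.frame` with `resno`, `nucleotide`,
#'   `distance`).
#' @export
genToyStructure <- function(nucleotides, distances, kind = c("polar", "carbon"),
                            method = "X-RAY DIFFRACTION", resolution = 2.0,
                            path = NULL) {
  kind <- match.arg(kind)
  nucleotides <- normalizeNucleotides(nucleotides)
  if (length(nucleotides) == 1L && nchar(nucleotides) > 1L) {
    nucleotides <- strsplit(nucleotides, "", fixed = TRUE)[[1L]]
  }
  if (!all(nucleotides %in% RNA_BASES)) {
    stop("nucleotides must be letters A/C/G/U")
  }
  n <- length(nucleotides)
  distances <- rep_len(as.numeric(distances), n)
  if (any(distances < 1)) {
    stop("planted distances below 1 Angstrom would overlap atoms")
  }
  protName <- if (kind == "polar") "N" else "CA"
  protElem <- if (kind == "polar") "N" else "C"
  rnaName <- if (kind == "polar") "O2'" else "C4'"
  rnaElem <- if (kind == "polar") "O" else "C"
  lines <- c(sprintf("EXPDTA    %s", method))
  if (!is.na(resolution)) {
    lines <- c(lines, sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.",
                              resolution))
  }
  serial <- 0L
  protLines <- character(0L)
  rnaLines <- character(0L)
  for (i in seq_len(n)) {
    xi <- 10 * i
    serial <- serial + 1L
    protLines <- c(protLines, pdbAtomLine(serial, protName, "GLY", "A", i,
                                          xi, 0, 0, protElem))
    # a second, remote carbon keeps the glycine residue multi-atom without
    # affecting any distance test
    serial <- serial + 1L
    protLines <- c(protLines, pdbAtomLine(serial, "C", "GLY", "A", i,
                                          xi, 100, 0, "C"))
  }
  for (i in seq_len(n)) {
    serial <- serial + 1L
    rnaLines <- c(rnaLines, pdbAtomLine(serial, rnaName, nucleotides[i],
                                        "B", i, 10 * i, 0, distances[i],
                                        rnaElem))
  }
  lines <- c(lines, protLines, "TER", rnaLines, "TER", "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(list(lines = lines, path = path,
                 truth = data.frame(resno = seq_len(n),
                                    nucleotide = nucleotides,
                                    distance = distances,
                                    stringsAsFactors = FALSE)))
}
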