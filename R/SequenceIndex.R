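# FM-index over a set of named nucleotide sequences.
#
# The sequences are concatenated with a sentinel after each one; the suffix
# array is built by prefix doubling (O(n log n) vectorised passes, ample at
# the 20 kb scan cap), and backward search over the BWT with full occurrence
# checkpoints answers count/locate queries. Each sentinel gets its own code,
# smaller than every nucleotide code and ordered by position: that keeps the
# BWT invertible for multi-sequence texts and guarantees matches cannot
# cross sequence boundaries (no pattern character ever equals a sentinel).
#
# Codes: sentinel after sequence j -> j (j = 1..k); letter -> k + rank in
# INDEX_LETTERS.

INDEX_LETTERS <- c("A", "C", "G", "N", "U")

#' SequenceIndex: BWT/FM-index over named nucleotide sequences
#'
#' Supports exact `count`/`locate` of patterns over `{A, C, G, U}` against a
#' set of named sequences (a FASTA or multi-FASTA input). Matching is
#' perfect-match only: `N` in the indexed text matches nothing, and a pattern
#' containing `N` (or any ambiguity code) has no hits — expand ambiguous
#' motifs with [iupacExpand()] first.
#'
#' @slot seqnames Sequence names, unique, in input order.
#' @slot seqlengths Integer lengths of the sequences.
#' @slot starts 1-based start offset of each sequence in the concatenated
#'   text (sentinels included).
#' @slot codes Integer encoding of the concatenated text (with sentinels).
#' @slot sa Suffix array of the concatenated text.
#' @slot bwt Integer-coded Burrows-Wheeler transform.
#' @slot occ Occurrence-count table for the nucleotide letters:
#'   `occ[i + 1, r]` is the number of occurrences of letter rank `r` in
#'   `bwt[1..i]`.
#' @slot ctab For each letter rank, the number of smaller-coded characters
#'   in the text (the `C` table of backward search; all sentinels sort below
#'   every letter).
#' @export
setClass("SequenceIndex",
         representation(seqnames = "character", seqlengths = "integer",
                        starts = "integer", codes = "integer",
                        sa = "integer", bwt = "integer", occ = "matrix",
                        ctab = "integer"))

setMethod("show", "SequenceIndex", function(object) {
  cat("SequenceIndex over", length(object@seqnames), "sequence(s),",
      sum(object@seqlengths), "nt total\n")
  invisible(object)
})

#' @describeIn SequenceIndex-class number of indexed sequences
#' @param x A `SequenceIndex`.
#' @export
setMethod("length", "SequenceIndex", function(x) length(x@seqnames))

# prefix-doubling suffix array; codes is a positive integer vector
suffixArray <- function(codes) {
  n <- length(codes)
  if (n == 1L) return(1L)
  rk <- match(codes, sort(unique(codes)))
  k <- 1L
  repeat {
    rk2 <- if (k < n) c(rk[(k + 1L):n], integer(k)) else integer(n)
    o <- order(rk, rk2, method = "radix")
    newrk <- integer(n)
    changed <- c(TRUE, rk[o[-1L]] != rk[o[-n]] | rk2[o[-1L]] != rk2[o[-n]])
    newrk[o] <- cumsum(changed)
    rk <- newrk
    if (rk[o[n]] == n) return(o)
    k <- k * 2L
  }
}

# normalize raw sequence input (character vector, XStringSet, or list) to a
# named character vector over A/C/G/U/N
asSequenceSet <- function(seqs) {
  if (methods::is(seqs, "XStringSet")) {
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  }
  seqs <- unlist(seqs)
  if (!length(seqs)) stop("empty sequence set")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    names(seqs) <- paste0("seq", seq_along(seqs))
  }
  if (anyDuplicated(names(seqs))) stop("sequence names must be unique")
  seqs <- normalizeNucleotides(seqs)
  bad <- grepl("[^ACGUN]", seqs)
  if (any(bad)) {
    stop("sequence(s) contain characters outside {A,C,G,U,T,N}: ",
         paste(names(seqs)[bad], collapse = ", "))
  }
  seqs
}

#' Read scan-target sequences from a FASTA/multi-FASTA file
#'
#' Sequences are normalized to the RNA alphabet (uppercase, `T` to `U`), so
#' DNA and RNA inputs scan identically.
#'
#' @param path Path to a FASTA or multi-FASTA file.
#' @return Named character vector of sequences over `{A, C, G, U, N}`.
#' @export
readScanFasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(x))
  asSequenceSet(stats::setNames(as.character(x), nm))
}

#' Write a named sequence set to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeScanFasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Build an FM-index over a sequence set
#'
#' @param seqs Named character vector (or `XStringSet`) of nucleotide
#'   sequences; normalized to uppercase RNA.
#' @param cap Maximum total input size in nucleotides (default 20000, the
#'   scan-input limit); exceeding it is an error. Use `Inf` for large
#'   background sets.
#' @return A [SequenceIndex-class].
#' @examples
#' idx <- buildIndex(c(chr = "ACGUACGU"))
#' locateMotif(idx, "ACGU")
#' @export
buildIndex <- function(seqs, cap = 20000L) {
  seqs <- asSequenceSet(seqs)
  total <- sum(nchar(seqs))
  if (total > cap) {
    stop("total input length ", total, " nt exceeds the ", cap,
         "-nt scan input limit")
  }
  if (any(nchar(seqs) == 0L)) stop("empty sequences are not indexable")
  k <- length(seqs)
  text <- paste0(seqs, "$", collapse = "")
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  codes <- match(chars, INDEX_LETTERS) + k
  codes[chars == "$"] <- seq_len(k)
  sa <- suffixArray(codes)
  n <- length(codes)
  bwt <- codes[ifelse(sa == 1L, n, sa - 1L)]
  nl <- length(INDEX_LETTERS)
  occ <- matrix(0L, nrow = n + 1L, ncol = nl)
  for (r in seq_len(nl)) occ[, r] <- c(0L, cumsum(bwt == k + r))
  letterCounts <- tabulate(codes - k, nbins = nl)
  ctab <- k + c(0L, cumsum(letterCounts))[seq_len(nl)]
  lens <- nchar(seqs)
  starts <- c(1L, cumsum(lens + 1L)[-length(lens)] + 1L)
  new("SequenceIndex", seqnames = names(seqs),
      seqlengths = as.integer(lens), starts = as.integer(starts),
      codes = as.integer(codes), sa = as.integer(sa),
      bwt = as.integer(bwt), occ = occ, ctab = as.integer(ctab))
}

# reconstruct the concatenated text (sentinels included) from the BWT via
# repeated LF-mapping; used to verify index integrity. A sentinel code j
# occurs once in the BWT and LF-maps to row j (sentinels are the j smallest
# characters in positional order); letters LF-map through ctab/occ.
inverseBWT <- function(index) {
  bwt <- index@bwt
  n <- length(bwt)
  k <- length(index@seqnames)
  lf <- integer(n)
  isSent <- bwt <= k
  lf[isSent] <- bwt[isSent]
  r <- bwt[!isSent] - k
  lf[!isSent] <- index@ctab[r] +
    index@occ[cbind(which(!isSent) + 1L, r)]
  out <- integer(n)
  # walk the text backwards: the row holding the whole text as its suffix is
  # preceded by the final character, and LF-mapping steps one position left
  row <- which(index@sa == 1L)
  for (i in n:1L) {
    out[i] <- bwt[row]
    row <- lf[row]
  }
  paste(c(rep("$", k), INDEX_LETTERS)[out], collapse = "")
}

# backward search over letter ranks: returns c(sp, ep) row range in the
# suffix array, or NULL when the pattern is absent
backwardSearch <- function(index, ranks) {
  ctab <- index@ctab
  occ <- index@occ
  n <- length(index@bwt)
  letterCounts <- occ[n + 1L, ]
  l <- length(ranks)
  r0 <- ranks[l]
  sp <- ctab[r0] + 1L
  ep <- ctab[r0] + letterCounts[r0]
  if (sp > ep) return(NULL)
  if (l > 1L) {
    for (i in (l - 1L):1L) {
      r <- ranks[i]
      sp <- ctab[r] + occ[sp, r] + 1L
      ep <- ctab[r] + occ[ep + 1L, r]
      if (sp > ep) return(NULL)
    }
  }
  c(sp, ep)
}

#' Locate exact occurrences of a concrete motif
#'
#' Reports every perfect-match position of the motif in the indexed
#' sequences, overlapping occurrences included. A pattern containing `N` or
#' an ambiguity code yields no hits.
#'
#' @param index A [SequenceIndex-class].
#' @param motif Single concrete motif string over `{A, C, G, U}` (`T`
#'   accepted).
#' @return A `data.frame` with columns `sequence` and `offset` (1-based
#'   start position, the first nucleotide being position 1), sorted by input
#'   sequence order then offset; zero rows if the motif is absent.
#' @export
locateMotif <- function(index, motif) {
  stopifnot(is(index, "SequenceIndex"))
  motif <- normalizeNucleotides(motif)
  p <- strsplit(motif, "", fixed = TRUE)[[1L]]
  if (!length(p)) stop("empty pattern")
  ranks <- match(p, INDEX_LETTERS)
  empty <- data.frame(sequence = character(), offset = integer(),
                      stringsAsFactors = FALSE)
  # exact matching over concrete letters only: N (and anything else) in the
  # pattern can never match
  if (anyNA(ranks) || any(p == "N")) return(empty)
  range <- backwardSearch(index, ranks)
  if (is.null(range)) return(empty)
  pos <- index@sa[range[1L]:range[2L]]
  seqIdx <- findInterval(pos, index@starts)
  offset <- pos - index@starts[seqIdx] + 1L
  # drop any placement that would overrun its sequence into the sentinel
  # (cannot happen for sentinel-free patterns, kept as a guard)
  keep <- offset + length(p) - 1L <= index@seqlengths[seqIdx]
  out <- data.frame(sequence = index@seqnames[seqIdx[keep]],
                    offset = as.integer(offset[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$sequence, index@seqnames), out$offset), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count exact occurrences of a concrete motif
#'
#' @param index A [SequenceIndex-class].
#' @param motif Single concrete motif string.
#' @return Integer total count across all indexed sequences (overlapping
#'   occurrences included).
#' @export
countMotif <- function(index, motif) {
  nrow(locateMotif(index, motif))
}

#' Scan sequences for motif-record matches
#'
#' Builds an FM-index over the input sequences, optionally filters the motif
#' records by organism and motif length, expands each surviving IUPAC motif
#' into its concrete sequences and locates every expansion. Records with
#' motif lengths outside 4-12 are skipped with a warning. Each hit carries
#' the record's provenance and the multiplicity `t`: how often that record's
#' motif (any expansion) occurs in that sequence, overlapping occurrences
#' counted.
#'
#' @param seqs Named character vector (or `XStringSet`) of scan targets, or
#'   a [SequenceIndex-class] built from them.
#' @param motifTable A [MotifTable-class] of (normalized) records.
#' @param organism Optional organism filter (exact match).
#' @param minLen,maxLen Optional inclusive motif-length bounds.
#' @param cap Total input size cap in nucleotides (default 20000).
#' @param expansionCap Per-motif IUPAC expansion cap (default 4096).
#' @return A `data.frame` with columns `sequence`, `offset`, `motif` (the
#'   record's motif as stored), `matched` (the concrete sequence at the hit),
#'   `gene_name`, `organism`, `experiment`, `t`, sorted by sequence order
#'   and offset.
#' @export
scanMotifs <- function(seqs, motifTable, organism = NULL, minLen = NULL,
                       maxLen = NULL, cap = 20000L, expansionCap = 4096L) {
  stopifnot(is(motifTable, "MotifTable"))
  index <- if (is(seqs, "SequenceIndex")) seqs else buildIndex(seqs, cap = cap)
  if (!is.null(minLen) && !is.null(maxLen) && minLen > maxLen) {
    stop("malformed length bounds: minLen exceeds maxLen")
  }
  df <- records(motifTable)
  # filter on the raw frame (not through subsetting) so malformed records
  # can still be reached and skipped with a warning below
  keep <- rep(TRUE, nrow(df))
  if (!is.null(organism)) keep <- keep & df$organism %in% organism
  if (!is.null(minLen)) keep <- keep & df$len >= minLen
  if (!is.null(maxLen)) keep <- keep & df$len <= maxLen
  df <- df[keep, , drop = FALSE]
  cols <- c("sequence", "offset", "motif", "matched", "gene_name",
            "organism", "experiment", "t")
  outRows <- list()
  for (i in seq_len(nrow(df))) {
    l <- df$len[i]
    if (l < 4L || l > 12L) {
      warning("skipping record ", i, " (", df$gene_name[i], "): motif length ",
              l, " outside [4, 12]")
      next
    }
    hits <- lapply(iupacExpand(df$motif[i], cap = expansionCap),
                   function(m) {
                     h <- locateMotif(index, m)
                     if (nrow(h)) h$matched <- m
                     h
                   })
    hits <- do.call(rbind, hits[vapply(hits, nrow, integer(1L)) > 0L])
    if (is.null(hits) || !nrow(hits)) next
    hits$motif <- df$motif[i]
    hits$gene_name <- df$gene_name[i]
    hits$organism <- df$organism[i]
    hits$experiment <- df$experiment[i]
    t_per_seq <- table(hits$sequence)
    hits$t <- as.integer(t_per_seq[hits$sequence])
    outRows[[length(outRows) + 1L]] <- hits[, cols]
  }
  if (!length(outRows)) {
    out <- data.frame(sequence = character(), offset = integer(),
                      motif = character(), matched = character(),
                      gene_name = character(), organism = character(),
                      experiment = character(), t = integer(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, outRows)
  out <- out[order(match(out$sequence, index@seqnames), out$offset,
                   out$gene_name, out$motif, out$matched), , drop = FALSE]
  rownames(out) <- NULL
  out
}
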