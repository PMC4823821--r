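#' PPM: position probability matrix for an RNA motif
#'
#' Per-position nucleotide probabilities over `{A, C, G, U}` describing a
#' binding preference. Curated motifs are 4-12 nt; shorter matrices (down to
#' one position) are permitted so elementary cases remain constructible.
#'
#' @slot probs Numeric matrix, 4 rows named `A`, `C`, `G`, `U`, one column
#'   per motif position; every column sums to 1 within `1e-9` and all
#'   entries are non-negative.
#' @slot matrixId Character identifier linking the matrix to motif records.
#' @export
setClass("PPM", representation(probs = "matrix", matrixId = "character"))

setValidity("PPM", function(object) {
  p <- object@probs
  if (!is.numeric(p)) return("probs must be numeric")
  if (nrow(p) != 4L || !identical(rownames(p), RNA_BASES)) {
    return("probs must have 4 rows named A, C, G, U")
  }
  if (ncol(p) < 1L || ncol(p) > 12L) {
    return("matrix length must be in [1, 12]")
  }
  if (any(p < 0)) return("negative probabilities")
  if (any(abs(colSums(p) - 1) > 1e-9)) {
    return("column sums deviate from 1 by more than 1e-9")
  }
  TRUE
})

setMethod("show", "PPM", function(object) {
  cat("PPM", if (nzchar(object@matrixId)) object@matrixId else "<unnamed>",
      "| length", ncol(object@probs), "\n")
  print(round(object@probs, 4L))
  invisible(object)
})

#' @describeIn PPM-class motif length (number of positions)
#' @param x A `PPM`.
#' @export
setMethod("length", "PPM", function(x) ncol(x@probs))

#' Probability matrix of a PPM
#'
#' @param x A [PPM-class].
#' @return The 4 x length numeric matrix (rows `A`, `C`, `G`, `U`).
#' @export
probMatrix <- function(x) {
  stopifnot(is(x, "PPM"))
  x@probs
}

#' Matrix identifier of a PPM
#'
#' @param x A [PPM-class].
#' @return Character scalar.
#' @export
matrixId <- function(x) {
  stopifnot(is(x, "PPM"))
  x@matrixId
}

#' Build a PPM from aligned winner sequences
#'
#' Winner sequences are the selection-experiment (e.g. SELEX) sequences with
#' the strongest binding preference; aligned to equal length, their
#' per-position empirical nucleotide frequencies define the PPM. No
#' pseudocounts are added: the matrix is the pure observed frequency table,
#' so a single winner sequence yields a deterministic 0/1 matrix.
#'
#' @param winners Character vector of one or more equal-length sequences
#'   over the concrete alphabet (`T` accepted and unified to `U`); IUPAC
#'   ambiguity codes are not allowed in winners.
#' @param matrixId Identifier stored on the matrix (default `""`).
#' @return A [PPM-class] of the common winner length.
#' @examples
#' ppmFromWinners(c("ACGU", "ACGA"))
#' @export
ppmFromWinners <- function(winners, matrixId = "") {
  if (length(winners) < 1L) stop("at least one winner sequence is required")
  winners <- normalizeNucleotides(winners)
  lens <- nchar(winners)
  if (length(unique(lens)) != 1L) {
    stop("winner sequences must be pre-aligned to equal length; got lengths ",
         paste(sort(unique(lens)), collapse = ", "))
  }
  l <- lens[1L]
  if (l < 1L || l > 12L) stop("winner length ", l, " outside [1, 12]")
  chars <- matrix(unlist(strsplit(winners, "", fixed = TRUE)),
                  nrow = length(winners), byrow = TRUE)
  if (!all(chars %in% RNA_BASES)) {
    stop("winner sequences must be concrete (A/C/G/U only); ",
         "ambiguity codes are not allowed")
  }
  probs <- vapply(seq_len(l), function(i) {
    tab <- table(factor(chars[, i], levels = RNA_BASES))
    as.numeric(tab) / length(winners)
  }, numeric(4L))
  probs <- matrix(probs, nrow = 4L, dimnames = list(RNA_BASES, NULL))
  new("PPM", probs = probs, matrixId = as.character(matrixId))
}

#' Build a PPM from an IUPAC consensus motif
#'
#' When winner sequences are not annotated, the matrix is generated from the
#' IUPAC consensus directly, treating the nucleotides encoded by an ambiguity
#' letter as equally likely: `R` gives `A = G = 0.5`, `N` gives `0.25` each.
#'
#' @param motif Single IUPAC motif string.
#' @param matrixId Identifier stored on the matrix (default `""`).
#' @return A [PPM-class] of the motif's length.
#' @examples
#' probMatrix(ppmFromIupac("ACGR"))
#' @export
ppmFromIupac <- function(motif, matrixId = "") {
  motif <- normalizeNucleotides(motif)
  letters <- strsplit(motif, "", fixed = TRUE)[[1L]]
  if (length(letters) < 1L || length(letters) > 12L) {
    stop("motif length ", length(letters), " outside [1, 12]")
  }
  members <- iupacMembers(letters)
  probs <- vapply(members, function(mem) {
    col <- stats::setNames(numeric(4L), RNA_BASES)
    col[mem] <- 1 / length(mem)
    col
  }, numeric(4L))
  probs <- matrix(probs, nrow = 4L, dimnames = list(RNA_BASES, NULL))
  new("PPM", probs = probs, matrixId = as.character(matrixId))
}

#' Quality score of a motif under a PPM
#'
#' The quality score estimates the binding affinity a motif represents within
#' its experiment: the probability of observing the motif under its PPM,
#' computed as the product over positions of the column probability of the
#' motif letter. Motifs from single-sequence experiments (EMSA, UV
#' cross-linking) therefore score exactly 1. For an IUPAC ambiguity letter
#' the column probability is the summed probability of its member
#' nucleotides, so an IUPAC-derived PPM scores its own consensus as 1.
#'
#' @param motif Single IUPAC motif string of the same length as `ppm`.
#' @param ppm A [PPM-class].
#' @return A number in `[0, 1]`.
#' @examples
#' qualityScore("ACGA", ppmFromWinners(c("ACGU", "ACGA")))  # 0.5
#' @export
qualityScore <- function(motif, ppm) {
  stopifnot(is(ppm, "PPM"))
  motif <- normalizeNucleotides(motif)
  letters <- strsplit(motif, "", fixed = TRUE)[[1L]]
  if (length(letters) != ncol(ppm@probs)) {
    stop("motif length (", length(letters),
         ") does not match PPM length (", ncol(ppm@probs), ")")
  }
  members <- iupacMembers(letters)
  p <- vapply(seq_along(members),
              function(i) sum(ppm@probs[members[[i]], i]),
              numeric(1L))
  prod(p)
}

#' Write PPMs to a text file
#'
#' One block per matrix: a `>matrix_id` header line followed by one row per
#' position with four tab-separated probabilities in `A`, `C`, `G`, `U`
#' order.
#'
#' @param ppms A [PPM-class] or list of them.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writePPM <- function(ppms, path) {
  if (is(ppms, "PPM")) ppms <- list(ppms)
  lines <- unlist(lapply(ppms, function(p) {
    stopifnot(is(p, "PPM"))
    id <- if (nzchar(p@matrixId)) p@matrixId else "matrix"
    body <- apply(p@probs, 2L, function(col)
      paste(sprintf("%.17g", col), collapse = "\t"))
    c(paste0(">", id), body)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read PPMs from a text file
#'
#' @param path Path to a file written by [writePPM()].
#' @return A named list of [PPM-class] objects (names are matrix ids).
#' @export
readPPM <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no '>matrix_id' header found in ", path)
  bounds <- c(heads, length(lines) + 1L)
  out <- lapply(seq_along(heads), function(k) {
    id <- sub("^>", "", lines[heads[k]])
    body <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    rows <- lapply(strsplit(body, "\t", fixed = TRUE), as.numeric)
    probs <- t(do.call(rbind, rows))
    rownames(probs) <- RNA_BASES
    new("PPM", probs = probs, matrixId = id)
  })
  stats::setNames(out, vapply(out, function(p) p@matrixId, character(1L)))
}
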