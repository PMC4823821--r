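#' IUPAC nucleotide ambiguity codes (RNA alphabet)
#'
#' Named list mapping each of the 15 IUPAC nucleotide codes to the set of
#' concrete RNA nucleotides it denotes. Concrete letters map to singleton
#' sets; `N` maps to all four.
#'
#' @format Named list of character vectors over `{A, C, G, U}`.
#' @export
IUPAC_RNA <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"),
  H = c("A", "C", "U"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "U")
)

RNA_BASES <- c("A", "C", "G", "U")

#' Normalize a nucleotide string to the uppercase RNA alphabet
#'
#' Uppercases and converts thymine to uracil, so DNA- and RNA-alphabet inputs
#' are matched on a single alphabet.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of the same length, uppercase with `T` replaced
#'   by `U`.
#' @examples
#' normalizeNucleotides("acgt")  # "ACGU"
#' @export
normalizeNucleotides <- function(x) {
  chartr("T", "U", toupper(x))
}

#' Member nucleotides of IUPAC letters
#'
#' @param letters Character vector of single IUPAC letters.
#' @return List of character vectors, the concrete nucleotides each letter
#'   denotes.
#' @keywords internal
iupacMembers <- function(letters) {
  out <- IUPAC_RNA[letters]
  bad <- vapply(out, is.null, logical(1L))
  if (any(bad)) {
    stop("invalid IUPAC letter(s) at position(s) ",
         paste(which(bad), collapse = ", "), ": ",
         paste(letters[bad], collapse = ", "))
  }
  out
}

#' Validate a motif string against the IUPAC alphabet
#'
#' @param motif Single nucleotide string (already normalized).
#' @param lengthRange Permitted length range, default the 4-12 nt range of
#'   curated RBP motifs; use `c(1, Inf)` to disable.
#' @return Invisibly `TRUE`; errors otherwise.
#' @keywords internal
checkMotif <- function(motif, lengthRange = c(4L, 12L)) {
  stopifnot(is.character(motif), length(motif) == 1L, !is.na(motif))
  l <- nchar(motif)
  if (l < lengthRange[1L] || l > lengthRange[2L]) {
    stop("motif length ", l, " outside [", lengthRange[1L], ", ",
         lengthRange[2L], "]: ", motif)
  }
  iupacMembers(strsplit(motif, "", fixed = TRUE)[[1L]])
  invisible(TRUE)
}

#' Expand an IUPAC motif into its concrete sequences
#'
#' Cartesian expansion of the per-position member sets: `"RCG"` expands to
#' `"ACG"` and `"GCG"`; a concrete motif expands to itself.
#'
#' @param motif Single IUPAC motif string (`T` is accepted and unified to
#'   `U` first).
#' @param cap Maximum number of expansions permitted (default 4096); a motif
#'   expanding beyond the cap is an error, which keeps highly degenerate
#'   motifs from exploding a scan.
#' @return Character vector of concrete strings over `{A, C, G, U}`, in
#'   lexicographic position order; length equals the product of the member
#'   set sizes.
#' @examples
#' iupacExpand("ACGU")
#' iupacExpand("RCG")
#' length(iupacExpand("NN"))  # 16
#' @export
iupacExpand <- function(motif, cap = 4096L) {
  motif <- normalizeNucleotides(motif)
  members <- iupacMembers(strsplit(motif, "", fixed = TRUE)[[1L]])
  sz <- prod(vapply(members, length, integer(1L)))
  if (sz > cap) {
    stop("motif ", motif, " expands to ", sz,
         " concrete sequences, above the cap of ", cap)
  }
  if (length(members) == 0L) return(character(0L))
  grid <- expand.grid(rev(members), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  sort(do.call(paste0, rev(grid)))
}
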