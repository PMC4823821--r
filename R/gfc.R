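GFC_CONTEXTS <- c("exon250", "intron", "cds")

#' GFCBackground: genomic-functional-context motif background
#'
#' Per-motif occurrence counts over one background sequence set — one of the
#' three genomic functional contexts (all exons with 250 nt flanks, all
#' introns, or all coding sequences) of a reference organism — together with
#' the effective number of motif placements per motif length,
#' `D_l = sum_i max(0, len(s_i) - l_m + 1)`. These are the denominator data
#' of the expected motif frequency.
#'
#' @slot context One of `"exon250"`, `"intron"`, `"cds"`.
#' @slot organism Organism the background belongs to.
#' @slot counts `data.frame` with columns `motif` (concrete string) and `c`
#'   (total overlapping occurrences across the background sequences).
#' @slot totals Named numeric vector: effective placement total `D_l` per
#'   motif length (names are the lengths).
#' @slot provenance `data.frame` describing the background sequences
#'   (`sequence`, `length`), so counts are reproducible from the source
#'   FASTA.
#' @export
setClass("GFCBackground",
         representation(context = "character", organism = "character",
                        counts = "data.frame", totals = "numeric",
                        provenance = "data.frame"))

setValidity("GFCBackground", function(object) {
  if (!object@context %in% GFC_CONTEXTS) {
    return(paste("context must be one of:", paste(GFC_CONTEXTS, collapse = ", ")))
  }
  if (any(object@counts$c < 0)) return("negative motif count")
  if (any(object@totals < 0)) return("negative placement total")
  TRUE
})

setMethod("show", "GFCBackground", function(object) {
  cat("GFCBackground:", object@context, "|", object@organism, "|",
      nrow(object@counts), "motif(s) over", nrow(object@provenance),
      "background sequence(s)\n")
  invisible(object)
})

#' Observed motif frequency in a scanned sequence
#'
#' `Obs = t / (l_s - l_m + 1)`: the motif's multiplicity divided by the
#' number of possible start positions in the sequence (overlapping
#' placements counted).
#'
#' @param t Number of occurrences of the motif in the sequence (>= 0).
#' @param l_s Length of the scanned sequence.
#' @param l_m Motif length; must not exceed `l_s`.
#' @return The observed frequency, a number in `[0, 1]` for feasible `t`.
#' @examples
#' observedFrequency(2, 20, 5)  # 0.125
#' @export
observedFrequency <- function(t, l_s, l_m) {
  stopifnot(t >= 0, l_m >= 1)
  if (l_s < l_m) {
    stop("sequence length (", l_s, ") shorter than motif length (", l_m, ")")
  }
  t / (l_s - l_m + 1)
}

#' Build a genomic-functional-context background
#'
#' Counts every motif's overlapping occurrences across the background
#' sequences with the FM-index scanner, and records the effective placement
#' total per motif length.
#'
#' @param seqs Named character vector (or `XStringSet`) of background
#'   sequences, or a path handled by [readScanFasta()] upstream.
#' @param motifs Character vector of concrete motif strings over
#'   `{A, C, G, U}` (expand IUPAC motifs first).
#' @param context One of `"exon250"`, `"intron"`, `"cds"`.
#' @param organism Organism label (default `""`).
#' @return A [GFCBackground-class].
#' @examples
#' bg <- buildBackground(c(bg = "ACGUACGU"), "ACGU", "cds")
#' @export
buildBackground <- function(seqs, motifs, context, organism = "") {
  context <- match.arg(context, GFC_CONTEXTS)
  seqs <- asSequenceSet(seqs)
  motifs <- unique(normalizeNucleotides(motifs))
  if (any(grepl("[^ACGU]", motifs))) {
    stop("background motifs must be concrete (A/C/G/U); expand IUPAC first")
  }
  index <- buildIndex(seqs, cap = Inf)
  counts <- data.frame(
    motif = motifs,
    c = vapply(motifs, function(m) countMotif(index, m), integer(1L)),
    stringsAsFactors = FALSE, row.names = NULL)
  lens <- nchar(seqs)
  lm <- sort(unique(nchar(motifs)))
  totals <- vapply(lm, function(l) sum(pmax(0, lens - l + 1)), numeric(1L))
  names(totals) <- lm
  new("GFCBackground", context = context, organism = as.character(organism),
      counts = counts, totals = totals,
      provenance = data.frame(sequence = names(seqs), length = unname(lens),
                              stringsAsFactors = FALSE))
}

#' Expected motif frequency under a background
#'
#' `Exp = c_m / D_l`: the motif's total occurrence count in the background
#' divided by the total number of possible placements of a motif of that
#' length across the background sequences.
#'
#' @param bg A [GFCBackground-class].
#' @param motif Concrete motif string; must have been counted when the
#'   background was built.
#' @return The expected frequency (0 when the motif is absent from the
#'   background).
#' @export
expectedFrequency <- function(bg, motif) {
  stopifnot(is(bg, "GFCBackground"))
  motif <- normalizeNucleotides(motif)
  i <- match(motif, bg@counts$motif)
  if (is.na(i)) stop("motif ", motif, " was not counted in this background")
  D <- bg@totals[as.character(nchar(motif))]
  if (is.na(D) || D == 0) {
    stop("no effective placements for motif length ", nchar(motif),
         " in this background")
  }
  bg@counts$c[i] / unname(D)
}

#' Log2 odds ratio of observed vs expected motif frequency
#'
#' `OR = log2(Obs / Exp)`. Positive values mean the motif is more likely in
#' the scanned sequence than in the genomic functional context; negative,
#' less likely. When the motif is absent from the background (`Exp = 0`) the
#' ratio is undefined and `NA` is returned as the sentinel.
#'
#' @param obs Observed frequency, must be positive (only found motifs are
#'   scored).
#' @param exp Expected frequency, non-negative.
#' @return `log2(obs / exp)`, or `NA_real_` when `exp` is 0.
#' @examples
#' logOdds(0.2, 0.1)  # 1
#' @export
logOdds <- function(obs, exp) {
  if (any(obs <= 0)) stop("observed frequency must be positive")
  ifelse(exp == 0, NA_real_, log2(obs / exp))
}

#' Score scan hits against the three genomic-functional-context backgrounds
#'
#' Adds to each hit the observed frequency `Obs = t / (l_s - l_m + 1)`
#' (computed with the per-sequence length of the entry the hit occurs in)
#' and one log2 odds-ratio column per context. Hits from organisms without
#' a matching background get `NA` in every context column; a motif absent
#' from one context gets `NA` for that context only.
#'
#' @param hits Scan hits as returned by [scanMotifs()].
#' @param seqs The scanned sequences (named character vector or
#'   `XStringSet`) — needed for the per-sequence lengths.
#' @param backgrounds List of [GFCBackground-class] objects; per organism at
#'   most one per context.
#' @return The hits `data.frame` with added columns `Obs`, `exon250`,
#'   `cds`, `intron`.
#' @export
scoreHits <- function(hits, seqs, backgrounds) {
  if (is(backgrounds, "GFCBackground")) backgrounds <- list(backgrounds)
  stopifnot(all(vapply(backgrounds, is, logical(1L), "GFCBackground")))
  seqs <- asSequenceSet(seqs)
  out <- hits
  lens <- nchar(seqs)
  l_s <- lens[out$sequence]
  l_m <- nchar(out$matched)
  out$Obs <- if (nrow(out)) out$t / (l_s - l_m + 1) else numeric(0L)
  bgOrg <- vapply(backgrounds, function(b) b@organism, character(1L))
  bgCtx <- vapply(backgrounds, function(b) b@context, character(1L))
  for (ctx in GFC_CONTEXTS) {
    out[[ctx]] <- rep(NA_real_, nrow(out))
    for (i in seq_len(nrow(out))) {
      j <- which(bgCtx == ctx & bgOrg == out$organism[i])
      if (length(j) != 1L) next
      expv <- tryCatch(expectedFrequency(backgrounds[[j]], out$matched[i]),
                       error = function(e) NA_real_)
      if (is.na(expv)) next
      out[[ctx]][i] <- logOdds(out$Obs[i], expv)
    }
  }
  out
}

#' Write background tables to TSV
#'
#' Layout: `context organism motif c D`, one row per motif, `D` being the
#' placement total for that motif's length.
#'
#' @param bgs A [GFCBackground-class] or list of them.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeBackground <- function(bgs, path) {
  if (is(bgs, "GFCBackground")) bgs <- list(bgs)
  rows <- lapply(bgs, function(b) {
    data.frame(context = b@context, organism = b@organism,
               motif = b@counts$motif, c = b@counts$c,
               D = unname(b@totals[as.character(nchar(b@counts$motif))]),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read background tables from TSV
#'
#' Reads the layout written by [writeBackground()]. Provenance (the source
#' FASTA digest) is not stored in the TSV and comes back empty.
#'
#' @param path Path to the TSV.
#' @return List of [GFCBackground-class] objects, one per
#'   (context, organism) pair in the file.
#' @export
readBackground <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("context", "organism", "motif", "c", "D")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("background TSV is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  df$organism[is.na(df$organism)] <- ""
  keys <- unique(df[, c("context", "organism")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$context == keys$context[i] & df$organism == keys$organism[i], ]
    totals <- tapply(sub$D, nchar(sub$motif), function(v) unique(v)[1L])
    new("GFCBackground", context = keys$context[i],
        organism = keys$organism[i],
        counts = data.frame(motif = sub$motif, c = as.integer(sub$c),
                            stringsAsFactors = FALSE),
        totals = stats::setNames(as.numeric(totals), names(totals)),
        provenance = data.frame(sequence = character(), length = integer(),
                                stringsAsFactors = FALSE))
  })
}
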