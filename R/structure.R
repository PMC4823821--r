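# Extraction of RNA binding-site motifs from protein-RNA complexes.
#
# Coordinates are parsed with bio3d::read.pdb (first model only, so NMR
# ensembles reduce to model 1). bio3d does not expose the EXPDTA method,
# the REMARK 2 resolution, or TER chain breaks, so those three fields come
# from a light scan of the raw header lines; atoms always come from bio3d.

AMINO_ACIDS <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "MSE", "PHE", "PRO",
                 "SER", "THR", "TRP", "TYR", "VAL")
RNA_RESIDUES <- c("A", "C", "G", "U")

#' Structure: a parsed protein-RNA complex
#'
#' Atomic coordinates and metadata of one coordinate file, reduced to the
#' first model for NMR ensembles. Chains are classified as `protein`
#' (standard amino-acid residues), `rna` (residues named A/C/G/U) or
#' `other`.
#'
#' @slot structureId Identifier (file stem by default).
#' @slot method Experimental method: `"X-ray"`, `"NMR"`, `"EM"` or
#'   `"unknown"`.
#' @slot resolution Resolution in Angstrom, `NA` when absent (e.g. NMR).
#' @slot atoms `data.frame` with columns `chain`, `resno`, `insert`,
#'   `resid`, `elety` (atom name), `elesy` (element), `x`, `y`, `z`,
#'   `segment` (TER-delimited segment index).
#' @slot chains `data.frame` with columns `chain` and `class`.
#' @slot rnaAbsent `TRUE` when the file contains no RNA chain.
#' @export
setClass("Structure",
         representation(structureId = "character", method = "character",
                        resolution = "numeric", atoms = "data.frame",
                        chains = "data.frame", rnaAbsent = "logical"))

setMethod("show", "Structure", function(object) {
  res <- if (is.na(object@resolution)) "n/a"
         else sprintf("%.2f A", object@resolution)
  cat("Structure", object@structureId, "|", object@method,
      "| resolution:", res, "\n")
  cl <- table(object@chains$class)
  cat(" ", nrow(object@atoms), "atoms;",
      paste(names(cl), as.integer(cl), collapse = ", "), "chain(s)",
      if (object@rnaAbsent) "(no RNA)" else "", "\n")
  invisible(object)
})

# classify a residue name
residueClass <- function(resid) {
  ifelse(resid %in% AMINO_ACIDS, "protein",
         ifelse(resid %in% RNA_RESIDUES, "rna", "other"))
}

# EXPDTA line -> method label
parseMethod <- function(lines) {
  exp <- grep("^EXPDTA", lines, value = TRUE)
  if (!length(exp)) return("unknown")
  e <- toupper(exp[1L])
  if (grepl("X-RAY", e)) return("X-ray")
  if (grepl("NMR", e)) return("NMR")
  if (grepl("ELECTRON MICROSCOPY|CRYO-EM", e)) return("EM")
  "unknown"
}

# REMARK 2 resolution line -> numeric Angstrom or NA
parseResolution <- function(lines) {
  rem <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (!length(rem)) return(NA_real_)
  # the line reads e.g. "REMARK   2 RESOLUTION.    2.10 ANGSTROMS."
  m <- regmatches(rem[1L],
                  regexpr("RESOLUTION\\.\\s*([0-9.]+)", rem[1L]))
  if (!length(m)) return(NA_real_)
  val <- suppressWarnings(as.numeric(sub("RESOLUTION\\.\\s*", "", m)))
  if (is.na(val)) NA_real_ else val
}

# per-atom segment index for model 1: increments at TER records
atomSegments <- function(lines) {
  rec <- substring(lines, 1L, 6L)
  model <- cumsum(rec == "MODEL ")
  keep <- model <= 1L  # records before MODEL 2 (single-model files: all)
  rec <- rec[keep]
  isAtom <- rec %in% c("ATOM  ", "HETATM")
  seg <- cumsum(rec == "TER   ") + 1L
  seg[isAtom]
}

#' Parse a protein-RNA complex from a PDB-format file
#'
#' @param path Path to a PDB-format coordinate file.
#' @param structureId Identifier to store; defaults to the file stem.
#' @return A [Structure-class]. Files without an RNA chain parse fine and
#'   are flagged `rnaAbsent`.
#' @export
readStructure <- function(path, structureId = NULL) {
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  if (is.null(structureId)) {
    structureId <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  seg <- atomSegments(lines)
  if (length(seg) != nrow(at)) {
    # alt-loc or other filtering inside bio3d; fall back to one segment
    seg <- rep(1L, nrow(at))
  }
  atoms <- data.frame(chain = at$chain, resno = at$resno,
                      insert = ifelse(is.na(at$insert), "", at$insert),
                      resid = trimws(at$resid), elety = trimws(at$elety),
                      elesy = toupper(trimws(at$elesy)),
                      x = at$x, y = at$y, z = at$z,
                      segment = seg, stringsAsFactors = FALSE)
  if (any(!is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    stop("non-finite coordinates in ", path)
  }
  # infer missing element symbols from the first letter of the atom name
  noEl <- !nzchar(atoms$elesy) | is.na(atoms$elesy)
  atoms$elesy[noEl] <- substring(gsub("[0-9']", "", atoms$elety[noEl]), 1L, 1L)
  perChain <- tapply(atoms$resid, atoms$chain, function(r) {
    cl <- residueClass(r)
    if (any(cl == "protein")) "protein"
    else if (any(cl == "rna")) "rna"
    else "other"
  })
  chains <- data.frame(chain = names(perChain),
                       class = as.character(perChain),
                       stringsAsFactors = FALSE)
  new("Structure", structureId = structureId, method = parseMethod(lines),
      resolution = parseResolution(lines), atoms = atoms, chains = chains,
      rnaAbsent = !any(chains$class == "rna"))
}

#' Is a structure eligible for motif extraction?
#'
#' NMR and electron-microscopy structures are always eligible; X-ray
#' structures require a resolution better than the cutoff (default 3.9
#' Angstrom). An X-ray structure without a resolution record is ineligible,
#' with a warning.
#'
#' @param s A [Structure-class].
#' @param maxResolution Resolution bound in Angstrom for X-ray entries.
#' @return `TRUE` or `FALSE`.
#' @export
isEligible <- function(s, maxResolution = 3.9) {
  stopifnot(is(s, "Structure"))
  if (s@method %in% c("NMR", "EM")) return(TRUE)
  if (s@method == "X-ray") {
    if (is.na(s@resolution)) {
      warning("X-ray structure ", s@structureId,
              " has no resolution record; treated as ineligible")
      return(FALSE)
    }
    return(s@resolution < maxResolution)
  }
  FALSE
}

#' Detect protein-RNA contacts by distance criteria
#'
#' For every RNA nucleotide (residues named A/C/G/U in RNA chains) the
#' minimum distance to the protein atoms is evaluated: a hydrogen-bond
#' contact is called when any polar (N/O) atom of the nucleotide lies within
#' `hbondCutoff` of any polar protein atom, and a van der Waals contact when
#' any atom pair lies within `vdwCutoff`. Cutoffs are inclusive; distances
#' are compared as squares, so a pair planted exactly on the cutoff
#' classifies as a contact.
#'
#' @param s A [Structure-class] with at least one protein and one RNA chain.
#' @param hbondCutoff Polar-atom distance cutoff in Angstrom (default 3.0).
#' @param vdwCutoff Any-atom distance cutoff in Angstrom (default 3.9).
#' @return A `data.frame` with one row per (RNA residue, contact kind):
#'   columns `rna_chain`, `rna_resno`, `nucleotide`, `kind` (`"hbond"` or
#'   `"vdw"`), `min_distance`, `protein_chain`, `protein_resno` (chain and
#'   residue of the closest qualifying protein atom).
#' @export
findContacts <- function(s, hbondCutoff = 3.0, vdwCutoff = 3.9) {
  stopifnot(is(s, "Structure"))
  if (s@rnaAbsent) stop("structure ", s@structureId, " has no RNA chain")
  atoms <- s@atoms
  chainClass <- stats::setNames(s@chains$class, s@chains$chain)
  prot <- atoms[chainClass[atoms$chain] == "protein" &
                  atoms$resid %in% AMINO_ACIDS, , drop = FALSE]
  rna <- atoms[chainClass[atoms$chain] == "rna" &
                 atoms$resid %in% RNA_RESIDUES, , drop = FALSE]
  if (!nrow(prot)) stop("structure ", s@structureId, " has no protein chain")
  pxyz <- as.matrix(prot[, c("x", "y", "z")])
  pPolar <- prot$elesy %in% c("N", "O")
  resKey <- paste(rna$chain, rna$resno, rna$insert, sep = "\r")
  out <- list()
  for (key in unique(resKey)) {
    rr <- rna[resKey == key, , drop = FALSE]
    rxyz <- as.matrix(rr[, c("x", "y", "z")])
    # squared distances, all residue atoms vs all protein atoms
    d2 <- outer(rowSums(rxyz^2), rowSums(pxyz^2), "+") -
      2 * rxyz %*% t(pxyz)
    d2[d2 < 0] <- 0
    minAll <- which(d2 == min(d2), arr.ind = TRUE)[1L, ]
    rows <- NULL
    if (d2[minAll[1L], minAll[2L]] <= vdwCutoff^2) {
      rows <- data.frame(rna_chain = rr$chain[1L], rna_resno = rr$resno[1L],
                         nucleotide = rr$resid[1L], kind = "vdw",
                         min_distance = sqrt(d2[minAll[1L], minAll[2L]]),
                         protein_chain = prot$chain[minAll[2L]],
                         protein_resno = prot$resno[minAll[2L]],
                         stringsAsFactors = FALSE)
    }
    rPolar <- rr$elesy %in% c("N", "O")
    if (any(rPolar) && any(pPolar)) {
      d2p <- d2[rPolar, pPolar, drop = FALSE]
      minP <- which(d2p == min(d2p), arr.ind = TRUE)[1L, ]
      if (d2p[minP[1L], minP[2L]] <= hbondCutoff^2) {
        pj <- which(pPolar)[minP[2L]]
        rows <- rbind(rows, data.frame(
          rna_chain = rr$chain[1L], rna_resno = rr$resno[1L],
          nucleotide = rr$resid[1L], kind = "hbond",
          min_distance = sqrt(d2p[minP[1L], minP[2L]]),
          protein_chain = prot$chain[pj],
          protein_resno = prot$resno[pj],
          stringsAsFactors = FALSE))
      }
    }
    if (!is.null(rows)) out[[length(out) + 1L]] <- rows
  }
  if (!length(out)) {
    return(data.frame(rna_chain = character(), rna_resno = integer(),
                      nucleotide = character(), kind = character(),
                      min_distance = numeric(), protein_chain = character(),
                      protein_resno = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call binding sites from contacted nucleotides
#'
#' A binding site is a maximal run of at least `minRun` contiguous RNA
#' nucleotides (consecutive residue numbers within one chain and
#' TER-delimited segment, no insertion codes) in which every nucleotide has
#' at least one contact of either kind. The site's motif is the nucleotide
#' sequence of the run, 5' to 3' by residue number.
#'
#' @param contacts Contacts from [findContacts()].
#' @param s The [Structure-class] the contacts came from.
#' @param minRun Minimum run length (default 4).
#' @return A `data.frame` with columns `structure_id`, `chain`, `start`,
#'   `end` (residue numbers) and `motif`; zero rows when no run qualifies.
#' @export
callBindingSites <- function(contacts, s, minRun = 4L) {
  stopifnot(is(s, "Structure"))
  empty <- data.frame(structure_id = character(), chain = character(),
                      start = integer(), end = integer(), motif = character(),
                      stringsAsFactors = FALSE)
  atoms <- s@atoms
  chainClass <- stats::setNames(s@chains$class, s@chains$chain)
  rna <- atoms[chainClass[atoms$chain] == "rna" &
                 atoms$resid %in% RNA_RESIDUES, , drop = FALSE]
  if (!nrow(rna) || !nrow(contacts)) return(empty)
  # one row per RNA residue (modified nucleotides already excluded; they
  # simply leave gaps in the residue ladder, breaking runs)
  resid <- unique(rna[, c("chain", "resno", "insert", "resid", "segment")])
  resid <- resid[order(resid$chain, resid$resno), , drop = FALSE]
  contacted <- unique(paste(contacts$rna_chain, contacts$rna_resno, sep = "\r"))
  resid$contact <- paste(resid$chain, resid$resno, sep = "\r") %in% contacted
  sites <- list()
  for (ch in unique(resid$chain)) {
    sub <- resid[resid$chain == ch, , drop = FALSE]
    runStart <- 1L
    flush <- function(from, to) {
      if (to - from + 1L >= minRun) {
        sites[[length(sites) + 1L]] <<- data.frame(
          structure_id = s@structureId, chain = ch,
          start = sub$resno[from], end = sub$resno[to],
          motif = paste(sub$resid[from:to], collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
    run <- 0L
    for (i in seq_len(nrow(sub))) {
      startsNew <- run == 0L ||
        sub$resno[i] != sub$resno[i - 1L] + 1L ||
        sub$segment[i] != sub$segment[i - 1L] ||
        nzchar(sub$insert[i])
      ok <- sub$contact[i] && !nzchar(sub$insert[i])
      if (!ok) {
        if (run > 0L) flush(runStart, i - 1L)
        run <- 0L
      } else if (startsNew) {
        if (run > 0L) flush(runStart, i - 1L)
        runStart <- i
        run <- 1L
      } else {
        run <- run + 1L
      }
    }
    if (run > 0L) flush(runStart, nrow(sub))
  }
  if (!length(sites)) return(empty)
  out <- do.call(rbind, sites)
  rownames(out) <- NULL
  out
}

#' Ungapped alignment mismatch count between two motifs
#'
#' Slides the shorter motif along the longer with full overlap and counts,
#' at each offset, the positions where the two letters' IUPAC member sets
#' are disjoint. Returns the offset with the fewest mismatches (smallest
#' offset on ties) and that minimum. Symmetric in its arguments up to the
#' reported offset.
#'
#' @param motifA,motifB IUPAC motif strings, length >= 4.
#' @return A list with elements `offset` (0-based shift of the shorter motif
#'   along the longer) and `mismatches`.
#' @examples
#' ungappedMismatches("ACGU", "UACGU")  # offset 1, 0 mismatches
#' @export
ungappedMismatches <- function(motifA, motifB) {
  a <- normalizeNucleotides(motifA)
  b <- normalizeNucleotides(motifB)
  if (nchar(a) < 4L || nchar(b) < 4L) {
    stop("both motifs must be at least 4 nt")
  }
  shorter <- if (nchar(a) <= nchar(b)) a else b
  longer <- if (nchar(a) <= nchar(b)) b else a
  sm <- iupacMembers(strsplit(shorter, "", fixed = TRUE)[[1L]])
  lm <- iupacMembers(strsplit(longer, "", fixed = TRUE)[[1L]])
  ls <- length(sm)
  best <- NULL
  for (off in 0:(length(lm) - ls)) {
    mm <- sum(vapply(seq_len(ls), function(i) {
      length(intersect(sm[[i]], lm[[i + off]])) == 0L
    }, logical(1L)))
    if (is.null(best) || mm < best$mismatches) {
      best <- list(offset = off, mismatches = mm)
    }
  }
  best
}

#' Classify extracted motifs against reference motifs
#'
#' For each extracted motif, the minimum ungapped mismatch count against any
#' reference motif is binned into the classes used to validate
#' structure-derived motifs: perfect (0), one mismatch, two mismatches, and
#' more than two.
#'
#' @param extracted Character vector of extracted motifs (length >= 4 each).
#' @param reference Character vector of reference motifs for the same RBP.
#' @return A `data.frame` with columns `motif`, `best_reference`,
#'   `offset`, `mismatches`, `class` (one of `"0"`, `"1"`, `"2"`, `">2"`).
#' @export
validateMotifs <- function(extracted, reference) {
  stopifnot(length(reference) >= 1L)
  rows <- lapply(extracted, function(m) {
    fits <- lapply(reference, function(r) ungappedMismatches(m, r))
    mm <- vapply(fits, function(f) f$mismatches, numeric(1L))
    j <- which.min(mm)
    cl <- c("0", "1", "2")[match(mm[j], 0:2)]
    if (is.na(cl)) cl <- ">2"
    data.frame(motif = m, best_reference = reference[j],
               offset = fits[[j]]$offset, mismatches = mm[j], class = cl,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
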