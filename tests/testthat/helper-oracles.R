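# Independent brute-force oracles, kept deliberately naive so they share no
# code path with the implementations they check.

# sliding-window exact search over one sequence; returns 1-based offsets,
# overlapping occurrences included
naiveLocateOne <- function(seq, pattern) {
  ls <- nchar(seq)
  lp <- nchar(pattern)
  if (lp > ls || lp == 0L) return(integer(0L))
  hits <- integer(0L)
  for (p in seq_len(ls - lp + 1L)) {
    if (substr(seq, p, p + lp - 1L) == pattern) hits <- c(hits, p)
  }
  hits
}

# sliding-window search over a named sequence set -> data.frame like
# locateMotif()
naiveLocate <- function(seqs, pattern) {
  rows <- lapply(names(seqs), function(nm) {
    off <- naiveLocateOne(seqs[[nm]], pattern)
    if (length(off)) data.frame(sequence = nm, offset = off,
                                stringsAsFactors = FALSE)
    else NULL
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) {
    return(data.frame(sequence = character(), offset = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

naiveCount <- function(seq, pattern) length(naiveLocateOne(seq, pattern))

# all-pairs double-loop contact detection on a Structure; one row per
# (RNA residue, kind), mirroring findContacts() output columns rna_chain,
# rna_resno, kind
naiveContacts <- function(s, hbond = 3.0, vdw = 3.9) {
  atoms <- s@atoms
  cls <- setNames(s@chains$class, s@chains$chain)
  aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "MSE", "PHE", "PRO", "SER", "THR",
          "TRP", "TYR", "VAL")
  prot <- atoms[cls[atoms$chain] == "protein" & atoms$resid %in% aa, ]
  rna <- atoms[cls[atoms$chain] == "rna" &
                 atoms$resid %in% c("A", "C", "G", "U"), ]
  out <- NULL
  for (key in unique(paste(rna$chain, rna$resno))) {
    rr <- rna[paste(rna$chain, rna$resno) == key, ]
    anyVdw <- FALSE
    anyHb <- FALSE
    for (i in seq_len(nrow(rr))) {
      for (j in seq_len(nrow(prot))) {
        d <- sqrt((rr$x[i] - prot$x[j])^2 + (rr$y[i] - prot$y[j])^2 +
                    (rr$z[i] - prot$z[j])^2)
        if (d <= vdw) anyVdw <- TRUE
        if (d <= hbond && rr$elesy[i] %in% c("N", "O") &&
              prot$elesy[j] %in% c("N", "O")) anyHb <- TRUE
      }
    }
    if (anyVdw) out <- rbind(out, data.frame(rna_chain = rr$chain[1L],
                                             rna_resno = rr$resno[1L],
                                             kind = "vdw"))
    if (anyHb) out <- rbind(out, data.frame(rna_chain = rr$chain[1L],
                                            rna_resno = rr$resno[1L],
                                            kind = "hbond"))
  }
  if (is.null(out)) {
    out <- data.frame(rna_chain = character(), rna_resno = integer(),
                      kind = character())
  }
  out[order(out$rna_chain, out$rna_resno, out$kind), , drop = FALSE]
}

# a small normalized record table used across tests
toyMotifTable <- function() {
  MotifTable(
    gene_name = c("SRSF1", "SRSF1", "RBM8A", "CELF1", "PTBP1"),
    motif = c("ACGCGCC", "RCGUUC", "ACGCGCC", "UGUU", "UCUUC"),
    organism = c("Homo sapiens", "Homo sapiens", "Homo sapiens",
                 "Homo sapiens", "Mus musculus"),
    experiment = c("SELEX", "SELEX", "RNAcompete", "SELEX", "EMSA"),
    synonyms = c("SFRS1", "SFRS1", "", "CUGBP1", ""),
    gene_id = c("ENSG00000136450", "ENSG00000136450", "ENSG00000131795",
                "ENSG00000149187", "ENSMUSG00000006498"),
    domain = c("RRM", "RRM", "RRM", "RRM", "RRM"),
    quality_score = c(1, 0.5, 1, 0.25, NA))
}

# random concrete motif of the given length
randomMotif <- function(l) {
  paste(sample(c("A", "C", "G", "U"), l, replace = TRUE), collapse = "")
}

# random sequence of the given length
randomSeq <- function(l) {
  paste(sample(c("A", "C", "G", "U"), l, replace = TRUE), collapse = "")
}
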