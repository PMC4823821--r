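#' @import methods
NULL

MOTIF_TSV_COLUMNS <- c("gene_name", "synonyms", "gene_id", "organism",
                       "motif", "len", "experiment", "pubmed", "domain",
                       "matrix_id", "quality_score")

#' MotifTable: a table of curated RBP motif records
#'
#' One record per motif x RBP x experiment x organism combination, carrying
#' provenance (PubMed id, experiment type, binding domain) and an optional
#' quality score in `[0, 1]`. Motifs are IUPAC nucleotide strings of length
#' 4-12 over the RNA alphabet (`T` is unified to `U` at construction).
#'
#' @slot records A `data.frame` with columns `gene_name`, `synonyms`
#'   (semicolon-delimited aliases), `gene_id`, `organism`, `motif`, `len`,
#'   `experiment`, `pubmed`, `domain`, `matrix_id`, `quality_score`.
#' @export
setClass("MotifTable", representation(records = "data.frame"))

setValidity("MotifTable", function(object) {
  df <- object@records
  missing <- setdiff(MOTIF_TSV_COLUMNS, names(df))
  if (length(missing)) {
    return(paste("missing column(s):", paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0L) return(TRUE)
  for (i in seq_len(nrow(df))) {
    m <- df$motif[i]
    ok <- tryCatch({ checkMotif(m); TRUE }, error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) return(sprintf("record %d: %s", i, ok))
  }
  if (!all(df$len == nchar(df$motif))) {
    return("len column disagrees with motif length")
  }
  qs <- df$quality_score
  bad <- !is.na(qs) & (qs < 0 | qs > 1)
  if (any(bad)) {
    return(paste("quality_score outside [0, 1] in record(s)",
                 paste(which(bad), collapse = ", ")))
  }
  TRUE
})

#' Construct a MotifTable from record fields
#'
#' @param gene_name Official (or raw, pre-normalization) gene names.
#' @param motif IUPAC motif strings, length 4-12; `T` is converted to `U`
#'   and letters uppercased.
#' @param organism Organism names (e.g. `"Homo sapiens"`).
#' @param experiment Experiment type (e.g. `"SELEX"`, `"EMSA"`, `"X-RAY"`).
#' @param synonyms Semicolon-delimited alias strings (default empty).
#' @param gene_id Gene identifiers (e.g. Ensembl ids; default empty).
#' @param pubmed PubMed identifiers (default empty).
#' @param domain RNA-binding domain names (e.g. `"RRM"`; default empty).
#' @param matrix_id Identifier of the associated PPM (default empty).
#' @param quality_score Numeric in `[0, 1]` or `NA` (default `NA`).
#' @return A [MotifTable-class] object.
#' @examples
#' tab <- MotifTable(gene_name = c("SRSF1", "RBM8A"),
#'                   motif = "ACGCGCC",
#'                   organism = "Homo sapiens",
#'                   experiment = "SELEX")
#' tab
#' @export
MotifTable <- function(gene_name = character(), motif = character(),
                       organism = character(), experiment = character(),
                       synonyms = "", gene_id = "", pubmed = "",
                       domain = "", matrix_id = "",
                       quality_score = NA_real_) {
  motif <- normalizeNucleotides(motif)
  df <- data.frame(gene_name = as.character(gene_name),
                   synonyms = as.character(synonyms),
                   gene_id = as.character(gene_id),
                   organism = as.character(organism),
                   motif = motif,
                   len = nchar(motif),
                   experiment = as.character(experiment),
                   pubmed = as.character(pubmed),
                   domain = as.character(domain),
                   matrix_id = as.character(matrix_id),
                   quality_score = as.numeric(quality_score),
                   stringsAsFactors = FALSE)
  new("MotifTable", records = df)
}

#' @describeIn MotifTable-class number of records
#' @param x A `MotifTable`.
#' @export
setMethod("length", "MotifTable", function(x) nrow(x@records))

#' Extract the record data.frame from a MotifTable
#'
#' @param x A [MotifTable-class].
#' @return The underlying `data.frame` (one row per record).
#' @export
records <- function(x) {
  stopifnot(is(x, "MotifTable"))
  x@records
}

#' @describeIn MotifTable-class subset records by row index
#' @param i Row indices.
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "MotifTable", function(x, i, j, ..., drop = FALSE) {
  df <- x@records[i, , drop = FALSE]
  rownames(df) <- NULL
  new("MotifTable", records = df)
})

setMethod("show", "MotifTable", function(object) {
  df <- object@records
  cat("MotifTable with", nrow(df), "record(s)\n")
  if (nrow(df)) {
    cat("  RBPs:", length(unique(df$gene_name)),
        "| organisms:", length(unique(df$organism)),
        "| motif lengths:", paste(range(df$len), collapse = "-"), "\n")
    print(utils::head(df[, c("gene_name", "organism", "motif",
                             "experiment", "quality_score")], 5L))
    if (nrow(df) > 5L) cat("  ...", nrow(df) - 5L, "more record(s)\n")
  }
  invisible(object)
})

# split a semicolon-delimited synonym field into a character vector
splitSynonyms <- function(s) {
  out <- strsplit(s, ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

joinSynonyms <- function(v) paste(v, collapse = ";")

#' Synonym table for gene-name normalization
#'
#' A per-organism mapping from alias gene names to official names, used to
#' collapse the diverging nomenclature of upstream motif databases (e.g.
#' human CUGBP1 -> CELF1). Official names are fixed points: an official name
#' used as an alias maps to itself.
#'
#' @param alias Character vector of alias names.
#' @param official Character vector of official names (recycled to match).
#' @param organism Character vector of organisms (recycled to match).
#' @return A `data.frame` with columns `alias`, `official`, `organism`,
#'   augmented with identity rows for every official name.
#' @examples
#' synonymTable("CUGBP1", "CELF1", "Homo sapiens")
#' @export
synonymTable <- function(alias, official, organism) {
  df <- data.frame(alias = as.character(alias),
                   official = as.character(official),
                   organism = as.character(organism),
                   stringsAsFactors = FALSE)
  # official names are fixed points of the mapping
  fix <- unique(df[, c("official", "organism")])
  fixRows <- data.frame(alias = fix$official, official = fix$official,
                        organism = fix$organism, stringsAsFactors = FALSE)
  out <- unique(rbind(df, fixRows))
  rownames(out) <- NULL
  out
}

#' Read a synonym table from TSV
#'
#' Expects a header line `alias  official  organism` (tab-separated).
#'
#' @param path Path to the TSV file.
#' @return A synonym table as from [synonymTable()].
#' @export
readSynonymTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("alias", "official", "organism")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("synonym table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  synonymTable(df$alias, df$official, df$organism)
}

#' Normalize motif records against a synonym table
#'
#' Rewrites each record's gene name to the official name for its organism and
#' appends the replaced alias to the record's synonym list, so records from
#' sources with diverging nomenclature deduplicate correctly. Motifs are
#' uppercased with `T` unified to `U` (already enforced at construction, and
#' re-applied here for records read from permissive sources). Records whose
#' organism has no entry in the table are left unchanged, with one warning
#' naming the organisms concerned.
#'
#' The operation is idempotent: official names map to themselves and aliases
#' already recorded are not duplicated.
#'
#' @param x A [MotifTable-class].
#' @param table A synonym table as from [synonymTable()].
#' @return A normalized `MotifTable`.
#' @examples
#' tab <- MotifTable("CUGBP1", "UGUU", "Homo sapiens", "SELEX")
#' syn <- synonymTable("CUGBP1", "CELF1", "Homo sapiens")
#' records(normalizeRecords(tab, syn))$gene_name  # "CELF1"
#' @export
normalizeRecords <- function(x, table) {
  stopifnot(is(x, "MotifTable"), is.data.frame(table))
  df <- x@records
  if (!nrow(df)) return(x)
  df$motif <- normalizeNucleotides(df$motif)
  df$len <- nchar(df$motif)
  knownOrg <- unique(table$organism)
  unknown <- setdiff(unique(df$organism), knownOrg)
  if (length(unknown)) {
    warning("no synonym entries for organism(s): ",
            paste(unknown, collapse = ", "),
            "; those records are left unchanged")
  }
  key <- paste(table$alias, table$organism, sep = "\r")
  hit <- match(paste(df$gene_name, df$organism, sep = "\r"), key)
  mapped <- !is.na(hit) & df$organism %in% knownOrg
  for (i in which(mapped)) {
    official <- table$official[hit[i]]
    if (!identical(official, df$gene_name[i])) {
      syn <- splitSynonyms(df$synonyms[i])[[1L]]
      syn <- unique(c(syn, df$gene_name[i]))
      df$synonyms[i] <- joinSynonyms(setdiff(syn, official))
      df$gene_name[i] <- official
    }
  }
  new("MotifTable", records = df)
}

#' Reduce records to distinct entries
#'
#' A motif is a distinct entry if it binds a different RBP, was identified
#' with a different experimental approach, or was identified in a different
#' organism; the deduplication key is therefore exactly
#' `(motif, gene_name, experiment, organism)`. The first occurrence of each
#' key is retained and input order is preserved. Idempotent.
#'
#' @param x A [MotifTable-class], normally already normalized.
#' @return A `MotifTable` with duplicate entries removed.
#' @examples
#' tab <- MotifTable(gene_name = c("SRSF1", "RBM8A"), motif = "ACGCGCC",
#'                   organism = "Homo sapiens", experiment = "SELEX")
#' length(distinctEntries(tab))  # 2: same motif, different RBP
#' @export
distinctEntries <- function(x) {
  stopifnot(is(x, "MotifTable"))
  df <- x@records
  key <- paste(df$motif, df$gene_name, df$experiment, df$organism,
               sep = "\r")
  x[!duplicated(key)]
}

#' Query motif records
#'
#' Filters records by any combination of criteria; all given criteria must
#' hold (conjunction). String criteria are exact, case-sensitive matches;
#' `synonym` matches any alias in a record's synonym list.
#'
#' @param x A [MotifTable-class].
#' @param gene Official gene name.
#' @param synonym Alias gene name, matched against the synonyms field.
#' @param geneId Gene identifier (e.g. Ensembl id).
#' @param organism Organism name.
#' @param experiment Experiment type.
#' @param domain Binding-domain name.
#' @param minLen,maxLen Inclusive bounds on motif length; `minLen > maxLen`
#'   is an error.
#' @return The matching records as a `MotifTable` (possibly empty).
#' @export
queryRecords <- function(x, gene = NULL, synonym = NULL, geneId = NULL,
                         organism = NULL, experiment = NULL, domain = NULL,
                         minLen = NULL, maxLen = NULL) {
  stopifnot(is(x, "MotifTable"))
  if (!is.null(minLen) && !is.null(maxLen) && minLen > maxLen) {
    stop("malformed length bounds: minLen (", minLen,
         ") exceeds maxLen (", maxLen, ")")
  }
  df <- x@records
  keep <- rep(TRUE, nrow(df))
  if (!is.null(gene)) keep <- keep & df$gene_name %in% gene
  if (!is.null(synonym)) {
    syn <- splitSynonyms(df$synonyms)
    keep <- keep & vapply(syn, function(v) any(synonym %in% v), logical(1L))
  }
  if (!is.null(geneId)) keep <- keep & df$gene_id %in% geneId
  if (!is.null(organism)) keep <- keep & df$organism %in% organism
  if (!is.null(experiment)) keep <- keep & df$experiment %in% experiment
  if (!is.null(domain)) keep <- keep & df$domain %in% domain
  if (!is.null(minLen)) keep <- keep & df$len >= minLen
  if (!is.null(maxLen)) keep <- keep & df$len <= maxLen
  x[keep]
}

#' Read motif records from TSV
#'
#' Expects the tab-separated layout written by [writeMotifRecords()]: a
#' header line with columns `gene_name synonyms gene_id organism motif len
#' experiment pubmed domain matrix_id quality_score` (the `len` column is
#' recomputed; `quality_score` may be empty/NA).
#'
#' @param path Path to the TSV file.
#' @return A [MotifTable-class].
#' @export
readMotifRecords <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  mandatory <- setdiff(MOTIF_TSV_COLUMNS, c("len", "quality_score"))
  missing <- setdiff(mandatory, names(df))
  if (length(missing)) {
    stop("motif TSV is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  motif <- normalizeNucleotides(df$motif)
  for (i in seq_along(motif)) {
    ok <- tryCatch({ checkMotif(motif[i]); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) {
      stop("malformed motif on line ", i + 1L, " of ", path, ": ", ok)
    }
  }
  qs <- if ("quality_score" %in% names(df)) {
    suppressWarnings(as.numeric(df$quality_score))
  } else NA_real_
  MotifTable(gene_name = df$gene_name, motif = motif,
             organism = df$organism, experiment = df$experiment,
             synonyms = df$synonyms, gene_id = df$gene_id,
             pubmed = df$pubmed, domain = df$domain,
             matrix_id = df$matrix_id, quality_score = qs)
}

#' Write motif records to TSV
#'
#' @param x A [MotifTable-class].
#' @param path Output path.
#' @return Invisibly, `path`. Reading the file back with
#'   [readMotifRecords()] reproduces every field.
#' @export
writeMotifRecords <- function(x, path) {
  stopifnot(is(x, "MotifTable"))
  df <- x@records
  # %.17g keeps the score bit-exact across a write/read round trip
  df$quality_score <- ifelse(is.na(df$quality_score), "NA",
                             sprintf("%.17g", df$quality_score))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
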