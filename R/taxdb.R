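#' Annotated sequence database
#'
#' An annotated database holds sequence records (accession, normalized
#' nucleotide sequence, per-rank lineage, source label). Sequences are
#' normalized on construction ([normalize_sequence()]) so that
#' identical-sequence matching between two databases is exact string
#' equality. Accessions must be unique within one database; identical
#' sequences under different accessions are allowed and tracked by the
#' sequence index.
#'
#' @param id Character vector of accessions (unique).
#' @param seq Character vector of sequences (normalized on construction).
#' @param lineage Character matrix with one row per record and rank-named
#'   columns (as from [parse_lineages()]), or a single lineage recycled.
#' @param source Database label (scalar), e.g. `"greengenes"`.
#' @return An object of class `taxdb`.
#' @export
taxdb <- function(id, seq, lineage, source = "db") {
  id <- as.character(id)
  if (anyDuplicated(id)) {
    stop("duplicate accession(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  seq <- unname(normalize_sequence(seq))
  if (length(seq) != length(id)) stop("id and seq lengths differ")
  if (!is.matrix(lineage)) lineage <- matrix(lineage, nrow = 1,
                                             dimnames = list(NULL, names(lineage)))
  if (nrow(lineage) == 1L && length(id) > 1L) {
    lineage <- lineage[rep(1L, length(id)), , drop = FALSE]
  }
  if (nrow(lineage) != length(id)) stop("lineage rows must match records")
  check_ranks(colnames(lineage))
  rownames(lineage) <- id
  structure(list(id = id, seq = seq, lineage = lineage,
                 source = as.character(source)[1]),
            class = "taxdb")
}

#' @export
print.taxdb <- function(x, ...) {
  cat("Annotated sequence database <", x$source, ">\n", sep = "")
  cat("  records: ", length(x$id),
      "  unique sequences: ", length(unique(x$seq)), "\n", sep = "")
  ann <- colSums(!is.na(x$lineage))
  cat("  annotated per rank: ",
      paste(sprintf("%s=%d", colnames(x$lineage), ann), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' @export
length.taxdb <- function(x) length(x$id)

#' Subset an annotated database
#'
#' @param x A `taxdb`.
#' @param i Indices or accession strings.
#' @param ... Unused.
#' @export
`[.taxdb` <- function(x, i, ...) {
  if (is.character(i)) {
    j <- match(i, x$id)
    if (anyNA(j)) stop("unknown accession(s): ", paste(i[is.na(j)], collapse = ", "))
    i <- j
  }
  taxdb(x$id[i], x$seq[i], x$lineage[i, , drop = FALSE], x$source)
}

#' Sequence index of a database
#'
#' Groups accessions by identical normalized sequence.
#'
#' @param db A `taxdb`.
#' @return Named list: normalized sequence -> character vector of accessions.
#' @export
seq_index <- function(db) {
  split(db$id, db$seq)
}

#' Per-record lineages of a database
#'
#' @param db A `taxdb`.
#' @param ranks Ranks (columns) to return; default the audit ranks.
#' @return Character matrix, rows named by accession.
#' @export
db_lineages <- function(db, ranks = audit_ranks()) {
  check_ranks(ranks)
  missing <- setdiff(ranks, colnames(db$lineage))
  if (length(missing)) {
    extra <- matrix(NA_character_, nrow = length(db$id), ncol = length(missing),
                    dimnames = list(db$id, missing))
    return(cbind(db$lineage, extra)[, ranks, drop = FALSE])
  }
  db$lineage[, ranks, drop = FALSE]
}

split_fasta_header <- function(desc) {
  sp <- regexpr("[[:space:]]", desc)
  id <- ifelse(sp > 0, substr(desc, 1L, sp - 1L), desc)
  rest <- ifelse(sp > 0, trimws(substr(desc, sp + 1L, nchar(desc))), "")
  list(id = id, annot = rest)
}

#' Read an annotated database from FASTA
#'
#' For the `"rdp"` and `"silva"` dialects (and header-annotated Greengenes
#' files) the lineage is embedded in each record's description line after
#' the accession. SILVA-style coordinate-suffixed accessions are kept
#' verbatim.
#'
#' @param path FASTA file path.
#' @param dialect Lineage dialect of the description line.
#' @param source Database label; defaults to the dialect.
#' @return A [taxdb()].
#' @export
read_taxdb_fasta <- function(path, dialect = c("rdp", "silva", "greengenes"),
                             source = NULL) {
  dialect <- match.arg(dialect)
  x <- Biostrings::readBStringSet(path)
  hdr <- split_fasta_header(names(x))
  lin <- parse_lineages(hdr$annot, dialect)
  taxdb(hdr$id, as.character(x), lin,
        source = if (is.null(source)) dialect else source)
}

#' Read a Greengenes-style database (FASTA plus taxonomy table)
#'
#' The taxonomy table is two-column tab-separated text: accession TAB
#' lineage string in the Greengenes dialect. Records without a taxonomy row
#' get an all-blank lineage.
#'
#' @param fasta_path FASTA of sequences (plain accession headers).
#' @param tax_path Two-column taxonomy table.
#' @param source Database label.
#' @return A [taxdb()].
#' @export
read_taxdb_greengenes <- function(fasta_path, tax_path, source = "greengenes") {
  x <- Biostrings::readBStringSet(fasta_path)
  id <- split_fasta_header(names(x))$id
  tax <- read.delim(tax_path, header = FALSE, sep = "\t",
                    colClasses = "character", quote = "")
  if (ncol(tax) < 2) stop("taxonomy table must have two tab-separated columns")
  lin_tab <- parse_lineages(tax[[2]], "greengenes")
  lin <- matrix(NA_character_, nrow = length(id), ncol = length(tax_ranks()),
                dimnames = list(NULL, tax_ranks()))
  hit <- match(id, tax[[1]])
  lin[!is.na(hit), ] <- lin_tab[hit[!is.na(hit)], , drop = FALSE]
  taxdb(id, as.character(x), lin, source = source)
}

#' Write an annotated database
#'
#' `write_taxdb()` dumps the canonical tab-separated form (accession,
#' one column per rank, sequence; UTF-8, LF). `write_taxdb_fasta()` writes
#' FASTA with the lineage serialized into the description in the requested
#' dialect; for `"greengenes"` a plain FASTA plus a two-column taxonomy
#' table (`<path>.tax`) are written instead.
#'
#' @param db A [taxdb()].
#' @param path Output file.
#' @param dialect Output lineage dialect.
#' @return `path`, invisibly.
#' @export
write_taxdb <- function(db, path) {
  d <- data.frame(id = db$id, db$lineage, seq = db$seq,
                  check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(colnames(d), collapse = "\t"), con)
  writeLines(do.call(paste, c(lapply(d, function(col) ifelse(is.na(col), "", col)),
                              sep = "\t")), con)
  invisible(path)
}

#' @rdname write_taxdb
#' @export
write_taxdb_fasta <- function(db, path,
                              dialect = c("rdp", "silva", "greengenes")) {
  dialect <- match.arg(dialect)
  seqs <- Biostrings::DNAStringSet(db$seq)
  if (dialect == "greengenes") {
    names(seqs) <- db$id
    Biostrings::writeXStringSet(seqs, path)
    lin <- format_lineage(db$lineage, "greengenes")
    writeLines(paste(db$id, lin, sep = "\t"), paste0(path, ".tax"))
  } else {
    names(seqs) <- paste(db$id, format_lineage(db$lineage, dialect))
    Biostrings::writeXStringSet(seqs, path)
  }
  invisible(path)
}
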