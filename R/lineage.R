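#' Parse a lineage annotation string
#'
#' Converts a database annotation string into a lineage: a named character
#' vector with one entry per rank in `ranks` (default all seven,
#' domain..species), blanks as `NA`. Three dialects are supported:
#'
#' * `"greengenes"`: semicolon-separated tokens with rank prefixes,
#'   e.g. `"k__Bacteria; p__Firmicutes; ...; g__Streptococcus"`. Ranks are
#'   assigned by prefix; bare prefixes (`"g__"`) are blanks.
#' * `"silva"`: semicolon-separated path assigned by position from domain,
#'   e.g. `"Bacteria;Proteobacteria;Gammaproteobacteria;;;"`.
#' * `"rdp"`: the training-set style. When the string carries rank tags
#'   (`"Bacteria;domain;Firmicutes;phylum;..."`, optionally prefixed by
#'   `"Lineage=Root;rootrank;"`), names are assigned by tag; otherwise the
#'   path is read positionally from domain. Tokens may be double-quoted.
#'
#' All names pass through [normalize_name()], so placeholder tokens become
#' blanks. Unconfigured ranks in the input are ignored.
#'
#' @param text Character vector of annotation strings.
#' @param dialect One of `"rdp"`, `"greengenes"`, `"silva"`.
#' @param ranks Ranks to populate (default all seven).
#' @return For a single string, a named character vector (the lineage); for
#'   a vector, a character matrix with one row per input and one column per
#'   rank.
#' @seealso [format_lineage()] for the inverse.
#' @export
parse_lineage <- function(text, dialect = c("greengenes", "silva", "rdp"),
                          ranks = tax_ranks()) {
  dialect <- match.arg(dialect)
  check_ranks(ranks)
  out <- parse_lineages(text, dialect, ranks)
  if (length(text) == 1L) out[1L, ] else out
}

#' @rdname parse_lineage
#' @export
parse_lineages <- function(text, dialect = c("greengenes", "silva", "rdp"),
                           ranks = tax_ranks()) {
  dialect <- match.arg(dialect)
  check_ranks(ranks)
  n <- length(text)
  out <- matrix(NA_character_, nrow = n, ncol = length(ranks),
                dimnames = list(NULL, ranks))
  if (n == 0L) return(out)
  parts <- strsplit(as.character(text), ";", fixed = TRUE)
  for (i in seq_len(n)) {
    out[i, ] <- parse_one_lineage(parts[[i]], dialect, ranks, text[[i]])
  }
  out
}

parse_one_lineage <- function(tok, dialect, ranks, orig) {
  tok <- trimws(tok)
  tok <- gsub('^"|"$', "", tok)
  tok <- sub("^Lineage=", "", tok)
  # drop the RDP Root;rootrank preamble as a unit so name/tag pairing survives
  tok <- tok[!(tolower(tok) %in% c("root", "rootrank"))]
  lin <- setNames(rep(NA_character_, length(ranks)), ranks)
  if (length(tok) == 0L) return(lin)

  if (dialect == "greengenes") {
    prefmap <- c(k = "domain", p = "phylum", c = "class", o = "order",
                 f = "family", g = "genus", s = "species")
    keep <- nzchar(tok)
    tok <- tok[keep]
    has_pref <- grepl("^[kpcofgs]__", tok)
    if (!all(has_pref)) {
      stop("greengenes lineage token without rank prefix in: ", orig)
    }
    rk <- prefmap[substr(tok, 1L, 1L)]
    for (j in seq_along(tok)) {
      if (rk[[j]] %in% ranks) lin[[rk[[j]]]] <- normalize_name(tok[[j]])
    }
    return(lin)
  }

  if (dialect == "rdp") {
    low <- tolower(tok)
    tagged <- any(low %in% c(tax_ranks(), "rootrank", "norank", "subclass",
                             "suborder"))
    if (tagged) {
      # name;tag pairs; tags not in the configured rank set are skipped
      j <- 1L
      while (j < length(tok)) {
        tag <- tolower(tok[[j + 1L]])
        if (tag %in% ranks) lin[[tag]] <- normalize_name(tok[[j]])
        j <- j + 2L
      }
      return(lin)
    }
    # fall through to positional
  }

  # positional from domain (silva, untagged rdp)
  if (length(tok) > length(ranks)) {
    stop("lineage has ", length(tok), " components but only ",
         length(ranks), " configured ranks (no rank tags): ", orig)
  }
  for (j in seq_along(tok)) lin[[ranks[[j]]]] <- normalize_name(tok[[j]])
  lin
}

#' Serialize a lineage to an annotation string
#'
#' Inverse of [parse_lineage()] up to canonical form: parsing the output in
#' the same dialect recovers the same lineage (blank-for-blank,
#' name-for-name).
#'
#' @param lineage Named character vector (rank -> name, `NA` = blank) or a
#'   matrix as returned by [parse_lineages()].
#' @param dialect Output dialect.
#' @return Character vector of annotation strings.
#' @export
format_lineage <- function(lineage, dialect = c("greengenes", "silva", "rdp")) {
  dialect <- match.arg(dialect)
  if (is.matrix(lineage)) {
    return(vapply(seq_len(nrow(lineage)),
                  function(i) format_lineage(lineage[i, ], dialect),
                  character(1)))
  }
  ranks <- names(lineage)
  check_ranks(ranks)
  ranks <- order_ranks(ranks)
  lineage <- lineage[ranks]
  if (dialect == "greengenes") {
    pref <- c(domain = "k__", phylum = "p__", class = "c__", order = "o__",
              family = "f__", genus = "g__", species = "s__")[ranks]
    val <- ifelse(is.na(lineage), "", lineage)
    return(paste0(pref, val, collapse = "; "))
  }
  if (dialect == "silva") {
    val <- ifelse(is.na(lineage), "", lineage)
    return(paste(val, collapse = ";"))
  }
  # rdp: tagged pairs for non-blank ranks
  keep <- !is.na(lineage)
  if (!any(keep)) return("Root;rootrank")
  paste(c("Root;rootrank",
          paste(lineage[keep], ranks[keep], sep = ";")), collapse = ";")
}
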