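#' Normalize a nucleotide sequence
#'
#' Uppercases, converts RNA U to T, strips whitespace and gap characters
#' (`-`, `.`), and maps every remaining character outside `{A,C,G,T}` to `N`.
#' Identical-sequence matching between databases is exact string equality of
#' normalized sequences, so all dialect differences (case, RNA vs DNA,
#' alignment gaps) must be erased here. Idempotent.
#'
#' @param raw Character vector of raw sequences.
#' @return Character vector of normalized sequences.
#' @examples
#' normalize_sequence("acgu")        # "ACGT"
#' normalize_sequence("AC-GT\nRR")   # "ACGTNN"
#' @export
normalize_sequence <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  if (!is.character(raw) || anyNA(raw)) stop("sequences must be character, non-NA")
  x <- toupper(raw)
  x <- gsub("[-.[:space:]]", "", x)
  x <- chartr("U", "T", x)
  x <- gsub("[^ACGT]", "N", x)
  if (any(!nzchar(x))) {
    stop("malformed record: empty sequence after normalization")
  }
  x
}

#' Normalize a taxon name
#'
#' Strips Greengenes rank prefixes (`k__`, `p__`, ..., `s__`), trims and
#' collapses whitespace, and maps blank tokens to the blank sentinel
#' (`NA`). Case and punctuation are preserved, so the combined genus
#' "Escherichia-Shigella" stays atomic and distinct from "Escherichia".
#' Name matching across nomenclatures is case-sensitive.
#'
#' Blank tokens are: the empty string, bare rank prefixes such as `"g__"`,
#' the placeholder names `"unclassified"`, `"unidentified"`, `"uncultured"`
#' (case-insensitive), and any name ending in `"_unclassified"`. The list is
#' configurable because database conventions vary and no canonical set
#' exists.
#'
#' @param raw Character vector of raw names (NA allowed, stays blank).
#' @param blank_tokens Lowercase placeholder names treated as blank.
#' @return Character vector; blank names are `NA_character_`.
#' @examples
#' normalize_name("g__Salmonella")  # "Salmonella"
#' normalize_name("g__")            # NA (blank sentinel)
#' @export
normalize_name <- function(raw,
                           blank_tokens = c("unclassified", "unidentified",
                                            "uncultured")) {
  if (length(raw) == 0L) return(character(0))
  x <- as.character(raw)
  x <- sub("^[kpcofgs]__", "", x)
  x <- gsub("[[:space:]]+", " ", x)
  x <- trimws(x)
  blank <- is.na(x) | !nzchar(x) |
    tolower(x) %in% blank_tokens |
    grepl("_unclassified$", x, ignore.case = TRUE)
  x[blank] <- NA_character_
  x
}

is_blank <- function(x) is.na(x)
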