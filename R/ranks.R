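#' Taxonomic ranks
#'
#' The fixed rank order used throughout the package is
#' domain < phylum < class < order < family < genus < species.
#' `tax_ranks()` returns all seven ranks in that order; `audit_ranks()`
#' returns the five ranks (phylum..genus) over which conflict, purity and
#' concurrence tabulations run by default. Domain and species annotations are
#' parsed and retained but excluded from those tabulations: reference
#' databases annotate them inconsistently and the audit tables are defined
#' over phylum..genus.
#'
#' @return Character vector of rank names, ordered from highest to lowest.
#' @export
tax_ranks <- function() {
  c("domain", "phylum", "class", "order", "family", "genus", "species")
}

#' @rdname tax_ranks
#' @export
audit_ranks <- function() {
  c("phylum", "class", "order", "family", "genus")
}

#' Numeric level of a rank
#'
#' Ranks compare by position in the fixed order; lower level means higher
#' (broader) rank. domain = 1, ..., species = 7.
#'
#' @param rank Character vector of rank names.
#' @return Integer vector of levels.
#' @export
rank_level <- function(rank) {
  lev <- match(rank, tax_ranks())
  if (anyNA(lev)) {
    stop("unknown rank(s): ", paste(rank[is.na(lev)], collapse = ", "))
  }
  lev
}

check_ranks <- function(ranks) {
  rank_level(ranks)
  ranks
}

# Ranks ordered highest-first among a configured subset.
order_ranks <- function(ranks) ranks[order(rank_level(ranks))]
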