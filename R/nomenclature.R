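#' Taxon names present in a database
#'
#' @param db A [taxdb()].
#' @param ranks Ranks to scan.
#' @return Data frame with columns `name`, `rank`, one row per distinct
#'   non-blank (name, rank) pair.
#' @export
name_rank_table <- function(db, ranks = audit_ranks()) {
  lin <- db_lineages(db, ranks)
  out <- unique(data.frame(
    name = as.vector(lin),
    rank = rep(colnames(lin), each = nrow(lin)),
    stringsAsFactors = FALSE))
  out <- out[!is.na(out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Majority parent map of a database
#'
#' For each non-blank taxon name at each rank below the highest configured
#' rank, the parent is the name at the next-higher configured rank that
#' co-occurs with it most often over the database's lineages (real databases
#' contain internally inconsistent lineages). Ties break lexicographically;
#' names whose parent rank is always blank get parent `NA`. One example
#' accession carrying the majority parent is recorded per name.
#'
#' @param db A [taxdb()].
#' @param ranks Configured ranks, highest first after ordering.
#' @return Data frame: `rank`, `name`, `parent`, `example_id`.
#' @export
parent_map <- function(db, ranks = audit_ranks()) {
  ranks <- order_ranks(check_ranks(ranks))
  lin <- db_lineages(db, ranks)
  out <- list()
  for (j in seq_along(ranks)[-1]) {
    child <- lin[, ranks[j]]
    par <- lin[, ranks[j - 1L]]
    keep <- !is.na(child) & !is.na(par)
    if (!any(keep)) next
    cc <- child[keep]; pp <- par[keep]; ids <- rownames(lin)[keep]
    tab <- table(cc, pp)
    maj <- apply(tab, 1L, function(r) colnames(tab)[which.max(r)])
    ex <- ids[match(paste(names(maj), maj[names(maj)]), paste(cc, pp))]
    # names seen only with blank parents
    only_blank <- setdiff(unique(child[!is.na(child)]), names(maj))
    out[[ranks[j]]] <- data.frame(
      rank = ranks[j],
      name = c(names(maj), only_blank),
      parent = c(unname(maj), rep(NA_character_, length(only_blank))),
      example_id = c(ex, rep(NA_character_, length(only_blank))),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(rank = character(), name = character(),
                                      parent = character(),
                                      example_id = character())
  rownames(res) <- NULL
  res
}

#' Common nomenclature of two databases
#'
#' The set of (name, rank) pairs appearing in at least one lineage of each
#' database, blanks excluded. The parent map is taken from the first
#' database's majority parents, restricted to common names. A name
#' appearing at more than one rank within the result is reported with a
#' warning (a nomenclature should use a name at a single rank).
#'
#' @param dbA,dbB [taxdb()] objects.
#' @param ranks Ranks to scan.
#' @return Object of class `nomenclature`: list with `names` (data frame
#'   name/rank), `names_by_rank` (list rank -> character vector), `parent`
#'   (data frame from `dbA`), `ranks`.
#' @export
common_nomenclature <- function(dbA, dbB, ranks = audit_ranks()) {
  ranks <- order_ranks(check_ranks(ranks))
  na <- name_rank_table(dbA, ranks)
  nb <- name_rank_table(dbB, ranks)
  key <- function(d) paste(d$rank, d$name, sep = "\r")
  common <- na[key(na) %in% key(nb), , drop = FALSE]
  rownames(common) <- NULL
  dup <- unique(common$name[duplicated(common$name)])
  if (length(dup)) {
    warning("name(s) present at more than one rank in the common nomenclature: ",
            paste(head(dup, 10), collapse = ", "))
  }
  by_rank <- lapply(setNames(ranks, ranks),
                    function(r) common$name[common$rank == r])
  pm <- parent_map(dbA, ranks)
  pm <- pm[key(pm) %in% key(common), , drop = FALSE]
  structure(list(names = common, names_by_rank = by_rank, parent = pm,
                 ranks = ranks),
            class = "nomenclature")
}

#' @export
print.nomenclature <- function(x, ...) {
  cat("Common nomenclature:", nrow(x$names), "names over ranks",
      paste(x$ranks, collapse = ", "), "\n")
  print(table(factor(x$names$rank, levels = x$ranks)))
  invisible(x)
}

in_nomenclature <- function(nomen, name, rank) {
  !is.na(name) & name %in% nomen$names_by_rank[[rank]]
}

#' Nomenclature hierarchy disagreements between two databases
#'
#' Finds taxon names in the common nomenclature whose majority parent
#' differs between the two databases, where at least one of the two parent
#' names is itself in the common nomenclature. These are unambiguous
#' disagreements about where a shared taxon sits in the hierarchy (e.g. a
#' family placed in different orders by the two databases). One example
#' accession per database is attached to each record.
#'
#' @param dbA,dbB [taxdb()] objects.
#' @param ranks Ranks to scan.
#' @param nomen Optional precomputed [common_nomenclature()].
#' @return Data frame: `name`, `rank`, `parentA`, `parentB`, `idA`, `idB`.
#' @export
hierarchy_disagreements <- function(dbA, dbB, ranks = audit_ranks(),
                                    nomen = NULL) {
  ranks <- order_ranks(check_ranks(ranks))
  if (is.null(nomen)) nomen <- common_nomenclature(dbA, dbB, ranks)
  pmA <- parent_map(dbA, ranks)
  pmB <- parent_map(dbB, ranks)
  key <- function(d) paste(d$rank, d$name, sep = "\r")
  common_key <- key(nomen$names)
  pmA <- pmA[key(pmA) %in% common_key, , drop = FALSE]
  m <- match(key(pmA), key(pmB))
  pmB2 <- pmB[m, , drop = FALSE]
  parent_rank <- ranks[match(pmA$rank, ranks) - 1L]
  par_common <- vapply(seq_len(nrow(pmA)), function(i) {
    r <- parent_rank[[i]]
    isTRUE(pmA$parent[[i]] %in% nomen$names_by_rank[[r]]) ||
      isTRUE(pmB2$parent[[i]] %in% nomen$names_by_rank[[r]])
  }, logical(1))
  ok <- !is.na(m) & !is.na(pmA$parent) & !is.na(pmB2$parent) &
    pmA$parent != pmB2$parent & par_common
  out <- data.frame(name = pmA$name[ok], rank = pmA$rank[ok],
                    parentA = pmA$parent[ok], parentB = pmB2$parent[ok],
                    idA = pmA$example_id[ok], idB = pmB2$example_id[ok],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
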