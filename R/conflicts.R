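#' Identical sequences shared by two databases
#'
#' Matches records of two databases by exact equality of their normalized
#' sequences. When a sequence occurs under k accessions in one database and
#' m in the other, all k*m pairs are returned; downstream tabulation
#' deduplicates to one verdict per unique sequence.
#'
#' @param dbA,dbB [taxdb()] objects.
#' @return Data frame: `idA`, `idB`, `seq`.
#' @export
find_identical <- function(dbA, dbB) {
  ixA <- seq_index(dbA)
  ixB <- seq_index(dbB)
  shared <- intersect(names(ixA), names(ixB))
  if (!length(shared)) {
    return(data.frame(idA = character(), idB = character(),
                      seq = character(), stringsAsFactors = FALSE))
  }
  out <- lapply(shared, function(s) {
    expand.grid(idA = ixA[[s]], idB = ixB[[s]],
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$seq <- rep(shared, vapply(ixA[shared], length, 1L) *
                   vapply(ixB[shared], length, 1L))
  rownames(out) <- NULL
  out
}

#' Classify the annotation conflict between two lineages
#'
#' Scans ranks from the highest (phylum) downward. At each rank:
#' * both names non-blank, different, and at least one in the common
#'   nomenclature -> `name_vs_name` conflict;
#' * exactly one name blank and the named one in the common nomenclature ->
#'   `blank_vs_name` conflict (a false negative in one database or a false
#'   positive in the other);
#' * otherwise no conflict at that rank.
#'
#' The record's `highest_rank` is the first conflicted rank top-down. A
#' rank is additionally flagged as a hierarchy conflict when both lineages
#' carry the same common-nomenclature name at that rank but disagree on its
#' parent with two common-nomenclature parent names: the conflict then
#' reflects a disagreement between the nomenclature hierarchies rather than
#' about the sequence itself.
#'
#' @param lineageA,lineageB Named character vectors (rank -> name).
#' @param nomen A [common_nomenclature()].
#' @param ranks Ranks to scan (ordered internally, highest first).
#' @return List: `conflicted`, `highest_rank` (or `NA`), `kind` at the
#'   highest conflicted rank, `hierarchy_ranks`, and `detail` (per-rank data
#'   frame with `nameA`, `nameB`, `conflict`, `hierarchy`).
#' @export
classify_conflict <- function(lineageA, lineageB, nomen,
                              ranks = audit_ranks()) {
  ranks <- order_ranks(check_ranks(ranks))
  nameA <- unname(lineageA[ranks])
  nameB <- unname(lineageB[ranks])
  inA <- vapply(seq_along(ranks),
                function(j) in_nomenclature(nomen, nameA[[j]], ranks[[j]]),
                logical(1))
  inB <- vapply(seq_along(ranks),
                function(j) in_nomenclature(nomen, nameB[[j]], ranks[[j]]),
                logical(1))
  conflict <- rep("none", length(ranks))
  both <- !is.na(nameA) & !is.na(nameB)
  conflict[both & nameA != nameB & (inA | inB)] <- "name_vs_name"
  one_blank <- xor(is.na(nameA), is.na(nameB))
  named_common <- ifelse(is.na(nameA), inB, inA)
  conflict[one_blank & named_common] <- "blank_vs_name"

  hier <- rep(FALSE, length(ranks))
  for (j in seq_along(ranks)[-1]) {
    same_child <- both[[j]] && nameA[[j]] == nameB[[j]] && inA[[j]] && inB[[j]]
    if (same_child && both[[j - 1L]] && nameA[[j - 1L]] != nameB[[j - 1L]] &&
        inA[[j - 1L]] && inB[[j - 1L]]) {
      hier[[j]] <- TRUE
    }
  }

  hit <- which(conflict != "none")
  list(conflicted = length(hit) > 0L,
       highest_rank = if (length(hit)) ranks[[hit[[1L]]]] else NA_character_,
       kind = if (length(hit)) conflict[[hit[[1L]]]] else NA_character_,
       hierarchy_ranks = ranks[hier],
       detail = data.frame(rank = ranks, nameA = nameA, nameB = nameB,
                           conflict = conflict, hierarchy = hier,
                           stringsAsFactors = FALSE))
}

#' Audit annotation conflicts between two databases
#'
#' End-to-end conflict audit: finds identical sequences, classifies every
#' cross-database annotation pair, deduplicates to one verdict per unique
#' shared sequence (a sequence is conflicted if any of its annotation pairs
#' conflict; the highest conflicted rank over pairs is recorded), tabulates
#' conflicts at the highest conflicted rank, and computes the lower bound
#' on the sum of the two databases' annotation error rates:
#' conflicted / (shared sequences annotated by the common nomenclature).
#'
#' @param dbA,dbB [taxdb()] objects.
#' @param ranks Ranks to audit.
#' @param nomen Optional precomputed [common_nomenclature()].
#' @return Object of class `conflict_audit`: list with `records` (one row
#'   per shared sequence), `table` (a `conflict_table`), `n_shared`,
#'   `denominator`, `lower_bound`, `nomenclature`.
#' @export
audit_conflicts <- function(dbA, dbB, ranks = audit_ranks(), nomen = NULL) {
  ranks <- order_ranks(check_ranks(ranks))
  if (is.null(nomen)) nomen <- common_nomenclature(dbA, dbB, ranks)
  pairs <- find_identical(dbA, dbB)
  seqs <- unique(pairs$seq)
  by_seq <- split(seq_len(nrow(pairs)), factor(pairs$seq, levels = seqs))
  linA <- db_lineages(dbA, ranks)
  linB <- db_lineages(dbB, ranks)

  rec <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    sub <- pairs[by_seq[[i]], , drop = FALSE]
    best <- NULL
    best_level <- Inf
    hier <- character(0)
    any_common <- FALSE
    rep_pair <- c(sub$idA[[1L]], sub$idB[[1L]])
    for (k in seq_len(nrow(sub))) {
      la <- linA[sub$idA[[k]], ]
      lb <- linB[sub$idB[[k]], ]
      cc <- classify_conflict(la, lb, nomen, ranks)
      pair_common <- any(vapply(seq_along(ranks), function(j) {
        in_nomenclature(nomen, la[[ranks[[j]]]], ranks[[j]]) ||
          in_nomenclature(nomen, lb[[ranks[[j]]]], ranks[[j]])
      }, logical(1)))
      any_common <- any_common || pair_common
      hier <- union(hier, cc$hierarchy_ranks)
      if (cc$conflicted) {
        lev <- rank_level(cc$highest_rank)
        if (lev < best_level) {
          best <- cc
          best_level <- lev
          rep_pair <- c(sub$idA[[k]], sub$idB[[k]])
        }
      }
    }
    rec[[i]] <- data.frame(
      seq = seqs[[i]], idA = rep_pair[[1L]], idB = rep_pair[[2L]],
      in_common = any_common,
      conflicted = !is.null(best),
      highest_rank = if (is.null(best)) NA_character_ else best$highest_rank,
      kind = if (is.null(best)) NA_character_ else best$kind,
      hierarchy_ranks = paste(hier, collapse = ","),
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rec)
  if (is.null(records)) {
    records <- data.frame(seq = character(), idA = character(),
                          idB = character(), in_common = logical(),
                          conflicted = logical(), highest_rank = character(),
                          kind = character(), hierarchy_ranks = character(),
                          stringsAsFactors = FALSE)
  }
  denominator <- sum(records$in_common)
  tab <- tabulate_conflicts(records, denominator, ranks)
  structure(list(records = records, table = tab,
                 n_shared = length(seqs), denominator = denominator,
                 lower_bound = if (denominator > 0)
                   error_rate_lower_bound(sum(records$conflicted), denominator)
                 else NA_real_,
                 nomenclature = nomen, ranks = ranks),
            class = "conflict_audit")
}

#' Tabulate conflict records at the highest conflicted rank
#'
#' Produces the per-rank conflict table: number of conflicted sequences
#' whose highest conflicted rank is the row's rank (and as a percentage of
#' the denominator), the number of those that are blank-vs-name conflicts,
#' and the number of sequences with a hierarchy conflict attributed to the
#' row's rank (the rank of the re-parented taxon name). Each sequence
#' counts once in the Conflicts column.
#'
#' @param records Deduplicated per-sequence records (see
#'   [audit_conflicts()]).
#' @param denominator Number of shared sequences annotated by the common
#'   nomenclature in one or both databases.
#' @param ranks Ranks tabulated.
#' @return A `conflict_table` data frame with a `Total` row.
#' @export
tabulate_conflicts <- function(records, denominator, ranks = audit_ranks()) {
  ranks <- order_ranks(check_ranks(ranks))
  if (denominator <= 0) stop("denominator must be positive")
  hier_list <- strsplit(records$hierarchy_ranks, ",", fixed = TRUE)
  rows <- lapply(ranks, function(r) {
    at <- records$conflicted & records$highest_rank %in% r
    data.frame(rank = r,
               conflicts = sum(at),
               pct = 100 * sum(at) / denominator,
               blank_vs_name = sum(at & records$kind == "blank_vs_name"),
               hierarchy = sum(vapply(hier_list, function(h) r %in% h,
                                      logical(1))),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  total <- data.frame(rank = "Total", conflicts = sum(tab$conflicts),
                      pct = 100 * sum(tab$conflicts) / denominator,
                      blank_vs_name = sum(tab$blank_vs_name),
                      hierarchy = sum(tab$hierarchy))
  out <- rbind(tab, total)
  rownames(out) <- NULL
  structure(out, denominator = denominator,
            class = c("conflict_table", "data.frame"))
}

#' Lower bound on the sum of two databases' annotation error rates
#'
#' If two databases annotate identical sequences with names drawn from
#' their common nomenclature, any disagreement implies an error in at least
#' one database; agreement may still hide identical errors in both. The
#' conflict fraction is therefore a lower bound on the sum of the two
#' annotation error rates.
#'
#' @param conflicted Number of identical sequences with common-nomenclature
#'   conflicts.
#' @param denominator Number of identical sequences annotated by the common
#'   nomenclature.
#' @return The bound, as a fraction in `[0, 1]`.
#' @examples
#' error_rate_lower_bound(249490, 732048)  # 0.3408... i.e. 34%
#' @export
error_rate_lower_bound <- function(conflicted, denominator) {
  if (length(conflicted) != 1L || length(denominator) != 1L ||
      is.na(conflicted) || is.na(denominator)) {
    stop("conflicted and denominator must be single numbers")
  }
  if (denominator <= 0) stop("denominator must be positive")
  if (conflicted < 0 || conflicted > denominator) {
    stop("conflicted must be between 0 and denominator")
  }
  conflicted / denominator
}

#' @export
print.conflict_audit <- function(x, ...) {
  cat("Conflict audit over ranks", paste(x$ranks, collapse = ", "), "\n")
  cat("  shared sequences:", x$n_shared,
      " annotated by common nomenclature:", x$denominator, "\n")
  print(x$table)
  cat(sprintf("Error-rate lower bound (sum of both databases): %.1f%%\n",
              100 * x$lower_bound))
  invisible(x)
}

#' @export
print.conflict_table <- function(x, ...) {
  d <- data.frame(Rank = x$rank,
                  Conflicts = sprintf("%d (%.1f%%)", x$conflicts, x$pct),
                  `Blank vs. name` = x$blank_vs_name,
                  Hierarchy = x$hierarchy, check.names = FALSE)
  print(d, row.names = FALSE)
  invisible(x)
}
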