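#' Do two trees concur on a taxon?
#'
#' Trees X and Y concur with respect to a taxon t when the same set of
#' taxon names (at t's rank) is found under the LCA of t in both trees.
#' Name sets rather than sequence sets are compared, so the trees concur if
#' they both imply that the same taxa overlap even when individual
#' sequences are placed differently. Singleton taxa (one annotated leaf)
#' are pure in every possible tree and are rejected.
#'
#' @param treeX,treeY Rooted `phylo` objects over the same leaf set.
#' @param annotations A [taxdb()] or rank-named annotation matrix.
#' @param taxon Taxon name.
#' @param rank Rank of the taxon.
#' @return `TRUE` or `FALSE`.
#' @export
concur <- function(treeX, treeY, annotations, taxon, rank) {
  ann <- as_annotations(annotations)
  nmX <- tip_names_at_rank(treeX, ann, rank)
  n_leaves <- sum(nmX %in% taxon)
  if (n_leaves < 2L) {
    stop("taxon is a singleton (or absent) at rank ", rank, ": ", taxon)
  }
  sx <- name_set_under_lca(treeX, ann, taxon, rank)
  sy <- name_set_under_lca(treeY, ann, taxon, rank)
  identical(sx, sy)
}

#' Taxonomy Concurrence Score between two trees
#'
#' Classifies every non-singleton taxon at each rank into one of five
#' categories by comparing the name set under its LCA in the two trees:
#' pure in both, pure in X only, pure in Y only, impure in both with the
#' same name set, impure in both with different name sets. The TCS at a
#' rank is the fraction of non-singleton taxa on which the trees concur,
#' i.e. (pure both + impure same set) / total. Both trees must carry the
#' identical leaf set; singleton-ness is evaluated locally on that leaf
#' set.
#'
#' @param treeX,treeY Rooted `phylo` objects over the same leaf set.
#' @param annotations A [taxdb()] or rank-named annotation matrix.
#' @param ranks Ranks to score.
#' @return Object of class `concurrence_table`: data frame with one row
#'   per rank and columns `rank`, `pure_both`, `pure_X_only`,
#'   `pure_Y_only`, `impure_same_set`, `impure_diff_set`, `total`, `tcs`.
#' @export
tcs <- function(treeX, treeY, annotations, ranks = audit_ranks()) {
  ranks <- order_ranks(check_ranks(ranks))
  ann <- as_annotations(annotations, tax_ranks())
  dx <- setdiff(treeX$tip.label, treeY$tip.label)
  dy <- setdiff(treeY$tip.label, treeX$tip.label)
  if (length(dx) || length(dy)) {
    stop("trees must share an identical leaf set; only in X: ",
         paste(head(dx, 5), collapse = ","), "; only in Y: ",
         paste(head(dy, 5), collapse = ","))
  }
  tipsX <- tips_under(treeX)
  tipsY <- tips_under(treeY)
  rows <- lapply(ranks, function(r) {
    sx <- taxon_stats_at_rank(treeX, ann, r, tipsX)
    sy <- taxon_stats_at_rank(treeY, ann, r, tipsY)
    sx <- sx[!sx$singleton, , drop = FALSE]
    sy <- sy[!sy$singleton, , drop = FALSE]
    stopifnot(identical(sx$taxon, sy$taxon))
    pureX <- sx$pure
    pureY <- sy$pure
    same <- sx$name_set == sy$name_set
    counts <- c(pure_both = sum(pureX & pureY),
                pure_X_only = sum(pureX & !pureY),
                pure_Y_only = sum(!pureX & pureY),
                impure_same_set = sum(!pureX & !pureY & same),
                impure_diff_set = sum(!pureX & !pureY & !same))
    total <- nrow(sx)
    data.frame(rank = r, as.list(counts), total = total,
               tcs = if (total > 0) tcs_from_counts(counts) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  structure(out, class = c("concurrence_table", "data.frame"))
}

#' Taxonomy Concurrence Score from category counts
#'
#' @param counts Numeric vector of the five category counts, in the order
#'   pure both, pure X only, pure Y only, impure same set, impure
#'   different set (names, if present, are checked).
#' @return (pure both + impure same set) / total, a fraction in `[0, 1]`.
#' @examples
#' tcs_from_counts(c(37, 0, 3, 3, 4))          # 40/47 = 0.851
#' tcs_from_counts(c(1449, 58, 74, 74, 101))   # 1523/1756 = 0.867
#' @export
tcs_from_counts <- function(counts) {
  if (length(counts) != 5L || anyNA(counts) || any(counts < 0)) {
    stop("counts must be five non-negative numbers")
  }
  if (!is.null(names(counts))) {
    expected <- c("pure_both", "pure_X_only", "pure_Y_only",
                  "impure_same_set", "impure_diff_set")
    if (!identical(names(counts), expected)) {
      stop("named counts must be in order: ", paste(expected, collapse = ", "))
    }
  }
  total <- sum(counts)
  if (total == 0) stop("total taxon count is zero; TCS undefined")
  unname((counts[[1L]] + counts[[4L]]) / total)
}

#' @export
print.concurrence_table <- function(x, ...) {
  pct <- function(n) sprintf("%d (%.1f%%)", n, 100 * n / pmax(x$total, 1L))
  d <- data.frame(Rank = x$rank, `Pure both` = pct(x$pure_both),
                  `Pure X only` = pct(x$pure_X_only),
                  `Pure Y only` = pct(x$pure_Y_only),
                  `Impure, same set` = pct(x$impure_same_set),
                  `Impure, diff. set` = pct(x$impure_diff_set),
                  TCS = sprintf("%d (%.1f%%)",
                                x$pure_both + x$impure_same_set, 100 * x$tcs),
                  check.names = FALSE)
  print(d, row.names = FALSE)
  invisible(x)
}
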