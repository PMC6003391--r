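# Coerce annotations to a rank-named character matrix with rownames = ids.
as_annotations <- function(annotations, ranks = NULL) {
  if (inherits(annotations, "taxdb")) {
    annotations <- db_lineages(annotations,
                               if (is.null(ranks)) audit_ranks() else ranks)
  }
  if (!is.matrix(annotations) || is.null(rownames(annotations))) {
    stop("annotations must be a taxdb or a rank-named matrix with id rownames")
  }
  check_ranks(colnames(annotations))
  annotations
}

# Names at `rank` for the tree's tips, NA where unannotated or absent.
tip_names_at_rank <- function(tree, ann, rank) {
  m <- match(tree$tip.label, rownames(ann))
  out <- rep(NA_character_, Ntip(tree))
  out[!is.na(m)] <- ann[m[!is.na(m)], rank]
  out
}

#' Set of taxon names under a taxon's LCA
#'
#' Finds the LCA of all leaves annotated with `taxon` at `rank`, then
#' returns the set of (non-blank) names at `rank` found among the leaves of
#' that LCA's subtree. A taxon is pure in the tree exactly when this set is
#' `{taxon}`.
#'
#' @param tree A rooted `phylo` object.
#' @param annotations A [taxdb()] or rank-named character matrix with
#'   accession rownames.
#' @param taxon Taxon name.
#' @param rank Rank of the taxon.
#' @return Character vector of names (sorted).
#' @export
name_set_under_lca <- function(tree, annotations, taxon, rank) {
  ann <- as_annotations(annotations)
  nm <- tip_names_at_rank(tree, ann, rank)
  tips <- which(nm %in% taxon)
  if (!length(tips)) stop("taxon has no annotated leaf in tree: ", taxon)
  node <- if (length(tips) == 1L) tips else getMRCA(tree, tips)
  under <- tips_under(tree)[[node]]
  sort(unique(nm[under[!is.na(nm[under])]]))
}

# Per-taxon LCA/purity statistics at one rank; shared by purity_report and
# the concurrence scorer.
taxon_stats_at_rank <- function(tree, ann, rank, tipsU = NULL) {
  nm <- tip_names_at_rank(tree, ann, rank)
  if (is.null(tipsU)) tipsU <- tips_under(tree)
  taxa <- sort(unique(nm[!is.na(nm)]))
  if (!length(taxa)) {
    return(data.frame(taxon = character(), n_leaves = integer(),
                      singleton = logical(), lca = integer(),
                      pure = logical(), name_set = character(),
                      leaves_under_lca = integer(), stringsAsFactors = FALSE))
  }
  tip_sets <- split(seq_len(Ntip(tree)), nm)
  res <- lapply(taxa, function(t) {
    tips <- tip_sets[[t]]
    node <- if (length(tips) == 1L) tips else getMRCA(tree, tips)
    under <- tipsU[[node]]
    nms <- nm[under]
    nms <- nms[!is.na(nms)]
    uset <- sort(unique(nms))
    data.frame(taxon = t, n_leaves = length(tips),
               singleton = length(tips) == 1L, lca = node,
               pure = identical(uset, t),
               name_set = paste(uset, collapse = ","),
               leaves_under_lca = length(nms), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Purity analysis of an annotated tree
#'
#' For each taxon at each requested rank, finds its LCA in the tree and the
#' set of same-rank taxon names under that LCA. A taxon is *pure* when no
#' other taxon appears under its LCA; an *overlapped* (impure) leaf lies
#' under the LCAs of two or more taxa at the same rank. Leaves blank at a
#' rank are invisible to that rank's analysis. The summary table follows
#' the conventional layout: singleton taxa are counted in their own row and
#' the pure/impure split covers non-singleton taxa only, while leaf counts
#' cover all annotated leaves (a singleton's leaf can still be overlapped
#' by another taxon's LCA subtree).
#'
#' @param tree A rooted `phylo` object (multifurcations allowed; branch
#'   lengths ignored).
#' @param annotations A [taxdb()] or rank-named character matrix with
#'   accession rownames.
#' @param ranks Ranks to analyse.
#' @return Object of class `purity_report`: list with `taxa` (per-taxon
#'   data frame: rank, taxon, n_leaves, singleton, lca, pure, name_set,
#'   leaves_under_lca) and `table` (per-rank counts: singletons,
#'   non_singletons, pure_taxa, impure_taxa, pure_leaves, impure_leaves).
#' @export
purity_report <- function(tree, annotations, ranks = audit_ranks()) {
  ranks <- order_ranks(check_ranks(ranks))
  ann <- as_annotations(annotations, tax_ranks())
  tipsU <- tips_under(tree)
  taxa_all <- list()
  rows <- list()
  for (r in ranks) {
    st <- taxon_stats_at_rank(tree, ann, r, tipsU)
    nm <- tip_names_at_rank(tree, ann, r)
    annotated <- which(!is.na(nm))
    membership <- integer(Ntip(tree))
    for (i in seq_len(nrow(st))) {
      under <- tipsU[[st$lca[[i]]]]
      under <- under[!is.na(nm[under])]
      membership[under] <- membership[under] + 1L
    }
    pure_leaves <- sum(membership[annotated] == 1L)
    ns <- !st$singleton
    rows[[r]] <- data.frame(
      rank = r,
      singletons = sum(st$singleton),
      non_singletons = sum(ns),
      pure_taxa = sum(st$pure & ns),
      impure_taxa = sum(!st$pure & ns),
      pure_leaves = pure_leaves,
      impure_leaves = length(annotated) - pure_leaves,
      stringsAsFactors = FALSE)
    if (nrow(st)) taxa_all[[r]] <- cbind(rank = r, st)
  }
  taxa <- do.call(rbind, c(taxa_all, list(make.row.names = FALSE)))
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  structure(list(taxa = taxa, table = tab), class = "purity_report")
}

#' @export
print.purity_report <- function(x, ...) {
  t <- x$table
  m <- rbind(
    Singletons = t$singletons,
    `Non-singletons` = t$non_singletons,
    `Pure taxa` = sprintf("%d (%.0f%%)", t$pure_taxa,
                          100 * t$pure_taxa / pmax(t$non_singletons, 1L)),
    `Impure taxa` = sprintf("%d (%.0f%%)", t$impure_taxa,
                            100 * t$impure_taxa / pmax(t$non_singletons, 1L)),
    `Pure leaves` = t$pure_leaves,
    `Impure leaves` = t$impure_leaves)
  colnames(m) <- t$rank
  print(m, quote = FALSE)
  invisible(x)
}

# Distinct non-blank child names at the next-lower configured rank for each
# taxon at `rank`, over the tree's annotated tips. A taxon with exactly one
# child taxon cannot be a lowest pure taxon (its single child would be pure
# whenever it is, at a lower rank).
child_counts <- function(tree, ann, rank, ranks) {
  i <- match(rank, ranks)
  if (i == length(ranks)) return(NULL)
  parent <- tip_names_at_rank(tree, ann, rank)
  child <- tip_names_at_rank(tree, ann, ranks[[i + 1L]])
  keep <- !is.na(parent) & !is.na(child)
  if (!any(keep)) return(integer(0))
  vapply(split(child[keep], parent[keep]), function(v) length(unique(v)), 1L)
}

#' Lowest pure taxon of a node
#'
#' Scans ranks from the lowest (genus) upward and returns the first
#' (taxon, rank) such that every leaf under `node` annotated at that rank
#' belongs to the taxon. A taxon containing exactly one child taxon at the
#' next-lower configured rank is ineligible, because its single child is
#' pure whenever it is and sits at a lower rank.
#'
#' @param tree A rooted `phylo` object.
#' @param node Node number (tip or internal).
#' @param annotations A [taxdb()] or annotation matrix.
#' @param ranks Configured ranks, highest to lowest.
#' @return List with `taxon` and `rank`, or `NULL` when no configured rank
#'   is uniform under the node.
#' @export
lowest_pure_taxon <- function(tree, node, annotations, ranks = audit_ranks()) {
  ann <- as_annotations(annotations, tax_ranks())
  ranks <- order_ranks(check_ranks(ranks))
  tipsU <- tips_under(tree)
  if (node < 1L || node > length(tipsU)) stop("node not in tree")
  cc <- lapply(setNames(ranks, ranks),
               function(r) child_counts(tree, ann, r, ranks))
  lpt_of_node(tree, node, ann, ranks, tipsU, cc)
}

lpt_of_node <- function(tree, node, ann, ranks, tipsU, cc) {
  under <- tipsU[[node]]
  for (i in rev(seq_along(ranks))) {
    r <- ranks[[i]]
    nms <- tip_names_at_rank(tree, ann, r)[under]
    nms <- nms[!is.na(nms)]
    if (!length(nms)) next
    u <- unique(nms)
    if (length(u) == 1L) {
      eligible <- i == length(ranks) || is.null(cc[[r]]) ||
        !identical(unname(cc[[r]][u]), 1L)
      if (eligible) return(list(taxon = u, rank = r))
    }
  }
  NULL
}

#' Classify tree edges as pure or impure
#'
#' An edge is pure when its two endpoint nodes have the same lowest pure
#' taxon ([lowest_pure_taxon()]); edges with an undefined LPT at either end
#' are impure.
#'
#' @inheritParams lowest_pure_taxon
#' @return Data frame with one row per edge: `parent`, `child` (node
#'   numbers), `child_label` (tip label or `NA`), `lpt_parent`,
#'   `lpt_child` (as "taxon/rank" strings or `NA`), `pure`.
#' @export
classify_edges <- function(tree, annotations, ranks = audit_ranks()) {
  ann <- as_annotations(annotations, tax_ranks())
  ranks <- order_ranks(check_ranks(ranks))
  tipsU <- tips_under(tree)
  cc <- lapply(setNames(ranks, ranks),
               function(r) child_counts(tree, ann, r, ranks))
  nn <- length(tipsU)
  lpt <- vector("list", nn)
  for (v in seq_len(nn)) lpt[[v]] <- lpt_of_node(tree, v, ann, ranks, tipsU, cc)
  lab <- function(x) if (is.null(x)) NA_character_ else paste(x$taxon, x$rank, sep = "/")
  labs <- vapply(lpt, lab, character(1))
  e <- tree$edge
  pure <- !is.na(labs[e[, 1L]]) & !is.na(labs[e[, 2L]]) &
    labs[e[, 1L]] == labs[e[, 2L]]
  data.frame(parent = e[, 1L], child = e[, 2L],
             child_label = ifelse(e[, 2L] <= Ntip(tree),
                                  tree$tip.label[e[, 2L]], NA_character_),
             lpt_parent = labs[e[, 1L]], lpt_child = labs[e[, 2L]],
             pure = pure, stringsAsFactors = FALSE)
}
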