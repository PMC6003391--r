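#' Simulation configuration
#'
#' Parameters for the synthetic audit-pair generator. The defaults emulate
#' a small but structurally realistic 16S reference database pair: a
#' strict five-level taxonomy (3 phyla x 2 classes x 2 orders x 2 families
#' x 3 genera = 72 genera), 2-6 near-full-length (1,500 nt) sequences per
#' genus with a fifth of genera kept as singletons, per-edge substitution
#' probability 0.01, independent annotation error rates of 0.17 per
#' database (the scale of error suggested for the large curated 16S
#' databases), and 10 leaf-regraft perturbations per guide tree.
#'
#' @param phyla,classes_per_phylum,orders_per_class,families_per_order,genera_per_family
#'   Taxonomy shape (all >= 1).
#' @param seqs_per_genus Inclusive range of sequences per non-singleton
#'   genus.
#' @param singleton_fraction Fraction of genera forced to a single record.
#' @param seq_length Sequence length in nt.
#' @param subst_prob Per-site substitution probability per tree edge.
#' @param error_rate_a,error_rate_b Annotation corruption rates of the two
#'   database copies.
#' @param moves Leaf prune-and-regraft moves applied to each guide tree.
#' @param seed Master seed; fixes all randomness of [build_audit_pair()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(phyla = 3, classes_per_phylum = 2, orders_per_class = 2,
                       families_per_order = 2, genera_per_family = 3,
                       seqs_per_genus = c(2, 6), singleton_fraction = 0.2,
                       seq_length = 1500, subst_prob = 0.01,
                       error_rate_a = 0.17, error_rate_b = 0.17,
                       moves = 10, seed = 1) {
  cfg <- list(phyla = phyla, classes_per_phylum = classes_per_phylum,
              orders_per_class = orders_per_class,
              families_per_order = families_per_order,
              genera_per_family = genera_per_family,
              seqs_per_genus = seqs_per_genus,
              singleton_fraction = singleton_fraction,
              seq_length = seq_length, subst_prob = subst_prob,
              error_rate_a = error_rate_a, error_rate_b = error_rate_b,
              moves = moves, seed = seed)
  counts <- unlist(cfg[1:5])
  if (any(counts < 1)) stop("all taxonomy counts must be >= 1")
  if (length(seqs_per_genus) != 2 || seqs_per_genus[1] < 1 ||
      seqs_per_genus[2] < seqs_per_genus[1]) {
    stop("seqs_per_genus must be an increasing range with minimum >= 1")
  }
  rates <- c(singleton_fraction, subst_prob, error_rate_a, error_rate_b)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  structure(cfg, class = "sim_config")
}

#' Sample a strict synthetic taxonomy
#'
#' Generates a tree-shaped hierarchy phylum..genus with globally unique
#' names ("Phy01", "Cla03", ...), assigns each genus a record quota drawn
#' from the configured range (designated singleton genera get quota 1) and
#' lays out per-leaf truth lineages with sequential accessions. Domain is
#' fixed to "Bacteria"; species is left blank.
#'
#' @param config A [sim_config()].
#' @param seed Seed; `NULL` uses the current RNG stream.
#' @return List of class `sim_taxonomy`: `genus_lineages` (matrix, one row
#'   per genus), `quotas` (named integer), `truth` (annotation matrix, one
#'   row per leaf accession).
#' @export
sample_taxonomy <- function(config = sim_config(), seed = config$seed) {
  with_seed(seed, {
    n_cla <- config$phyla * config$classes_per_phylum
    n_ord <- n_cla * config$orders_per_class
    n_fam <- n_ord * config$families_per_order
    n_gen <- n_fam * config$genera_per_family
    phy <- sprintf("Phy%02d", seq_len(config$phyla))
    cla <- sprintf("Cla%02d", seq_len(n_cla))
    ord <- sprintf("Ord%02d", seq_len(n_ord))
    fam <- sprintf("Fam%02d", seq_len(n_fam))
    gen <- sprintf("Gen%03d", seq_len(n_gen))
    lin <- cbind(
      domain = "Bacteria",
      phylum = rep(phy, each = n_gen / config$phyla),
      class = rep(cla, each = n_gen / n_cla),
      order = rep(ord, each = n_gen / n_ord),
      family = rep(fam, each = n_gen / n_fam),
      genus = gen,
      species = NA_character_)
    rownames(lin) <- gen
    n_single <- round(config$singleton_fraction * n_gen)
    singles <- sample(n_gen, n_single)
    quotas <- sample(config$seqs_per_genus[1]:config$seqs_per_genus[2],
                     n_gen, replace = TRUE)
    quotas[singles] <- 1L
    names(quotas) <- gen
    ids <- sprintf("s%05d", seq_len(sum(quotas)))
    truth <- lin[rep(seq_len(n_gen), quotas), , drop = FALSE]
    rownames(truth) <- ids
    structure(list(genus_lineages = lin, quotas = quotas, truth = truth),
              class = "sim_taxonomy")
  })
}

# Join a list of newick fragments (no trailing lengths) into one random
# bifurcating subtree, drawing a branch length per merged child.
random_join <- function(parts) {
  while (length(parts) > 1L) {
    i <- sample.int(length(parts), 2L)
    bl <- round(runif(2, 0.02, 0.2), 4)
    merged <- sprintf("(%s:%s,%s:%s)", parts[[i[1L]]], bl[[1L]],
                      parts[[i[2L]]], bl[[2L]])
    parts <- c(parts[-i], merged)
  }
  parts[[1L]]
}

#' Sample a taxonomy-consistent true tree
#'
#' Builds a random rooted bifurcating tree in which every taxon at every
#' rank is a clean clade, by recursively joining random bifurcating
#' subtrees: leaves within a genus, genera within a family, and so on up
#' to phyla at the root. By construction a purity analysis of this tree
#' reports zero impure taxa at every rank, realizing the consistency
#' assumption that the audit measures departures from.
#'
#' @param taxonomy A [sample_taxonomy()] result.
#' @param seed Seed; `NULL` uses the current RNG stream.
#' @return A `phylo` object whose tip labels are the truth accessions.
#' @export
sample_true_tree <- function(taxonomy, seed = NULL) {
  with_seed(seed, {
    truth <- taxonomy$truth
    build <- function(rows, ranks_left) {
      if (!length(ranks_left)) {
        return(random_join(as.list(rownames(truth)[rows])))
      }
      r <- ranks_left[[1L]]
      groups <- split(rows, truth[rows, r])
      random_join(lapply(groups, build, ranks_left = ranks_left[-1L]))
    }
    nwk <- paste0(build(seq_len(nrow(truth)),
                        c("phylum", "class", "order", "family", "genus")),
                  ";")
    read_newick(nwk)
  })
}

#' Evolve sequences down a tree
#'
#' The root sequence is uniform over ACGT; along each edge every site
#' mutates independently with probability `subst_prob` to one of the three
#' other bases (a single-parameter substitution model without rate
#' heterogeneity or indels; the audit computations are label- and
#' topology-driven, so a richer model would add nothing the tests could
#' detect).
#'
#' @param tree A rooted `phylo` object.
#' @param seq_length Sequence length.
#' @param subst_prob Per-site per-edge substitution probability.
#' @param seed Seed; `NULL` uses the current RNG stream.
#' @return Named character vector of leaf sequences.
#' @export
evolve_sequences <- function(tree, seq_length = 1500, subst_prob = 0.01,
                             seed = NULL) {
  with_seed(seed, {
    n <- Ntip(tree)
    root <- n + 1L
    seqs <- vector("list", n + tree$Nnode)
    seqs[[root]] <- sample.int(4L, seq_length, replace = TRUE)
    eo <- stats::reorder(tree, "cladewise")$edge
    for (k in seq_len(nrow(eo))) {
      parent <- eo[k, 1L]; child <- eo[k, 2L]
      s <- seqs[[parent]]
      hit <- which(runif(seq_length) < subst_prob)
      if (length(hit)) {
        s[hit] <- ((s[hit] - 1L + sample.int(3L, length(hit),
                                             replace = TRUE)) %% 4L) + 1L
      }
      seqs[[child]] <- s
    }
    out <- vapply(seq_len(n), function(i) {
      paste(c("A", "C", "G", "T")[seqs[[i]]], collapse = "")
    }, character(1))
    setNames(out, tree$tip.label)
  })
}

#' Perturb a tree by random leaf prune-and-regraft moves
#'
#' Each move removes a uniformly chosen leaf and reattaches it at a
#' uniformly chosen edge of the remaining tree, at a uniform position
#' along that edge. This models branching-order errors in inferred guide
#' trees; the leaf set is preserved.
#'
#' @param tree A rooted `phylo` object with at least 4 leaves.
#' @param n_moves Number of moves (>= 0).
#' @param seed Seed; `NULL` uses the current RNG stream.
#' @return List: `tree` (perturbed `phylo`) and `moves` (data frame log
#'   with the moved leaf and an example leaf below the attachment edge).
#' @export
perturb_tree <- function(tree, n_moves, seed = NULL) {
  if (n_moves < 0) stop("n_moves must be >= 0")
  if (Ntip(tree) < 4L) stop("tree must have at least 4 leaves")
  with_seed(seed, {
    log <- list()
    for (mv in seq_len(n_moves)) {
      leaf <- sample(tree$tip.label, 1L)
      pruned <- drop.tip(tree, leaf)
      e <- sample.int(nrow(pruned$edge), 1L)
      child <- pruned$edge[e, 2L]
      el <- if (is.null(pruned$edge.length)) 0.1 else pruned$edge.length[[e]]
      pos <- runif(1L, 0, el)
      below <- tips_under(pruned)[[child]][1L]
      tree <- bind.tip(pruned, leaf, edge.length = max(el, 0.05),
                       where = child, position = pos)
      log[[mv]] <- data.frame(move = mv, leaf = leaf,
                              attached_above = pruned$tip.label[[below]],
                              position = pos, stringsAsFactors = FALSE)
    }
    moves <- if (length(log)) do.call(rbind, log) else
      data.frame(move = integer(), leaf = character(),
                 attached_above = character(), position = numeric(),
                 stringsAsFactors = FALSE)
    list(tree = tree, moves = moves)
  })
}

#' Corrupt annotations at a fixed rate with ground truth
#'
#' Selects exactly `round(rate * n)` records without replacement (an exact
#' count rather than per-record Bernoulli draws, so tests can assert
#' equality) and replaces each one's lineage from a uniformly chosen rank
#' downward with the names of a different record's lineage whose name at
#' that rank differs. Corrupted annotations therefore stay inside the
#' taxonomy's existing nomenclature and are always detectable as
#' name-vs-name disagreements against a clean copy.
#'
#' @param db A [taxdb()].
#' @param rate Corruption rate in `[0, 1]`.
#' @param seed Seed; `NULL` uses the current RNG stream.
#' @param ranks Ranks eligible for corruption.
#' @param exclude Accessions that must not be corrupted (used to keep the
#'   corrupted sets of a database pair disjoint).
#' @return List: `db` (corrupted copy) and `log` (data frame `id`, `rank`,
#'   `old`, `new`).
#' @export
corrupt_annotations <- function(db, rate, seed = NULL, ranks = audit_ranks(),
                                exclude = character(0)) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  ranks <- order_ranks(check_ranks(ranks))
  with_seed(seed, {
    n <- length(db$id)
    n_corrupt <- round(rate * n)
    eligible <- which(!(db$id %in% exclude))
    if (n_corrupt > length(eligible)) {
      stop("not enough eligible records to corrupt")
    }
    chosen <- sample(eligible, n_corrupt)
    lin <- db$lineage
    all_ranks <- colnames(lin)
    log <- list()
    for (i in chosen) {
      rks <- sample(ranks)
      done <- FALSE
      for (r in rks) {
        donors <- which(!is.na(lin[, r]) &
                          (is.na(lin[i, r]) | lin[, r] != lin[i, r]) &
                          seq_len(n) != i)
        if (!length(donors)) next
        d <- if (length(donors) == 1L) donors else sample(donors, 1L)
        lower <- all_ranks[rank_level(all_ranks) >= rank_level(r)]
        old <- lin[i, r]
        lin[i, lower] <- db$lineage[d, lower]
        log[[length(log) + 1L]] <- data.frame(
          id = db$id[[i]], rank = r, old = old, new = lin[i, r],
          stringsAsFactors = FALSE)
        done <- TRUE
        break
      }
      if (!done) stop("no valid donor lineage for record ", db$id[[i]])
    }
    log <- if (length(log)) do.call(rbind, log) else
      data.frame(id = character(), rank = character(), old = character(),
                 new = character(), stringsAsFactors = FALSE)
    list(db = taxdb(db$id, db$seq, lin, db$source), log = log)
  })
}

#' Build a synthetic audit pair with full ground truth
#'
#' One truth taxonomy, tree and sequence set; two database copies sharing
#' all sequences, independently corrupted at the configured error rates
#' (disjoint corrupted sets); and two guide trees independently perturbed
#' from the truth tree. Fully deterministic under `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List of class `audit_pair`: `dbA`, `dbB`, `treeA`, `treeB`,
#'   `truth_tree`, `truth` (annotation matrix), and `ground_truth` (lists
#'   `corrupted_a`, `corrupted_b`, `moves_a`, `moves_b`).
#' @export
build_audit_pair <- function(config = sim_config()) {
  with_seed(config$seed, {
    tax <- sample_taxonomy(config, seed = NULL)
    tree <- sample_true_tree(tax, seed = NULL)
    seqs <- evolve_sequences(tree, config$seq_length, config$subst_prob,
                             seed = NULL)
    ids <- rownames(tax$truth)
    base <- taxdb(ids, seqs[ids], tax$truth, source = "truth")
    ca <- corrupt_annotations(base, config$error_rate_a, seed = NULL)
    ca$db$source <- "dbA"
    cb <- corrupt_annotations(base, config$error_rate_b, seed = NULL,
                              exclude = ca$log$id)
    cb$db$source <- "dbB"
    pa <- perturb_tree(tree, config$moves, seed = NULL)
    pb <- perturb_tree(tree, config$moves, seed = NULL)
    structure(list(dbA = ca$db, dbB = cb$db, treeA = pa$tree, treeB = pb$tree,
                   truth_tree = tree, truth = tax$truth, taxonomy = tax,
                   ground_truth = list(corrupted_a = ca$log,
                                       corrupted_b = cb$log,
                                       moves_a = pa$moves,
                                       moves_b = pb$moves),
                   config = config),
              class = "audit_pair")
  })
}
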