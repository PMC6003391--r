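# Shared fixtures: the two worked-example trees from the background theory
# (a consistent tree with a singleton genus, and a tree where two genera
# overlap), plus small database builders. Everything is built in code.

# Named lineage vector over all ranks.
make_lineage <- function(...) {
  args <- list(...)
  lin <- setNames(rep(NA_character_, length(taxaudit::tax_ranks())),
                  taxaudit::tax_ranks())
  for (r in names(args)) lin[[r]] <- args[[r]]
  lin
}

# Annotation matrix from per-id lineages given as a list.
make_ann <- function(lins) {
  do.call(rbind, lins)
}

# Consistent example tree: genera G = {g1, g2} (LCA = their cherry) and
# singleton S = {s}, all in family F. The cherry node is "g", the root "f".
fig1_fixture <- function() {
  tree <- taxaudit::read_newick("((g1:1,g2:1)g:1,s:1)f;")
  ann <- make_ann(list(
    g1 = make_lineage(domain = "Bacteria", phylum = "P", class = "C",
                      order = "O", family = "F", genus = "G"),
    g2 = make_lineage(domain = "Bacteria", phylum = "P", class = "C",
                      order = "O", family = "F", genus = "G"),
    s = make_lineage(domain = "Bacteria", phylum = "P", class = "C",
                     order = "O", family = "F", genus = "S")))
  # node numbers under ape's reading: tips in input order, then root, then
  # internals in preorder
  list(tree = tree, ann = ann,
       node_g = which(tree$node.label == "g") + ape::Ntip(tree),
       node_f = which(tree$node.label == "f") + ape::Ntip(tree))
}

# Overlapping example tree: G = {g1, g2, g3}, H = {h1, h2, h3}; the LCA of
# G ("i") is above h1 and the LCA of H ("j", the root) is above everything.
fig2_fixture <- function() {
  tree <- taxaudit::read_newick("(((g1,g2)k,(h1,g3)m)i,(h2,h3)n)j;")
  glin <- function(g) make_lineage(domain = "Bacteria", phylum = "P",
                                   class = "C", order = "O", family = "F",
                                   genus = g)
  ann <- make_ann(list(g1 = glin("G"), g2 = glin("G"), g3 = glin("G"),
                       h1 = glin("H"), h2 = glin("H"), h3 = glin("H")))
  list(tree = tree, ann = ann,
       node_i = which(tree$node.label == "i") + ape::Ntip(tree),
       node_j = which(tree$node.label == "j") + ape::Ntip(tree))
}

# Distinct random sequences (deterministic under the caller's RNG).
rand_seqs <- function(n, len = 60) {
  repeat {
    s <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, "")
    if (!anyDuplicated(s)) return(s)
  }
}

# Build a taxdb from a data.frame with columns id, seq and rank columns.
quick_db <- function(df, source = "db") {
  ranks <- intersect(taxaudit::tax_ranks(), colnames(df))
  lin <- matrix(NA_character_, nrow(df), length(taxaudit::tax_ranks()),
                dimnames = list(NULL, taxaudit::tax_ranks()))
  for (r in ranks) lin[, r] <- df[[r]]
  taxaudit::taxdb(df$id, df$seq, lin, source)
}

# A small fully annotated database of `n_per` records in each of the given
# genus lineages (list of make_lineage results), with random sequences.
lineage_db <- function(lineages, n_per = 2, len = 60, source = "db",
                       prefix = "r") {
  n <- length(lineages) * n_per
  ids <- sprintf("%s%03d", prefix, seq_len(n))
  lin <- make_ann(rep(lineages, each = n_per))
  rownames(lin) <- NULL
  taxaudit::taxdb(ids, rand_seqs(n, len), lin, source)
}
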