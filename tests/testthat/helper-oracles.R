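# Independent brute-force oracles used to validate the package's tree and
# alignment computations on small random instances. These deliberately use
# only the raw edge matrix / naive recursions, never the package internals.

# Root-to-node path via the raw edge matrix.
oracle_path <- function(tree, node) {
  parent <- integer(ape::Ntip(tree) + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  path <- node
  while (parent[node] != 0L) {
    node <- parent[node]
    path <- c(node, path)
  }
  path
}

# LCA as the deepest node common to all root-to-leaf paths.
oracle_lca <- function(tree, leaf_labels) {
  tips <- match(leaf_labels, tree$tip.label)
  paths <- lapply(tips, function(t) oracle_path(tree, t))
  common <- Reduce(intersect, paths)
  depths <- vapply(common, function(n) length(oracle_path(tree, n)), 1L)
  common[which.max(depths)]
}

# Leaves under a node: every tip whose root path passes through it.
oracle_leaves_under <- function(tree, node) {
  tips <- seq_len(ape::Ntip(tree))
  tips[vapply(tips, function(t) node %in% oracle_path(tree, t), logical(1))]
}

# Rooted triplet topology: which pair of {a,b,c} forms the cherry, i.e. has
# a strictly deeper MRCA than the other two pairs; "star" if unresolved.
oracle_triplet <- function(tree, a, b, c) {
  d <- function(x, y) length(oracle_path(tree, oracle_lca(tree, c(x, y))))
  ab <- d(a, b); ac <- d(a, c); bc <- d(b, c)
  if (ab > ac && ab > bc) return("ab")
  if (ac > ab && ac > bc) return("ac")
  if (bc > ab && bc > ac) return("bc")
  "star"
}

# Straightforward Gotoh dynamic program for ends-free overlap alignment,
# full score matrices plus traceback, written independently of the
# package's kernel. Returns score, matches, columns, identity.
oracle_align <- function(a, b, match = 1, mismatch = -2, gap_open = 10,
                         gap_ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e18
  M <- Ix <- Iy <- matrix(NEG, n + 1, m + 1)
  tM <- tX <- tY <- matrix(NA_integer_, n + 1, m + 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      amb <- A[i - 1] == "N" || B[j - 1] == "N"
      sub <- if (!amb && A[i - 1] == B[j - 1]) match else mismatch
      cand <- c(if (i == 2 || j == 2) 0 else NEG,
                M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
      w <- which.max(cand)
      M[i, j] <- cand[w] + sub
      tM[i, j] <- c(0, 1, 2, 3)[w]
      if (i > 2) {
        cand <- c(M[i - 1, j] - gap_open - gap_ext, Ix[i - 1, j] - gap_ext,
                  Iy[i - 1, j] - gap_open - gap_ext)
        w <- which.max(cand)
        Ix[i, j] <- cand[w]; tX[i, j] <- w
      }
      if (j > 2) {
        cand <- c(M[i, j - 1] - gap_open - gap_ext, Iy[i, j - 1] - gap_ext,
                  Ix[i, j - 1] - gap_open - gap_ext)
        w <- which.max(cand)
        Iy[i, j] <- cand[w]; tY[i, j] <- c(1, 3, 2)[w]
      }
    }
  }
  best <- NEG; bi <- bj <- bs <- NA
  for (j in (m + 1):2) for (s in 1:3) {
    v <- list(M, Ix, Iy)[[s]][n + 1, j]
    if (v > best) { best <- v; bi <- n + 1; bj <- j; bs <- s }
  }
  for (i in (n + 1):2) for (s in 1:3) {
    v <- list(M, Ix, Iy)[[s]][i, m + 1]
    if (v > best) { best <- v; bi <- i; bj <- m + 1; bs <- s }
  }
  i <- bi; j <- bj; s <- bs
  matches <- 0L; columns <- 0L
  repeat {
    if (s == 1) {
      amb <- A[i - 1] == "N" || B[j - 1] == "N"
      if (!amb && A[i - 1] == B[j - 1]) matches <- matches + 1L
      columns <- columns + 1L
      s2 <- tM[i, j]; i <- i - 1; j <- j - 1
      if (s2 == 0) break
      s <- s2
    } else if (s == 2) {
      columns <- columns + 1L
      s <- tX[i, j]; i <- i - 1
    } else {
      columns <- columns + 1L
      s <- tY[i, j]; j <- j - 1
    }
  }
  list(score = best, matches = matches, columns = columns,
       identity = matches / columns)
}

# Random mutated sequence pair: substitutions plus occasional short indels.
random_seq_pair <- function(len, n_sub = 3, n_indel = 1) {
  bases <- c("A", "C", "G", "T")
  x <- sample(bases, len, replace = TRUE)
  y <- x
  pos <- sample(len, min(n_sub, len))
  y[pos] <- vapply(y[pos], function(ch) sample(setdiff(bases, ch), 1), "")
  y <- unlist(strsplit(paste(y, collapse = ""), ""))
  for (q in seq_len(n_indel)) {
    if (runif(1) < 0.5 && length(y) > 4) {
      at <- sample(length(y) - 2, 1)
      y <- y[-(at:(at + 1))]
    } else {
      at <- sample(length(y), 1)
      y <- append(y, sample(bases, 2, replace = TRUE), after = at)
    }
  }
  c(paste(x, collapse = ""), paste(y, collapse = ""))
}

# Random rooted tree with labeled tips (via ape) and a random labeling of
# tips into n_taxa groups at one rank.
random_labeled_tree <- function(n_tips, n_taxa, rank = "genus") {
  tr <- ape::rtree(n_tips, tip.label = sprintf("t%02d", seq_len(n_tips)))
  ann <- matrix(NA_character_, n_tips, length(taxaudit::tax_ranks()),
                dimnames = list(tr$tip.label, taxaudit::tax_ranks()))
  ann[, rank] <- sample(sprintf("Tax%02d", seq_len(n_taxa)), n_tips,
                        replace = TRUE)
  list(tree = tr, ann = ann)
}

# Clade-set comparison: two rooted trees are isomorphic (as rooted,
# unordered trees, ignoring branch lengths) iff their sets of tip-label
# clades are equal.
clade_sets_equal <- function(t1, t2) {
  clades <- function(tr) {
    n <- ape::Ntip(tr)
    sets <- lapply((n + 1):(n + tr$Nnode), function(nd) {
      sort(tr$tip.label[oracle_leaves_under(tr, nd)])
    })
    sort(vapply(sets, paste, "", collapse = "|"))
  }
  setequal(t1$tip.label, t2$tip.label) && identical(clades(t1), clades(t2))
}

# Direct-count metric oracle given explicit per-query classes.
oracle_metrics <- function(truth, pred, ref_names) {
  known <- truth %in% ref_names
  list(N = length(truth), K = sum(known), L = sum(!known),
       TP = sum(known & !is.na(pred) & pred == truth),
       MC = sum(known & !is.na(pred) & pred != truth),
       UC = sum(known & is.na(pred)),
       OC = sum(!known & !is.na(pred)))
}
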