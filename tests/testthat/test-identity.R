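test_that("identity has the expected analytic values", {
  s <- strrep("ACGT", 25)
  expect_equal(pairwise_identity(s, s), 1.0)
  # one substitution in 100 positions, no gaps
  s2 <- paste0(substr(s, 1, 49), "T", substr(s, 51, 100))
  expect_equal(pairwise_identity(s, s2), 0.99)
  # a leading truncation is a free terminal gap: identity stays 1
  expect_equal(pairwise_identity(s, substr(s, 11, 100)), 1.0)
  # N matches nothing
  expect_equal(pairwise_identity("ACGTACGTNN", "ACGTACGTNN"), 0.8)
  expect_error(pairwise_identity("", "ACGT"), "empty")
})

test_that("identity is symmetric", {
  withr::with_seed(70, {
    for (i in 1:25) {
      p <- random_seq_pair(sample(20:60, 1), n_sub = 4, n_indel = 2)
      expect_equal(pairwise_identity(p[1], p[2]),
                   pairwise_identity(p[2], p[1]))
    }
  })
})

test_that("the alignment kernel agrees with a dynamic-programming oracle", {
  withr::with_seed(71, {
    for (i in 1:100) {
      p <- random_seq_pair(sample(15:60, 1), n_sub = sample(0:5, 1),
                           n_indel = sample(0:2, 1))
      p <- sort(p)  # the kernel canonicalizes orientation; align same way
      got <- align_overlap(p[1], p[2])
      orc <- oracle_align(p[1], p[2])
      expect_equal(got$score, orc$score, label = paste(p, collapse = " vs "))
      expect_equal(got$identity, orc$identity,
                   label = paste(p, collapse = " vs "))
    }
  })
})

test_that("alignment scores match an independent alignment library", {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  withr::with_seed(72, {
    compared <- 0
    for (i in 1:40) {
      p <- random_seq_pair(sample(20:60, 1), n_sub = sample(0:6, 1),
                           n_indel = sample(0:2, 1))
      ours <- align_overlap(p[1], p[2])$score
      ref <- Biostrings::pairwiseAlignment(p[1], p[2], type = "overlap",
                                           substitutionMatrix = mat,
                                           gapOpening = 10, gapExtension = 1,
                                           scoreOnly = TRUE)
      # the library scores an empty overlap as 0; our kernel always aligns
      # at least one column, so conventions only coincide for overlaps
      # worth keeping
      if (ref > 0) {
        compared <- compared + 1
        expect_equal(ours, ref)
      }
    }
    expect_gte(compared, 25)
  })
})

test_that("lowest common rank follows the shared-prefix rule", {
  la <- make_lineage(domain = "Bacteria", phylum = "Proteobacteria",
                     class = "Gammaproteobacteria", order = "Vibrionales",
                     family = "Vibrionaceae", genus = "Vibrio")
  lb <- la; lb[["genus"]] <- "Photobacterium"
  expect_equal(lowest_common_rank(la, lb), "family")
  # same phylum, different classes
  lc <- la; lc[["class"]] <- "Betaproteobacteria"
  lc[c("order", "family", "genus")] <- c("X", "Y", "Z")
  expect_equal(lowest_common_rank(la, lc), "phylum")
  expect_equal(lowest_common_rank(la, la), "genus")
  # disagreement at phylum: no common rank
  ld <- la; ld[["phylum"]] <- "Firmicutes"
  expect_true(is.na(lowest_common_rank(la, ld)))
  # a blank breaks sharing at and below it
  le <- la; le[["order"]] <- NA_character_
  expect_equal(lowest_common_rank(la, le), "class")
  hd <- highest_distinct_taxa(la, lc)
  expect_equal(hd$rank, "class")
  expect_setequal(c(hd$nameA, hd$nameB),
                  c("Gammaproteobacteria", "Betaproteobacteria"))
})

test_that("lcr is NA exactly when the top-rank names differ or are blank", {
  ranks <- audit_ranks()
  withr::with_seed(73, {
    for (i in 1:50) {
      mk <- function() {
        v <- make_lineage()
        v[ranks] <- sample(c("A", "B", NA), length(ranks), replace = TRUE)
        v
      }
      la <- mk(); lb <- mk()
      lcr <- lowest_common_rank(la, lb)
      top_shared <- !is.na(la[["phylum"]]) && !is.na(lb[["phylum"]]) &&
        la[["phylum"]] == lb[["phylum"]]
      expect_equal(is.na(lcr), !top_shared)
    }
  })
})

test_that("a planted identical cross-phylum pair tops the outlier scan", {
  withr::with_seed(74, {
    db <- lineage_db(list(
      make_lineage(phylum = "P1", class = "C1", order = "O1",
                   family = "F1", genus = "G1"),
      make_lineage(phylum = "P1", class = "C2", order = "O2",
                   family = "F2", genus = "G2"),
      make_lineage(phylum = "P2", class = "C3", order = "O3",
                   family = "F3", genus = "G3")), n_per = 2, len = 80)
    # plant: two identical sequences annotated in different classes of P1
    planted <- rand_seqs(1, 80)
  })
  db2 <- taxdb(c(db$id, "outA", "outB"), c(db$seq, planted, planted),
               rbind(db$lineage, db$lineage[c(1, 3), ]), "db")
  db2$lineage[c("outA", "outB"), "phylum"] <- "P1"
  db2$lineage["outB", c("class", "order", "family", "genus")] <-
    c("C2", "O2", "F2", "G2")
  db2$lineage["outA", c("class", "order", "family", "genus")] <-
    c("C1", "O1", "F1", "G1")
  sc <- scan_outliers(db2, min_shared_kmers = 0)
  top_phylum <- sc[sc$lcr == "phylum", ][1, ]
  expect_setequal(c(top_phylum$idA, top_phylum$idB), c("outA", "outB"))
  expect_equal(top_phylum$identity, 1.0)
  expect_equal(top_phylum$distinct_rank, "class")
})

test_that("identities are non-increasing within each LCR bucket and the
           prefilter reproduces the exhaustive scan", {
  # homologous sequences, as in a real marker-gene database: evolved down
  # a random tree so every pair is alignable end to end
  withr::with_seed(75, {
    lins <- list(
      make_lineage(phylum = "P1", class = "C1", order = "O1",
                   family = "F1", genus = "G1"),
      make_lineage(phylum = "P1", class = "C1", order = "O1",
                   family = "F1", genus = "G2"),
      make_lineage(phylum = "P1", class = "C1", order = "O2",
                   family = "F2", genus = "G3"),
      make_lineage(phylum = "P1", class = "C2", order = "O3",
                   family = "F3", genus = "G4"))
    tr <- ape::rtree(8, tip.label = sprintf("s%d", 1:8))
    seqs <- evolve_sequences(tr, seq_length = 150, subst_prob = 0.01)
    db <- taxdb(sprintf("s%d", 1:8), seqs[sprintf("s%d", 1:8)],
                make_ann(c(lins, lins)), "db")
  })
  exhaustive <- scan_outliers(db, min_shared_kmers = 0)
  filtered <- scan_outliers(db, min_shared_kmers = 8)
  for (r in unique(exhaustive$lcr)) {
    ids <- exhaustive$identity[exhaustive$lcr == r]
    expect_true(all(diff(ids) <= 1e-12))
  }
  # on an alignable database the prefilter reproduces the exhaustive scan
  expect_equal(as.data.frame(filtered), as.data.frame(exhaustive))
  # all sequences in one genus: nothing to report
  one <- db
  one$lineage[, c("phylum", "class", "order", "family", "genus")] <-
    matrix(rep(c("P", "C", "O", "F", "G"), each = 8), nrow = 8)
  expect_equal(nrow(scan_outliers(one, min_shared_kmers = 0)), 0)
})

test_that("top-hit identity distribution bins queries correctly", {
  withr::with_seed(76, {
    db <- lineage_db(list(make_lineage(genus = "G1"),
                          make_lineage(genus = "G2")), n_per = 2, len = 100)
  })
  # self-reference with duplicate sequences under other accessions
  dup <- taxdb(paste0(db$id, "x"), db$seq, db$lineage, "dup")
  th <- top_hit_identity_distribution(db, dup)
  expect_equal(th$count[th$bin_low == 99], length(db))
  expect_equal(sum(th$count), length(db))
  expect_true(all(attr(th, "top_hits") == 1))
  # a single query against three references: max identity wins
  q <- db[1]
  hits <- vapply(seq_along(db$id), function(j)
    pairwise_identity(q$seq[1], db$seq[j]), numeric(1))
  th2 <- top_hit_identity_distribution(q, db)
  # the query's own accession is excluded, its duplicate sequence is not
  expect_equal(unname(attr(th2, "top_hits")[1]), max(hits[-1]))
  # determinism
  th3 <- top_hit_identity_distribution(q, db)
  expect_identical(th2, th3)
})
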