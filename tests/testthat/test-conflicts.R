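# Lineages used across the conflict tests.
strep <- function() make_lineage(domain = "Bacteria", phylum = "Firmicutes",
                                 class = "Bacilli", order = "Lactobacillales",
                                 family = "Streptococcaceae",
                                 genus = "Streptococcus")
xanth <- function() make_lineage(domain = "Bacteria",
                                 phylum = "Proteobacteria",
                                 class = "Gammaproteobacteria",
                                 order = "Xanthomonadales",
                                 family = "Xanthomonadaceae",
                                 genus = "Xanthomonas")
gamma_fam <- function(fam, gen) {
  make_lineage(domain = "Bacteria", phylum = "Proteobacteria",
               class = "Gammaproteobacteria", order = "Vibrionales",
               family = fam, genus = gen)
}

# Pair of databases holding the same sequences with given lineage lists.
db_pair <- function(linA, linB, len = 60) {
  n <- length(linA)
  seqs <- rand_seqs(n, len)
  ids <- sprintf("q%03d", seq_len(n))
  list(A = taxdb(ids, seqs, make_ann(linA), "A"),
       B = taxdb(paste0(ids, "b"), seqs, make_ann(linB), "B"))
}

test_that("find_identical matches sequences, not accessions", {
  withr::with_seed(10, {
    shared <- rand_seqs(5)
    privA <- rand_seqs(3)
    privB <- rand_seqs(2)
  })
  lin <- make_ann(rep(list(strep()), 8))
  dbA <- taxdb(sprintf("a%d", 1:8), c(shared, privA), lin, "A")
  dbB <- taxdb(sprintf("b%d", 1:7), c(shared, privB), lin[1:7, ], "B")
  hits <- find_identical(dbA, dbB)
  expect_equal(nrow(hits), 5)
  expect_setequal(hits$idA, sprintf("a%d", 1:5))
  # self-join over unique sequences gives one pair per record
  expect_equal(nrow(find_identical(dbA, dbA)), 8)
  # disjoint databases share nothing
  expect_equal(nrow(find_identical(dbA[6:8], dbB[6:7])), 0)
})

test_that("conflicts are classified at the highest conflicted rank", {
  withr::with_seed(11, {
    # both family names occur in both databases (via q003), as required
    # for a common-nomenclature disagreement
    p <- db_pair(list(strep(), gamma_fam("Pseudoalteromonadaceae", "X"),
                      gamma_fam("Vibrionaceae", "V"), strep()),
                 list(xanth(), gamma_fam("Vibrionaceae", "Y"),
                      gamma_fam("Pseudoalteromonadaceae", "V"), strep()))
  })
  nom <- common_nomenclature(p$A, p$B)
  linA <- db_lineages(p$A, tax_ranks())
  linB <- db_lineages(p$B, tax_ranks())

  # phylum-level: Streptococcus/Firmicutes vs Xanthomonas/Proteobacteria
  cc <- classify_conflict(linA["q001", ], linB["q001b", ], nom)
  expect_true(cc$conflicted)
  expect_equal(cc$highest_rank, "phylum")
  expect_equal(cc$kind, "name_vs_name")

  # family-level: higher ranks equal, families differ
  cc <- classify_conflict(linA["q002", ], linB["q002b", ], nom)
  expect_equal(cc$highest_rank, "family")

  # identical lineages do not conflict
  cc <- classify_conflict(linA["q004", ], linB["q004b", ], nom)
  expect_false(cc$conflicted)
  expect_true(is.na(cc$highest_rank))
})

test_that("a blank genus against a common name is a blank-vs-name conflict", {
  salm <- make_lineage(domain = "Bacteria", phylum = "Proteobacteria",
                       class = "Gammaproteobacteria",
                       order = "Enterobacteriales",
                       family = "Enterobacteriaceae", genus = "Salmonella")
  blank <- salm
  blank[["genus"]] <- NA_character_
  withr::with_seed(12, {
    p <- db_pair(list(blank, salm), list(salm, salm))
  })
  nom <- common_nomenclature(p$A, p$B)
  cc <- classify_conflict(db_lineages(p$A, tax_ranks())[1, ],
                          db_lineages(p$B, tax_ranks())[1, ], nom)
  expect_true(cc$conflicted)
  expect_equal(cc$highest_rank, "genus")
  expect_equal(cc$kind, "blank_vs_name")
})

test_that("conflict classification is symmetric up to which side is blank", {
  withr::with_seed(13, {
    p <- db_pair(list(strep(), gamma_fam("FamQ", "GenQ")),
                 list(xanth(), gamma_fam("FamR", "GenR")))
  })
  nom <- common_nomenclature(p$A, p$B)
  linA <- db_lineages(p$A, tax_ranks())
  linB <- db_lineages(p$B, tax_ranks())
  for (i in 1:2) {
    f <- classify_conflict(linA[i, ], linB[i, ], nom)
    r <- classify_conflict(linB[i, ], linA[i, ], nom)
    expect_equal(f$conflicted, r$conflicted)
    expect_equal(f$highest_rank, r$highest_rank)
    expect_equal(f$kind, r$kind)
    if (f$conflicted) {
      # a conflicted pair differs at one or more ranks
      expect_true(any(f$detail$nameA != f$detail$nameB, na.rm = TRUE) ||
                    any(is.na(f$detail$nameA) != is.na(f$detail$nameB)))
    }
  }
})

test_that("tabulation counts each sequence once at its highest rank", {
  # 10 shared sequences: 3 genus conflicts, 1 phylum conflict, 6 clean
  linA <- c(rep(list(strep()), 7),
            lapply(c("GenA", "GenB", "GenC"), function(g)
              gamma_fam("FamShared", g)))
  linB <- c(list(xanth()), rep(list(strep()), 6),
            lapply(c("GenB", "GenC", "GenA"), function(g)
              gamma_fam("FamShared", g)))
  withr::with_seed(14, p <- db_pair(linA, linB))
  aud <- audit_conflicts(p$A, p$B)
  tab <- aud$table
  expect_equal(tab$conflicts[tab$rank == "genus"], 3)
  expect_equal(tab$conflicts[tab$rank == "phylum"], 1)
  expect_equal(tab$conflicts[tab$rank == "Total"], 4)
  expect_equal(tab$pct[tab$rank == "Total"], 40)
  expect_equal(aud$denominator, 10)
  expect_equal(aud$lower_bound, 0.4)
  # per-sequence accounting: rank rows sum to the total
  expect_equal(sum(tab$conflicts[tab$rank != "Total"]),
               sum(aud$records$conflicted))
})

test_that("error rate lower bound is the conflict fraction", {
  expect_equal(error_rate_lower_bound(249490, 732048), 249490 / 732048)
  expect_equal(error_rate_lower_bound(0, 1000), 0)
  expect_error(error_rate_lower_bound(5, 0), "positive")
  expect_error(error_rate_lower_bound(10, 5), "between")
})

test_that("planted corruption is recovered exactly by the audit", {
  cfg <- sim_config(phyla = 2, classes_per_phylum = 2, orders_per_class = 2,
                    families_per_order = 2, genera_per_family = 2,
                    seq_length = 200, subst_prob = 0.03,
                    error_rate_a = 0.1, error_rate_b = 0, moves = 0,
                    seed = 15)
  pair <- build_audit_pair(cfg)
  n_planted <- nrow(pair$ground_truth$corrupted_a)
  expect_equal(n_planted, round(0.1 * length(pair$dbA)))
  aud <- audit_conflicts(pair$dbA, pair$dbB)
  expect_equal(sum(aud$records$conflicted), n_planted)
  # per-rank: the planted corruption rank is the highest conflicted rank
  planted_by_rank <- table(pair$ground_truth$corrupted_a$rank)
  tab <- aud$table
  for (r in names(planted_by_rank)) {
    expect_equal(tab$conflicts[tab$rank == r],
                 unname(planted_by_rank[[r]]), label = r)
  }
})

test_that("one-sided planted error rates are recovered by the lower bound", {
  bounds <- vapply(1:20, function(s) {
    cfg <- sim_config(phyla = 2, classes_per_phylum = 1, orders_per_class = 2,
                      families_per_order = 2, genera_per_family = 2,
                      seq_length = 150, subst_prob = 0.04,
                      error_rate_a = 0.1, error_rate_b = 0, moves = 0,
                      seed = 100 + s)
    pair <- build_audit_pair(cfg)
    audit_conflicts(pair$dbA, pair$dbB)$lower_bound
  }, numeric(1))
  # every conflict is a planted one-database error here, so the bound
  # matches the planted rate up to quota rounding
  expect_true(all(abs(bounds - 0.1) < 0.02))
  expect_lt(abs(mean(bounds) - 0.1), 0.01)
})

test_that("two-sided planted errors respect the lower-bound inequalities", {
  eA <- 0.15; eB <- 0.1
  res <- vapply(1:20, function(s) {
    cfg <- sim_config(phyla = 2, classes_per_phylum = 1, orders_per_class = 2,
                      families_per_order = 2, genera_per_family = 2,
                      seq_length = 150, subst_prob = 0.04,
                      error_rate_a = eA, error_rate_b = eB, moves = 0,
                      seed = 200 + s)
    pair <- build_audit_pair(cfg)
    c(bound = audit_conflicts(pair$dbA, pair$dbB)$lower_bound,
      n = length(pair$dbA))
  }, numeric(2))
  bounds <- res["bound", ]
  n <- res["n", ]
  sigma <- sqrt((eA + eB) * (1 - eA - eB) / n)
  # the generator plants exact counts round(e * n), so the realized sum of
  # planted rates can exceed eA + eB by at most 1/n of rounding
  expect_true(all(bounds <= eA + eB + 1 / n + 1e-9))
  expect_true(all(bounds >= max(eA, eB) - 3 * sigma))
})
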