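#' Pairwise sequence identity
#'
#' Global (ends-free) alignment identity between two nucleotide sequences:
#' matches divided by alignment columns, with terminal gap columns
#' excluded, the convention used for near-full-length 16S comparisons.
#' Alignment parameters only affect identity through the column count of
#' the optimal alignment. `N` matches nothing. Symmetric in its arguments.
#'
#' `align_overlap()` exposes the full alignment result (score, matches,
#' columns, identity).
#'
#' @param seqA,seqB Sequences (normalized on entry).
#' @param match,mismatch Substitution scores.
#' @param gap_open,gap_ext Affine gap penalties (positive costs); a gap of
#'   length L costs `gap_open + L * gap_ext`.
#' @return `pairwise_identity`: a fraction in `[0, 1]`.
#' @examples
#' pairwise_identity(strrep("ACGT", 25), strrep("ACGT", 25))  # 1
#' @export
pairwise_identity <- function(seqA, seqB, match = 1, mismatch = -2,
                              gap_open = 10, gap_ext = 1) {
  align_overlap(seqA, seqB, match, mismatch, gap_open, gap_ext)$identity
}

#' @rdname pairwise_identity
#' @export
align_overlap <- function(seqA, seqB, match = 1, mismatch = -2,
                          gap_open = 10, gap_ext = 1) {
  a <- normalize_sequence(seqA)
  b <- normalize_sequence(seqB)
  # canonical argument order: co-optimal alignments can differ in identity,
  # and the tie-broken traceback depends on which sequence comes first
  if (a > b) {
    t <- a; a <- b; b <- t
  }
  .align_overlap_cpp(a, b, match, mismatch, gap_open, gap_ext)
}

#' Lowest common rank of two lineages
#'
#' The lowest configured rank at which both lineages carry the same
#' non-blank name, with agreement at all higher configured ranks; two
#' sequences in different genera of the same family have LCR family. A
#' blank or disagreement at a rank breaks sharing at and below it.
#'
#' @param lineageA,lineageB Named character vectors (rank -> name).
#' @param ranks Configured ranks.
#' @return The rank name, or `NA` when the lineages disagree already at
#'   the highest configured rank.
#' @export
lowest_common_rank <- function(lineageA, lineageB, ranks = audit_ranks()) {
  ranks <- order_ranks(check_ranks(ranks))
  lcr <- NA_character_
  for (r in ranks) {
    a <- lineageA[[r]]
    b <- lineageB[[r]]
    if (is.na(a) || is.na(b) || a != b) break
    lcr <- r
  }
  lcr
}

# Highest rank at which the two lineages are assigned to distinct taxa
# (first top-down rank where both are named and differ), with the names.
highest_distinct_taxa <- function(lineageA, lineageB, ranks = audit_ranks()) {
  ranks <- order_ranks(check_ranks(ranks))
  for (r in ranks) {
    a <- lineageA[[r]]
    b <- lineageB[[r]]
    if (!is.na(a) && !is.na(b) && a != b) {
      return(list(rank = r, nameA = a, nameB = b))
    }
  }
  list(rank = NA_character_, nameA = NA_character_, nameB = NA_character_)
}

# Candidate pairs sharing at least min_shared distinct k-mers, as a
# two-column matrix of record indices. min_shared = 0 gives all pairs.
kmer_candidate_pairs <- function(seqs, k = 16, min_shared = 8) {
  n <- length(seqs)
  if (n < 2L) return(matrix(integer(0), ncol = 2))
  all_pairs <- t(utils::combn(n, 2L))
  if (min_shared <= 0) return(all_pairs)
  words <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    unique(substring(s, 1:(L - k + 1L), k:L))
  })
  counts <- new.env(hash = TRUE, parent = emptyenv())
  idx <- split(rep(seq_len(n), lengths(words)), unlist(words))
  for (grp in idx) {
    if (length(grp) < 2L) next
    pr <- utils::combn(grp, 2L)
    for (q in seq_len(ncol(pr))) {
      key <- paste0(pr[1L, q], "_", pr[2L, q])
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    }
  }
  keys <- ls(counts)
  hit <- keys[vapply(keys, function(k2) counts[[k2]] >= min_shared, logical(1))]
  if (!length(hit)) return(matrix(integer(0), ncol = 2))
  do.call(rbind, lapply(strsplit(hit, "_", fixed = TRUE),
                        function(v) as.integer(v)))
}

#' Scan a database for high-identity outlier pairs
#'
#' Finds, for each lowest common rank (LCR) from phylum down to the rank
#' above the lowest configured one, the sequence pairs with the highest
#' pairwise identity. A high identity combined with a high LCR (e.g. two
#' nearly identical sequences that share only their phylum) indicates a
#' likely annotation error. Pairs sharing the lowest configured rank
#' (genus) are not outliers and pairs disagreeing already at the highest
#' rank are skipped. Candidate pairs are prefiltered by shared distinct
#' k-mer count before alignment; set `min_shared_kmers = 0` for a fully
#' exhaustive scan.
#'
#' @param db A [taxdb()].
#' @param max_pairs_per_lcr Hits reported per LCR.
#' @param min_shared_kmers Prefilter threshold (distinct shared k-mers).
#' @param k Prefilter word length.
#' @param ranks Configured ranks.
#' @inheritParams pairwise_identity
#' @return Object of class `outlier_scan`: data frame with columns `lcr`,
#'   `idA`, `idB`, `identity`, `distinct_rank`, `nameA`, `nameB`, sorted by
#'   LCR (highest first) then identity (descending).
#' @export
scan_outliers <- function(db, max_pairs_per_lcr = 10, min_shared_kmers = 8,
                          k = 16, ranks = audit_ranks(), match = 1,
                          mismatch = -2, gap_open = 10, gap_ext = 1) {
  ranks <- order_ranks(check_ranks(ranks))
  lcr_levels <- ranks[-length(ranks)]
  lin <- db_lineages(db, ranks)
  cand <- kmer_candidate_pairs(db$seq, k = k, min_shared = min_shared_kmers)
  rows <- list()
  if (nrow(cand)) {
    for (q in seq_len(nrow(cand))) {
      i <- cand[q, 1L]; j <- cand[q, 2L]
      r <- lowest_common_rank(lin[i, ], lin[j, ], ranks)
      if (is.na(r) || !(r %in% lcr_levels)) next
      hd <- highest_distinct_taxa(lin[i, ], lin[j, ], ranks)
      idy <- pairwise_identity(db$seq[[i]], db$seq[[j]], match, mismatch,
                               gap_open, gap_ext)
      rows[[length(rows) + 1L]] <- data.frame(
        lcr = r, idA = db$id[[i]], idB = db$id[[j]], identity = idy,
        distinct_rank = hd$rank, nameA = hd$nameA, nameB = hd$nameB,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lcr = character(), idA = character(), idB = character(),
               identity = numeric(), distinct_rank = character(),
               nameA = character(), nameB = character(),
               stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(lcr_levels, function(r) {
    sub <- out[out$lcr == r, , drop = FALSE]
    sub <- sub[order(-sub$identity, sub$idA, sub$idB), , drop = FALSE]
    head(sub, max_pairs_per_lcr)
  }))
  rownames(out) <- NULL
  structure(out, class = c("outlier_scan", "data.frame"))
}

#' @export
print.outlier_scan <- function(x, ...) {
  if (!nrow(x)) {
    cat("No high-identity outliers found\n")
    return(invisible(x))
  }
  d <- data.frame(`%Id` = sprintf("%.1f", 100 * x$identity), LCR = x$lcr,
                  Accessions = paste(x$idA, x$idB, sep = " / "),
                  `Highest distinct taxa` = paste(x$nameA, x$nameB, sep = " / "),
                  check.names = FALSE)
  print(d, row.names = FALSE)
  invisible(x)
}

#' Top-hit identity distribution
#'
#' For each query, the top-hit identity is the maximum pairwise identity
#' over all reference records with a different accession (duplicate
#' sequences under other accessions are deliberately retained: the shape
#' of the distribution near 100% depends on them). Counts are binned at
#' 1-percentage-point steps `[x, x+1)` with 100% included in the final
#' closed bin.
#'
#' @param queries,reference [taxdb()] objects.
#' @inheritParams pairwise_identity
#' @return Object of class `thid`: data frame `bin_low`, `count`, with the
#'   per-query top-hit identities in attribute `top_hits`.
#' @export
top_hit_identity_distribution <- function(queries, reference, match = 1,
                                          mismatch = -2, gap_open = 10,
                                          gap_ext = 1) {
  if (!length(reference$id)) stop("reference must be non-empty")
  top <- rep(NA_real_, length(queries$id))
  for (i in seq_along(queries$id)) {
    other <- which(reference$id != queries$id[[i]])
    if (!length(other)) next
    top[[i]] <- max(vapply(other, function(j) {
      pairwise_identity(queries$seq[[i]], reference$seq[[j]], match,
                        mismatch, gap_open, gap_ext)
    }, numeric(1)))
  }
  names(top) <- queries$id
  pct <- 100 * top[!is.na(top)]
  bin <- pmin(floor(pct), 99)
  counts <- tabulate(bin + 1L, nbins = 100L)
  structure(data.frame(bin_low = 0:99, count = counts),
            top_hits = top, class = c("thid", "data.frame"))
}
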