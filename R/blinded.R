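#' Blinded query split between two database versions
#'
#' Returns the records of the newer database whose normalized sequence
#' does not occur in the older one. When the older version is used as the
#' classifier reference, the newer version's annotations of these new
#' sequences are an authoritative truth standard that the classifier has
#' never seen: a blinded test.
#'
#' @param old_db,new_db [taxdb()] objects (older and newer versions).
#' @return A [taxdb()] with the new records (annotations from `new_db`).
#' @export
blinded_split <- function(old_db, new_db) {
  new_db[!(new_db$seq %in% old_db$seq)]
}

# Distinct k-words of one sequence.
seq_words <- function(s, k) {
  L <- nchar(s)
  if (L < k) stop("query shorter than word length k = ", k)
  unique(substring(s, 1:(L - k + 1L), k:L))
}

#' Train the word-frequency classifier on a reference database
#'
#' Builds the per-genus k-word profile used by [nbc_classify()]: for each
#' genus, the number of reference sequences containing each distinct
#' k-word, the sequence count, and the genus's representative lineage (the
#' most frequent full lineage among its records, ties lexicographic).
#' Records blank at genus are excluded.
#'
#' @param reference A [taxdb()].
#' @param k Word length.
#' @return Object of class `nbc_reference`.
#' @export
nbc_train <- function(reference, k = 8) {
  lin <- db_lineages(reference, tax_ranks())
  genus <- lin[, "genus"]
  keep <- which(!is.na(genus))
  if (!length(keep)) stop("reference has no genus-annotated records")
  genera <- sort(unique(genus[keep]))
  words <- lapply(reference$seq[keep], seq_words, k = k)
  by_genus <- split(seq_along(keep), genus[keep])
  counts <- lapply(by_genus, function(ix) table(unlist(words[ix])))
  n_seqs <- vapply(by_genus, length, 1L)
  # majority full lineage, ties lexicographic
  lineages <- lapply(by_genus, function(ix) {
    rows <- lin[keep[ix], , drop = FALSE]
    key <- apply(rows, 1L, paste, collapse = "\r")
    tab <- table(key)
    best <- names(tab)[which.max(tab)]  # table names are sorted: ties lexicographic
    rows[match(best, key), ]
  })
  structure(list(genera = genera, counts = counts[genera],
                 n_seqs = n_seqs[genera], lineages = lineages[genera],
                 k = k),
            class = "nbc_reference")
}

#' Word-frequency (naive Bayes) taxonomy classifier
#'
#' A stand-in implementation of the familiar k-word naive Bayes classifier
#' with bootstrap confidence, sufficient to exercise the blinded-test
#' pipeline end to end; parity with any external classifier build is not a
#' goal. The genus score of a query is the sum over the query's distinct
#' k-words of the log smoothed within-genus word frequency
#' `(n_g(w) + 0.5) / (N_g + 1)`; the winning genus contributes its full
#' reference lineage as the raw prediction. Each of `B` bootstrap
#' replicates rescores a random subsample of `ceiling(W/8)` of the query's
#' `W` distinct words; per-rank confidence is the fraction of replicates
#' whose winner agrees with the raw prediction at that rank, and ranks
#' below the confidence cutoff are blanked. Genus-score ties break to the
#' lexicographically smallest genus, so output is deterministic under a
#' seed.
#'
#' @param query A sequence string, or a [taxdb()] of queries.
#' @param reference A [taxdb()] or a prebuilt [nbc_train()] profile.
#' @param k Word length.
#' @param B Bootstrap replicates.
#' @param conf_cutoff Confidence below which a rank is blanked.
#' @param seed Seed for the bootstrap subsampling.
#' @return For a single query, a list with `lineage` (named character
#'   vector, blanked below the cutoff), `confidence` (named numeric),
#'   `genus` (raw winner). For a `taxdb`, a list with matrices `lineage`
#'   and `confidence` (rows = query accessions).
#' @export
nbc_classify <- function(query, reference, k = 8, B = 100, conf_cutoff = 0.8,
                         seed = NULL) {
  ref <- if (inherits(reference, "nbc_reference")) reference
         else nbc_train(reference, k)
  if (inherits(query, "taxdb")) {
    res <- with_seed(seed, lapply(query$seq, nbc_classify_one, ref = ref,
                                  B = B, conf_cutoff = conf_cutoff))
    lineage <- do.call(rbind, lapply(res, `[[`, "lineage"))
    confidence <- do.call(rbind, lapply(res, `[[`, "confidence"))
    rownames(lineage) <- rownames(confidence) <- query$id
    return(list(lineage = lineage, confidence = confidence,
                genus = vapply(res, `[[`, character(1), "genus")))
  }
  with_seed(seed, nbc_classify_one(normalize_sequence(query), ref, B,
                                   conf_cutoff))
}

nbc_classify_one <- function(seq, ref, B, conf_cutoff) {
  w <- seq_words(seq, ref$k)
  W <- length(w)
  G <- length(ref$genera)
  logp <- matrix(0, nrow = G, ncol = W)
  for (g in seq_len(G)) {
    ng <- as.numeric(ref$counts[[g]][w])
    ng[is.na(ng)] <- 0
    logp[g, ] <- log((ng + 0.5) / (ref$n_seqs[[g]] + 1))
  }
  winner <- which.max(rowSums(logp))  # first max: lexicographic tie-break
  raw <- ref$lineages[[winner]]
  m <- ceiling(W / 8)
  agree <- matrix(0L, nrow = B, ncol = length(raw))
  for (b in seq_len(B)) {
    idx <- sample.int(W, m)
    wb <- which.max(rowSums(logp[, idx, drop = FALSE]))
    lb <- ref$lineages[[wb]]
    agree[b, ] <- (!is.na(lb) & !is.na(raw) & lb == raw) |
      (is.na(lb) & is.na(raw))
  }
  confidence <- setNames(colMeans(agree), names(raw))
  out <- raw
  out[confidence < conf_cutoff] <- NA_character_
  list(lineage = out, confidence = confidence, genus = ref$genera[[winner]])
}

#' Blinded-test prediction metrics
#'
#' Scores predicted lineages against a truth standard, per rank. A query
#' is *known* at a rank when its true name occurs in the reference's name
#' set at that rank, otherwise *novel*; queries with blank truth at a rank
#' are excluded from that rank's totals. Known queries split into true
#' positives (prediction equals truth), misclassifications (non-blank
#' wrong name) and under-classifications (blank prediction). A novel query
#' with a non-blank prediction is an over-classification; a novel query
#' left blank counts as no error. Rates divide each error count by the
#' number of opportunities: TPR = TP/K, MCR = MC/K, UCR = UC/K,
#' OCR = OC/L, and Acc = TP/(K + OC). TPR + MCR + UCR = 1 by construction
#' whenever K > 0.
#'
#' @param predictions Matrix of predicted names (rows = query accessions,
#'   columns = ranks), e.g. `nbc_classify(...)$lineage`, or a list with a
#'   `lineage` element.
#' @param truth A [taxdb()] or annotation matrix with the true lineages.
#' @param reference The reference database (its name sets define "known").
#' @param ranks Ranks to score.
#' @return Object of class `metric_set`: data frame with one row per rank
#'   and columns `rank`, `N`, `K`, `L`, `TP`, `MC`, `OC`, `UC`, `TPR`,
#'   `MCR`, `OCR`, `UCR`, `Acc` (rates as fractions, `NA` when undefined).
#' @export
score_predictions <- function(predictions, truth, reference,
                              ranks = audit_ranks()) {
  ranks <- order_ranks(check_ranks(ranks))
  if (is.list(predictions) && !is.null(predictions$lineage)) {
    predictions <- predictions$lineage
  }
  truth <- as_annotations(truth, tax_ranks())
  ids <- rownames(predictions)
  if (is.null(ids) || !all(ids %in% rownames(truth))) {
    stop("every query must have a truth lineage")
  }
  ref_names <- name_rank_table(reference, ranks)
  rows <- lapply(ranks, function(r) {
    tr <- truth[ids, r]
    pr <- if (r %in% colnames(predictions)) predictions[, r] else
      rep(NA_character_, length(ids))
    keep <- !is.na(tr)
    tr <- tr[keep]; pr <- pr[keep]
    known <- tr %in% ref_names$name[ref_names$rank == r]
    TP <- sum(known & !is.na(pr) & pr == tr)
    MC <- sum(known & !is.na(pr) & pr != tr)
    UC <- sum(known & is.na(pr))
    OC <- sum(!known & !is.na(pr))
    K <- sum(known); N <- length(tr); L <- N - K
    data.frame(rank = r, N = N, K = K, L = L, TP = TP, MC = MC, OC = OC,
               UC = UC,
               TPR = if (K > 0) TP / K else NA_real_,
               MCR = if (K > 0) MC / K else NA_real_,
               OCR = if (L > 0) OC / L else NA_real_,
               UCR = if (K > 0) UC / K else NA_real_,
               Acc = if (K + OC > 0) TP / (K + OC) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  structure(out, class = c("metric_set", "data.frame"))
}

#' @export
print.metric_set <- function(x, ...) {
  p <- function(v) ifelse(is.na(v), "-", sprintf("%.1f", 100 * v))
  d <- data.frame(Rank = x$rank, `TPR (%)` = p(x$TPR), `MCR (%)` = p(x$MCR),
                  `OCR (%)` = p(x$OCR), `UCR (%)` = p(x$UCR),
                  `Acc (%)` = p(x$Acc), check.names = FALSE)
  print(d, row.names = FALSE)
  invisible(x)
}
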