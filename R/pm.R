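# Proximity-matrix (nearest-neighbour similarity) T-number classifier.

new_similarity_matrix <- function(ids) {
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 100
  class(m) <- c("similarity_matrix", class(m))
  m
}

#' Load a pairwise similarity matrix from blast tabular output
#'
#' Reads the standard 12-column tabular dialect (`qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore`),
#' drops rows with e-value above 0.001, uses percent identity as the
#' similarity, and symmetrizes by taking the maximum when several scores
#' exist for a pair.
#'
#' @param path Path to a blast tabular file (no header).
#' @param evalue_max Maximum e-value kept (default 0.001).
#' @param ids Optional full id set for the matrix dimensions (ids with no
#'   surviving hits otherwise drop out).
#' @return A `similarity_matrix`: numeric matrix in [0, 100] with `NA`
#'   where no alignment was reported; `sim[x, x] = 100`.
#' @export
load_similarity <- function(path, evalue_max = 0.001, ids = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  nf <- vapply(strsplit(lines, "\t", fixed = TRUE), length, integer(1))
  bad <- which(nf != 12)
  if (length(bad)) {
    stop("malformed blast tabular row at line ", bad[1], ": expected 12 ",
         "tab-separated columns, found ", nf[bad[1]])
  }
  df <- utils::read.table(text = lines, sep = "\t",
                          col.names = c("qseqid", "sseqid", "pident",
                                        "length", "mismatch", "gapopen",
                                        "qstart", "qend", "sstart", "send",
                                        "evalue", "bitscore"),
                          stringsAsFactors = FALSE)
  df <- df[df$evalue <= evalue_max, , drop = FALSE]
  all_ids <- if (is.null(ids)) unique(c(df$qseqid, df$sseqid)) else ids
  m <- new_similarity_matrix(all_ids)
  for (r in seq_len(nrow(df))) {
    a <- df$qseqid[r]; b <- df$sseqid[r]
    if (!(a %in% all_ids) || !(b %in% all_ids)) next
    v <- df$pident[r]
    cur <- m[a, b]
    if (is.na(cur) || v > cur) {
      m[a, b] <- v; m[b, a] <- v
    }
  }
  diag(m) <- 100
  m
}

#' Pairwise percent identity by local alignment
#'
#' Self-contained alternative to external blastp output: Smith-Waterman
#' local alignment with BLOSUM62 scoring and affine gap penalties
#' (open 11, extend 1); similarity is percent identity over the local
#' alignment length. Alignments are screened with a Karlin-Altschul
#' e-value computed from the raw score (gapped BLOSUM62 constants
#' lambda = 0.267, K = 0.041, search space = product of the two sequence
#' lengths); pairs above `evalue_max` are recorded as absent, mirroring
#' the e-value filter applied to external blast tabular input and
#' suppressing spurious short perfect matches. This approximates, but
#' does not exactly reproduce, blastp `pident`.
#'
#' @param seqs Named character vector (or `AAStringSet`) of amino-acid
#'   sequences; at least 2, all non-empty.
#' @param evalue_max Maximum e-value for a pair to be recorded
#'   (default 0.001).
#' @return A `similarity_matrix`. The number of alignments performed
#'   (n(n-1)/2, quadratic in the library size) is recorded in attribute
#'   `n_alignments`.
#' @export
align_similarity <- function(seqs, evalue_max = 0.001) {
  if (length(seqs) < 2) stop("need at least 2 sequences")
  if (is.character(seqs) && is.null(names(seqs))) {
    names(seqs) <- paste0("seq", seq_along(seqs))
  }
  set <- Biostrings::AAStringSet(seqs)
  if (any(Biostrings::width(set) == 0)) stop("empty sequence")
  lambda <- 0.267; kappa <- 0.041
  ids <- names(set)
  w <- Biostrings::width(set)
  m <- new_similarity_matrix(ids)
  n_aln <- 0L
  for (i in seq_len(length(set) - 1)) {
    for (j in (i + 1):length(set)) {
      aln <- Biostrings::pairwiseAlignment(
        set[[i]], set[[j]], type = "local",
        substitutionMatrix = "BLOSUM62",
        gapOpening = 11, gapExtension = 1
      )
      n_aln <- n_aln + 1L
      s <- Biostrings::score(aln)
      evalue <- kappa * w[i] * w[j] * exp(-lambda * s)
      if (s > 0 && evalue <= evalue_max) {
        v <- Biostrings::pid(aln, type = "PID1")
        m[ids[i], ids[j]] <- v
        m[ids[j], ids[i]] <- v
      }
    }
  }
  attr(m, "n_alignments") <- n_aln
  m
}

#' Nearest-neighbour T-number prediction
#'
#' Predicts the T label of a query as the label of its most similar
#' training entry, provided the similarity reaches `min_similarity`;
#' otherwise no call is made. Ties at the maximum similarity are broken
#' deterministically: smaller T label first (with `"elongated"` sorting
#' last), then lexicographic id.
#'
#' @param matrix A `similarity_matrix`.
#' @param train_labels Named character vector: training id -> T label.
#' @param query_id Query id (must not be in the training set).
#' @param min_similarity Minimum percent similarity to call (default 0).
#' @return A list with `label` (`NA_character_` for no call),
#'   `similarity`, `train_id`, and attribute-free element `comparisons`
#'   (number of training entries examined; linear in the training size).
#' @export
predict_nearest <- function(matrix, train_labels, query_id,
                            min_similarity = 0) {
  train_ids <- names(train_labels)
  if (query_id %in% train_ids) stop("query must not be in the training set")
  sims <- matrix[query_id, train_ids]
  ok <- !is.na(sims) & sims >= min_similarity
  if (!any(ok)) {
    return(list(label = NA_character_, similarity = NA_real_,
                train_id = NA_character_, comparisons = length(train_ids)))
  }
  best <- max(sims[ok])
  tied <- train_ids[ok][sims[ok] == best]
  if (length(tied) > 1) {
    tnum <- suppressWarnings(as.numeric(train_labels[tied]))
    tnum[is.na(tnum)] <- Inf  # "elongated" sorts last
    tied <- tied[order(tnum, tied)]
  }
  list(label = unname(train_labels[tied[1]]), similarity = unname(best),
       train_id = tied[1], comparisons = length(train_ids))
}

#' Evaluate the proximity-matrix classifier over repeated 80/20 splits
#'
#' Generates `n_splits` random 80/20 training/test splits of the library
#' and, for each minimum-similarity threshold, reports the fraction of
#' test entries for which a call was made (coverage) and the accuracy
#' over the called subset (a prediction is correct when it equals the
#' library label). Accuracy over zero calls is undefined and reported as
#' `NA`, never 0.
#'
#' @param library Labelled library data.frame (`id`, `t_label`).
#' @param matrix A `similarity_matrix` covering the library ids.
#' @param n_splits Number of random splits (default 1000).
#' @param thresholds Minimum-similarity thresholds in percent
#'   (default 0, 10, ..., 100).
#' @param seed Integer seed.
#' @param train_frac Training fraction (default 0.8).
#' @return A data.frame with columns `threshold`, `fraction_predicted`,
#'   `accuracy`.
#' @export
evaluate_pm <- function(library, matrix, n_splits = 1000,
                        thresholds = seq(0, 100, by = 10), seed,
                        train_frac = 0.8) {
  if (missing(seed)) stop("seed is required")
  if (!all(library$id %in% rownames(matrix))) {
    stop("library ids missing from the similarity matrix")
  }
  set.seed(seed)
  n <- nrow(library)
  n_train <- max(1, round(train_frac * n))
  labels <- stats::setNames(library$t_label, library$id)
  calls <- stats::setNames(numeric(length(thresholds)), thresholds)
  correct <- calls; tested <- calls
  for (s in seq_len(n_splits)) {
    tr <- sample.int(n, n_train)
    train_ids <- library$id[tr]
    test_ids <- library$id[-tr]
    sims <- matrix[test_ids, train_ids, drop = FALSE]
    # best training hit per query (precomputed once per split)
    for (ti in seq_along(thresholds)) {
      th <- thresholds[ti]
      okm <- !is.na(sims) & sims >= th
      has_call <- rowSums(okm) > 0
      tested[ti] <- tested[ti] + length(test_ids)
      if (!any(has_call)) next
      pred <- vapply(which(has_call), function(q) {
        srow <- sims[q, ]
        ok <- okm[q, ]
        best <- max(srow[ok])
        tied <- train_ids[ok][srow[ok] == best]
        if (length(tied) > 1) {
          tnum <- suppressWarnings(as.numeric(labels[tied]))
          tnum[is.na(tnum)] <- Inf
          tied <- tied[order(tnum, tied)]
        }
        unname(labels[tied[1]])
      }, character(1))
      calls[ti] <- calls[ti] + sum(has_call)
      correct[ti] <- correct[ti] + sum(pred == labels[test_ids[has_call]])
    }
  }
  data.frame(threshold = thresholds,
             fraction_predicted = unname(calls / tested),
             accuracy = unname(ifelse(calls > 0, correct / calls, NA_real_)))
}

#' Relative T-number difference by similarity bin
#'
#' For every pair of library entries with a recorded similarity, bins the
#' pair by similarity and summarizes the relative T-number difference
#' \eqn{|T_i - T_j| / \min(T_i, T_j)} per bin (pairs involving an
#' elongated label carry no T and are skipped). The min denominator makes
#' the difference unbounded above, matching the asymmetric range of
#' observed differences.
#'
#' @param library Labelled library (`id`, `t_label`).
#' @param matrix A `similarity_matrix`.
#' @param bin_edges Increasing similarity bin edges covering [0, 100].
#' @return A data.frame per bin: `lo`, `hi`, `n_pairs`, `mean`, `min`,
#'   `q25`, `median`, `q75`, `max`.
#' @export
t_difference_by_bin <- function(library, matrix,
                                bin_edges = seq(0, 100, by = 20)) {
  if (bin_edges[1] > 0 || bin_edges[length(bin_edges)] < 100) {
    stop("bins must cover [0, 100]")
  }
  tnum <- suppressWarnings(as.numeric(library$t_label))
  ids <- library$id
  pairs <- utils::combn(seq_along(ids), 2)
  sim <- matrix[cbind(ids[pairs[1, ]], ids[pairs[2, ]])]
  keep <- !is.na(sim) & !is.na(tnum[pairs[1, ]]) & !is.na(tnum[pairs[2, ]])
  sim <- sim[keep]
  ta <- tnum[pairs[1, keep]]; tb <- tnum[pairs[2, keep]]
  rel <- abs(ta - tb) / pmin(ta, tb)
  bin <- cut(sim, bin_edges, include.lowest = TRUE)
  out <- lapply(levels(bin), function(lv) {
    r <- rel[bin == lv]
    i <- match(lv, levels(bin))
    data.frame(lo = bin_edges[i], hi = bin_edges[i + 1],
               n_pairs = length(r),
               mean = if (length(r)) mean(r) else NA_real_,
               min = if (length(r)) min(r) else NA_real_,
               q25 = if (length(r)) unname(stats::quantile(r, 0.25)) else NA_real_,
               median = if (length(r)) stats::median(r) else NA_real_,
               q75 = if (length(r)) unname(stats::quantile(r, 0.75)) else NA_real_,
               max = if (length(r)) max(r) else NA_real_)
  })
  do.call(rbind, out)
}
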