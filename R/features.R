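# The 22 sequence-derived features used by the random-forest classifier:
# sequence length (canonical residues), isoelectric point, and the 20
# amino-acid frequencies.

CANONICAL_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Feature names in canonical order
#'
#' Length, isoelectric point, then the 20 amino-acid frequencies in
#' alphabetical one-letter order.
#'
#' @return Character vector of 22 names.
#' @export
feature_names <- function() c("length", "pI", paste0("freq_", CANONICAL_AA))

#' Load the packaged pKa table
#'
#' The simplified Bjellqvist dissociation constants shipped with the
#' package (see `inst/extdata/pka_bjellqvist.tsv`): positive groups
#' N-terminus, K, R, H; negative groups C-terminus, D, E, C, Y.
#'
#' @param path Optional path to an alternative pKa TSV with columns
#'   `group`, `type` (`pos`/`neg`) and `pka`.
#' @return Data.frame with columns `group`, `type`, `pka`.
#' @export
load_pka_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pka_bjellqvist.tsv",
                        package = "capsidarch", mustWork = TRUE)
  }
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

# Net charge of a sequence at a given pH under the Henderson-Hasselbalch
# model: each positive group contributes 1/(1 + 10^(pH - pKa)), each
# negative group -1/(1 + 10^(pKa - pH)).
protein_charge <- function(counts, pH, pka) {
  pos <- pka[pka$type == "pos", ]
  neg <- pka[pka$type == "neg", ]
  n_pos <- vapply(pos$group, function(g)
    if (g == "Nterm") 1 else counts[[g]] %||% 0, numeric(1))
  n_neg <- vapply(neg$group, function(g)
    if (g == "Cterm") 1 else counts[[g]] %||% 0, numeric(1))
  sum(n_pos / (1 + 10^(pH - pos$pka))) -
    sum(n_neg / (1 + 10^(neg$pka - pH)))
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Isoelectric point of a protein sequence
#'
#' The pH at which the net charge of the protein is zero, found by
#' bisection on [0, 14] to |charge| < 1e-4. The charge model counts one
#' N-terminal and one C-terminal group plus the ionizable side chains
#' (K, R, H positive; D, E, C, Y negative) with the packaged simplified
#' Bjellqvist pKa values; ambiguity codes are ignored.
#'
#' @param sequence Amino-acid sequence (single string).
#' @param pka pKa table from [load_pka_table()].
#' @param tol Charge tolerance for the bisection (default 1e-4).
#' @return The isoelectric point (pH units).
#' @examples
#' isoelectric_point("DDDDD") < 7   # acidic
#' isoelectric_point("KKKKK") > 7   # basic
#' @export
isoelectric_point <- function(sequence, pka = load_pka_table(), tol = 1e-4) {
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  aa <- strsplit(toupper(sequence), "")[[1]]
  counts <- as.list(table(factor(aa[aa %in% CANONICAL_AA],
                                 levels = CANONICAL_AA)))
  lo <- 0; hi <- 14
  c_lo <- protein_charge(counts, lo, pka)
  c_hi <- protein_charge(counts, hi, pka)
  if (c_lo <= 0) return(lo)
  if (c_hi >= 0) return(hi)
  repeat {
    mid <- (lo + hi) / 2
    cm <- protein_charge(counts, mid, pka)
    if (abs(cm) < tol || (hi - lo) < 1e-12) return(mid)
    if (cm > 0) lo <- mid else hi <- mid
  }
}

#' Compute the 22-feature vector of an MCP sequence
#'
#' Length counts canonical residues only; the 20 amino-acid frequencies
#' are taken over canonical residues (ambiguity codes such as X are
#' excluded from both numerator and denominator, with the excluded count
#' reported via `message()`); the isoelectric point comes from
#' [isoelectric_point()].
#'
#' @param sequence Amino-acid sequence (single string).
#' @param pka pKa table for the isoelectric point.
#' @return Named numeric vector of length 22 (see [feature_names()]);
#'   frequencies sum to 1.
#' @export
compute_features <- function(sequence, pka = load_pka_table()) {
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  aa <- strsplit(toupper(sequence), "")[[1]]
  canon <- aa[aa %in% CANONICAL_AA]
  n_ambig <- length(aa) - length(canon)
  if (n_ambig > 0) {
    message(n_ambig, " non-canonical residue(s) excluded from features")
  }
  if (length(canon) == 0) stop("sequence has no canonical residues")
  freqs <- table(factor(canon, levels = CANONICAL_AA)) / length(canon)
  out <- c(length(canon), isoelectric_point(sequence, pka), as.numeric(freqs))
  names(out) <- feature_names()
  out
}

#' Featurize a library into a model matrix
#'
#' @param library MCP entry data.frame with a `sequence` column.
#' @param pka pKa table.
#' @return Numeric matrix, one row per entry (rownames = ids), 22
#'   columns.
#' @export
featurize_library <- function(library, pka = load_pka_table()) {
  m <- t(vapply(library$sequence,
                function(s) suppressMessages(compute_features(s, pka)),
                numeric(22)))
  rownames(m) <- library$id
  m
}
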