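# Metagenome survey front end: filter putative MCPs by function score,
# dereplicate, featurize, predict architectures with the random-forest
# model and tally class frequencies.

#' Read a PhANNs-style function-score table
#'
#' TSV with columns `id`, `predicted_class`, `score`.
#'
#' @param path Path to the TSV.
#' @return Data.frame with those columns.
#' @export
read_function_scores <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("id", "predicted_class", "score")
  if (!all(need %in% names(df))) {
    stop("score TSV must have columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Survey capsid architectures in a metagenome protein set
#'
#' Pipeline: keep sequences whose top-ranked function is major capsid
#' protein AND whose score is at least `score_min` (two independent
#' predicates); dereplicate identical sequences; compute the 22
#' features; predict T classes with the random-forest model; tally
#' per-class counts and percentages. The three most frequent classes are
#' annotated with the genome-length range of their member T-numbers via
#' [t_to_genome_range()].
#'
#' @param sequences Named character vector or `AAStringSet` of protein
#'   sequences (e.g. from `Biostrings::readAAStringSet`).
#' @param scores Function-score data.frame (`id`, `predicted_class`,
#'   `score`) or `NULL` to disable filtering.
#' @param model A trained `mcp_rf_model`.
#' @param scheme The `t_class_scheme` the model was trained under.
#' @param fit A `g2t_fit` (for genome-range annotation).
#' @param mre Margin for the genome ranges.
#' @param mcp_class Label used for the MCP class in `scores`
#'   (default `"major_capsid"`).
#' @param score_min Minimum score (default 2).
#' @return A list of class `survey_report`: `report` (data.frame
#'   `predicted_class`, `count`, `percent`), `top_classes` (top three
#'   with `genome_lo`, `genome_hi`), `n_input`, `n_filtered`,
#'   `n_dereplicated`. Zero-row report (with a warning) when nothing
#'   passes the filter.
#' @export
survey_metagenome <- function(sequences, scores, model, scheme, fit,
                              mre = 0.09, mcp_class = "major_capsid",
                              score_min = 2) {
  if (methods::is(sequences, "XStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  n_input <- length(sequences)
  ids <- names(sequences)
  if (is.null(ids)) stop("sequences must be named")
  if (!is.null(scores)) {
    keep_ids <- scores$id[scores$predicted_class == mcp_class &
                          scores$score >= score_min]
    sequences <- sequences[ids %in% keep_ids]
    ids <- names(sequences)
  }
  n_filtered <- length(sequences)
  if (n_filtered == 0) {
    warning("no sequences passed the MCP/score filter")
    report <- data.frame(predicted_class = character(0), count = integer(0),
                         percent = numeric(0))
    return(structure(list(report = report, top_classes = report,
                          n_input = n_input, n_filtered = 0,
                          n_dereplicated = 0),
                     class = "survey_report"))
  }
  dup <- duplicated(unname(sequences))
  sequences <- sequences[!dup]
  ids <- names(sequences)
  n_derep <- length(sequences)
  feats <- t(vapply(sequences,
                    function(s) suppressMessages(compute_features(s)),
                    numeric(22)))
  rownames(feats) <- ids
  pred <- predict.mcp_rf_model(model, feats)
  tab <- sort(table(pred$predicted_class), decreasing = TRUE)
  report <- data.frame(predicted_class = names(tab),
                       count = as.integer(tab),
                       percent = 100 * as.integer(tab) / n_derep,
                       stringsAsFactors = FALSE)
  top <- utils::head(report, 3)
  rng <- t(vapply(top$predicted_class, function(cl) {
    members <- scheme_members(scheme, cl)
    if (!length(members)) return(c(NA_real_, NA_real_))
    r <- vapply(members, function(t) t_to_genome_range(fit, mre, t),
                numeric(2))
    c(min(r[1, ]), max(r[2, ]))
  }, numeric(2)))
  top$genome_lo <- rng[, 1]; top$genome_hi <- rng[, 2]
  structure(list(report = report, top_classes = top, n_input = n_input,
                 n_filtered = n_filtered, n_dereplicated = n_derep,
                 predictions = data.frame(id = ids,
                                          predicted_class =
                                            pred$predicted_class,
                                          class_probability =
                                            pred$class_probability,
                                          stringsAsFactors = FALSE)),
            class = "survey_report")
}

#' @export
print.survey_report <- function(x, ...) {
  cat("Survey:", x$n_input, "input,", x$n_filtered, "passed filter,",
      x$n_dereplicated, "after dereplication\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Agreement between genome-length and MCP-sequence predictions
#'
#' Compares, over shared ids, the class predicted from the genome length
#' (G2T route) with the class predicted from the MCP sequence (random
#' forest route): per-class counts where both routes agree, and the
#' total agreement fraction.
#'
#' @param genome_predictions Data.frame `id`, `predicted_class`.
#' @param mcp_predictions Data.frame `id`, `predicted_class`.
#' @return A list with `per_class` (data.frame `predicted_class`,
#'   `n_agree`), `n_shared`, `n_agree`, `agreement_fraction`.
#' @export
genome_vs_mcp_agreement <- function(genome_predictions, mcp_predictions) {
  merged <- merge(genome_predictions, mcp_predictions, by = "id",
                  suffixes = c("_genome", "_mcp"))
  agree <- merged$predicted_class_genome == merged$predicted_class_mcp
  per_class <- if (any(agree)) {
    tab <- table(merged$predicted_class_genome[agree])
    data.frame(predicted_class = names(tab), n_agree = as.integer(tab),
               stringsAsFactors = FALSE)
  } else {
    data.frame(predicted_class = character(0), n_agree = integer(0))
  }
  list(per_class = per_class, n_shared = nrow(merged),
       n_agree = sum(agree),
       agreement_fraction = if (nrow(merged)) mean(agree) else NA_real_)
}

#' Write a JSON run manifest
#'
#' Records inputs, parameters, seed and the package version for a CLI
#' run.
#'
#' @param path Output JSON path.
#' @param inputs Named list of input paths.
#' @param parameters Named list of parameters.
#' @param seed Seed used (or `NA`).
#' @return `path` invisibly.
#' @export
write_run_manifest <- function(path, inputs = list(), parameters = list(),
                               seed = NA) {
  jsonlite::write_json(
    list(package = "capsidarch",
         version = as.character(utils::packageVersion("capsidarch")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         inputs = inputs, parameters = parameters, seed = seed),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
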