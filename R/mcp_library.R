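# Construction of the MCP/T library: candidate selection from annotated
# genomes, function-score filtering, dereplication, and T labelling from
# high-resolution structures or the G2T model.

#' Construct MCP entries
#'
#' An MCP entry ties a major-capsid-protein amino-acid sequence to its
#' source phage and genome length; after [build_library()] it also
#' carries a T label. Entries are rows of an ordinary data.frame.
#'
#' @param id Unique entry ids.
#' @param phage_name Source phage names.
#' @param genome_kbp Positive genome lengths (kbp).
#' @param sequence Amino-acid sequences (20-letter alphabet plus
#'   ambiguity codes).
#' @param function_score Optional numeric function score per entry.
#' @param hk97_validated Logical flag, externally supplied fold
#'   validation; defaults to `TRUE` for all entries (with a notice),
#'   since fold validation depends on external structure services.
#' @return A data.frame of MCP entries.
#' @export
mcp_entries <- function(id, phage_name, genome_kbp, sequence,
                        function_score = NA_real_, hk97_validated = NULL) {
  if (any(!nzchar(sequence))) stop("sequences must be non-empty")
  if (any(!is.finite(genome_kbp)) || any(genome_kbp <= 0)) {
    stop("genome_kbp must be positive")
  }
  if (is.null(hk97_validated)) {
    message("hk97_validated not supplied; defaulting to TRUE for all entries")
    hk97_validated <- TRUE
  }
  data.frame(id = as.character(id), phage_name = as.character(phage_name),
             genome_kbp = genome_kbp, sequence = toupper(sequence),
             function_score = function_score,
             hk97_validated = hk97_validated,
             stringsAsFactors = FALSE)
}

#' Read MCP entries from a pre-extracted TSV
#'
#' Expects columns `id`, `phage`, `genome_kbp`, `sequence` (a
#' `function_score` column is carried through if present).
#'
#' @param path Path to a TSV file.
#' @return A data.frame of MCP entries.
#' @export
read_mcp_entries <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("id", "phage", "genome_kbp", "sequence")
  if (!all(need %in% names(df))) {
    stop("entries TSV must have columns: ", paste(need, collapse = ", "))
  }
  mcp_entries(df$id, df$phage, df$genome_kbp, df$sequence,
              function_score = if ("function_score" %in% names(df))
                df$function_score else NA_real_,
              hk97_validated = if ("hk97_validated" %in% names(df))
                as.logical(df$hk97_validated) else TRUE)
}

#' Extract MCP candidates from GenBank records
#'
#' Selects protein-coding (CDS) features whose `/product` qualifier
#' contains the keyword (case-insensitive substring match on the product
#' only), one candidate per matching CDS, carrying the record's genome
#' length in kbp. CDS features without a translation are skipped with a
#' warning; records without CDS yield no candidates (with a warning).
#'
#' @param genome_records Parsed records from [read_genbank_cds()].
#' @param keyword Product keyword (default `"major capsid"`).
#' @return A data.frame of MCP entries (possibly zero rows).
#' @export
extract_mcp_candidates <- function(genome_records, keyword = "major capsid") {
  out <- list()
  for (rec in genome_records) {
    if (is.null(rec$cds) || nrow(rec$cds) == 0) {
      warning("record ", rec$name, " has no CDS features")
      next
    }
    hit <- grepl(keyword, rec$cds$product, ignore.case = TRUE, fixed = FALSE)
    hit[is.na(hit)] <- FALSE
    for (i in which(hit)) {
      tr <- rec$cds$translation[i]
      if (is.na(tr) || !nzchar(tr)) {
        warning("CDS '", rec$cds$product[i], "' in ", rec$name,
                " has no translation; skipped")
        next
      }
      out[[length(out) + 1]] <- data.frame(
        id = paste0(rec$name, "_cds", i),
        phage_name = rec$name,
        genome_kbp = rec$length_bp / 1000,
        sequence = toupper(tr),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(id = character(0), phage_name = character(0),
                      genome_kbp = numeric(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Filter MCP entries by function score
#'
#' Keeps entries whose score is at least `threshold` (boundary
#' inclusive). A score of 2 corresponds to ~98% true-positive confidence
#' in PhANNs-style structural-function scoring. Entries missing from the
#' score table are excluded with a warning.
#'
#' @param entries MCP entry data.frame.
#' @param scores Either a data.frame with columns `id` and `score`, or a
#'   named numeric vector.
#' @param threshold Minimum score (default 2).
#' @return Filtered entries, with a `function_score` column attached.
#' @export
filter_by_function_score <- function(entries, scores, threshold = 2) {
  if (is.data.frame(scores)) {
    sc <- stats::setNames(scores$score, scores$id)
  } else {
    sc <- scores
  }
  got <- entries$id %in% names(sc)
  if (any(!got)) {
    warning(sum(!got), " entries without a function score were excluded: ",
            paste(utils::head(entries$id[!got], 5), collapse = ", "))
  }
  entries <- entries[got, , drop = FALSE]
  entries$function_score <- unname(sc[entries$id])
  entries[entries$function_score >= threshold, , drop = FALSE]
}

#' Dereplicate identical sequences
#'
#' Keeps one representative per identical amino-acid sequence (the first
#' by input order) and logs the number removed.
#'
#' @param entries MCP entry data.frame.
#' @return Dereplicated entries.
#' @export
dereplicate <- function(entries) {
  dup <- duplicated(entries$sequence)
  if (any(dup)) message("dereplication removed ", sum(dup), " duplicate sequences")
  entries[!dup, , drop = FALSE]
}

#' Build the labelled MCP/T library
#'
#' Attaches a T label to every entry. Entries whose phage matches a
#' high-resolution record take the structure-determined T-number
#' (`label_source = "structure"`); all others are labelled by applying
#' the G2T model to their genome length via [assign_architecture()]
#' (`label_source = "g2t"`), recording alternative candidate T-numbers,
#' with `"elongated"` allowed.
#'
#' @param entries MCP entry data.frame with `genome_kbp`.
#' @param high_res_records Capsid records matched by `phage_name`.
#' @param fit A `g2t_fit`.
#' @param mre Assignment margin (mean relative error).
#' @param architectures Architecture table.
#' @return The entries with columns `t_label` (formatted T or
#'   `"elongated"`), `t_numeric` (`NA` for elongated), `lattice`,
#'   `label_source`, `alt_labels` (comma-separated). Counts by label
#'   source are reported via `message()`.
#' @export
build_library <- function(entries, high_res_records, fit, mre,
                          architectures = enumerate_architectures()) {
  if (any(!is.finite(entries$genome_kbp))) {
    stop("entries with unknown genome length cannot be labelled")
  }
  n <- nrow(entries)
  t_label <- character(n); t_numeric <- rep(NA_real_, n)
  lattice <- rep(NA_character_, n); src <- character(n)
  alt <- character(n)
  hr <- high_res_records
  for (i in seq_len(n)) {
    j <- match(entries$phage_name[i], hr$phage_name)
    if (!is.na(j)) {
      t_label[i] <- format_t(hr$t_value[j])
      t_numeric[i] <- hr$t_value[j]
      lattice[i] <- if ("lattice" %in% names(hr)) hr$lattice[j] else NA
      src[i] <- "structure"
      alt[i] <- ""
    } else {
      a <- assign_architecture(fit, mre, entries$genome_kbp[i], architectures)
      t_label[i] <- a$t_label
      if (!identical(a$selected, "elongated")) {
        t_numeric[i] <- a$selected$t_value
        lattice[i] <- a$selected$lattice
      }
      src[i] <- "g2t"
      alt[i] <- if (is.data.frame(a$alternatives) && nrow(a$alternatives)) {
        paste(format_t(a$alternatives$t_value), collapse = ",")
      } else ""
    }
  }
  out <- entries
  out$t_label <- t_label; out$t_numeric <- t_numeric
  out$lattice <- lattice; out$label_source <- src; out$alt_labels <- alt
  message("library labels: ", sum(src == "structure"), " from structure, ",
          sum(src == "g2t"), " from the G2T model (",
          sum(t_label == "elongated"), " elongated)")
  out
}

#' Write / read a labelled MCP/T library TSV
#'
#' @param library Labelled library from [build_library()].
#' @param path Output TSV path.
#' @return `path` invisibly (`write_library`); the library data.frame
#'   (`read_library`).
#' @export
write_library <- function(library, path) {
  cols <- intersect(c("id", "phage_name", "genome_kbp", "sequence",
                      "t_label", "t_numeric", "lattice", "label_source",
                      "alt_labels"), names(library))
  utils::write.table(library[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  df$t_label <- as.character(df$t_label)
  df
}
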