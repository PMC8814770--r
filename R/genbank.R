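# Minimal GenBank flat-file reader: enough to recover, per record, the
# locus name, sequence length (bp) and the CDS features' /product and
# /translation qualifiers. Feature-table parsing with qualifiers is not
# provided by the installed sequence packages, so it is done here.

#' Read CDS features from GenBank flat files
#'
#' Parses one or more GenBank flat files and returns, per record, the
#' locus name, genome length (from the LOCUS line, in bp) and a table of
#' CDS features with their `/product` and `/translation` qualifiers.
#' Qualifier values spanning multiple lines are joined; translation
#' whitespace is stripped.
#'
#' @param paths Paths to GenBank flat files (each may hold several
#'   records separated by `//`).
#' @return A list of records; each a list with `name`, `length_bp`,
#'   `organism` (may be `NA`) and `cds` (data.frame with columns
#'   `product`, `translation`).
#' @export
read_genbank_cds <- function(paths) {
  records <- list()
  for (path in paths) {
    lines <- readLines(path, warn = FALSE)
    breaks <- c(0, which(trimws(lines) == "//"))
    for (b in seq_len(length(breaks) - 1)) {
      chunk <- lines[(breaks[b] + 1):(breaks[b + 1] - 1)]
      if (!length(chunk) || !any(startsWith(chunk, "LOCUS"))) next
      records[[length(records) + 1]] <- parse_genbank_record(chunk)
    }
  }
  records
}

parse_genbank_record <- function(lines) {
  locus <- lines[startsWith(lines, "LOCUS")][1]
  toks <- strsplit(trimws(locus), "\\s+")[[1]]
  name <- toks[2]
  length_bp <- suppressWarnings(as.integer(toks[3]))
  org_line <- lines[grepl("^\\s*ORGANISM", lines)]
  organism <- if (length(org_line)) {
    trimws(sub("^\\s*ORGANISM\\s*", "", org_line[1]))
  } else NA_character_

  feat_start <- which(startsWith(lines, "FEATURES"))
  cds <- data.frame(product = character(0), translation = character(0),
                    stringsAsFactors = FALSE)
  if (length(feat_start)) {
    feat_end <- which(startsWith(lines, "ORIGIN"))
    feat_end <- if (length(feat_end)) feat_end[1] - 1 else length(lines)
    feat <- lines[(feat_start[1] + 1):feat_end]
    # feature keys sit at column 6; qualifier/continuation lines at column 22
    is_key <- grepl("^ {5}\\S", feat)
    key_idx <- which(is_key)
    keys <- sub("^\\s*(\\S+).*", "\\1", feat[key_idx])
    cds_feats <- which(keys == "CDS")
    for (ci in cds_feats) {
      from <- key_idx[ci] + 1
      to <- if (ci < length(key_idx)) key_idx[ci + 1] - 1 else length(feat)
      if (from > to) {
        cds <- rbind(cds, data.frame(product = NA_character_,
                                     translation = NA_character_))
        next
      }
      quals <- parse_qualifiers(feat[from:to])
      cds <- rbind(cds, data.frame(
        product = if (!is.null(quals$product)) quals$product else NA_character_,
        translation = if (!is.null(quals$translation)) {
          gsub("\\s", "", quals$translation)
        } else NA_character_,
        stringsAsFactors = FALSE
      ))
    }
  }
  list(name = name, length_bp = length_bp, organism = organism, cds = cds)
}

parse_qualifiers <- function(lines) {
  lines <- trimws(lines)
  starts <- which(startsWith(lines, "/"))
  out <- list()
  for (si in seq_along(starts)) {
    from <- starts[si]
    to <- if (si < length(starts)) starts[si + 1] - 1 else length(lines)
    text <- paste(lines[from:to], collapse = " ")
    m <- regmatches(text, regexec("^/([A-Za-z_]+)=?\"?(.*?)\"?$", text))[[1]]
    if (length(m) == 3) out[[m[2]]] <- m[3]
  }
  out
}
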