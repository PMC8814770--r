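# Shared fixtures, built in code at test time.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Amino-acid weight vector concentrated on `dominant` residues.
aa_profile <- function(dominant, dominant_frac = 0.6) {
  w <- stats::setNames(rep((1 - dominant_frac) / (20 - length(dominant)), 20),
                       AA20)
  w[dominant] <- dominant_frac / length(dominant)
  w / sum(w)
}

# Two well-separated synthetic MCP classes (length and composition).
separable_profiles <- function() {
  list(
    mcp_class_profile("T7", 7, 300, 10, aa_profile(c("G", "A"))),
    mcp_class_profile("T19", 19, 500, 10, aa_profile(c("F", "K")))
  )
}

# A minimal GenBank flat file with the given CDS (product, translation)
# pairs; translation = NA writes a CDS without /translation.
write_toy_genbank <- function(path, name = "TOYPHAGE", length_bp = 41000,
                              cds = list(c("major capsid protein", "MKTAYIAKQR"))) {
  lines <- c(
    sprintf("LOCUS       %s             %d bp    DNA     linear   PHG 01-JAN-2020",
            name, length_bp),
    sprintf("DEFINITION  %s, complete genome.", name),
    "  ORGANISM  Caudovirales; toy phage",
    "FEATURES             Location/Qualifiers",
    "     source          1..41000"
  )
  pos <- 1
  for (item in cds) {
    lines <- c(lines,
               sprintf("     CDS             %d..%d", pos, pos + 299),
               sprintf("                     /product=\"%s\"", item[1]))
    if (!is.na(item[2])) {
      lines <- c(lines,
                 sprintf("                     /translation=\"%s\"", item[2]))
    }
    pos <- pos + 300
  }
  lines <- c(lines, "ORIGIN", "//")
  writeLines(lines, path)
  path
}

# Blast tabular (outfmt 6) rows -> file. Each row: qseqid, sseqid,
# pident, evalue.
write_toy_blast <- function(path, rows) {
  lines <- vapply(rows, function(r) {
    paste(r[1], r[2], r[3], 100, 5, 0, 1, 100, 1, 100, r[4], 200,
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  path
}
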