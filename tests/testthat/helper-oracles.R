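# Independent oracles and fixture builders shared across the test files.
# The oracles deliberately re-derive results from first principles (full
# scans, textbook formulas) and never call the code paths they check.

# Build a kinase_msa directly from gapped strings.
make_msa <- function(seqs, offsets = rep(1L, length(seqs)),
                     genes = sprintf("G%02d", seq_along(seqs)),
                     reference_index = 1L) {
  kinase_msa(gene = genes,
             protein_id = sprintf("P%02d", seq_along(seqs)),
             offset = offsets, sequence = seqs,
             reference_index = reference_index)
}

# A minimal structure consistent with the reference row of an MSA.
make_structure_for <- function(msa) {
  generate_reference_structure(msa)
}

# Random gapped MSA for oracle tests (independent of generate_msa): builds
# rows character-by-character, guaranteeing each row has >= 1 residue and
# the reference >= 1 residue.
random_msa <- function(n_rows, n_cols) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seqs <- vapply(seq_len(n_rows), function(i) {
    ch <- ifelse(runif(n_cols) < 0.3, "-", sample(aa, n_cols, replace = TRUE))
    if (all(ch == "-")) ch[sample(n_cols, 1)] <- sample(aa, 1)
    paste(ch, collapse = "")
  }, "")
  make_msa(seqs, offsets = sample(1:500, n_rows, replace = TRUE))
}

# Brute-force coordinate mapping: scan a row character by character,
# assigning consecutive residue numbers from the offset, and scan the
# reference row to number the structure residues. Returns a list with
# column, ref_residue and status for one (gene, residue_number) query.
brute_force_map <- function(msa, structure, gene, residue_number,
                            ref_aa = NULL) {
  rows <- which(msa$rows$gene == gene)
  if (length(rows) == 0) return(list(status = "unmatched_gene"))
  hits <- list()
  for (i in rows) {
    ch <- strsplit(msa$rows$sequence[i], "")[[1]]
    resno <- msa$rows$offset[i] - 1L
    for (col in seq_along(ch)) {
      if (ch[col] == "-") next
      resno <- resno + 1L
      if (resno == residue_number)
        hits[[length(hits) + 1]] <- list(row = i, col = col, aa = ch[col])
    }
  }
  if (length(hits) == 0) return(list(status = "excluded_out_of_domain"))
  stopifnot(length(hits) == 1)
  hit <- hits[[1]]
  refch <- strsplit(msa$rows$sequence[msa$reference_index], "")[[1]]
  if (refch[hit$col] == "-") return(list(status = "excluded_reference_gap"))
  k <- 0L
  for (col in seq_len(hit$col)) if (refch[col] != "-") k <- k + 1L
  if (!is.null(ref_aa) && hit$aa != ref_aa)
    return(list(status = "excluded_ref_mismatch"))
  list(status = "mapped", column = hit$col,
       ref_residue = structure$residues$residue_number[k], aa = hit$aa)
}

# Textbook Pearson chi-square on a 2x2 table: sum((O - E)^2 / E) with
# margin-product expected counts.
chi2_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# A small variant data frame in the raw table layout.
make_variant_df <- function(gene, protein_change,
                            clinical_significance = "Pathogenic",
                            conditions = "Melanoma",
                            allele_frequency = NA_real_) {
  n <- length(protein_change)
  data.frame(record_id = sprintf("R%03d", seq_len(n)),
             gene = rep_len(gene, n),
             protein_change = protein_change,
             clinical_significance = rep_len(clinical_significance, n),
             conditions = rep_len(conditions, n),
             allele_frequency = rep_len(allele_frequency, n),
             stringsAsFactors = FALSE)
}

# Parse + validate a raw variant data frame the way read_variant_table does,
# without the file round trip.
as_records <- function(df) {
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  read_variant_table(path)
}
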