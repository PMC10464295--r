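#' Convert a protein residue number to an alignment column
#'
#' For row `row` of the alignment, returns the 1-based column holding the
#' residue with full-protein number `residue_number`, i.e. the
#' `(residue_number - offset + 1)`-th non-gap character of the row. Residue
#' numbers before the domain start or past its last residue are out of
#' domain and return `NA`.
#'
#' @param msa a [kinase_msa].
#' @param row row index.
#' @param residue_number integer vector of full-protein residue numbers.
#' @return integer vector of alignment columns (`NA` = out of domain).
#' @export
residue_to_column <- function(msa, row, residue_number) {
  stopifnot(inherits(msa, "kinase_msa"))
  if (length(row) != 1 || row < 1 || row > nrow(msa$rows))
    stop_input("row index out of range")
  cols <- msa_residue_columns(msa, row)
  k <- as.integer(residue_number) - msa$rows$offset[row] + 1L
  out <- rep(NA_integer_, length(k))
  ok <- !is.na(k) & k >= 1 & k <= length(cols)
  out[ok] <- cols[k[ok]]
  out
}

#' Convert an alignment column to a reference-structure residue number
#'
#' Returns the residue number (author numbering of the structure file) of the
#' reference residue in the given column, or `NA` when the reference row is
#' gapped there — variants landing in reference-gap columns are excluded from
#' all downstream counts.
#'
#' @param msa a [kinase_msa].
#' @param structure a [ref_structure] consistent with the reference row (same
#'   residue count).
#' @param column integer vector of 1-based alignment columns.
#' @return integer vector of residue numbers (`NA` = reference gap).
#' @export
column_to_reference_residue <- function(msa, structure, column) {
  stopifnot(inherits(msa, "kinase_msa"), inherits(structure, "ref_structure"))
  ch <- msa_row_chars(msa, msa$reference_index)
  n_res <- sum(ch != "-")
  if (n_res != nrow(structure$residues))
    stop_input("reference row has ", n_res, " residues but the structure ",
               "has ", nrow(structure$residues),
               " CA records; inputs are inconsistent")
  column <- as.integer(column)
  if (any(!is.na(column) & (column < 1 | column > msa$n_columns)))
    stop_input("alignment column out of range 1..", msa$n_columns)
  k <- cumsum(ch != "-")
  k[ch == "-"] <- NA_integer_
  idx <- k[column]
  out <- rep(NA_integer_, length(column))
  out[!is.na(idx)] <- structure$residues$residue_number[idx[!is.na(idx)]]
  out
}

#' Map variant records onto the reference structure
#'
#' Composes the two coordinate conversions for every record: gene -> MSA row,
#' residue number -> alignment column, column -> reference residue number.
#' Each record receives a status:
#'
#' * `mapped` — a reference residue was found;
#' * `unmatched_gene` — the gene has no row in the alignment;
#' * `excluded_out_of_domain` — the residue lies outside the aligned domain
#'   of every row of the gene;
#' * `excluded_reference_gap` — the residue aligns to a column where the
#'   reference is gapped;
#' * `excluded_ref_mismatch` — with `verify_ref_aa = TRUE`, the row's residue
#'   at the mapped position differs from the substitution's stated reference
#'   amino acid (isoform/numbering disagreements are excluded, not fatal).
#'
#' Genes with several alignment rows (multi-domain kinases) are mapped
#' against every row; a residue in-domain in two or more rows is ambiguous
#' and raises an error. Input records are conserved:
#' `nrow(input) == mapped + excluded + unmatched`.
#'
#' @param variants variant record data frame with parsed `ref_aa`,
#'   `position`, `alt_aa` columns (as from [read_variant_table()]).
#' @param msa a [kinase_msa].
#' @param structure a [ref_structure].
#' @param verify_ref_aa check the stated reference amino acid against the
#'   alignment (default `TRUE`).
#' @return the input data frame plus columns `msa_row`, `alignment_column`,
#'   `ref_residue`, `status`; non-mapped rows are also listed in the
#'   attached exclusion log ([exclusions()]).
#' @export
map_variants <- function(variants, msa, structure, verify_ref_aa = TRUE) {
  stopifnot(inherits(msa, "kinase_msa"), inherits(structure, "ref_structure"))
  need <- c("record_id", "gene", "position", "ref_aa")
  if (!all(need %in% names(variants)))
    stop_input("variants must carry parsed columns ",
               paste(need, collapse = ", "),
               " (use read_variant_table())")
  n <- nrow(variants)
  msa_row <- rep(NA_integer_, n)
  column <- rep(NA_integer_, n)
  status <- rep(NA_character_, n)

  rows_by_gene <- split(seq_len(nrow(msa$rows)), msa$rows$gene)
  res_cols <- lapply(seq_len(nrow(msa$rows)),
                     function(i) msa_residue_columns(msa, i))
  for (v in seq_len(n)) {
    rows <- rows_by_gene[[variants$gene[v]]]
    if (is.null(rows)) {
      status[v] <- "unmatched_gene"
      next
    }
    hit_row <- hit_col <- integer(0)
    for (i in rows) {
      k <- variants$position[v] - msa$rows$offset[i] + 1L
      if (k >= 1 && k <= length(res_cols[[i]])) {
        hit_row <- c(hit_row, i)
        hit_col <- c(hit_col, res_cols[[i]][k])
      }
    }
    if (length(hit_row) == 0) {
      status[v] <- "excluded_out_of_domain"
    } else if (length(hit_row) > 1) {
      stop_input("residue ", variants$position[v], " of gene '",
                 variants$gene[v], "' is in-domain in ", length(hit_row),
                 " alignment rows; ambiguous mapping")
    } else {
      msa_row[v] <- hit_row
      column[v] <- hit_col
    }
  }

  todo <- which(is.na(status))
  ref_res <- rep(NA_integer_, n)
  if (length(todo) > 0)
    ref_res[todo] <- column_to_reference_residue(msa, structure, column[todo])
  for (v in todo) {
    if (is.na(ref_res[v])) {
      status[v] <- "excluded_reference_gap"
      next
    }
    if (verify_ref_aa) {
      aa <- substr(msa$rows$sequence[msa_row[v]], column[v], column[v])
      if (aa != variants$ref_aa[v]) {
        status[v] <- "excluded_ref_mismatch"
        ref_res[v] <- NA_integer_
        next
      }
    }
    status[v] <- "mapped"
  }
  ref_res[status != "mapped"] <- NA_integer_
  column[!status %in% c("mapped", "excluded_reference_gap",
                        "excluded_ref_mismatch")] <- NA_integer_

  out <- variants
  out$msa_row <- msa_row
  out$alignment_column <- column
  out$ref_residue <- ref_res
  out$status <- status
  dropped <- status != "mapped"
  log <- bind_exclusions(
    exclusions(variants),
    new_exclusion_log(record_id = out$record_id[dropped],
                      gene = out$gene[dropped],
                      protein_change = out$protein_change[dropped] %||%
                        rep("", sum(dropped)),
                      reason = status[dropped],
                      detail = ""))
  set_exclusions(out, log)
}
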