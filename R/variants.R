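#' Read a variant table (TSV)
#'
#' Reads a tab-separated variant table in the style of a ClinVar or gnomAD
#' export. Required columns: `gene`, `protein_change`,
#' `clinical_significance`, `conditions` (semicolon-separated condition
#' strings). Optional: `allele_frequency`, `record_id` (synthesized from the
#' row ordinal when absent). Rows whose `protein_change` is not a single
#' amino-acid substitution are dropped and logged with the parser's reason
#' code; retrieve the log with [exclusions()].
#'
#' @param path path to a TSV file with a header row.
#' @return a data frame of variant records with parsed substitution columns
#'   `ref_aa`, `position`, `alt_aa`; the exclusion log is attached as an
#'   attribute.
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) stop_input("variant table not found: ", path)
  tab <- read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", check.names = FALSE,
                    quote = "", comment.char = "")
  required <- c("gene", "protein_change", "clinical_significance",
                "conditions")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0)
    stop_input("variant table ", path, " is missing required column(s): ",
               paste(missing, collapse = ", "))
  if (!"record_id" %in% names(tab))
    tab$record_id <- as.character(seq_len(nrow(tab)))
  tab$allele_frequency <-
    if ("allele_frequency" %in% names(tab))
      suppressWarnings(as.numeric(tab$allele_frequency))
    else rep(NA_real_, nrow(tab))
  as_variant_table(tab)
}

# Validate/parse a raw variant data frame into the package's record layout:
# drops non-substitution rows with a logged reason.
as_variant_table <- function(tab) {
  if (anyDuplicated(tab$record_id))
    stop_input("record_id values must be unique within a table")
  parsed <- parse_protein_change(tab$protein_change)
  keep <- parsed$valid
  log <- new_exclusion_log(
    record_id = tab$record_id[!keep],
    gene = tab$gene[!keep],
    protein_change = tab$protein_change[!keep],
    reason = "not_single_aa_substitution",
    detail = parsed$reason[!keep])
  out <- tab[keep, , drop = FALSE]
  out$ref_aa <- parsed$ref_aa[keep]
  out$position <- parsed$position[keep]
  out$alt_aa <- parsed$alt_aa[keep]
  rownames(out) <- NULL
  set_exclusions(out, log)
}

#' Write a variant table (TSV)
#'
#' Inverse of [read_variant_table()] for the columns the pipeline consumes.
#'
#' @param records variant record data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(records, path) {
  cols <- intersect(c("record_id", "gene", "protein_change",
                      "clinical_significance", "conditions",
                      "allele_frequency"), names(records))
  write_tsv(records[, cols, drop = FALSE], path)
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
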