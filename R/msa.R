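#' Construct an aligned kinase-domain set
#'
#' The central alignment container: one row per kinase domain, all gapped
#' sequences over a common column space, each row carrying the residue number
#' of its first aligned residue in full-protein coordinates (`offset`). One
#' designated row is the reference onto which all variants are projected.
#'
#' @param gene character vector of gene symbols.
#' @param protein_id character vector of protein identifiers (e.g. UniProt).
#' @param offset integer vector, 1-based residue number of the first aligned
#'   residue of each row in full-protein coordinates.
#' @param sequence character vector of gapped sequences (gap character `-`),
#'   all of equal length, over the 20-residue alphabet.
#' @param reference_index index of the reference row (default 1).
#' @return an object of class `kinase_msa`: a list with elements `rows`
#'   (data frame `gene`, `protein_id`, `offset`, `sequence`),
#'   `reference_index` and `n_columns`.
#' @export
kinase_msa <- function(gene, protein_id, offset, sequence,
                       reference_index = 1L) {
  n <- length(sequence)
  if (n < 1) stop_input("an alignment needs at least one row")
  if (length(gene) != n || length(protein_id) != n || length(offset) != n)
    stop_input("gene, protein_id, offset and sequence must have equal length")
  sequence <- toupper(as.character(sequence))
  widths <- nchar(sequence)
  if (length(unique(widths)) != 1) {
    bad <- which(widths != widths[1])[1]
    stop_input("ragged alignment: record '", gene[bad], "|", protein_id[bad],
               "' has length ", widths[bad], ", expected ", widths[1])
  }
  ok <- grepl(paste0("^[", paste(AA1, collapse = ""), "-]*$"), sequence)
  if (!all(ok)) {
    bad <- which(!ok)[1]
    chars <- setdiff(strsplit(sequence[bad], "")[[1]], c(AA1, "-"))
    stop_input("record '", gene[bad], "|", protein_id[bad],
               "' contains characters outside the amino-acid alphabet: ",
               paste(chars, collapse = " "))
  }
  offset <- as.integer(offset)
  if (any(is.na(offset)) || any(offset < 1))
    stop_input("offset must be an integer >= 1 for every row")
  key <- paste(gene, protein_id, sep = "|")
  if (anyDuplicated(key))
    stop_input("duplicate gene|protein_id pair: ", key[duplicated(key)][1])
  reference_index <- as.integer(reference_index)
  if (is.na(reference_index) || reference_index < 1 || reference_index > n)
    stop_input("reference_index out of range")
  structure(list(
    rows = data.frame(gene = as.character(gene),
                      protein_id = as.character(protein_id),
                      offset = offset, sequence = sequence,
                      stringsAsFactors = FALSE),
    reference_index = reference_index,
    n_columns = widths[1]
  ), class = "kinase_msa")
}

#' @export
print.kinase_msa <- function(x, ...) {
  cat("kinase_msa:", nrow(x$rows), "rows x", x$n_columns, "columns;",
      "reference:", x$rows$gene[x$reference_index], "\n")
  invisible(x)
}

# column indices of the non-gap characters of row i (1-based)
msa_residue_columns <- function(msa, i) {
  which(strsplit(msa$rows$sequence[i], "", fixed = TRUE)[[1]] != "-")
}

msa_row_chars <- function(msa, i) {
  strsplit(msa$rows$sequence[i], "", fixed = TRUE)[[1]]
}

# ungapped sequence of the reference row
msa_reference_residues <- function(msa) {
  ch <- msa_row_chars(msa, msa$reference_index)
  ch[ch != "-"]
}

#' Read an aligned multi-FASTA of kinase domains
#'
#' Headers follow `>GENE|PROTEIN_ID|offset=N`; the offset token is optional
#' and defaults to 1 (the domain starts at the first residue of the protein).
#' Sequences may be lower case (upcased on read); all records must have equal
#' gapped length.
#'
#' @param path path to an aligned FASTA file.
#' @param reference gene symbol (or `GENE|PROTEIN_ID` key) of the reference
#'   row; default `NULL` selects the first record.
#' @return a [kinase_msa] object.
#' @export
read_msa <- function(path, reference = NULL) {
  if (!file.exists(path)) stop_input("MSA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) < 1) stop_input("MSA file has no records: ", path)
  headers <- sub("\\s.*$", "", names(set))
  parts <- strsplit(headers, "|", fixed = TRUE)
  gene <- vapply(parts, `[`, "", 1)
  protein_id <- vapply(parts, function(p) if (length(p) >= 2) p[2] else "", "")
  offset <- vapply(parts, function(p) {
    tok <- grep("^offset=", p, value = TRUE)
    if (length(tok) == 0) 1L else {
      v <- suppressWarnings(as.integer(sub("^offset=", "", tok[1])))
      if (is.na(v)) stop_input("malformed offset token in header: ",
                               paste(p, collapse = "|"))
      v
    }
  }, 1L)
  seqs <- as.character(set)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1) {
    bad <- which(widths != widths[1])[1]
    stop_input("ragged alignment in ", path, ": record '", headers[bad],
               "' has length ", widths[bad], ", expected ", widths[1])
  }
  ref_idx <- 1L
  if (!is.null(reference)) {
    key <- paste(gene, protein_id, sep = "|")
    hit <- which(gene == reference | key == reference)
    if (length(hit) != 1)
      stop_input("reference '", reference, "' matches ", length(hit),
                 " records (need exactly 1)")
    ref_idx <- hit
  }
  kinase_msa(gene, protein_id, offset, seqs, reference_index = ref_idx)
}

#' Write an aligned kinase set to FASTA
#'
#' @param msa a [kinase_msa].
#' @param path output path.
#' @param width line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path, width = 80L) {
  headers <- sprintf(">%s|%s|offset=%d", msa$rows$gene, msa$rows$protein_id,
                     msa$rows$offset)
  wrap <- function(s) {
    n <- nchar(s)
    substring(s, seq(1, n, width), pmin(seq(1, n, width) + width - 1L, n))
  }
  lines <- unlist(Map(function(h, s) c(h, wrap(s)), headers,
                      msa$rows$sequence), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}
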