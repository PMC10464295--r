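#' Construct a reference structure (C-alpha trace)
#'
#' One alpha-carbon record per reference residue. Residue numbers follow the
#' author numbering of the structure file, which is how hotspot positions are
#' reported. The B-factor column is where per-residue mutation counts are
#' written for visualisation.
#'
#' @param residue_number strictly increasing integer residue numbers.
#' @param residue_name 3-letter residue codes.
#' @param x,y,z C-alpha coordinates in Angstrom.
#' @param b_factor per-residue B-factors; each must fit the fixed-width PDB
#'   field (<= 999.99).
#' @param chain_id single-character chain identifier.
#' @return an object of class `ref_structure`: a list with a `residues` data
#'   frame and `chain_id`.
#' @export
ref_structure <- function(residue_number, residue_name, x, y, z,
                          b_factor = 0, chain_id = "A") {
  n <- length(residue_number)
  if (n < 1) stop_input("a reference structure needs at least one residue")
  residue_number <- as.integer(residue_number)
  if (any(diff(residue_number) <= 0))
    stop_input("residue numbers must be strictly increasing")
  b_factor <- rep_len(as.numeric(b_factor), n)
  if (any(b_factor < 0) || any(b_factor > 999.99))
    stop_input("b_factor outside the representable PDB range [0, 999.99]")
  if (nchar(chain_id) != 1) stop_input("chain_id must be a single character")
  structure(list(
    residues = data.frame(residue_number = residue_number,
                          residue_name = as.character(residue_name),
                          x = as.numeric(x), y = as.numeric(y),
                          z = as.numeric(z), b_factor = b_factor,
                          stringsAsFactors = FALSE),
    chain_id = chain_id
  ), class = "ref_structure")
}

#' @export
print.ref_structure <- function(x, ...) {
  r <- x$residues$residue_number
  cat("ref_structure: chain", x$chain_id, "-", nrow(x$residues),
      "CA residues,", r[1], "..", r[length(r)], "\n")
  invisible(x)
}

#' Read a reference structure from a PDB file
#'
#' Reads the C-alpha trace of one chain from a PDB file (first model). The
#' accepted dialect is deliberately strict: single model, no alternate
#' locations, no insertion codes; violations are errors, not warnings, because
#' the per-residue mapping would otherwise be ambiguous.
#'
#' @param path path to a PDB file.
#' @param chain chain identifier; default `NULL` accepts a single-chain file
#'   and errors if several chains are present.
#' @return a [ref_structure].
#' @export
read_structure <- function(path, chain = NULL) {
  if (!file.exists(path)) stop_input("structure file not found: ", path)
  if (sum(grepl("^MODEL ", readLines(path, warn = FALSE))) > 1)
    stop_input("multi-model PDB files are not supported: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  atoms <- pdb$atom[pdb$atom$type == "ATOM" & pdb$atom$elety == "CA", ,
                    drop = FALSE]
  if (nrow(atoms) == 0) stop_input("no CA ATOM records in ", path)
  if (any(!is.na(atoms$insert)))
    stop_input("insertion codes are not supported (residue ",
               atoms$resno[which(!is.na(atoms$insert))[1]], " in ", path, ")")
  if (any(!is.na(atoms$alt)))
    stop_input("alternate locations are not supported in ", path)
  chains <- unique(atoms$chain)
  if (is.null(chain)) {
    if (length(chains) > 1)
      stop_input("file has chains ", paste(chains, collapse = ", "),
                 "; specify `chain`")
    chain <- chains[1]
  }
  atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  if (nrow(atoms) == 0)
    stop_input("no CA atoms on chain '", chain, "' in ", path)
  if (anyDuplicated(atoms$resno))
    stop_input("duplicate residue number on chain '", chain, "': ",
               atoms$resno[duplicated(atoms$resno)][1])
  atoms <- atoms[order(atoms$resno), , drop = FALSE]
  ref_structure(atoms$resno, atoms$resid, atoms$x, atoms$y, atoms$z,
                b_factor = atoms$b, chain_id = chain)
}

#' Write a reference structure as a PDB file
#'
#' Fixed-column ATOM records, CA atoms only, occupancy 1.00, B-factor written
#' with two decimals.
#'
#' @param structure a [ref_structure].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  r <- structure$residues
  xyz <- as.numeric(t(as.matrix(r[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, resno = r$residue_number,
                   resid = r$residue_name,
                   elety = rep("CA", nrow(r)),
                   chain = rep(structure$chain_id, nrow(r)),
                   o = rep(1, nrow(r)), b = r$b_factor)
  invisible(path)
}

#' Write per-residue mutation counts into the B-factor column
#'
#' Encodes a map residue number -> mutation count into the B-factor field of
#' the reference structure's CA records, so structure viewers can colour the
#' structure by mutation load. Residues without a count get 0.00. Counts above
#' 999 do not fit the fixed-width field and are a hard error rather than being
#' clipped, which would silently corrupt the output.
#'
#' @param structure a [ref_structure].
#' @param counts named numeric vector (names = residue numbers) or a data
#'   frame with columns `position` and `count`; counts are non-negative
#'   integers.
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_annotated_pdb <- function(structure, counts, path) {
  if (is.data.frame(counts)) {
    cnt <- counts$count
    names(cnt) <- counts$position
    counts <- cnt
  }
  counts <- counts[!is.na(counts)]
  pos <- suppressWarnings(as.integer(names(counts)))
  if (length(counts) > 0 && (is.null(names(counts)) || any(is.na(pos))))
    stop_input("counts must be named by residue number")
  val <- as.numeric(counts)
  if (any(val < 0) || any(val != round(val)))
    stop_input("counts must be non-negative integers")
  if (any(val > 999))
    stop_input("count ", max(val), " exceeds 999 and cannot be encoded in ",
               "the fixed-width B-factor field")
  known <- pos %in% structure$residues$residue_number
  if (!all(known))
    stop_input("counts refer to residue number(s) absent from the ",
               "structure: ", paste(pos[!known], collapse = ", "))
  b <- rep(0, nrow(structure$residues))
  b[match(pos, structure$residues$residue_number)] <- val
  out <- structure
  out$residues$b_factor <- b
  write_structure(out, path)
}
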