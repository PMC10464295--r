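# Amino-acid alphabet used throughout: the 20 standard residues, one- and
# three-letter codes. Gap character in alignments is "-".
AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
         G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
         M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
         S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")

AA3_TO_1 <- setNames(names(AA3), unname(AA3))

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so generation never perturbs user-level randomness.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# ---- exclusion log ----------------------------------------------------------
# Every operation that drops records attaches a machine-readable log as the
# "exclusions" attribute: one row per dropped record with a reason code.

new_exclusion_log <- function(record_id = character(), gene = character(),
                              protein_change = character(),
                              reason = character(), detail = character()) {
  n <- length(record_id)
  data.frame(record_id = as.character(record_id),
             gene = rep_len(as.character(gene), n),
             protein_change = rep_len(as.character(protein_change), n),
             reason = rep_len(as.character(reason), n),
             detail = rep_len(as.character(detail), n),
             stringsAsFactors = FALSE)
}

#' Retrieve the exclusion log attached to a result
#'
#' Filtering and mapping functions never silently drop a record: each dropped
#' row is recorded in an exclusion log attached to the returned object, with a
#' machine-readable reason code (`not_single_aa_substitution`,
#' `unmatched_gene`, `excluded_reference_gap`, ...).
#'
#' @param x an object returned by a filtering, parsing or mapping function.
#' @return a data frame with columns `record_id`, `gene`, `protein_change`,
#'   `reason`, `detail` (zero rows when nothing was dropped).
#' @export
exclusions <- function(x) {
  log <- attr(x, "exclusions")
  if (is.null(log)) new_exclusion_log() else log
}

set_exclusions <- function(x, log) {
  attr(x, "exclusions") <- log
  x
}

bind_exclusions <- function(...) {
  do.call(rbind, Filter(function(d) !is.null(d) && nrow(d) > 0, list(...))) ->
    out
  if (is.null(out)) new_exclusion_log() else out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

split_conditions <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE), function(v) {
    v <- trimws(v)
    v[nzchar(v)]
  })
}
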