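#' Parse protein-change notation into single amino-acid substitutions
#'
#' Accepts the three common dialects of a missense protein change —
#' `p.Val600Glu`, `p.V600E` and `V600E` — case-insensitively, and normalises
#' to one-letter codes. Everything that is not a single amino-acid
#' substitution (frameshift, nonsense, deletion, insertion, duplication,
#' extension, synonymous, or unparsable text) is rejected with a reason code;
#' the analysis is restricted to variants causing single amino-acid
#' substitutions.
#'
#' @param text character vector of protein-change strings.
#' @return a data frame with one row per input: `input`, `ref_aa`,
#'   `position`, `alt_aa`, `valid` (logical), `reason` (`NA` when valid;
#'   otherwise one of `frameshift`, `nonsense`, `deletion`, `insertion`,
#'   `duplication`, `extension`, `synonymous`, `invalid_aa`, `unparsable`,
#'   `empty`).
#' @examples
#' parse_protein_change(c("p.Val600Glu", "D835Y", "p.Val600fs", "p.Val600="))
#' @export
parse_protein_change <- function(text) {
  text <- as.character(text)
  n <- length(text)
  out <- data.frame(input = text, ref_aa = rep(NA_character_, n),
                    position = rep(NA_integer_, n),
                    alt_aa = rep(NA_character_, n),
                    valid = rep(FALSE, n), reason = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  s <- trimws(text)
  body <- sub("^[pP]\\.", "", s)
  low <- tolower(body)

  reason <- rep(NA_character_, n)
  reason[is.na(s) | !nzchar(s)] <- "empty"
  reason[is.na(reason) & grepl("fs", low, fixed = TRUE)] <- "frameshift"
  reason[is.na(reason) & grepl("delins", low, fixed = TRUE)] <- "deletion"
  reason[is.na(reason) & grepl("del", low, fixed = TRUE)] <- "deletion"
  reason[is.na(reason) & grepl("ins", low, fixed = TRUE)] <- "insertion"
  reason[is.na(reason) & grepl("dup", low, fixed = TRUE)] <- "duplication"
  reason[is.na(reason) & grepl("ext", low, fixed = TRUE)] <- "extension"
  reason[is.na(reason) &
           (grepl("\\*$", body) | grepl("ter$", low))] <- "nonsense"
  reason[is.na(reason) & grepl("=$", body)] <- "synonymous"

  pat <- "^([A-Za-z]{3}|[A-Za-z])([0-9]+)([A-Za-z]{3}|[A-Za-z])$"
  todo <- which(is.na(reason))
  m <- regmatches(body[todo], regexec(pat, body[todo]))
  norm_aa <- function(tok) {
    tok <- toupper(tok)
    if (nchar(tok) == 1) {
      if (tok %in% AA1) tok else NA_character_
    } else {
      unname(AA3_TO_1[tok])
    }
  }
  for (j in seq_along(todo)) {
    i <- todo[j]
    g <- m[[j]]
    if (length(g) != 4) {
      reason[i] <- "unparsable"
      next
    }
    ref <- norm_aa(g[2])
    alt <- norm_aa(g[4])
    pos <- suppressWarnings(as.integer(g[3]))
    if (is.na(ref) || is.na(alt)) {
      reason[i] <- "invalid_aa"
    } else if (is.na(pos) || pos < 1) {
      reason[i] <- "unparsable"
    } else if (ref == alt) {
      reason[i] <- "synonymous"
    } else {
      out$ref_aa[i] <- ref
      out$position[i] <- pos
      out$alt_aa[i] <- alt
      out$valid[i] <- TRUE
    }
  }
  out$reason <- reason
  out
}
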