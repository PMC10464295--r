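#' Count mutations per reference position by disease class
#'
#' Each mapped pathogenic record contributes +1 at its reference residue to
#' every disease class it belongs to (a record related to both a cancer and
#' a non-cancer condition counts once in each class); mapped benign records
#' contribute to the benign column. The deduplication unit is the input
#' record x class.
#'
#' @param mapped mapped pathogenic records (all `status == "mapped"`) with
#'   class flags `is_cancer` / `is_noncancer` (see [assign_classes()]).
#' @param benign_mapped mapped benign records, or `NULL`.
#' @param positions integer vector of reference residue numbers forming the
#'   position universe (typically the structure's residue numbers); defaults
#'   to the positions observed in the inputs.
#' @return a data frame of class `position_counts`: `position`, `cancer`,
#'   `noncancer`, `benign`, with class totals in `attr(, "totals")`.
#' @export
count_by_position <- function(mapped, benign_mapped = NULL,
                              positions = NULL) {
  if (nrow(mapped) > 0) {
    if (!all(c("is_cancer", "is_noncancer") %in% names(mapped)))
      stop_input("mapped records need is_cancer/is_noncancer flags")
    if (any(mapped$status != "mapped"))
      stop_input("count_by_position() requires mapped records only")
  }
  if (!is.null(benign_mapped) && nrow(benign_mapped) > 0 &&
      any(benign_mapped$status != "mapped"))
    stop_input("count_by_position() requires mapped benign records only")
  if (is.null(positions))
    positions <- sort(unique(c(mapped$ref_residue,
                               benign_mapped$ref_residue)))
  positions <- sort(unique(as.integer(positions)))
  tally <- function(pos) {
    if (length(pos) == 0) return(integer(length(positions)))
    as.integer(table(factor(pos, levels = positions)))
  }
  out <- data.frame(
    position = positions,
    cancer = tally(mapped$ref_residue[mapped$is_cancer]),
    noncancer = tally(mapped$ref_residue[mapped$is_noncancer]),
    benign = tally(benign_mapped$ref_residue))
  attr(out, "totals") <- c(C = sum(out$cancer), N = sum(out$noncancer),
                           B = sum(out$benign))
  class(out) <- c("position_counts", "data.frame")
  out
}

#' Select top-quantile mutation hotspots for a class
#'
#' Hotspots are the top 5 percent (by default) most mutated positions of a
#' disease class. The candidate set is the positions carrying at least one
#' mutation of the class; `k = ceiling(quantile * length(candidates))`
#' positions are taken by descending count, and every position tied with the
#' k-th count is included, so selection is deterministic and never drops a
#' tied position arbitrarily. Benign counts never participate.
#'
#' @param counts a `position_counts` from [count_by_position()].
#' @param class `"cancer"` or `"noncancer"`.
#' @param quantile top fraction to call (default 0.05).
#' @param base what "top 5 percent of positions" is taken over:
#'   `"mutated"` (default) counts only positions carrying at least one
#'   mutation of the class, so the hotspot count tracks the mutation data
#'   rather than the domain length; `"structure"` takes the quantile over
#'   every reference position. The two coincide when most positions are
#'   mutated and diverge on sparse data.
#' @return data frame `rank`, `position`, `count`, ordered by count
#'   descending then position ascending.
#' @export
select_hotspots <- function(counts, class = c("cancer", "noncancer"),
                            quantile = 0.05,
                            base = c("mutated", "structure")) {
  class <- match.arg(class)
  base <- match.arg(base)
  if (quantile <= 0 || quantile > 1)
    stop_input("quantile must be in (0, 1]")
  cnt <- counts[[class]]
  cand <- counts$position[cnt > 0]
  cval <- cnt[cnt > 0]
  if (length(cand) == 0) {
    warning("no position carries a ", class, " mutation; no hotspots",
            call. = FALSE)
    return(data.frame(rank = integer(), position = integer(),
                      count = integer()))
  }
  ord <- order(-cval, cand)
  cand <- cand[ord]
  cval <- cval[ord]
  m <- if (base == "mutated") length(cand) else nrow(counts)
  k <- min(ceiling(quantile * m), length(cand))
  cutoff <- cval[k]
  keep <- cval >= cutoff
  data.frame(rank = seq_len(sum(keep)), position = cand[keep],
             count = cval[keep])
}

# conditions of one record restricted to a class
conditions_of_class <- function(conditions, class, lexicon) {
  v <- split_conditions(conditions)[[1]]
  if (length(v) == 0) return(character(0))
  cls <- classify_condition(v, lexicon)
  want <- if (class == "cancer") "cancer" else "non-cancer"
  unique(v[cls == want])
}

#' Gene and disease breakdown of one hotspot position
#'
#' The two-layer composition behind a hotspot: genes contributing mutations
#' at the position (inner layer) and, per gene, the class-matching medical
#' conditions of those mutations (outer layer). A record with several
#' conditions of the class contributes one gene-layer count but one
#' condition-layer entry per condition, so the outer layer can exceed the
#' inner one.
#'
#' @param mapped mapped records with class flags.
#' @param position reference residue number with at least one record of the
#'   class.
#' @param class `"cancer"` or `"noncancer"`.
#' @param lexicon a [disease_lexicon].
#' @return a list of class `hotspot_breakdown`: `position`, `class`,
#'   `count`, `genes` (named integer vector) and `diseases` (data frame
#'   `gene`, `condition`, `count`).
#' @export
position_breakdown <- function(mapped, position,
                               class = c("cancer", "noncancer"),
                               lexicon = disease_lexicon()) {
  class <- match.arg(class)
  flag <- if (class == "cancer") mapped$is_cancer else mapped$is_noncancer
  sel <- mapped[flag & mapped$ref_residue == position &
                  !is.na(mapped$ref_residue), , drop = FALSE]
  if (nrow(sel) == 0)
    stop_input("no ", class, " records at position ", position)
  genes <- sort(table(sel$gene), decreasing = TRUE)
  genes <- setNames(as.integer(genes), names(genes))
  pieces <- lapply(seq_len(nrow(sel)), function(i) {
    conds <- conditions_of_class(sel$conditions[i], class, lexicon)
    if (length(conds) == 0) return(NULL)
    data.frame(gene = sel$gene[i], condition = conds,
               stringsAsFactors = FALSE)
  })
  dis <- do.call(rbind, Filter(Negate(is.null), pieces))
  diseases <- if (is.null(dis)) {
    data.frame(gene = character(), condition = character(),
               count = integer(), stringsAsFactors = FALSE)
  } else {
    agg <- aggregate(list(count = rep(1L, nrow(dis))),
                     by = dis[, c("gene", "condition")], FUN = sum)
    agg[order(agg$gene, -agg$count, agg$condition), , drop = FALSE]
  }
  rownames(diseases) <- NULL
  structure(list(position = position, class = class, count = nrow(sel),
                 genes = genes, diseases = diseases),
            class = "hotspot_breakdown")
}

#' @export
print.hotspot_breakdown <- function(x, ...) {
  cat("hotspot", x$position, "(", x$class, "):", x$count, "mutations in",
      length(x$genes), "gene(s)\n")
  invisible(x)
}

#' Rank genes by mutation count within a class
#'
#' Per-gene totals over all mapped positions of the class, sorted by count
#' descending with alphabetical tie-break.
#'
#' @inheritParams position_breakdown
#' @return data frame `gene`, `count`.
#' @export
rank_genes <- function(mapped, class = c("cancer", "noncancer")) {
  class <- match.arg(class)
  flag <- if (class == "cancer") mapped$is_cancer else mapped$is_noncancer
  sel <- mapped[flag, , drop = FALSE]
  if (nrow(sel) == 0)
    return(data.frame(gene = character(), count = integer()))
  tab <- table(sel$gene)
  out <- data.frame(gene = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export hotspot breakdowns as a JSON tree
#'
#' @param breakdowns a list of [position_breakdown()] results.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_breakdowns_json <- function(breakdowns, path) {
  tree <- lapply(breakdowns, function(b) {
    list(position = b$position, class = b$class, count = b$count,
         genes = as.list(b$genes),
         diseases = b$diseases)
  })
  jsonlite::write_json(tree, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
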