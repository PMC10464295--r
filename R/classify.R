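#' Disease-class lexicon
#'
#' Classifying each ClinVar-style condition string as cancer-related or not
#' is, in the source data, a manual curation step. This package replaces it
#' with a reproducible surrogate: a keyword lexicon (any keyword appearing as
#' a substring of the lower-cased condition marks it cancer) plus an exact
#' override table that takes precedence over keywords. The special class
#' `ignore` (overrides only) removes uninformative entries such as
#' "not provided" from classification.
#'
#' @param cancer_keywords character vector of lowercase substrings.
#' @param overrides named character vector: names are exact condition strings
#'   (matched case-insensitively after trimming), values in
#'   `cancer` / `non-cancer` / `ignore`.
#' @return an object of class `disease_lexicon`.
#' @export
disease_lexicon <- function(cancer_keywords = default_cancer_keywords(),
                            overrides = default_overrides()) {
  cancer_keywords <- tolower(as.character(cancer_keywords))
  if (length(cancer_keywords) < 1)
    stop_input("cancer_keywords must be non-empty")
  if (length(overrides) > 0) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop_input("overrides must be a named character vector")
    names(overrides) <- tolower(trimws(names(overrides)))
    if (anyDuplicated(names(overrides)))
      stop_input("duplicate override condition: ",
                 names(overrides)[duplicated(names(overrides))][1])
    bad <- setdiff(unique(overrides), c("cancer", "non-cancer", "ignore"))
    if (length(bad) > 0)
      stop_input("override class must be cancer, non-cancer or ignore; got ",
                 paste(bad, collapse = ", "))
  }
  structure(list(cancer_keywords = cancer_keywords, overrides = overrides),
            class = "disease_lexicon")
}

#' @rdname disease_lexicon
#' @export
default_cancer_keywords <- function() {
  c("cancer", "carcinoma", "melanoma", "leukemia", "leukaemia", "lymphoma",
    "neoplasm", "neoplasia", "tumor", "tumour", "sarcoma", "blastoma",
    "myeloma", "adenoma", "glioma", "gist", "gastrointestinal stromal",
    "malignan", "myelodysplastic", "polycythemia", "thrombocythemia",
    "myelofibrosis", "mesothelioma", "carcinomatosis")
}

#' @rdname disease_lexicon
#' @export
default_overrides <- function() {
  c("not provided" = "ignore",
    "not specified" = "ignore",
    "see cases" = "ignore")
}

#' Read lexicon overrides from a TSV file
#'
#' Two tab-separated columns, `condition` and `class`
#' (cancer / non-cancer / ignore), merged over the default overrides.
#'
#' @param path TSV path.
#' @param lexicon base lexicon to extend.
#' @return a [disease_lexicon].
#' @export
read_lexicon_overrides <- function(path, lexicon = disease_lexicon()) {
  if (!file.exists(path)) stop_input("override file not found: ", path)
  tab <- read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", check.names = FALSE)
  if (!all(c("condition", "class") %in% names(tab)))
    stop_input("override TSV needs columns `condition` and `class`")
  ov <- setNames(tab$class, tolower(trimws(tab$condition)))
  merged <- lexicon$overrides
  merged[names(ov)] <- ov
  disease_lexicon(lexicon$cancer_keywords, merged)
}

#' Classify a condition string as cancer, non-cancer or ignore
#'
#' The override table is consulted first; otherwise the condition is cancer
#' iff any cancer keyword is a substring of the lower-cased condition, and
#' non-cancer otherwise. Classification depends only on the condition string
#' and the lexicon.
#'
#' @param condition character vector of condition strings.
#' @param lexicon a [disease_lexicon].
#' @return character vector in `cancer` / `non-cancer` / `ignore`.
#' @export
classify_condition <- function(condition, lexicon = disease_lexicon()) {
  stopifnot(inherits(lexicon, "disease_lexicon"))
  key <- tolower(trimws(condition))
  out <- rep(NA_character_, length(key))
  if (length(lexicon$overrides) > 0) {
    hit <- match(key, names(lexicon$overrides))
    out[!is.na(hit)] <- unname(lexicon$overrides[hit[!is.na(hit)]])
  }
  todo <- which(is.na(out))
  if (length(todo) > 0) {
    is_cancer <- Reduce(`|`, lapply(lexicon$cancer_keywords, function(kw)
      grepl(kw, key[todo], fixed = TRUE)))
    out[todo] <- ifelse(is_cancer, "cancer", "non-cancer")
  }
  out
}

#' Assign disease classes to a variant record
#'
#' A record's classes are the union of its per-condition classes (dropping
#' `ignore`): one mutation can be related to several diseases, so a record
#' with both cancer and non-cancer conditions belongs to both classes and is
#' counted once per class downstream.
#'
#' @param conditions a single semicolon-separated condition string, or a
#'   character vector of conditions.
#' @param lexicon a [disease_lexicon].
#' @return character vector, a subset of `c("cancer", "non-cancer")` (empty
#'   when every condition is ignored).
#' @export
assign_classes <- function(conditions, lexicon = disease_lexicon()) {
  conds <- if (length(conditions) == 1 && grepl(";", conditions))
    split_conditions(conditions)[[1]]
  else {
    v <- trimws(as.character(conditions))
    v[nzchar(v)]
  }
  if (length(conds) == 0) return(character(0))
  cls <- classify_condition(conds, lexicon)
  intersect(c("cancer", "non-cancer"), unique(cls))
}

#' Add per-record disease-class membership flags
#'
#' Applies [assign_classes()] to every record, adding logical columns
#' `is_cancer` and `is_noncancer`. Records whose conditions are all ignored
#' get neither flag and are added to the exclusion log.
#'
#' @param records variant record data frame.
#' @param lexicon a [disease_lexicon].
#' @return `records` with the two flag columns.
#' @export
variant_classes <- function(records, lexicon = disease_lexicon()) {
  conds <- split_conditions(records$conditions)
  cls <- lapply(conds, function(v) {
    if (length(v) == 0) character(0)
    else setdiff(unique(classify_condition(v, lexicon)), "ignore")
  })
  records$is_cancer <- vapply(cls, function(x) "cancer" %in% x, TRUE)
  records$is_noncancer <- vapply(cls, function(x) "non-cancer" %in% x, TRUE)
  empty <- !records$is_cancer & !records$is_noncancer
  log <- bind_exclusions(
    exclusions(records),
    new_exclusion_log(record_id = records$record_id[empty],
                      gene = records$gene[empty],
                      protein_change = records$protein_change[empty],
                      reason = "no_informative_condition",
                      detail = records$conditions[empty]))
  set_exclusions(records, log)
}

normalize_significance <- function(x) {
  lapply(strsplit(tolower(gsub("[_-]", " ", as.character(x))), "/",
                  fixed = TRUE),
         function(v) {
           v <- gsub("[[:space:]]+", " ", trimws(v))
           v[nzchar(v)]
         })
}

#' Keep pathogenic and likely-pathogenic records
#'
#' Retains exactly the records whose clinical significance contains
#' `Pathogenic` or `Likely pathogenic`, matched case-insensitively; composite
#' labels such as `Pathogenic/Likely pathogenic` are treated as multi-label
#' and kept. All other records are logged and dropped. Idempotent.
#'
#' @param records variant record data frame.
#' @return the filtered data frame with the exclusion log extended.
#' @export
filter_pathogenic <- function(records) {
  labels <- normalize_significance(records$clinical_significance)
  keep <- vapply(labels, function(v)
    any(v %in% c("pathogenic", "likely pathogenic")), TRUE)
  log <- bind_exclusions(
    exclusions(records),
    new_exclusion_log(record_id = records$record_id[!keep],
                      gene = records$gene[!keep],
                      protein_change = records$protein_change[!keep],
                      reason = "not_pathogenic",
                      detail = records$clinical_significance[!keep]))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  set_exclusions(out, log)
}

#' Keep common benign records (allele-frequency filter)
#'
#' Retains records with clinical significance `Benign` (optionally also
#' `Likely benign`) whose population allele frequency is at or above the
#' threshold — the threshold is inclusive: AF = 0.01 is kept at the default
#' 1 percent cutoff. Records without an allele frequency are dropped and
#' logged. Idempotent.
#'
#' @param records variant record data frame with `allele_frequency`.
#' @param af_threshold inclusive allele-frequency threshold (default 0.01).
#' @param include_likely_benign also keep `Likely benign` (default `FALSE`).
#' @return the filtered data frame with the exclusion log extended.
#' @export
filter_benign <- function(records, af_threshold = 0.01,
                          include_likely_benign = FALSE) {
  if (af_threshold < 0 || af_threshold > 1)
    stop_input("af_threshold must be in [0, 1]")
  wanted <- c("benign", if (include_likely_benign) "likely benign")
  labels <- normalize_significance(records$clinical_significance)
  sig_ok <- vapply(labels, function(v) any(v %in% wanted), TRUE)
  af <- records$allele_frequency %||% rep(NA_real_, nrow(records))
  reason <- rep(NA_character_, nrow(records))
  reason[!sig_ok] <- "not_benign"
  reason[sig_ok & is.na(af)] <- "missing_allele_frequency"
  reason[sig_ok & !is.na(af) & af < af_threshold] <-
    "allele_frequency_below_threshold"
  keep <- is.na(reason)
  log <- bind_exclusions(
    exclusions(records),
    new_exclusion_log(record_id = records$record_id[!keep],
                      gene = records$gene[!keep],
                      protein_change = records$protein_change[!keep],
                      reason = reason[!keep],
                      detail = as.character(af[!keep])))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  set_exclusions(out, log)
}

#' Audit table of condition classifications
#'
#' Every distinct condition string across the records, the class it was
#' assigned, whether an override or a keyword (or the non-cancer default)
#' decided it, and how many records carry it — the reviewable record of the
#' automated stand-in for manual condition curation.
#'
#' @param records variant record data frame.
#' @param lexicon a [disease_lexicon].
#' @return data frame: `condition`, `class`, `source`, `n_records`.
#' @export
condition_audit <- function(records, lexicon = disease_lexicon()) {
  conds <- unlist(split_conditions(records$conditions), use.names = FALSE)
  if (length(conds) == 0)
    return(data.frame(condition = character(), class = character(),
                      source = character(), n_records = integer(),
                      stringsAsFactors = FALSE))
  tab <- table(conds)
  condition <- names(tab)
  key <- tolower(trimws(condition))
  cls <- classify_condition(condition, lexicon)
  overridden <- key %in% names(lexicon$overrides)
  keyword_hit <- Reduce(`|`, lapply(lexicon$cancer_keywords, function(kw)
    grepl(kw, key, fixed = TRUE)))
  source <- ifelse(overridden, "override",
                   ifelse(keyword_hit, "keyword", "default"))
  out <- data.frame(condition = condition, class = cls, source = source,
                    n_records = as.integer(tab), stringsAsFactors = FALSE)
  out[order(out$condition), , drop = FALSE]
}
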