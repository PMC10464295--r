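#' Default disease-condition pools for simulation
#'
#' Condition strings drawn by the generator, mirroring the kinds of entries a
#' clinical variant export contains: recognisable cancer diagnoses for the
#' cancer pool and Mendelian/developmental syndromes for the non-cancer pool.
#' @name condition_pools
NULL

default_cancer_pool <- function() {
  c("Melanoma", "Lung adenocarcinoma", "Acute myeloid leukemia",
    "Neoplasm of the large intestine", "Gastrointestinal stromal tumor",
    "Hepatocellular carcinoma", "Multiple myeloma",
    "Squamous cell carcinoma of the head and neck")
}

default_noncancer_pool <- function() {
  c("Noonan syndrome", "Cardiofaciocutaneous syndrome",
    "Developmental and epileptic encephalopathy", "Hypochondroplasia",
    "Pulmonary hypertension", "X-linked agammaglobulinemia",
    "Leber congenital amaurosis", "Intellectual developmental disorder")
}

#' Simulation configuration
#'
#' Defines a complete synthetic study: an aligned set of kinase domains, a
#' reference structure, pathogenic variants (background plus planted
#' hotspots) and benign variants with population allele frequencies. The same
#' configuration (including `seed`) always produces byte-identical outputs.
#'
#' @param n_proteins number of alignment rows (row 1 is the reference).
#' @param ref_length ungapped length of the reference row.
#' @param gap_fraction probability that a reference column is gapped in a
#'   non-reference row, in `[0, 1)`.
#' @param planted_hotspots data frame with columns `position` (1-based index
#'   into the ungapped reference sequence), `class` (`cancer`, `non-cancer`
#'   or `benign`) and `mean_mutations` (Poisson mean of the planted count).
#'   `NULL` for none.
#' @param background_rate mean number of background mutations per protein per
#'   pathogenic class (cancer, non-cancer); background positions are uniform
#'   over each row's ungapped residues.
#' @param n_benign number of background benign records.
#' @param cancer_conditions,noncancer_conditions condition-string pools.
#' @param mixed_condition_prob probability that a pathogenic record also
#'   carries one condition from the opposite pool (such records belong to
#'   both disease classes downstream).
#' @param insert_columns number of alignment columns in which the reference
#'   is gapped (inserted relative to the reference); variants landing there
#'   exercise the reference-gap exclusion. Default: 4 percent of
#'   `ref_length`.
#' @param include_threshold_af if `TRUE` and `n_benign >= 2`, one benign
#'   record gets allele frequency exactly 0.01 and one gets 0.005, so the
#'   benign filter's inclusive threshold is exercised from both sides.
#' @param seed integer RNG seed.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 100L, ref_length = 250L,
                       gap_fraction = 0.15, planted_hotspots = NULL,
                       background_rate = 0.02, n_benign = 30L,
                       cancer_conditions = default_cancer_pool(),
                       noncancer_conditions = default_noncancer_pool(),
                       mixed_condition_prob = 0.05,
                       insert_columns = NULL,
                       include_threshold_af = TRUE,
                       seed = 0L) {
  chk_count <- function(x, nm, min = 1) {
    if (length(x) != 1 || is.na(x) || x != round(x) || x < min)
      stop_input("invalid configuration: `", nm, "` must be an integer >= ",
                 min)
    as.integer(x)
  }
  n_proteins <- chk_count(n_proteins, "n_proteins")
  ref_length <- chk_count(ref_length, "ref_length")
  n_benign <- chk_count(n_benign, "n_benign", min = 0)
  if (length(gap_fraction) != 1 || is.na(gap_fraction) ||
      gap_fraction < 0 || gap_fraction >= 1)
    stop_input("invalid configuration: `gap_fraction` must be in [0, 1)")
  if (length(background_rate) != 1 || is.na(background_rate) ||
      background_rate < 0)
    stop_input("invalid configuration: `background_rate` must be >= 0")
  if (length(mixed_condition_prob) != 1 || mixed_condition_prob < 0 ||
      mixed_condition_prob > 1)
    stop_input("invalid configuration: `mixed_condition_prob` in [0, 1]")
  if (is.null(insert_columns)) insert_columns <- round(0.04 * ref_length)
  insert_columns <- chk_count(insert_columns, "insert_columns", min = 0)
  if (length(cancer_conditions) < 1 || length(noncancer_conditions) < 1)
    stop_input("invalid configuration: condition pools must be non-empty")
  if (!is.null(planted_hotspots)) {
    planted_hotspots <- as.data.frame(planted_hotspots)
    need <- c("position", "class", "mean_mutations")
    if (!all(need %in% names(planted_hotspots)))
      stop_input("invalid configuration: `planted_hotspots` needs columns ",
                 paste(need, collapse = ", "))
    if (any(planted_hotspots$position < 1) ||
        any(planted_hotspots$position > ref_length))
      stop_input("invalid configuration: `planted_hotspots$position` must ",
                 "lie in [1, ref_length]")
    if (!all(planted_hotspots$class %in% c("cancer", "non-cancer", "benign")))
      stop_input("invalid configuration: `planted_hotspots$class` must be ",
                 "cancer, non-cancer or benign")
    if (any(planted_hotspots$mean_mutations <= 0))
      stop_input("invalid configuration: `planted_hotspots$mean_mutations` ",
                 "must be positive")
  }
  seed <- chk_count(seed, "seed", min = 0)
  structure(list(n_proteins = n_proteins, ref_length = ref_length,
                 gap_fraction = gap_fraction,
                 planted_hotspots = planted_hotspots,
                 background_rate = background_rate, n_benign = n_benign,
                 cancer_conditions = cancer_conditions,
                 noncancer_conditions = noncancer_conditions,
                 mixed_condition_prob = mixed_condition_prob,
                 insert_columns = insert_columns,
                 include_threshold_af = include_threshold_af,
                 seed = seed),
            class = "sim_config")
}

#' Generate a synthetic structure-based MSA
#'
#' Row 1 is the reference: it has no gaps over its own `ref_length` residues,
#' but `insert_columns` extra columns are interleaved where the reference is
#' gapped and other rows may carry residues, so the reference-gap exclusion
#' path is exercised. Non-reference rows are gapped at reference columns with
#' probability `gap_fraction`. Each row gets a residue-number offset sampled
#' in [1, 500] to force nontrivial coordinate arithmetic.
#'
#' @param config a [sim_config].
#' @return a [kinase_msa].
#' @export
generate_msa <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(config$seed, {
    n <- config$n_proteins
    L <- config$ref_length
    n_cols <- L + config$insert_columns
    ins <- sort(sample.int(n_cols, config$insert_columns))
    is_ins <- seq_len(n_cols) %in% ins
    gene <- sprintf("KIN%04d", seq_len(n))
    protein_id <- sprintf("P%05d", seq_len(n))
    offset <- sample.int(500L, n, replace = TRUE)
    seqs <- character(n)
    for (i in seq_len(n)) {
      ch <- rep("-", n_cols)
      if (i == 1) {
        ch[!is_ins] <- sample(AA1, L, replace = TRUE)
      } else {
        ref_cols <- which(!is_ins)
        gapped <- runif(L) < config$gap_fraction
        ch[ref_cols[!gapped]] <- sample(AA1, sum(!gapped), replace = TRUE)
        occupied <- runif(config$insert_columns) < 0.3
        if (any(occupied))
          ch[ins[occupied]] <- sample(AA1, sum(occupied), replace = TRUE)
      }
      seqs[i] <- paste(ch, collapse = "")
    }
    kinase_msa(gene, protein_id, offset, seqs, reference_index = 1L)
  })
}

#' Generate the reference structure for a synthetic MSA
#'
#' One CA record per ungapped reference residue, numbered
#' `offset .. offset + ref_length - 1`, with placeholder coordinates on an
#' ideal alpha helix (rise 1.5 A, 100 degrees per residue, radius 2.3 A) and
#' B-factors initialised to 0.00.
#'
#' @param msa a [kinase_msa] with a designated reference row.
#' @return a [ref_structure].
#' @export
generate_reference_structure <- function(msa) {
  stopifnot(inherits(msa, "kinase_msa"))
  res <- msa_reference_residues(msa)
  L <- length(res)
  if (L == 0) stop_input("reference row has no residues")
  offset <- msa$rows$offset[msa$reference_index]
  t <- seq_len(L) - 1
  ang <- t * 100 * pi / 180
  ref_structure(residue_number = offset + t,
                residue_name = unname(AA3[res]),
                x = round(2.3 * cos(ang), 3),
                y = round(2.3 * sin(ang), 3),
                z = round(1.5 * t, 3),
                b_factor = 0, chain_id = "A")
}

# Per-row residue bookkeeping shared by the variant generators.
row_residue_info <- function(msa, i) {
  cols <- msa_residue_columns(msa, i)
  list(cols = cols, chars = msa_row_chars(msa, i)[cols],
       resno = msa$rows$offset[i] + seq_along(cols) - 1L)
}

# 1-based reference position of each alignment column (NA where the
# reference is gapped).
reference_position_of_column <- function(msa) {
  ch <- msa_row_chars(msa, msa$reference_index)
  idx <- cumsum(ch != "-")
  idx[ch == "-"] <- NA_integer_
  idx
}

random_protein_change <- function(ref_aa, resno) {
  alt <- vapply(ref_aa, function(a) sample(setdiff(AA1, a), 1), "")
  dialect <- sample(1:3, length(ref_aa), replace = TRUE)
  ifelse(dialect == 1,
         sprintf("p.%s%d%s", AA3[ref_aa], resno, AA3[alt]),
         ifelse(dialect == 2,
                sprintf("p.%s%d%s", ref_aa, resno, alt),
                sprintf("%s%d%s", ref_aa, resno, alt)))
}

sample_conditions <- function(class, config) {
  own <- if (class == "cancer") config$cancer_conditions
         else config$noncancer_conditions
  other <- if (class == "cancer") config$noncancer_conditions
           else config$cancer_conditions
  conds <- sample(own, sample(1:2, 1))
  if (runif(1) < config$mixed_condition_prob)
    conds <- c(conds, sample(other, 1))
  paste(unique(conds), collapse = ";")
}

# Draw background and planted mutation events for the given classes.
# Returns a data frame of (row, residue_index, class, planted).
draw_events <- function(msa, config, classes) {
  info <- lapply(seq_len(nrow(msa$rows)), function(i) row_residue_info(msa, i))
  ev <- list()
  for (cl in classes) {
    if (cl %in% c("cancer", "non-cancer") && config$background_rate > 0) {
      k <- rpois(nrow(msa$rows), config$background_rate)
      for (i in which(k > 0)) {
        idx <- sample.int(length(info[[i]]$cols), k[i], replace = TRUE)
        ev[[length(ev) + 1]] <- data.frame(row = i, residue_index = idx,
                                          class = cl, planted = FALSE)
      }
    }
  }
  ph <- config$planted_hotspots
  if (!is.null(ph)) {
    ref_cols <- msa_residue_columns(msa, msa$reference_index)
    for (j in seq_len(nrow(ph))) {
      if (!ph$class[j] %in% classes) next
      col <- ref_cols[ph$position[j]]
      eligible <- which(vapply(seq_len(nrow(msa$rows)), function(i) {
        col %in% info[[i]]$cols
      }, TRUE))
      if (identical(eligible, msa$reference_index))
        warning("planted position ", ph$position[j],
                " is gapped in all non-reference rows; ",
                "hotspot emitted on the reference row only", call. = FALSE)
      k <- rpois(1, ph$mean_mutations[j])
      if (k == 0) next
      rows <- sample(eligible, k, replace = TRUE)
      idx <- vapply(rows, function(i) match(col, info[[i]]$cols), 1L)
      ev[[length(ev) + 1]] <- data.frame(row = rows, residue_index = idx,
                                        class = ph$class[j], planted = TRUE)
    }
  }
  events <- if (length(ev) > 0) do.call(rbind, ev)
            else data.frame(row = integer(), residue_index = integer(),
                            class = character(), planted = logical())
  attr(events, "row_info") <- info
  events
}

events_to_records <- function(msa, events, id_prefix) {
  info <- attr(events, "row_info")
  n <- nrow(events)
  if (n == 0) {
    return(data.frame(record_id = character(), gene = character(),
                      protein_change = character(),
                      clinical_significance = character(),
                      conditions = character(),
                      allele_frequency = numeric(),
                      row = integer(), residue_number = integer(),
                      ref_aa = character(), stringsAsFactors = FALSE))
  }
  ref_aa <- character(n)
  resno <- integer(n)
  for (e in seq_len(n)) {
    inf <- info[[events$row[e]]]
    ref_aa[e] <- inf$chars[events$residue_index[e]]
    resno[e] <- inf$resno[events$residue_index[e]]
  }
  data.frame(record_id = sprintf("%s%05d", id_prefix, seq_len(n)),
             gene = msa$rows$gene[events$row],
             protein_change = random_protein_change(ref_aa, resno),
             clinical_significance = NA_character_,
             conditions = NA_character_,
             allele_frequency = NA_real_,
             row = events$row, residue_number = resno, ref_aa = ref_aa,
             stringsAsFactors = FALSE)
}

# True reference position of each event: the ungapped reference index of the
# alignment column the event sits in (NA at insert columns).
true_reference_position <- function(msa, events) {
  info <- attr(events, "row_info")
  refpos <- reference_position_of_column(msa)
  vapply(seq_len(nrow(events)), function(e) {
    col <- info[[events$row[e]]]$cols[events$residue_index[e]]
    refpos[col]
  }, NA_integer_)
}

#' Generate pathogenic variant records with a ground-truth sidecar
#'
#' Background variants are placed uniformly over the ungapped residues of
#' random rows at rate `background_rate` per protein per class; planted
#' hotspot variants land on rows carrying a residue in the hotspot's
#' reference column, with Poisson counts. Clinical significance is drawn from
#' Pathogenic / Likely pathogenic and conditions from the matching pool (with
#' a small probability of also carrying a condition from the other pool, so
#' some records belong to both disease classes).
#'
#' The returned table carries a `truth` attribute: `record_id`, the true
#' reference position (`NA` for variants at columns where the reference is
#' gapped) and the true class of every emitted variant. The truth table is
#' written as a separate sidecar file by [simulate_dataset()] and is never
#' read by any analysis stage.
#'
#' @param msa a [kinase_msa] from [generate_msa()].
#' @param config the [sim_config] used to build `msa`.
#' @return a variant record data frame with attribute `truth`.
#' @export
generate_variants <- function(msa, config) {
  stopifnot(inherits(msa, "kinase_msa"), inherits(config, "sim_config"))
  local_seed(config$seed + 1L, {
    events <- draw_events(msa, config, c("cancer", "non-cancer"))
    rec <- events_to_records(msa, events, "V")
    n <- nrow(rec)
    if (n > 0) {
      rec$clinical_significance <- sample(c("Pathogenic", "Likely pathogenic"),
                                          n, replace = TRUE)
      rec$conditions <- vapply(events$class, sample_conditions, "",
                               config = config)
    }
    truth <- data.frame(record_id = rec$record_id,
                        gene = rec$gene,
                        residue_number = rec$residue_number,
                        true_ref_position = true_reference_position(msa,
                                                                    events),
                        class = events$class,
                        planted = events$planted,
                        stringsAsFactors = FALSE)
    rec$row <- rec$residue_number <- rec$ref_aa <- NULL
    attr(rec, "truth") <- truth
    rec
  })
}

#' Generate benign variant records with population allele frequencies
#'
#' `n_benign` background benign records are placed uniformly over random
#' rows; planted hotspots of class `benign` add Poisson-distributed records
#' at their reference column with allele frequencies at or above 0.01 (so
#' they survive the benign filter). Background allele frequencies are drawn
#' log-uniformly in (0.0001, 0.5]; when `include_threshold_af` is set and at
#' least two records exist, one record is pinned to exactly 0.01 and one to
#' 0.005 to exercise the inclusive 1 percent threshold from both sides.
#'
#' @inheritParams generate_variants
#' @return a benign record data frame with attribute `truth`.
#' @export
generate_benign_variants <- function(msa, config) {
  stopifnot(inherits(msa, "kinase_msa"), inherits(config, "sim_config"))
  local_seed(config$seed + 2L, {
    info <- lapply(seq_len(nrow(msa$rows)),
                   function(i) row_residue_info(msa, i))
    ev <- list()
    if (config$n_benign > 0) {
      rows <- sample.int(nrow(msa$rows), config$n_benign, replace = TRUE)
      idx <- vapply(rows, function(i)
        sample.int(length(info[[i]]$cols), 1), 1L)
      ev[[1]] <- data.frame(row = rows, residue_index = idx,
                            class = "benign", planted = FALSE)
    }
    ph <- config$planted_hotspots
    if (!is.null(ph) && any(ph$class == "benign")) {
      ref_cols <- msa_residue_columns(msa, msa$reference_index)
      for (j in which(ph$class == "benign")) {
        col <- ref_cols[ph$position[j]]
        eligible <- which(vapply(seq_len(nrow(msa$rows)), function(i)
          col %in% info[[i]]$cols, TRUE))
        k <- rpois(1, ph$mean_mutations[j])
        if (k == 0) next
        rows <- sample(eligible, k, replace = TRUE)
        idx <- vapply(rows, function(i) match(col, info[[i]]$cols), 1L)
        ev[[length(ev) + 1]] <- data.frame(row = rows, residue_index = idx,
                                          class = "benign", planted = TRUE)
      }
    }
    events <- if (length(ev) > 0) do.call(rbind, ev)
              else data.frame(row = integer(), residue_index = integer(),
                              class = character(), planted = logical())
    attr(events, "row_info") <- info
    rec <- events_to_records(msa, events, "B")
    n <- nrow(rec)
    if (n > 0) {
      rec$clinical_significance <- "Benign"
      rec$conditions <- "not provided"
      af <- 10^runif(n, -4, log10(0.5))
      af[events$planted] <- runif(sum(events$planted), 0.01, 0.5)
      bg <- which(!events$planted)
      if (config$include_threshold_af && length(bg) >= 2) {
        af[bg[1]] <- 0.01
        af[bg[2]] <- 0.005
      }
      rec$allele_frequency <- round(af, 6)
    }
    truth <- data.frame(record_id = rec$record_id,
                        gene = rec$gene,
                        residue_number = rec$residue_number,
                        true_ref_position = true_reference_position(msa,
                                                                    events),
                        class = events$class,
                        planted = events$planted,
                        stringsAsFactors = FALSE)
    rec$row <- rec$residue_number <- rec$ref_aa <- NULL
    attr(rec, "truth") <- truth
    rec
  })
}

#' Generate and write a complete synthetic dataset
#'
#' Writes the four pipeline inputs (aligned FASTA, reference PDB, pathogenic
#' variant TSV, benign variant TSV) plus a `truth.tsv` sidecar giving every
#' variant's true reference position and class. The sidecar exists only for
#' validation; no analysis stage reads it.
#'
#' @param config a [sim_config].
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the generated objects and file paths
#'   (`msa`, `structure`, `variants`, `benign`, `paths`).
#' @export
simulate_dataset <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  msa <- generate_msa(config)
  structure <- generate_reference_structure(msa)
  variants <- generate_variants(msa, config)
  benign <- generate_benign_variants(msa, config)
  paths <- list(msa = file.path(outdir, "msa.fasta"),
                structure = file.path(outdir, "structure.pdb"),
                variants = file.path(outdir, "variants.tsv"),
                benign = file.path(outdir, "benign.tsv"),
                truth = file.path(outdir, "truth.tsv"))
  write_msa(msa, paths$msa)
  write_structure(structure, paths$structure)
  write_variant_table(variants, paths$variants)
  write_variant_table(benign, paths$benign)
  truth <- rbind(attr(variants, "truth"), attr(benign, "truth"))
  write_tsv(truth, paths$truth)
  invisible(list(msa = msa, structure = structure, variants = variants,
                 benign = benign, truth = truth, paths = paths))
}
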