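#' Configuration of a full analysis run
#'
#' Bundles the input paths and the analysis parameters: hotspot quantile
#' (top 5 percent by default), significance level, inclusive benign
#' allele-frequency threshold (1 percent by default), continuity-correction
#' and reference-verification flags.
#'
#' @param msa path to the aligned FASTA of kinase domains.
#' @param structure path to the reference PDB.
#' @param variants path to the pathogenic variant TSV.
#' @param benign optional path to the benign variant TSV.
#' @param lexicon_overrides optional path to a condition override TSV.
#' @param outdir output directory.
#' @param reference reference row selector passed to [read_msa()].
#' @param chain structure chain passed to [read_structure()].
#' @param quantile hotspot quantile in (0, 1).
#' @param quantile_base quantile base for [select_hotspots()]: `"mutated"`
#'   (default) or `"structure"`.
#' @param alpha significance level in (0, 1).
#' @param af_threshold inclusive benign allele-frequency threshold in [0, 1].
#' @param yates chi-square continuity correction (default on).
#' @param verify_ref_aa verify stated reference residues against the MSA.
#' @param collapse_aa collapse duplicate records of the same gene and amino
#'   acid change to one before counting (default off: the counting unit is
#'   the input record).
#' @param include_likely_benign also admit `Likely benign` records to the
#'   benign branch.
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(msa, structure, variants, benign = NULL,
                       lexicon_overrides = NULL, outdir = ".",
                       reference = NULL, chain = NULL,
                       quantile = 0.05, quantile_base = c("mutated", "structure"),
                       alpha = 0.05, af_threshold = 0.01,
                       yates = TRUE, verify_ref_aa = TRUE,
                       collapse_aa = FALSE, include_likely_benign = FALSE) {
  if (quantile <= 0 || quantile >= 1) stop_input("quantile must be in (0, 1)")
  quantile_base <- match.arg(quantile_base)
  if (alpha <= 0 || alpha >= 1) stop_input("alpha must be in (0, 1)")
  if (af_threshold < 0 || af_threshold > 1)
    stop_input("af_threshold must be in [0, 1]")
  cfg <- list(msa = msa, structure = structure, variants = variants,
              benign = benign, lexicon_overrides = lexicon_overrides,
              outdir = outdir, reference = reference, chain = chain,
              quantile = quantile, quantile_base = quantile_base,
              alpha = alpha,
              af_threshold = af_threshold, yates = yates,
              verify_ref_aa = verify_ref_aa, collapse_aa = collapse_aa,
              include_likely_benign = include_likely_benign)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; relative input paths are
#' resolved against the YAML file's directory.
#'
#' @param path YAML path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: ", path)
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  args <- y
  for (key in c("msa", "structure", "variants", "benign",
                "lexicon_overrides"))
    args[[key]] <- resolve(y[[key]])
  do.call(run_config, args)
}

#' Summarise mapped benign mutations
#'
#' Total benign mutation count, per-position counts, and the per-position
#' maximum: the summary of each residue's intrinsic tendency to vary in the
#' healthy population.
#'
#' @param benign_counts integer vector of per-position benign counts (e.g.
#'   the `benign` column of [count_by_position()]), or a `position_counts`.
#' @return list: `total`, `max_per_position`, `per_position` (data frame).
#' @export
summarize_benign <- function(benign_counts) {
  if (inherits(benign_counts, "position_counts")) {
    per <- data.frame(position = benign_counts$position,
                      count = benign_counts$benign)
  } else {
    per <- data.frame(position = seq_along(benign_counts),
                      count = as.integer(benign_counts))
  }
  list(total = sum(per$count),
       max_per_position = if (nrow(per) == 0) 0L else max(per$count),
       per_position = per)
}

collapse_aa_records <- function(records) {
  key <- paste(records$gene, records$ref_aa, records$position,
               records$alt_aa, sep = ":")
  out <- records[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  set_exclusions(out, exclusions(records))
}

#' Run the full hotspot analysis
#'
#' Executes the whole pipeline: read inputs, keep pathogenic records, map
#' them through the alignment onto the reference structure, classify
#' conditions into cancer / non-cancer, count mutations per reference
#' position, call top-quantile hotspots per class with their gene/disease
#' breakdowns, compute per-position representation statistics, run the
#' benign branch (allele-frequency filter, mapping, per-position counts and
#' maximum), and write all result tables, four B-factor-annotated PDBs
#' (cancer, non-cancer, benign, total), the exclusion log, the condition
#' audit table and a JSON run manifest into `outdir`.
#'
#' Input consistency (reference row versus structure) is checked before any
#' output is written; failures abort with no partial outputs.
#'
#' @param config a [run_config].
#' @return invisibly, a list with every intermediate and final object:
#'   `msa`, `structure`, `mapped`, `counts`, `hotspots` (per class),
#'   `breakdowns`, `stats`, `gene_ranking`, `benign`, `paths`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (key in c("msa", "structure", "variants"))
    if (!file.exists(config[[key]]))
      stop_input("input file not found: ", config[[key]])
  if (!is.null(config$benign) && !file.exists(config$benign))
    stop_input("input file not found: ", config$benign)

  msa <- read_msa(config$msa, reference = config$reference)
  structure <- read_structure(config$structure, chain = config$chain)
  if (length(msa_reference_residues(msa)) != nrow(structure$residues))
    stop_input("reference row and structure are inconsistent: ",
               length(msa_reference_residues(msa)), " reference residues vs ",
               nrow(structure$residues), " CA records")
  lexicon <- if (!is.null(config$lexicon_overrides))
    read_lexicon_overrides(config$lexicon_overrides)
  else disease_lexicon()

  variants <- read_variant_table(config$variants)
  path_filtered <- filter_pathogenic(variants)
  mapped_all <- map_variants(path_filtered, msa, structure,
                             verify_ref_aa = config$verify_ref_aa)
  mapped <- mapped_all[mapped_all$status == "mapped", , drop = FALSE]
  mapped <- set_exclusions(mapped, exclusions(mapped_all))
  if (config$collapse_aa) mapped <- collapse_aa_records(mapped)
  mapped <- variant_classes(mapped, lexicon)
  informative <- mapped$is_cancer | mapped$is_noncancer
  counted <- mapped[informative, , drop = FALSE]

  benign_mapped <- NULL
  if (!is.null(config$benign)) {
    ben <- read_variant_table(config$benign)
    ben <- filter_benign(ben, af_threshold = config$af_threshold,
                         include_likely_benign = config$include_likely_benign)
    ben_mapped_all <- map_variants(ben, msa, structure,
                                   verify_ref_aa = config$verify_ref_aa)
    benign_mapped <- ben_mapped_all[ben_mapped_all$status == "mapped", ,
                                    drop = FALSE]
    benign_mapped <- set_exclusions(benign_mapped,
                                    exclusions(ben_mapped_all))
  }

  counts <- count_by_position(counted, benign_mapped,
                              positions = structure$residues$residue_number)
  hotspots <- list(
    cancer = if (sum(counts$cancer) > 0)
      select_hotspots(counts, "cancer", config$quantile,
                      base = config$quantile_base)
    else data.frame(rank = integer(), position = integer(),
                    count = integer()),
    noncancer = if (sum(counts$noncancer) > 0)
      select_hotspots(counts, "noncancer", config$quantile,
                      base = config$quantile_base)
    else data.frame(rank = integer(), position = integer(),
                    count = integer()))
  breakdowns <- lapply(c(cancer = "cancer", noncancer = "noncancer"),
                       function(cl) {
    lapply(hotspots[[cl]]$position, function(p)
      position_breakdown(counted, p, cl, lexicon))
  })
  stats <- classify_positions(counts, alpha = config$alpha,
                              yates = config$yates)
  gene_ranking <- list(cancer = rank_genes(counted, "cancer"),
                       noncancer = rank_genes(counted, "noncancer"))
  benign_summary <- summarize_benign(counts)

  # ---- outputs --------------------------------------------------------------
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)
  paths <- list(counts = out("position_counts.tsv"),
                hotspots_cancer = out("hotspots_cancer.tsv"),
                hotspots_noncancer = out("hotspots_noncancer.tsv"),
                breakdowns_cancer = out("breakdowns_cancer.json"),
                breakdowns_noncancer = out("breakdowns_noncancer.json"),
                stats = out("position_stats.tsv"),
                genes_cancer = out("gene_ranking_cancer.tsv"),
                genes_noncancer = out("gene_ranking_noncancer.tsv"),
                pdb_cancer = out("annotated_cancer.pdb"),
                pdb_noncancer = out("annotated_noncancer.pdb"),
                pdb_benign = out("annotated_benign.pdb"),
                pdb_total = out("annotated_total.pdb"),
                exclusions = out("exclusions.tsv"),
                audit = out("condition_audit.tsv"),
                benign_summary = out("benign_summary.tsv"),
                manifest = out("manifest.json"))
  t0 <- proc.time()[["elapsed"]]
  write_tsv(as.data.frame(counts), paths$counts)
  write_tsv(hotspots$cancer, paths$hotspots_cancer)
  write_tsv(hotspots$noncancer, paths$hotspots_noncancer)
  write_breakdowns_json(breakdowns$cancer, paths$breakdowns_cancer)
  write_breakdowns_json(breakdowns$noncancer, paths$breakdowns_noncancer)
  write_tsv(stats, paths$stats)
  write_tsv(gene_ranking$cancer, paths$genes_cancer)
  write_tsv(gene_ranking$noncancer, paths$genes_noncancer)
  ann <- function(col) setNames(counts[[col]], counts$position)
  write_annotated_pdb(structure, ann("cancer"), paths$pdb_cancer)
  write_annotated_pdb(structure, ann("noncancer"), paths$pdb_noncancer)
  write_annotated_pdb(structure, ann("benign"), paths$pdb_benign)
  write_annotated_pdb(structure,
                      setNames(counts$cancer + counts$noncancer,
                               counts$position), paths$pdb_total)
  all_exclusions <- bind_exclusions(exclusions(mapped),
                                    if (!is.null(benign_mapped))
                                      exclusions(benign_mapped))
  write_tsv(all_exclusions, paths$exclusions)
  write_tsv(condition_audit(counted, lexicon), paths$audit)
  write_tsv(benign_summary$per_position, paths$benign_summary)

  inputs <- Filter(Negate(is.null),
                   config[c("msa", "structure", "variants", "benign",
                            "lexicon_overrides")])
  manifest <- list(
    tool = "kinasehotspots",
    version = as.character(utils::packageVersion("kinasehotspots")),
    parameters = config[c("quantile", "quantile_base", "alpha",
                          "af_threshold", "yates",
                          "verify_ref_aa", "collapse_aa",
                          "include_likely_benign")],
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(md5sum(p)))),
    n_input_variants = nrow(variants) + nrow(exclusions(variants)),
    n_mapped = nrow(mapped),
    n_counted = nrow(counted),
    exclusion_reasons = as.list(table(all_exclusions$reason)),
    totals = as.list(attr(counts, "totals")),
    elapsed_seconds = round(proc.time()[["elapsed"]] - t0, 3))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(msa = msa, structure = structure, lexicon = lexicon,
                 mapped = mapped, counted = counted,
                 benign_mapped = benign_mapped, counts = counts,
                 hotspots = hotspots, breakdowns = breakdowns,
                 stats = stats, gene_ranking = gene_ranking,
                 benign = benign_summary, exclusions = all_exclusions,
                 paths = paths))
}
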