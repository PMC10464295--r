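test_that("protein-change parsing accepts the three missense dialects", {
  p <- parse_protein_change(c("p.Val600Glu", "p.V600E", "V600E", "d835y",
                              "p.ARG371HIS"))
  expect_true(all(p$valid))
  expect_equal(p$ref_aa, c("V", "V", "V", "D", "R"))
  expect_equal(p$position, c(600L, 600L, 600L, 835L, 371L))
  expect_equal(p$alt_aa, c("E", "E", "E", "Y", "H"))
})

test_that("non-substitution notations are rejected with reason codes", {
  p <- parse_protein_change(c("p.Val600fs", "p.Trp26Ter", "p.W26*",
                              "p.Val600del", "p.Lys601_Ser602insArg",
                              "p.Val600dup", "p.Val600=", "V600V",
                              "p.Met1ext-5", "c.1799T>A", "B600E", ""))
  expect_false(any(p$valid))
  expect_equal(p$reason,
               c("frameshift", "nonsense", "nonsense", "deletion",
                 "insertion", "duplication", "synonymous", "synonymous",
                 "extension", "unparsable", "invalid_aa", "empty"))
})

test_that("residue-to-column handles gaps, offsets and domain bounds", {
  msa <- make_msa(c("AC-DE"), offsets = 1L)
  # positions 1..4 occupy columns 1,2,4,5
  expect_equal(residue_to_column(msa, 1, 1:4), c(1L, 2L, 4L, 5L))
  expect_true(is.na(residue_to_column(msa, 1, 5)))
  expect_true(is.na(residue_to_column(msa, 1, 0)))
  msa10 <- make_msa(c("AC-DE"), offsets = 10L)
  expect_equal(residue_to_column(msa10, 1, 10), 1L)
  expect_equal(residue_to_column(msa10, 1, 13), 5L)
})

test_that("column-to-reference-residue respects reference gaps and numbering", {
  msa <- make_msa(c("A-CD", "DEFG"), offsets = c(122L, 1L))
  st <- ref_structure(122:124, c("ALA", "CYS", "ASP"), x = 1:3, y = 1:3,
                      z = 1:3)
  expect_equal(column_to_reference_residue(msa, st, 1), 122L)
  expect_true(is.na(column_to_reference_residue(msa, st, 2)))
  expect_equal(column_to_reference_residue(msa, st, 3), 123L)
  expect_equal(column_to_reference_residue(msa, st, 4), 124L)
  # structure/reference length mismatch is a consistency error
  st2 <- ref_structure(122:125, rep("ALA", 4), x = 1:4, y = 1:4, z = 1:4)
  expect_error(column_to_reference_residue(msa, st2, 1), "inconsistent")
})

test_that("residue_to_column is strictly increasing per row", {
  set.seed(7)
  for (rep in 1:20) {
    msa <- random_msa(1, 40)
    n_res <- length(msa_residue_columns(msa, 1))
    cols <- residue_to_column(msa, 1,
                              msa$rows$offset[1] + seq_len(n_res) - 1L)
    expect_false(any(is.na(cols)))
    expect_true(all(diff(cols) > 0))
  }
})

test_that("residue->column and column->residue are mutually inverse on the reference", {
  set.seed(8)
  msa <- random_msa(5, 50)
  st <- make_structure_for(msa)
  ref_cols <- msa_residue_columns(msa, 1)
  for (col in ref_cols) {
    resno <- column_to_reference_residue(msa, st, col)
    expect_identical(residue_to_column(msa, 1, resno), col)
  }
})

test_that("map_variants statuses match the brute-force oracle", {
  set.seed(123)
  msa <- random_msa(8, 30)
  st <- make_structure_for(msa)
  genes <- c(msa$rows$gene, "NOGENE")
  n <- 60
  df <- data.frame(record_id = as.character(1:n),
                   gene = sample(genes, n, replace = TRUE),
                   protein_change = NA, clinical_significance = "Pathogenic",
                   conditions = "Melanoma", stringsAsFactors = FALSE)
  df$position <- sample(1:520, n, replace = TRUE)
  df$ref_aa <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
                      replace = TRUE)
  df$alt_aa <- "A"
  df$protein_change <- sprintf("%s%d%s", df$ref_aa, df$position, df$alt_aa)
  mapped <- map_variants(df, msa, st, verify_ref_aa = TRUE)
  for (v in seq_len(n)) {
    oracle <- brute_force_map(msa, st, df$gene[v], df$position[v],
                              ref_aa = df$ref_aa[v])
    expect_identical(mapped$status[v], oracle$status, label = paste("row", v))
    if (oracle$status == "mapped") {
      expect_identical(mapped$alignment_column[v], oracle$column)
      expect_identical(mapped$ref_residue[v], oracle$ref_residue)
    }
  }
  # conservation: every record has exactly one status
  expect_equal(nrow(mapped), n)
  expect_false(any(is.na(mapped$status)))
})

test_that("reference-gap variants are excluded from all counts", {
  msa <- make_msa(c("A-CD", "DEFG"), offsets = c(1L, 1L),
                  genes = c("REF", "KIN2"))
  st <- make_structure_for(msa)
  df <- make_variant_df("KIN2", c("p.Asp1Ala", "p.Glu2Ala", "p.Phe3Ala"))
  rec <- as_records(df)
  mapped <- map_variants(rec, msa, st, verify_ref_aa = TRUE)
  expect_equal(mapped$status, c("mapped", "excluded_reference_gap", "mapped"))
  kept <- variant_classes(mapped[mapped$status == "mapped", ])
  counts <- count_by_position(kept)
  expect_equal(sum(counts$cancer), 2)
  expect_false(any(is.na(counts$position)))
})

test_that("stated reference residue disagreements are excluded, not fatal", {
  msa <- make_msa(c("ACDE", "FGHI"), genes = c("REF", "KIN2"))
  st <- make_structure_for(msa)
  rec <- as_records(make_variant_df("KIN2", "p.Ala2Tyr"))  # row has G at 2
  mapped <- map_variants(rec, msa, st, verify_ref_aa = TRUE)
  expect_equal(mapped$status, "excluded_ref_mismatch")
  relaxed <- map_variants(rec, msa, st, verify_ref_aa = FALSE)
  expect_equal(relaxed$status, "mapped")
})

test_that("a residue in-domain in two rows of one gene is an ambiguity error", {
  msa <- kinase_msa(gene = c("REF", "DUP", "DUP"),
                    protein_id = c("P1", "P2a", "P2b"),
                    offset = c(1L, 1L, 3L),
                    sequence = c("ACDEFG", "HIKLMN", "PQRSTV"))
  st <- make_structure_for(msa)
  rec <- as_records(make_variant_df("DUP", "p.His4Ala"))
  expect_error(map_variants(rec, msa, st), "ambiguous")
})

test_that("mapping conserves records: mapped + excluded + unmatched = input", {
  set.seed(9)
  for (rep in 1:10) {
    msa <- random_msa(6, 25)
    st <- make_structure_for(msa)
    n <- 40
    df <- data.frame(record_id = as.character(1:n),
                     gene = sample(c(msa$rows$gene, "MISSING"), n, TRUE),
                     protein_change = "x", clinical_significance = "P",
                     conditions = "c",
                     position = sample(1:520, n, TRUE),
                     ref_aa = "A", alt_aa = "G",
                     stringsAsFactors = FALSE)
    mapped <- map_variants(df, msa, st, verify_ref_aa = FALSE)
    tab <- table(mapped$status)
    expect_equal(sum(tab), n)
    expect_equal(sum(mapped$status == "mapped") + nrow(exclusions(mapped)), n)
  }
})

test_that("on simulated data every mapped variant matches the truth sidecar", {
  cfg <- sim_config(n_proteins = 30, ref_length = 80, background_rate = 0.4,
                    planted_hotspots = data.frame(
                      position = c(15, 60), class = c("cancer", "non-cancer"),
                      mean_mutations = c(10, 10)),
                    n_benign = 10, seed = 21)
  msa <- generate_msa(cfg)
  st <- generate_reference_structure(msa)
  variants <- generate_variants(msa, cfg)
  truth <- attr(variants, "truth")
  mapped <- map_variants(as_records(variants), msa, st)
  m <- merge(mapped, truth, by = "record_id")
  offset <- msa$rows$offset[1]
  is_mapped <- m$status == "mapped"
  # mapped variants land exactly on their true reference position
  expect_true(all(m$ref_residue[is_mapped] ==
                    m$true_ref_position[is_mapped] + offset - 1L))
  # variants with no true reference position (insert columns) are excluded
  expect_true(all(m$status[is.na(m$true_ref_position)] ==
                    "excluded_reference_gap"))
  expect_true(all(is_mapped == !is.na(m$true_ref_position)))
})
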