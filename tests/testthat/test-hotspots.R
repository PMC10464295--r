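# Build a minimal mapped+classified data frame directly.
make_mapped <- function(ref_residue, is_cancer = TRUE, is_noncancer = FALSE,
                        gene = "BRAF", conditions = "Melanoma") {
  n <- length(ref_residue)
  data.frame(record_id = sprintf("M%03d", seq_len(n)),
             gene = rep_len(gene, n),
             protein_change = "p.V600E",
             conditions = rep_len(conditions, n),
             ref_residue = as.integer(ref_residue),
             status = "mapped",
             is_cancer = rep_len(is_cancer, n),
             is_noncancer = rep_len(is_noncancer, n),
             stringsAsFactors = FALSE)
}

test_that("per-position counts are additive and conserve class totals", {
  mapped <- make_mapped(c(280, 280, 280, 195),
                        gene = c("BRAF", "EGFR", "FLT3", "KIT"))
  counts <- count_by_position(mapped)
  expect_equal(counts$cancer[counts$position == 280], 3)
  expect_equal(counts$cancer[counts$position == 195], 1)
  totals <- attr(counts, "totals")
  expect_equal(unname(totals["C"]), sum(counts$cancer))
  expect_equal(unname(totals["N"]), sum(counts$noncancer))
})

test_that("a dual-class record counts once in each class at its position", {
  mapped <- make_mapped(280, is_cancer = TRUE, is_noncancer = TRUE,
                        conditions = "Melanoma;Noonan syndrome")
  counts <- count_by_position(mapped)
  expect_equal(counts$cancer[counts$position == 280], 1)
  expect_equal(counts$noncancer[counts$position == 280], 1)
})

test_that("count totals match a brute-force recount on random inputs", {
  set.seed(31)
  for (rep in 1:10) {
    n <- 50
    mapped <- make_mapped(sample(100:120, n, TRUE),
                          is_cancer = sample(c(TRUE, FALSE), n, TRUE),
                          is_noncancer = sample(c(TRUE, FALSE), n, TRUE))
    mapped <- mapped[mapped$is_cancer | mapped$is_noncancer, ]
    counts <- count_by_position(mapped)
    # oracle: count (record, class) pairs by explicit enumeration
    expect_equal(unname(attr(counts, "totals")["C"]), sum(mapped$is_cancer))
    expect_equal(unname(attr(counts, "totals")["N"]),
                 sum(mapped$is_noncancer))
    for (p in unique(mapped$ref_residue)) {
      expect_equal(counts$cancer[counts$position == p],
                   sum(mapped$is_cancer & mapped$ref_residue == p))
    }
  }
})

test_that("unmapped rows are a programming error in counting", {
  mapped <- make_mapped(10)
  mapped$status <- "excluded_reference_gap"
  expect_error(count_by_position(mapped), "mapped records only")
})

test_that("hotspot selection takes ceiling(q*m) positions plus boundary ties", {
  # 100 mutated positions with all-distinct counts: exactly 5 hotspots
  mapped <- make_mapped(rep(1:100, times = 1:100))
  hs <- select_hotspots(count_by_position(mapped), "cancer")
  expect_equal(nrow(hs), 5)
  expect_equal(hs$position, 100:96)
  expect_equal(hs$count, 100:96)

  # counts [9,5,5,5,2,2,1,1,1,1]: k = 1 and the ties do not reach rank 1
  cnts <- c(9, 5, 5, 5, 2, 2, 1, 1, 1, 1)
  mapped <- make_mapped(rep(1:10, times = cnts))
  hs <- select_hotspots(count_by_position(mapped), "cancer")
  expect_equal(hs$position, 1L)
  expect_equal(hs$count, 9)

  # full tie at the boundary: all three positions returned
  mapped <- make_mapped(rep(1:3, times = c(4, 4, 4)))
  hs <- select_hotspots(count_by_position(mapped), "cancer")
  expect_equal(nrow(hs), 3)
})

test_that("hotspot selection is scale-invariant and monotone", {
  set.seed(17)
  pos <- sample(1:40, 200, replace = TRUE)
  mapped <- make_mapped(pos)
  counts <- count_by_position(mapped)
  hs <- select_hotspots(counts, "cancer")
  # duplicating every variant leaves the hotspot set unchanged
  dup <- make_mapped(rep(pos, 2))
  hs2 <- select_hotspots(count_by_position(dup), "cancer")
  expect_equal(hs2$position, hs$position)
  # size bound
  m <- sum(counts$cancer > 0)
  expect_gte(nrow(hs), ceiling(0.05 * m))
  # adding a variant at the top hotspot never drops it
  more <- make_mapped(c(pos, hs$position[1]))
  hs3 <- select_hotspots(count_by_position(more), "cancer")
  expect_equal(hs3$position[1], hs$position[1])
})

test_that("an all-zero class yields an empty hotspot list with a warning", {
  counts <- count_by_position(make_mapped(1:3))
  expect_warning(hs <- select_hotspots(counts, "noncancer"), "no position")
  expect_equal(nrow(hs), 0)
})

test_that("hotspot breakdowns nest genes then class-matched conditions", {
  mapped <- make_mapped(
    rep(280, 3), gene = c("BRAF", "BRAF", "EGFR"),
    conditions = c("Melanoma", "Melanoma", "Lung adenocarcinoma"))
  b <- position_breakdown(mapped, 280, "cancer")
  expect_equal(b$count, 3)
  expect_equal(b$genes, c(BRAF = 2L, EGFR = 1L))
  expect_equal(sum(b$genes), b$count)
  expect_equal(b$diseases$count[b$diseases$gene == "BRAF"], 2L)
  # every disease entry's gene appears in the gene layer
  expect_true(all(b$diseases$gene %in% names(b$genes)))
  # a record with two cancer conditions: 1 gene-layer count, 2 entries
  mapped2 <- make_mapped(280,
                         conditions = "Melanoma;Lung adenocarcinoma")
  b2 <- position_breakdown(mapped2, 280, "cancer")
  expect_equal(unname(b2$genes), 1L)
  expect_equal(nrow(b2$diseases), 2)
  expect_error(position_breakdown(mapped, 999, "cancer"), "no cancer")
})

test_that("breakdown totals agree with an independent recount", {
  set.seed(5)
  mapped <- make_mapped(sample(c(10, 20), 30, TRUE),
                        gene = sample(c("A1", "B2", "C3"), 30, TRUE))
  for (p in c(10, 20)) {
    b <- position_breakdown(mapped, p, "cancer")
    expect_equal(b$count, sum(mapped$ref_residue == p))
    for (g in names(b$genes))
      expect_equal(unname(b$genes[g]),
                   sum(mapped$ref_residue == p & mapped$gene == g))
  }
})

test_that("gene ranking orders by count with alphabetical ties", {
  mapped <- make_mapped(1:7,
                        gene = c("BRAF", "BRAF", "BRAF", "ALK", "ALK",
                                 "ABL1", "ABL1"))
  rk <- rank_genes(mapped, "cancer")
  expect_equal(rk$gene, c("BRAF", "ABL1", "ALK"))
  expect_equal(rk$count, c(3L, 2L, 2L))
  expect_equal(sum(rk$count), sum(mapped$is_cancer))
  # single variant
  one <- rank_genes(make_mapped(5), "cancer")
  expect_equal(nrow(one), 1)
  expect_equal(one$count, 1L)
})

test_that("planted gene dominance is recovered in the ranking", {
  cfg <- sim_config(n_proteins = 20, ref_length = 60, background_rate = 0.05,
                    planted_hotspots = data.frame(position = 30,
                                                  class = "cancer",
                                                  mean_mutations = 25),
                    n_benign = 0, seed = 12)
  msa <- generate_msa(cfg)
  st <- generate_reference_structure(msa)
  variants <- generate_variants(msa, cfg)
  truth <- attr(variants, "truth")
  heavy <- names(which.max(table(truth$gene[truth$planted])))
  mapped <- map_variants(as_records(variants), msa, st)
  mapped <- variant_classes(mapped[mapped$status == "mapped", ])
  rk <- rank_genes(mapped, "cancer")
  expect_true(heavy %in% rk$gene[seq_len(3)])
})
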