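test_that("observed frequency handles zero counts and empty classes", {
  expect_equal(observed_frequency(5, 50), 0.1)
  expect_equal(observed_frequency(0, 50), 0)
  expect_true(is.na(observed_frequency(3, 0)))
  expect_error(observed_frequency(-1, 10), "non-negative")
})

test_that("representation ratios match the defining formulas", {
  expect_equal(representation_ratio(5, 5, 50, 50),
               c(ratio_cancer = 1, ratio_noncancer = 1))
  # all-cancer position with equal class totals: (4/40)/(4/80) = 2
  expect_equal(representation_ratio(4, 0, 40, 40)[["ratio_cancer"]], 2)
  # hand arithmetic: c=6,C=60,n=2,N=40 -> f_exp = 8/100,
  # ratio_cancer = (6/60)/(8/100) = 1.25, ratio_noncancer = (2/40)/0.08
  rr <- representation_ratio(6, 2, 60, 40)
  expect_equal(rr[["ratio_cancer"]], 1.25)
  expect_equal(rr[["ratio_noncancer"]], 0.625)
})

test_that("see-saw property: the two ratios sit on opposite sides of 1", {
  set.seed(13)
  for (i in 1:200) {
    C <- sample(10:100, 1); N <- sample(10:100, 1)
    c_i <- sample(0:10, 1); n_i <- sample(0:10, 1)
    if (c_i + n_i == 0) next
    rr <- representation_ratio(c_i, n_i, C, N)
    s <- sign(c(rr[["ratio_cancer"]] - 1, rr[["ratio_noncancer"]] - 1))
    expect_true(all(s == 0) || prod(s) <= 0)
  }
})

test_that("chi-square matches the spec's worked 2x2 example", {
  un <- chi_square_position(10, 2, 100, 100, yates = FALSE)
  expect_equal(un$chi2, 2 * (16 / 6 + 16 / 94), tolerance = 1e-12)
  expect_equal(un$chi2, 5.6738, tolerance = 1e-4)
  ya <- chi_square_position(10, 2, 100, 100, yates = TRUE)
  expect_equal(ya$chi2, 2 * (12.25 / 6 + 12.25 / 94), tolerance = 1e-12)
  expect_equal(ya$chi2, 4.3440, tolerance = 1e-4)
  expect_false(un$small_expected)  # smallest expected cell is 6
  expect_true(chi_square_position(2, 1, 100, 100)$small_expected)
})

test_that("symmetric tables give chi2 = 0 and p = 1 exactly", {
  for (yates in c(TRUE, FALSE)) {
    r <- chi_square_position(5, 5, 50, 50, yates = yates)
    expect_identical(r$chi2, 0)
    expect_identical(r$p_value, 1)
  }
})

test_that("uncorrected chi-square agrees with the textbook oracle", {
  set.seed(77)
  for (i in 1:500) {
    C <- sample(5:200, 1); N <- sample(5:200, 1)
    c_i <- sample(0:C, 1); n_i <- sample(0:N, 1)
    if (c_i + n_i == 0 || c_i + n_i == C + N) next
    got <- chi_square_position(c_i, n_i, C, N, yates = FALSE)
    tab <- rbind(c(c_i, C - c_i), c(n_i, N - n_i))
    expect_equal(got$chi2, chi2_oracle(tab), tolerance = 1e-9)
  }
})

test_that("p-value decreases as the cancer count grows past expectation", {
  C <- 100; N <- 100
  p <- vapply(5:30, function(c_i)
    chi_square_position(c_i, 5, C, N, yates = FALSE)$p_value, 1)
  expect_true(all(diff(p) < 0))
})

test_that("count bounds are validated", {
  expect_error(chi_square_position(11, 0, 10, 10), "exceeds")
  expect_error(chi_square_position(1, 1, 0, 10), "positive")
  r <- chi_square_position(0, 0, 10, 10)
  expect_true(is.na(r$chi2))
})

test_that("per-position stats satisfy normalization and convexity identities", {
  set.seed(19)
  mapped <- data.frame(record_id = as.character(1:120),
                       gene = "G", protein_change = "x",
                       conditions = "c",
                       ref_residue = sample(1:30, 120, TRUE),
                       status = "mapped",
                       is_cancer = sample(c(TRUE, FALSE), 120, TRUE),
                       stringsAsFactors = FALSE)
  mapped$is_noncancer <- !mapped$is_cancer
  counts <- count_by_position(mapped)
  st <- classify_positions(counts)
  expect_equal(sum(st$f_obs_cancer), 1, tolerance = 1e-12)
  expect_equal(sum(st$f_obs_noncancer), 1, tolerance = 1e-12)
  expect_equal(sum(st$f_exp), 1, tolerance = 1e-12)
  totals <- attr(counts, "totals")
  C <- unname(totals["C"]); N <- unname(totals["N"])
  conv <- (C * st$f_obs_cancer + N * st$f_obs_noncancer) / (C + N)
  expect_true(all(abs(st$f_exp - conv) < 1e-12))
})

test_that("labels swap when the class roles swap", {
  set.seed(23)
  mapped <- data.frame(record_id = as.character(1:150),
                       gene = "G", protein_change = "x", conditions = "c",
                       ref_residue = sample(1:25, 150, TRUE),
                       status = "mapped",
                       is_cancer = sample(c(TRUE, FALSE), 150, TRUE),
                       stringsAsFactors = FALSE)
  mapped$is_noncancer <- !mapped$is_cancer
  # concentrate cancer mutations at position 1 to force a significant label
  extra <- mapped[rep(1, 20), ]
  extra$ref_residue <- 1L
  extra$is_cancer <- TRUE
  extra$is_noncancer <- FALSE
  mapped <- rbind(mapped, extra)
  counts <- count_by_position(mapped)
  st <- classify_positions(counts)
  swapped <- mapped
  swapped$is_cancer <- mapped$is_noncancer
  swapped$is_noncancer <- mapped$is_cancer
  st2 <- classify_positions(count_by_position(swapped))
  relabel <- c(over_cancer = "over_noncancer",
               over_noncancer = "over_cancer",
               not_significant = "not_significant",
               undefined = "undefined")
  expect_identical(unname(relabel[st$label]), st2$label)
  expect_equal(st$chi2, st2$chi2)
  expect_true("over_cancer" %in% st$label)
})

test_that("a heavily cancer-planted position is labeled over_cancer", {
  cfg <- sim_config(n_proteins = 40, ref_length = 100,
                    background_rate = 0.3,
                    planted_hotspots = data.frame(position = 50,
                                                  class = "cancer",
                                                  mean_mutations = 30),
                    n_benign = 0, seed = 41, mixed_condition_prob = 0)
  msa <- generate_msa(cfg)
  st <- generate_reference_structure(msa)
  mapped <- map_variants(as_records(generate_variants(msa, cfg)), msa, st)
  mapped <- variant_classes(mapped[mapped$status == "mapped", ])
  counts <- count_by_position(mapped,
                              positions = st$residues$residue_number)
  stats <- classify_positions(counts)
  planted_res <- st$residues$residue_number[50]
  expect_equal(stats$label[stats$position == planted_res], "over_cancer")
})

test_that("identically composed positions are never significant", {
  # every position has the same 1:1 cancer:non-cancer composition
  mapped <- data.frame(record_id = as.character(1:40),
                       gene = "G", protein_change = "x", conditions = "c",
                       ref_residue = rep(1:10, each = 4),
                       status = "mapped",
                       is_cancer = rep(c(TRUE, TRUE, FALSE, FALSE), 10),
                       stringsAsFactors = FALSE)
  mapped$is_noncancer <- !mapped$is_cancer
  st <- classify_positions(count_by_position(mapped))
  expect_true(all(st$label == "not_significant"))
  expect_true(all(st$chi2 == 0))
})
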