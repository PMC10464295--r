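#' Observed mutation frequency of a class at a position
#'
#' The number of mutations of a class at the position divided by the class
#' total over the whole structure. An empty class (total 0) yields `NA`
#' rather than a division error.
#'
#' @param count_at_position mutation count at the position.
#' @param class_total total mutations of the class.
#' @return numeric frequency, `NA` when `class_total` is 0.
#' @export
observed_frequency <- function(count_at_position, class_total) {
  if (any(class_total < 0) || any(count_at_position < 0))
    stop_input("counts must be non-negative")
  n <- max(length(count_at_position), length(class_total))
  cnt <- rep_len(as.numeric(count_at_position), n)
  tot <- rep_len(as.numeric(class_total), n)
  out <- cnt / tot
  out[tot == 0] <- NA_real_
  out
}

#' Observed/expected representation ratio at a position
#'
#' The expected frequency at a position is the pooled frequency
#' `(c_i + n_i) / (C + N)`; each class's ratio is its observed frequency over
#' that expectation. A ratio above 1 means the class is over-represented at
#' the position (and, necessarily, the other class under-represented).
#'
#' @param c_i,n_i cancer and non-cancer counts at the position.
#' @param C,N class totals.
#' @return named numeric vector `c(ratio_cancer, ratio_noncancer)`; `NA`
#'   where a denominator is zero.
#' @export
representation_ratio <- function(c_i, n_i, C, N) {
  if (C + N <= 0) return(c(ratio_cancer = NA_real_, ratio_noncancer = NA_real_))
  f_exp <- (c_i + n_i) / (C + N)
  rc <- if (C > 0 && f_exp > 0) (c_i / C) / f_exp else NA_real_
  rn <- if (N > 0 && f_exp > 0) (n_i / N) / f_exp else NA_real_
  c(ratio_cancer = rc, ratio_noncancer = rn)
}

#' Chi-square test of class representation at one position
#'
#' Pearson chi-square (1 df) on the 2x2 table `[[c_i, C - c_i],
#' [n_i, N - n_i]]` — mutations of each class at the position versus
#' elsewhere. Yates continuity correction is applied by default, matching
#' the default behaviour of 2x2 `chisq.test()` in R, where the original
#' analysis environment ran; set `yates = FALSE` for the uncorrected
#' statistic. Positions whose expected counts fall below 5 are flagged (the
#' chi-square approximation is then questionable) but still tested.
#'
#' @param c_i,n_i class counts at the position.
#' @param C,N class totals (`c_i <= C`, `n_i <= N`).
#' @param yates apply continuity correction (default `TRUE`).
#' @return list: `chi2`, `p_value`, `small_expected` (any expected cell
#'   < 5). `c_i + n_i == 0` gives `NA` statistics (position untestable).
#' @export
chi_square_position <- function(c_i, n_i, C, N, yates = TRUE) {
  if (C <= 0 || N <= 0) stop_input("both class totals must be positive")
  if (c_i > C || n_i > N)
    stop_input("per-position count exceeds its class total")
  if (c_i < 0 || n_i < 0) stop_input("counts must be non-negative")
  if (c_i + n_i == 0)
    return(list(chi2 = NA_real_, p_value = NA_real_, small_expected = NA))
  tab <- rbind(c(c_i, C - c_i), c(n_i, N - n_i))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(colSums(tab) == 0)) {
    # degenerate margin: both classes sit entirely in one column, the row
    # profiles are identical and there is nothing to test
    return(list(chi2 = 0, p_value = 1, small_expected = TRUE))
  }
  ht <- suppressWarnings(chisq.test(tab, correct = yates))
  list(chi2 = unname(ht$statistic), p_value = unname(ht$p.value),
       small_expected = any(expected < 5))
}

#' Per-position representation statistics and labels
#'
#' For every reference position computes the observed class frequencies, the
#' expected (pooled) frequency, the representation ratios, the chi-square
#' statistic and p-value, and a label: `over_cancer` when significant with
#' cancer ratio above 1, `over_noncancer` when significant with cancer ratio
#' below 1, `not_significant` otherwise, `undefined` for positions without
#' pathogenic mutations. Raw p-values are compared to `alpha` (no
#' multiple-testing correction, as in the original analysis); setting
#' `bh = TRUE` labels on Benjamini-Hochberg adjusted p-values instead, as a
#' clearly optional extension.
#'
#' @param counts a `position_counts` from [count_by_position()].
#' @param alpha significance level (default 0.05).
#' @param yates continuity correction flag, see [chi_square_position()].
#' @param bh use BH-adjusted p-values for labelling (default `FALSE`).
#' @return data frame: `position`, `cancer`, `noncancer`, `benign`,
#'   `f_obs_cancer`, `f_obs_noncancer`, `f_exp`, `ratio_cancer`,
#'   `ratio_noncancer`, `chi2`, `p_value`, `label`, `small_expected`.
#' @export
classify_positions <- function(counts, alpha = 0.05, yates = TRUE,
                               bh = FALSE) {
  if (alpha <= 0 || alpha >= 1) stop_input("alpha must be in (0, 1)")
  totals <- attr(counts, "totals")
  C <- unname(totals["C"])
  N <- unname(totals["N"])
  n <- nrow(counts)
  out <- data.frame(position = counts$position, cancer = counts$cancer,
                    noncancer = counts$noncancer, benign = counts$benign,
                    f_obs_cancer = observed_frequency(counts$cancer, C),
                    f_obs_noncancer = observed_frequency(counts$noncancer, N),
                    f_exp = NA_real_, ratio_cancer = NA_real_,
                    ratio_noncancer = NA_real_, chi2 = NA_real_,
                    p_value = NA_real_, label = "undefined",
                    small_expected = NA)
  if (C + N > 0)
    out$f_exp <- (counts$cancer + counts$noncancer) / (C + N)
  testable <- which(counts$cancer + counts$noncancer > 0 & C > 0 & N > 0)
  for (i in testable) {
    rr <- representation_ratio(counts$cancer[i], counts$noncancer[i], C, N)
    out$ratio_cancer[i] <- rr["ratio_cancer"]
    out$ratio_noncancer[i] <- rr["ratio_noncancer"]
    cs <- chi_square_position(counts$cancer[i], counts$noncancer[i], C, N,
                              yates = yates)
    out$chi2[i] <- cs$chi2
    out$p_value[i] <- cs$p_value
    out$small_expected[i] <- cs$small_expected
  }
  p_label <- out$p_value
  if (bh)
    p_label[testable] <- p.adjust(out$p_value[testable], method = "BH")
  sig <- !is.na(p_label) & p_label < alpha
  out$label[testable] <- "not_significant"
  out$label[sig & !is.na(out$ratio_cancer) & out$ratio_cancer > 1] <-
    "over_cancer"
  out$label[sig & !is.na(out$ratio_cancer) & out$ratio_cancer < 1] <-
    "over_noncancer"
  out
}
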