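test_that("Yates goodness-of-fit test reproduces the study selection tests", {
  ctl <- yates_gof_test(5, 4, NONSYN_SITES, SYN_SITES)
  expect_equal(round(ctl$statistic, 2), 1.67)
  expect_equal(round(ctl$p_value, 2), 0.20)
  trt <- yates_gof_test(11, 2, NONSYN_SITES, SYN_SITES)
  expect_equal(round(trt$statistic, 2), 0.03)
  expect_equal(round(trt$p_value, 2), 0.86)
})

test_that("floored correction gives zero statistic at a near-perfect fit", {
  out <- yates_gof_test(787, 213, 787, 213)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
  expect_error(yates_gof_test(0, 0, 1, 1), "no observed")
})

test_that("Yates GOF statistic never exceeds the uncorrected Pearson statistic", {
  cases <- withr::with_seed(99, tibble::tibble(
    a = stats::rpois(50, 8) + 1, b = stats::rpois(50, 4) + 1
  ))
  for (i in seq_len(nrow(cases))) {
    o <- c(cases$a[i], cases$b[i])
    e <- sum(o) * c(0.787, 0.213)
    pearson <- sum((o - e)^2 / e)
    expect_lte(yates_gof_test(o[1], o[2], 787, 213)$statistic, pearson)
  }
})

test_that("2x2 Yates test reproduces the between-group comparison", {
  out <- yates_2x2_test(5, 4, 11, 2)
  expect_equal(round(out$statistic, 2), 1.04)
  expect_equal(round(out$p_value, 2), 0.31)
  flat <- yates_2x2_test(10, 10, 10, 10)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_error(yates_2x2_test(0, 0, 3, 4), "margin")
})

test_that("2x2 shortcut equals the cell-wise Yates computation and chisq.test", {
  cellwise <- function(a, b, c, d) {
    o <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
    e <- outer(rowSums(o), colSums(o)) / sum(o)
    sum(pmax(abs(o - e) - 0.5, 0)^2 / e)
  }
  tabs <- withr::with_seed(7, matrix(stats::rpois(4000, 6) + 1, ncol = 4))
  for (i in seq_len(nrow(tabs))) {
    t4 <- tabs[i, ]
    got <- yates_2x2_test(t4[1], t4[2], t4[3], t4[4])
    expect_equal(got$statistic, cellwise(t4[1], t4[2], t4[3], t4[4]))
    oracle <- suppressWarnings(stats::chisq.test(
      matrix(t4, 2, 2, byrow = TRUE), correct = TRUE))
    expect_equal(got$statistic, unname(oracle$statistic))
    expect_equal(got$p_value, oracle$p.value)
  }
})

test_that("2x2 Yates test is invariant under simultaneous row/column swaps", {
  expect_equal(yates_2x2_test(5, 4, 11, 2)$statistic,
               yates_2x2_test(2, 11, 4, 5)$statistic)
})

test_that("r x 2 contingency test matches brute force and delegates for 2x2", {
  t22 <- chisq_contingency(matrix(c(5, 4, 11, 2), 2, 2, byrow = TRUE))
  expect_equal(t22$statistic, yates_2x2_test(5, 4, 11, 2)$statistic)

  same <- matrix(c(3, 6, 3, 6, 3, 6), ncol = 2, byrow = TRUE)
  expect_equal(chisq_contingency(same)$statistic, 0)

  tab <- withr::with_seed(31, matrix(stats::rpois(6, 20) + 1, ncol = 2))
  got <- chisq_contingency(tab)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(got$statistic, sum((tab - e)^2 / e))
  expect_equal(got$df, 2L)
  oracle <- stats::chisq.test(tab, correct = FALSE)
  expect_equal(got$statistic, unname(oracle$statistic))
  expect_equal(got$p_value, oracle$p.value)
})

test_that("codon site fractions match single-base-change enumeration", {
  # hand-checked codons
  expect_equal(unname(unlist(
    count_syn_nonsyn_sites("TTT")[c("syn_sites", "nonsyn_sites")])),
    c(1 / 3, 8 / 3))
  expect_equal(count_syn_nonsyn_sites("TGG")$syn_sites, 0)
  expect_equal(count_syn_nonsyn_sites("TGG")$nonsyn_sites, 3)
  expect_equal(count_syn_nonsyn_sites("GGG")$syn_sites, 1)
  expect_equal(count_syn_nonsyn_sites("GGG")$nonsyn_sites, 2)

  # independent brute-force oracle over all 61 sense codons
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  tab <- codon_site_table()
  for (codon in names(code)[code != "*"]) {
    syn <- 0
    for (pos in 1:3) {
      for (b in bases) {
        if (b == substr(codon, pos, pos)) next
        mut <- codon
        substr(mut, pos, pos) <- b
        if (code[[mut]] == code[[codon]]) syn <- syn + 1 / 3
      }
    }
    expect_equal(tab[codon, "syn"], syn, label = codon)
    expect_equal(tab[codon, "syn"] + tab[codon, "nonsyn"], 3,
                 label = codon)
  }
})

test_that("CDS site counting validates frame and stop codons", {
  expect_error(count_syn_nonsyn_sites("TTTG"), "frame error")
  expect_error(count_syn_nonsyn_sites("TTTTAAGGG"), "internal stop")
  # trailing stop codon is ignored
  with_stop <- count_syn_nonsyn_sites("TTTTAA")
  expect_equal(with_stop$n_codons, 1L)
  # excluding stop-creating changes removes opportunity from the totals
  incl <- count_syn_nonsyn_sites("TGG")
  excl <- count_syn_nonsyn_sites("TGG", stop_changes = "exclude")
  expect_lt(excl$nonsyn_sites, incl$nonsyn_sites)
  expect_equal(excl$syn_sites, incl$syn_sites)
})
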