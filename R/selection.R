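.ma_htest <- function(statistic, df, p_value, method, observed = NULL,
                      expected = NULL) {
  structure(
    list(statistic = statistic, df = df, p_value = p_value, method = method,
         observed = observed, expected = expected),
    class = "ma_htest"
  )
}

#' @export
print.ma_htest <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  X-squared = %.4g, df = %d, p-value = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Tidy a chi-square test result
#'
#' @param x An `ma_htest` object.
#' @param ... Unused.
#' @return A one-row tibble with `statistic`, `df` (as `parameter`),
#'   `p.value` and `method`.
#' @export
tidy.ma_htest <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, parameter = x$df,
                 p.value = x$p_value, method = x$method)
}

# floored Yates deviation: max(|O-E| - 0.5, 0), cell-wise
.yates_stat <- function(obs, expected) {
  dev <- pmax(abs(obs - expected) - 0.5, 0)
  sum(dev^2 / expected)
}

#' Yates-corrected goodness-of-fit test for coding-mutation selection
#'
#' Tests whether observed nonsynonymous and synonymous mutation counts are
#' consistent with the genomic ratio of nonsynonymous to synonymous sites.
#' Expected counts are proportional to the site totals; the statistic is
#' the continuity-corrected chi-square with the deviation floored at zero,
#' sum(max(|O - E| - 0.5, 0)^2 / E), on 1 degree of freedom. Under
#' near-neutral mutation accumulation a non-significant result indicates
#' selection did not distort the accumulated coding mutations.
#'
#' @param obs_nonsyn,obs_syn Observed mutation counts.
#' @param nonsyn_sites,syn_sites Genomic site totals (real-valued, e.g. from
#'   [count_syn_nonsyn_sites()]).
#' @return An `ma_htest` object.
#' @export
#' @examples
#' yates_gof_test(5, 4, 6074090, 1641376) # X-squared = 1.67, p = 0.20
yates_gof_test <- function(obs_nonsyn, obs_syn, nonsyn_sites, syn_sites) {
  stopifnot(nonsyn_sites > 0, syn_sites > 0,
            obs_nonsyn >= 0, obs_syn >= 0)
  n <- obs_nonsyn + obs_syn
  if (n < 1) stop("no observed coding mutations to test", call. = FALSE)
  p <- nonsyn_sites / (nonsyn_sites + syn_sites)
  expected <- n * c(p, 1 - p)
  stat <- .yates_stat(c(obs_nonsyn, obs_syn), expected)
  .ma_htest(stat, 1L, stats::pchisq(stat, 1, lower.tail = FALSE),
            "Chi-square goodness-of-fit with Yates continuity correction",
            observed = c(nonsyn = obs_nonsyn, syn = obs_syn),
            expected = stats::setNames(expected, c("nonsyn", "syn")))
}

#' Yates-corrected 2x2 contingency test
#'
#' The shortcut form N(|ad - bc| - N/2)^2 / [(a+b)(c+d)(a+c)(b+d)], with
#' the correction clamped so that |ad - bc| <= N/2 gives a statistic of
#' exactly 0; algebraically identical to the cell-wise floored Yates
#' computation.
#'
#' @param a,b,c,d Cell counts, row-wise: (a, b) is the first group's
#'   (nonsynonymous, synonymous) pair, (c, d) the second group's.
#' @return An `ma_htest` object.
#' @export
#' @examples
#' yates_2x2_test(5, 4, 11, 2) # X-squared = 1.04, p = 0.31
yates_2x2_test <- function(a, b, c, d) {
  tab <- c(a, b, c, d)
  stopifnot(all(tab >= 0))
  n <- sum(tab)
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    stop("degenerate 2x2 table: a row or column margin is zero",
         call. = FALSE)
  }
  dev <- max(abs(a * d - b * c) - n / 2, 0)
  stat <- n * dev^2 / prod(margins)
  .ma_htest(stat, 1L, stats::pchisq(stat, 1, lower.tail = FALSE),
            "2x2 chi-square with Yates continuity correction",
            observed = matrix(tab, 2, 2, byrow = TRUE))
}

#' Pearson chi-square test for an r x 2 contingency table
#'
#' Generic independence test used, e.g., to compare mutation-category
#' counts among several strains. The Yates correction is honoured only for
#' 2 x 2 tables (where the call delegates to [yates_2x2_test()]).
#'
#' @param table An r x 2 matrix (or data frame) of counts, r >= 2.
#' @param yates Apply the continuity correction when the table is 2 x 2.
#' @return An `ma_htest` object with df = r - 1.
#' @export
chisq_contingency <- function(table, yates = TRUE) {
  tab <- as.matrix(table)
  stopifnot(ncol(tab) == 2, nrow(tab) >= 2, all(tab >= 0))
  if (nrow(tab) == 2 && yates) {
    return(yates_2x2_test(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    stop("degenerate table: zero expected cell", call. = FALSE)
  }
  stat <- sum((tab - expected)^2 / expected)
  df <- nrow(tab) - 1L
  .ma_htest(stat, df, stats::pchisq(stat, df, lower.tail = FALSE),
            "Pearson chi-square contingency test",
            observed = tab, expected = expected)
}
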