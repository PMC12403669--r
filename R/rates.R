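#' Exposure denominator of an MA group
#'
#' The exposure denominator g of a group of MA lines is the total mutation
#' opportunity, the sum over lines of callable sites times total cell
#' divisions. Mutation rates are event counts divided by g, in units of
#' per nucleotide site per cell division.
#'
#' When per-line callable sites are unavailable the grand-mean product
#' `n_lines * mean_sites * mean(total_divisions)` is used instead and the
#' result is flagged (`approximate = TRUE`); published MA studies often
#' report only group means, so this fallback reproduces their printed
#' denominators.
#'
#' @param lines A tibble of MA-line metadata with columns `line_id`,
#'   `total_divisions` and (preferably) `callable_sites`; an optional
#'   `group` column yields one row per group.
#' @param mean_sites Mean callable sites per line, used only for lines with
#'   no `callable_sites` value.
#' @return A tibble with columns `group`, `value` (g, site-division units),
#'   `n_lines`, `mean_divisions` and `approximate`.
#' @export
#' @examples
#' lines <- tibble::tibble(line_id = c("L1", "L2"),
#'                         callable_sites = c(100, 200),
#'                         total_divisions = c(10, 20))
#' exposure(lines) # g = 100*10 + 200*20 = 5000
exposure <- function(lines, mean_sites = NULL) {
  stopifnot(is.data.frame(lines))
  lines <- tibble::as_tibble(lines)
  if (!"total_divisions" %in% names(lines)) {
    if (all(c("transfers", "divisions_per_transfer") %in% names(lines))) {
      lines$total_divisions <- lines$transfers * lines$divisions_per_transfer
    } else {
      stop("lines need a `total_divisions` column (or transfers and ",
           "divisions_per_transfer)", call. = FALSE)
    }
  }
  if (!"group" %in% names(lines)) lines$group <- "all"
  bad <- !is.finite(lines$total_divisions) | lines$total_divisions <= 0
  if (any(bad)) {
    stop("non-positive total_divisions for line(s) ",
         paste(lines$line_id[which(bad)], collapse = ", "), call. = FALSE)
  }
  has_sites <- "callable_sites" %in% names(lines) &&
    !anyNA(lines$callable_sites)
  if (has_sites && any(lines$callable_sites <= 0)) {
    stop("non-positive callable_sites for line(s) ",
         paste(lines$line_id[which(lines$callable_sites <= 0)],
               collapse = ", "), call. = FALSE)
  }
  if (!has_sites && is.null(mean_sites)) {
    stop("per-line callable_sites absent: supply `mean_sites` for the ",
         "grand-mean fallback", call. = FALSE)
  }
  dplyr::summarise(
    dplyr::group_by(lines, .data$group),
    value = if (has_sites) {
      sum(.data$callable_sites * .data$total_divisions)
    } else {
      dplyr::n() * mean_sites * mean(.data$total_divisions)
    },
    n_lines = dplyr::n(),
    mean_divisions = mean(.data$total_divisions),
    approximate = !has_sites,
    .groups = "drop"
  )
}

#' Exact (Garwood) Poisson confidence interval
#'
#' Two-sided exact confidence bounds for a Poisson mean given an observed
#' event count, from chi-square quantiles:
#' lower = Q(alpha/2; 2k)/2 (0 when k = 0) and
#' upper = Q(1 - alpha/2; 2k + 2)/2. The interval is conservative: its
#' coverage is at least the nominal level for every true mean.
#'
#' @param count Non-negative integer event count(s); vectorized.
#' @param conf Two-sided confidence level, in (0, 1).
#' @return A tibble with columns `count`, `low`, `high`, `conf`, in event
#'   units (divide by an exposure to obtain rate bounds).
#' @export
#' @examples
#' garwood_ci(18) # bounds 10.668 and 28.448 events
garwood_ci <- function(count, conf = 0.95) {
  if (any(count < 0) || any(count != floor(count))) {
    stop("count must be a non-negative integer", call. = FALSE)
  }
  stopifnot(length(conf) == 1, conf > 0, conf < 1)
  alpha <- 1 - conf
  low <- ifelse(count == 0, 0, stats::qchisq(alpha / 2, 2 * count) / 2)
  high <- stats::qchisq(1 - alpha / 2, 2 * count + 2) / 2
  tibble::tibble(count = as.numeric(count), low = low, high = high,
                 conf = conf)
}

#' Per-site per-division mutation-rate estimate
#'
#' Point estimate mu = count / g with the Garwood interval scaled by the
#' same exposure denominator g.
#'
#' @param count Non-negative integer event count(s).
#' @param exposure Exposure denominator g: a positive number or a one-row
#'   tibble from [exposure()].
#' @param conf Confidence level.
#' @param mclass Optional class label(s) carried through to the output.
#' @return A tibble with columns `mclass`, `count`, `exposure`, `mu`,
#'   `ci_low`, `ci_high`, `conf`.
#' @export
#' @examples
#' estimate_rate(18, 5.02822e11) # mu = 3.58e-11
estimate_rate <- function(count, exposure, conf = 0.95, mclass = NA_character_) {
  if (is.data.frame(exposure)) exposure <- exposure$value
  if (any(!is.finite(exposure)) || any(exposure <= 0)) {
    stop("exposure must be positive and finite", call. = FALSE)
  }
  ci <- garwood_ci(count, conf)
  tibble::tibble(
    mclass = mclass,
    count = as.numeric(count),
    exposure = exposure,
    mu = count / exposure,
    ci_low = ci$low / exposure,
    ci_high = ci$high / exposure,
    conf = conf
  )
}

#' Two-group Poisson rate-ratio test
#'
#' Compares two Poisson rates observed as `x1` events over exposure `g1`
#' (reference group) and `x2` events over `g2`. Reports the rate ratio
#' RR = (x2/g2)/(x1/g1), the Wald interval on the log scale
#' exp(ln RR +/- z * sqrt(1/x1 + 1/x2)) with its two-sided p-value, and
#' the exact conditional binomial p-value: given the total x1 + x2, x2 is
#' binomial with success probability g2/(g1+g2) under equal rates.
#'
#' @param x1,x2 Event counts in the reference and comparison groups.
#' @param g1,g2 Exposure denominators (site-division units).
#' @param conf Confidence level for the Wald interval.
#' @return An object of class `rate_comparison`; see [tidy.rate_comparison()].
#' @export
#' @examples
#' rate_ratio_test(18, 5.02822e11, 24, 5.37022e11) # RR = 1.25
rate_ratio_test <- function(x1, g1, x2, g2, conf = 0.95) {
  stopifnot(g1 > 0, g2 > 0, x1 >= 0, x2 >= 0)
  if (x1 + x2 < 1) {
    stop("undefined ratio: both event counts are zero", call. = FALSE)
  }
  p0 <- g2 / (g1 + g2)
  p_exact <- min(1, stats::binom.test(x2, x1 + x2, p = p0)$p.value)
  degenerate <- x1 == 0
  if (degenerate) {
    # one-sided interval: only a lower bound is informative
    rr <- Inf
    se <- NA_real_
    z <- qnorm_half(conf)
    ci <- c(exp(log((x2 / g2) * g1 / 0.5) - z * sqrt(1 / 0.5 + 1 / x2)), Inf)
    p_wald <- NA_real_
  } else {
    rr <- (x2 / g2) / (x1 / g1)
    se <- sqrt(1 / x1 + 1 / x2)
    z <- qnorm_half(conf)
    ci <- exp(log(rr) + c(-1, 1) * z * se)
    p_wald <- 2 * stats::pnorm(-abs(log(rr) / se))
  }
  structure(
    list(rr = rr, ci_low = ci[1], ci_high = ci[2], conf = conf,
         p_wald = p_wald, p_exact = p_exact, se_log_rr = se,
         x1 = x1, g1 = g1, x2 = x2, g2 = g2, p0 = p0,
         degenerate = degenerate),
    class = "rate_comparison"
  )
}

qnorm_half <- function(conf) stats::qnorm(1 - (1 - conf) / 2)

#' @export
print.rate_comparison <- function(x, ...) {
  cat("Two-group Poisson rate comparison\n")
  cat(sprintf("  counts: %g over g1 = %.6g vs %g over g2 = %.6g\n",
              x$x1, x$g1, x$x2, x$g2))
  cat(sprintf("  RR = %.3g, %d%% Wald CI (%.3g, %.3g)\n",
              x$rr, round(100 * x$conf), x$ci_low, x$ci_high))
  cat(sprintf("  P (Wald) = %.3g, P (exact conditional binomial) = %.3g\n",
              x$p_wald, x$p_exact))
  invisible(x)
}

#' Tidy a rate comparison
#'
#' @param x A `rate_comparison` object.
#' @param ... Unused.
#' @return `tidy()`: a one-row tibble with `estimate` (the rate ratio),
#'   `conf.low`, `conf.high`, `p.value` (Wald) and `p.exact`. `glance()`:
#'   the same row plus the inputs.
#' @export
tidy.rate_comparison <- function(x, ...) {
  tibble::tibble(
    estimate = x$rr, conf.low = x$ci_low, conf.high = x$ci_high,
    conf.level = x$conf, p.value = x$p_wald, p.exact = x$p_exact,
    method = "Poisson rate ratio (Wald log-RR + exact conditional binomial)"
  )
}

#' @rdname tidy.rate_comparison
#' @export
glance.rate_comparison <- function(x, ...) {
  dplyr::bind_cols(
    tidy.rate_comparison(x),
    tibble::tibble(x1 = x$x1, g1 = x$g1, x2 = x$x2, g2 = x$g2, p0 = x$p0)
  )
}

#' Per-class mutation rates for one or more groups
#'
#' Counts mutations per class (BPS, INSERTION, DELETION, SV) within each
#' group and scales by the group's exposure denominator, with Garwood
#' intervals. A pooled `INDEL` row (insertions + deletions) mirrors how MA
#' studies report the small-indel rate.
#'
#' @param mutations Classified mutation tibble (needs `line_id`, `mclass`).
#' @param lines MA-line metadata tibble (needs `group` when several groups
#'   are present).
#' @param conf Confidence level.
#' @param mean_sites Passed to [exposure()].
#' @return A tibble with one row per group x class.
#' @export
estimate_rates <- function(mutations, lines, conf = 0.95, mean_sites = NULL) {
  stopifnot(is.data.frame(mutations), is.data.frame(lines))
  lines <- tibble::as_tibble(lines)
  if (!"group" %in% names(lines)) lines$group <- "all"
  unresolved <- setdiff(unique(mutations$line_id), lines$line_id)
  if (length(unresolved) > 0) {
    stop("mutation line_id(s) not in metadata: ",
         paste(unresolved, collapse = ", "), call. = FALSE)
  }
  expo <- exposure(lines, mean_sites = mean_sites)
  muts <- dplyr::left_join(
    tibble::as_tibble(mutations),
    dplyr::select(lines, "line_id", "group"),
    by = "line_id"
  )
  counts <- dplyr::count(muts, .data$group, mclass = as.character(.data$mclass))
  indel <- dplyr::summarise(
    dplyr::group_by(counts[counts$mclass %in% c("INSERTION", "DELETION"), ],
                    .data$group),
    mclass = "INDEL", n = sum(.data$n), .groups = "drop"
  )
  grid <- tidyr::expand_grid(
    group = expo$group,
    mclass = c(mutation_classes(), "INDEL")
  )
  counts <- dplyr::left_join(grid, dplyr::bind_rows(counts, indel),
                             by = c("group", "mclass"))
  counts$n[is.na(counts$n)] <- 0
  out <- dplyr::left_join(counts, expo, by = "group")
  est <- estimate_rate(out$n, out$value, conf = conf, mclass = out$mclass)
  dplyr::bind_cols(
    dplyr::select(out, "group", "n_lines", "mean_divisions"),
    est
  )
}
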