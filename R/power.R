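#' Configuration for the Monte-Carlo power analysis
#'
#' Defines the two-group MA design whose power to detect a multiplicative
#' mutation-rate increase is estimated by simulation: control counts are
#' Poisson with mean `mu_control * g1`, treatment counts Poisson with mean
#' `mu_control * (1 + effect) * g2`, and each replicate is analysed with
#' the exact conditional binomial test of the treatment count out of the
#' total against p0 = g2/(g1 + g2).
#'
#' Defaults are the study conditions of a paired 46/48-line fission-yeast
#' MA experiment: exposures g1 = 5.02822e11 and g2 = 5.37022e11
#' site-divisions and a control rate of 3.58e-11 per site per division.
#'
#' @param mu_control Control mutation rate (per site per cell division).
#' @param g1,g2 Exposure denominators (site-division units).
#' @param effect_grid Multiplicative increases to scan; 0 = null, 1 = a
#'   100% increase (doubling).
#' @param reps Monte-Carlo replicates per effect size.
#' @param alpha Significance level.
#' @param sided `"one"` (toward a rate increase, the mutagenicity
#'   alternative) or `"two"`.
#' @param condition_on_control If `TRUE`, hold the control count fixed at
#'   `control_count` (the observed data) and simulate only treatment
#'   counts; if `FALSE` (default) both counts are simulated.
#' @param control_count Observed control count used when conditioning.
#' @param seed Integer seed; each effect size uses an independent
#'   deterministic substream derived from it.
#' @return A validated list of class `power_config`.
#' @export
power_config <- function(mu_control = 3.58e-11,
                         g1 = 5.02822e11, g2 = 5.37022e11,
                         effect_grid = seq(0, 3, by = 0.1),
                         reps = 1000, alpha = 0.05,
                         sided = c("one", "two"),
                         condition_on_control = FALSE,
                         control_count = 18,
                         seed = 1L) {
  sided <- match.arg(sided)
  stopifnot(mu_control >= 0, g1 > 0, g2 > 0, reps >= 1,
            alpha > 0, alpha < 1, all(effect_grid >= 0),
            control_count >= 0)
  structure(
    list(mu_control = mu_control, g1 = g1, g2 = g2,
         effect_grid = sort(unique(effect_grid)), reps = as.integer(reps),
         alpha = alpha, sided = sided,
         condition_on_control = isTRUE(condition_on_control),
         control_count = control_count, seed = as.integer(seed)),
    class = "power_config"
  )
}

#' Exact binomial test p-value, vectorized
#'
#' The conditional test of one Poisson rate against another: given the
#' total count n, the comparison-group count x is Binomial(n, p0) under
#' equal rates. One-sided p is the upper tail P(X >= x); two-sided p sums
#' all outcomes with probability not exceeding that of x (the
#' [stats::binom.test()] definition).
#'
#' @param x Comparison-group counts (vectorized).
#' @param n Total counts.
#' @param p0 Null success probability g2/(g1 + g2).
#' @param sided `"one"` or `"two"`.
#' @return Numeric vector of p-values; entries with `n == 0` are 1.
#' @export
binom_test_p <- function(x, n, p0, sided = c("one", "two")) {
  sided <- match.arg(sided)
  p <- rep(1, length(x))
  pos <- n > 0
  if (sided == "one") {
    p[pos] <- stats::pbinom(x[pos] - 1, n[pos], p0, lower.tail = FALSE)
  } else {
    idx <- which(pos)
    key <- paste(x[idx], n[idx])
    uniq <- !duplicated(key)
    pv <- vapply(idx[uniq], function(i) {
      stats::binom.test(x[i], n[i], p = p0)$p.value
    }, numeric(1))
    p[idx] <- pv[match(key, key[uniq])]
  }
  pmin(p, 1)
}

.draw_counts <- function(cfg, effect) {
  lam1 <- cfg$mu_control * cfg$g1
  lam2 <- cfg$mu_control * (1 + effect) * cfg$g2
  x1 <- if (cfg$condition_on_control) {
    rep(cfg$control_count, cfg$reps)
  } else {
    stats::rpois(cfg$reps, lam1)
  }
  x2 <- stats::rpois(cfg$reps, lam2)
  list(x1 = x1, x2 = x2)
}

.rejections <- function(cfg, x1, x2) {
  p0 <- cfg$g2 / (cfg$g1 + cfg$g2)
  p <- binom_test_p(x2, x1 + x2, p0, sided = cfg$sided)
  # an empty experiment (no mutations at all) can never reject
  p <= cfg$alpha & (x1 + x2) > 0
}

#' Simulate one replicate of the rate-comparison experiment
#'
#' Draws one pair of group counts under the configured effect size and
#' returns whether the conditional binomial test rejects at `cfg$alpha`.
#' Deterministic for fixed `cfg` and `effect` (the draw is made under
#' `cfg$seed`).
#'
#' @param cfg A [power_config()].
#' @param effect Multiplicative rate increase in the treatment group.
#' @return Logical: was the null rejected?
#' @export
simulate_once <- function(cfg, effect) {
  stopifnot(inherits(cfg, "power_config"), effect >= 0)
  cfg1 <- cfg
  cfg1$reps <- 1L
  withr::with_seed(cfg$seed, {
    d <- .draw_counts(cfg1, effect)
    as.logical(.rejections(cfg1, d$x1, d$x2))
  })
}

#' Monte-Carlo power curve for a two-group rate comparison
#'
#' For each effect size in `cfg$effect_grid`, simulates `cfg$reps`
#' replicate experiments and reports the rejection fraction with its
#' binomial Monte-Carlo standard error. Each effect size uses its own
#' deterministic substream of `cfg$seed`, so the curve is reproducible and
#' extending the grid does not perturb existing points.
#'
#' @param cfg A [power_config()].
#' @return A tibble of class `power_curve` with columns `effect`, `power`,
#'   `mc_se`, `rejections`, `reps`.
#' @export
#' @examples
#' pc <- power_curve(power_config(effect_grid = c(0, 1), reps = 200))
#' pc
power_curve <- function(cfg) {
  stopifnot(inherits(cfg, "power_config"))
  rows <- purrr::imap(cfg$effect_grid, function(effect, i) {
    sub_seed <- (cfg$seed + 7919L * i) %% .Machine$integer.max
    rej <- withr::with_seed(sub_seed, {
      d <- .draw_counts(cfg, effect)
      .rejections(cfg, d$x1, d$x2)
    })
    p_hat <- mean(rej)
    tibble::tibble(effect = effect, power = p_hat,
                   mc_se = sqrt(p_hat * (1 - p_hat) / cfg$reps),
                   rejections = sum(rej), reps = cfg$reps)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "config") <- cfg
  class(out) <- c("power_curve", class(out))
  out
}

#' Minimum detectable effect at a target power
#'
#' The smallest effect size on the simulated grid whose estimated power
#' reaches the target. With `interpolate = TRUE` the crossing point is
#' linearly interpolated between the bracketing grid points and flagged in
#' the `interpolated` attribute.
#'
#' @param curve A [power_curve()] result (or a [power_config()], in which
#'   case the curve is simulated first).
#' @param target_power Required power, in (0, 1).
#' @param interpolate Linearly interpolate between grid points.
#' @return The effect size (a single number), or `NA` with a warning when
#'   the target is unreachable on the grid.
#' @export
minimum_detectable_effect <- function(curve, target_power = 0.8,
                                      interpolate = FALSE) {
  stopifnot(target_power >= 0, target_power < 1)
  if (inherits(curve, "power_config")) curve <- power_curve(curve)
  hit <- which(curve$power >= target_power)
  if (length(hit) == 0) {
    warning("target power ", target_power,
            " not reached anywhere on the simulated effect grid")
    return(NA_real_)
  }
  i <- hit[1]
  if (!interpolate || i == 1 || target_power == 0) {
    return(curve$effect[i])
  }
  e <- stats::approx(curve$power[(i - 1):i], curve$effect[(i - 1):i],
                     xout = target_power)$y
  structure(e, interpolated = TRUE)
}

#' @export
print.power_curve <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "Monte-Carlo power curve (%s-sided exact conditional binomial, alpha = %g, %d reps)\n",
    cfg$sided, cfg$alpha, cfg$reps))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' Tidy and summarise a power curve
#'
#' @param x A `power_curve`.
#' @param target_power Target used by `glance()` for the minimum
#'   detectable effect.
#' @param ... Unused.
#' @return `tidy()`: the underlying tibble. `glance()`: a one-row summary
#'   with the configuration and the minimum detectable effect.
#' @export
tidy.power_curve <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "power_curve")
  attr(out, "config") <- NULL
  tibble::as_tibble(out)
}

#' @rdname tidy.power_curve
#' @export
glance.power_curve <- function(x, target_power = 0.8, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(
    mu_control = cfg$mu_control, g1 = cfg$g1, g2 = cfg$g2,
    reps = cfg$reps, alpha = cfg$alpha, sided = cfg$sided,
    condition_on_control = cfg$condition_on_control,
    n_effects = nrow(x),
    mde = suppressWarnings(minimum_detectable_effect(x, target_power)),
    target_power = target_power
  )
}

#' Plot a power curve
#'
#' Rejection probability against multiplicative effect size, with a
#' pointwise 95% Monte-Carlo error ribbon.
#'
#' @param object A `power_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$effect, y = .data$power)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = pmax(.data$power - 1.96 * .data$mc_se, 0),
                   ymax = pmin(.data$power + 1.96 * .data$mc_se, 1)),
      fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_continuous(labels = function(e) paste0(100 * e, "%")) +
    ggplot2::labs(x = "Multiplicative rate increase",
                  y = "Estimated power") +
    ggplot2::theme_classic()
}

#' @rdname autoplot.power_curve
#' @param curve A `power_curve` object.
#' @export
plot_power_curve <- function(curve, ...) autoplot.power_curve(curve, ...)
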