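test_that("exposure sums per-line sites x divisions and validates input", {
  lines <- tibble::tibble(line_id = c("L1", "L2"),
                          callable_sites = c(100, 200),
                          total_divisions = c(10, 20))
  expect_equal(exposure(lines)$value, 5000)
  expect_equal(exposure(lines[1, ] |> dplyr::mutate(
    callable_sites = 1, total_divisions = 1))$value, 1)
  expect_false(exposure(lines)$approximate)

  bad <- dplyr::mutate(lines, total_divisions = c(10, -1))
  expect_error(exposure(bad), "L2")
})

test_that("grand-mean exposure fallback reproduces the study denominator", {
  mean_sites <- G1 / (46 * 890)
  lines <- tibble::tibble(line_id = sprintf("C%02d", 1:46),
                          total_divisions = 890)
  got <- exposure(lines, mean_sites = mean_sites)
  expect_equal(got$value, G1, tolerance = 1e-12)
  expect_true(got$approximate)
  expect_error(exposure(lines), "mean_sites")
})

test_that("Garwood bounds equal the half chi-square quantiles", {
  # frozen from the chi-square quantile oracle:
  # qchisq(.975, 2)/2 = 3.68888; qchisq(.025, 36)/2 = 10.66833;
  # qchisq(.975, 38)/2 = 28.44837
  g0 <- garwood_ci(0)
  expect_equal(g0$low, 0)
  expect_equal(g0$high, 3.6889, tolerance = 1e-4)
  g18 <- garwood_ci(18)
  expect_equal(g18$low, 10.668, tolerance = 1e-4)
  expect_equal(g18$high, 28.448, tolerance = 1e-4)
  expect_error(garwood_ci(-1), "non-negative")
})

test_that("Garwood bounds are monotone in the count", {
  ci <- garwood_ci(0:50)
  expect_true(all(diff(ci$high) > 0))
  expect_true(all(diff(ci$low) >= 0))
  expect_true(all(ci$low <= 0:50 & 0:50 <= ci$high))
})

test_that("Garwood interval coverage is at least nominal", {
  # exact interval is conservative: simulated coverage stays >= 95%
  for (lambda_g in c(1, 5, 20)) {
    counts <- withr::with_seed(42 + lambda_g, stats::rpois(2000, lambda_g))
    ci <- garwood_ci(counts)
    covered <- ci$low <= lambda_g & lambda_g <= ci$high
    expect_gte(mean(covered), 0.95)
  }
})

test_that("rate estimates scale counts by exposure, reproducing study rates", {
  expect_equal(signif(estimate_rate(18, G1)$mu, 3), 3.58e-11)
  expect_equal(signif(estimate_rate(24, G2)$mu, 3), 4.47e-11)
  zero <- estimate_rate(0, 1e12)
  expect_equal(zero$mu, 0)
  expect_equal(zero$ci_low, 0)
  expect_equal(zero$ci_high, 3.6889e-12, tolerance = 1e-4)
  expect_error(estimate_rate(1, 0), "exposure")
})

test_that("rate estimation is scale-equivariant in the exposure", {
  for (k in c(0, 3, 18)) {
    for (scale in c(0.5, 2, 1e6)) {
      base <- estimate_rate(k, 1e10)
      scaled <- estimate_rate(k, scale * 1e10)
      expect_equal(scaled$mu, base$mu / scale)
      expect_equal(scaled$ci_low, base$ci_low / scale)
      expect_equal(scaled$ci_high, base$ci_high / scale)
    }
  }
})

test_that("rate-ratio test reproduces the study comparison", {
  rc <- rate_ratio_test(18, G1, 24, G2)
  expect_equal(round(rc$rr, 2), 1.25)
  # Wald interval from the closed form exp(ln rr +/- 1.96 sqrt(1/x1+1/x2))
  se <- sqrt(1 / 18 + 1 / 24)
  expect_equal(rc$ci_low, exp(log(rc$rr) - qnorm(0.975) * se))
  expect_equal(rc$ci_high, exp(log(rc$rr) + qnorm(0.975) * se))
  expect_equal(round(rc$ci_low, 2), 0.68)
  expect_equal(round(rc$ci_high, 2), 2.30)
  expect_equal(round(rc$p_wald, 2), 0.48)
  # exact conditional binomial p agrees with the oracle call
  expect_equal(rc$p_exact,
               stats::binom.test(24, 42, p = G2 / (G1 + G2))$p.value)
})

test_that("rate-ratio test is symmetric and handles degenerate counts", {
  eq <- rate_ratio_test(10, 1e9, 10, 1e9)
  expect_equal(eq$rr, 1)
  expect_equal(eq$p_exact, 1)

  a <- rate_ratio_test(18, G1, 24, G2)
  b <- rate_ratio_test(24, G2, 18, G1)
  expect_equal(a$rr * b$rr, 1)

  expect_error(rate_ratio_test(0, 1e9, 0, 1e9), "both event counts")
  flagged <- rate_ratio_test(0, 1e9, 5, 1e9)
  expect_true(is.infinite(flagged$rr))
  expect_true(flagged$degenerate)
  expect_true(is.finite(flagged$ci_low))
})

test_that("per-class group rates mirror counts over the group exposure", {
  exp <- simulate_experiment(sim_config(seed = 21))
  rates <- estimate_rates(exp$mutations, exp$lines)
  expect_setequal(unique(rates$mclass),
                  c("BPS", "INSERTION", "DELETION", "SV", "INDEL"))
  expo <- exposure(exp$lines)
  for (g in c("control", "treatment")) {
    sub <- rates[rates$group == g, ]
    gm <- exp$mutations[exp$mutations$line_id %in%
                          exp$lines$line_id[exp$lines$group == g], ]
    expect_equal(sub$count[sub$mclass == "BPS"],
                 sum(as.character(gm$mclass) == "BPS"))
    expect_equal(sub$mu, sub$count / expo$value[expo$group == g])
    # pooled indel row = insertions + deletions
    expect_equal(sub$count[sub$mclass == "INDEL"],
                 sub$count[sub$mclass == "INSERTION"] +
                   sub$count[sub$mclass == "DELETION"])
  }
})
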