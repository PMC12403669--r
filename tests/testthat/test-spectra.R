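test_that("spectrum counts partition BPS records into the six classes", {
  m <- classify_mutations(tibble::tibble(ref = c("C", "G", "A"),
                                         alt = c("T", "A", "G")))
  counts <- spectrum_counts(m)
  expect_equal(counts$count[counts$class == "G:C>A:T"], 2L)
  expect_equal(counts$count[counts$class == "A:T>G:C"], 1L)
  expect_equal(sum(counts$count), 3L)

  empty <- classify_mutations(tibble::tibble(ref = character(),
                                             alt = character()))
  expect_equal(spectrum_counts(empty)$count, rep(0L, 6))
})

test_that("large simulated spectra match generator class probabilities", {
  probs <- sim_config()$spectrum_probs
  classes <- withr::with_seed(42, sample(bps_classes(), 10000,
                                         replace = TRUE, prob = probs))
  m <- tibble::tibble(
    mclass = factor("BPS", levels = mutation_classes()),
    bps_subclass = factor(classes, levels = bps_classes())
  )
  counts <- spectrum_counts(m)
  expect_equal(sum(counts$count), 10000L)
  # each class frequency within 3 multinomial standard deviations
  sd3 <- 3 * sqrt(probs * (1 - probs) / 10000)
  expect_true(all(abs(counts$count / 10000 - probs[counts$class]) <= sd3))
})

test_that("conditional rates divide class counts by origin sites and divisions", {
  comp <- genome_composition(at_sites = 2e6, gc_sites = 1e6)
  lines <- tibble::tibble(line_id = "L1", callable_sites = 3e6,
                          total_divisions = 100)
  m <- classify_mutations(tibble::tibble(
    line_id = "L1", contig = "c", position = 1L, ref = "C", alt = "T"))
  spec <- conditional_spectrum_rates(m, lines, comp)
  expect_equal(spec$rate[spec$class == "G:C>A:T"], 1e-8)
  expect_equal(spec$sem, rep(0, 6)) # single line

  # two identical lines: SEM 0 for every class
  lines2 <- tibble::tibble(line_id = c("L1", "L2"), callable_sites = 3e6,
                           total_divisions = 100)
  m2 <- classify_mutations(tibble::tibble(
    line_id = c("L1", "L2"), contig = "c", position = c(1L, 2L),
    ref = "C", alt = "T"))
  spec2 <- conditional_spectrum_rates(m2, lines2, comp)
  expect_equal(spec2$sem, rep(0, 6))
})

test_that("conditional rates pooled over one line recover the total BPS count", {
  exp <- simulate_experiment(sim_config(seed = 13))
  comp <- exp$composition
  ctl <- exp$lines[exp$lines$group == "control", ]
  m <- exp$mutations[exp$mutations$line_id %in% ctl$line_id, ]
  # pool the group into a single line so rate x opportunity is exact
  pooled_line <- tibble::tibble(
    line_id = "pool", callable_sites = comp$genome_length,
    total_divisions = 1
  )
  mp <- dplyr::mutate(m, line_id = "pool")
  spec <- conditional_spectrum_rates(mp, pooled_line, comp)
  origin <- ifelse(startsWith(spec$class, "A:T"), comp$at_sites,
                   comp$gc_sites)
  expect_equal(sum(spec$rate * origin), sum(spec$count))
})

test_that("multi-line spectrum rate estimates are unbiased within MC error", {
  # 10 seeds x 6 classes: truth should fall inside mean +/- 2 SEM for the
  # large majority of class intervals (~95% nominal coverage)
  covered <- 0; total <- 0
  for (seed in 1:10) {
    cfg <- sim_config(n_lines_treatment = 1, treatment_fold = 0,
                      mu_indel = 0, mu_sv = 0, mu_bps = 3.58e-10,
                      n_lines_control = 50, seed = seed)
    exp <- simulate_experiment(cfg)
    ctl <- exp$lines[exp$lines$group == "control", ]
    m <- exp$mutations[exp$mutations$line_id %in% ctl$line_id, ]
    spec <- conditional_spectrum_rates(m, ctl, exp$composition)
    # truth: class rate conditioned on origin sites
    origin <- ifelse(startsWith(spec$class, "A:T"),
                     exp$composition$at_sites, exp$composition$gc_sites)
    truth <- cfg$mu_bps * cfg$spectrum_probs[spec$class] *
      exp$composition$genome_length / origin
    inside <- abs(spec$rate - truth) <= 2 * pmax(spec$sem, 1e-15)
    covered <- covered + sum(inside); total <- total + length(inside)
  }
  expect_gte(covered / total, 0.8)
})

test_that("ts/tv ratio splits transitions over transversions", {
  counts <- c("A:T>G:C" = 3, "G:C>A:T" = 9, "G:C>T:A" = 2, "A:T>T:A" = 2,
              "A:T>C:G" = 1, "G:C>C:G" = 1)
  expect_equal(ts_tv_ratio(counts), 2.00)
  expect_equal(ts_tv_ratio(c("A:T>G:C" = 1, "A:T>T:A" = 1)), 1.0)
  # the 15/9 split yields the treatment group's printed 1.67
  expect_equal(round(ts_tv_ratio(c("A:T>G:C" = 4, "G:C>A:T" = 11,
                                   "G:C>T:A" = 4, "A:T>T:A" = 2,
                                   "A:T>C:G" = 2, "G:C>C:G" = 1)), 2), 1.67)
  pure_ts <- ts_tv_ratio(c("A:T>G:C" = 5, "G:C>A:T" = 7))
  expect_true(is.infinite(pure_ts))
  expect_true(attr(pure_ts, "degenerate"))
})

test_that("A/T bias conditions directional counts on base composition", {
  comp <- genome_composition(at_sites = 8e6, gc_sites = 4e6)
  counts <- c("G:C>A:T" = 4, "G:C>T:A" = 2, "A:T>G:C" = 1, "A:T>C:G" = 1)
  expect_equal(at_bias(counts, comp), (6 / 4e6) / (2 / 8e6)) # = 6
  # equal conditional rates in both directions -> bias 1
  sym <- genome_composition(at_sites = 4e6, gc_sites = 4e6)
  expect_equal(at_bias(c("G:C>A:T" = 3, "A:T>G:C" = 3), sym), 1.0)
  expect_equal(at_bias(c("G:C>A:T" = 4, "A:T>G:C" = 2), sym), 2.0)
  # invariant under doubling all counts and site totals
  double <- genome_composition(at_sites = 16e6, gc_sites = 8e6)
  expect_equal(at_bias(counts * 2, double), at_bias(counts, comp))
  flagged <- at_bias(c("G:C>A:T" = 4), comp)
  expect_true(is.infinite(flagged) && attr(flagged, "degenerate"))
})

test_that("insertion/deletion ratio reproduces the study values", {
  m <- function(ins, del) tibble::tibble(
    mclass = factor(c(rep("INSERTION", ins), rep("DELETION", del)),
                    levels = mutation_classes()))
  expect_equal(ins_del_ratio(m(21, 3)), 7.00)
  expect_equal(ins_del_ratio(m(28, 2)), 14.00)
  expect_equal(ins_del_ratio(m(5, 5)), 1.0)
  flagged <- ins_del_ratio(m(3, 0))
  expect_true(is.infinite(flagged) && attr(flagged, "degenerate"))
})
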