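#' Configuration for a synthetic two-group MA experiment
#'
#' Defaults emulate a fission-yeast MA design: 46 control and 48 treatment
#' lines, a 12.52-Mb genome at 36.06% GC, 46 serial single-colony
#' transfers with ~19.35 cell divisions each (~890 divisions per line),
#' ~98% of the genome callable, a base-substitution rate of 3.58e-11 per
#' site per division with a 25% higher treatment rate, a small-indel rate
#' of 4.77e-11 with 7/8 of indels being insertions, an SV rate of
#' 1.19e-11, and a six-class substitution spectrum with ts/tv = 2.0 and a
#' composition-conditioned A/T bias of 4.33.
#'
#' @param n_lines_control,n_lines_treatment Lines per group.
#' @param genome_length Genome size (bp).
#' @param gc_content G+C fraction of the genome.
#' @param coding_fraction Fraction of sites in coding sequence.
#' @param nonsyn_syn_site_ratio Ratio of nonsynonymous to synonymous sites
#'   within coding sequence.
#' @param mu_bps,mu_indel,mu_sv Control-group rates per site per division.
#' @param treatment_fold Multiplier applied to every rate in the treatment
#'   group (1 = no effect).
#' @param spectrum_probs Probability vector over [bps_classes()].
#' @param ins_del_prob Probability that a small indel is an insertion.
#' @param transfers,divisions_per_transfer Serial-transfer design.
#' @param callable_fraction Fraction of the genome passing coverage filters
#'   in every line.
#' @param cfu_sigma Lognormal (natural-log scale) noise SD of CFU counts.
#' @param seed Integer master seed; each line draws from its own
#'   deterministic substream so adding lines does not perturb earlier ones.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_lines_control = 46, n_lines_treatment = 48,
                       genome_length = 12521788, gc_content = 0.3606,
                       coding_fraction = 0.6162,
                       nonsyn_syn_site_ratio = 3.7007,
                       mu_bps = 3.58e-11, mu_indel = 4.77e-11,
                       mu_sv = 1.19e-11, treatment_fold = 1.25,
                       spectrum_probs = c(
                         "A:T>G:C" = 3, "A:T>T:A" = 1.5, "A:T>C:G" = 1.5,
                         "G:C>A:T" = 9, "G:C>T:A" = 2, "G:C>C:G" = 1
                       ) / 18,
                       ins_del_prob = 21 / 24,
                       transfers = 46, divisions_per_transfer = 890 / 46,
                       callable_fraction = 0.9808,
                       cfu_sigma = 0.2, seed = 1L) {
  stopifnot(
    n_lines_control >= 1, n_lines_treatment >= 1, genome_length >= 1,
    gc_content >= 0, gc_content <= 1,
    coding_fraction >= 0, coding_fraction <= 1, nonsyn_syn_site_ratio > 0,
    mu_bps >= 0, mu_indel >= 0, mu_sv >= 0, treatment_fold >= 0,
    length(spectrum_probs) == 6, all(spectrum_probs >= 0),
    abs(sum(spectrum_probs) - 1) < 1e-8,
    ins_del_prob >= 0, ins_del_prob <= 1,
    transfers >= 1, divisions_per_transfer > 0,
    callable_fraction > 0, callable_fraction <= 1, cfu_sigma >= 0
  )
  names(spectrum_probs) <- bps_classes()
  structure(
    list(n_lines_control = n_lines_control,
         n_lines_treatment = n_lines_treatment,
         genome_length = genome_length, gc_content = gc_content,
         coding_fraction = coding_fraction,
         nonsyn_syn_site_ratio = nonsyn_syn_site_ratio,
         mu_bps = mu_bps, mu_indel = mu_indel, mu_sv = mu_sv,
         treatment_fold = treatment_fold, spectrum_probs = spectrum_probs,
         ins_del_prob = ins_del_prob, transfers = transfers,
         divisions_per_transfer = divisions_per_transfer,
         callable_fraction = callable_fraction,
         cfu_sigma = cfu_sigma, seed = as.integer(seed)),
    class = "sim_config"
  )
}

.line_seed <- function(seed, index) {
  (abs(seed) * 1009L + index * 7L) %% 2147483647L
}

.sim_composition <- function(cfg) {
  gc <- round(cfg$gc_content * cfg$genome_length)
  coding <- cfg$coding_fraction * cfg$genome_length
  r <- cfg$nonsyn_syn_site_ratio
  genome_composition(
    at_sites = cfg$genome_length - gc, gc_sites = gc,
    genome_length = cfg$genome_length,
    nonsyn_sites = coding * r / (1 + r), syn_sites = coding / (1 + r)
  )
}

# one class label -> (ref, alt) pair on a uniformly chosen strand
.bps_alleles <- function(class) {
  from <- substr(class, 1, 3)
  to <- substr(class, 5, 7)
  top <- stats::runif(length(class)) < 0.5
  ref <- ifelse(top, substr(from, 1, 1), substr(from, 3, 3))
  alt <- ifelse(top, substr(to, 1, 1), substr(to, 3, 3))
  list(ref = ref, alt = alt)
}

.rand_bases <- function(sizes) {
  vapply(sizes, function(s) {
    paste(sample(c("A", "C", "G", "T"), s, replace = TRUE), collapse = "")
  }, character(1))
}

.simulate_line <- function(cfg, line_id, fold) {
  sites <- round(cfg$genome_length * cfg$callable_fraction)
  div <- cfg$transfers * cfg$divisions_per_transfer
  opp <- sites * div
  n_bps <- stats::rpois(1, fold * cfg$mu_bps * opp)
  n_ind <- stats::rpois(1, fold * cfg$mu_indel * opp)
  n_sv <- stats::rpois(1, fold * cfg$mu_sv * opp)

  rows <- list()
  if (n_bps > 0) {
    class <- sample(bps_classes(), n_bps, replace = TRUE,
                    prob = cfg$spectrum_probs)
    al <- .bps_alleles(class)
    r <- cfg$nonsyn_syn_site_ratio
    coding <- stats::runif(n_bps) < cfg$coding_fraction
    nonsyn <- stats::runif(n_bps) < r / (1 + r)
    rows$bps <- tibble::tibble(
      line_id = line_id, contig = "contig_1",
      position = sample.int(cfg$genome_length, n_bps, replace = TRUE),
      ref = al$ref, alt = al$alt, class = "BPS",
      coding_effect = ifelse(!coding, "noncoding",
                             ifelse(nonsyn, "nonsynonymous", "synonymous"))
    )
  }
  if (n_ind > 0) {
    is_ins <- stats::runif(n_ind) < cfg$ins_del_prob
    # most small indels are 1 bp; geometric tail capped below the SV boundary
    size <- pmin(stats::rgeom(n_ind, 0.7) + 1L, SV_SIZE_BOUNDARY - 1L)
    anchor <- .rand_bases(rep(1L, n_ind))
    inserted <- .rand_bases(size)
    rows$indel <- tibble::tibble(
      line_id = line_id, contig = "contig_1",
      position = sample.int(cfg$genome_length - 1L, n_ind, replace = TRUE),
      ref = ifelse(is_ins, anchor, paste0(anchor, inserted)),
      alt = ifelse(is_ins, paste0(anchor, inserted), anchor),
      class = ifelse(is_ins, "INSERTION", "DELETION"),
      coding_effect = NA_character_
    )
  }
  if (n_sv > 0) {
    size <- SV_SIZE_BOUNDARY + stats::rgeom(n_sv, 0.02)
    anchor <- .rand_bases(rep(1L, n_sv))
    rows$sv <- tibble::tibble(
      line_id = line_id, contig = "contig_1",
      position = sample.int(cfg$genome_length - max(size), n_sv,
                            replace = TRUE),
      ref = paste0(anchor, .rand_bases(size)),
      alt = anchor, class = "SV",
      coding_effect = NA_character_
    )
  }
  dplyr::bind_rows(rows)
}

#' Simulate a complete two-group MA experiment
#'
#' Per line, mutation counts for each class are Poisson with mean rate x
#' callable sites x total divisions (treatment rates multiplied by
#' `treatment_fold`); base substitutions receive a spectrum class, a
#' uniformly drawn position, strand-uniform ref/alt alleles, and a
#' probabilistic coding effect; indel sizes are 1-49 bp and SV sizes >= 50
#' bp. Duplicate (line, contig, position) draws — vanishingly rare at MA
#' rates — are dropped with a message.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `ma_experiment` with elements `mutations`
#'   (classified mutation tibble for both groups), `lines` (metadata
#'   tibble), `composition` ([genome_composition()]) and `truth` (the
#'   generating parameters plus per-group exposures and expected counts).
#' @export
#' @examples
#' exp <- simulate_experiment(sim_config(seed = 7))
#' dplyr::count(exp$mutations, exp$mutations$mclass)
simulate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sites <- round(cfg$genome_length * cfg$callable_fraction)
  div <- cfg$transfers * cfg$divisions_per_transfer
  n_tot <- cfg$n_lines_control + cfg$n_lines_treatment
  expected <- (cfg$mu_bps + cfg$mu_indel + cfg$mu_sv) *
    max(1, cfg$treatment_fold) * sites * div *
    max(cfg$n_lines_control, cfg$n_lines_treatment)
  if (expected > 1e6) {
    stop("refusing to simulate > 1e6 expected mutations per group; ",
         "reduce rates or exposures", call. = FALSE)
  }

  groups <- c(rep("control", cfg$n_lines_control),
              rep("treatment", cfg$n_lines_treatment))
  ids <- sprintf("%s_%02d", ifelse(groups == "control", "C", "T"),
                 c(seq_len(cfg$n_lines_control),
                   seq_len(cfg$n_lines_treatment)))
  muts <- purrr::map(seq_len(n_tot), function(i) {
    withr::with_seed(.line_seed(cfg$seed, i), {
      fold <- if (groups[i] == "treatment") cfg$treatment_fold else 1
      .simulate_line(cfg, ids[i], fold)
    })
  })
  muts <- dplyr::bind_rows(muts)
  if (nrow(muts) > 0) {
    dup <- duplicated(muts[c("line_id", "contig", "position")])
    if (any(dup)) {
      message("dropped ", sum(dup), " duplicate-position mutation(s)")
      muts <- muts[!dup, , drop = FALSE]
    }
    muts <- classify_mutations(muts)
    muts <- dplyr::arrange(muts, .data$contig, .data$position, .data$line_id)
  } else {
    muts <- classify_mutations(
      tibble::tibble(line_id = character(), contig = character(),
                     position = integer(), ref = "A"[0], alt = "G"[0],
                     class = character(), coding_effect = character())
    )
  }

  lines <- tibble::tibble(
    line_id = ids, group = groups, transfers = cfg$transfers,
    divisions_per_transfer = cfg$divisions_per_transfer,
    total_divisions = div, callable_sites = sites
  )
  truth <- list(
    cfg = cfg,
    g_control = cfg$n_lines_control * sites * div,
    g_treatment = cfg$n_lines_treatment * sites * div,
    expected_bps_control = cfg$mu_bps * cfg$n_lines_control * sites * div,
    expected_bps_treatment = cfg$treatment_fold * cfg$mu_bps *
      cfg$n_lines_treatment * sites * div
  )
  structure(
    list(mutations = muts, lines = lines,
         composition = .sim_composition(cfg), truth = truth),
    class = "ma_experiment"
  )
}

#' Simulate a CFU measurement series
#'
#' Colony-forming-unit counts of colonies grown from single cells that
#' underwent `T` doublings: CFU = round(2^T x lognormal noise), floored at
#' 1. The divisions-per-transfer estimator recovers `T` as the mean of
#' log2(CFU).
#'
#' @param cfg A [sim_config()] (supplies `divisions_per_transfer`,
#'   `cfu_sigma` and `seed`).
#' @param n_samples Colonies measured per round.
#' @param rounds Number of sampling rounds.
#' @return A tibble with columns `round`, `sample` and `cfu`.
#' @export
simulate_cfu_series <- function(cfg, n_samples = 10, rounds = 1) {
  stopifnot(inherits(cfg, "sim_config"), n_samples >= 1, rounds >= 1)
  withr::with_seed(.line_seed(cfg$seed, 999983L), {
    out <- tidyr::expand_grid(round = seq_len(rounds),
                              sample = seq_len(n_samples))
    noise <- exp(stats::rnorm(nrow(out), 0, cfg$cfu_sigma))
    out$cfu <- pmax(1, round(2^cfg$divisions_per_transfer * noise))
    out
  })
}

#' Simulate a random genome sequence at a target GC content
#'
#' @param length Sequence length (bp).
#' @param gc_content Probability that a base is G or C.
#' @param seed Integer seed.
#' @return A `Biostrings::DNAStringSet` of one sequence named
#'   `"synthetic_contig_1"`.
#' @export
simulate_genome <- function(length, gc_content = 0.3606, seed = 1L) {
  stopifnot(length >= 1, gc_content >= 0, gc_content <= 1)
  bases <- withr::with_seed(seed, {
    sample(c("A", "T", "G", "C"), length, replace = TRUE,
           prob = c((1 - gc_content) / 2, (1 - gc_content) / 2,
                    gc_content / 2, gc_content / 2))
  })
  out <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(out) <- "synthetic_contig_1"
  out
}

#' Write a simulated experiment to disk
#'
#' Emits the TSV dialects consumed by [read_mutation_table()] and
#' [read_line_metadata()] plus a JSON ground-truth file; byte-identical
#' for identical configurations.
#'
#' @param experiment An `ma_experiment` from [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return The paths written, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "ma_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    mutations = file.path(dir, "mutations.tsv"),
    lines = file.path(dir, "lines.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_mutation_table(experiment$mutations, paths[["mutations"]])
  readr::write_tsv(experiment$lines, paths[["lines"]], progress = FALSE)
  truth <- experiment$truth
  truth$cfg <- unclass(truth$cfg)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
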