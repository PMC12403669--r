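#' Full MA-experiment analysis
#'
#' Composes the whole analysis for a (optionally two-group) MA experiment:
#' per-class mutation rates with exact Poisson intervals, six-class
#' conditional spectra with SEM, ts/tv, A/T bias and In/Del summary
#' statistics, between-group Poisson rate comparisons for BPS, indels and
#' SVs, Yates-corrected selection tests, harmonic-mean effective
#' population size, and (optionally) the Monte-Carlo power curve.
#'
#' @param mutations Classified mutation tibble (see
#'   [read_mutation_table()]).
#' @param lines MA-line metadata tibble with a `group` column.
#' @param composition A [genome_composition()]; `nonsyn_sites`/`syn_sites`
#'   are needed for the selection tests.
#' @param conf Confidence level for rate intervals.
#' @param mean_sites Optional grand-mean callable sites for the exposure
#'   fallback (see [exposure()]).
#' @param reference_group Group treated as the comparison baseline;
#'   defaults to the first group in `lines`.
#' @param power A [power_config()] to append a power analysis, or `NULL`.
#' @return An object of class `ma_report`: a list with tibbles `summary`
#'   (one row per group: lines, divisions, counts, ts/tv, AT bias, In/Del,
#'   Ne), `rates` (per group x class with CIs), `comparisons` (per class),
#'   `selection` (tidied test rows), and optionally `power_curve`.
#' @export
analyze_experiment <- function(mutations, lines, composition,
                               conf = 0.95, mean_sites = NULL,
                               reference_group = NULL, power = NULL) {
  lines <- tibble::as_tibble(lines)
  if (!"group" %in% names(lines)) lines$group <- "all"
  group_names <- unique(lines$group)
  if (is.null(reference_group)) reference_group <- group_names[1]
  stopifnot(reference_group %in% group_names)
  mutations <- tibble::as_tibble(mutations)
  unresolved <- setdiff(unique(mutations$line_id), lines$line_id)
  if (length(unresolved) > 0) {
    stop("mutation line_id(s) not in metadata: ",
         paste(unresolved, collapse = ", "), call. = FALSE)
  }
  mutations <- dplyr::left_join(
    mutations, dplyr::select(lines, "line_id", "group"), by = "line_id"
  )

  rates <- estimate_rates(dplyr::select(mutations, -"group"), lines,
                          conf = conf, mean_sites = mean_sites)

  per_group <- lapply(group_names, function(g) {
    gm <- mutations[mutations$group == g, , drop = FALSE]
    gl <- lines[lines$group == g, , drop = FALSE]
    counts <- spectrum_counts(gm)
    spec <- conditional_spectrum_rates(gm, gl, composition)
    t_bar <- mean(gl$divisions_per_transfer)
    list(
      group = g,
      spectrum = spec,
      summary = tibble::tibble(
        group = g,
        n_lines = nrow(gl),
        mean_divisions = mean(gl$total_divisions),
        n_bps = sum(counts$count),
        n_insertion = sum(as.character(gm$mclass) == "INSERTION"),
        n_deletion = sum(as.character(gm$mclass) == "DELETION"),
        n_sv = sum(as.character(gm$mclass) == "SV"),
        ts_tv = as.numeric(ts_tv_ratio(counts)),
        at_bias = as.numeric(at_bias(counts, composition)),
        ins_del = as.numeric(ins_del_ratio(gm)),
        ne = effective_population_size(t_bar)
      )
    )
  })
  summary_tbl <- dplyr::bind_rows(lapply(per_group, `[[`, "summary"))
  spectra <- stats::setNames(lapply(per_group, `[[`, "spectrum"),
                             group_names)

  comparisons <- NULL
  selection <- .selection_tests(mutations, composition, group_names)
  if (length(group_names) == 2) {
    other <- setdiff(group_names, reference_group)
    expo <- exposure(lines, mean_sites = mean_sites)
    g1 <- expo$value[expo$group == reference_group]
    g2 <- expo$value[expo$group == other]
    comparisons <- dplyr::bind_rows(lapply(
      c("BPS", "INDEL", "SV"),
      function(cl) {
        x1 <- rates$count[rates$group == reference_group & rates$mclass == cl]
        x2 <- rates$count[rates$group == other & rates$mclass == cl]
        if (x1 + x2 < 1) {
          return(tibble::tibble(mclass = cl, estimate = NA_real_))
        }
        dplyr::bind_cols(tibble::tibble(mclass = cl),
                         tidy(rate_ratio_test(x1, g1, x2, g2, conf = conf)))
      }
    ))
  }

  pc <- if (!is.null(power)) power_curve(power) else NULL

  out <- structure(
    list(summary = summary_tbl, rates = rates, spectra = spectra,
         comparisons = comparisons, selection = selection,
         power_curve = pc, composition = composition,
         conf = conf, reference_group = reference_group,
         multiple_testing = paste(
           "p-values are reported raw; no multiple-testing adjustment is",
           "applied across this handful of planned tests")),
    class = "ma_report"
  )
  .check_report_consistency(out, mutations, composition)
  out
}

.selection_tests <- function(mutations, composition, group_names) {
  if (is.na(composition$nonsyn_sites) || is.na(composition$syn_sites) ||
      !"coding_effect" %in% names(mutations)) {
    return(NULL)
  }
  coding <- dplyr::count(
    mutations[!is.na(mutations$coding_effect) &
                mutations$coding_effect != "noncoding" &
                as.character(mutations$mclass) == "BPS", ],
    .data$group, .data$coding_effect
  )
  obs <- function(g, eff) {
    v <- coding$n[coding$group == g & coding$coding_effect == eff]
    if (length(v) == 0) 0L else v
  }
  rows <- list()
  for (g in group_names) {
    if (obs(g, "nonsynonymous") + obs(g, "synonymous") >= 1) {
      t <- tidy(yates_gof_test(obs(g, "nonsynonymous"), obs(g, "synonymous"),
                               composition$nonsyn_sites,
                               composition$syn_sites))
      rows[[g]] <- dplyr::bind_cols(tibble::tibble(test = paste0(
        "nonsyn/syn vs site expectation (", g, ")")), t)
    }
  }
  if (length(group_names) == 2) {
    a <- obs(group_names[1], "nonsynonymous"); b <- obs(group_names[1], "synonymous")
    c2 <- obs(group_names[2], "nonsynonymous"); d <- obs(group_names[2], "synonymous")
    ok <- (a + b) > 0 && (c2 + d) > 0 && (a + c2) > 0 && (b + d) > 0
    if (ok) {
      rows$between <- dplyr::bind_cols(
        tibble::tibble(test = "nonsyn/syn between groups (2x2)"),
        tidy(yates_2x2_test(a, b, c2, d))
      )
    }
  }
  if (length(rows) == 0) NULL else dplyr::bind_rows(rows)
}

# emit-time internal consistency: summary statistics must re-derive from
# the record set
.check_report_consistency <- function(report, mutations, composition) {
  for (g in report$summary$group) {
    gm <- mutations[mutations$group == g, , drop = FALSE]
    counts <- spectrum_counts(gm)
    row <- report$summary[report$summary$group == g, ]
    stopifnot(
      sum(counts$count) == row$n_bps,
      isTRUE(all.equal(as.numeric(ts_tv_ratio(counts)), row$ts_tv)),
      isTRUE(all.equal(as.numeric(at_bias(counts, composition)), row$at_bias)),
      isTRUE(all.equal(as.numeric(ins_del_ratio(gm)), row$ins_del))
    )
    # classification partition: the four classes exhaust the records
    stopifnot(sum(row$n_bps, row$n_insertion, row$n_deletion, row$n_sv) ==
                nrow(gm))
  }
  invisible(TRUE)
}

#' Run the full analysis from a configuration file
#'
#' Reads a YAML (or JSON) configuration naming the input tables and
#' options, loads and validates the inputs, and calls
#' [analyze_experiment()]. Recognised keys:
#'
#' * `mutation_table`, `metadata_table` — TSV paths (required).
#' * `genome_fasta` — FASTA path scanned for base composition, or
#' * `composition` — explicit counts: `at_sites`, `gc_sites`,
#'   `genome_length`, `nonsyn_sites`, `syn_sites`.
#' * `conf_level` (default 0.95), `reference_group`, `mean_sites`.
#' * `power` — sub-keys passed to [power_config()] (`enabled: true` plus
#'   any of its arguments), `seed`.
#'
#' Relative paths are resolved against the configuration file's directory.
#'
#' @param config Path to a YAML/JSON configuration file, or an equivalent
#'   named list.
#' @return An `ma_report`; see [analyze_experiment()].
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) {
    base_dir <- dirname(config)
    cfg <- tryCatch(
      yaml::read_yaml(config),
      error = function(e) stop("config error: cannot parse ", config, ": ",
                               conditionMessage(e), call. = FALSE)
    )
  } else {
    base_dir <- "."
    cfg <- config
  }
  if (!is.list(cfg)) stop("config error: configuration must be a mapping",
                          call. = FALSE)
  need <- function(key) {
    if (is.null(cfg[[key]])) {
      stop("config error: missing required key `", key, "`", call. = FALSE)
    }
    cfg[[key]]
  }
  resolve <- function(p) {
    if (file.exists(p)) p else file.path(base_dir, p)
  }
  mutations <- read_mutation_table(resolve(need("mutation_table")))
  lines <- read_line_metadata(resolve(need("metadata_table")))
  composition <- if (!is.null(cfg$genome_fasta)) {
    comp <- scan_genome_composition(resolve(cfg$genome_fasta))
    if (!is.null(cfg$composition)) {
      comp$nonsyn_sites <- cfg$composition$nonsyn_sites %||% NA_real_
      comp$syn_sites <- cfg$composition$syn_sites %||% NA_real_
    }
    comp
  } else if (!is.null(cfg$composition)) {
    cc <- cfg$composition
    genome_composition(
      at_sites = cc$at_sites, gc_sites = cc$gc_sites,
      genome_length = cc$genome_length %||% (cc$at_sites + cc$gc_sites),
      nonsyn_sites = cc$nonsyn_sites %||% NA_real_,
      syn_sites = cc$syn_sites %||% NA_real_
    )
  } else {
    stop("config error: provide `genome_fasta` or `composition`",
         call. = FALSE)
  }
  power <- NULL
  if (isTRUE(cfg$power$enabled)) {
    args <- cfg$power
    args$enabled <- NULL
    if (!is.null(cfg$seed) && is.null(args$seed)) args$seed <- cfg$seed
    power <- do.call(power_config, args)
  }
  analyze_experiment(
    mutations, lines, composition,
    conf = cfg$conf_level %||% 0.95,
    mean_sites = cfg$mean_sites,
    reference_group = cfg$reference_group,
    power = power
  )
}

#' @export
print.ma_report <- function(x, ...) {
  cat("MA-experiment analysis report\n\n")
  cat("Per-group summary:\n")
  print(x$summary)
  cat("\nPer-class rates (per site per cell division):\n")
  print(x$rates)
  if (!is.null(x$comparisons)) {
    cat("\nBetween-group rate comparisons (reference:",
        x$reference_group, "):\n")
    print(x$comparisons)
  }
  if (!is.null(x$selection)) {
    cat("\nSelection tests:\n")
    print(x$selection)
  }
  if (!is.null(x$power_curve)) {
    cat("\nPower analysis:\n")
    print(x$power_curve)
  }
  cat("\nNote:", x$multiple_testing, "\n")
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits `report.json` (the full report), plus plot-ready TSVs:
#' `summary.tsv`, `rates.tsv`, `comparisons.tsv`, `selection.tsv`,
#' `spectrum_<group>.tsv` and `power_curve.tsv` as applicable. Re-running
#' with identical inputs produces byte-identical files.
#'
#' @param report An `ma_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "ma_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(df, name) {
    if (!is.null(df)) {
      readr::write_tsv(tibble::as_tibble(df), file.path(dir, name),
                       progress = FALSE)
    }
  }
  emit(report$summary, "summary.tsv")
  emit(report$rates, "rates.tsv")
  emit(report$comparisons, "comparisons.tsv")
  emit(report$selection, "selection.tsv")
  for (g in names(report$spectra)) {
    emit(report$spectra[[g]], paste0("spectrum_", g, ".tsv"))
  }
  if (!is.null(report$power_curve)) {
    emit(tidy(report$power_curve), "power_curve.tsv")
  }
  json <- list(
    summary = report$summary, rates = report$rates,
    comparisons = report$comparisons, selection = report$selection,
    spectra = report$spectra,
    power_curve = if (!is.null(report$power_curve)) {
      tidy(report$power_curve)
    },
    conf = report$conf, reference_group = report$reference_group,
    note = report$multiple_testing
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
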