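#' Six-class base-substitution spectrum counts
#'
#' Tallies BPS records into the six strand-collapsed substitution classes.
#'
#' @param mutations Classified mutation tibble; only `mclass == "BPS"` rows
#'   are used and each must carry a `bps_subclass`.
#' @return A tibble with columns `class` (all six classes, fixed order) and
#'   `count`.
#' @export
#' @examples
#' m <- classify_mutations(tibble::tibble(ref = c("C", "G", "A"),
#'                                        alt = c("T", "A", "G")))
#' spectrum_counts(m)
spectrum_counts <- function(mutations) {
  stopifnot(is.data.frame(mutations))
  bps <- mutations[as.character(mutations$mclass) == "BPS", , drop = FALSE]
  if (anyNA(bps$bps_subclass)) {
    stop("BPS record(s) without a substitution subclass; run ",
         "classify_mutations() first", call. = FALSE)
  }
  counts <- table(factor(bps$bps_subclass, levels = bps_classes()))
  tibble::tibble(class = bps_classes(), count = as.integer(counts))
}

.origin_sites <- function(class, composition) {
  ifelse(startsWith(class, "A:T"), composition$at_sites, composition$gc_sites)
}

#' Composition-conditional spectrum rates with per-line SEM
#'
#' For each substitution class the per-line rate divides the line's class
#' count by the number of origin-base sites available to it (A/T sites for
#' A:T-origin classes, G/C sites for G:C-origin classes, scaled by the
#' line's callable fraction) times the line's total divisions. The class
#' rate is the mean over lines; the SEM is the between-line standard
#' deviation over sqrt(n_lines), the error bar of a spectrum plot.
#'
#' @param mutations Classified mutation tibble for one group.
#' @param lines Metadata tibble for the same group (columns `line_id`,
#'   `callable_sites`, `total_divisions`).
#' @param composition A [genome_composition()] with `at_sites`/`gc_sites`.
#' @return A tibble of class `ma_spectrum` with columns `class`, `count`,
#'   `rate`, `sem`, `n_lines`.
#' @export
conditional_spectrum_rates <- function(mutations, lines, composition) {
  stopifnot(is.data.frame(lines), nrow(lines) > 0)
  if (composition$at_sites <= 0 || composition$gc_sites <= 0) {
    stop("composition must have positive A/T and G/C site counts",
         call. = FALSE)
  }
  bps <- mutations[as.character(mutations$mclass) == "BPS", , drop = FALSE]
  if (anyNA(bps$bps_subclass)) {
    stop("BPS record(s) without a substitution subclass", call. = FALSE)
  }
  lines <- tibble::as_tibble(lines)
  if (!"total_divisions" %in% names(lines)) {
    lines$total_divisions <- lines$transfers * lines$divisions_per_transfer
  }
  callable_frac <- if ("callable_sites" %in% names(lines)) {
    lines$callable_sites / composition$genome_length
  } else {
    rep(1, nrow(lines))
  }

  per_line <- tidyr::expand_grid(line_id = lines$line_id,
                                 class = bps_classes())
  tallies <- dplyr::count(
    dplyr::mutate(bps, class = as.character(.data$bps_subclass)),
    .data$line_id, .data$class
  )
  per_line <- dplyr::left_join(per_line, tallies,
                               by = c("line_id", "class"))
  per_line$n[is.na(per_line$n)] <- 0
  per_line <- dplyr::left_join(
    per_line,
    tibble::tibble(line_id = lines$line_id,
                   callable_frac = callable_frac,
                   total_divisions = lines$total_divisions),
    by = "line_id"
  )
  per_line$origin <- .origin_sites(per_line$class, composition)
  per_line$rate <- per_line$n /
    (per_line$origin * per_line$callable_frac * per_line$total_divisions)

  out <- dplyr::summarise(
    dplyr::group_by(per_line, class = factor(.data$class, levels = bps_classes())),
    count = sum(.data$n),
    # sem before the mean so `rate` still names the per-line values
    sem = if (dplyr::n() > 1) stats::sd(.data$rate) / sqrt(dplyr::n()) else 0,
    rate = mean(.data$rate),
    n_lines = dplyr::n(),
    .groups = "drop"
  )
  out <- out[, c("class", "count", "rate", "sem", "n_lines")]
  out$class <- as.character(out$class)
  class(out) <- c("ma_spectrum", class(out))
  out
}

.counts_vector <- function(class_counts) {
  if (is.data.frame(class_counts)) {
    stats::setNames(class_counts$count, class_counts$class)[bps_classes()]
  } else {
    out <- stats::setNames(rep(0, 6), bps_classes())
    out[names(class_counts)] <- class_counts
    out
  }
}

#' Transition/transversion ratio
#'
#' Transitions are the A:T>G:C and G:C>A:T classes; the other four classes
#' are transversions. A spectrum with no transversions yields `Inf` with
#' attribute `degenerate = TRUE` rather than an error.
#'
#' @param class_counts Output of [spectrum_counts()] (or a named count
#'   vector over the six classes).
#' @return The ratio as a single number.
#' @export
ts_tv_ratio <- function(class_counts) {
  k <- .counts_vector(class_counts)
  ts <- sum(k[transition_classes()])
  tv <- sum(k) - ts
  if (tv == 0) {
    return(structure(Inf, degenerate = TRUE))
  }
  ts / tv
}

#' Mutation bias in the A/T direction
#'
#' Ratio of the composition-conditional rate of mutations toward A/T
#' (classes G:C>A:T and G:C>T:A, per G/C site) over the rate toward G/C
#' (classes A:T>G:C and A:T>C:G, per A/T site). The direction-neutral
#' classes G:C>C:G and A:T>T:A change neither composition and are
#' excluded.
#'
#' @inheritParams ts_tv_ratio
#' @param composition A [genome_composition()].
#' @return The bias ratio; `Inf` with attribute `degenerate = TRUE` when no
#'   A/T-origin directional events were observed.
#' @export
at_bias <- function(class_counts, composition) {
  k <- .counts_vector(class_counts)
  toward_at <- k["G:C>A:T"] + k["G:C>T:A"]
  toward_gc <- k["A:T>G:C"] + k["A:T>C:G"]
  if (toward_gc == 0) {
    return(structure(Inf, degenerate = TRUE))
  }
  unname((toward_at / composition$gc_sites) /
           (toward_gc / composition$at_sites))
}

#' Insertion/deletion ratio among small indels
#'
#' @param mutations Classified mutation tibble.
#' @return insertions / deletions; `Inf` with attribute `degenerate = TRUE`
#'   when no deletions were observed.
#' @export
ins_del_ratio <- function(mutations) {
  cls <- as.character(mutations$mclass)
  ins <- sum(cls == "INSERTION")
  del <- sum(cls == "DELETION")
  if (del == 0) {
    return(structure(Inf, degenerate = TRUE))
  }
  ins / del
}

#' Plot a mutation spectrum
#'
#' Bar chart of per-class conditional rates with SEM error bars, the
#' standard MA-study spectrum figure.
#'
#' @param object An `ma_spectrum` from [conditional_spectrum_rates()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ma_spectrum <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$class <- factor(df$class, levels = bps_classes())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$rate)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$rate - .data$sem, 0),
                   ymax = .data$rate + .data$sem),
      width = 0.25
    ) +
    ggplot2::labs(x = NULL, y = "Conditional mutation rate\n(per site per cell division)") +
    ggplot2::theme_classic()
}

#' @rdname autoplot.ma_spectrum
#' @param spectrum An `ma_spectrum` object.
#' @export
plot_spectrum <- function(spectrum, ...) autoplot.ma_spectrum(spectrum, ...)
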