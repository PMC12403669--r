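#' Cell divisions per transfer from colony-forming units
#'
#' A colony founded by a single cell that has undergone T doublings
#' contains about 2^T cells, so log2 of the colony's CFU estimates T. With
#' multiplicative (lognormal) plating noise the unbiased summary is the
#' geometric mean, so T is estimated as the mean of log2(CFU); when the
#' measurements come from several sampling rounds the grand mean of the
#' per-round estimates is returned.
#'
#' @param cfu Numeric vector of CFU counts (all >= 1), or a data frame with
#'   columns `cfu` and optionally `round`.
#' @return Estimated divisions per transfer T (a single number).
#' @export
#' @examples
#' divisions_per_transfer_from_cfu(c(524288)) # 2^19 -> 19
divisions_per_transfer_from_cfu <- function(cfu) {
  if (is.data.frame(cfu)) {
    rounds <- if ("round" %in% names(cfu)) cfu$round else 1L
    per_round <- tapply(cfu$cfu, rounds,
                        divisions_per_transfer_from_cfu)
    return(mean(per_round))
  }
  if (length(cfu) == 0 || any(!is.finite(cfu)) || any(cfu < 1)) {
    stop("CFU values must all be >= 1", call. = FALSE)
  }
  mean(log2(cfu))
}

#' Total cell divisions of an MA line
#'
#' The product of the grand-mean divisions-per-transfer estimate and the
#' number of serial transfers.
#'
#' @param grand_mean_T Divisions per transfer (positive).
#' @param transfers Number of transfers (positive).
#' @return Total divisions.
#' @export
#' @examples
#' total_divisions(19.35, 46) # ~890
total_divisions <- function(grand_mean_T, transfers) {
  stopifnot(grand_mean_T > 0, transfers > 0)
  grand_mean_T * transfers
}

#' Harmonic-mean effective population size of a bottlenecked colony
#'
#' Between single-cell transfers a colony doubles T times through census
#' sizes 1, 2, 4, ..., 2^T; the variance-effective size over that cycle is
#' the harmonic mean, Ne = (T + 1) / sum_{i=0}^{T} 2^{-i}. The geometric
#' sum is evaluated in closed form as 2 - 2^{-T}, which extends the
#' integer-T definition continuously to real T (an average over colonies).
#' Ne approaches (T + 1)/2 for large T.
#'
#' @param T Divisions between transfers (>= 0); vectorized.
#' @return Effective population size Ne.
#' @export
#' @examples
#' effective_population_size(19.35) # ~10.17
effective_population_size <- function(T) {
  if (any(T < 0)) stop("T must be non-negative", call. = FALSE)
  (T + 1) / (2 - 2^(-T))
}
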