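#' Synonymous and nonsynonymous site counts from codon degeneracy
#'
#' For each codon of each in-frame CDS, every position contributes f/3
#' synonymous sites, where f is the number of the three possible
#' single-base changes at that position that leave the encoded amino acid
#' unchanged, and (3 - f)/3 nonsynonymous sites; a codon therefore always
#' contributes exactly 3 sites in total. Changes that create a stop codon
#' count as nonsynonymous by default (set `stop_changes` to `"exclude"` to
#' drop them from both tallies).
#'
#' @param cds_sequences In-frame coding sequences: a character vector or a
#'   `Biostrings::DNAStringSet`. A trailing stop codon, if present, is
#'   ignored; internal stop codons are an error.
#' @param genetic_code Named character vector mapping codons to amino
#'   acids, as `Biostrings::GENETIC_CODE` (the default, the standard
#'   nuclear code).
#' @param stop_changes How single-base changes producing a stop codon are
#'   counted: `"nonsynonymous"` (default) or `"exclude"`.
#' @return A one-row tibble with columns `nonsyn_sites`, `syn_sites`,
#'   `n_codons`.
#' @export
#' @examples
#' count_syn_nonsyn_sites("TTTGGG") # Phe: 1/3 syn; Gly: 1 syn
count_syn_nonsyn_sites <- function(cds_sequences,
                                   genetic_code = Biostrings::GENETIC_CODE,
                                   stop_changes = c("nonsynonymous", "exclude")) {
  stop_changes <- match.arg(stop_changes)
  seqs <- toupper(as.character(cds_sequences))
  bad_len <- nchar(seqs) %% 3 != 0 | nchar(seqs) == 0
  if (any(bad_len)) {
    stop("frame error: CDS length not a positive multiple of 3 for ",
         "sequence(s) ", paste(utils::head(which(bad_len), 5), collapse = ", "),
         call. = FALSE)
  }
  site_table <- codon_site_table(genetic_code, stop_changes)

  codons <- unlist(lapply(seqs, function(s) {
    k <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    # a trailing stop codon is not a mutational-opportunity site
    if (length(k) > 0 && genetic_code[k[length(k)]] %in% "*") {
      k <- k[-length(k)]
    }
    k
  }))
  unknown <- !codons %in% names(genetic_code)
  if (any(unknown)) {
    stop("non-ACGT codon(s): ", paste(unique(codons[unknown]), collapse = ", "),
         call. = FALSE)
  }
  aa <- genetic_code[codons]
  if (any(aa == "*")) {
    stop("internal stop codon at codon index ",
         paste(utils::head(which(aa == "*"), 5), collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    nonsyn_sites = sum(site_table[codons, "nonsyn"]),
    syn_sites = sum(site_table[codons, "syn"]),
    n_codons = length(codons)
  )
}

#' Per-codon degeneracy site contributions
#'
#' Enumerates, for every sense codon, its synonymous and nonsynonymous
#' site contributions under the degeneracy-fraction definition (each
#' position contributes syn-fraction f/3 where f of its 3 single-base
#' changes are synonymous).
#'
#' @inheritParams count_syn_nonsyn_sites
#' @return A numeric matrix with one row per sense codon and columns
#'   `syn` and `nonsyn` (rows sum to 3 when `stop_changes` is
#'   `"nonsynonymous"`).
#' @export
codon_site_table <- function(genetic_code = Biostrings::GENETIC_CODE,
                             stop_changes = c("nonsynonymous", "exclude")) {
  stop_changes <- match.arg(stop_changes)
  bases <- c("A", "C", "G", "T")
  sense <- names(genetic_code)[genetic_code != "*"]
  out <- matrix(0, nrow = length(sense), ncol = 2,
                dimnames = list(sense, c("syn", "nonsyn")))
  for (codon in sense) {
    aa <- genetic_code[[codon]]
    for (pos in 1:3) {
      for (b in setdiff(bases, substr(codon, pos, pos))) {
        mutant <- codon
        substr(mutant, pos, pos) <- b
        maa <- genetic_code[[mutant]]
        if (maa == "*" && stop_changes == "exclude") next
        cell <- if (maa == aa) "syn" else "nonsyn"
        out[codon, cell] <- out[codon, cell] + 1 / 3
      }
    }
  }
  out
}
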