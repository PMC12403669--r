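#' Read a curated mutation table
#'
#' Reads a tab-separated mutation list with mandatory columns `line_id`,
#' `contig`, `position`, `ref`, `alt` and optional columns `class` (whose
#' `"SV"` entries mark imported structural-variant calls) and
#' `coding_effect` (`nonsynonymous`, `synonymous` or `noncoding`). Any
#' further columns are preserved as annotations. Records are validated,
#' classified with [classify_mutation()] and returned in deterministic
#' (contig, position, line_id) order.
#'
#' @param path Path to a TSV file with a header row; positions are 1-based.
#' @return A tibble of mutation records with `mclass` and `bps_subclass`
#'   columns appended.
#' @seealso [write_mutation_table()], [read_vcf_minimal()]
#' @export
read_mutation_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  mandatory <- c("line_id", "contig", "position", "ref", "alt")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0) {
    stop("mutation table schema error: missing mandatory column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  pos <- suppressWarnings(as.numeric(raw$position))
  bad_pos <- is.na(pos) | pos < 1 | pos != floor(pos)
  if (any(bad_pos)) {
    stop("unparseable position in row(s) ",
         paste(utils::head(which(bad_pos), 5L), collapse = ", "),
         " of ", path, call. = FALSE)
  }
  raw$position <- as.integer(pos)
  out <- tryCatch(
    classify_mutations(raw),
    error = function(e) {
      stop("invalid mutation record while reading ", path, ": ",
           conditionMessage(e), call. = FALSE)
    }
  )
  if ("coding_effect" %in% names(out)) {
    known <- c("nonsynonymous", "synonymous", "noncoding")
    bad <- !is.na(out$coding_effect) & !out$coding_effect %in% known
    if (any(bad)) {
      stop("unknown coding_effect value(s): ",
           paste(unique(out$coding_effect[bad]), collapse = ", "), call. = FALSE)
    }
  }
  dplyr::arrange(out, .data$contig, .data$position, .data$line_id)
}

#' Write a mutation table
#'
#' Writes the TSV dialect read by [read_mutation_table()]. The derived
#' `mclass`/`bps_subclass` columns are written as text so a write/read
#' round trip is the identity on valid tables.
#'
#' @param mutations A mutation tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(mutations, path) {
  out <- dplyr::mutate(
    tibble::as_tibble(mutations),
    dplyr::across(dplyr::where(is.factor), as.character)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read per-line MA metadata
#'
#' Reads a TSV with columns `line_id`, `group`, `transfers`,
#' `divisions_per_transfer` and `callable_sites`. `total_divisions` is
#' computed as `divisions_per_transfer * transfers` when absent and checked
#' for consistency when present.
#'
#' @param path Path to the metadata TSV.
#' @return A tibble of MA-line records.
#' @export
read_line_metadata <- function(path) {
  meta <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  mandatory <- c("line_id", "group", "transfers", "divisions_per_transfer")
  missing_cols <- setdiff(mandatory, names(meta))
  if (length(missing_cols) > 0) {
    stop("metadata schema error: missing mandatory column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  meta <- tibble::as_tibble(meta)
  derived <- meta$divisions_per_transfer * meta$transfers
  if (!"total_divisions" %in% names(meta)) {
    meta$total_divisions <- derived
  } else {
    off <- abs(meta$total_divisions - derived) >
      1e-9 * pmax(1, abs(derived))
    if (any(off, na.rm = TRUE)) {
      stop("total_divisions inconsistent with transfers x divisions_per_transfer ",
           "for line(s) ", paste(meta$line_id[which(off)], collapse = ", "),
           call. = FALSE)
    }
  }
  bad <- meta$transfers <= 0 | meta$divisions_per_transfer <= 0
  if ("callable_sites" %in% names(meta)) {
    bad <- bad | (!is.na(meta$callable_sites) & meta$callable_sites <= 0)
  }
  if (any(bad, na.rm = TRUE)) {
    stop("non-positive line quantity for line(s) ",
         paste(meta$line_id[which(bad)], collapse = ", "), call. = FALSE)
  }
  meta
}

#' Minimal VCF ingestion
#'
#' Converts a VCF 4.x file of curated calls into mutation records using the
#' same classification rules as [read_mutation_table()]. Multi-allelic
#' records are split into one record per ALT allele; rows whose FILTER
#' field is neither `PASS` nor `.` are skipped and counted.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF file.
#' @param line_id Line identifier to assign to the records (a VCF per MA
#'   line genome is the expected layout); defaults to the file name.
#' @return A tibble of mutation records; the number of FILTER-skipped rows
#'   is available as `attr(x, "skipped")`.
#' @export
read_vcf_minimal <- function(path, line_id = NULL) {
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (is.null(line_id)) line_id <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  keep <- is.na(fix$FILTER) | fix$FILTER %in% c("PASS", ".")
  skipped <- sum(!keep)
  fix <- fix[keep, , drop = FALSE]
  rec <- tibble::tibble(
    line_id = line_id,
    contig = fix$CHROM,
    position = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT
  )
  rec <- tidyr::separate_rows(rec, "alt", sep = ",")
  rec <- rec[rec$alt != "*", , drop = FALSE]
  out <- if (nrow(rec) > 0) classify_mutations(rec) else {
    tibble::add_column(rec,
                       mclass = factor(character(), levels = mutation_classes()),
                       bps_subclass = factor(character(), levels = bps_classes()))
  }
  out <- dplyr::arrange(out, .data$contig, .data$position, .data$line_id)
  attr(out, "skipped") <- skipped
  out
}

#' Genome base and coding-site composition
#'
#' A one-row tibble holding the A/T vs G/C site counts (and optionally the
#' nonsynonymous/synonymous site totals) used to condition mutation
#' spectra and selection tests on genome composition.
#'
#' @param at_sites,gc_sites Counts of unambiguous A/T and G/C bases.
#' @param genome_length Total unambiguous length; defaults to their sum.
#' @param nonsyn_sites,syn_sites Optional coding-site totals (real-valued,
#'   from codon degeneracy fractions).
#' @param ambiguous Count of ambiguous (non-ACGT) bases, tallied separately.
#' @return A tibble of class `genome_composition`.
#' @export
#' @examples
#' genome_composition(at_sites = 8e6, gc_sites = 4.5e6,
#'                    nonsyn_sites = 6074090, syn_sites = 1641376)
genome_composition <- function(at_sites, gc_sites,
                               genome_length = at_sites + gc_sites,
                               nonsyn_sites = NA_real_, syn_sites = NA_real_,
                               ambiguous = genome_length - at_sites - gc_sites) {
  stopifnot(at_sites >= 0, gc_sites >= 0,
            at_sites + gc_sites <= genome_length)
  if (!is.na(nonsyn_sites) && !is.na(syn_sites)) {
    stopifnot(nonsyn_sites >= 0, syn_sites >= 0,
              nonsyn_sites + syn_sites <= genome_length)
  }
  out <- tibble::tibble(
    at_sites = at_sites, gc_sites = gc_sites,
    ambiguous = ambiguous, genome_length = genome_length,
    nonsyn_sites = nonsyn_sites, syn_sites = syn_sites
  )
  class(out) <- c("genome_composition", class(out))
  out
}

#' Scan a genome FASTA for base composition
#'
#' Counts A/T and G/C sites over all sequences, case-insensitively.
#' Ambiguous bases (N and other IUPAC codes) are excluded from the A/T and
#' G/C counts and tallied in the `ambiguous` column.
#'
#' @param fasta A FASTA file path or a `Biostrings::DNAStringSet`.
#' @return A [genome_composition()] tibble (A/T-G/C fields only).
#' @export
scan_genome_composition <- function(fasta) {
  seqs <- if (inherits(fasta, "DNAStringSet")) {
    fasta
  } else {
    Biostrings::readDNAStringSet(fasta)
  }
  if (length(seqs) == 0 || sum(Biostrings::width(seqs)) == 0) {
    stop("empty FASTA: no sequence data in input", call. = FALSE)
  }
  freq <- colSums(Biostrings::letterFrequency(seqs, c("A", "C", "G", "T")))
  total <- sum(Biostrings::width(seqs))
  at <- unname(freq["A"] + freq["T"])
  gc <- unname(freq["C"] + freq["G"])
  genome_composition(at_sites = at, gc_sites = gc, genome_length = total,
                     ambiguous = total - at - gc)
}
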