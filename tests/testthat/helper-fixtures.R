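# Study constants used across tests: a two-group fission-yeast MA design
# with printed exposures, counts and site totals.
G1 <- 5.02822e11
G2 <- 5.37022e11
NONSYN_SITES <- 6074090
SYN_SITES <- 1641376
GENOME_LENGTH <- 12521788

study_composition <- function() {
  gc <- round(0.3606 * GENOME_LENGTH)
  genome_composition(
    at_sites = GENOME_LENGTH - gc, gc_sites = gc,
    genome_length = GENOME_LENGTH,
    nonsyn_sites = NONSYN_SITES, syn_sites = SYN_SITES
  )
}

# Build one group's mutation tibble realizing exact class/spectrum/coding
# totals, spread round-robin over the group's lines.
make_group_mutations <- function(line_ids, spectrum, n_ins, n_del, n_sv,
                                 n_nonsyn, n_syn) {
  alleles <- list(
    "A:T>G:C" = c("A", "G"), "A:T>T:A" = c("A", "T"),
    "A:T>C:G" = c("A", "C"), "G:C>A:T" = c("C", "T"),
    "G:C>T:A" = c("C", "A"), "G:C>C:G" = c("C", "G")
  )
  ref <- character(0); alt <- character(0); cls <- character(0)
  for (k in names(spectrum)) {
    n <- spectrum[[k]]
    ref <- c(ref, rep(alleles[[k]][1], n))
    alt <- c(alt, rep(alleles[[k]][2], n))
    cls <- c(cls, rep("BPS", n))
  }
  n_bps <- length(ref)
  ref <- c(ref, rep("A", n_ins), rep("ACT", n_del),
           rep(paste(rep("A", 61), collapse = ""), n_sv))
  alt <- c(alt, rep("ATG", n_ins), rep("A", n_del), rep("A", n_sv))
  cls <- c(cls, rep("INSERTION", n_ins), rep("DELETION", n_del),
           rep("SV", n_sv))
  n <- length(ref)
  coding <- rep(NA_character_, n)
  coding[seq_len(n_bps)] <- c(rep("nonsynonymous", n_nonsyn),
                              rep("synonymous", n_syn),
                              rep("noncoding", n_bps - n_nonsyn - n_syn))
  classify_mutations(tibble::tibble(
    line_id = rep_len(line_ids, n),
    contig = "contig_1",
    position = seq_len(n) * 1000L,
    ref = ref, alt = alt, class = cls, coding_effect = coding
  ))
}

# The two-group experiment with the study's printed totals entered as a
# pre-curated input: 18/24 BPS (ts/tv 2.00 and 1.67), 21+3 / 28+2 indels,
# 6/13 SVs, 5/4 and 11/2 coding substitutions, exposures ~g1 and ~g2.
study_counts_experiment <- function() {
  lines <- dplyr::bind_rows(
    tibble::tibble(
      line_id = sprintf("C_%02d", 1:46), group = "control",
      transfers = 46, divisions_per_transfer = 890 / 46,
      total_divisions = 890,
      callable_sites = round(G1 / (46 * 890))
    ),
    tibble::tibble(
      line_id = sprintf("T_%02d", 1:48), group = "treatment",
      transfers = 46, divisions_per_transfer = 911 / 46,
      total_divisions = 911,
      callable_sites = round(G2 / (48 * 911))
    )
  )
  control <- make_group_mutations(
    sprintf("C_%02d", 1:46),
    spectrum = c("G:C>A:T" = 9, "A:T>G:C" = 3, "G:C>T:A" = 2,
                 "A:T>T:A" = 2, "A:T>C:G" = 1, "G:C>C:G" = 1),
    n_ins = 21, n_del = 3, n_sv = 6, n_nonsyn = 5, n_syn = 4
  )
  treatment <- make_group_mutations(
    sprintf("T_%02d", 1:48),
    spectrum = c("G:C>A:T" = 11, "A:T>G:C" = 4, "G:C>T:A" = 4,
                 "A:T>T:A" = 2, "A:T>C:G" = 2, "G:C>C:G" = 1),
    n_ins = 28, n_del = 2, n_sv = 13, n_nonsyn = 11, n_syn = 2
  )
  list(mutations = dplyr::bind_rows(control, treatment), lines = lines,
       composition = study_composition())
}

write_minimal_vcf <- function(path, rows) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=contig_1>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  writeLines(c(header, rows), path)
  path
}
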