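# Full synthetic host-assignment scenario: one function wires every module
# together on generated data with known truth. Used by the examples, the
# end-to-end tests and the acceptance script.

# i.i.d. random genome at a target AT content (internal helper)
random_genome <- function(length, at_percent, seed, id = "random_genome") {
  p <- at_percent / 100
  with_rng_seed(seed, {
    s <- sample(c("A", "T", "C", "G"), length, replace = TRUE,
                prob = c(p / 2, p / 2, (1 - p) / 2, (1 - p) / 2))
    nuc_sequence(paste(s, collapse = ""), id = id)
  })
}

#' Run a full synthetic host-assignment scenario
#'
#' Builds a complete virus-plus-host world with known ground truth and runs
#' the whole pipeline on it:
#'
#' 1. Two candidate host mitochondria (insect-like and fungal-like codon
#'    usage, [mito_codon_profile()]), each as a coding-sequence set.
#' 2. A viral genome generated to match the chosen host's compositional
#'    signature ([gen_viral_genome()] with the host family's base weights).
#' 3. A small-RNA library with the host-appropriate signature
#'    ([gen_srna_reads()]), mapped, profiled and classified.
#' 4. RNA-library abundance records and a DNA library without an integrated
#'    viral copy, giving the exogenous EVE status.
#' 5. [integrate_evidence()] over all of it.
#'
#' Scenario constants (host AT contents, virus AT and UGA targets, library
#' sizes) are part of the stated synthetic world; see the package vignette.
#'
#' @param host `"insect"` or `"fungal"`: the true host of the virus.
#' @param seed Integer seed; every generator derives its stream from it.
#' @param n_srna_reads Small-RNA library size.
#' @param n_dna_reads DNA library size.
#' @param integrated Plant an integrated viral copy in the DNA library
#'   (default FALSE, the exogenous-virus world).
#' @return List with `report` (the [integrate_evidence()] result), `virus`
#'   (genome + truth), `srna_class`, `profile`, `candidates`, `eve_status`,
#'   `abundance`.
#' @export
synthetic_host_scenario <- function(host = c("insect", "fungal"), seed = 1,
                                    n_srna_reads = 10000L,
                                    n_dna_reads = 5000L,
                                    integrated = FALSE) {
  host <- match.arg(host)
  seed <- as.integer(seed)
  insect <- mito_codon_profile("insect")
  fungal <- mito_codon_profile("fungal")

  insect_cds <- gen_cds_set(insect$codon_probs, 20000L, seed = seed + 11L,
                            code = insect$code, source = "insect_mito")
  fungal_cds <- gen_cds_set(fungal$codon_probs, 20000L, seed = seed + 12L,
                            code = fungal$code, source = "fungal_mito")
  candidates <- list(
    host_signatures("insect_mito", "insect_mito", insect_cds),
    host_signatures("fungal_mito", "fungal_mito", fungal_cds))

  # virus tuned to the true host's compositional world
  vs_par <- if (host == "insect") {
    list(code_id = 5, at_target = 77, trp_uga_frac = 97,
         weights = insect$base_weights, preset = "siRNA_insect")
  } else {
    list(code_id = 4, at_target = 69, trp_uga_frac = 80,
         weights = fungal$base_weights, preset = "fungal_siRNA")
  }
  vg <- gen_viral_genome(orf_codons = 500, code_id = vs_par$code_id,
                         at_target = vs_par$at_target,
                         trp_uga_frac = vs_par$trp_uga_frac,
                         seed = seed + 21L, base_weights = vs_par$weights)
  virus <- virus_signatures(vg$seq, genetic_code(vs_par$code_id))

  # small-RNA evidence
  reads <- gen_srna_reads(vg$seq, vs_par$preset, n_reads = n_srna_reads,
                          seed = seed + 31L)
  aln <- map_reads(reads, vg$seq, max_mm = 1L)
  profile <- size_profile(aln)
  enr <- five_prime_enrichment(aln, vg$seq)
  srna_class <- classify_signature(profile, enr)

  # abundance across three synthetic RNA libraries (virus present in all)
  abundance <- lapply(1:3, function(i) {
    rpm_abundance(mapped = nrow(aln), total = n_srna_reads * 10,
                  library_id = paste0("rna_lib", i), ref_id = vg$seq$id)
  })

  # DNA library: host mitochondrial genome as positive control
  host_mito <- random_genome(12000L, at_percent = if (host == "insect") 78 else 70,
                             seed = seed + 41L, id = paste0(host, "_mito_genome"))
  dna <- gen_dna_library(host_mito, vg$seq, integrated = integrated,
                         n_reads = n_dna_reads, seed = seed + 42L)
  dna_virus <- map_reads(dna, vg$seq, max_mm = 1L)
  dna_ctrl <- map_reads(dna, host_mito, max_mm = 1L)
  eve <- eve_call(
    dna_virus_rpm = rpm_abundance(nrow(dna_virus), n_dna_reads)$rpm,
    dna_control_rpm = rpm_abundance(nrow(dna_ctrl), n_dna_reads)$rpm,
    rna_virus_rpm = abundance[[1]]$rpm)

  report <- integrate_evidence(virus, candidates, srna_class = srna_class,
                               abundance = abundance, eve_status = eve)
  list(report = report, virus = vg, virus_signatures = virus,
       srna_class = srna_class, profile = profile, candidates = candidates,
       eve_status = eve, abundance = abundance)
}
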