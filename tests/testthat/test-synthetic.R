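test_that("gen_viral_genome honors its contract and recounts truth", {
  g <- gen_viral_genome(orf_codons = 804, code_id = 5, at_target = 69.74,
                        trp_uga_frac = 73.3, seed = 1)
  expect_equal(g$truth$genome_length, 2697L)
  expect_lte(abs(g$truth$at_content - 69.74), 2)
  expect_equal(g$truth$trp_uga_fraction, 73.3, tolerance = 0.1)
  # truth matches a full re-measurement of the emitted sequence
  expect_equal(base_composition(g$seq)$AT_percent, g$truth$at_content)
  top <- find_orfs(g$seq, genetic_code(5), min_codons = 100)[1, ]
  expect_equal(c(top$start, top$end), g$truth$orf_span)
  expect_equal(top$aa_length, 804L)
  # determinism: same seed, byte-identical output
  g2 <- gen_viral_genome(orf_codons = 804, code_id = 5, at_target = 69.74,
                         trp_uga_frac = 73.3, seed = 1)
  expect_identical(g$seq$residues, g2$seq$residues)
  g3 <- gen_viral_genome(orf_codons = 804, code_id = 5, at_target = 69.74,
                         trp_uga_frac = 73.3, seed = 2)
  expect_false(identical(g$seq$residues, g3$seq$residues))
})

test_that("trp_uga_frac = 0 yields a standard-code-readable ORF", {
  g <- gen_viral_genome(orf_codons = 200, code_id = 1, at_target = 55,
                        trp_uga_frac = 0, seed = 4)
  orfs <- find_orfs(g$seq, genetic_code(1), min_codons = 100)
  expect_equal(orfs$aa_length[1], 200L)
  expect_false(grepl("\\*", orfs$protein[1]))
})

test_that("infeasible genome requests fail loudly", {
  # TGA is a stop under tables 1 and 16: UGA(Trp) impossible
  expect_error(gen_viral_genome(orf_codons = 100, code_id = 16,
                                trp_uga_frac = 50, seed = 1), "infeasible")
  # unreachable AT target
  expect_error(gen_viral_genome(orf_codons = 100, at_target = 1, seed = 1),
               "infeasible")
  expect_error(gen_viral_genome(orf_codons = 100, at_target = 99.9, seed = 1),
               "infeasible")
})

test_that("gen_cds_set validates stops and handles the empty case", {
  code <- genetic_code(5)
  all64 <- names(code$codon_to_aa)
  p <- setNames(rep(0, 64), all64); p[["ATG"]] <- 1
  expect_equal(gen_cds_set(p, 10, seed = 1)$cds, strrep("ATG", 10))
  # nonzero stop probability is an error
  pbad <- setNames(rep(0, 64), all64); pbad[["ATG"]] <- 0.9; pbad[["TAA"]] <- 0.1
  expect_error(gen_cds_set(pbad, 10, seed = 1), "stop")
  # n = 0: empty set; downstream ops refuse it
  empty <- gen_cds_set(p, 0, seed = 1)
  expect_equal(nrow(empty), 0L)
  expect_error(codon_usage(empty), "empty")
  expect_error(trp_codon_stats(empty), "empty")
})

test_that("small-RNA reads are exact substrings with the requested geometry", {
  ref <- gen_viral_genome(orf_codons = 300, at_target = 65, trp_uga_frac = 70,
                          seed = 41)$seq
  rs <- gen_srna_reads(ref, "siRNA_insect", 800, seed = 5)
  truth <- attr(rs, "truth")$reads
  rc <- revcomp(ref)
  L <- nchar(ref$residues)
  for (i in seq_len(200)) { # spot-check a subset for speed
    if (truth$strand[i] == "+") {
      expect_equal(rs$seq[i], substr(ref$residues, truth$start[i] + 1,
                                     truth$start[i] + truth$size[i]))
    } else {
      st <- L - (truth$start[i] + truth$size[i])
      expect_equal(rs$seq[i], substr(rc, st + 1, st + truth$size[i]))
    }
  }
  expect_true(all(truth$size >= 15 & truth$size <= 35))
  # strand_ratio 1: no antisense reads
  rs1 <- gen_srna_reads(ref, list(peak_size = 21, size_sd = 1,
                                  strand_ratio = 1, five_prime_bias = NA),
                        300, seed = 6)
  expect_true(all(attr(rs1, "truth")$reads$strand == "+"))
  # determinism
  rs2 <- gen_srna_reads(ref, "siRNA_insect", 800, seed = 5)
  expect_identical(rs$seq, rs2$seq)
  # short reference is refused
  expect_error(gen_srna_reads(nuc_sequence(strrep("A", 30)), "piRNA", 10, 1),
               "shorter")
})

test_that("5'-U bias raises the U-start fraction to b + (1-b) f_U", {
  ref <- gen_viral_genome(orf_codons = 300, at_target = 65, trp_uga_frac = 70,
                          seed = 43)$seq
  b <- 0.9
  rs <- gen_srna_reads(ref, list(peak_size = 27, size_sd = 1.8,
                                 strand_ratio = 0.85, five_prime_bias = b),
                       4000, seed = 7)
  u_frac <- mean(substr(rs$seq, 1, 1) == "T")
  f_u <- base_composition(ref)$base_fractions[["T"]]
  f_u_minus <- base_composition(ref)$base_fractions[["A"]]
  lo <- b + (1 - b) * min(f_u, f_u_minus) - 0.03
  expect_gte(u_frac, lo)
})

test_that("long reads tile at the requested depth and error rate", {
  ref <- gen_viral_genome(orf_codons = 300, at_target = 60, trp_uga_frac = 50,
                          seed = 47)$seq
  rs <- gen_long_reads(ref, coverage = 20, read_len = 75, err_rate = 0, seed = 8)
  L <- nchar(ref$residues)
  expect_equal(nrow(rs) * 75 / L, 20, tolerance = 0.05)
  # error-free reads are exact substrings (sense or antisense)
  truth <- attr(rs, "truth")
  for (i in 1:50) {
    sub <- substr(ref$residues, truth$start[i] + 1, truth$start[i] + 75)
    expect_equal(rs$seq[i], if (truth$strand[i] == "+") sub else revcomp(sub))
  }
  # substitution errors appear at the requested rate
  rs_err <- gen_long_reads(ref, coverage = 20, read_len = 75, err_rate = 0.01,
                           seed = 9)
  expect_equal(mean(attr(rs_err, "truth")$n_errors) / 75, 0.01, tolerance = 0.4)
  expect_identical(gen_long_reads(ref, 20, 75, 0, seed = 8)$seq, rs$seq)
})

test_that("DNA libraries contain viral reads only when integrated", {
  host <- gen_viral_genome(orf_codons = 500, at_target = 75, trp_uga_frac = 90,
                           seed = 51)$seq
  virus <- gen_viral_genome(orf_codons = 300, at_target = 65, trp_uga_frac = 70,
                            seed = 52)$seq
  lib0 <- gen_dna_library(host, virus, integrated = FALSE, n_reads = 500,
                          seed = 10)
  expect_true(all(attr(lib0, "truth")$origin == "host"))
  lib1 <- gen_dna_library(host, virus, integrated = TRUE, n_reads = 2000,
                          seed = 11, viral_fraction = 0.05)
  frac <- mean(attr(lib1, "truth")$origin == "virus")
  expect_gt(frac, 0.02); expect_lt(frac, 0.09)
  expect_error(gen_dna_library(host, virus, FALSE, 0, 1), "n_reads")
})

test_that("truth sidecars serialize to TSV", {
  g <- gen_viral_genome(orf_codons = 60, at_target = 60, trp_uga_frac = 50,
                        seed = 3, flank5 = 12, flank3 = 12)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth_tsv(g$truth, path)
  tab <- read.table(path, sep = "\t", header = TRUE)
  expect_true("genome_length" %in% tab$field)
})
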