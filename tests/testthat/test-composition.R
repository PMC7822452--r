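test_that("dinucleotide odds ratios match the brute-force oracle", {
  # degenerate: homopolymer has odds(AA) = 1 exactly
  p <- dinucleotide_odds(nuc_sequence(strrep("A", 1000)))
  expect_equal(p[["AA"]], 1)
  # fixed 200-nt string and random strings vs the sliding-window oracle
  set.seed(42)
  for (i in 1:20) {
    s <- rand_dna(200, probs = runif(4, 0.1, 0.4) / sum(runif(4, 0.1, 0.4)))
    mine <- dinucleotide_odds(nuc_sequence(s, id = "x"))
    expect_equal(unclass(mine)[sort(names(mine))],
                 oracle_dinuc_odds(s)[sort(names(mine))],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("dinucleotide odds converge to 1 on i.i.d. sequence", {
  set.seed(11)
  s <- rand_dna(100000)
  p <- dinucleotide_odds(nuc_sequence(s, id = "iid"))
  expect_true(all(p >= 0.95 & p <= 1.05))
})

test_that("dinucleotide bias classification uses a closed unbiased interval", {
  fake <- structure(setNames(rep(1, 16), names(dinucleotide_odds(
    nuc_sequence(strrep("ACGT", 50))))), class = "dinucleotide_profile")
  fake[1:4] <- c(1.0, 0.78, 1.25, 0.779)
  cls <- classify_dinucleotide_bias(fake)
  expect_equal(unname(cls[1:4]),
               c("unbiased", "unbiased", "unbiased", "biased"))
  # construction truth: a CC/GG-enriched genome flags CC and GG
  set.seed(13)
  s <- paste(sample(c("CC", "GG", "AT", "TA", "AC", "GT"), 3000,
                    replace = TRUE, prob = c(0.3, 0.3, 0.1, 0.1, 0.1, 0.1)),
             collapse = "")
  cls2 <- classify_dinucleotide_bias(dinucleotide_odds(nuc_sequence(s, id = "cc")))
  expect_equal(unname(cls2[c("CC", "GG")]), c("biased", "biased"))
})

test_that("codon usage counts, per-1000 and synonymous fractions are exact", {
  cu <- codon_usage(cds_set("ATGATGTAA", code_id = 1))
  expect_equal(cu$count[cu$codon == "ATG"], 2L)
  expect_equal(cu$count[cu$codon == "TAA"], 1L)
  expect_equal(cu$per_1000[cu$codon == "ATG"], 2000 / 3, tolerance = 1e-9)
  expect_equal(sum(cu$per_1000), 1000)
  expect_equal(cu$syn_fraction[cu$codon == "ATG"], 1)
  expect_error(codon_usage(cds_set()), "empty")
})

test_that("codon usage per-1000 sums to 1000 for arbitrary CDS sets", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(30:300, 1)
    cds <- vapply(1:3, function(j) rand_dna(3 * n), character(1))
    cu <- codon_usage(cds_set(cds, code_id = 5))
    expect_equal(sum(cu$per_1000), 1000, tolerance = 0.5)
    # synonymous fractions sum to 1 within each observed family
    fam <- split(cu, cu$aa)
    for (f in fam) {
      if (sum(f$count) > 0) expect_equal(sum(f$syn_fraction), 1, tolerance = 1e-9)
    }
  }
})

test_that("generated codon frequencies converge to the generator's table", {
  code <- genetic_code(5)
  all64 <- names(code$codon_to_aa)
  # all mass on ATG
  p1 <- setNames(rep(0, 64), all64); p1[["ATG"]] <- 1
  cu1 <- codon_usage(gen_cds_set(p1, 100, seed = 1))
  expect_equal(cu1$per_1000[cu1$codon == "ATG"], 1000)
  # uniform over the 62 sense codons of table 5, n = 62000: each within 3 s.e.
  sense <- setdiff(all64, code$stop_codons)
  p2 <- setNames(rep(0, 64), all64); p2[sense] <- 1 / length(sense)
  n <- 1000 * length(sense)
  cu2 <- codon_usage(gen_cds_set(p2, n, seed = 7))
  se <- sqrt((1 / 62) * (1 - 1 / 62) / n) * 1000
  expect_true(all(abs(cu2$per_1000[cu2$codon %in% sense] - 1000 / 62) <= 3 * se + 1e-9))
  expect_true(all(cu2$per_1000[!cu2$codon %in% sense] == 0))
})

test_that("UGA(Trp) statistics follow the terminal-stop curation rule", {
  # internal TGA x3 and TGG x1 -> 75%
  cds <- cds_set(paste0("ATG", "TGA", "TGA", "TGA", "TGG", "TAA"), code_id = 5)
  st <- trp_codon_stats(cds, genetic_code(5))
  expect_equal(st$uga_count, 3L)
  expect_equal(st$ugg_count, 1L)
  expect_equal(st$uga_trp_percent, 75)
  # a CDS whose only TGA is terminal: counted as stop, not Trp
  st2 <- trp_codon_stats(cds_set("ATGGCTTGA", code_id = 5), genetic_code(5))
  expect_equal(st2$uga_count, 0L)
  expect_equal(st2$terminal_uga_count, 1L)
  expect_true(is.na(st2$uga_trp_percent))
  # standard code requires explicit opt-in
  expect_error(trp_codon_stats(cds, genetic_code(1)), "allow_standard")
  expect_silent(trp_codon_stats(cds, genetic_code(1), allow_standard = TRUE))
})

test_that("UGA(Trp) fraction of generated genomes recovers the target", {
  for (frac in c(0, 50, 73.3, 100)) {
    g <- gen_viral_genome(orf_codons = 804, at_target = 68,
                          trp_uga_frac = frac, seed = 31)
    # 15 Trp codons -> discretization grid of 1/15
    expect_equal(g$truth$trp_uga_fraction, frac, tolerance = 100 / 15 / 2 + 1e-9)
    orf_cds <- cds_set(substr(g$seq$residues, g$truth$orf_span[1] + 1,
                              g$truth$orf_span[2]), code_id = 5)
    st <- trp_codon_stats(orf_cds, genetic_code(5))
    expect_equal(st$uga_trp_percent, g$truth$trp_uga_fraction)
  }
})

test_that("profile correlation matches the closed-form Pearson oracle", {
  v1 <- c(1, 2, 3, 4, 5); v2 <- c(2, 1, 4, 3, 6); v3 <- c(-1, -2, -3, -4, -5)
  r <- profile_correlation(list(a = v1, b = v2, c = v3))
  expect_equal(r["a", "a"], 1)
  expect_equal(r["a", "c"], -1)
  expect_equal(r["a", "b"], oracle_pearson(v1, v2))
  expect_equal(r["b", "c"], oracle_pearson(v2, v3))
  expect_equal(r, t(r))
  # zero-variance profile yields NA correlations
  rz <- profile_correlation(list(a = v1, z = rep(2, 5)))
  expect_true(is.na(rz["a", "z"]))
})

test_that("correlation clustering enforces the all-pairs threshold", {
  base <- c(1, 5, 2, 8, 3, 9, 4, 7, 6, 2)
  prof <- list(a = base, b = base + 0.01, c = rev(base))
  cl <- cluster_by_correlation(profile_correlation(prof), threshold = 0.8)
  expect_equal(cl$cluster[["a"]], cl$cluster[["b"]])
  expect_true(is.na(cl$cluster[["c"]]))
  # a pair at exactly r = 0.79 is not clustered at 0.8
  vr <- vectors_with_r(0.79)
  cl2 <- cluster_by_correlation(profile_correlation(list(p = vr$x, q = vr$y)),
                                threshold = 0.8)
  expect_true(all(is.na(cl2$cluster)))
  vr3 <- vectors_with_r(0.81)
  cl3 <- cluster_by_correlation(profile_correlation(list(p = vr3$x, q = vr3$y)),
                                threshold = 0.8)
  expect_equal(unname(cl3$cluster), c(1L, 1L))
})

test_that("clustering recovers the two synthetic mitochondrial families", {
  mk <- function(family, i) {
    p <- mito_codon_profile(family, jitter_sd = 0.15, seed = 100 * i)
    cu <- codon_usage(gen_cds_set(p$codon_probs, 8000, seed = 100 * i + 1,
                                  code = p$code))
    setNames(cu$per_1000, cu$codon)
  }
  prof <- c(setNames(lapply(1:3, function(i) mk("insect", i)), paste0("ins", 1:3)),
            setNames(lapply(1:3, function(i) mk("fungal", i + 10)), paste0("fun", 1:3)))
  cl <- cluster_by_correlation(profile_correlation(prof), threshold = 0.8)
  expect_equal(length(unique(cl$cluster)), 2L)
  expect_equal(length(unique(cl$cluster[paste0("ins", 1:3)])), 1L)
  expect_equal(length(unique(cl$cluster[paste0("fun", 1:3)])), 1L)
  expect_false(cl$cluster[["ins1"]] == cl$cluster[["fun1"]])
  # order invariance
  cl2 <- cluster_by_correlation(profile_correlation(rev(prof)), threshold = 0.8)
  expect_equal(cl$cluster[sort(names(cl$cluster))],
               cl2$cluster[sort(names(cl2$cluster))])
})
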