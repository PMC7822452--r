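ref_for_tests <- function(seed = 77, orf = 400) {
  gen_viral_genome(orf_codons = orf, at_target = 68, trp_uga_frac = 70,
                   seed = seed)$seq
}

test_that("read filtering applies the length and quality rule", {
  q <- function(phred, n) strrep(intToUtf8(phred + 33), n)
  reads <- read_set(
    seq = c(strrep("A", 25), strrep("A", 19), strrep("A", 30), strrep("A", 30)),
    id = paste0("r", 1:4),
    qual = c(q(30, 25),                       # kept
             q(40, 19),                       # too short
             paste0(q(30, 21), q(10, 9)),     # 21/30 = 70% good -> discarded
             paste0(q(30, 24), q(10, 6))))    # 24/30 = 80% good -> kept
  out <- filter_reads(reads)
  expect_equal(out$id, c("r1", "r4"))
})

test_that("FASTQ round-trip and malformed-record diagnostics", {
  path <- withr::local_tempfile(fileext = ".fastq")
  rs <- read_set(c("ACGTACGTACGTACGTACGTA", "TTTTACGTACGTACGTACGT"))
  write_fastq(rs, path)
  back <- read_fastq(path)
  expect_equal(back$seq, rs$seq)
  writeLines(c("@r1", "ACGT", "+", "III"), path) # quality too short
  expect_error(read_fastq(path), "record 1")
})

test_that("map_reads agrees with the quadratic oracle", {
  set.seed(55)
  ref <- rand_dna(500)
  refseq <- nuc_sequence(ref, id = "ref")
  mutate1 <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    at <- sample(length(ch), k)
    for (j in at) ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1)
    paste(ch, collapse = "")
  }
  reads <- character(0)
  for (i in 1:40) {
    st <- sample(0:(500 - 22), 1)
    r <- substr(ref, st + 1, st + 22)
    r <- mutate1(r, sample(0:2, 1))              # 0-2 substitutions
    if (runif(1) < 0.5) r <- revcomp(r)
    reads <- c(reads, r)
  }
  reads <- c(reads, rand_dna(22))                # likely unmappable
  aln <- map_reads(read_set(reads, id = paste0("r", seq_along(reads))),
                   refseq, max_mm = 1)
  for (i in seq_along(reads)) {
    oracle <- oracle_map_read(ref, reads[i], max_mm = 1)
    row <- aln[aln$read_id == paste0("r", i), ]
    if (is.null(oracle)) {
      expect_equal(nrow(row), 0L)
    } else {
      expect_equal(nrow(row), 1L)
      expect_equal(row$start, oracle$start)
      expect_equal(row$strand, oracle$strand)
      expect_equal(row$mismatches, oracle$mm)
    }
  }
})

test_that("map_reads is exact on generator reads and rejects 2-mismatch reads", {
  ref <- ref_for_tests()
  rs <- gen_srna_reads(ref, "siRNA_insect", n_reads = 1000, seed = 8)
  aln <- map_reads(rs, ref, max_mm = 1)
  truth <- attr(rs, "truth")$reads
  expect_gte(nrow(aln), 999) # >= 99.9% mapped
  m <- match(aln$read_id, rs$id)
  expect_true(all(aln$length == truth$size[m]))
  expect_true(all(aln$mismatches == 0L))
  # repeated placements: same start recovered for almost all (repeats allowed)
  expect_gte(mean(aln$start == truth$start[m]), 0.99)
  # a read with two substitutions is unmapped at max_mm = 1
  bad <- substr(ref$residues, 11, 32)
  substr(bad, 3, 3) <- if (substr(bad, 3, 3) == "A") "C" else "A"
  substr(bad, 10, 10) <- if (substr(bad, 10, 10) == "G") "T" else "G"
  expect_equal(nrow(map_reads(read_set(bad), ref, max_mm = 1)), 0L)
})

test_that("size profiles normalize jointly over strands with Z-scores", {
  ref <- ref_for_tests()
  aln <- map_reads(
    gen_srna_reads(ref, "siRNA_insect", 500, seed = 3), ref)
  sp <- size_profile(aln)
  expect_equal(sum(sp$freq), 1)
  expect_equal(mean(sp$zscore), 0, tolerance = 1e-12)
  expect_equal(sd(as.numeric(sp$zscore)), 1, tolerance = 1e-9)
  # all reads 21 nt on + strand
  one <- alignment_set(data.frame(
    read_id = paste0("r", 1:10), start = 0L, length = 21L, strand = "+",
    mismatches = 0L, stringsAsFactors = FALSE), "ref", 100L)
  sp1 <- size_profile(one)
  expect_equal(sp1$freq["21", "+"], 1)
  expect_equal(sum(sp1$freq), 1)
  # empty alignment set: empty profile, all-zero Z (documented convention)
  sp0 <- size_profile(alignment_set(one[0, ], "ref", 100L))
  expect_equal(sp0$n_reads, 0L)
  expect_true(all(sp0$zscore == 0))
})

test_that("5' enrichment detects forced U starts and nothing under uniform starts", {
  ref <- ref_for_tests()
  rs <- gen_srna_reads(ref, srna_preset("fungal_siRNA"), 2000, seed = 12)
  aln <- map_reads(rs, ref)
  enr <- five_prime_enrichment(aln, ref)
  tcells <- enr[enr$base == "T" & enr$tested & enr$size %in% 20:22, ]
  expect_true(any(tcells$enriched))
  expect_true(all(enr$p_adj[enr$tested] >= enr$p[enr$tested], na.rm = TRUE))
  # expected fractions sum to 1 within each cell
  agg <- aggregate(expected_frac ~ size + strand, enr, sum)
  expect_true(all(abs(agg$expected_frac - 1) < 1e-9))
  # unbiased preset: no cell enriched at the classifier's region level
  rs2 <- gen_srna_reads(ref, "siRNA_insect", 2000, seed = 13)
  aln2 <- map_reads(rs2, ref)
  enr2 <- five_prime_enrichment(aln2, ref)
  cls <- classify_signature(size_profile(aln2), enr2)
  expect_equal(as.character(cls), "siRNA_insect_like")
})

test_that("coverage tracks conserve read footprints", {
  ref <- ref_for_tests()
  rs <- gen_srna_reads(ref, "siRNA_insect", 3000, seed = 21)
  aln <- map_reads(rs, ref)
  cov <- coverage_track(aln)
  expect_equal(sum(cov$depth), sum(aln$length))
  expect_gte(cov$covered_fraction, 0.99)
  expect_gte(cov$strand_depth_ratio, 0.8)
  expect_lte(cov$strand_depth_ratio, 1.25)
  # single read at position 0
  a1 <- alignment_set(data.frame(
    read_id = "r", start = 0L, length = 21L, strand = "+", mismatches = 0L,
    stringsAsFactors = FALSE), "ref", 50L)
  c1 <- coverage_track(a1)
  expect_equal(unname(c1$depth["+", 1:21]), rep(1L, 21))
  expect_equal(sum(c1$depth), 21L)
  # empty set: all-zero track
  c0 <- coverage_track(a1[0, ])
  expect_true(all(c0$depth == 0))
})

test_that("bedGraph export round-trips total depth", {
  ref <- ref_for_tests()
  aln <- map_reads(gen_srna_reads(ref, "siRNA_insect", 200, seed = 5), ref)
  cov <- coverage_track(aln)
  path <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(cov, path)
  bg <- read.table(path, sep = "\t")
  expect_equal(sum(abs(bg$V4) * (bg$V3 - bg$V2)), sum(aln$length))
})

test_that("KS comparison: degenerate cases and asymptotic agreement", {
  x <- rep(21L, 400)
  expect_equal(ecdf_ks_compare(x, x)$statistic, 0)
  expect_equal(ecdf_ks_compare(rep(21L, 50), rep(28L, 50))$statistic, 1)
  # D agrees with stats::ks.test on expanded samples
  set.seed(9)
  a <- sample(19:23, 500, replace = TRUE, prob = c(1, 2, 5, 2, 1))
  b <- sample(20:26, 400, replace = TRUE)
  D_ref <- suppressWarnings(stats::ks.test(a, b)$statistic)
  expect_equal(ecdf_ks_compare(a, b)$statistic, unname(D_ref))
  p_asym <- ecdf_ks_compare(a, b, method = "asymptotic")$p.value
  expect_lt(p_asym, 0.01) # clearly different distributions
})

test_that("signature classification recovers each preset and rejects junk", {
  ref <- ref_for_tests()
  for (preset in c("siRNA_insect", "fungal_siRNA", "piRNA")) {
    rs <- gen_srna_reads(ref, preset, 10000, seed = 99)
    aln <- map_reads(rs, ref)
    cls <- classify_signature(size_profile(aln), five_prime_enrichment(aln, ref))
    expected <- c(siRNA_insect = "siRNA_insect_like",
                  fungal_siRNA = "fungal_siRNA_like",
                  piRNA = "piRNA_like")[[preset]]
    expect_equal(as.character(cls), expected)
  }
  # uniform sizes 15-35 on one strand only: no signature
  set.seed(33)
  sizes <- sample(15:35, 500, replace = TRUE)
  starts <- sample(0:800, 500, replace = TRUE)
  flat <- read_set(substring(ref$residues, starts + 1, starts + sizes))
  aln_f <- map_reads(flat, ref)
  cls_f <- classify_signature(size_profile(aln_f),
                              five_prime_enrichment(aln_f, ref))
  expect_equal(as.character(cls_f), "none")
})

test_that("profile clustering groups replicate presets and splits classes", {
  ref <- ref_for_tests()
  mk <- function(preset, seed) {
    size_profile(map_reads(gen_srna_reads(ref, preset, 3000, seed = seed), ref))
  }
  profs <- list(si1 = mk("siRNA_insect", 1), si2 = mk("siRNA_insect", 2),
                pi1 = mk("piRNA", 3), pi2 = mk("piRNA", 4))
  cl <- profile_cluster(profs)
  expect_equal(cl$cluster[["si1"]], cl$cluster[["si2"]])
  expect_equal(cl$cluster[["pi1"]], cl$cluster[["pi2"]])
  expect_false(cl$cluster[["si1"]] == cl$cluster[["pi1"]])
})

test_that("SAM ingestion matches the internal mapper", {
  ref <- ref_for_tests()
  rs <- gen_srna_reads(ref, "siRNA_insect", 50, seed = 44)
  aln <- map_reads(rs, ref)
  path <- withr::local_tempfile(fileext = ".sam")
  lines <- c(sprintf("@SQ\tSN:%s\tLN:%d", ref$id, nchar(ref$residues)),
             vapply(seq_len(nrow(aln)), function(i) {
               flag <- if (aln$strand[i] == "-") 16L else 0L
               seqi <- rs$seq[match(aln$read_id[i], rs$id)]
               if (aln$strand[i] == "-") seqi <- revcomp(seqi)
               sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                       aln$read_id[i], flag, ref$id, aln$start[i] + 1L,
                       aln$length[i], seqi, aln$mismatches[i])
             }, character(1)))
  writeLines(lines, path)
  back <- alignment_set_from_sam(path, ref, max_mm = 1)
  expect_equal(nrow(back), nrow(aln))
  ord <- order(back$read_id); ord0 <- order(aln$read_id)
  expect_equal(back$start[ord], aln$start[ord0])
  expect_equal(back$strand[ord], aln$strand[ord0])
})
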