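# Synthetic-data generators. Every downstream stage of the pipeline is
# testable offline because these emit genomes, coding sequences and read
# libraries with recorded ground truth ("recount on emission": the truth
# object is re-measured from the emitted sequence, never assumed).

#' Ground truth for a synthetic viral genome
#' @keywords internal
synthetic_truth <- function(genome_length, at_content, code_id, orf_span,
                            trp_uga_fraction, signature_class = "none",
                            rng_seed = NA_integer_) {
  stopifnot((orf_span[2] - orf_span[1]) %% 3 == 0,
            at_content >= 0, at_content <= 100)
  structure(list(genome_length = genome_length, at_content = at_content,
                 code_id = code_id, orf_span = orf_span,
                 trp_uga_fraction = trp_uga_fraction,
                 signature_class = signature_class, rng_seed = rng_seed),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> ", x$genome_length, " nt, AT ",
      sprintf("%.2f", x$at_content), "%, code ", x$code_id,
      ", ORF [", x$orf_span[1], ",", x$orf_span[2], "), UGA(Trp) ",
      sprintf("%.1f", x$trp_uga_fraction), "%\n", sep = "")
  invisible(x)
}

# expected AT fraction of a codon distribution: weights is a 3x4 matrix of
# per-position base probabilities (cols A,C,G,T), forbidden codons excluded
codon_expectation <- function(weights, forbidden) {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(b1 = bases, b2 = bases, b3 = bases,
                      stringsAsFactors = FALSE)
  codon <- paste0(grid$b1, grid$b2, grid$b3)
  p <- weights[1, grid$b1] * weights[2, grid$b2] * weights[3, grid$b3]
  p[codon %in% forbidden] <- 0
  p <- p / sum(p)
  at <- (grid$b1 %in% c("A", "T")) + (grid$b2 %in% c("A", "T")) +
    (grid$b3 %in% c("A", "T"))
  list(codon = codon, p = p, mean_at = sum(p * at) / 3)
}

# apply an AT "temperature" to base weights: multiply A/T entries by
# exp(theta), C/G by exp(-theta), renormalize rows
temper_weights <- function(weights, theta) {
  w <- weights
  w[, c("A", "T")] <- w[, c("A", "T")] * exp(theta)
  w[, c("C", "G")] <- w[, c("C", "G")] * exp(-theta)
  sweep(w, 1, rowSums(w), "/")
}

default_base_weights <- function() {
  matrix(0.25, nrow = 3, ncol = 4, dimnames = list(NULL, c("A", "C", "G", "T")))
}

#' Generate a mitovirus-like synthetic genome
#'
#' Emits a linear ssRNA(+)-style genome (in DNA space) carrying exactly one
#' long open reading frame of `orf_codons` amino acids under the requested
#' genetic code, flanked by non-coding sequence. The ORF starts with ATG,
#' ends with a TAA stop, and contains `trp_codons` tryptophan codons of
#' which a fraction `trp_uga_frac` are written TGA (the rest TGG) — the
#' UGA(Trp) signature of mitochondrial residency. All other codons are drawn
#' from per-position base weights tempered so the whole genome hits
#' `at_target` (realized AT within +/- 2 percentage points; AT is tuned only
#' through the free codon positions and flanks, never through the forced
#' ATG/TGA/TGG/TAA codons). A guard stop is placed at the end of the 5'
#' flank so no upstream in-frame ATG can extend the planted ORF.
#'
#' The defaults emulate the published parameters of an insect mitovirus
#' genome: an 804-aa RdRp ORF read with the invertebrate mitochondrial code,
#' overall AT content 69.74%, and 73.3% of Trp codons written UGA, in a
#' 2697-nt genome.
#'
#' @param orf_codons Protein length in amino acids (>= 50).
#' @param code_id NCBI translation table (1, 4, 5 or 16). Codes in which TGA
#'   is a stop (1, 16) are incompatible with `trp_uga_frac > 0`.
#' @param at_target Target AT percentage of the whole genome.
#' @param trp_uga_frac Percent of Trp codons written TGA (0-100).
#' @param seed Integer RNG seed; output is a pure function of the arguments.
#' @param trp_codons Number of Trp codons in the ORF (default scales the 15
#'   Trp of an 804-aa RdRp: `round(orf_codons * 15/804)`, at least 1).
#' @param flank5,flank3 Non-coding flank lengths (nt).
#' @param base_weights Optional 3x4 matrix (rows = codon positions, cols =
#'   A,C,G,T) of base weights for the free ORF codons; used by the synthetic
#'   host families to imprint third-position codon preferences. Default
#'   uniform (AT content then comes from the tempering alone).
#' @return List with `seq` (a [nuc_sequence()]) and `truth`
#'   (a `synthetic_truth`, re-measured from the emitted sequence).
#' @export
gen_viral_genome <- function(orf_codons = 804, code_id = 5,
                             at_target = 69.74, trp_uga_frac = 73.3,
                             seed = 1, trp_codons = NULL,
                             flank5 = 141, flank3 = 141,
                             base_weights = NULL) {
  stopifnot(orf_codons >= 50, trp_uga_frac >= 0, trp_uga_frac <= 100,
            at_target >= 0, at_target <= 100, flank5 >= 3, flank3 >= 0)
  code <- genetic_code(code_id)
  if (code$codon_to_aa[["TGA"]] != "W" && trp_uga_frac > 0) {
    stop("infeasible: TGA is a stop codon under table ", code_id,
         " so trp_uga_frac must be 0")
  }
  if (is.null(trp_codons)) trp_codons <- max(1L, round(orf_codons * 15 / 804))
  if (trp_codons > orf_codons - 1L) stop("more Trp codons than free positions")
  n_uga <- round(trp_uga_frac / 100 * trp_codons)
  if (is.null(base_weights)) base_weights <- default_base_weights()
  stopifnot(is.matrix(base_weights), nrow(base_weights) == 3)
  forbidden <- union(code$stop_codons, c("TGA", "TGG", "TAA", "TAG"))
  n_free <- orf_codons - 1L - trp_codons # minus start, minus Trp slots
  # forced base content: ATG (2 AT) + n_uga TGA (2) + (trp-n_uga) TGG (1) +
  # terminal TAA (3) + guard TAA in the 5' flank (3, part of flank length)
  fixed_at <- 2 + 2 * n_uga + 1 * (trp_codons - n_uga) + 3 + 3
  fixed_nt <- 3 * (1L + trp_codons + 1L) + 3
  genome_length <- flank5 + 3L * (orf_codons + 1L) + flank3
  flank_free <- flank5 - 3L + flank3
  target_frac <- at_target / 100
  expected_at <- function(theta) {
    ce <- codon_expectation(temper_weights(base_weights, theta), forbidden)
    mono <- colMeans(temper_weights(base_weights, theta))
    (fixed_at + 3 * n_free * ce$mean_at +
        flank_free * (mono[["A"]] + mono[["T"]])) / genome_length
  }
  lo <- expected_at(-6); hi <- expected_at(6)
  if (target_frac < lo || target_frac > hi) {
    stop("infeasible: at_target ", at_target,
         "% is outside the achievable range [",
         sprintf("%.1f", 100 * lo), ", ", sprintf("%.1f", 100 * hi),
         "] for these constraints")
  }
  theta <- stats::uniroot(function(t) expected_at(t) - target_frac,
                          lower = -6, upper = 6)$root
  w <- temper_weights(base_weights, theta)
  ce <- codon_expectation(w, forbidden)
  mono <- colMeans(w)
  bases <- c("A", "C", "G", "T")

  build <- function() {
    codons <- character(orf_codons)
    codons[1] <- "ATG"
    slots <- 1L + sample.int(orf_codons - 1L, trp_codons)
    uga_slots <- if (n_uga > 0) slots[seq_len(n_uga)] else integer(0)
    codons[slots] <- "TGG"
    codons[uga_slots] <- "TGA"
    free_idx <- setdiff(seq_len(orf_codons), c(1L, slots))
    codons[free_idx] <- sample(ce$codon, length(free_idx), replace = TRUE,
                               prob = ce$p)
    f5 <- paste0(paste(sample(bases, flank5 - 3L, replace = TRUE, prob = mono),
                       collapse = ""), "TAA")
    f3 <- paste(sample(bases, flank3, replace = TRUE, prob = mono), collapse = "")
    paste0(f5, paste(codons, collapse = ""), "TAA", f3)
  }

  result <- with_rng_seed(seed, {
    good <- NULL
    for (attempt in 1:50) {
      g <- build()
      comp <- base_composition(nuc_sequence(g, id = "try"))
      if (abs(comp$AT_percent - at_target) > 2) next
      orfs <- find_orfs(nuc_sequence(g, id = "try"), code,
                        min_codons = min(50L, orf_codons))
      if (nrow(orfs) == 0L) next
      top <- orfs[1, ]
      ok <- top$aa_length == orf_codons && top$strand == "+" &&
        top$start == flank5 && top$end == flank5 + 3L * (orf_codons + 1L) &&
        (nrow(orfs) < 2L || orfs$aa_length[2] < orf_codons)
      if (ok) { good <- g; break }
    }
    if (is.null(good)) stop("failed to realize the requested genome in 50 attempts; ",
                            "the parameter combination is likely infeasible")
    good
  })
  seq <- nuc_sequence(result, id = sprintf("synthetic_mitovirus_seed%d", seed))
  # recount truth from the emitted sequence
  comp <- base_composition(seq)
  span <- c(flank5, flank5 + 3L * (orf_codons + 1L))
  orf_codons_str <- split_codons(substr(seq$residues, span[1] + 1L, span[2]))
  internal <- orf_codons_str[-length(orf_codons_str)]
  uga <- sum(internal == "TGA"); ugg <- sum(internal == "TGG")
  truth <- synthetic_truth(
    genome_length = nchar(seq$residues),
    at_content = comp$AT_percent,
    code_id = code$table_id,
    orf_span = span,
    trp_uga_fraction = if (uga + ugg > 0) 100 * uga / (uga + ugg) else NA_real_,
    signature_class = "none",
    rng_seed = as.integer(seed))
  list(seq = seq, truth = truth)
}

#' Generate a coding-sequence set from a codon probability table
#'
#' Draws `n_codons` codons i.i.d. from a 64-entry probability table —
#' ground truth for codon-usage recovery. Stop codons (under `code`) must
#' have probability zero: a CDS with internal stops is not a coding
#' sequence.
#'
#' @param codon_probs Named numeric vector over the 64 codons (DNA names,
#'   e.g. `"TGA"`), summing to 1 within 1e-9.
#' @param n_codons Number of codons to draw (0 gives an empty set).
#' @param seed Integer RNG seed.
#' @param code [genetic_code()] whose stop codons are checked.
#' @param source Source id recorded on the set.
#' @return A [cds_set()] with one CDS (or zero rows when `n_codons = 0`).
#' @export
gen_cds_set <- function(codon_probs, n_codons, seed, code = genetic_code(5),
                        source = "synthetic_cds") {
  all64 <- names(code$codon_to_aa)
  if (is.null(names(codon_probs)) || !setequal(names(codon_probs), all64)) {
    stop("codon_probs must be named with all 64 codons")
  }
  codon_probs <- codon_probs[all64]
  if (abs(sum(codon_probs) - 1) > 1e-9) stop("codon probabilities must sum to 1")
  if (any(codon_probs < 0)) stop("negative codon probability")
  if (any(codon_probs[code$stop_codons] > 0)) {
    stop("nonzero internal stop probability (",
         paste(code$stop_codons[codon_probs[code$stop_codons] > 0],
               collapse = ","), ")")
  }
  if (n_codons == 0L) return(cds_set(character(0), code_id = code$table_id))
  codons <- with_rng_seed(seed, {
    sample(all64, n_codons, replace = TRUE, prob = codon_probs)
  })
  cds_set(paste(codons, collapse = ""), source = source,
          code_id = code$table_id)
}

#' Synthetic mitochondrial codon-usage profiles
#'
#' Two synthetic host families emulating the observed split between insect
#' and fungal mitochondrial codon usage: both are AT-rich, but the insect
#' family prefers A at third codon positions and writes nearly all Trp as
#' TGA (UGA), while the fungal family prefers T at third positions with a
#' lower (but still high) TGA share. Codon probabilities are the product of
#' per-position base weights with stop codons zeroed and the Trp mass split
#' by the family's UGA fraction. Optional log-normal jitter makes distinct
#' family members.
#'
#' @param family `"insect"` or `"fungal"`.
#' @param jitter_sd Standard deviation of log-normal per-codon jitter
#'   (0 = the family centroid).
#' @param seed RNG seed for the jitter (required when `jitter_sd > 0`).
#' @return List with `codon_probs` (named 64-vector), `base_weights`
#'   (3x4 matrix), `uga_frac`, `code` (a [genetic_code()]).
#' @export
mito_codon_profile <- function(family = c("insect", "fungal"),
                               jitter_sd = 0, seed = NULL) {
  family <- match.arg(family)
  if (family == "insect") {
    w <- rbind(c(A = 0.36, C = 0.11, G = 0.13, T = 0.40),
               c(A = 0.34, C = 0.15, G = 0.10, T = 0.41),
               c(A = 0.52, C = 0.09, G = 0.05, T = 0.34))
    uga_frac <- 0.99
    code <- genetic_code(5)
  } else {
    w <- rbind(c(A = 0.30, C = 0.15, G = 0.18, T = 0.37),
               c(A = 0.31, C = 0.17, G = 0.13, T = 0.39),
               c(A = 0.20, C = 0.13, G = 0.06, T = 0.61))
    uga_frac <- 0.85
    code <- genetic_code(4)
  }
  ce <- codon_expectation(w, forbidden = code$stop_codons)
  p <- setNames(ce$p, ce$codon)[names(code$codon_to_aa)]
  trp_mass <- p[["TGA"]] + p[["TGG"]]
  p[["TGA"]] <- trp_mass * uga_frac
  p[["TGG"]] <- trp_mass * (1 - uga_frac)
  if (jitter_sd > 0) {
    if (is.null(seed)) stop("jitter requires a seed")
    p <- with_rng_seed(seed, p * exp(rnorm(64, 0, jitter_sd)))
  }
  p <- p / sum(p)
  list(codon_probs = p, base_weights = w, uga_frac = uga_frac, code = code)
}

#' Small-RNA signature presets
#'
#' Parameter bundles for [gen_srna_reads()] describing the three canonical
#' virus-derived small-RNA signatures: the insect siRNA signature (21-nt
#' symmetric peak, both strands, no 5' bias), the fungal siRNA signature
#' (20-22-nt symmetric peak with 5'-U preference) and the piRNA signature
#' (24-30 nt, 5'-U bias, strand asymmetry).
#'
#' @param class One of `"siRNA_insect"`, `"fungal_siRNA"`, `"piRNA"`.
#' @return List with `peak_size`, `size_sd`, `strand_ratio` (probability a
#'   read is sense), `five_prime_bias` (probability a read is forced to start
#'   on U; `NA` = no bias), and `class`.
#' @export
srna_preset <- function(class = c("siRNA_insect", "fungal_siRNA", "piRNA")) {
  class <- match.arg(class)
  switch(class,
    siRNA_insect = list(class = class, peak_size = 21, size_sd = 1,
                        strand_ratio = 0.5, five_prime_bias = NA),
    fungal_siRNA = list(class = class, peak_size = 21, size_sd = 1,
                        strand_ratio = 0.5, five_prime_bias = 0.75),
    piRNA = list(class = class, peak_size = 27, size_sd = 1.8,
                 strand_ratio = 0.85, five_prime_bias = 0.9))
}

#' Generate virus-derived small-RNA reads
#'
#' Reads are exact substrings of the reference (sense) or its reverse
#' complement (antisense). Sizes follow a discretized Gaussian truncated to
#' 15-35 nt; strand is Bernoulli(`strand_ratio`); with 5'-U bias `b`, a read
#' is forced (with probability `b`) to start at a position whose 5' base on
#' its strand is U/T — rejection-free, by sampling directly from the valid
#' start positions, so reads remain exact substrings. The realized 5'-U
#' fraction is therefore `b + (1-b) * f_U` where `f_U` is the background U
#' start frequency.
#'
#' @param ref A [nuc_sequence()] (must be at least 35 nt).
#' @param signature A preset name or a list as returned by [srna_preset()].
#' @param n_reads Number of reads.
#' @param seed Integer RNG seed.
#' @return A [read_set()] with attribute `truth`: data.frame of the true
#'   `start`, `size`, `strand` per read, plus the signature parameters.
#' @export
gen_srna_reads <- function(ref, signature = "siRNA_insect", n_reads, seed) {
  ref <- as_nuc_sequence(ref)
  if (is.character(signature)) signature <- srna_preset(signature)
  p <- signature
  stopifnot(p$peak_size >= 15, p$peak_size <= 35,
            p$strand_ratio >= 0, p$strand_ratio <= 1, n_reads >= 1)
  L <- nchar(ref$residues)
  if (L < 35L) stop("reference shorter than the maximum read size (35 nt)")
  chars <- strsplit(ref$residues, "", fixed = TRUE)[[1]]
  t_pos_plus <- which(chars == "T")            # 1-based 5' starts on + with U
  a_pos <- which(chars == "A")                 # 1-based ref pos giving 5' U on -
  with_rng_seed(seed, {
    sizes <- round(rnorm(n_reads, p$peak_size, p$size_sd))
    while (any(bad <- sizes < 15 | sizes > 35)) {
      sizes[bad] <- round(rnorm(sum(bad), p$peak_size, p$size_sd))
    }
    strand <- ifelse(runif(n_reads) < p$strand_ratio, "+", "-")
    biased <- if (is.na(p$five_prime_bias)) rep(FALSE, n_reads) else
      runif(n_reads) < p$five_prime_bias
    start <- integer(n_reads) # 0-based
    for (i in seq_len(n_reads)) {
      sz <- sizes[i]
      if (biased[i]) {
        if (strand[i] == "+") {
          cand <- t_pos_plus[t_pos_plus <= L - sz + 1L]
        } else {
          cand <- a_pos[a_pos >= sz] - sz + 1L   # 5' base of - read is at start+sz-1
        }
        if (length(cand)) {
          start[i] <- cand[sample.int(length(cand), 1L)] - 1L
          next
        }
      }
      start[i] <- sample.int(L - sz + 1L, 1L) - 1L
    }
    seqs <- substring(ref$residues, start + 1L, start + sizes)
    flip <- strand == "-"
    seqs[flip] <- vapply(seqs[flip], revcomp, character(1), USE.NAMES = FALSE)
    out <- read_set(seqs, id = sprintf("srna%06d", seq_len(n_reads)))
    attr(out, "truth") <- list(
      reads = data.frame(start = start, size = sizes, strand = strand,
                         stringsAsFactors = FALSE),
      signature = p, ref_id = ref$id, rng_seed = as.integer(seed))
    out
  })
}

#' Generate long reads tiling a reference
#'
#' Fixed-length reads with uniform start positions on both strands and i.i.d.
#' substitution errors — the assembly test fixture. Expected per-base depth
#' is `coverage`.
#'
#' @param ref A [nuc_sequence()].
#' @param coverage Target fold-coverage (> 0).
#' @param read_len Read length (< reference length).
#' @param err_rate Per-base substitution probability.
#' @param seed Integer RNG seed.
#' @return A [read_set()] with attribute `truth` (`start`, `strand`,
#'   `n_errors` per read).
#' @export
gen_long_reads <- function(ref, coverage, read_len = 75L, err_rate = 0, seed = 1) {
  ref <- as_nuc_sequence(ref)
  L <- nchar(ref$residues)
  stopifnot(coverage > 0, read_len < L, err_rate >= 0, err_rate < 1)
  n <- max(1L, ceiling(coverage * L / read_len))
  with_rng_seed(seed, {
    start <- sample.int(L - read_len + 1L, n, replace = TRUE) - 1L
    strand <- sample(c("+", "-"), n, replace = TRUE)
    seqs <- substring(ref$residues, start + 1L, start + read_len)
    nerr <- integer(n)
    if (err_rate > 0) {
      nerr <- stats::rbinom(n, read_len, err_rate)
      bases <- c("A", "C", "G", "T")
      for (i in which(nerr > 0)) {
        s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
        at <- sample.int(read_len, nerr[i])
        for (j in at) s[j] <- sample(setdiff(bases, s[j]), 1L)
        seqs[i] <- paste(s, collapse = "")
      }
    }
    flip <- strand == "-"
    seqs[flip] <- vapply(seqs[flip], revcomp, character(1), USE.NAMES = FALSE)
    out <- read_set(seqs, id = sprintf("long%06d", seq_len(n)))
    attr(out, "truth") <- data.frame(start = start, strand = strand,
                                     n_errors = nerr, stringsAsFactors = FALSE)
    out
  })
}

#' Generate a DNA sequencing library with or without an integrated virus
#'
#' Emulates the endogenous-viral-element (EVE) check: a whole-genome DNA
#' library contains host-derived reads always, and virus-derived reads only
#' if the viral sequence is integrated in the host genome. The number of
#' viral reads in the integrated case is Binomial(`n_reads`,
#' `viral_fraction`).
#'
#' @param host_ref Host genome [nuc_sequence()].
#' @param virus_ref Viral genome [nuc_sequence()].
#' @param integrated Logical: is a viral copy present in the DNA?
#' @param n_reads Library size (> 0).
#' @param seed Integer RNG seed.
#' @param viral_fraction Fraction of reads of viral origin when integrated.
#' @param read_len DNA read length.
#' @return A [read_set()] with attribute `truth` (`origin` per read:
#'   `"host"`/`"virus"`).
#' @export
gen_dna_library <- function(host_ref, virus_ref, integrated, n_reads, seed,
                            viral_fraction = 0.01, read_len = 100L) {
  if (n_reads <= 0) stop("n_reads must be > 0")
  host_ref <- as_nuc_sequence(host_ref); virus_ref <- as_nuc_sequence(virus_ref)
  rl_h <- min(read_len, nchar(host_ref$residues))
  rl_v <- min(read_len, nchar(virus_ref$residues))
  with_rng_seed(seed, {
    n_virus <- if (integrated) stats::rbinom(1L, n_reads, viral_fraction) else 0L
    origin <- c(rep("virus", n_virus), rep("host", n_reads - n_virus))
    draw <- function(refseq, rl, m) {
      if (m == 0L) return(character(0))
      L <- nchar(refseq)
      start <- sample.int(L - rl + 1L, m, replace = TRUE) - 1L
      s <- substring(refseq, start + 1L, start + rl)
      flip <- runif(m) < 0.5
      s[flip] <- vapply(s[flip], revcomp, character(1), USE.NAMES = FALSE)
      s
    }
    seqs <- c(draw(virus_ref$residues, rl_v, n_virus),
              draw(host_ref$residues, rl_h, n_reads - n_virus))
    out <- read_set(seqs, id = sprintf("dna%06d", seq_len(n_reads)))
    attr(out, "truth") <- data.frame(origin = origin, stringsAsFactors = FALSE)
    out
  })
}

#' Write a ground-truth sidecar table
#'
#' @param truth A `synthetic_truth` or the `truth` attribute of a generated
#'   read set.
#' @param path Output TSV file.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  if (inherits(truth, "synthetic_truth")) {
    df <- data.frame(field = names(unlist(truth)), value = unlist(truth))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (is.data.frame(truth)) {
    write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (is.list(truth) && is.data.frame(truth$reads)) {
    write.table(truth$reads, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else stop("unsupported truth object")
  invisible(path)
}
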