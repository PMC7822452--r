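# Small-RNA analysis: read filtering, mapping, strand-resolved size
# profiling with Z-score normalization, 5'-base enrichment, coverage tracks,
# ECDF/Kolmogorov-Smirnov comparison and rule-based signature classification.

SIZE_RANGE <- 15:35

#' Read set container
#'
#' @param seq Character vector of read sequences.
#' @param id Read identifiers (default generated).
#' @param qual Phred+33 quality strings (default all `"I"`, Q40).
#' @return Object of class `read_set`: data.frame with `id`, `seq`, `qual`.
#' @export
read_set <- function(seq, id = NULL, qual = NULL) {
  seq <- toupper(chartr("Uu", "Tt", seq))
  n <- length(seq)
  if (is.null(id)) id <- sprintf("read%06d", seq_len(n))
  if (is.null(qual)) qual <- vapply(nchar(seq), function(L) strrep("I", L), character(1))
  if (any(nchar(qual) != nchar(seq))) stop("quality length != sequence length")
  df <- data.frame(id = as.character(id), seq = seq, qual = as.character(qual),
                   stringsAsFactors = FALSE)
  class(df) <- c("read_set", "data.frame")
  df
}

#' @export
print.read_set <- function(x, ...) {
  cat("<read_set> ", nrow(x), " reads, lengths ",
      if (nrow(x)) paste0(min(nchar(x$seq)), "-", max(nchar(x$seq))) else "-",
      " nt\n", sep = "")
  invisible(x)
}

#' Read a FASTQ file
#'
#' Strict 4-line-per-record reader with per-record diagnostics; malformed
#' records raise an error naming the record index.
#'
#' @param path FASTQ file (Phred+33).
#' @return A [read_set()].
#' @export
read_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: ", length(lines), " lines is not a multiple of 4")
  }
  n <- length(lines) %/% 4L
  i1 <- 4L * seq_len(n) - 3L
  bad <- which(substr(lines[i1], 1, 1) != "@")
  if (length(bad)) stop("malformed FASTQ record ", bad[1], ": header must start with '@'")
  bad <- which(substr(lines[i1 + 2L], 1, 1) != "+")
  if (length(bad)) stop("malformed FASTQ record ", bad[1], ": separator must start with '+'")
  seqs <- lines[i1 + 1L]
  quals <- lines[i1 + 3L]
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad)) stop("malformed FASTQ record ", bad[1], ": quality length mismatch")
  read_set(seqs, id = sub("^@", "", sub("\\s.*$", "", lines[i1])), qual = quals)
}

#' Write a FASTQ file
#'
#' @param reads A [read_set()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "read_set"))
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads)) {
    writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual), con)
  }
  invisible(path)
}

#' Quality-filter small-RNA reads
#'
#' Keeps a read iff its length is at least `min_len` *and* the fraction of
#' bases with Phred quality >= `q_thresh` is at least `min_good_frac`
#' (equivalently: discard reads with more than 20% of bases below Q20, or
#' shorter than 20 nt, at the defaults).
#'
#' @param reads A [read_set()] with Phred+33 qualities.
#' @param min_len Minimum read length (nt).
#' @param q_thresh Phred quality threshold.
#' @param min_good_frac Minimum fraction of bases at or above `q_thresh`.
#' @return Filtered [read_set()].
#' @export
filter_reads <- function(reads, min_len = 20L, q_thresh = 20L, min_good_frac = 0.80) {
  stopifnot(inherits(reads, "read_set"))
  if (nrow(reads) == 0L) return(reads)
  keep <- vapply(seq_len(nrow(reads)), function(i) {
    L <- nchar(reads$seq[i])
    if (L < min_len) return(FALSE)
    q <- utf8ToInt(reads$qual[i]) - 33L
    mean(q >= q_thresh) >= min_good_frac
  }, logical(1))
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("read_set", "data.frame")
  out
}

#' Alignment set container
#'
#' Container for ungapped read placements on a reference, as produced by
#' [map_reads()] or [alignment_set_from_sam()]; constructable directly for
#' alignments from other sources.
#'
#' @param df data.frame with columns `read_id`, `start` (0-based), `length`,
#'   `strand` (`"+"`/`"-"`), `mismatches`.
#' @param ref_id,ref_length Reference identifier and length.
#' @return Object of class `alignment_set`.
#' @export
alignment_set <- function(df, ref_id, ref_length) {
  stopifnot(all(c("read_id", "start", "length", "strand", "mismatches") %in% names(df)))
  if (nrow(df) && any(df$start + df$length > ref_length)) {
    stop("alignment exceeds reference length")
  }
  structure(df, ref_id = ref_id, ref_length = ref_length,
            class = c("alignment_set", "data.frame"))
}

#' @export
`[.alignment_set` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "ref_id") <- attr(x, "ref_id")
    attr(out, "ref_length") <- attr(x, "ref_length")
    class(out) <- c("alignment_set", "data.frame")
  }
  out
}

#' @export
print.alignment_set <- function(x, ...) {
  cat("<alignment_set> ", nrow(x), " alignments on ", attr(x, "ref_id"),
      " (", attr(x, "ref_length"), " nt); + strand: ", sum(x$strand == "+"),
      ", - strand: ", sum(x$strand == "-"), "\n", sep = "")
  invisible(x)
}

#' Map reads to a reference (ungapped, end-to-end)
#'
#' Emulates short-read mapping with up to `max_mm` substitutions and no
#' indels, on both strands. A read with several placements is assigned once:
#' to the placement with the fewest mismatches, then the lowest start
#' coordinate, then `+` before `-`. Reads with no placement are dropped.
#'
#' @param reads A [read_set()] or character vector of read sequences.
#' @param ref A [nuc_sequence()].
#' @param max_mm Maximum substitutions allowed.
#' @return An `alignment_set`: data.frame with `read_id`, `start` (0-based),
#'   `length`, `strand`, `mismatches`; attributes `ref_id`, `ref_length`.
#' @export
map_reads <- function(reads, ref, max_mm = 1L) {
  ref <- as_nuc_sequence(ref)
  if (nchar(ref$residues) == 0L) stop("empty reference")
  if (!inherits(reads, "read_set")) reads <- read_set(reads)
  hits <- cpp_map_reads(ref$residues, reads$seq, as.integer(max_mm))
  df <- data.frame(read_id = reads$id[hits$read], start = hits$start,
                   length = hits$length, strand = hits$strand,
                   mismatches = hits$mismatches, stringsAsFactors = FALSE)
  alignment_set(df, ref_id = ref$id, ref_length = nchar(ref$residues))
}

#' Import alignments from a SAM or BAM file
#'
#' For users who map with their own tool. Plain-text SAM is parsed directly;
#' BAM requires the Rsamtools package. Only primary, mapped, ungapped
#' single-M-CIGAR records against `ref_id` are kept, and the mismatch filter
#' is re-applied from the `NM` tag when present.
#'
#' @param path SAM (`.sam`) or BAM (`.bam`) file.
#' @param ref A [nuc_sequence()] the alignments refer to.
#' @param max_mm Maximum mismatches retained (records without `NM` pass).
#' @return An `alignment_set`.
#' @export
alignment_set_from_sam <- function(path, ref, max_mm = 1L) {
  ref <- as_nuc_sequence(ref)
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    if (!requireNamespace("Rsamtools", quietly = TRUE)) {
      stop("reading BAM requires the Rsamtools package")
    }
    b <- Rsamtools::scanBam(path,
      param = Rsamtools::ScanBamParam(
        what = c("qname", "rname", "pos", "strand", "cigar", "qwidth"),
        tag = "NM"))[[1]]
    df <- data.frame(qname = b$qname, rname = as.character(b$rname),
                     pos = b$pos, strand = as.character(b$strand),
                     cigar = b$cigar, qwidth = b$qwidth,
                     nm = if (is.null(b$tag$NM)) NA_integer_ else b$tag$NM,
                     stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!startsWith(lines, "@")]
    f <- strsplit(lines, "\t", fixed = TRUE)
    df <- data.frame(
      qname = vapply(f, `[`, "", 1L),
      flag = as.integer(vapply(f, `[`, "", 2L)),
      rname = vapply(f, `[`, "", 3L),
      pos = as.integer(vapply(f, `[`, "", 4L)),
      cigar = vapply(f, `[`, "", 6L),
      qwidth = nchar(vapply(f, `[`, "", 10L)),
      stringsAsFactors = FALSE)
    df$strand <- ifelse(bitwAnd(df$flag, 16L) > 0L, "-", "+")
    df <- df[bitwAnd(df$flag, 4L) == 0L & bitwAnd(df$flag, 256L) == 0L, , drop = FALSE]
    nm <- vapply(f, function(x) {
      hit <- grep("^NM:i:", x, value = TRUE)
      if (length(hit)) as.integer(sub("^NM:i:", "", hit[1])) else NA_integer_
    }, integer(1))
    df$nm <- nm[as.integer(rownames(df))]
  }
  df <- df[df$rname == ref$id & grepl("^[0-9]+M$", df$cigar), , drop = FALSE]
  df <- df[is.na(df$nm) | df$nm <= max_mm, , drop = FALSE]
  out <- data.frame(read_id = df$qname, start = df$pos - 1L, length = df$qwidth,
                    strand = df$strand,
                    mismatches = ifelse(is.na(df$nm), 0L, df$nm),
                    stringsAsFactors = FALSE)
  alignment_set(out, ref_id = ref$id, ref_length = nchar(ref$residues))
}

#' Strand-resolved small-RNA size profile
#'
#' Frequency of each read size from 15 to 35 nt, per strand, normalized
#' jointly over both strands (the 42 cells sum to 1 for non-empty input), plus
#' the Z-score normalization of those 42 frequencies used for heatmaps and
#' clustering. A zero-variance frequency vector yields all-zero Z-scores.
#'
#' @param aln An `alignment_set` (reads outside 15-35 nt are ignored).
#' @return Object of class `size_profile`: list with `ref_id`, `freq` and
#'   `zscore` (21 x 2 matrices, rows = sizes, cols = `+`/`-`), `n_reads`.
#' @export
size_profile <- function(aln) {
  stopifnot(inherits(aln, "alignment_set"))
  keep <- aln$length >= min(SIZE_RANGE) & aln$length <= max(SIZE_RANGE)
  a <- aln[keep, , drop = FALSE]
  freq <- matrix(0, nrow = length(SIZE_RANGE), ncol = 2,
                 dimnames = list(SIZE_RANGE, c("+", "-")))
  for (s in c("+", "-")) {
    counts <- table(factor(a$length[a$strand == s], levels = SIZE_RANGE))
    freq[, s] <- as.numeric(counts)
  }
  n <- sum(freq)
  if (n > 0) freq <- freq / n
  v <- as.numeric(freq)
  sdv <- sd(v)
  z <- if (is.na(sdv) || sdv == 0) rep(0, length(v)) else (v - mean(v)) / sdv
  zscore <- matrix(z, nrow = length(SIZE_RANGE),
                   dimnames = dimnames(freq))
  structure(list(ref_id = attr(aln, "ref_id"), freq = freq, zscore = zscore,
                 n_reads = as.integer(n)),
            class = "size_profile")
}

#' @export
print.size_profile <- function(x, ...) {
  cat("<size_profile> ", x$ref_id, ": ", x$n_reads, " reads in 15-35 nt\n", sep = "")
  if (x$n_reads > 0) {
    mode_p <- SIZE_RANGE[which.max(x$freq[, "+"])]
    mode_m <- SIZE_RANGE[which.max(x$freq[, "-"])]
    cat("  modal size: +", mode_p, " / -", mode_m,
        "; + strand fraction ", sprintf("%.2f", sum(x$freq[, "+"])), "\n", sep = "")
  }
  invisible(x)
}

#' 5'-base enrichment statistics
#'
#' For every (read size, strand) cell with at least `min_reads` alignments,
#' tests each 5' base (in read space, i.e. the transcribed strand; U is
#' reported as T) against the base composition of the corresponding reference
#' strand with a two-sided binomial test, Bonferroni-corrected over the four
#' bases within each cell. `enriched` flags over-represented bases at
#' adjusted p < `alpha`. Cells below `min_reads` are reported untested.
#'
#' @param aln An `alignment_set`.
#' @param ref The [nuc_sequence()] the alignments refer to.
#' @param min_reads Minimum cell count for testing.
#' @param alpha Significance level on the adjusted p-value.
#' @return Object of class `five_prime_enrichment`: data.frame with columns
#'   `size`, `strand`, `base`, `cell_n`, `observed`, `expected_frac`, `p`,
#'   `p_adj`, `tested`, `enriched`.
#' @export
five_prime_enrichment <- function(aln, ref, min_reads = 20L, alpha = 0.05) {
  stopifnot(inherits(aln, "alignment_set"))
  if (nrow(aln) == 0L) stop("need at least one alignment")
  ref <- as_nuc_sequence(ref)
  comp <- base_composition(ref)$base_fractions
  # expected 5'-base fractions per strand: + reads start on ref bases; - reads
  # start on the complement of ref bases (reverse-complement composition)
  expected <- list("+" = comp,
                   "-" = setNames(comp[c("T", "G", "C", "A")], c("A", "C", "G", "T")))
  chars <- strsplit(ref$residues, "", fixed = TRUE)[[1]]
  five <- ifelse(aln$strand == "+",
                 chars[aln$start + 1L],
                 chartr("ACGTN", "TGCAN", chars[aln$start + aln$length]))
  keep <- aln$length >= min(SIZE_RANGE) & aln$length <= max(SIZE_RANGE)
  rows <- list()
  for (s in c("+", "-")) for (sz in SIZE_RANGE) {
    i <- which(keep & aln$strand == s & aln$length == sz)
    n <- length(i)
    obs <- table(factor(five[i], levels = c("A", "C", "G", "T")))
    tested <- n >= min_reads
    for (b in c("A", "C", "G", "T")) {
      p <- NA_real_
      if (tested) {
        p <- binom.test(obs[[b]], n, p = expected[[s]][[b]])$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        size = sz, strand = s, base = b, cell_n = n,
        observed = as.integer(obs[[b]]),
        expected_frac = expected[[s]][[b]], p = p,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df$p_adj <- pmin(1, df$p * 4)
  df$tested <- !is.na(df$p)
  df$enriched <- df$tested & df$p_adj < alpha &
    df$observed / pmax(df$cell_n, 1L) > df$expected_frac
  class(df) <- c("five_prime_enrichment", "data.frame")
  df
}

#' Per-position coverage track
#'
#' Full read-footprint depth per reference position and strand. The summary
#' reports the fraction of positions covered (either strand) and the ratio of
#' total + to - strand depth.
#'
#' @param aln An `alignment_set`.
#' @param ref The [nuc_sequence()] the alignments refer to (optional; length
#'   is taken from the alignment set when omitted).
#' @return Object of class `coverage_track`: list with `depth` (2-row matrix
#'   `+`/`-` by position), `covered_fraction`, `strand_depth_ratio`.
#' @export
coverage_track <- function(aln, ref = NULL) {
  stopifnot(inherits(aln, "alignment_set"))
  L <- attr(aln, "ref_length")
  depth <- matrix(0L, nrow = 2, ncol = L, dimnames = list(c("+", "-"), NULL))
  for (s in c("+", "-")) {
    i <- which(aln$strand == s)
    if (!length(i)) next
    delta <- integer(L + 1L)
    st <- aln$start[i] + 1L
    en <- aln$start[i] + aln$length[i] + 1L
    for (k in seq_along(i)) {
      delta[st[k]] <- delta[st[k]] + 1L
      delta[en[k]] <- delta[en[k]] - 1L
    }
    depth[s, ] <- cumsum(delta)[seq_len(L)]
  }
  total <- colSums(depth)
  plus <- sum(depth["+", ]); minus <- sum(depth["-", ])
  structure(list(
    ref_id = attr(aln, "ref_id"),
    depth = depth,
    covered_fraction = mean(total > 0),
    strand_depth_ratio = if (minus > 0) plus / minus else Inf
  ), class = "coverage_track")
}

#' Write a coverage track as bedGraph
#'
#' One file per strand suffix is avoided: the strand is written as a fourth
#' column sign (negative depth for the `-` strand), the common convention for
#' stranded bedGraph pairs collapsed into one file.
#'
#' @param cov A [coverage_track()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(cov, path) {
  stopifnot(inherits(cov, "coverage_track"))
  con <- file(path, "w")
  on.exit(close(con))
  for (s in c("+", "-")) {
    d <- cov$depth[s, ]
    r <- rle(d)
    ends <- cumsum(r$lengths)
    starts <- c(0L, head(ends, -1L))
    keep <- r$values != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%d", cov$ref_id,
                         starts[keep], ends[keep],
                         if (s == "+") r$values[keep] else -r$values[keep]), con)
    }
  }
  invisible(path)
}

# normalize assorted inputs to a named count vector over SIZE_RANGE
as_size_counts <- function(x) {
  if (inherits(x, "size_profile")) {
    if (x$n_reads == 0L) stop("empty size profile")
    return(round(rowSums(x$freq) * x$n_reads))
  }
  if (inherits(x, "alignment_set")) x <- x$length
  if (is.data.frame(x)) {
    counts <- setNames(rep(0, length(SIZE_RANGE)), SIZE_RANGE)
    counts[as.character(x$size)] <- x$count
    return(counts)
  }
  x <- x[x >= min(SIZE_RANGE) & x <= max(SIZE_RANGE)]
  if (!length(x)) stop("no sizes within 15-35 nt")
  as.numeric(table(factor(x, levels = SIZE_RANGE)))
}

#' Compare two small-RNA size distributions (ECDF / Kolmogorov-Smirnov)
#'
#' Two-sample KS test on read-size distributions. Because read sizes are
#' small integers the samples are heavily tied, where the classical
#' asymptotic KS p-value is conservative; the default therefore computes the
#' p-value by Monte-Carlo permutation of the pooled sample (exact level under
#' exchangeability), with the asymptotic Kolmogorov formula available via
#' `method = "asymptotic"`.
#'
#' @param a,b Size samples: integer vectors of read sizes, `size_profile`
#'   objects, `alignment_set`s, or data.frames with `size` and `count`.
#' @param method `"permutation"` (default) or `"asymptotic"`.
#' @param B Number of permutations.
#' @param perm_seed Seed for the permutation draw (kept separate from the
#'   data-generating seeds so the test is reproducible).
#' @return List with `statistic` (D), `p.value`, `method`, `n` (the two
#'   sample sizes).
#' @export
ecdf_ks_compare <- function(a, b, method = c("permutation", "asymptotic"),
                            B = 999L, perm_seed = 421L) {
  method <- match.arg(method)
  ca <- as_size_counts(a); cb <- as_size_counts(b)
  n <- sum(ca); m <- sum(cb)
  if (n == 0 || m == 0) stop("both samples must be non-empty")
  D <- max(abs(cumsum(ca) / n - cumsum(cb) / m))
  if (method == "asymptotic") {
    en <- sqrt(n * m / (n + m))
    lambda <- (en + 0.12 + 0.11 / en) * D
    k <- 1:100
    p <- 2 * sum((-1)^(k - 1) * exp(-2 * lambda^2 * k^2))
    p <- min(1, max(0, p))
  } else {
    pooled <- rep.int(seq_along(ca), ca + cb) # sizes as indices into SIZE_RANGE
    nexc <- 0L
    p <- with_rng_seed(perm_seed, {
      for (i in seq_len(B)) {
        idx <- sample.int(n + m, n)
        t1 <- tabulate(pooled[idx], nbins = length(ca))
        t2 <- (ca + cb) - t1
        Dp <- max(abs(cumsum(t1) / n - cumsum(t2) / m))
        if (Dp >= D - 1e-12) nexc <- nexc + 1L
      }
      (1 + nexc) / (B + 1)
    })
  }
  list(statistic = D, p.value = p, method = method, n = c(n, m))
}

#' Classify a small-RNA signature
#'
#' Rule-based call on a size profile plus 5'-base enrichment, mirroring the
#' canonical virus-derived small-RNA signatures in insects and fungi:
#'
#' * `siRNA_insect_like` — modal size within 19-23 nt on both strands,
#'   balanced strand usage (frequency ratio within `[1/3, 3]`), and no
#'   significant 5'-base enrichment in the 19-23 nt cells (Dicer-2 products).
#' * `fungal_siRNA_like` — modal size within 20-22 nt on both strands with a
#'   significant 5'-U preference.
#' * `piRNA_like` — modal size within 24-30 nt, 5'-U preference, and strand
#'   asymmetry (ratio outside `[1/3, 3]`).
#' * `none` — anything else.
#'
#' piRNA is tested first, then fungal, then insect.
#'
#' Enrichment calls here are made at the *region* level: the statement
#' "no 5' enrichment in the 19-23 nt cells" is a joint null over every
#' tested (size, strand, base) combination in the region, so the raw
#' binomial p-values are Bonferroni-corrected across all of them (not just
#' within one cell as in [five_prime_enrichment()]'s per-cell flags).
#'
#' @param profile A [size_profile()].
#' @param enr The matching [five_prime_enrichment()].
#' @param strand_ratio_range Balanced-strand interval for the siRNA calls.
#' @param alpha Family-wise level for the region-level enrichment calls.
#'   The default is stringent (0.01) because the insect-siRNA call asserts an
#'   *absence* of enrichment jointly over many cells, while the biases the
#'   positive calls rely on are far from the null at realistic read counts.
#' @return Character scalar: one of `siRNA_insect_like`, `fungal_siRNA_like`,
#'   `piRNA_like`, `none`. The thresholds used are attached as attributes.
#' @export
classify_signature <- function(profile, enr,
                               strand_ratio_range = c(1 / 3, 3),
                               alpha = 0.01) {
  stopifnot(inherits(profile, "size_profile"))
  if (profile$n_reads == 0L) stop("empty size profile")
  fp <- sum(profile$freq[, "+"]); fm <- sum(profile$freq[, "-"])
  ratio <- if (fm > 0) fp / fm else Inf
  mode_all <- SIZE_RANGE[which.max(rowSums(profile$freq))]
  mode_p <- if (fp > 0) SIZE_RANGE[which.max(profile$freq[, "+"])] else NA_integer_
  mode_m <- if (fm > 0) SIZE_RANGE[which.max(profile$freq[, "-"])] else NA_integer_
  region_flags <- function(sizes, base = NULL) {
    i <- enr$tested & enr$size %in% sizes
    if (!is.null(base)) i <- i & enr$base == base
    m <- sum(i) # joint Bonferroni over all tested hypotheses in the region
    over <- enr$observed / pmax(enr$cell_n, 1L) > enr$expected_frac
    any(i & over & enr$p * m < alpha)
  }
  u_enriched_in <- function(sizes) region_flags(sizes, base = "T")
  any_enriched_in <- function(sizes) region_flags(sizes)
  balanced <- ratio >= strand_ratio_range[1] && ratio <= strand_ratio_range[2]
  call <- "none"
  if (mode_all %in% 24:30 && u_enriched_in(24:30) && !balanced) {
    call <- "piRNA_like"
  } else if (!is.na(mode_p) && !is.na(mode_m) &&
             mode_p %in% 20:22 && mode_m %in% 20:22 &&
             balanced && u_enriched_in(20:22)) {
    call <- "fungal_siRNA_like"
  } else if (!is.na(mode_p) && !is.na(mode_m) &&
             mode_p %in% 19:23 && mode_m %in% 19:23 &&
             balanced && !any_enriched_in(19:23)) {
    call <- "siRNA_insect_like"
  }
  structure(call, strand_ratio = ratio, modal_size = mode_all,
            strand_ratio_range = strand_ratio_range)
}

#' Cluster small-RNA size profiles
#'
#' Pearson correlation of the Z-score vectors (42 cells: sizes 15-35 on each
#' strand), then UPGMA clustering with the all-pairs `r >= threshold` cut of
#' [cluster_by_correlation()].
#'
#' @param profiles Named list of [size_profile()] objects.
#' @param threshold Minimum pairwise Pearson r within a cluster.
#' @return A `correlation_clustering`.
#' @export
profile_cluster <- function(profiles, threshold = 0.8) {
  stopifnot(length(profiles) >= 2L)
  vecs <- lapply(profiles, function(p) as.numeric(p$zscore))
  if (is.null(names(vecs))) {
    names(vecs) <- vapply(profiles, function(p) p$ref_id, character(1))
  }
  cluster_by_correlation(profile_correlation(vecs), threshold = threshold)
}
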