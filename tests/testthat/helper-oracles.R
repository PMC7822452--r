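# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's own code paths.

# random DNA string (uses the ambient RNG; callers wrap in withr::with_seed
# or set.seed inside test blocks)
rand_dna <- function(n, probs = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

# brute-force overlapping dinucleotide odds ratios (Karlin convention)
oracle_dinuc_odds <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  L <- length(chars)
  pairs <- paste0(chars[-L], chars[-1])
  pairs <- pairs[!grepl("N", pairs)]
  bases <- c("A", "C", "G", "T")
  fx <- table(factor(chars[chars != "N"], levels = bases))
  fx <- fx / sum(fx)
  fxy <- table(factor(pairs, levels = as.vector(outer(bases, bases, paste0))))
  fxy <- fxy / sum(fxy)
  out <- numeric(16)
  names(out) <- sort(as.vector(outer(bases, bases, paste0)))
  for (d in names(out)) {
    b <- strsplit(d, "")[[1]]
    out[d] <- fxy[[d]] / (fx[[b[1]]] * fx[[b[2]]])
  }
  out
}

# quadratic brute-force ungapped mapper: best placement by (mm, start, +<-)
oracle_map_read <- function(ref, read, max_mm) {
  L <- nchar(ref); n <- nchar(read)
  refc <- strsplit(ref, "")[[1]]
  best <- NULL
  for (strand in c("+", "-")) {
    rd <- if (strand == "+") read else mitovir::revcomp(read)
    rdc <- strsplit(rd, "")[[1]]
    for (st in 0:(L - n)) {
      mm <- sum(refc[(st + 1):(st + n)] != rdc)
      if (mm <= max_mm) {
        cand <- list(start = st, strand = strand, mm = mm)
        if (is.null(best) || mm < best$mm ||
            (mm == best$mm && st < best$start) ||
            (mm == best$mm && st == best$start && strand == "+" && best$strand == "-")) {
          best <- cand
        }
      }
    }
  }
  best
}

# brute-force recruit oracle: does read overlap a contig end / interior with
# >= min_overlap matched region and <= max_mm substitutions (either strand)?
oracle_is_recruited <- function(contig, read, min_overlap, max_mm) {
  cl <- nchar(contig); n <- nchar(read)
  cc <- strsplit(contig, "")[[1]]
  for (rd in c(read, mitovir::revcomp(read))) {
    rc <- strsplit(rd, "")[[1]]
    for (p in (-(n - min_overlap)):(cl - min_overlap)) {
      a <- max(0, -p); b <- min(n, cl - p)
      if (b - a < min_overlap) next
      idx <- (a + 1):b
      if (sum(cc[p + idx] != rc[idx]) <= max_mm) return(TRUE)
    }
  }
  FALSE
}

# hand-rolled Pearson correlation (textbook formula)
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# two vectors with an exact target Pearson correlation
vectors_with_r <- function(r, n = 10, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  z <- rnorm(n)
  z <- residuals(lm(z ~ x)) # orthogonal to x
  x <- (x - mean(x)) / sd(x)
  z <- z / sd(z)
  list(x = x, y = r * x + sqrt(1 - r^2) * z)
}

# a small GenBank flat-file fixture with known CDS strings
genbank_fixture <- function(path) {
  txt <- c(
    "LOCUS       SYNREC1                  60 bp    DNA     linear   SYN 01-JAN-2024",
    "ACCESSION   SYNREC1",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "     CDS             complement(4..12)",
    "                     /gene=\"revgene\"",
    "                     /transl_table=5",
    "     CDS             join(16..21,31..36)",
    "                     /gene=\"splitgene\"",
    "ORIGIN      ",
    "        1 atgttacatg ggtaaatggc tattcgatta agccagctaa catcagcaat ggtcagctaa",
    "//")
  writeLines(txt, path)
  path
}
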