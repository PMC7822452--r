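#' Nucleotide sequence container
#'
#' Light container for a single linear nucleotide sequence. Residues are
#' normalized on ingest: uppercased and RNA `U` converted to DNA `T`, so all
#' downstream statistics are computed in DNA space (UGA is reported as TGA in
#' codon tables; documentation uses the RNA names where the literature does).
#'
#' @param residues Character scalar over `A,C,G,T,U,N` (case-insensitive).
#' @param id Sequence identifier.
#' @return An object of class `nuc_sequence`: a list with `id` and `residues`.
#' @examples
#' s <- nuc_sequence("AUGGCU", id = "demo")
#' s$residues # "ATGGCT"
#' @export
nuc_sequence <- function(residues, id = "seq") {
  stopifnot(is.character(residues), length(residues) == 1L)
  r <- chartr("u", "t", toupper(residues))
  r <- chartr("U", "T", r)
  if (nchar(r) == 0L) stop("empty sequence")
  if (grepl("[^ACGTN]", r)) {
    bad <- regmatches(r, regexpr("[^ACGTN]", r))
    stop("invalid residue '", bad, "' in sequence '", id, "'")
  }
  structure(list(id = as.character(id), residues = r), class = "nuc_sequence")
}

#' @export
print.nuc_sequence <- function(x, ...) {
  n <- nchar(x$residues)
  cat("<nuc_sequence> ", x$id, ": ", n, " nt\n", sep = "")
  cat(" ", if (n > 60) paste0(substr(x$residues, 1, 57), "...") else x$residues, "\n")
  invisible(x)
}

#' @export
length.nuc_sequence <- function(x) nchar(x$residues)

# Coerce character / Biostrings input to nuc_sequence.
as_nuc_sequence <- function(x, id = "seq") {
  if (inherits(x, "nuc_sequence")) return(x)
  if (methods::is(x, "DNAString") || methods::is(x, "RNAString")) {
    return(nuc_sequence(as.character(x), id = id))
  }
  nuc_sequence(as.character(x), id = id)
}

#' Reverse complement of a nucleotide string
#'
#' @param x Character scalar or `nuc_sequence`.
#' @return Character scalar (the reverse complement; `N` maps to `N`).
#' @export
revcomp <- function(x) {
  s <- if (inherits(x, "nuc_sequence")) x$residues else toupper(x)
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]), collapse = "")
}

#' Genetic code table
#'
#' Wraps the NCBI translation tables as shipped with Biostrings. The tables
#' relevant to mitovirus work are 1 (standard), 4 (mold/protozoan
#' mitochondrial), 5 (invertebrate mitochondrial) and 16 (chlorophycean
#' mitochondrial). Tables 4 and 5 read TGA as tryptophan; table 16 keeps TGA
#' as a stop but reads TAG as leucine.
#'
#' @param table_id Integer NCBI translation table id (one of 1, 4, 5, 16).
#' @return An object of class `genetic_code`: list with `table_id`,
#'   `codon_to_aa` (named character vector of 64 codons, stops as `"*"`) and
#'   `stop_codons`.
#' @examples
#' genetic_code(5)$codon_to_aa[["TGA"]] # "W"
#' @export
genetic_code <- function(table_id = 5) {
  table_id <- as.integer(table_id)
  if (!table_id %in% c(1L, 4L, 5L, 16L)) {
    stop("unsupported genetic code table: ", table_id, " (supported: 1, 4, 5, 16)")
  }
  map <- Biostrings::getGeneticCode(as.character(table_id))
  structure(
    list(
      table_id = table_id,
      codon_to_aa = map,
      stop_codons = names(map)[map == "*"]
    ),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("<genetic_code> NCBI table", x$table_id,
      "| stops:", paste(x$stop_codons, collapse = ","),
      "| TGA =", x$codon_to_aa[["TGA"]], "\n")
  invisible(x)
}

# Split a nucleotide string into complete codons (trailing partial dropped).
split_codons <- function(s) {
  n <- nchar(s) %/% 3L
  if (n == 0L) return(character(0))
  substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Translate a nucleotide sequence
#'
#' One amino acid per complete codon; stop codons are rendered `*`; any codon
#' containing an ambiguous base (`N`) translates to `X`; a trailing partial
#' codon is ignored.
#'
#' @param seq A `nuc_sequence` (or character scalar).
#' @param code A [genetic_code()].
#' @param frame Reading frame offset 0, 1 or 2 on the reading strand.
#' @param strand `"+"` to read the sequence as given, `"-"` to read its
#'   reverse complement.
#' @return Protein string.
#' @examples
#' translate_seq("ATGTGATAA", genetic_code(5)) # "MW*"
#' translate_seq("ATGTGATAA", genetic_code(1)) # "M**"
#' @export
translate_seq <- function(seq, code = genetic_code(5), frame = 0, strand = "+") {
  seq <- as_nuc_sequence(seq)
  stopifnot(inherits(code, "genetic_code"), frame %in% 0:2, strand %in% c("+", "-"))
  s <- if (strand == "-") revcomp(seq) else seq$residues
  if (nchar(s) < frame + 3) stop("sequence shorter than one codon in frame ", frame)
  s <- substr(s, frame + 1L, nchar(s))
  codons <- split_codons(s)
  aa <- unname(code$codon_to_aa[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Open reading frame record
#'
#' Constructor used internally by [find_orfs()]. Coordinates are 0-based
#' half-open on the + strand of the scanned sequence; `end` includes the
#' closing stop codon when `has_stop`.
#' @keywords internal
orf_record <- function(start, end, strand, frame, protein, has_stop) {
  structure(
    list(start = start, end = end, strand = strand, frame = frame,
         aa_length = nchar(protein), protein = protein, has_stop = has_stop),
    class = "orf_record"
  )
}

#' @export
print.orf_record <- function(x, ...) {
  cat("<orf_record> [", x$start, ",", x$end, ") strand ", x$strand,
      " frame ", x$frame, " | ", x$aa_length, " aa",
      if (x$has_stop) " (stop-closed)" else " (open)", "\n", sep = "")
  invisible(x)
}

#' Find open reading frames under a genetic code
#'
#' Scans all six frames for maximal ORFs. An ORF runs from a start codon
#' (policy `ATG_only`) or from the first codon after the previous stop
#' (policy `any_sense_codon`) to the next stop codon. Coordinates are 0-based
#' half-open projected onto the + strand of `seq`; for stop-closed ORFs the
#' span includes the stop, so `aa_length = (end - start)/3 - 1`.
#'
#' This is the operation that separates mitoviruses from noise: under the
#' standard code a UGA-rich RdRp CDS fragments into short ORFs, while under a
#' mitochondrial code (UGA = Trp) a single long ORF appears.
#'
#' @param seq A `nuc_sequence`.
#' @param code A [genetic_code()].
#' @param min_codons Minimum protein length (aa) to report.
#' @param start_policy `"ATG_only"` (default) or `"any_sense_codon"`.
#' @return A data.frame of class `orf_table` sorted by `aa_length` decreasing,
#'   then start coordinate; columns `start, end, strand, frame, aa_length,
#'   protein, has_stop`.
#' @export
find_orfs <- function(seq, code = genetic_code(5), min_codons = 50,
                      start_policy = c("ATG_only", "any_sense_codon")) {
  seq <- as_nuc_sequence(seq)
  start_policy <- match.arg(start_policy)
  stopifnot(min_codons >= 1)
  L <- nchar(seq$residues)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "-") revcomp(seq) else seq$residues
    for (frame in 0:2) {
      ncod <- (L - frame) %/% 3L
      if (ncod < 1L) next
      codons <- substring(s, frame + 3L * (seq_len(ncod) - 1L) + 1L,
                          frame + 3L * seq_len(ncod))
      aa <- unname(code$codon_to_aa[codons])
      aa[is.na(aa)] <- "X"
      is_stop <- aa == "*"
      # segment boundaries: stops close segments
      seg_end <- which(is_stop)
      starts_of_seg <- c(1L, seg_end + 1L)
      ends_of_seg <- c(seg_end, ncod)           # codon index of stop (or last codon)
      closed <- c(rep(TRUE, length(seg_end)), FALSE)
      for (k in seq_along(starts_of_seg)) {
        a <- starts_of_seg[k]; b <- ends_of_seg[k]
        if (a > b) next
        last_sense <- if (closed[k]) b - 1L else b
        if (last_sense < a) next
        first <- if (start_policy == "ATG_only") {
          hit <- which(codons[a:last_sense] == "ATG")
          if (length(hit) == 0L) next
          a + hit[1L] - 1L
        } else a
        n_aa <- last_sense - first + 1L
        if (n_aa < min_codons) next
        # codon index range [first, b] in reading-strand coords
        rs_start <- frame + 3L * (first - 1L)          # 0-based on reading strand
        rs_end <- frame + 3L * b                       # half-open, includes stop if closed
        if (strand == "+") {
          st <- rs_start; en <- rs_end
        } else {
          st <- L - rs_end; en <- L - rs_start
        }
        out[[length(out) + 1L]] <- list(
          start = st, end = en, strand = strand, frame = frame,
          aa_length = n_aa,
          protein = paste(aa[first:last_sense], collapse = ""),
          has_stop = closed[k]
        )
      }
    }
  }
  if (length(out) == 0L) {
    df <- data.frame(start = integer(0), end = integer(0), strand = character(0),
                     frame = integer(0), aa_length = integer(0),
                     protein = character(0), has_stop = logical(0),
                     stringsAsFactors = FALSE)
  } else {
    df <- do.call(rbind, lapply(out, as.data.frame, stringsAsFactors = FALSE))
    df <- df[order(-df$aa_length, df$start, df$strand), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("orf_table", "data.frame")
  df
}

#' Base composition of a sequence
#'
#' `N` bases are excluded from the denominator, so `AT_percent + GC_percent`
#' is always 100 for sequences with at least one unambiguous base.
#'
#' @param seq A `nuc_sequence`.
#' @return List with `AT_percent`, `GC_percent`, and `base_fractions`
#'   (named numeric over A, C, G, T).
#' @examples
#' base_composition(nuc_sequence("ACGT"))$AT_percent # 50
#' @export
base_composition <- function(seq) {
  seq <- as_nuc_sequence(seq)
  counts <- table(factor(strsplit(seq$residues, "", fixed = TRUE)[[1]],
                         levels = c("A", "C", "G", "T", "N")))
  n <- sum(counts[c("A", "C", "G", "T")])
  if (n == 0L) stop("sequence '", seq$id, "' has no unambiguous bases")
  frac <- as.numeric(counts[c("A", "C", "G", "T")]) / n
  names(frac) <- c("A", "C", "G", "T")
  list(
    AT_percent = 100 * (frac[["A"]] + frac[["T"]]),
    GC_percent = 100 * (frac[["C"]] + frac[["G"]]),
    base_fractions = frac
  )
}

#' Scan for an ambigrammatic (reverse-frame) ORF
#'
#' Some narnaviruses keep a second long ORF on the reverse complement of
#' their RdRp CDS, maintained by avoiding the codons CTA, TTA and TCA (the
#' reverse complements of the stop codons). Mitoviruses do not. This scan
#' reports the longest reverse-strand ORF overlapping a given forward ORF and
#' an observed/expected odds ratio for the three avoided codons, with the
#' expectation computed from the CDS mononucleotide composition.
#'
#' @param seq A `nuc_sequence`.
#' @param fwd_orf One row of a [find_orfs()] table (or an equivalent list with
#'   `start`, `end`, `strand = "+"`).
#' @param code A [genetic_code()].
#' @param min_codons Minimum reverse ORF length to report.
#' @return List with `reverse_orf` (row of an `orf_table`, or `NULL`),
#'   `avoided_codon_stat` (observed/expected ratio; 0 when the CDS contains
#'   none of the three codons) and the underlying counts.
#' @export
ambigram_scan <- function(seq, fwd_orf, code = genetic_code(5), min_codons = 50) {
  seq <- as_nuc_sequence(seq)
  stopifnot(fwd_orf$strand == "+", fwd_orf$start >= 0,
            fwd_orf$end <= nchar(seq$residues))
  cds <- substr(seq$residues, fwd_orf$start + 1L, fwd_orf$end)
  codons <- split_codons(cds)
  # drop terminal stop from the codon pool if present
  if (length(codons) && !is.na(code$codon_to_aa[codons[length(codons)]]) &&
      code$codon_to_aa[codons[length(codons)]] == "*") {
    codons <- codons[-length(codons)]
  }
  avoided <- c("CTA", "TTA", "TCA")
  obs <- sum(codons %in% avoided)
  comp <- base_composition(nuc_sequence(paste(codons, collapse = ""), id = "cds"))
  f <- comp$base_fractions
  p <- vapply(avoided, function(cd) {
    b <- strsplit(cd, "", fixed = TRUE)[[1]]
    f[[b[1]]] * f[[b[2]]] * f[[b[3]]]
  }, numeric(1))
  expected <- length(codons) * sum(p)
  stat <- if (obs == 0) 0 else obs / expected
  # longest reverse-strand ORF overlapping the forward ORF
  rev_orfs <- find_orfs(seq, code, min_codons = min_codons,
                        start_policy = "any_sense_codon")
  rev_orfs <- rev_orfs[rev_orfs$strand == "-" &
                         rev_orfs$end > fwd_orf$start &
                         rev_orfs$start < fwd_orf$end, , drop = FALSE]
  reverse_orf <- if (nrow(rev_orfs)) rev_orfs[1, , drop = FALSE] else NULL
  list(reverse_orf = reverse_orf, avoided_codon_stat = stat,
       avoided_codon_count = obs, avoided_codon_expected = expected,
       n_codons = length(codons))
}

#' Coding-sequence set
#'
#' A set of in-frame nucleotide coding sequences with their genetic-code
#' context; the unit of codon-usage and tryptophan-codon analysis.
#'
#' @param cds Character vector of in-frame CDS strings (DNA; may include the
#'   terminal stop codon).
#' @param source Source identifiers (recycled).
#' @param code_id NCBI translation table ids (recycled).
#' @return Object of class `cds_set`: data.frame with columns
#'   `source`, `cds`, `code_id`.
#' @export
cds_set <- function(cds = character(0), source = "cds", code_id = 5L) {
  cds <- toupper(chartr("Uu", "Tt", cds))
  if (length(cds) && any(nchar(cds) %% 3L != 0L)) {
    stop("CDS length not divisible by 3 at index ",
         which(nchar(cds) %% 3L != 0L)[1])
  }
  df <- data.frame(source = rep_len(as.character(source), length(cds)),
                   cds = as.character(cds),
                   code_id = rep_len(as.integer(code_id), length(cds)),
                   stringsAsFactors = FALSE)
  class(df) <- c("cds_set", "data.frame")
  df
}

#' @export
print.cds_set <- function(x, ...) {
  cat("<cds_set> ", nrow(x), " CDS, ",
      sum(nchar(x$cds)) %/% 3L, " codons total\n", sep = "")
  invisible(x)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return List of `nuc_sequence` objects (named by id).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(x), function(i) {
    nuc_sequence(as.character(x[[i]]), id = sub("\\s.*$", "", names(x)[i]))
  })
  names(out) <- vapply(out, function(s) s$id, character(1))
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs A `nuc_sequence` or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "nuc_sequence")) seqs <- list(seqs)
  set <- Biostrings::DNAStringSet(vapply(seqs, function(s) s$residues, character(1)))
  names(set) <- vapply(seqs, function(s) s$id, character(1))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Summary statistics of a (viral) genome sequence
#'
#' Convenience wrapper reproducing the headline numbers used to describe a
#' mitovirus genome: length, AT/GC content, the longest ORF under a
#' mitochondrial genetic code, and the UGA(Trp) percentage of that ORF.
#'
#' @param seq A `nuc_sequence`.
#' @param code A [genetic_code()] used for the ORF scan (default table 5).
#' @param min_codons Minimum ORF length for the scan.
#' @return List with `length_nt`, `GC_percent`, `AT_percent`, `orf_aa_length`,
#'   `orf` (top `orf_table` row or NULL), `uga_trp_percent`.
#' @export
genome_stats <- function(seq, code = genetic_code(5), min_codons = 100) {
  seq <- as_nuc_sequence(seq)
  comp <- base_composition(seq)
  orfs <- find_orfs(seq, code, min_codons = min_codons)
  orf <- if (nrow(orfs)) orfs[1, , drop = FALSE] else NULL
  uga <- NA_real_
  if (!is.null(orf)) {
    cs <- cds_set(substr(seq$residues, orf$start + 1L, orf$end),
                  source = seq$id, code_id = code$table_id)
    uga <- trp_codon_stats(cs, code)$uga_trp_percent
  }
  list(length_nt = nchar(seq$residues),
       GC_percent = comp$GC_percent, AT_percent = comp$AT_percent,
       orf_aa_length = if (is.null(orf)) NA_integer_ else orf$aa_length,
       orf = orf, uga_trp_percent = uga)
}
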