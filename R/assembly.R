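# Seed-driven progressive assembly, desk-scale: iteratively recruit reads
# that overlap the current contig and extend each end by majority-vote
# consensus of the overhanging bases. Ungapped overlaps only (substitutions,
# no indels), matching the synthetic read generator's error model.

#' Recruit reads overlapping a contig
#'
#' A read is recruited when it has an ungapped placement against the contig
#' (either strand) whose overlapping region spans at least `min_overlap`
#' bases with at most `max_mm` substitutions. The placement may hang off
#' either contig end (those reads drive extension) or lie fully interior
#' (those support the consensus but cannot extend).
#'
#' @param contig A [nuc_sequence()].
#' @param reads A [read_set()] or character vector.
#' @param min_overlap Minimum overlap length (>= 15).
#' @param max_mm Maximum substitutions within the overlap.
#' @return data.frame with one row per recruited read: `read_id`, `seq`
#'   (oriented to the contig strand), `pos` (0-based placement of the read's
#'   first base, may be negative), `strand`, `mismatches`, `overlap`.
#' @export
recruit_reads <- function(contig, reads, min_overlap = 20L, max_mm = 1L) {
  contig <- as_nuc_sequence(contig)
  if (min_overlap < 15L) stop("min_overlap must be >= 15")
  if (!inherits(reads, "read_set")) reads <- read_set(reads)
  hits <- cpp_overlap_scan(contig$residues, reads$seq,
                           as.integer(min_overlap), as.integer(max_mm))
  seqs <- reads$seq[hits$read]
  flip <- hits$strand == "-"
  seqs[flip] <- vapply(seqs[flip], revcomp, character(1), USE.NAMES = FALSE)
  data.frame(read_id = reads$id[hits$read], seq = seqs, pos = hits$pos,
             strand = hits$strand, mismatches = hits$mismatches,
             overlap = hits$overlap, stringsAsFactors = FALSE)
}

# majority-vote consensus over a list of overhang strings (offset-aligned at
# 1); returns the extension string, stopping at the first offset with depth
# < min_depth; ties broken by lexicographic base order (A < C < G < T)
consensus_extension <- function(overhangs, min_depth) {
  if (length(overhangs) == 0L) return("")
  maxlen <- max(nchar(overhangs))
  out <- character(0)
  for (i in seq_len(maxlen)) {
    bases <- substr(overhangs, i, i)
    bases <- bases[bases != ""]
    bases <- bases[bases %in% c("A", "C", "G", "T")]
    if (length(bases) < min_depth) break
    counts <- table(factor(bases, levels = c("A", "C", "G", "T")))
    out <- c(out, names(counts)[which.max(counts)]) # which.max: first = lexicographic
  }
  paste(out, collapse = "")
}

#' Seed-driven progressive assembly
#'
#' Starting from a seed contig, repeatedly: recruit overlapping reads
#' ([recruit_reads()]), extend each contig end with the majority-vote
#' consensus of the overhanging read bases (positions supported by fewer
#' than `min_depth` overhangs are not called), and stop when neither end
#' extends or `max_rounds` is reached. Deterministic: consensus ties break by
#' lexicographic base order.
#'
#' @param seed A [nuc_sequence()] seed (length >= `min_overlap`).
#' @param reads A [read_set()].
#' @param min_overlap Minimum read-contig overlap.
#' @param max_mm Maximum substitutions within an overlap.
#' @param min_depth Minimum overhang depth to call an extension base.
#' @param max_rounds Round cap.
#' @return Object of class `assembly_result`: list with `contig` (a
#'   [nuc_sequence()]), `rounds`, `log` (per-round data.frame with
#'   `left_ext`, `right_ext`, `reads_recruited`), `reads_used` (count of
#'   distinct recruited reads). Finding no recruitable read in round 1 is not
#'   an error: the result is the seed with `rounds = 0`.
#' @export
progressive_assemble <- function(seed, reads, min_overlap = 20L, max_mm = 1L,
                                 min_depth = 2L, max_rounds = 100L) {
  seed <- as_nuc_sequence(seed)
  if (nchar(seed$residues) < min_overlap) {
    stop("seed shorter than min_overlap")
  }
  if (!inherits(reads, "read_set")) reads <- read_set(reads)
  contig <- seed$residues
  used <- character(0)
  log_rows <- list()
  rounds <- 0L
  repeat {
    if (rounds >= max_rounds) break
    rec <- recruit_reads(nuc_sequence(contig, id = seed$id), reads,
                         min_overlap = min_overlap, max_mm = max_mm)
    if (nrow(rec) == 0L) break
    used <- union(used, rec$read_id)
    cl <- nchar(contig)
    # right overhangs: read tail beyond the contig end
    right <- rec[rec$pos + nchar(rec$seq) > cl, , drop = FALSE]
    right_oh <- substr(right$seq, cl - right$pos + 1L, nchar(right$seq))
    # left overhangs: read head before contig start, reversed so offset 1 is
    # adjacent to the contig
    left <- rec[rec$pos < 0L, , drop = FALSE]
    left_oh <- vapply(substr(left$seq, 1L, -left$pos), function(s) {
      paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
    ext_r <- consensus_extension(right_oh, min_depth)
    ext_l_rev <- consensus_extension(left_oh, min_depth)
    ext_l <- paste(rev(strsplit(ext_l_rev, "", fixed = TRUE)[[1]]), collapse = "")
    rounds <- rounds + 1L
    log_rows[[rounds]] <- data.frame(
      round = rounds, left_ext = nchar(ext_l), right_ext = nchar(ext_r),
      reads_recruited = nrow(rec), contig_length = nchar(contig) +
        nchar(ext_l) + nchar(ext_r))
    if (nchar(ext_l) == 0L && nchar(ext_r) == 0L) break
    contig <- paste0(ext_l, contig, ext_r)
  }
  structure(list(
    contig = nuc_sequence(contig, id = paste0(seed$id, "_assembled")),
    rounds = rounds,
    log = if (length(log_rows)) do.call(rbind, log_rows) else
      data.frame(round = integer(0), left_ext = integer(0),
                 right_ext = integer(0), reads_recruited = integer(0),
                 contig_length = integer(0)),
    reads_used = length(used)
  ), class = "assembly_result")
}

#' @export
print.assembly_result <- function(x, ...) {
  cat("<assembly_result> ", nchar(x$contig$residues), " nt after ",
      x$rounds, " round(s), ", x$reads_used, " reads used\n", sep = "")
  invisible(x)
}

#' Identity between a contig and a reference
#'
#' Helper for assessing assembly recovery against a known truth: aligns the
#' contig (either orientation) to the reference with a global-local pairwise
#' alignment and reports the percent identity of the better orientation.
#'
#' @param contig,ref [nuc_sequence()] objects.
#' @return List with `identity` (fraction of aligned contig bases matching
#'   the reference) and `length_fraction` (contig length / reference length).
#' @export
assembly_identity <- function(contig, ref) {
  contig <- as_nuc_sequence(contig); ref <- as_nuc_sequence(ref)
  subject <- Biostrings::DNAString(ref$residues)
  best <- 0
  for (s in c(contig$residues, revcomp(contig))) {
    aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(s), subject,
                                         type = "global-local")
    best <- max(best, Biostrings::pid(aln) / 100)
  }
  list(identity = best,
       length_fraction = nchar(contig$residues) / nchar(ref$residues))
}
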