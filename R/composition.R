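# Compositional signatures: dinucleotide odds ratios, codon usage tables,
# UGA/UGG tryptophan statistics, and Pearson/UPGMA correlation clustering.
# These are the genome-intrinsic half of the host-assignment evidence.

#' Dinucleotide odds-ratio profile
#'
#' Overlapping dinucleotide frequencies divided by their expectation. The
#' default expectation is the Karlin convention: `expected f(xy) = f(x) f(y)`
#' from the mononucleotide composition of the same strand, so the 16 ratios
#' measure neighbor dependence net of base composition. `expectation =
#' "uniform"` instead compares each dinucleotide frequency against 1/16
#' (the EMBOSS compseq default).
#'
#' @param seq A [nuc_sequence()]. Windows containing `N` are skipped.
#' @param expectation `"karlin"` (default) or `"uniform"`.
#' @return Object of class `dinucleotide_profile`: named numeric vector of 16
#'   odds ratios (AA, AC, ... TT) with attributes `id`, `expectation`, `n_windows`.
#' @examples
#' p <- dinucleotide_odds(nuc_sequence(strrep("A", 1000)))
#' p[["AA"]] # 1
#' @export
dinucleotide_odds <- function(seq, expectation = c("karlin", "uniform")) {
  seq <- as_nuc_sequence(seq)
  expectation <- match.arg(expectation)
  L <- nchar(seq$residues)
  if (L < 2L) stop("sequence too short for dinucleotide analysis")
  if (L < 100L) warning("sequence shorter than 100 nt; odds ratios will be noisy")
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq$residues),
                                                 width = 2L)
  total <- sum(counts)
  if (total == 0L) stop("no unambiguous dinucleotide windows in '", seq$id, "'")
  fxy <- counts / total
  comp <- base_composition(seq)
  f <- comp$base_fractions
  bases <- c("A", "C", "G", "T")
  odds <- numeric(16)
  names(odds) <- names(counts)
  for (x in bases) for (y in bases) {
    d <- paste0(x, y)
    expct <- if (expectation == "karlin") f[[x]] * f[[y]] else 1 / 16
    odds[d] <- if (expct > 0) fxy[[d]] / expct else NA_real_
  }
  structure(odds, id = seq$id, expectation = expectation, n_windows = total,
            class = "dinucleotide_profile")
}

#' @export
print.dinucleotide_profile <- function(x, ...) {
  cat("<dinucleotide_profile> ", attr(x, "id"),
      " (expectation: ", attr(x, "expectation"), ")\n", sep = "")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Classify dinucleotide odds ratios as biased or unbiased
#'
#' A ratio is biased when it falls strictly outside `[lo, hi]`; the boundary
#' values themselves are classified unbiased (the interval is closed). The
#' default cutoffs 0.78 and 1.25 are the conventional over/under-representation
#' bounds used for genomic dinucleotide signatures.
#'
#' @param profile A [dinucleotide_odds()] profile.
#' @param lo,hi Unbiased interval bounds (`lo < hi`).
#' @return Named character vector over the 16 dinucleotides:
#'   `"biased"` or `"unbiased"`.
#' @export
classify_dinucleotide_bias <- function(profile, lo = 0.78, hi = 1.25) {
  stopifnot(lo < hi)
  r <- as.numeric(profile)
  out <- ifelse(r < lo | r > hi, "biased", "unbiased")
  names(out) <- names(profile)
  out
}

#' Codon usage table
#'
#' Pools codon counts over all coding sequences in a [cds_set()] and reports,
#' for each of the 64 codons, the raw count, the frequency per 1000 codons,
#' and the synonymous fraction within its amino-acid family under a stated
#' genetic code (the "proportion of usage of each codon among its redundant
#' set"). All 64 codons are always present, zeros included.
#'
#' @param cds A non-empty [cds_set()].
#' @param code A [genetic_code()] used for the amino-acid families; defaults
#'   to the table recorded on the first CDS.
#' @return Object of class `codon_usage_table`: data.frame with columns
#'   `codon`, `aa`, `count`, `per_1000`, `syn_fraction`; attribute `source`.
#' @export
codon_usage <- function(cds, code = NULL) {
  stopifnot(inherits(cds, "cds_set"))
  if (nrow(cds) == 0L || sum(nchar(cds$cds)) == 0L) stop("empty input: no codons")
  if (any(nchar(cds$cds) %% 3L != 0L)) stop("CDS length not divisible by 3")
  if (is.null(code)) code <- genetic_code(cds$code_id[1])
  codons <- unlist(lapply(cds$cds, split_codons), use.names = FALSE)
  if (any(grepl("N", codons, fixed = TRUE))) {
    codons <- codons[!grepl("N", codons, fixed = TRUE)]
  }
  all64 <- names(code$codon_to_aa)
  count <- as.integer(table(factor(codons, levels = all64)))
  total <- sum(count)
  per_1000 <- 1000 * count / total
  aa <- unname(code$codon_to_aa[all64])
  syn <- numeric(64)
  for (a in unique(aa)) {
    i <- which(aa == a)
    fam <- sum(count[i])
    syn[i] <- if (fam > 0) count[i] / fam else NA_real_
  }
  df <- data.frame(codon = all64, aa = aa, count = count,
                   per_1000 = per_1000, syn_fraction = syn,
                   stringsAsFactors = FALSE)
  attr(df, "source") <- cds$source[1]
  attr(df, "code_id") <- code$table_id
  class(df) <- c("codon_usage_table", "data.frame")
  df
}

#' UGA/UGG tryptophan codon statistics
#'
#' Under mitochondrial genetic codes (NCBI tables 4 and 5) TGA codes for
#' tryptophan instead of terminating translation, and the fraction of Trp
#' codons written as TGA tracks the AT pressure of the replication
#' compartment. This counts in-frame TGA and TGG over a CDS set, applying the
#' curation rule that a TGA occurring as the final codon of a CDS is a stop,
#' not a tryptophan, and is excluded from the TGA(Trp) count.
#'
#' @param cds A non-empty [cds_set()].
#' @param code A [genetic_code()]. Must read TGA as Trp (tables 4/5) unless
#'   `allow_standard = TRUE`, in which case internal TGAs are still counted
#'   (they are then putative read-through or annotation artifacts).
#' @param allow_standard Permit codes where TGA is a stop (tables 1/16).
#' @return Object of class `trp_codon_stats`: list with `source`, `uga_count`
#'   (internal TGA), `ugg_count`, `uga_trp_percent` (`NA` when no Trp codon is
#'   observed), `terminal_uga_count`, and `at_percent` of the CDS set.
#' @export
trp_codon_stats <- function(cds, code = genetic_code(5), allow_standard = FALSE) {
  stopifnot(inherits(cds, "cds_set"))
  if (nrow(cds) == 0L || sum(nchar(cds$cds)) == 0L) stop("empty input: no codons")
  if (code$codon_to_aa[["TGA"]] != "W" && !allow_standard) {
    stop("genetic code table ", code$table_id, " reads TGA as '",
         code$codon_to_aa[["TGA"]],
         "'; pass allow_standard = TRUE to count TGA under a standard-type code")
  }
  uga <- 0L; ugg <- 0L; term <- 0L
  for (s in cds$cds) {
    codons <- split_codons(s)
    if (length(codons) == 0L) next
    last <- codons[length(codons)]
    internal <- codons[-length(codons)]
    # the final codon: TGA there is a stop by the curation rule; any other
    # codon in last position still counts (e.g. CDS annotated without stop)
    if (last == "TGA") term <- term + 1L else internal <- c(internal, last)
    uga <- uga + sum(internal == "TGA")
    ugg <- ugg + sum(internal == "TGG")
  }
  pct <- if (uga + ugg > 0) 100 * uga / (uga + ugg) else NA_real_
  comp <- base_composition(nuc_sequence(paste(cds$cds, collapse = ""), id = "cds"))
  structure(list(source = cds$source[1], uga_count = uga, ugg_count = ugg,
                 uga_trp_percent = pct, terminal_uga_count = term,
                 at_percent = comp$AT_percent),
            class = "trp_codon_stats")
}

#' @export
print.trp_codon_stats <- function(x, ...) {
  cat("<trp_codon_stats> ", x$source, ": UGA(Trp) ", x$uga_count,
      ", UGG ", x$ugg_count, " -> UGA(Trp)% = ",
      if (is.na(x$uga_trp_percent)) "n/a" else sprintf("%.1f", x$uga_trp_percent),
      " | AT% = ", sprintf("%.2f", x$at_percent), "\n", sep = "")
  invisible(x)
}

#' Pairwise Pearson correlation of signature profiles
#'
#' @param profiles A named list of equal-length numeric vectors (codon-usage
#'   per-1000 vectors, dinucleotide odds, or small-RNA Z-score vectors), or a
#'   matrix with one profile per row.
#' @return Symmetric Pearson correlation matrix with unit diagonal. Pairs
#'   involving a zero-variance profile are `NA`.
#' @export
profile_correlation <- function(profiles) {
  m <- profiles_as_matrix(profiles)
  if (nrow(m) < 2L) stop("need at least 2 profiles")
  r <- suppressWarnings(cor(t(m), method = "pearson"))
  diag(r) <- 1
  r
}

profiles_as_matrix <- function(profiles) {
  if (is.matrix(profiles)) {
    m <- profiles
  } else if (is.list(profiles)) {
    lens <- vapply(profiles, length, integer(1))
    if (length(unique(lens)) != 1L) stop("profiles must have equal dimension")
    m <- do.call(rbind, lapply(profiles, as.numeric))
    if (!is.null(names(profiles))) rownames(m) <- names(profiles)
  } else stop("profiles must be a list or matrix")
  if (is.null(rownames(m))) rownames(m) <- paste0("p", seq_len(nrow(m)))
  m
}

#' Cluster profiles by correlation (UPGMA, all-pairs threshold)
#'
#' Builds a UPGMA dendrogram on distance `1 - r` and cuts it into the maximal
#' groups whose members are *all* pairwise correlated at `r >= threshold`
#' (strictly: a group is reported only when every internal pair meets the
#' threshold). Items that join no group of size >= 2 remain unassigned
#' singletons (`NA` cluster). Profiles with undefined correlations
#' (zero variance) are excluded from clustering and reported unassigned.
#' Labels are sorted before clustering so the result is invariant to input
#' order.
#'
#' @param corr Symmetric correlation matrix from [profile_correlation()].
#' @param threshold Minimum pairwise Pearson r within a cluster.
#' @return Object of class `correlation_clustering`: list with `labels`, `r`
#'   (the input matrix), `tree` (an `hclust`, over the clusterable items) and
#'   `cluster` (named integer vector, `NA` = unassigned singleton).
#' @export
cluster_by_correlation <- function(corr, threshold = 0.8) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  labels <- rownames(corr)
  if (is.null(labels)) labels <- paste0("p", seq_len(nrow(corr)))
  ord <- order(labels)
  corr <- corr[ord, ord, drop = FALSE]
  labels <- labels[ord]
  usable <- apply(corr, 1L, function(row) !anyNA(row))
  cluster <- setNames(rep(NA_integer_, length(labels)), labels)
  tree <- NULL
  if (sum(usable) >= 2L) {
    sub <- corr[usable, usable, drop = FALSE]
    tree <- hclust(as.dist(1 - sub), method = "average")
    groups <- list()
    # walk the dendrogram top-down; emit a node's leaf set as a cluster when
    # all pairwise correlations within it reach the threshold
    emit <- function(node) {
      leaves <- dendrogram_leaves(tree, node)
      if (length(leaves) >= 2L &&
          min(sub[leaves, leaves][lower.tri(matrix(0, length(leaves), length(leaves)))]) >=
            threshold) {
        groups[[length(groups) + 1L]] <<- leaves
        return(invisible())
      }
      if (length(leaves) <= 1L) return(invisible())
      merge_row <- tree$merge[node, ]
      for (child in merge_row) {
        if (child < 0) next else emit(child)
      }
      invisible()
    }
    emit(nrow(tree$merge))
    # groups found at internal nodes miss pairs split at the very first merge
    # only if the root test failed; leaf-only children are singletons
    for (g in seq_along(groups)) cluster[groups[[g]]] <- g
  }
  structure(list(labels = labels, r = corr, tree = tree, cluster = cluster,
                 threshold = threshold),
            class = "correlation_clustering")
}

# leaf labels under a given merge-node index of an hclust tree
dendrogram_leaves <- function(tree, node) {
  stack <- node
  leaves <- integer(0)
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    row <- tree$merge[nd, ]
    for (child in row) {
      if (child < 0) leaves <- c(leaves, -child) else stack <- c(stack, child)
    }
  }
  tree$labels[leaves]
}

#' @export
print.correlation_clustering <- function(x, ...) {
  k <- length(unique(x$cluster[!is.na(x$cluster)]))
  cat("<correlation_clustering> ", length(x$labels), " profiles, ",
      k, " cluster(s) at r >= ", x$threshold, "\n", sep = "")
  for (g in sort(unique(x$cluster[!is.na(x$cluster)]))) {
    cat("  cluster ", g, ": ",
        paste(names(x$cluster)[!is.na(x$cluster) & x$cluster == g], collapse = ", "),
        "\n", sep = "")
  }
  un <- names(x$cluster)[is.na(x$cluster)]
  if (length(un)) cat("  unassigned: ", paste(un, collapse = ", "), "\n", sep = "")
  invisible(x)
}
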