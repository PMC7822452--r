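# Abundance quantification, the exogenous-vs-EVE decision, and integration
# of all computed signatures into a multi-criterion host-evidence report.

#' Reads-per-million abundance
#'
#' @param mapped Mapped read count.
#' @param total Library size (> 0, >= mapped).
#' @param library_id,ref_id Identifiers recorded on the record.
#' @return Object of class `abundance_record`: list with `library_id`,
#'   `ref_id`, `mapped`, `total`, `rpm` (exact; printed to 2 decimals).
#' @examples
#' rpm_abundance(10, 1e6)$rpm # 10
#' @export
rpm_abundance <- function(mapped, total, library_id = "lib", ref_id = "ref") {
  if (total <= 0) stop("total must be > 0")
  if (mapped < 0 || mapped > total) stop("mapped must be in [0, total]")
  structure(list(library_id = library_id, ref_id = ref_id,
                 mapped = as.numeric(mapped), total = as.numeric(total),
                 rpm = mapped * 1e6 / total),
            class = "abundance_record")
}

#' @export
print.abundance_record <- function(x, ...) {
  cat("<abundance_record> ", x$library_id, " vs ", x$ref_id, ": ",
      x$mapped, "/", x$total, " = ", sprintf("%.2f", x$rpm), " RPM\n", sep = "")
  invisible(x)
}

#' Exogenous-virus versus endogenous-viral-element call
#'
#' A replicating RNA virus with no DNA stage leaves abundant RNA reads but no
#' DNA reads; an endogenous viral element (EVE) leaves DNA reads. The host
#' mitochondrial RPM in the same DNA library acts as the positive control:
#' without it, absence of viral DNA reads is uninformative.
#'
#' * `exogenous` — control DNA RPM at least `min_control_rpm`, viral DNA RPM
#'   at most `max_virus_dna_rpm`, and viral RNA RPM positive.
#' * `candidate_EVE` — viral DNA RPM above `max_virus_dna_rpm`.
#' * `indeterminate` — anything else (e.g. failed positive control).
#'
#' @param dna_virus_rpm Viral RPM in the DNA library.
#' @param dna_control_rpm Host-mitochondrial RPM in the DNA library.
#' @param rna_virus_rpm Viral RPM in an RNA library.
#' @param min_control_rpm Positive-control floor (default 10).
#' @param max_virus_dna_rpm Maximum viral DNA RPM still read as absence
#'   (default 0.1; the paper-scale observation is "complete absence", so the
#'   default is conservative and configurable).
#' @return Character scalar: `"exogenous"`, `"candidate_EVE"` or
#'   `"indeterminate"`.
#' @export
eve_call <- function(dna_virus_rpm, dna_control_rpm, rna_virus_rpm,
                     min_control_rpm = 10, max_virus_dna_rpm = 0.1) {
  if (dna_virus_rpm > max_virus_dna_rpm) return("candidate_EVE")
  if (dna_control_rpm >= min_control_rpm && rna_virus_rpm > 0) return("exogenous")
  "indeterminate"
}

#' Compute the signature bundle of a candidate host mitochondrion
#'
#' @param label Candidate label.
#' @param type `"insect_mito"` or `"fungal_mito"`.
#' @param cds A [cds_set()] of mitochondrial coding sequences.
#' @param genome Optional [nuc_sequence()] for AT/dinucleotide statistics
#'   (default: the concatenated CDS).
#' @return List with `label`, `type`, `at_percent`, `uga_trp_percent`,
#'   `codon_per1000`, `dinuc`.
#' @export
host_signatures <- function(label, type = c("insect_mito", "fungal_mito"),
                            cds, genome = NULL) {
  type <- match.arg(type)
  code <- genetic_code(cds$code_id[1])
  if (is.null(genome)) {
    genome <- nuc_sequence(paste(cds$cds, collapse = ""), id = label)
  }
  cu <- codon_usage(cds, code)
  trp <- trp_codon_stats(cds, code, allow_standard = TRUE)
  list(label = label, type = type,
       at_percent = base_composition(genome)$AT_percent,
       uga_trp_percent = trp$uga_trp_percent,
       codon_per1000 = setNames(cu$per_1000, cu$codon),
       dinuc = as.numeric(dinucleotide_odds(genome)))
}

#' Compute the signature bundle of a viral genome
#'
#' Runs the compositional pipeline on a viral genome: base composition,
#' longest ORF under `code`, codon usage and UGA(Trp) statistics of that ORF,
#' and the dinucleotide odds profile.
#'
#' @param seq Viral genome [nuc_sequence()].
#' @param code [genetic_code()] for the ORF scan.
#' @param min_codons Minimum ORF size.
#' @return List with `label`, `at_percent`, `orf_aa_length`,
#'   `uga_trp_percent`, `codon_per1000`, `dinuc`.
#' @export
virus_signatures <- function(seq, code = genetic_code(5), min_codons = 100) {
  seq <- as_nuc_sequence(seq)
  gs <- genome_stats(seq, code, min_codons = min_codons)
  if (is.null(gs$orf)) stop("no ORF of >= ", min_codons, " codons found")
  cds <- cds_set(substr(seq$residues, gs$orf$start + 1L, gs$orf$end),
                 source = seq$id, code_id = code$table_id)
  cu <- codon_usage(cds, code)
  list(label = seq$id, at_percent = gs$AT_percent,
       orf_aa_length = gs$orf_aa_length,
       uga_trp_percent = gs$uga_trp_percent,
       codon_per1000 = setNames(cu$per_1000, cu$codon),
       dinuc = as.numeric(dinucleotide_odds(seq)))
}

verdict_for_type <- function(type) {
  if (is.na(type)) "neutral"
  else if (type == "insect_mito") "supports_insect_mito"
  else "supports_fungal"
}

#' Integrate all signatures into a host-evidence report
#'
#' Operationalizes the eight-point body of evidence used to host-assign a
#' mitovirus. Criteria 1 (phylogeny) and 7 (wet-lab confirmation) are outside
#' this package and reported `not_evaluated`. The computable criteria:
#'
#' 2. AT-content closeness: the virus supports the host type whose candidate
#'    mitochondrion has the closest AT%, when the two types differ by more
#'    than `at_margin` points.
#' 3. Codon-usage cluster co-membership at Pearson r >= `cluster_threshold`
#'    (UPGMA, all-pairs rule).
#' 4. UGA(Trp) concordance, margin `uga_margin` points.
#' 5. Dinucleotide-profile correlation (highest mean r per type, margin
#'    `dinuc_margin`).
#' 6. Small-RNA signature class: insect-siRNA-like supports the insect host,
#'    fungal-siRNA-like the fungal host; a piRNA-like class is evidence of an
#'    endogenous element, not of replication, and is neutral here but blocks
#'    the overall call (below).
#' 8. Abundance + EVE: detection in at least half of the RNA libraries at
#'    RPM >= `prevalence_min_rpm` together with an `exogenous` EVE status
#'    supports the host type indicated by the small-RNA class.
#'
#' Overall call: a host type is called when at least `min_support` evaluated
#' criteria support it and none supports the alternative, *and* the data do
#' not contradict active exogenous replication (a piRNA-like small-RNA class
#' or a `candidate_EVE` status forces `indeterminate`). Every verdict is
#' reported with its underlying numbers so the rule can be overridden.
#'
#' @param virus [virus_signatures()] bundle.
#' @param candidates List of [host_signatures()] bundles (both types ideally
#'   represented; with no candidates only virus-intrinsic criteria report).
#' @param srna_class Output of [classify_signature()] (optional).
#' @param abundance List of RNA-library [rpm_abundance()] records (optional).
#' @param eve_status Output of [eve_call()] (optional).
#' @param config Named list overriding `at_margin` (2), `uga_margin` (10),
#'   `dinuc_margin` (0.05), `dinuc_min_r` (0.5), `cluster_threshold` (0.8),
#'   `prevalence_min_rpm`
#'   (1), `min_support` (4).
#' @return Object of class `evidence_report`: list with `criteria`
#'   (data.frame: `criterion`, `description`, `verdict`, `detail`),
#'   `overall_call` (`"insect_mitochondrial"`, `"fungal"`, or
#'   `"indeterminate"`), `eve_status`, `config`.
#' @export
integrate_evidence <- function(virus, candidates = list(), srna_class = NULL,
                               abundance = NULL, eve_status = NULL,
                               config = list()) {
  cfg <- modifyList(list(at_margin = 2, uga_margin = 10, dinuc_margin = 0.05,
                         dinuc_min_r = 0.5, cluster_threshold = 0.8,
                         prevalence_min_rpm = 1, min_support = 4), config)
  types <- vapply(candidates, function(c) c$type, character(1))
  has_both <- all(c("insect_mito", "fungal_mito") %in% types)

  crit <- list()
  add <- function(id, description, verdict, detail) {
    crit[[length(crit) + 1L]] <<- data.frame(
      criterion = id, description = description, verdict = verdict,
      detail = detail, stringsAsFactors = FALSE)
  }

  add(1L, "sequence similarity and phylogenetic placement", "not_evaluated",
      "requires external phylogenetics")

  nearest_type <- function(value, field, margin) {
    if (!has_both || is.na(value)) return(list(type = NA_character_, detail = "no candidates"))
    d <- vapply(candidates, function(c) abs(value - c[[field]]), numeric(1))
    best <- vapply(split(d, types), min, numeric(1))
    gap <- abs(diff(sort(best)[1:2]))
    list(type = if (gap > margin) names(best)[which.min(best)] else NA_character_,
         detail = sprintf("virus %.2f; nearest insect %.2f, fungal %.2f",
                          value, best[["insect_mito"]], best[["fungal_mito"]]))
  }

  at <- nearest_type(virus$at_percent, "at_percent", cfg$at_margin)
  add(2L, "AT content closeness to candidate mitochondria",
      if (has_both) verdict_for_type(at$type) else "not_evaluated", at$detail)

  if (has_both) {
    vecs <- c(list(virus = virus$codon_per1000),
              setNames(lapply(candidates, function(c) c$codon_per1000),
                       vapply(candidates, function(c) c$label, character(1))))
    cl <- cluster_by_correlation(profile_correlation(vecs),
                                 threshold = cfg$cluster_threshold)
    vg <- cl$cluster[["virus"]]
    mates <- if (is.na(vg)) character(0) else
      setdiff(names(cl$cluster)[!is.na(cl$cluster) & cl$cluster == vg], "virus")
    mate_types <- unique(types[match(mates, vapply(candidates, function(c) c$label,
                                                   character(1)))])
    ctype <- if (length(mate_types) == 1L) mate_types else NA_character_
    add(3L, "codon-usage cluster co-membership",
        verdict_for_type(ctype),
        if (length(mates)) paste("virus clusters with:", paste(mates, collapse = ", "))
        else "virus unclustered at threshold")
  } else {
    add(3L, "codon-usage cluster co-membership", "not_evaluated", "no candidates")
  }

  uga <- nearest_type(virus$uga_trp_percent, "uga_trp_percent", cfg$uga_margin)
  add(4L, "UGA(Trp) usage concordance",
      if (has_both) verdict_for_type(uga$type) else "not_evaluated", uga$detail)

  if (has_both) {
    r <- vapply(candidates, function(c)
      suppressWarnings(cor(virus$dinuc, c$dinuc)), numeric(1))
    mean_r <- vapply(split(r, types), mean, numeric(1))
    gap <- abs(diff(mean_r))
    # support requires a substantive positive correlation, not just a gap:
    # profiles without real dinucleotide structure correlate near 0 and are
    # uninformative in either direction
    dtype <- if (!anyNA(mean_r) && gap > cfg$dinuc_margin &&
                 max(mean_r) >= cfg$dinuc_min_r)
      names(mean_r)[which.max(mean_r)] else NA_character_
    add(5L, "dinucleotide-profile correlation", verdict_for_type(dtype),
        sprintf("mean r: insect %.3f, fungal %.3f",
                mean_r[["insect_mito"]], mean_r[["fungal_mito"]]))
  } else {
    add(5L, "dinucleotide-profile correlation", "not_evaluated", "no candidates")
  }

  srna_dir <- NA_character_
  if (is.null(srna_class)) {
    add(6L, "small-RNA signature class", "not_evaluated", "no small-RNA data")
  } else {
    cls <- as.character(srna_class)
    srna_dir <- switch(cls, siRNA_insect_like = "insect_mito",
                       fungal_siRNA_like = "fungal_mito", NA_character_)
    add(6L, "small-RNA signature class", verdict_for_type(srna_dir), cls)
  }

  add(7L, "RT-PCR / Sanger confirmation", "not_evaluated", "wet lab")

  if (is.null(abundance) || is.null(eve_status)) {
    add(8L, "library prevalence and EVE status", "not_evaluated",
        "no abundance/DNA data")
  } else {
    rpms <- vapply(abundance, function(a) a$rpm, numeric(1))
    prev <- mean(rpms >= cfg$prevalence_min_rpm)
    ptype <- if (prev >= 0.5 && identical(eve_status, "exogenous"))
      srna_dir else NA_character_
    add(8L, "library prevalence and EVE status", verdict_for_type(ptype),
        sprintf("detected in %.0f%% of RNA libraries; EVE status %s",
                100 * prev, eve_status))
  }

  criteria <- do.call(rbind, crit)
  n_insect <- sum(criteria$verdict == "supports_insect_mito")
  n_fungal <- sum(criteria$verdict == "supports_fungal")
  blocked <- identical(as.character(srna_class), "piRNA_like") ||
    identical(eve_status, "candidate_EVE")
  overall <- "indeterminate"
  if (!blocked) {
    if (n_insect >= cfg$min_support && n_fungal == 0L) {
      overall <- "insect_mitochondrial"
    } else if (n_fungal >= cfg$min_support && n_insect == 0L) {
      overall <- "fungal"
    }
  }
  structure(list(criteria = criteria, overall_call = overall,
                 eve_status = if (is.null(eve_status)) "indeterminate" else eve_status,
                 support = c(insect = n_insect, fungal = n_fungal),
                 config = cfg),
            class = "evidence_report")
}

#' @export
print.evidence_report <- function(x, ...) {
  cat("<evidence_report> overall call:", x$overall_call,
      "| EVE status:", x$eve_status, "\n")
  for (i in seq_len(nrow(x$criteria))) {
    cat(sprintf("  (%d) %-45s %s\n", x$criteria$criterion[i],
                x$criteria$description[i], x$criteria$verdict[i]))
  }
  invisible(x)
}

#' Serialize an evidence report to JSON
#'
#' @param report An [integrate_evidence()] report.
#' @param path Optional output file; when omitted the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "evidence_report"))
  j <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                        pretty = TRUE)
  if (!is.null(path)) {
    writeLines(j, path)
    return(invisible(j))
  }
  j
}
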