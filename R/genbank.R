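# Minimal GenBank flat-file support: enough to pull CDS features (with
# join/complement locations and the transl_table qualifier) out of the
# organelle and virus records this package works with. No installed R package
# parses GenBank text, hence the hand-rolled reader.

#' Read a GenBank flat file
#'
#' Parses LOCUS/ACCESSION, the FEATURES table and the ORIGIN sequence of one
#' or more records in a GenBank flat file. Only the pieces needed for CDS
#' extraction are retained.
#'
#' @param path GenBank flat file (possibly multi-record).
#' @return List of `genbank_record` objects; each has `accession`, `sequence`
#'   (a [nuc_sequence()]) and `features` (list with `key`, `location`,
#'   `qualifiers`).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ends <- which(lines == "//")
  if (length(ends) == 0L) ends <- length(lines)
  starts <- c(1L, head(ends, -1L) + 1L)
  records <- Map(function(a, b) parse_genbank_record(lines[a:b]), starts, ends)
  names(records) <- vapply(records, function(r) r$accession, character(1))
  records
}

parse_genbank_record <- function(lines) {
  acc <- "unknown"
  hit <- grep("^(ACCESSION|LOCUS)\\s+", lines, value = TRUE)
  if (length(hit)) acc <- strsplit(trimws(sub("^\\S+\\s+", "", hit[1])), "\\s+")[[1]][1]
  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  if (length(orig_i) == 0L) stop("GenBank record ", acc, ": no ORIGIN block")
  seq_lines <- lines[(orig_i[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  residues <- gsub("[0-9 ]", "", paste(seq_lines, collapse = ""))
  features <- list()
  if (length(feat_i)) {
    flines <- lines[(feat_i[1] + 1L):(orig_i[1] - 1L)]
    # a feature starts with 5 spaces + key; qualifiers/continuations are deeper
    starts <- grep("^ {5}\\S", flines)
    for (k in seq_along(starts)) {
      a <- starts[k]
      b <- if (k < length(starts)) starts[k + 1L] - 1L else length(flines)
      block <- flines[a:b]
      key <- sub("^ {5}(\\S+).*$", "\\1", block[1])
      rest <- trimws(sub("^ {5}\\S+\\s*", "", block[1]))
      body <- c(rest, trimws(block[-1]))
      qual_i <- grep("^/", body)
      loc <- paste(body[seq_len(if (length(qual_i)) qual_i[1] - 1L else length(body))],
                   collapse = "")
      quals <- list()
      if (length(qual_i)) {
        qstarts <- qual_i
        for (j in seq_along(qstarts)) {
          qa <- qstarts[j]
          qb <- if (j < length(qstarts)) qstarts[j + 1L] - 1L else length(body)
          qtxt <- paste(body[qa:qb], collapse = " ")
          qname <- sub("^/([^=]+)=?.*$", "\\1", qtxt)
          qval <- if (grepl("=", qtxt)) sub("^/[^=]+=", "", qtxt) else TRUE
          if (is.character(qval)) qval <- gsub("^\"|\"$", "", qval)
          quals[[qname]] <- qval
        }
      }
      features[[length(features) + 1L]] <-
        list(key = key, location = loc, qualifiers = quals)
    }
  }
  structure(list(accession = acc,
                 sequence = nuc_sequence(residues, id = acc),
                 features = features),
            class = "genbank_record")
}

# Parse a GenBank location string into a strand and a matrix of 1-based
# inclusive intervals. Handles complement(), join(), order() and <,> partials.
parse_gb_location <- function(loc) {
  loc <- gsub("\\s", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc)) {
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  }
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  iv <- t(vapply(parts, function(p) {
    p <- gsub("[<>]", "", p)
    if (grepl("\\.\\.", p)) {
      as.integer(strsplit(p, "..", fixed = TRUE)[[1]][1:2])
    } else {
      rep(as.integer(p), 2L)
    }
  }, integer(2)))
  list(strand = strand, intervals = iv)
}

#' Extract coding sequences from a GenBank record
#'
#' Returns each CDS feature as a spliced, strand-corrected in-frame
#' nucleotide sequence. The `transl_table` qualifier is honored when present
#' (falling back to `default_code`). A CDS whose spliced length is not a
#' multiple of 3 triggers a warning and is truncated to the last complete
#' codon.
#'
#' @param record A `genbank_record` from [read_genbank()].
#' @param default_code Translation table assumed when the feature carries no
#'   `transl_table` qualifier.
#' @return A [cds_set()] with one row per CDS feature.
#' @export
extract_cds <- function(record, default_code = 1L) {
  stopifnot(inherits(record, "genbank_record"))
  feats <- Filter(function(f) f$key == "CDS", record$features)
  if (length(feats) == 0L) stop("record ", record$accession, " has no CDS feature")
  seqs <- character(0); codes <- integer(0); ids <- character(0)
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    loc <- parse_gb_location(f$location)
    pieces <- apply(loc$intervals, 1L, function(ab) {
      substr(record$sequence$residues, ab[1], ab[2])
    })
    s <- paste(pieces, collapse = "")
    if (loc$strand == "-") s <- revcomp(s)
    if (nchar(s) %% 3L != 0L) {
      warning("CDS ", i, " of ", record$accession,
              " length not divisible by 3; truncating ",
              nchar(s) %% 3L, " trailing base(s)")
      s <- substr(s, 1L, nchar(s) - nchar(s) %% 3L)
    }
    tt <- f$qualifiers[["transl_table"]]
    codes <- c(codes, if (is.null(tt)) as.integer(default_code) else as.integer(tt))
    ids <- c(ids, paste0(record$accession, ".CDS", i))
    seqs <- c(seqs, s)
  }
  cds_set(seqs, source = ids, code_id = codes)
}
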