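# GenBank flat-file reading and writing.
#
# The parser covers the subset of the format that annotated plastomes use:
# LOCUS (length + circular/linear), DEFINITION, ACCESSION, ORGANISM,
# a FEATURES table with gene/CDS/tRNA/rRNA/repeat_region entries whose
# locations may be single intervals, join(...) compounds or complement(...)
# of either, and an ORIGIN sequence block. Compound locations are split into
# exon parts and the gaps between consecutive parts become derived `intron`
# features, so downstream class tallies can stratify by intron. Coordinates
# are kept 1-based closed as in the file.

GB_KIND_MAP <- c(gene = "gene", CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                 repeat_region = "repeat_region")

parse_gb_location <- function(loc, lineno) {
  strand <- "+"
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  if (grepl("^complement\\(", loc)) { # join(complement(..)) variants
    strand <- "-"
    loc <- gsub("complement\\(([^)]*)\\)", "\\1", loc)
  }
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([0-9]+)(\\.\\.([0-9]+))?$", parts))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad) || !length(parts))
    stopf("GenBank parse error at line %d: cannot parse location '%s'",
          lineno, loc)
  start <- vapply(m, function(x) as.integer(x[2]), 1L)
  end <- vapply(m, function(x) {
    if (nzchar(x[4])) as.integer(x[4]) else as.integer(x[2])
  }, 1L)
  list(start = start, end = end, strand = strand)
}

#' Read an annotated genome from a GenBank flat file
#'
#' Sequence is upper-cased; `join(...)` locations are split into their parts
#' (one feature with several rows in the feature table) and the gaps between
#' consecutive parts of a gene/CDS become derived `intron` features named
#' `"<gene>-intron<k>"`. The circular flag is taken from the LOCUS line.
#'
#' @param path path to a GenBank flat file containing one record.
#' @param sampleId sample identifier; defaults to the LOCUS name.
#' @param subgenus optional subgenus label to attach.
#' @return an [AnnotatedGenome-class].
#' @seealso [writeGenBank()]
#' @export
readGenBank <- function(path, sampleId = NULL, subgenus = "") {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (!length(locus_i))
    stopf("GenBank parse error: no LOCUS line in '%s'", path)
  locus <- strsplit(trimws(lines[locus_i[1]]), "\\s+")[[1]]
  locus_name <- if (length(locus) >= 2) locus[2] else "record"
  circular <- any(tolower(locus) == "circular")

  accession <- ""
  acc_i <- grep("^ACCESSION", lines)
  if (length(acc_i)) {
    acc <- strsplit(trimws(lines[acc_i[1]]), "\\s+")[[1]]
    if (length(acc) >= 2) accession <- acc[2]
  }
  species <- ""
  org_i <- grep("^\\s{0,2}ORGANISM", lines)
  if (length(org_i))
    species <- trimws(sub("^\\s*ORGANISM\\s*", "", lines[org_i[1]]))

  # ---- FEATURES table ----
  feat_i <- grep("^FEATURES", lines)
  origin_i <- grep("^ORIGIN", lines)
  if (!length(origin_i))
    stopf("GenBank parse error: no ORIGIN block in '%s'", path)
  origin_i <- origin_i[1]

  rows <- list()
  introns <- list()
  fid <- 0L
  if (length(feat_i) && feat_i[1] < origin_i) {
    i <- feat_i[1] + 1L
    while (i < origin_i) {
      line <- lines[i]
      key <- trimws(substr(line, 1, 21))
      if (nzchar(key) && !startsWith(trimws(line), "/")) {
        loc <- trimws(substr(line, 22, nchar(line)))
        lineno <- i
        # location continuation lines (no key, not a qualifier)
        j <- i + 1L
        while (j < origin_i && !nzchar(trimws(substr(lines[j], 1, 21))) &&
               !startsWith(trimws(lines[j]), "/")) {
          loc <- paste0(loc, trimws(lines[j]))
          j <- j + 1L
        }
        # qualifiers until next key
        gene_name <- NA_character_
        while (j < origin_i && !nzchar(trimws(substr(lines[j], 1, 21)))) {
          q <- trimws(lines[j])
          if (grepl("^/gene=", q) && is.na(gene_name))
            gene_name <- gsub('"', "", sub("^/gene=", "", q))
          if (grepl("^/product=", q) && is.na(gene_name))
            gene_name <- gsub('"', "", sub("^/product=", "", q))
          j <- j + 1L
        }
        if (key %in% names(GB_KIND_MAP)) {
          p <- parse_gb_location(loc, lineno)
          fid <- fid + 1L
          id <- sprintf("f%04d", fid)
          nm <- if (!is.na(gene_name)) gene_name else sprintf("%s_%d", key, fid)
          rows[[length(rows) + 1L]] <- data.frame(
            feature_id = id, kind = GB_KIND_MAP[[key]], name = nm,
            start = p$start, end = p$end, strand = p$strand,
            part = seq_along(p$start), stringsAsFactors = FALSE)
          if (length(p$start) > 1L && key %in% c("gene", "CDS")) {
            o <- order(p$start)
            s <- p$start[o]; e <- p$end[o]
            for (k in seq_len(length(s) - 1L)) {
              if (s[k + 1L] > e[k] + 1L) {
                fid <- fid + 1L
                introns[[length(introns) + 1L]] <- data.frame(
                  feature_id = sprintf("f%04d", fid), kind = "intron",
                  name = sprintf("%s-intron%d", nm, k),
                  start = e[k] + 1L, end = s[k + 1L] - 1L,
                  strand = p$strand, part = 1L, stringsAsFactors = FALSE)
              }
            }
          }
        }
        i <- j
      } else i <- i + 1L
    }
  }

  # ---- ORIGIN block ----
  seq_lines <- lines[(origin_i + 1L):length(lines)]
  end_i <- grep("^//", seq_lines)
  if (length(end_i)) seq_lines <- seq_lines[seq_len(end_i[1] - 1L)]
  seq <- toupper(gsub("[0-9 \t]", "", paste(seq_lines, collapse = "")))
  if (!nchar(seq))
    stopf("GenBank parse error: empty sequence in '%s'", path)

  # drop intron rows duplicated by both a gene and its CDS carrying the join
  ft <- do.call(rbind, c(rows, introns))
  if (is.null(ft)) ft <- emptyFeatures()
  if (nrow(ft)) {
    is_in <- ft$kind == "intron"
    key <- paste(ft$kind, ft$start, ft$end)
    keep <- !is_in | !duplicated(key)
    ft <- ft[keep, , drop = FALSE]
    rownames(ft) <- NULL
  }

  AnnotatedGenome(seq, sampleId = sampleId %||% locus_name,
                  species = species, subgenus = subgenus,
                  circular = circular, features = ft,
                  sourceAccession = accession)
}

#' Write an AnnotatedGenome as a GenBank flat file
#'
#' Multi-part features are written as `join(...)` locations. Derived feature
#' kinds (`intron`, `IGS`) are not written: they are recomputed on read from
#' the joins and the gene layout, so read-write-read is the identity on the
#' complete feature set.
#'
#' @param genome an [AnnotatedGenome-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGenBank <- function(genome, path) {
  seq <- genomeSequence(genome)
  L <- nchar(seq)
  out <- c(sprintf("LOCUS       %s %d bp    DNA     %s PLN %s",
                   sampleId(genome), L,
                   if (isCircular(genome)) "circular" else "linear",
                   format(Sys.Date(), "%d-%b-%Y")),
           sprintf("DEFINITION  %s chloroplast, complete genome.",
                   if (nzchar(genome@species)) genome@species else
                     sampleId(genome)),
           sprintf("ACCESSION   %s",
                   if (nzchar(genome@sourceAccession))
                     genome@sourceAccession else sampleId(genome)),
           sprintf("SOURCE      %s",
                   if (nzchar(genome@species)) genome@species else "."),
           sprintf("  ORGANISM  %s",
                   if (nzchar(genome@species)) genome@species else "."),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", L))
  ft <- features(genome)
  ft <- ft[!(ft$kind %in% c("intron", "IGS")), , drop = FALSE]
  gb_key <- c(gene = "gene", CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
              repeat_region = "repeat_region", misc = "misc_feature")
  for (id in unique(ft$feature_id)) {
    f <- ft[ft$feature_id == id, , drop = FALSE]
    f <- f[order(f$part), , drop = FALSE]
    loc <- paste(sprintf("%d..%d", f$start, f$end), collapse = ",")
    if (nrow(f) > 1L) loc <- sprintf("join(%s)", loc)
    if (f$strand[1] == "-") loc <- sprintf("complement(%s)", loc)
    key <- gb_key[[f$kind[1]]] %||% "misc_feature"
    out <- c(out,
             sprintf("     %-16s%s", key, loc),
             sprintf("                     /gene=\"%s\"", f$name[1]))
  }
  out <- c(out, "ORIGIN")
  starts <- seq(1L, L, by = 60L)
  for (s in starts) {
    chunk <- substr(seq, s, min(s + 59L, L))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", s, tolower(paste(tens, collapse = " "))))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}
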