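# FASTA / aligned-FASTA input and output, IGS derivation and the TSV report
# writer shared by the pipeline stages.

#' Read a whole-genome multiple alignment from aligned FASTA
#'
#' @param path aligned FASTA file; all rows must have the same length.
#' @param referenceId reference row id (annotation projection target);
#'   defaults to the first record.
#' @return a [PlastomeAlignment-class].
#' @export
readMsa <- function(path, referenceId = NULL) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  w <- nchar(seqs)
  if (length(unique(w)) > 1L)
    stopf("ragged alignment rows in '%s': %s", path,
          paste(sprintf("%s=%d", names(seqs), w), collapse = ", "))
  PlastomeAlignment(seqs, referenceId = referenceId %||% names(seqs)[1])
}

#' Write a multiple alignment (or unaligned set of genomes) as FASTA
#'
#' @param x a [PlastomeAlignment-class], or a named character vector of
#'   sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path) {
  seqs <- if (is(x, "PlastomeAlignment")) alignmentRows(x) else x
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    writeLines(substring(s, seq(1, nchar(s), 70),
                         pmin(seq(70, nchar(s) + 69, 70), nchar(s))), con)
  }
  invisible(path)
}

#' Write a report table as TSV
#'
#' All pipeline reports go through this writer: tab-separated, a fixed header
#' row, no quoting, no row names.
#'
#' @param df data frame to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeReportTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# union of gene-bearing extents (gene/CDS/tRNA/rRNA parts) as an IRanges
gene_span_ranges <- function(genome) {
  ft <- features(genome)
  ft <- ft[ft$kind %in% c("gene", "CDS", "tRNA", "rRNA"), , drop = FALSE]
  if (!nrow(ft)) return(IRanges::IRanges())
  IRanges::reduce(IRanges::IRanges(start = ft$start, end = ft$end))
}

#' Derive intergenic spacer (IGS) features
#'
#' Gaps between consecutive gene spans (the union of gene/tRNA/rRNA/CDS
#' extents, in circular genome order) become `IGS` features named
#' `"geneA-geneB"` after the flanking genes. On a circular genome the gap
#' spanning the origin is included (stored as two parts). Existing IGS
#' features are replaced.
#'
#' @param genome an [AnnotatedGenome-class] with at least one gene feature.
#' @return the genome with IGS features added; total IGS length plus gene
#'   span length equals the genome length.
#' @export
deriveIgs <- function(genome) {
  spans <- gene_span_ranges(genome)
  if (!length(spans)) stopf("deriveIgs: genome has no gene features")
  L <- genomeLength(genome)
  ft <- features(genome)
  ft <- ft[ft$kind != "IGS", , drop = FALSE]

  # name of the gene whose span covers a position (for IGS naming)
  genes <- ft[ft$kind %in% c("gene", "tRNA", "rRNA", "CDS"), , drop = FALSE]
  name_at <- function(pos) {
    hit <- genes[genes$start <= pos & genes$end >= pos, , drop = FALSE]
    if (!nrow(hit)) return("NA")
    hit <- hit[order(match(hit$kind, c("gene", "tRNA", "rRNA", "CDS"))), ]
    hit$name[1]
  }

  s <- IRanges::start(spans); e <- IRanges::end(spans)
  n <- length(spans)
  igs <- list()
  add_igs <- function(a, b, left, right, wrap_tail = NULL) {
    id <- sprintf("igs%04d", length(igs) + 1L)
    nm <- sprintf("%s-%s", left, right)
    df <- data.frame(feature_id = id, kind = "IGS", name = nm,
                     start = a, end = b, strand = "+", part = 1L,
                     stringsAsFactors = FALSE)
    if (!is.null(wrap_tail)) {
      df <- rbind(df, data.frame(feature_id = id, kind = "IGS", name = nm,
                                 start = wrap_tail[1], end = wrap_tail[2],
                                 strand = "+", part = 2L,
                                 stringsAsFactors = FALSE))
    }
    igs[[length(igs) + 1L]] <<- df
  }
  for (i in seq_len(n - 1L)) {
    if (s[i + 1L] > e[i] + 1L)
      add_igs(e[i] + 1L, s[i + 1L] - 1L, name_at(e[i]), name_at(s[i + 1L]))
  }
  # wrap gap between last span and first span (circular); linear tail kept too
  if (isCircular(genome)) {
    tail_len <- L - e[n]
    head_len <- s[1] - 1L
    if (tail_len + head_len > 0L) {
      if (tail_len > 0L && head_len > 0L)
        add_igs(e[n] + 1L, L, name_at(e[n]), name_at(s[1]),
                wrap_tail = c(1L, head_len))
      else if (tail_len > 0L)
        add_igs(e[n] + 1L, L, name_at(e[n]), name_at(s[1]))
      else
        add_igs(1L, head_len, name_at(e[n]), name_at(s[1]))
    }
  } else {
    if (e[n] < L) add_igs(e[n] + 1L, L, name_at(e[n]), "end")
    if (s[1] > 1L) add_igs(1L, s[1] - 1L, "start", name_at(s[1]))
  }
  out <- rbind(ft, do.call(rbind, c(list(emptyFeatures()), igs)))
  rownames(out) <- NULL
  methods::initialize(genome, features = out)
}

#' Total IGS length of a genome (sum over IGS feature parts)
#' @param genome an [AnnotatedGenome-class] (after [deriveIgs()]).
#' @return integer length in bp.
#' @export
igsLength <- function(genome) {
  ft <- features(genome)
  ft <- ft[ft$kind == "IGS", , drop = FALSE]
  as.integer(sum(ft$end - ft$start + 1L))
}
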