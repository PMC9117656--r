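#' @import methods
NULL

VALID_SUBGENERA <- c("Amaranthus", "Acnida", "Albersia", "outgroup")
FEATURE_KINDS <- c("gene", "CDS", "tRNA", "rRNA", "intron", "IGS",
                   "repeat_region", "misc")

#' Empty feature table
#'
#' Features are stored as a data frame with one row per feature part.
#' Coordinates are 1-based closed intervals on the genome; a feature that
#' wraps the circular origin is stored as several rows sharing one
#' `feature_id`, with `part` giving genome order of the pieces.
#'
#' @return zero-row data frame with the canonical feature columns.
#' @export
emptyFeatures <- function() {
  data.frame(feature_id = character(), kind = character(), name = character(),
             start = integer(), end = integer(), strand = character(),
             part = integer(), stringsAsFactors = FALSE)
}

#' AnnotatedGenome: a circular plastome with its feature annotation
#'
#' The central container of the package: one chloroplast genome sequence
#' plus sample metadata and a feature table (gene/CDS/tRNA/rRNA/intron/IGS
#' intervals, 1-based closed, origin-wrapping features split into parts).
#'
#' @slot sampleId unique sample identifier.
#' @slot species species binomial (free text).
#' @slot subgenus one of `"Amaranthus"`, `"Acnida"`, `"Albersia"`,
#'   `"outgroup"`, or `""` when unknown.
#' @slot sequence uppercase DNA string over A/C/G/T/N.
#' @slot circular is the molecule circular?
#' @slot features feature table, see [emptyFeatures()].
#' @slot sourceAccession GenBank accession the record came from, or "".
#' @export
setClass("AnnotatedGenome",
  representation(sampleId = "character", species = "character",
                 subgenus = "character", sequence = "character",
                 circular = "logical", features = "data.frame",
                 sourceAccession = "character"),
  prototype(sampleId = "sample", species = "", subgenus = "",
            sequence = "", circular = TRUE, features = emptyFeatures(),
            sourceAccession = ""))

setValidity("AnnotatedGenome", function(object) {
  msgs <- character()
  if (nchar(object@sequence) == 0L)
    msgs <- c(msgs, "sequence must be non-empty")
  if (grepl("[^ACGTN]", object@sequence))
    msgs <- c(msgs, "sequence may only contain A, C, G, T, N")
  if (!(object@subgenus %in% c(VALID_SUBGENERA, "")))
    msgs <- c(msgs, sprintf("unknown subgenus label '%s'", object@subgenus))
  ft <- object@features
  need <- c("feature_id", "kind", "name", "start", "end", "strand", "part")
  if (!all(need %in% names(ft)))
    msgs <- c(msgs, "features is missing canonical columns")
  else if (nrow(ft)) {
    L <- nchar(object@sequence)
    if (any(ft$start < 1L | ft$end > L | ft$start > ft$end))
      msgs <- c(msgs, "feature intervals must lie within [1, genome length]")
    if (!all(ft$kind %in% FEATURE_KINDS))
      msgs <- c(msgs, "unknown feature kind")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an AnnotatedGenome
#'
#' @param sequence DNA string (coerced to upper case).
#' @param sampleId sample identifier.
#' @param species,subgenus,sourceAccession optional metadata.
#' @param circular logical; chloroplast genomes are circular molecules.
#' @param features feature table as in [emptyFeatures()].
#' @return an [AnnotatedGenome-class] object.
#' @examples
#' g <- AnnotatedGenome("ACGTACGT", sampleId = "toy")
#' genomeLength(g)
#' @export
AnnotatedGenome <- function(sequence, sampleId = "sample", species = "",
                            subgenus = "", circular = TRUE,
                            features = emptyFeatures(),
                            sourceAccession = "") {
  new("AnnotatedGenome", sampleId = sampleId, species = species,
      subgenus = subgenus, sequence = toupper(as.character(sequence)),
      circular = circular, features = features,
      sourceAccession = sourceAccession)
}

#' QuadripartiteStructure: the LSC/IRa/SSC/IRb partition of a plastome
#'
#' Intervals are 1-based closed on the (possibly rotated) genome; an interval
#' whose `end` is smaller than its `start` wraps the circular origin.
#' Lengths satisfy lsc + ssc + 2 * ir = total.
#'
#' @slot lsc,ira,ssc,irb integer c(start, end) intervals.
#' @slot lscLength,sscLength,irLength,totalLength lengths in bp.
#' @slot gcPercent genome GC content in percent, one decimal.
#' @export
setClass("QuadripartiteStructure",
  representation(lsc = "integer", ira = "integer", ssc = "integer",
                 irb = "integer", lscLength = "integer",
                 sscLength = "integer", irLength = "integer",
                 totalLength = "integer", gcPercent = "numeric"))

setValidity("QuadripartiteStructure", function(object) {
  if (object@lscLength + object@sscLength + 2L * object@irLength !=
      object@totalLength)
    return("lsc + ssc + 2*ir must equal total length")
  if (object@lscLength < object@sscLength)
    return("LSC must be at least as long as SSC")
  TRUE
})

#' PlastomeAlignment: a whole-genome multiple sequence alignment
#'
#' Gapped rows of equal length over A/C/G/T/N/-, one per sample, plus the
#' identifier of the reference row whose annotation is projected onto
#' alignment columns.
#'
#' @slot seqs named character vector of equal-length gapped sequences.
#' @slot referenceId name of the reference row.
#' @export
setClass("PlastomeAlignment",
  representation(seqs = "character", referenceId = "character"))

setValidity("PlastomeAlignment", function(object) {
  ids <- names(object@seqs)
  if (is.null(ids) || any(ids == "") || anyDuplicated(ids))
    return("alignment rows must have unique non-empty sample ids")
  w <- nchar(object@seqs)
  if (length(unique(w)) > 1L) {
    bad <- ids[w != stats::median(w)]
    return(sprintf("ragged alignment rows: %s", paste(bad, collapse = ", ")))
  }
  if (!(object@referenceId %in% ids))
    return("referenceId must be one of the row ids")
  if (any(grepl("[^ACGTN-]", object@seqs)))
    return("alignment rows may only contain A, C, G, T, N, -")
  TRUE
})

#' Construct a PlastomeAlignment
#'
#' @param seqs named character vector of gapped rows (upper-cased).
#' @param referenceId reference row id; defaults to the first row.
#' @return a [PlastomeAlignment-class] object.
#' @export
PlastomeAlignment <- function(seqs, referenceId = names(seqs)[1]) {
  new("PlastomeAlignment", seqs = toupper(seqs), referenceId = referenceId)
}

#' VariantTable: per-column variant calls and per-class tallies
#'
#' @slot sites data frame, one row per alignment column carrying a variant:
#'   `column`, `consensus_pos` (NA for all-gap-in-consensus columns), `class`,
#'   `snp`, `indel`, `alleles`.
#' @slot classTally data frame with `class`, `region_length`, `snp_count`,
#'   `indel_count`, `snp_frequency`, `indel_frequency` (percent).
#' @slot consensus the consensus sequence the tallies are measured on.
#' @slot ingroup sample ids included in the tallies.
#' @export
setClass("VariantTable",
  representation(sites = "data.frame", classTally = "data.frame",
                 consensus = "character", ingroup = "character"))

setMethod("show", "AnnotatedGenome", function(object) {
  cat(sprintf("AnnotatedGenome '%s' (%s%s): %s bp, %s, %d features\n",
              object@sampleId,
              if (nzchar(object@species)) object@species else "unknown species",
              if (nzchar(object@subgenus))
                paste0(", subgen. ", object@subgenus) else "",
              format(nchar(object@sequence), big.mark = ","),
              if (object@circular) "circular" else "linear",
              length(unique(object@features$feature_id))))
})

setMethod("show", "QuadripartiteStructure", function(object) {
  cat(sprintf(paste0("QuadripartiteStructure: total %s bp | LSC %s | ",
                     "SSC %s | IR %s | GC %.1f%%\n"),
              format(object@totalLength, big.mark = ","),
              format(object@lscLength, big.mark = ","),
              format(object@sscLength, big.mark = ","),
              format(object@irLength, big.mark = ","), object@gcPercent))
})

setMethod("show", "PlastomeAlignment", function(object) {
  cat(sprintf("PlastomeAlignment: %d rows x %s columns (reference '%s')\n",
              length(object@seqs),
              format(nchar(object@seqs[1]), big.mark = ","),
              object@referenceId))
})

setMethod("show", "VariantTable", function(object) {
  cat(sprintf("VariantTable: %d variant columns on a %s bp consensus (%d ingroup rows)\n",
              nrow(object@sites), format(nchar(object@consensus),
                                         big.mark = ","),
              length(object@ingroup)))
  print(object@classTally, row.names = FALSE)
})
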