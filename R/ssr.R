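# MISA-equivalent simple sequence repeat (SSR) scanning and the
# species-discriminating marker-combination search.
#
# Only perfect tandem repeats are called. The default unit-count thresholds
# are 10, 5, 4, 3, 3, 3 for mono- to hexanucleotide motifs. A run is reported
# once, under its primitive motif (a motif that is itself a tandem of a
# shorter motif is suppressed: the run is already called at the shorter
# period), and calls whose interval is contained in another call's interval
# are dropped.

DEFAULT_SSR_THRESHOLDS <- c(`1` = 10L, `2` = 5L, `3` = 4L, `4` = 3L,
                            `5` = 3L, `6` = 3L)

# minimal period of a motif string
minimal_period <- function(motif) {
  p <- nchar(motif)
  for (d in seq_len(p - 1L)) {
    if (p %% d == 0L &&
        motif == strrep(substr(motif, 1L, d), p / d)) return(d)
  }
  p
}

#' Canonical SSR motif
#'
#' Lexicographic minimum over all rotations of the motif and of its reverse
#' complement, so that e.g. `"AG"`, `"GA"`, `"CT"` and `"TC"` share one
#' marker-matrix key.
#'
#' @param motif repeat unit (1-6 bp).
#' @return canonical representative string.
#' @export
canonicalMotif <- function(motif) {
  rots <- function(x) {
    n <- nchar(x)
    vapply(seq_len(n), function(i)
      paste0(substr(x, i, n), substr(x, 1L, i - 1L)), "")
  }
  min(c(rots(motif), rots(revcomp(motif))))
}

# core scan of a linear character string; returns start/period/copies
scan_ssrs_linear <- function(seq, thresholds) {
  cs <- seq_to_chars(seq)
  n <- length(cs)
  out <- list()
  for (p in 1:6) {
    thr <- thresholds[[as.character(p)]]
    if (is.null(thr) || n < p * thr) next
    eq <- cs[seq_len(n - p)] == cs[(p + 1L):n] &
      cs[seq_len(n - p)] != "N"
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & (r$lengths + p) >= p * thr)
    for (h in hit) {
      s <- starts[h]
      total <- r$lengths[h] + p
      copies <- total %/% p
      motif <- substr(seq, s, s + p - 1L)
      if (minimal_period(motif) != p) next
      out[[length(out) + 1L]] <- data.frame(
        start = s, period = p, copies = copies, motif = motif,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), period = integer(),
                      copies = integer(), motif = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Find simple sequence repeats (microsatellites)
#'
#' All maximal perfect tandem runs whose unit count reaches the threshold for
#' their period. Circular genomes are scanned on a doubled sequence and
#' wrapped calls deduplicated, so runs crossing the origin are found once.
#'
#' @param genome an [AnnotatedGenome-class] or a DNA string.
#' @param thresholds named vector of minimum unit counts per period
#'   (names `"1"`..`"6"`); default 10/5/4/3/3/3.
#' @param structure optional [QuadripartiteStructure-class] used to label the
#'   `region` column.
#' @return data frame, one row per SSR: `sample`, `motif`,
#'   `canonical_motif`, `period`, `copies`, `start`, `end`, `length`,
#'   `region`, `context`, `context_kind`, `at_only`. `end < start` marks a
#'   run wrapping the circular origin.
#' @examples
#' findSSRs(paste0("GCGCGTT", strrep("A", 10), "GTGCCGT"))
#' @export
findSSRs <- function(genome, thresholds = DEFAULT_SSR_THRESHOLDS,
                     structure = NULL) {
  is_g <- is(genome, "AnnotatedGenome")
  seq <- if (is_g) genomeSequence(genome) else toupper(genome)
  sid <- if (is_g) sampleId(genome) else "seq"
  circular <- is_g && isCircular(genome)
  L <- nchar(seq)

  raw <- scan_ssrs_linear(if (circular) paste0(seq, seq) else seq, thresholds)
  if (circular && nrow(raw)) {
    raw <- raw[raw$start <= L, , drop = FALSE]
    # cap runs at one full circle
    over <- raw$copies * raw$period > L
    raw$copies[over] <- L %/% raw$period[over]
  }
  raw$length <- raw$copies * raw$period
  raw$end_lin <- raw$start + raw$length - 1L

  # drop calls contained in another call's interval
  if (nrow(raw) > 1L) {
    keep <- rep(TRUE, nrow(raw))
    for (i in seq_len(nrow(raw))) {
      inside <- raw$start <= raw$start[i] & raw$end_lin >= raw$end_lin[i] &
        !(raw$start == raw$start[i] & raw$end_lin == raw$end_lin[i])
      if (any(inside & keep)) keep[i] <- FALSE
    }
    raw <- raw[keep, , drop = FALSE]
  }
  if (!nrow(raw)) {
    return(data.frame(sample = character(), motif = character(),
                      canonical_motif = character(), period = integer(),
                      copies = integer(), start = integer(), end = integer(),
                      length = integer(), region = character(),
                      context = character(), context_kind = character(),
                      at_only = logical(), stringsAsFactors = FALSE))
  }
  raw <- raw[order(raw$start, raw$period), , drop = FALSE]
  end <- if (circular) wrap1(raw$end_lin, L) else pmin(raw$end_lin, L)

  rec <- data.frame(
    sample = sid, motif = raw$motif,
    canonical_motif = vapply(raw$motif, canonicalMotif, ""),
    period = as.integer(raw$period), copies = as.integer(raw$copies),
    start = as.integer(raw$start), end = as.integer(end),
    length = as.integer(raw$length),
    region = NA_character_, context = NA_character_,
    context_kind = NA_character_,
    at_only = !grepl("[CG]", raw$motif), stringsAsFactors = FALSE)
  rownames(rec) <- NULL

  if (!is.null(structure))
    rec$region <- regionOf(structure, wrap1(rec$start + rec$length %/% 2L, L))
  if (is_g && nrow(features(genome))) {
    ctx <- feature_context(genome, wrap1(rec$start + rec$length %/% 2L, L))
    rec$context <- ctx$name
    rec$context_kind <- ctx$kind
  }
  rec
}

# gene/IGS context of positions: genic features win over IGS
feature_context <- function(genome, pos) {
  ft <- features(genome)
  prio <- c("CDS", "tRNA", "rRNA", "intron", "gene", "IGS")
  ft <- ft[ft$kind %in% prio, , drop = FALSE]
  ft <- ft[order(match(ft$kind, prio)), , drop = FALSE]
  name <- rep(NA_character_, length(pos))
  kind <- rep(NA_character_, length(pos))
  for (r in seq_len(nrow(ft))) {
    inside <- pos >= ft$start[r] & pos <= ft$end[r] & is.na(name)
    name[inside] <- ft$name[r]
    kind[inside] <- ft$kind[r]
  }
  list(name = name, kind = kind)
}

#' Composition summary of an SSR record set
#'
#' @param records data frame from [findSSRs()] (possibly rbind-ed over
#'   samples); `region`/`context_kind` must be filled for the location
#'   fractions.
#' @return list with `percent_at_only`, `percent_lsc`, `percent_igs` (each to
#'   two decimals), and `period_histogram` (counts, ordered by count).
#' @export
ssrCompositionStats <- function(records) {
  if (!nrow(records)) stopf("ssrCompositionStats: empty record list")
  pct <- function(x) round_half_up(100 * mean(x, na.rm = TRUE), 2)
  hist <- sort(table(period = records$period), decreasing = TRUE)
  list(percent_at_only = pct(records$at_only),
       percent_lsc = if (all(is.na(records$region))) NA_real_ else
         pct(records$region == "LSC"),
       percent_igs = if (all(is.na(records$context_kind))) NA_real_ else
         pct(records$context_kind == "IGS"),
       period_histogram = hist)
}

#' Build the SSR marker matrix
#'
#' Rows are samples, columns are SSR loci keyed by `(context, canonical
#' motif)`, entries are total copy numbers (NA where a sample lacks the
#' locus).
#'
#' @param recordList list of [findSSRs()] data frames, one per sample.
#' @return numeric matrix with sample row names and locus column names.
#' @export
ssrMarkerMatrix <- function(recordList) {
  all <- do.call(rbind, recordList)
  if (!nrow(all)) stopf("ssrMarkerMatrix: no SSR records")
  all$key <- paste(ifelse(is.na(all$context), "unplaced", all$context),
                   all$canonical_motif, sep = "|")
  samples <- unique(all$sample)
  keys <- sort(unique(all$key))
  m <- matrix(NA_real_, length(samples), length(keys),
              dimnames = list(samples, keys))
  agg <- stats::aggregate(copies ~ sample + key, data = all, FUN = sum)
  m[cbind(match(agg$sample, samples), match(agg$key, keys))] <- agg$copies
  m
}

#' Smallest SSR marker combinations separating each species pair
#'
#' For every unordered pair of rows of the marker matrix, exhaustive search
#' over column subsets of increasing cardinality (up to `maxSize`) for the
#' first subset, in lexicographic column order, on which the two rows differ
#' (NA = locus absent counts as a distinguishing state against a number).
#' Pairs with identical full rows are reported inseparable.
#'
#' @param matrix marker matrix from [ssrMarkerMatrix()].
#' @param maxSize largest subset size to try (default 4).
#' @return list with `combinations` (data frame: sample_a, sample_b,
#'   size, markers) and `inseparable` (data frame: sample_a, sample_b).
#' @export
discriminatingCombinations <- function(matrix, maxSize = 4L) {
  if (maxSize < 1L) stopf("maxSize must be >= 1")
  if (nrow(matrix) < 2L) stopf("need at least two samples")
  samples <- rownames(matrix)
  cols <- colnames(matrix)
  differs <- function(a, b) (is.na(a) != is.na(b)) |
    (!is.na(a) & !is.na(b) & a != b)
  comb_rows <- list(); insep <- list()
  for (i in seq_len(nrow(matrix) - 1L)) for (j in (i + 1L):nrow(matrix)) {
    d <- differs(matrix[i, ], matrix[j, ])
    if (!any(d)) {
      insep[[length(insep) + 1L]] <- data.frame(
        sample_a = samples[i], sample_b = samples[j],
        stringsAsFactors = FALSE)
      next
    }
    found <- NULL
    for (size in seq_len(min(maxSize, length(cols)))) {
      cc <- utils::combn(seq_along(cols), size)
      hit <- which(apply(cc, 2, function(ix) any(d[ix])))
      if (length(hit)) { found <- cc[, hit[1]]; break }
    }
    comb_rows[[length(comb_rows) + 1L]] <- data.frame(
      sample_a = samples[i], sample_b = samples[j], size = length(found),
      markers = paste(cols[found], collapse = ";"), stringsAsFactors = FALSE)
  }
  list(combinations = do.call(rbind, c(list(data.frame(
         sample_a = character(), sample_b = character(), size = integer(),
         markers = character(), stringsAsFactors = FALSE)), comb_rows)),
       inseparable = do.call(rbind, c(list(data.frame(
         sample_a = character(), sample_b = character(),
         stringsAsFactors = FALSE)), insep)))
}
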