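# SNP/indel calling on a whole-genome multiple alignment: consensus
# construction, per-column variant classification stratified by annotation
# class (CDS / tRNA / rRNA / intron / IGS, with Gene = CDS + tRNA + rRNA +
# intron), pairwise sample differences and indel-event extraction.
#
# Counting units: class tallies count variant COLUMNS (an indel column is an
# alignment column where at least one ingroup row has a gap and another a
# base); pairwise reports count maximal-run EVENTS. Frequencies are true
# percentages of the class length measured on the consensus.

msa_matrix <- function(msa) {
  rows <- alignmentRows(msa)
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  rownames(m) <- names(rows)
  m
}

#' Build the majority consensus of an alignment
#'
#' Per column the most frequent non-gap base, ties broken alphabetically
#' (A < C < G < T); columns that are gaps in every row are dropped.
#'
#' @param msa a [PlastomeAlignment-class].
#' @return list with `consensus` (string), `columnMap` (per alignment column,
#'   its 1-based consensus coordinate, NA for dropped columns).
#' @export
buildConsensus <- function(msa) {
  m <- msa_matrix(msa)
  if (nrow(m) < 2L) stopf("buildConsensus: need >= 2 rows")
  counts <- vapply(c("A", "C", "G", "T"), function(b) colSums(m == b),
                   numeric(ncol(m)))
  if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1,
                                      dimnames = list(NULL,
                                                      c("A", "C", "G", "T")))
  best <- max.col(counts, ties.method = "first")  # first = alphabetical tie
  base <- c("A", "C", "G", "T")[best]
  any_base <- rowSums(counts) > 0
  has_n <- colSums(m == "N") > 0
  base[!any_base & has_n] <- "N"
  keep <- any_base | has_n
  if (!any(keep)) stopf("buildConsensus: all-gap alignment")
  columnMap <- rep(NA_integer_, ncol(m))
  columnMap[keep] <- seq_len(sum(keep))
  list(consensus = paste(base[keep], collapse = ""), columnMap = columnMap)
}

# per-column class and feature-name painting from the reference annotation.
# Precedence CDS > tRNA > rRNA > intron > IGS; columns not covered by any
# projected feature are IGS (non-coding insertions relative to the reference).
paint_columns <- function(msa, annotation) {
  rows <- alignmentRows(msa)
  rid <- sampleId(annotation)
  if (!(rid %in% names(rows)))
    stopf("annotation sample '%s' has no alignment row", rid)
  ft <- features(annotation)
  if (!any(ft$kind == "IGS")) {
    annotation <- deriveIgs(annotation)
    ft <- features(annotation)
  }
  rc <- seq_to_chars(rows[[rid]])
  col_of <- which(rc != "-")
  W <- length(rc)
  cls <- rep(NA_character_, W)
  nm <- rep(NA_character_, W)
  prio <- c("CDS", "tRNA", "rRNA", "intron", "IGS")
  for (kind in rev(prio)) {  # paint low precedence first, overwrite later
    f <- ft[ft$kind == kind, , drop = FALSE]
    for (r in seq_len(nrow(f))) {
      if (f$start[r] > length(col_of) || f$end[r] > length(col_of)) {
        warning(sprintf("feature %s extends past the reference row; skipped",
                        f$name[r]))
        next
      }
      span <- col_of[f$start[r]]:col_of[f$end[r]]
      cls[span] <- kind
      nm[span] <- f$name[r]
    }
  }
  cls[is.na(cls)] <- "IGS"
  list(class = cls, name = nm)
}

#' Call SNP and indel columns and tally them by annotation class
#'
#' A SNP site is an alignment column with at least two distinct non-gap,
#' non-N bases among the ingroup rows; an indel site is a column where at
#' least one ingroup row has a gap and at least one a base. Each column is
#' assigned one class by projecting the reference features (precedence
#' CDS > tRNA > rRNA > intron > IGS); the Gene tally is
#' CDS + tRNA + rRNA + intron, and class lengths are measured on the
#' consensus.
#'
#' @param msa a [PlastomeAlignment-class].
#' @param annotation the reference [AnnotatedGenome-class] (its `sampleId`
#'   must be a row of `msa`).
#' @param ingroup sample ids included in the tallies (default: all rows);
#'   outgroups are typically excluded.
#' @return a [VariantTable-class].
#' @export
callVariants <- function(msa, annotation, ingroup = NULL) {
  m <- msa_matrix(msa)
  ingroup <- ingroup %||% rownames(m)
  miss <- setdiff(ingroup, rownames(m))
  if (length(miss)) stopf("unknown ingroup ids: %s", paste(miss, collapse = ", "))
  mi <- m[ingroup, , drop = FALSE]

  nb <- vapply(c("A", "C", "G", "T"), function(b) colSums(mi == b),
               numeric(ncol(mi)))
  if (ncol(mi) == 1L) nb <- matrix(nb, nrow = 1)
  snp <- rowSums(nb > 0) >= 2L
  gaps <- colSums(mi == "-")
  bases <- colSums(mi != "-" & mi != "N")
  indel <- gaps >= 1L & (bases + colSums(mi == "N")) >= 1L

  cons <- buildConsensus(msa)
  paint <- paint_columns(msa, annotation)
  on_cons <- !is.na(cons$columnMap)

  classes <- c("CDS", "tRNA", "rRNA", "intron", "IGS")
  tally <- lapply(classes, function(cl) {
    sel <- paint$class == cl
    data.frame(class = cl,
               region_length = sum(sel & on_cons),
               snp_count = sum(snp & sel), indel_count = sum(indel & sel),
               stringsAsFactors = FALSE)
  })
  tally <- do.call(rbind, tally)
  gene <- data.frame(class = "Gene",
                     region_length = sum(tally$region_length[tally$class != "IGS"]),
                     snp_count = sum(tally$snp_count[tally$class != "IGS"]),
                     indel_count = sum(tally$indel_count[tally$class != "IGS"]),
                     stringsAsFactors = FALSE)
  total <- data.frame(class = "Consensus",
                      region_length = sum(tally$region_length),
                      snp_count = sum(snp), indel_count = sum(indel),
                      stringsAsFactors = FALSE)
  tally <- rbind(total, gene, tally)
  tally$snp_frequency <- round_half_up(
    100 * tally$snp_count / pmax(tally$region_length, 1L), 2)
  tally$indel_frequency <- round_half_up(
    100 * tally$indel_count / pmax(tally$region_length, 1L), 2)

  var_cols <- which(snp | indel)
  alleles <- vapply(var_cols, function(j) {
    paste(sort(unique(mi[, j])), collapse = "/")
  }, "")
  sites <- data.frame(column = var_cols,
                      consensus_pos = cons$columnMap[var_cols],
                      class = paint$class[var_cols],
                      feature = paint$name[var_cols],
                      snp = snp[var_cols], indel = indel[var_cols],
                      alleles = alleles, stringsAsFactors = FALSE)
  new("VariantTable", sites = sites, classTally = tally,
      consensus = cons$consensus, ingroup = ingroup)
}

#' Pairwise differences between two aligned samples
#'
#' SNPs are columns where both samples have bases (not gap/N) and they
#' differ; indel events are maximal runs of columns where exactly one of the
#' two samples has gaps.
#'
#' @param msa a [PlastomeAlignment-class].
#' @param sampleA,sampleB row ids.
#' @param annotation optional reference [AnnotatedGenome-class] used to name
#'   the feature each event falls in.
#' @return list with `snp_count`, `indel_event_count` and `indel_events`
#'   (data frame: start_col, end_col, length, carrier, feature).
#' @export
pairwiseDifferences <- function(msa, sampleA, sampleB, annotation = NULL) {
  rows <- alignmentRows(msa)
  miss <- setdiff(c(sampleA, sampleB), names(rows))
  if (length(miss)) stopf("unknown sample id(s): %s", paste(miss, collapse = ", "))
  a <- seq_to_chars(rows[[sampleA]])
  b <- seq_to_chars(rows[[sampleB]])
  base <- function(x) x != "-" & x != "N"
  snp_count <- sum(base(a) & base(b) & a != b)

  paint <- if (!is.null(annotation)) paint_columns(msa, annotation) else NULL
  events <- list()
  for (carrier in c(sampleA, sampleB)) {
    g <- if (carrier == sampleA) a == "-" & b != "-" else b == "-" & a != "-"
    r <- rle(g)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (h in which(r$values)) {
      events[[length(events) + 1L]] <- data.frame(
        start_col = starts[h], end_col = ends[h], length = r$lengths[h],
        carrier = carrier,
        feature = if (is.null(paint)) NA_character_ else {
          fn <- paint$name[starts[h]:ends[h]]
          fn <- fn[!is.na(fn)]
          if (length(fn)) names(sort(table(fn), decreasing = TRUE))[1]
          else NA_character_
        },
        stringsAsFactors = FALSE)
    }
  }
  events <- do.call(rbind, c(list(data.frame(
    start_col = integer(), end_col = integer(), length = integer(),
    carrier = character(), feature = character(), stringsAsFactors = FALSE)),
    events))
  events <- events[order(events$start_col), , drop = FALSE]
  rownames(events) <- NULL
  list(snp_count = snp_count, indel_event_count = nrow(events),
       indel_events = events)
}

#' Indel events across the whole alignment
#'
#' An event is a maximal run of contiguous columns in which a fixed,
#' non-empty, proper subset of the ingroup rows has gaps.
#'
#' @param msa a [PlastomeAlignment-class].
#' @param annotation optional reference annotation for feature naming.
#' @param ingroup rows to consider (default all).
#' @return data frame: start_col, end_col, length, samples (";"-joined gap
#'   carriers), feature.
#' @export
indelEvents <- function(msa, annotation = NULL, ingroup = NULL) {
  m <- msa_matrix(msa)
  ingroup <- ingroup %||% rownames(m)
  mi <- m[ingroup, , drop = FALSE]
  gap <- mi == "-"
  ng <- colSums(gap)
  active <- ng > 0L & ng < nrow(mi)
  subset_id <- rep("", ncol(mi))
  if (any(active))
    subset_id[active] <- apply(gap[, active, drop = FALSE], 2,
                               function(col) paste(which(col), collapse = ","))
  r <- rle(subset_id)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  hit <- which(r$values != "")
  paint <- if (!is.null(annotation)) paint_columns(msa, annotation) else NULL
  out <- lapply(hit, function(h) {
    carriers <- ingroup[as.integer(strsplit(r$values[h], ",")[[1]])]
    data.frame(start_col = starts[h], end_col = ends[h],
               length = r$lengths[h],
               samples = paste(carriers, collapse = ";"),
               feature = if (is.null(paint)) NA_character_ else {
                 fn <- paint$name[starts[h]:ends[h]]
                 fn <- fn[!is.na(fn)]
                 if (length(fn)) names(sort(table(fn), decreasing = TRUE))[1]
                 else NA_character_
               },
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(list(data.frame(
    start_col = integer(), end_col = integer(), length = integer(),
    samples = character(), feature = character(), stringsAsFactors = FALSE)),
    out))
}

#' Longest indel events
#'
#' @param events data frame of indel events (from [indelEvents()] or
#'   [pairwiseDifferences()]).
#' @param k how many to return.
#' @return the top-`k` events sorted by length (ties by coordinate).
#' @export
longestIndels <- function(events, k = 5L) {
  if (k < 1L) stopf("k must be >= 1")
  if (!nrow(events)) stopf("longestIndels: no events")
  events <- events[order(-events$length, events$start_col), , drop = FALSE]
  utils::head(events, k)
}
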