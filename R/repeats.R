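# Dispersed repeat detection in the four REPuter senses: forward (direct
# copy), palindromic (reverse-complement copy), reverse (reversed copy) and
# complement (base-complemented copy). A repeat pair must be >= minLen bp with
# identity >= minIdentity; the mismatch model is Hamming (no gaps), so every
# call re-validates by direct base comparison under its kind's transform.
#
# Detection: exact k-mer seeds between the sequence S and its transformed
# copy T, grouped by diagonal, greedily extended run-by-run while global
# identity stays above the threshold, then trimmed so both ends are matches.

REPEAT_KINDS <- c("forward", "palindromic", "reverse", "complement")

transform_seq <- function(seq, kind) {
  switch(kind,
         forward = seq,
         palindromic = revcomp(seq),
         reverse = reverse_seq(seq),
         complement = complement_seq(seq),
         stopf("unknown repeat kind '%s'", kind))
}

# map an interval on T back onto S coordinates
untransform_interval <- function(lo, hi, kind, L) {
  if (kind %in% c("palindromic", "reverse")) c(L - hi + 1L, L - lo + 1L)
  else c(lo, hi)
}

# seeds (i, j): exact k-mer matches between character strings s and t.
# `same = TRUE` (t is s) drops kmers occurring once (they only self-pair).
# Kmers whose occurrence product exceeds `cap` are skipped (low-complexity
# guard); kmers containing N never seed.
kmer_seeds <- function(s, t, k, same = FALSE, cap = 200L) {
  n1 <- nchar(s); n2 <- nchar(t)
  if (n1 < k || n2 < k) return(NULL)
  kS <- substring(s, 1:(n1 - k + 1L), k:n1)
  kT <- if (same) kS else substring(t, 1:(n2 - k + 1L), k:n2)
  u <- unique(kS)
  u <- u[!grepl("N", u, fixed = TRUE)]
  iS <- match(kS, u)
  iT <- if (same) iS else match(kT, u)
  cntS <- tabulate(iS, length(u))
  cntT <- if (same) cntS else tabulate(iT[!is.na(iT)], length(u))
  ok <- cntS > 0L & cntT > 0L & cntS * cntT <= cap
  if (same) ok <- ok & cntS >= 2L
  sel <- which(ok)
  if (!length(sel)) return(NULL)
  sS <- !is.na(iS) & iS %in% sel
  sT <- !is.na(iT) & iT %in% sel
  posS <- split(which(sS), iS[sS])
  posT <- split(which(sT), iT[sT])
  posT <- posT[names(posS)]
  li <- vector("list", length(posS)); lj <- li
  for (x in seq_along(posS)) {
    a <- posS[[x]]; b <- posT[[x]]
    li[[x]] <- rep(a, times = length(b))
    lj[[x]] <- rep(b, each = length(a))
  }
  cbind(i = unlist(li, use.names = FALSE), j = unlist(lj, use.names = FALSE))
}

# maximal-scoring extension of an exact seed run on one diagonal:
# match +1, mismatch -(theta / (1 - theta)) so an extension is score-positive
# only while it keeps local identity above the threshold; the window is then
# trimmed, if needed, until global identity >= theta. Ends always match.
# m: logical match vector indexed by offset t.
extend_seed <- function(m, t0, t1, min_identity) {
  penalty <- if (min_identity < 1) min_identity / (1 - min_identity) else Inf
  xdrop <- 3 * penalty + 5
  n <- length(m)
  # ties (score-neutral stretches, identity exactly at threshold) extend:
  # prefer the longer window
  b <- t1; sc <- 0; best <- 0; t <- t1
  while (t < n) {
    t <- t + 1L
    sc <- sc + if (m[t]) 1 else -penalty
    if (m[t] && sc >= best) { best <- sc; b <- t }
    if (sc < best - xdrop) break
  }
  a <- t0; sc <- 0; best <- 0; t <- t0
  while (t > 1L) {
    t <- t - 1L
    sc <- sc + if (m[t]) 1 else -penalty
    if (m[t] && sc >= best) { best <- sc; a <- t }
    if (sc < best - xdrop) break
  }
  mm <- sum(!m[a:b])
  # trim outermost extension runs until the global identity qualifies
  while (mm > (b - a + 1L) * (1 - min_identity) && (a < t0 || b > t1)) {
    shrink_left <- function() {
      a2 <- a + 1L
      while (a2 < t0 && m[a2]) a2 <- a2 + 1L
      while (a2 < t0 && !m[a2]) a2 <- a2 + 1L
      a2
    }
    shrink_right <- function() {
      b2 <- b - 1L
      while (b2 > t1 && m[b2]) b2 <- b2 - 1L
      while (b2 > t1 && !m[b2]) b2 <- b2 - 1L
      b2
    }
    if (a < t0 && (b <= t1 || sum(!m[shrink_left():b]) <=
                     sum(!m[a:shrink_right()]))) a <- shrink_left()
    else b <- shrink_right()
    mm <- sum(!m[a:b])
  }
  c(a = a, b = b, mismatches = mm)
}

#' Find dispersed repeats
#'
#' @param genome an [AnnotatedGenome-class] or DNA string (scanned as a
#'   linear sequence).
#' @param minLen minimum repeat length in bp (default 30).
#' @param minIdentity minimum identity fraction in (0, 1] (default 0.90).
#' @param kinds subset of `"forward"`, `"palindromic"`, `"reverse"`,
#'   `"complement"`.
#' @param structure optional [QuadripartiteStructure-class]; when given, arm
#'   regions are labelled and the whole-IR palindromic self-hit (both arms
#'   inside IRa+IRb — that is the quadripartite structure itself) is
#'   suppressed.
#' @param k seed k-mer size.
#' @return data frame, one row per repeat pair: `sample`, `kind`,
#'   `start1`, `end1`, `start2`, `end2`, `length`, `identity`,
#'   `region1`, `region2`.
#' @export
findRepeats <- function(genome, minLen = 30L, minIdentity = 0.90,
                        kinds = REPEAT_KINDS, structure = NULL, k = 12L) {
  if (minIdentity <= 0 || minIdentity > 1)
    stopf("minIdentity must be in (0, 1]")
  is_g <- is(genome, "AnnotatedGenome")
  seq <- if (is_g) genomeSequence(genome) else toupper(genome)
  sid <- if (is_g) sampleId(genome) else "seq"
  L <- nchar(seq)
  if (L < 2L * minLen) stopf("sequence shorter than 2 x minLen")
  cs <- seq_to_chars(seq)

  rows <- list()
  for (kind in kinds) {
    tseq <- transform_seq(seq, kind)
    ct <- seq_to_chars(tseq)
    seeds <- kmer_seeds(seq, tseq, k, same = (kind == "forward"))
    if (is.null(seeds)) next
    if (kind == "forward") seeds <- seeds[seeds[, 1] < seeds[, 2], ,
                                          drop = FALSE]
    if (!nrow(seeds)) next
    dg <- seeds[, 2] - seeds[, 1]
    done <- character()
    for (dd in unique(dg)) {
      # offsets t on this diagonal: S pos = t, T pos = t + dd
      lo <- max(1L, 1L - dd); hi <- min(L, L - dd)
      if (hi - lo + 1L < minLen) next
      m <- cs[lo:hi] == ct[(lo + dd):(hi + dd)] & cs[lo:hi] != "N"
      ii <- sort(unique(seeds[dg == dd, 1])) - lo + 1L
      cl <- ii[c(TRUE, diff(ii) > 2L * k)]
      for (i0 in cl) {
        t0 <- i0; t1 <- i0
        while (t1 < length(m) && m[t1 + 1L]) t1 <- t1 + 1L
        while (t0 > 1L && m[t0 - 1L]) t0 <- t0 - 1L
        ext <- extend_seed(m, t0, t1, minIdentity)
        len <- ext[["b"]] - ext[["a"]] + 1L
        if (len < minLen) next
        s1 <- lo + ext[["a"]] - 1L; e1 <- lo + ext[["b"]] - 1L
        arm2 <- untransform_interval(s1 + dd, e1 + dd, kind, L)
        key <- paste(kind, min(s1, arm2[1]), max(s1, arm2[1]),
                     min(e1, arm2[2]), max(e1, arm2[2]))
        if (key %in% done) next
        done <- c(done, key)
        if (s1 == arm2[1] && e1 == arm2[2]) next  # self hit
        a <- if (s1 < arm2[1] || (s1 == arm2[1] && e1 <= arm2[2]))
          c(s1, e1, arm2) else c(arm2, s1, e1)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sid, kind = kind, start1 = a[1], end1 = a[2],
          start2 = a[3], end2 = a[4], length = len,
          identity = (len - ext[["mismatches"]]) / len,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, c(list(data.frame(
    sample = character(), kind = character(), start1 = integer(),
    end1 = integer(), start2 = integer(), end2 = integer(),
    length = integer(), identity = numeric(), stringsAsFactors = FALSE)),
    rows))
  out <- unique(out)

  # drop records whose both arms are contained within another record's arms
  # of the same kind
  if (nrow(out) > 1L) {
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out))) {
      o <- out
      cont <- o$kind == out$kind[i] &
        o$start1 <= out$start1[i] & o$end1 >= out$end1[i] &
        o$start2 <= out$start2[i] & o$end2 >= out$end2[i] &
        !(o$start1 == out$start1[i] & o$end1 == out$end1[i] &
            o$start2 == out$start2[i] & o$end2 == out$end2[i])
      if (any(cont & keep)) keep[i] <- FALSE
    }
    out <- out[keep, , drop = FALSE]
  }

  out$region1 <- NA_character_
  out$region2 <- NA_character_
  if (!is.null(structure) && nrow(out)) {
    out$region1 <- regionOf(structure, (out$start1 + out$end1) %/% 2L)
    out$region2 <- regionOf(structure, (out$start2 + out$end2) %/% 2L)
    ir_pair <- out$kind == "palindromic" &
      out$region1 %in% c("IRa", "IRb") & out$region2 %in% c("IRa", "IRb") &
      out$length >= 0.9 * structure@irLength
    out <- out[!ir_pair, , drop = FALSE]
  }
  out <- out[order(out$start1, out$start2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Validate a repeat record by direct comparison
#'
#' Recomputes the identity of a reported arm pair under its kind's transform.
#'
#' @param seq the genome sequence the record was called on.
#' @param record one row of a [findRepeats()] data frame.
#' @return identity fraction (matches / length).
#' @export
repeatIdentity <- function(seq, record) {
  seq <- toupper(seq)
  a1 <- substr(seq, record$start1, record$end1)
  a2 <- substr(seq, record$start2, record$end2)
  a2t <- switch(record$kind, forward = a2, palindromic = revcomp(a2),
                reverse = reverse_seq(a2), complement = complement_seq(a2))
  c1 <- seq_to_chars(a1); c2 <- seq_to_chars(a2t)
  if (length(c1) != length(c2)) return(0)
  mean(c1 == c2)
}

#' Cluster repeat records into cross-sample loci
#'
#' Arm-1 intervals of every sample's records are projected through the
#' alignment onto the reference genome and single-linkage clustered: records
#' whose projected intervals lie within `linkGap` bp of each other share a
#' locus. Loci are labelled R1, R2, ... in reference order; a locus is
#' `common` when every sample contributes a record, and `variable_length`
#' when member lengths differ.
#'
#' @param recordList named list of [findRepeats()] data frames (names are
#'   sample ids).
#' @param msa a [PlastomeAlignment-class] containing every sample.
#' @param referenceId reference row; defaults to the alignment's.
#' @param linkGap single-linkage distance in bp (default 2000).
#' @return data frame, one row per record, with `locus`, `anchor_start`,
#'   `anchor_end`, `common`, `variable_length` columns added.
#' @export
clusterRepeatLoci <- function(recordList, msa, referenceId = NULL,
                              linkGap = 2000L) {
  referenceId <- referenceId %||% referenceId(msa)
  rows <- alignmentRows(msa)
  if (!(referenceId %in% names(rows)))
    stopf("reference '%s' has no alignment row", referenceId)
  miss <- setdiff(names(recordList), names(rows))
  if (length(miss))
    stopf("samples missing from the alignment: %s",
          paste(miss, collapse = ", "))

  # per sample: genome position -> reference position (via columns)
  ref_chars <- seq_to_chars(rows[[referenceId]])
  # reference position at-or-before each column (gap columns inherit the
  # position of the previous reference base)
  ref_pos_of_col <- pmax(cumsum(ref_chars != "-"), 1L)
  project <- function(sample, pos) {
    sc <- seq_to_chars(rows[[sample]])
    col_of_pos <- which(sc != "-")
    ref_pos_of_col[col_of_pos[pos]]
  }
  all <- do.call(rbind, lapply(names(recordList), function(sid) {
    r <- recordList[[sid]]
    if (!nrow(r)) return(NULL)
    r$sample <- sid
    r$proj_start <- project(sid, r$start1)
    r$proj_end <- project(sid, r$end1)
    r
  }))
  if (is.null(all) || !nrow(all)) stopf("no repeat records to cluster")
  all <- all[order(all$proj_start, all$proj_end), , drop = FALSE]

  locus <- integer(nrow(all))
  cur <- 1L; locus[1] <- 1L; reach <- all$proj_end[1]
  if (nrow(all) > 1L) for (i in 2:nrow(all)) {
    if (all$proj_start[i] > reach + linkGap) cur <- cur + 1L
    locus[i] <- cur
    reach <- max(reach, all$proj_end[i])
  }
  all$locus <- sprintf("R%d", locus)
  n_samples <- length(recordList)
  agg <- lapply(split(all, all$locus), function(g) {
    data.frame(locus = g$locus[1],
               anchor_start = min(g$proj_start), anchor_end = max(g$proj_end),
               common = length(unique(g$sample)) == n_samples,
               variable_length = length(unique(g$length)) > 1L,
               stringsAsFactors = FALSE)
  })
  agg <- do.call(rbind, agg)
  merge(all, agg, by = "locus", sort = FALSE)
}

#' Angular symmetry report for repeat arms on the circular genome
#'
#' Each arm midpoint is mapped to an angle in [0, 360) degrees on the circle;
#' the antipodality score of a record is `|180 - angular separation|` of its
#' two arms, so arms at exactly opposite positions score 0.
#'
#' @param records [findRepeats()] data frame.
#' @param structure the genome's [QuadripartiteStructure-class] (for the
#'   circle length and region labels).
#' @return the records with `angle1`, `angle2`, `separation_deg`,
#'   `antipodality_deg` columns added.
#' @export
symmetryReport <- function(records, structure) {
  L <- structure@totalLength
  ang <- function(p) 360 * ((p - 1) %% L) / L
  a1 <- ang((records$start1 + records$end1) / 2)
  a2 <- ang((records$start2 + records$end2) / 2)
  sep <- abs(a1 - a2)
  sep <- pmin(sep, 360 - sep)
  records$angle1 <- a1
  records$angle2 <- a2
  records$separation_deg <- sep
  records$antipodality_deg <- abs(180 - sep)
  records
}
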