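# Quadripartite structure: locate the inverted-repeat pair of a plastome and
# partition the circle into LSC / IRa / SSC / IRb.
#
# Detection seeds on exact k-mer matches between the sequence and its reverse
# complement, groups seeds by diagonal, extends each candidate to the maximal
# exact inverted match with circular (mod-length) indexing, and keeps the
# longest pair of disjoint arms. Amaranthus IR copies are near-identical, so
# the exact-match definition is the appropriate one.

# maximal exact inverted-repeat matches of S against itself, circular.
# Returns data.frame(s1, e1, s2, e2, len) with 1-based, possibly wrapping
# intervals (e < s means the arm wraps the origin).
ir_candidates <- function(seq, min_len, k = 25L) {
  L <- nchar(seq)
  if (L < 2L * k) return(NULL)
  rc <- revcomp(seq)
  seeds <- kmer_seeds(seq, rc, k, cap = 64L)
  if (is.null(seeds) || !nrow(seeds)) return(NULL)
  seeds_i <- seeds[, 1]
  seeds_j <- seeds[, 2]

  cs <- seq_to_chars(seq)
  comp <- chartr("ACGTN", "TGCAN", cs)
  at <- function(p) cs[wrap1(p, L)]
  comp_at <- function(p) comp[wrap1(p, L)]

  d <- seeds_i - seeds_j
  out <- list()
  for (dd in unique(d)) {
    ii <- sort(seeds_i[d == dd])
    cl_start <- c(TRUE, diff(ii) > 2L * k)
    for (i0 in ii[cl_start]) {
      j0 <- i0 - dd
      # arm2 (read 3'->5') anchor: position on S paired with i0 + t is q0 - t
      q0 <- L - j0 + 1L
      b <- k - 1L  # match covers offsets 0..b so far
      while (b - 0L + 1L < L && at(i0 + b + 1L) != "N" &&
             at(i0 + b + 1L) == comp_at(q0 - b - 1L)) b <- b + 1L
      a <- 0L
      while (a + b + 1L < L && at(i0 - a - 1L) != "N" &&
             at(i0 - a - 1L) == comp_at(q0 + a + 1L)) a <- a + 1L
      len <- a + b + 1L
      if (len < min_len) next
      s1 <- wrap1(i0 - a, L); e1 <- wrap1(i0 + b, L)
      s2 <- wrap1(q0 - b, L); e2 <- wrap1(q0 + a, L)
      out[[length(out) + 1L]] <- c(s1, e1, s2, e2, len)
    }
  }
  if (!length(out)) return(NULL)
  m <- unique(do.call(rbind, out))
  # normalise arm order (arm with smaller start first) and dedupe mirrors
  sw <- m[, 1] > m[, 3]
  m[sw, ] <- m[sw, c(3, 4, 1, 2, 5), drop = FALSE]
  m <- unique(m)
  data.frame(s1 = m[, 1], e1 = m[, 2], s2 = m[, 3], e2 = m[, 4], len = m[, 5])
}

# circular positions covered by a wrapping interval
circ_positions <- function(s, e, L) {
  if (s <= e) s:e else c(s:L, 1:e)
}

circ_len <- function(s, e, L) if (s <= e) e - s + 1L else L - s + e + 1L

# does interval [s1,e1] overlap [s2,e2] on a circle of size L?
circ_overlap <- function(s1, e1, s2, e2, L) {
  segs <- function(s, e) if (s <= e) list(c(s, e)) else
    list(c(s, L), c(1L, e))
  for (x in segs(s1, e1)) for (y in segs(s2, e2))
    if (x[1] <= y[2] && y[1] <= x[2]) return(TRUE)
  FALSE
}

#' Detect the inverted repeats and partition a plastome
#'
#' Finds the longest pair of disjoint intervals whose sequences are exact
#' reverse complements of each other, each at least `minIrLen` bp, and labels
#' the two remaining arcs LSC (the longer) and SSC (the shorter). Reported
#' genome order is LSC, IRa, SSC, IRb with the LSC first. Detection is
#' rotation-invariant: the four lengths do not depend on where the circular
#' sequence was opened.
#'
#' @param genome an [AnnotatedGenome-class] (circular).
#' @param minIrLen minimum inverted-repeat arm length in bp (default 1000).
#' @return a [QuadripartiteStructure-class].
#' @examples
#' set.seed(1)
#' lsc <- randomDna(6000, gc = 0.4)
#' ir <- randomDna(1200, gc = 0.4)
#' ssc <- randomDna(800, gc = 0.4)
#' g <- AnnotatedGenome(paste0(lsc, ir, ssc, reverseComplementSeq(ir)))
#' detectInvertedRepeat(g, minIrLen = 1000)
#' @export
detectInvertedRepeat <- function(genome, minIrLen = 1000L) {
  seq <- genomeSequence(genome)
  L <- nchar(seq)
  if (L < 4L * minIrLen)
    stopf("genome (%d bp) shorter than 4 x minIrLen", L)
  cand <- ir_candidates(seq, minIrLen)
  if (!is.null(cand)) {
    ok <- !mapply(circ_overlap, cand$s1, cand$e1, cand$s2, cand$e2,
                  MoreArgs = list(L = L))
    cand <- cand[ok & 2L * cand$len < L, , drop = FALSE]
  }
  if (is.null(cand) || !nrow(cand))
    stopf("no quadripartite structure: no inverted repeat >= %d bp (genome reported as single-copy)",
          minIrLen)
  cand <- cand[order(-cand$len, cand$s1), , drop = FALSE]
  hit <- cand[1, ]

  # the two arcs between the arms
  arc1 <- c(wrap1(hit$e1 + 1L, L), wrap1(hit$s2 - 1L, L))
  arc2 <- c(wrap1(hit$e2 + 1L, L), wrap1(hit$s1 - 1L, L))
  len1 <- circ_len(arc1[1], arc1[2], L)
  len2 <- circ_len(arc2[1], arc2[2], L)
  if (len1 + len2 + 2L * hit$len != L)  # arm adjacency leaves a null arc
    stopf("inverted repeat arms leave no single-copy arcs")
  if (len1 >= len2) {
    lsc <- arc1; ssc <- arc2
    ira <- c(hit$s2, hit$e2); irb <- c(hit$s1, hit$e1)
  } else {
    lsc <- arc2; ssc <- arc1
    ira <- c(hit$s1, hit$e1); irb <- c(hit$s2, hit$e2)
  }
  new("QuadripartiteStructure",
      lsc = as.integer(lsc), ira = as.integer(ira), ssc = as.integer(ssc),
      irb = as.integer(irb),
      lscLength = as.integer(max(len1, len2)),
      sscLength = as.integer(min(len1, len2)),
      irLength = as.integer(hit$len), totalLength = as.integer(L),
      gcPercent = gcContent(genome))
}

#' GC content in percent
#'
#' 100 x (G + C) / (A + C + G + T), rounded half away from zero to one
#' decimal. N bases are excluded from numerator and denominator.
#'
#' @param genome an [AnnotatedGenome-class] or a DNA string.
#' @return numeric percentage with one decimal.
#' @export
gcContent <- function(genome) {
  seq <- if (is(genome, "AnnotatedGenome")) genomeSequence(genome) else
    toupper(genome)
  f <- Biostrings::letterFrequency(Biostrings::DNAString(seq),
                                   letters = c("A", "C", "G", "T"))
  tot <- sum(f)
  if (tot == 0) stopf("gcContent: sequence has no A/C/G/T bases")
  round_half_up(100 * (f[["C"]] + f[["G"]]) / tot, 1)
}

#' Which region of the quadripartite structure contains a position
#'
#' @param structure a [QuadripartiteStructure-class].
#' @param pos vector of 1-based genome positions.
#' @return character vector over `"LSC"`, `"IRa"`, `"SSC"`, `"IRb"`.
#' @export
regionOf <- function(structure, pos) {
  L <- structure@totalLength
  lab <- rep(NA_character_, length(pos))
  for (rg in list(c("LSC", structure@lsc), c("IRa", structure@ira),
                  c("SSC", structure@ssc), c("IRb", structure@irb))) {
    s <- as.integer(rg[2]); e <- as.integer(rg[3])
    inside <- if (s <= e) pos >= s & pos <= e else pos >= s | pos <= e
    lab[inside & is.na(lab)] <- rg[1]
  }
  lab
}

#' Table-1 style summary row for one genome
#'
#' @param genome an [AnnotatedGenome-class].
#' @param minIrLen passed to [detectInvertedRepeat()].
#' @return one-row data frame: sample, species, subgenus, total_bp, lsc_bp,
#'   ssc_bp, ir_bp, gc_percent.
#' @export
plastomeSummary <- function(genome, minIrLen = 1000L) {
  qs <- detectInvertedRepeat(genome, minIrLen)
  data.frame(sample = sampleId(genome), species = genome@species,
             subgenus = subgenus(genome),
             total_bp = qs@totalLength, lsc_bp = qs@lscLength,
             ssc_bp = qs@sscLength, ir_bp = qs@irLength,
             gc_percent = qs@gcPercent, stringsAsFactors = FALSE)
}

#' Subgenus-level summary of SSC lengths
#'
#' For every subgenus and every unordered subgenus pair, the mean and the
#' population (divide-by-n) standard deviation of the SSC lengths, each
#' rounded to two decimals. Pairs pool the samples of both subgenera.
#'
#' @param ssc data frame with columns `subgenus` and `ssc_bp` (e.g. from
#'   rbinding [plastomeSummary()] rows), or a list of
#'   [QuadripartiteStructure-class] plus a `subgenus` character vector in
#'   `metadata`.
#' @param metadata optional character vector of subgenus labels, parallel to
#'   `ssc` when `ssc` is a list of structures.
#' @return data frame with columns `group1`, `group2`, `n`, `mean_bp`,
#'   `sd_bp`; rows where `group1 == group2` are within-subgenus summaries.
#' @export
sscSummaryBySubgenus <- function(ssc, metadata = NULL) {
  if (is.list(ssc) && !is.data.frame(ssc)) {
    vals <- vapply(ssc, function(q) q@sscLength, 1L)
    df <- data.frame(subgenus = metadata, ssc_bp = vals,
                     stringsAsFactors = FALSE)
  } else df <- ssc
  bad <- setdiff(unique(df$subgenus), VALID_SUBGENERA)
  if (length(bad))
    stopf("unknown subgenus label(s): %s", paste(bad, collapse = ", "))
  groups <- unique(df$subgenus)
  out <- list()
  for (i in seq_along(groups)) for (j in seq_len(i)) {
    g1 <- groups[j]; g2 <- groups[i]
    x <- df$ssc_bp[df$subgenus %in% c(g1, g2)]
    out[[length(out) + 1L]] <- data.frame(
      group1 = g1, group2 = g2, n = length(x),
      mean_bp = round_half_up(mean(x), 2),
      sd_bp = round_half_up(sd_pop(x), 2), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Published Amaranthus plastome summary table
#'
#' The summary table of the 22 deposited Amaranthus chloroplast genomes
#' (accession, species, subgenus, total/LSC/SSC/IR lengths, GC percent),
#' shipped with the package as a plain-text fixture.
#'
#' @return data frame, one row per sample.
#' @examples
#' tab <- amaranthusPlastomes()
#' sscSummaryBySubgenus(data.frame(subgenus = tab$subgenus,
#'                                 ssc_bp = tab$ssc_bp))
#' @export
amaranthusPlastomes <- function() {
  path <- system.file("extdata", "amaranthus_plastomes.tsv",
                      package = "plastcomp", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
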