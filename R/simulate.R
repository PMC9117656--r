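# Synthetic plastome simulator.
#
# Builds an ancestral circular genome with the canonical quadripartite
# architecture (LSC + IRa + SSC + IRb, IRb the exact reverse complement of
# IRa), a gene/intron/tRNA/rRNA/IGS layout, planted SSRs and dispersed
# repeats, then evolves it along a three-clade subgenus tree with
# class-specific substitution and indel rates, emitting the true homology
# alignment and a ground-truth record of every mutation, so each analysis
# module can be validated against planted truth without any external aligner.
#
# Modelling choices: branch lengths are per-site substitution probability
# multipliers (per class); inverted repeats evolve in concert (substitutions
# drawn on IRa are mirrored into IRb, indels are suppressed inside the IRs);
# inserted material is not itself mutated further down the tree.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulation configuration
#'
#' Defaults reproduce the architecture and variation structure of the
#' published Amaranthus plastomes: region lengths 84,000 / 18,000 / 24,300
#' bp (LSC/SSC/IR), GC 36.6%, per-class substitution rates equal to the
#' published class-wise SNP site frequencies (CDS 0.0129, tRNA 0.0032, rRNA
#' 0.0007, intron 0.0168, IGS 0.0326) with the ingroup tree normalised to
#' total length 1, per-class indel column rates from the published indel
#' frequencies, a 6 + 6 + 10 three-clade taxon sample plus one outgroup,
#' around 30 planted SSRs per genome (about 56% A/T-only, mostly LSC and
#' IGS), four planted dispersed repeats including an antipodal LSC/SSC pair,
#' and two planted long deletions (387 bp in the gene `ycf2` on the Acnida
#' stem, 384 bp in the spacer `psbM-trnD` on the Amaranthus stem).
#'
#' @param seed integer seed; identical config + seed gives byte-identical
#'   output.
#' @param nTaxa named integer vector of clade sizes
#'   (`Amaranthus`/`Acnida`/`Albersia`).
#' @param outgroup include one outgroup taxon?
#' @param lscLength,sscLength,irLength region lengths in bp.
#' @param gc target GC fraction.
#' @param subRates per-class per-unit-branch substitution probabilities.
#' @param indelColRates per-class target indel column frequencies.
#' @param indelGeomP geometric length parameter for background indels
#'   (mean length `1/indelGeomP`).
#' @param treeScale total ingroup tree length (sum of non-outgroup branch
#'   lengths after normalisation).
#' @param outgroupBranch outgroup terminal branch length (same units).
#' @param nSsrs planted SSR count.
#' @param ssrAtFraction fraction of planted SSRs with A/T-only motifs.
#' @param ssrLscFraction fraction planted in the LSC (the rest in the SSC).
#' @param ssrIgsFraction fraction planted inside intergenic spacers.
#' @param plantedRepeats list of planted dispersed repeats; each element a
#'   list with `kind`, `length`, `mismatches`, `antipodal` (logical: arm 1
#'   in LSC, arm 2 at the opposite point of the circle in the SSC).
#' @param plantedIndels list of planted long indels; each a list with
#'   `feature` (target gene or IGS name), `length`, `clade` (the event goes
#'   on that clade's stem branch).
#' @param hotspots list of planted high-variability segments; each a list
#'   with `region` (`"LSC"`/`"SSC"`), `at` (fractional position within the
#'   region), `length` (bp) and `multiplier` applied to the substitution
#'   rate.
#' @return a `SimulationConfig` list.
#' @export
simulationConfig <- function(
    seed = 1L,
    nTaxa = c(Amaranthus = 6L, Acnida = 6L, Albersia = 10L),
    outgroup = TRUE,
    lscLength = 84000L, sscLength = 18000L, irLength = 24300L,
    gc = 0.366,
    subRates = c(CDS = 0.0129, tRNA = 0.0032, rRNA = 0.0007,
                 intron = 0.0168, IGS = 0.0326),
    indelColRates = c(CDS = 0.0107, tRNA = 0, rRNA = 0,
                      intron = 0.0219, IGS = 0.0732),
    indelGeomP = 0.5,
    treeScale = 1,
    outgroupBranch = 0.3,
    nSsrs = 30L, ssrAtFraction = 0.5556, ssrLscFraction = 0.7778,
    ssrIgsFraction = 0.7191,
    plantedRepeats = list(
      list(kind = "forward", length = 40L, mismatches = 2L, antipodal = TRUE),
      list(kind = "reverse", length = 35L, mismatches = 2L, antipodal = TRUE),
      list(kind = "forward", length = 40L, mismatches = 0L, antipodal = FALSE),
      list(kind = "palindromic", length = 35L, mismatches = 2L,
           antipodal = FALSE)),
    plantedIndels = list(
      list(feature = "ycf2", length = 387L, clade = "Acnida"),
      list(feature = "psbM-trnD", length = 384L, clade = "Amaranthus")),
    hotspots = list(
      list(region = "LSC", at = 0.30, length = 1000L, multiplier = 4),
      list(region = "LSC", at = 0.60, length = 1000L, multiplier = 4))) {
  stopifnot(all(subRates >= 0 & subRates <= 1),
            all(indelColRates >= 0 & indelColRates <= 1),
            lscLength > 0, sscLength > 0, irLength > 0,
            gc > 0, gc < 1, treeScale > 0, indelGeomP > 0, indelGeomP <= 1)
  if (lscLength < sscLength) stopf("lscLength must be >= sscLength")
  if (!all(c("Amaranthus", "Acnida", "Albersia") %in% names(nTaxa)))
    stopf("nTaxa must name the clades Amaranthus, Acnida and Albersia")
  cfg <- as.list(environment())
  class(cfg) <- "SimulationConfig"
  cfg
}

# named genes laid out first, with realistic-scale lengths (bp)
LSC_NAMED_GENES <- c(psbA = 1062, matK = 1530, rbcL = 1428, ycf2 = 6000,
                     psbM = 105, trnD = 74, rpoC2 = 4100, atpB = 1497,
                     `trnT-UGU` = 73, `trnK-UUU` = 72, atpF = 555,
                     psbE = 252, clpP = 591, rpl14 = 369, rps19 = 279)
SSC_NAMED_GENES <- c(ndhF = 2220, rpl32 = 171, ycf1 = 5400, ndhD = 1503,
                     ndhE = 306, ndhG = 531, ndhI = 543)
IR_RRNA <- c(rrn16 = 1491, rrn23 = 2804, `rrn4.5` = 103, rrn5 = 121)

# lay out one single-copy region: alternating genes and IGS gaps.
# Returns a local-coordinate feature table (no IGS rows; gaps are implicit).
layout_region <- function(regionLen, named, prefix,
                          meanCds = 900, sdCds = 250, intronProb = 0.18,
                          meanIntron = 550, trnaProb = 0.25, trnaLen = 74,
                          meanIgs = 320) {
  rows <- list()
  fid <- 0L
  pos <- 1L
  queue <- names(named)
  add <- function(kind, name, s, e, parts = NULL) {
    fid <<- fid + 1L
    id <- sprintf("%s%03d", prefix, fid)
    if (is.null(parts)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        feature_id = id, kind = kind, name = name, start = s, end = e,
        strand = "+", part = 1L, stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <<- data.frame(
        feature_id = id, kind = kind, name = name,
        start = parts$start, end = parts$end, strand = "+",
        part = seq_along(parts$start), stringsAsFactors = FALSE)
    }
  }
  # atpF and clpP are the canonical intron-bearing genes of the layout, so
  # the intron class is always present when they fit
  named_introns <- c("atpF", "clpP")
  repeat {
    gap <- max(30L, round(stats::rexp(1, 1 / meanIgs)))
    pos <- pos + gap
    remaining <- regionLen - pos - 200L
    if (remaining < 200L) break
    if (length(queue)) {
      nm <- queue[1]; queue <- queue[-1]
      len <- min(unname(named[[nm]]), remaining)
      kind <- if (grepl("^trn", nm)) "tRNA" else "CDS"
      if (nm %in% named_introns && remaining - len > 900L) {
        ilen <- round(stats::rnorm(1, 700, 50))
        ex1 <- len %/% 3L
        add("CDS", nm, NA, NA, parts = list(
          start = c(pos, pos + ex1 + ilen),
          end = c(pos + ex1 - 1L, pos + len + ilen - 1L)))
        add("intron", sprintf("%s-intron1", nm), pos + ex1,
            pos + ex1 + ilen - 1L)
        pos <- pos + len + ilen
      } else {
        add(kind, nm, pos, pos + len - 1L)
        pos <- pos + len
      }
    } else if (stats::runif(1) < trnaProb) {
      add("tRNA", sprintf("trn%s%02d", prefix, fid + 1L), pos,
          pos + trnaLen - 1L)
      pos <- pos + trnaLen
    } else {
      len <- round(stats::rnorm(1, meanCds, sdCds))
      len <- max(150L, min(len, remaining))
      if (stats::runif(1) < intronProb && len > 600L) {
        ilen <- min(round(stats::rnorm(1, meanIntron, 100)), remaining - len)
        if (ilen > 100L) {
          ex1 <- len %/% 2L
          nm <- sprintf("%sg%03d", prefix, fid + 1L)
          add("CDS", nm, NA, NA, parts = list(
            start = c(pos, pos + ex1 + ilen),
            end = c(pos + ex1 - 1L, pos + len + ilen - 1L)))
          add("intron", sprintf("%s-intron1", nm), pos + ex1,
              pos + ex1 + ilen - 1L)
          pos <- pos + len + ilen
        } else {
          add("CDS", sprintf("%sg%03d", prefix, fid + 1L), pos,
              pos + len - 1L)
          pos <- pos + len
        }
      } else {
        add("CDS", sprintf("%sg%03d", prefix, fid + 1L), pos,
            pos + len - 1L)
        pos <- pos + len
      }
    }
  }
  do.call(rbind, c(list(emptyFeatures()), rows))
}

# one inverted-repeat copy: the four rRNAs, a few tRNAs, CDS filler
layout_ir <- function(irLen) {
  rows <- list(); pos <- 150L; fid <- 0L
  add <- function(kind, name, len) {
    fid <<- fid + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      feature_id = sprintf("ir%03d", fid), kind = kind, name = name,
      start = pos, end = pos + len - 1L, strand = "+", part = 1L,
      stringsAsFactors = FALSE)
    pos <<- pos + len + 200L
  }
  add("CDS", "ndhB", 1533L)
  add("tRNA", "trnI-GAU", 74L)
  for (nm in names(IR_RRNA)) add("rRNA", nm, unname(IR_RRNA[[nm]]))
  add("tRNA", "trnA-UGC", 73L)
  add("tRNA", "trnN-GUU", 72L)
  while (pos + 1100L < irLen - 150L) add("CDS", sprintf("irg%03d", fid + 1L),
                                         900L)
  ft <- do.call(rbind, rows)
  ft[ft$end <= irLen - 100L, , drop = FALSE]
}

# name IGS gaps between consecutive feature extents within [1, regionLen]
igs_from_layout <- function(ft, regionLen, prefix) {
  if (!nrow(ft)) return(emptyFeatures())
  sp <- IRanges::reduce(IRanges::IRanges(ft$start, ft$end))
  s <- IRanges::start(sp); e <- IRanges::end(sp)
  name_at <- function(p) {
    hit <- ft[ft$start <= p & ft$end >= p & ft$kind != "intron", , drop = FALSE]
    if (nrow(hit)) hit$name[1] else "NA"
  }
  rows <- list()
  add <- function(a, b, l, r) rows[[length(rows) + 1L]] <<- data.frame(
    feature_id = sprintf("%sigs%03d", prefix, length(rows) + 1L),
    kind = "IGS", name = sprintf("%s-%s", l, r), start = a, end = b,
    strand = "+", part = 1L, stringsAsFactors = FALSE)
  if (s[1] > 1L) add(1L, s[1] - 1L, "start", name_at(s[1]))
  for (i in seq_len(length(s) - 1L))
    if (s[i + 1L] > e[i] + 1L)
      add(e[i] + 1L, s[i + 1L] - 1L, name_at(e[i]), name_at(s[i + 1L]))
  if (e[length(e)] < regionLen)
    add(e[length(e)] + 1L, regionLen, name_at(e[length(e)]), "end")
  do.call(rbind, c(list(emptyFeatures()), rows))
}

shift_features <- function(ft, offset) {
  ft$start <- ft$start + offset
  ft$end <- ft$end + offset
  ft
}

# mismatch positions that keep the leading exact stretch >= 13 bp (seedable)
# and stay >= 10 bp away from the arm ends (so extension recovers full arms)
mismatch_positions <- function(len, mm) {
  if (mm == 0L) return(integer())
  unique(pmin(len - 10L, round(seq(14, max(14, len - 10L),
                                   length.out = mm))))
}

#' Build the ancestral synthetic plastome
#'
#' @param config a [simulationConfig()].
#' @return list with `genome` (an [AnnotatedGenome-class], sample id
#'   `"ancestor"`) and `truth` (planted SSR/repeat/hotspot coordinates,
#'   class layout, region boundaries).
#' @export
buildAncestor <- function(config) with_seed(config$seed, {
  lscL <- config$lscLength; sscL <- config$sscLength; irL <- config$irLength
  L <- lscL + sscL + 2L * irL

  ft_lsc <- layout_region(lscL, LSC_NAMED_GENES, "L")
  ft_ssc <- layout_region(sscL, SSC_NAMED_GENES, "S")
  ft_ir <- layout_ir(irL)
  igs_lsc <- igs_from_layout(ft_lsc, lscL, "L")
  igs_ssc <- igs_from_layout(ft_ssc, sscL, "S")
  igs_ir <- igs_from_layout(ft_ir, irL, "I")

  ira_off <- lscL
  ssc_off <- lscL + irL
  irb_off <- lscL + irL + sscL
  mirror_ir <- function(ft) {
    if (!nrow(ft)) return(ft)
    m <- ft
    m$start <- irL - ft$end + 1L
    m$end <- irL - ft$start + 1L
    m$strand <- ifelse(ft$strand == "+", "-", "+")
    m$feature_id <- paste0(m$feature_id, "b")
    m[order(m$start), , drop = FALSE]
  }
  ft <- rbind(
    rbind(ft_lsc, igs_lsc),
    shift_features(rbind(ft_ir, igs_ir), ira_off),
    shift_features(rbind(ft_ssc, igs_ssc), ssc_off),
    shift_features(mirror_ir(rbind(ft_ir, igs_ir)), irb_off))
  rownames(ft) <- NULL

  lsc_seq <- random_dna_exact(lscL, config$gc)
  ira_seq <- random_dna_exact(irL, config$gc)
  ssc_seq <- random_dna_exact(sscL, config$gc)
  cs <- seq_to_chars(paste0(lsc_seq, ira_seq, ssc_seq, revcomp(ira_seq)))

  # break accidental IR boundary extension so detection recovers the
  # configured lengths exactly
  comp1 <- function(b) chartr("ACGT", "TGCA", b)
  flip <- function(i, avoid) {
    cs[i] <<- sample(setdiff(c("A", "C", "G", "T"), avoid), 1L)
  }
  # right of IRa (first SSC base) pairs with the base left of IRb
  if (cs[ssc_off + 1L] == comp1(cs[irb_off])) flip(ssc_off + 1L,
                                                   c(cs[ssc_off + 1L]))
  # left of IRa (last LSC base) pairs with the base right of IRb (pos 1)
  if (cs[ira_off] == comp1(cs[1L])) flip(ira_off, c(cs[ira_off]))

  occ_s <- c(ira_off + 1L, irb_off + 1L)
  occ_e <- c(ssc_off, L)
  claim <- function(s, e) {
    if (any(s <= occ_e & e >= occ_s)) return(FALSE)
    occ_s <<- c(occ_s, s); occ_e <<- c(occ_e, e)
    TRUE
  }

  # ---- planted SSRs ----
  thr <- DEFAULT_SSR_THRESHOLDS
  period_mix <- c(`1` = 10, `4` = 4, `2` = 3, `3` = 2, `5` = 1, `6` = 1)
  ssr_rows <- list()
  igs_pool <- ft[ft$kind == "IGS", , drop = FALSE]
  cds_pool <- ft[ft$kind == "CDS", , drop = FALSE]
  n_try <- 0L
  while (length(ssr_rows) < config$nSsrs && n_try < 20L * config$nSsrs) {
    n_try <- n_try + 1L
    p <- as.integer(sample(names(period_mix), 1L, prob = period_mix))
    at_only <- stats::runif(1) < config$ssrAtFraction
    alpha <- if (at_only) c("A", "T") else c("A", "C", "G", "T")
    motif <- paste(sample(alpha, p, replace = TRUE), collapse = "")
    if (minimal_period(motif) != p) next
    if (!at_only && !grepl("[CG]", motif)) next
    copies <- thr[[as.character(p)]] + sample(0:2, 1L)
    len <- p * copies
    region_lo <- if (stats::runif(1) < config$ssrLscFraction)
      c(1L, lscL) else c(ssc_off + 1L, ssc_off + sscL)
    pool <- if (stats::runif(1) < config$ssrIgsFraction) igs_pool else cds_pool
    pool <- pool[pool$start >= region_lo[1] & pool$end <= region_lo[2] &
                   (pool$end - pool$start + 1L) >= len + 20L, , drop = FALSE]
    if (!nrow(pool)) next
    f <- pool[sample(nrow(pool), 1L), ]
    s <- f$start + sample.int(f$end - f$start - len - 10L, 1L) + 4L
    e <- s + len - 1L
    if (!claim(s - 6L, e + 6L)) next
    cs[s:e] <- seq_to_chars(strrep(motif, copies))
    # break flanks so the planted run is maximal and not extended
    brk <- if (at_only) c("G", "C") else setdiff(c("A", "C", "G", "T"),
                                                 seq_to_chars(motif))
    if (!length(brk)) brk <- "N"
    cs[s - 1L] <- brk[1L]
    cs[e + 1L] <- brk[(length(brk) >= 2L) + 0L + 1L]
    ssr_rows[[length(ssr_rows) + 1L]] <- data.frame(
      motif = motif, period = p, copies = copies, start = s, end = e,
      region = if (region_lo[1] == 1L) "LSC" else "SSC",
      context = f$name, context_kind = f$kind, at_only = at_only,
      stringsAsFactors = FALSE)
  }
  ssr_truth <- do.call(rbind, c(list(data.frame()), ssr_rows))

  # ---- planted dispersed repeats ----
  rep_rows <- list()
  for (pr in config$plantedRepeats) {
    len <- pr$length; mm <- pr$mismatches
    # mismatches must be spaced so inter-mismatch runs keep the local
    # identity at threshold (and the arm stays k-mer seedable)
    if (mm > 0L && len < 24L + (mm - 1L) * 11L)
      stopf("planted repeat of %d bp cannot carry %d detectable mismatches",
            len, mm)
    placed <- FALSE
    for (try in 1:200) {
      if (isTRUE(pr$antipodal)) {
        mid2 <- ssc_off + sample.int(sscL - 2L * len, 1L) + len
        mid1 <- wrap1(mid2 - L %/% 2L + sample(-1500L:1500L, 1L), L)
        if (mid1 < len + 2L || mid1 > lscL - len - 2L) next
        s1 <- mid1 - len %/% 2L
        s2 <- mid2 - len %/% 2L
      } else {
        s1 <- sample.int(lscL - 3L * len - 6000L, 1L) + len
        s2 <- s1 + len + sample(2000:5000, 1L)
      }
      e1 <- s1 + len - 1L; e2 <- s2 + len - 1L
      if (!claim(s1 - 2L, e1 + 2L)) next
      if (!claim(s2 - 2L, e2 + 2L)) next
      arm1 <- randomDna(len, config$gc)
      arm2 <- transform_seq(arm1, pr$kind)
      a2 <- seq_to_chars(arm2)
      for (mp in mismatch_positions(len, mm)) {
        # mismatch position indexed on arm1; map through the transform
        q <- if (pr$kind %in% c("palindromic", "reverse")) len - mp + 1L
        else mp
        a2[q] <- sample(setdiff(c("A", "C", "G", "T"), a2[q]), 1L)
      }
      cs[s1:e1] <- seq_to_chars(arm1)
      cs[s2:e2] <- a2
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        kind = pr$kind, start1 = s1, end1 = e1, start2 = s2, end2 = e2,
        length = len, mismatches = mm,
        antipodal = isTRUE(pr$antipodal), stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
    if (!placed)
      stopf("could not place planted repeat of length %d (region capacity)",
            len)
  }
  rep_truth <- do.call(rbind, c(list(data.frame()), rep_rows))
  if (nrow(ssr_truth) < config$nSsrs)
    stopf("could only place %d of %d planted SSRs (region capacity)",
          nrow(ssr_truth), config$nSsrs)

  # ---- planted hotspot segments (rate multipliers; no sequence edit) ----
  hs_rows <- lapply(config$hotspots, function(h) {
    off <- if (h$region == "LSC") 0L else ssc_off
    width <- if (h$region == "LSC") lscL else sscL
    s <- off + max(1L, round(h$at * width))
    data.frame(start = s, end = s + h$length - 1L,
               multiplier = h$multiplier, region = h$region,
               stringsAsFactors = FALSE)
  })
  hs_truth <- do.call(rbind, c(list(data.frame()), hs_rows))

  genome <- AnnotatedGenome(chars_to_seq(cs), sampleId = "ancestor",
                            species = "synthetic", circular = TRUE,
                            features = ft)
  gcv <- gcContent(genome)
  if (abs(gcv - 100 * config$gc) > 0.5)
    stopf("ancestor GC %.2f%% deviates more than 0.5%% from target", gcv)

  cls <- class_vector(genome)
  list(genome = genome,
       truth = list(
         ssrs = ssr_truth, repeats = rep_truth, hotspots = hs_truth,
         regions = c(lsc = lscL, ira = irL, ssc = sscL, irb = irL),
         region_bounds = list(lsc = c(1L, lscL),
                              ira = c(ira_off + 1L, ssc_off),
                              ssc = c(ssc_off + 1L, irb_off),
                              irb = c(irb_off + 1L, L)),
         class_lengths = table(cls),
         igs_total = sum(cls == "IGS")))
})

# per-position class vector (CDS > tRNA > rRNA > intron > IGS, default IGS)
class_vector <- function(genome) {
  L <- genomeLength(genome)
  cls <- rep("IGS", L)
  ft <- features(genome)
  for (kind in c("intron", "rRNA", "tRNA", "CDS")) {
    f <- ft[ft$kind == kind, , drop = FALSE]
    for (r in seq_len(nrow(f))) cls[f$start[r]:f$end[r]] <- kind
  }
  cls
}

# newick for the preset three-clade subgenus topology
preset_tree <- function(config, tip = 0.03, internal = 0.015) {
  lad <- function(ids) {
    s <- sprintf("%s:%g", ids[length(ids)], tip)
    if (length(ids) > 1L)
      for (i in (length(ids) - 1L):1L)
        s <- sprintf("(%s:%g,%s):%g", ids[i], tip, s, internal)
    s
  }
  ids <- lapply(names(config$nTaxa), function(cl)
    sprintf("%s_%d", cl, seq_len(config$nTaxa[[cl]])))
  names(ids) <- names(config$nTaxa)
  core <- sprintf("((%s,%s):%g,%s", lad(ids$Acnida), lad(ids$Amaranthus),
                  internal, lad(ids$Albersia))
  nwk <- if (config$outgroup)
    sprintf("%s,outgroup_1:%g);", core, config$outgroupBranch)
  else paste0(core, ");")
  tr <- ape::read.tree(text = nwk)
  og <- match("outgroup_1", tr$tip.label)
  ingroup_edges <- if (is.na(og)) seq_len(nrow(tr$edge)) else
    which(tr$edge[, 2] != og)
  sc <- config$treeScale / sum(tr$edge.length[ingroup_edges])
  tr$edge.length <- tr$edge.length * sc
  tr
}

tips_below <- function(tree, node) {
  nt <- length(tree$tip.label)
  if (node <= nt) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, function(k) tips_below(tree, k)))
}

#' Evolve the ancestor along a tree, emitting leaves, the true MSA and truth
#'
#' Substitutions are drawn per branch per site with probability
#' `subRates[class] * branch length` (times the planted hotspot multiplier
#' inside hotspot segments); indel events with per-site probability
#' `indelColRates[class] * indelGeomP * branch length` and geometric lengths,
#' half deletions and half insertions. Substitutions in IRa are mirrored
#' into IRb (concerted evolution) and indels are suppressed inside the IRs
#' and inside planted-indel windows, so planted events stay clean. The true
#' homology alignment is emitted directly; no aligner is involved.
#'
#' @param ancestor list from [buildAncestor()].
#' @param config the same [simulationConfig()].
#' @param tree optional `ape::phylo`; default is the preset three-clade
#'   subgenus topology.
#' @return list with `genomes` (named list of leaf
#'   [AnnotatedGenome-class]es), `msa` (the true [PlastomeAlignment-class],
#'   reference = first leaf), `tree`, and `truth` (per-edge substitution and
#'   indel records plus the planted-event ledger).
#' @export
evolveGenomes <- function(ancestor, config, tree = NULL)
  with_seed(config$seed + 1L, {
  genome <- ancestor$genome
  L <- genomeLength(genome)
  anc <- seq_to_chars(genomeSequence(genome))
  cls <- class_vector(genome)
  tree <- tree %||% preset_tree(config)
  if (length(tree$tip.label) < 2L) stopf("tree must have >= 2 leaves")

  p_sub <- unname(config$subRates[cls])
  hs <- ancestor$truth$hotspots
  if (!is.null(hs) && nrow(hs))
    for (i in seq_len(nrow(hs)))
      p_sub[hs$start[i]:hs$end[i]] <- p_sub[hs$start[i]:hs$end[i]] *
        hs$multiplier[i]
  if (max(p_sub) * max(tree$edge.length) > 0.5)
    stopf("per-branch substitution probability exceeds 0.5 (saturation)")

  rb <- ancestor$truth$region_bounds
  in_ir <- logical(L)
  in_ir[rb$ira[1]:rb$ira[2]] <- TRUE
  in_ir[rb$irb[1]:rb$irb[2]] <- TRUE
  p_ind <- unname(config$indelColRates[cls]) * config$indelGeomP
  p_ind[in_ir] <- 0
  # the configured rates are observed column frequencies over the whole
  # class; indels are suppressed inside the concerted IRs, so the
  # per-eligible-site event rate is scaled up by total/eligible to keep the
  # emitted class frequency at its configured value
  for (cl in unique(cls)) {
    sel <- cls == cl
    n_el <- sum(sel & !in_ir)
    if (n_el > 0L)
      p_ind[sel & !in_ir] <- p_ind[sel & !in_ir] * sum(sel) / n_el
  }

  # planted indels: locate windows, suppress background indels inside them
  ftab <- features(genome)
  planted <- lapply(config$plantedIndels, function(pi_) {
    f <- ftab[ftab$name == pi_$feature, , drop = FALSE]
    if (!nrow(f)) stopf("planted indel target '%s' not found", pi_$feature)
    mid <- (f$start[1] + f$end[1]) %/% 2L
    s <- mid - pi_$length %/% 2L
    list(clade = pi_$clade, feature = pi_$feature, start = s,
         end = s + pi_$length - 1L, length = pi_$length)
  })
  for (p in planted) p_ind[max(1L, p$start - 2L):min(L, p$end + 2L)] <- 0

  # IRb mirror of an IRa position
  mirror <- function(pos) rb$irb[2] - (pos - rb$ira[1])

  nt <- length(tree$tip.label)
  root <- nt + 1L
  edges <- tree$edge
  eord <- rev(ape::postorder(tree))  # parent-before-child traversal
  seqs <- vector("list", max(edges))
  alive <- vector("list", max(edges))
  ins_sets <- vector("list", max(edges))
  seqs[[root]] <- anc
  alive[[root]] <- rep(TRUE, L)
  ins_sets[[root]] <- integer()

  stem_of <- function(clade) {
    tips <- grep(sprintf("^%s_", clade), tree$tip.label)
    node <- if (length(tips) == 1L) tips else ape::getMRCA(tree, tips)
    which(edges[, 2] == node)
  }
  planted_edge <- vapply(planted, function(p) stem_of(p$clade), 1L)

  sub_records <- vector("list", nrow(edges))
  indel_records <- vector("list", nrow(edges))
  insertions <- list()  # global registry: id, edge, pos, seq

  comp_b <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  not_irb <- rep(TRUE, L)
  not_irb[rb$irb[1]:rb$irb[2]] <- FALSE
  for (ei in eord) {
    par <- edges[ei, 1]; chl <- edges[ei, 2]
    bl <- tree$edge.length[ei]
    s <- seqs[[par]]
    al <- alive[[par]]

    # substitutions (never drawn inside IRb; mirrored there)
    idx <- which(stats::runif(L) < p_sub * bl & al & not_irb)
    subs <- NULL
    if (length(idx)) {
      from <- s[idx]
      to <- vapply(from, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
      s[idx] <- to
      ira_idx <- idx[idx >= rb$ira[1] & idx <= rb$ira[2]]
      if (length(ira_idx)) {
        mpos <- mirror(ira_idx)
        s[mpos] <- unname(comp_b[s[ira_idx]])
      }
      subs <- data.frame(pos = idx, from = from, to = to,
                         stringsAsFactors = FALSE)
    }
    sub_records[[ei]] <- subs

    # background indels + planted events on this edge
    ind_idx <- which(stats::runif(L) < p_ind * bl & al)
    ind <- NULL
    if (length(ind_idx)) {
      lens <- as.integer(stats::rgeom(length(ind_idx), config$indelGeomP)) + 1L
      type <- ifelse(stats::runif(length(ind_idx)) < 0.5, "del", "ins")
      ind <- data.frame(type = type, pos = ind_idx, length = lens,
                        planted = FALSE, stringsAsFactors = FALSE)
    }
    pe <- which(planted_edge == ei)
    if (length(pe)) {
      ind <- rbind(ind, do.call(rbind, lapply(planted[pe], function(p)
        data.frame(type = "del", pos = p$start, length = p$length,
                   planted = TRUE, stringsAsFactors = FALSE))))
    }
    new_ins <- integer()
    if (!is.null(ind) && nrow(ind)) {
      ind <- ind[order(ind$pos), , drop = FALSE]
      ind$seq <- NA_character_
      for (r in seq_len(nrow(ind))) {
        if (ind$type[r] == "del") {
          # silence the next `length` alive positions from pos
          win <- ind$pos[r]:min(L, ind$pos[r] + ind$length[r] + 200L)
          kill <- utils::head(win[al[win]], ind$length[r])
          if (length(kill) < ind$length[r]) {
            av <- which(al & seq_len(L) >= ind$pos[r])
            kill <- utils::head(av, ind$length[r])
          }
          al[kill] <- FALSE
          ind$length[r] <- length(kill)
        } else {
          iseq <- randomDna(ind$length[r], config$gc)
          ind$seq[r] <- iseq
          id <- length(insertions) + 1L
          insertions[[id]] <- list(id = id, edge = ei,
                                   pos = as.integer(ind$pos[r]), seq = iseq)
          new_ins <- c(new_ins, id)
        }
      }
    }
    indel_records[[ei]] <- ind
    seqs[[chl]] <- s
    alive[[chl]] <- al
    ins_sets[[chl]] <- c(ins_sets[[par]], new_ins)
  }

  # ---- assemble the true alignment ----
  leaf_ids <- tree$tip.label
  ins_df <- if (length(insertions))
    data.frame(id = vapply(insertions, `[[`, 1L, "id"),
               pos = vapply(insertions, `[[`, 1L, "pos"),
               len = vapply(insertions, function(x) nchar(x$seq), 1L))
  else data.frame(id = integer(), pos = integer(), len = integer())
  ins_df <- ins_df[order(ins_df$pos, ins_df$id), , drop = FALSE]

  rows <- vapply(leaf_ids, function(lid) {
    node <- match(lid, tree$tip.label)
    base <- ifelse(alive[[node]], seqs[[node]], "-")
    mine <- ins_sets[[node]]
    if (!nrow(ins_df)) return(chars_to_seq(base))
    pieces <- character(2L * nrow(ins_df) + 1L)
    cur <- 1L; pi2 <- 1L
    for (r in seq_len(nrow(ins_df))) {
      p <- ins_df$pos[r]
      pieces[pi2] <- if (p >= cur) paste(base[cur:p], collapse = "") else ""
      cur <- max(cur, p + 1L)
      pieces[pi2 + 1L] <- if (ins_df$id[r] %in% mine)
        insertions[[ins_df$id[r]]]$seq else strrep("-", ins_df$len[r])
      pi2 <- pi2 + 2L
    }
    pieces[pi2] <- if (cur <= L) paste(base[cur:L], collapse = "") else ""
    paste(pieces, collapse = "")
  }, "")
  msa <- PlastomeAlignment(rows, referenceId = leaf_ids[1])

  # ---- leaf genomes with lifted features ----
  clade_of <- function(lid) sub("_.*$", "", lid)
  genomes <- lapply(leaf_ids, function(lid) {
    node <- match(lid, tree$tip.label)
    row <- rows[[lid]]
    rc <- seq_to_chars(row)
    leafpos <- cumsum(rc != "-")
    # alignment column of each ancestral position: shifted right by the
    # total width of insertion blocks at earlier positions
    if (nrow(ins_df)) {
      tb <- tapply(ins_df$len, ins_df$pos, sum)
      pos_shift <- integer(L)
      pos_shift[as.integer(names(tb))] <- as.integer(tb)
      anc_col <- seq_len(L) + c(0L, cumsum(pos_shift))[seq_len(L)]
    } else anc_col <- seq_len(L)
    al <- alive[[node]]
    lp_of_anc <- ifelse(al, leafpos[anc_col], NA_integer_)
    ft2 <- ftab
    map1 <- function(p, up) {
      # nearest alive ancestral position at/after (up) or at/before (!up)
      if (up) {
        w <- which(al[p:L])
        if (!length(w)) return(NA_integer_)
        lp_of_anc[p + w[1L] - 1L]
      } else {
        w <- which(al[1:p])
        if (!length(w)) return(NA_integer_)
        lp_of_anc[w[length(w)]]
      }
    }
    ft2$start <- vapply(ftab$start, map1, 1L, up = TRUE)
    ft2$end <- vapply(ftab$end, map1, 1L, up = FALSE)
    ft2 <- ft2[!is.na(ft2$start) & !is.na(ft2$end) & ft2$start <= ft2$end, ,
               drop = FALSE]
    AnnotatedGenome(gsub("-", "", row, fixed = TRUE), sampleId = lid,
                    species = lid, subgenus = clade_of(lid),
                    circular = TRUE, features = ft2)
  })
  names(genomes) <- leaf_ids

  list(genomes = genomes, msa = msa, tree = tree,
       truth = list(edges = edges, edge_lengths = tree$edge.length,
                    substitutions = sub_records, indels = indel_records,
                    insertions = insertions,
                    planted_indels = planted,
                    clades = split(leaf_ids, sub("_.*$", "", leaf_ids))))
})

#' Run the full simulation
#'
#' [buildAncestor()] followed by [evolveGenomes()]; one call, one seed,
#' byte-reproducible output.
#'
#' @param config a [simulationConfig()].
#' @return list with `ancestor`, `genomes`, `msa`, `tree`, `truth` (the
#'   combined ancestor + evolution ground truth).
#' @export
simulatePlastomes <- function(config = simulationConfig()) {
  anc <- buildAncestor(config)
  ev <- evolveGenomes(anc, config)
  list(ancestor = anc$genome, genomes = ev$genomes, msa = ev$msa,
       tree = ev$tree,
       truth = c(anc$truth, ev$truth))
}

#' Replay recorded mutations to reproduce a leaf
#'
#' Independent re-application of the ground-truth records: substitutions and
#' deletions along the root-to-leaf path, then insertions, must reproduce
#' the emitted leaf sequence exactly.
#'
#' @param ancestor list from [buildAncestor()].
#' @param evolved list from [evolveGenomes()].
#' @param leafId leaf to reproduce.
#' @return the reconstructed (ungapped) leaf sequence string.
#' @export
replayLeaf <- function(ancestor, evolved, leafId) {
  tree <- evolved$tree
  tr <- evolved$truth
  node <- match(leafId, tree$tip.label)
  if (is.na(node)) stopf("unknown leaf '%s'", leafId)
  # root-to-leaf edge path
  path <- integer()
  cur <- node
  root <- length(tree$tip.label) + 1L
  while (cur != root) {
    ei <- which(tr$edges[, 2] == cur)
    path <- c(ei, path)
    cur <- tr$edges[ei, 1]
  }
  s <- seq_to_chars(genomeSequence(ancestor$genome))
  L <- length(s)
  alive <- rep(TRUE, L)
  rb <- ancestor$truth$region_bounds
  comp_b <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  mirror <- function(pos) rb$irb[2] - (pos - rb$ira[1])
  my_ins <- integer()
  for (ei in path) {
    subs <- tr$substitutions[[ei]]
    if (!is.null(subs) && nrow(subs)) {
      s[subs$pos] <- subs$to
      ira_idx <- subs$pos[subs$pos >= rb$ira[1] & subs$pos <= rb$ira[2]]
      if (length(ira_idx)) s[mirror(ira_idx)] <- unname(comp_b[s[ira_idx]])
    }
    ind <- tr$indels[[ei]]
    if (!is.null(ind) && nrow(ind)) {
      for (r in seq_len(nrow(ind))) {
        if (ind$type[r] == "del") {
          av <- which(alive & seq_len(L) >= ind$pos[r])
          alive[utils::head(av, ind$length[r])] <- FALSE
        }
      }
    }
  }
  for (ins in tr$insertions) if (ins$edge %in% path) my_ins <- c(my_ins, ins$id)
  # splice inherited insertions into the surviving sequence
  base <- s
  base[!alive] <- ""
  out <- character(L)
  out[] <- base
  if (length(my_ins)) {
    addons <- split(vapply(tr$insertions[my_ins], `[[`, "", "seq"),
                    vapply(tr$insertions[my_ins], `[[`, 1L, "pos"))
    ord <- lapply(addons, paste, collapse = "")
    for (p in names(ord)) {
      ip <- as.integer(p)
      out[ip] <- paste0(out[ip], ord[[p]])
    }
  }
  paste(out, collapse = "")
}
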