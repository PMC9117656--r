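# SNP-density hotspot discovery: an exhaustive sliding-window scan over the
# consensus (every start position, step 1 by default), a window qualifying
# when it holds strictly more than `minSnps - 1` SNP sites, followed by
# merging of overlapping qualifying windows into maximal hotspot regions and
# a tree-concordance screen of each region.

snp_indicator <- function(variants) {
  L <- nchar(consensusSequence(variants))
  ind <- logical(L)
  s <- variantSites(variants)
  pos <- s$consensus_pos[s$snp & !is.na(s$consensus_pos)]
  ind[pos] <- TRUE
  ind
}

#' Exhaustive SNP-density window scan
#'
#' Every start position on the consensus is examined (`step = 1` is the
#' exhaustive scan; larger steps are a speed knob). A window qualifies when
#' it contains at least `minSnps` SNP sites (the default 11 implements
#' "more than 10 per 1000 bp"). On circular consensi, wrap-around windows
#' are included.
#'
#' @param variants a [VariantTable-class].
#' @param window window length in bp (default 1000).
#' @param step start-position step (default 1).
#' @param minSnps minimum SNP sites per qualifying window (default 11).
#' @param circular include wrap-around windows (default TRUE).
#' @return data frame of qualifying windows: `start`, `end` (1-based on the
#'   consensus; `end` may exceed the consensus length for wrapped windows),
#'   `snp_count`.
#' @export
scanWindows <- function(variants, window = 1000L, step = 1L, minSnps = 11L,
                        circular = TRUE) {
  if (window < 1L || minSnps < 1L || step < 1L)
    stopf("window, step and minSnps must all be >= 1")
  window <- as.integer(window); step <- as.integer(step)
  ind <- snp_indicator(variants)
  L <- length(ind)
  if (L < window) stopf("window (%d) larger than consensus (%d)", window, L)
  x <- if (circular) c(ind, ind[seq_len(window - 1L)]) else ind
  cs <- c(0L, cumsum(x))
  starts <- seq.int(1L, L - if (circular) 0L else window - 1L, by = step)
  counts <- cs[starts + window] - cs[starts]
  hit <- counts >= minSnps
  data.frame(start = as.integer(starts[hit]),
             end = as.integer(starts[hit] + window - 1L),
             snp_count = as.integer(counts[hit]))
}

#' Merge qualifying windows into hotspot regions
#'
#' Overlapping or adjacent qualifying windows are unioned into maximal
#' regions; SNP count and frequency are recomputed on each merged interval.
#' Merged regions may have an SNP frequency below the window threshold: the
#' flanks contributed by outer windows dilute the density. That is expected,
#' not a defect.
#'
#' @param windows data frame from [scanWindows()].
#' @param variants the [VariantTable-class] the windows were scanned on.
#' @return data frame of hotspot regions: `start`, `end`, `length`,
#'   `snp_count`, `snp_frequency` (percent), `n_windows`, `features`
#'   (";"-joined names of features carrying the region's SNPs).
#' @export
mergeHotspots <- function(windows, variants) {
  empty <- data.frame(start = integer(), end = integer(), length = integer(),
                      snp_count = integer(), snp_frequency = numeric(),
                      n_windows = integer(), features = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(windows)) return(empty)
  ind <- snp_indicator(variants)
  L <- length(ind)
  w <- windows[order(windows$start), , drop = FALSE]
  rs <- w$start[1]; re <- w$end[1]; n <- 1L
  regions <- list()
  flush <- function() regions[[length(regions) + 1L]] <<-
    c(start = rs, end = re, n = n)
  if (nrow(w) > 1L) for (i in 2:nrow(w)) {
    if (w$start[i] <= re + 1L) {
      re <- max(re, w$end[i]); n <- n + 1L
    } else { flush(); rs <- w$start[i]; re <- w$end[i]; n <- 1L }
  }
  flush()
  m <- do.call(rbind, regions)
  # a trailing wrapped region that reaches the first region closes the circle
  if (nrow(m) > 1L && m[nrow(m), "end"] >= L + m[1, "start"]) {
    m[1, "start"] <- m[nrow(m), "start"]
    m[1, "n"] <- m[1, "n"] + m[nrow(m), "n"]
    m[1, "end"] <- max(m[1, "end"], m[nrow(m), "end"] - L)
    m <- m[-nrow(m), , drop = FALSE]
  }
  sites <- variantSites(variants)
  sites <- sites[sites$snp & !is.na(sites$consensus_pos), , drop = FALSE]
  out <- lapply(seq_len(nrow(m)), function(i) {
    s <- m[i, "start"]; e <- m[i, "end"]
    if (e < s) e <- e + L  # region closed over the circular origin
    if (e - s + 1L > L) e <- s + L - 1L  # cap at one full circle
    pos <- wrap1(s:e, L)
    cnt <- sum(ind[pos])
    len <- e - s + 1L
    feats <- unique(sites$feature[sites$consensus_pos %in% pos])
    feats <- feats[!is.na(feats)]
    data.frame(start = as.integer(s), end = as.integer(wrap1(e, L)),
               length = as.integer(len), snp_count = as.integer(cnt),
               snp_frequency = round_half_up(100 * cnt / len, 2),
               n_windows = as.integer(m[i, "n"]),
               features = paste(feats, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(list(empty), out))
}

#' Tree-concordance screen of hotspot regions
#'
#' For each region, a neighbor-joining tree is built from the region's
#' sub-alignment and each labelled clade is tested for monophyly; clade
#' support is estimated by `b` site-resampling replicates (columns resampled
#' with replacement), reporting the fraction of replicates in which every
#' clade is monophyletic. Regions with no variable column are non-concordant
#' by definition (they carry no signal).
#'
#' @param msa a [PlastomeAlignment-class].
#' @param regions data frame from [mergeHotspots()] (consensus coordinates).
#' @param cladeMap named list: clade name -> character vector of sample ids.
#' @param variants the [VariantTable-class] (for consensus-to-column
#'   mapping).
#' @param outgroup optional sample id to root at.
#' @param b number of site-resampling replicates (default 100).
#' @param minRegionLen regions shorter than this are skipped with a warning
#'   (default 100).
#' @return data frame: region coordinates plus `concordant` and
#'   `recovery_fraction`.
#' @export
screenMarkers <- function(msa, regions, cladeMap, variants, outgroup = NULL,
                          b = 100L, minRegionLen = 100L) {
  if (length(alignmentRows(msa)) < 3L) stopf("need >= 3 samples")
  if (length(cladeMap) < 2L) stopf("need >= 2 clades")
  cons <- buildConsensus(msa)
  col_of_cons <- which(!is.na(cons$columnMap))
  L <- length(col_of_cons)
  m <- msa_matrix(msa)

  clades_mono <- function(cols) {
    sub <- m[, cols, drop = FALSE]
    var_col <- apply(sub, 2, function(x) {
      bb <- x[x != "-" & x != "N"]
      length(unique(bb)) >= 2L
    })
    if (!any(var_col)) return(FALSE)
    am <- PlastomeAlignment(apply(sub, 1, paste, collapse = ""),
                            referenceId = referenceId(msa))
    dm <- tryCatch(pDistance(am), error = function(e) NULL)
    if (is.null(dm)) return(FALSE)
    tr <- neighborJoining(dm)
    all(vapply(cladeMap, function(ids)
      isMonophyletic(tr, ids, outgroup = outgroup), TRUE))
  }

  out <- lapply(seq_len(nrow(regions)), function(i) {
    len <- regions$length[i]
    if (len < minRegionLen) {
      warning(sprintf("region %d-%d shorter than %d bp; skipped",
                      regions$start[i], regions$end[i], minRegionLen))
      return(NULL)
    }
    pos <- wrap1(regions$start[i] + 0:(len - 1L), L)
    cols <- col_of_cons[pos]
    conc <- clades_mono(cols)
    hits <- vapply(seq_len(b), function(r)
      clades_mono(sample(cols, length(cols), replace = TRUE)), TRUE)
    data.frame(start = regions$start[i], end = regions$end[i],
               length = len, concordant = conc,
               recovery_fraction = mean(hits), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(list(data.frame(start = integer(), end = integer(),
                                   length = integer(), concordant = logical(),
                                   recovery_fraction = numeric(),
                                   stringsAsFactors = FALSE)), out))
}
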