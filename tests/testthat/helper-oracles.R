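# Independent oracles and fixture generators used across the suite.
# Oracles are deliberately naive (direct loops / exhaustive enumeration) and
# share no code with the package implementations they check.

rand_dna <- function(n, probs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# ---- SSR brute force: every (start, period) extension, maximal runs only ----
oracle_ssrs <- function(seq, thresholds = c(`1` = 10, `2` = 5, `3` = 4,
                                            `4` = 3, `5` = 3, `6` = 3)) {
  cs <- strsplit(seq, "")[[1]]
  n <- length(cs)
  is_primitive <- function(motif) {
    p <- nchar(motif)
    for (d in seq_len(p - 1)) {
      if (p %% d == 0 && motif == strrep(substr(motif, 1, d), p / d))
        return(FALSE)
    }
    TRUE
  }
  recs <- list()
  for (p in 1:6) {
    thr <- thresholds[[as.character(p)]]
    s <- 1L
    while (s + p * thr - 1L <= n) {
      # maximal-left run start only
      if (s > 1L && s - 1L + p <= n && cs[s - 1L] != "N" &&
          cs[s - 1L] == cs[s - 1L + p]) { s <- s + 1L; next }
      e <- s + p - 1L
      if (e > n) break
      while (e + 1L <= n && cs[e + 1L] == cs[e + 1L - p] &&
             cs[e + 1L] != "N") e <- e + 1L
      copies <- (e - s + 1L) %/% p
      motif <- paste(cs[s:(s + p - 1L)], collapse = "")
      if (copies >= thr && !grepl("N", motif) && is_primitive(motif)) {
        recs[[length(recs) + 1L]] <- data.frame(
          start = s, period = p, copies = copies, motif = motif,
          end = s + copies * p - 1L, stringsAsFactors = FALSE)
      }
      s <- s + 1L
    }
  }
  out <- do.call(rbind, c(list(data.frame(start = integer(),
                                          period = integer(),
                                          copies = integer(),
                                          motif = character(),
                                          end = integer())), recs))
  out <- unique(out)
  if (nrow(out) > 1L) {  # containment dedup, as documented for the scanner
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out))) {
      inside <- out$start <= out$start[i] & out$end >= out$end[i] &
        !(out$start == out$start[i] & out$end == out$end[i])
      if (any(inside & keep)) keep[i] <- FALSE
    }
    out <- out[keep, , drop = FALSE]
  }
  out[order(out$start, out$period), , drop = FALSE]
}

# ---- exact dispersed repeats: full per-diagonal scan, no seeding ----
oracle_transform <- function(seq, kind) {
  rc <- function(x) paste(rev(strsplit(chartr("ACGTN", "TGCAN", x),
                                       "")[[1]]), collapse = "")
  switch(kind,
         forward = seq,
         palindromic = rc(seq),
         reverse = paste(rev(strsplit(seq, "")[[1]]), collapse = ""),
         complement = chartr("ACGTN", "TGCAN", seq))
}

oracle_exact_repeats <- function(seq, kinds = c("forward", "palindromic",
                                                "reverse", "complement"),
                                 minLen = 30L) {
  cs <- strsplit(seq, "")[[1]]
  n <- length(cs)
  recs <- list()
  for (kind in kinds) {
    ct <- strsplit(oracle_transform(seq, kind), "")[[1]]
    for (d in (-(n - minLen)):(n - minLen)) {
      lo <- max(1L, 1L - d); hi <- min(n, n - d)
      if (hi - lo + 1L < minLen) next
      m <- cs[lo:hi] == ct[(lo + d):(hi + d)] & cs[lo:hi] != "N"
      r <- rle(m)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (h in which(r$values & r$lengths >= minLen)) {
        s1 <- lo + starts[h] - 1L; e1 <- lo + ends[h] - 1L
        j1 <- s1 + d; j2 <- e1 + d
        arm2 <- if (kind %in% c("palindromic", "reverse"))
          c(n - j2 + 1L, n - j1 + 1L) else c(j1, j2)
        if (s1 == arm2[1] && e1 == arm2[2]) next
        a <- if (s1 < arm2[1] || (s1 == arm2[1] && e1 <= arm2[2]))
          c(s1, e1, arm2) else c(arm2, s1, e1)
        recs[[length(recs) + 1L]] <- data.frame(
          kind = kind, start1 = a[1], end1 = a[2], start2 = a[3],
          end2 = a[4], length = e1 - s1 + 1L, stringsAsFactors = FALSE)
      }
    }
  }
  out <- unique(do.call(rbind, c(list(data.frame(
    kind = character(), start1 = integer(), end1 = integer(),
    start2 = integer(), end2 = integer(), length = integer())), recs)))
  if (nrow(out) > 1L) {
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out))) {
      cont <- out$kind == out$kind[i] &
        out$start1 <= out$start1[i] & out$end1 >= out$end1[i] &
        out$start2 <= out$start2[i] & out$end2 >= out$end2[i] &
        !(out$start1 == out$start1[i] & out$end1 == out$end1[i] &
            out$start2 == out$start2[i] & out$end2 == out$end2[i])
      if (any(cont & keep)) keep[i] <- FALSE
    }
    out <- out[keep, , drop = FALSE]
  }
  out[order(out$kind, out$start1, out$start2), , drop = FALSE]
}

# direct Hamming qualification of one reported repeat record
oracle_validates_repeat <- function(seq, rec, minLen = 30L,
                                    minIdentity = 0.9) {
  a1 <- strsplit(substr(seq, rec$start1, rec$end1), "")[[1]]
  a2raw <- substr(seq, rec$start2, rec$end2)
  a2 <- strsplit(oracle_transform(a2raw, rec$kind), "")[[1]]
  if (length(a1) != length(a2)) return(FALSE)
  m <- a1 == a2
  length(m) >= minLen && mean(m) >= minIdentity && m[1] && m[length(m)]
}

# plant a repeat pair into a sequence; returns list(seq, truth row)
plant_repeat <- function(seq, kind, len, mm, s1, s2) {
  arm1 <- rand_dna(len, c(A = .25, C = .25, G = .25, T = .25))
  a2 <- strsplit(oracle_transform(arm1, kind), "")[[1]]
  mps <- if (mm > 0) unique(round(seq(14, len - 10, length.out = mm)))
  else integer()
  for (mp in mps) {
    q <- if (kind %in% c("palindromic", "reverse")) len - mp + 1L else mp
    a2[q] <- sample(setdiff(c("A", "C", "G", "T"), a2[q]), 1)
  }
  cs <- strsplit(seq, "")[[1]]
  cs[s1:(s1 + len - 1L)] <- strsplit(arm1, "")[[1]]
  cs[s2:(s2 + len - 1L)] <- a2
  list(seq = paste(cs, collapse = ""),
       truth = data.frame(kind = kind, start1 = s1, end1 = s1 + len - 1L,
                          start2 = s2, end2 = s2 + len - 1L, length = len,
                          stringsAsFactors = FALSE))
}

# ---- hotspot window recount ----
oracle_window_counts <- function(snp_positions, L, window, circular = TRUE) {
  ind <- rep(0L, L)
  ind[snp_positions] <- 1L
  starts <- seq_len(if (circular) L else L - window + 1L)
  vapply(starts, function(s) {
    pos <- ((s:(s + window - 1L) - 1L) %% L) + 1L
    sum(ind[pos])
  }, 1L)
}

# ---- additive distance matrix from a random tree ----
additive_case <- function(n) {
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.05, 0.5))
  list(tree = tr, dm = ape::cophenetic.phylo(tr))
}

# small simulation preset used by several tests (fast, still quadripartite)
small_config <- function(seed, ...) {
  args <- list(seed = seed,
               nTaxa = c(Amaranthus = 3, Acnida = 3, Albersia = 4),
               lscLength = 20000, sscLength = 5000, irLength = 6000,
               nSsrs = 10)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulationConfig, args)
}

# fix accidental IR-boundary extensions in hand-built genomes
fix_boundaries <- function(seq, lsc, ir, ssc) {
  cs <- strsplit(seq, "")[[1]]
  comp <- function(b) chartr("ACGT", "TGCA", b)
  flip <- function(i) cs[i] <<- setdiff(c("A", "C", "G", "T"), cs[i])[1]
  if (cs[lsc + ir + 1L] == comp(cs[lsc + ir + ssc])) flip(lsc + ir + 1L)
  if (cs[lsc] == comp(cs[1L])) flip(lsc)
  paste(cs, collapse = "")
}
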