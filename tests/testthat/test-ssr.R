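# SSR scanning, composition statistics and the marker-combination search.

test_that("threshold boundaries and primitivity are enforced", {
  r <- findSSRs(paste0("GCGCGTT", strrep("A", 10), "GTGCCGT"))
  expect_identical(nrow(r), 1L)
  expect_identical(r$motif, "A")
  expect_identical(r$copies, 10L)
  expect_identical(nrow(findSSRs(paste0("GCGCGTT", strrep("A", 9),
                                        "GTGCCGT"))), 0L)

  # (AT)x5 is one period-2 SSR, never also a period-4 "ATAT" call
  r2 <- findSSRs(paste0("GCGGC", strrep("AT", 5), "GCCGG"))
  expect_identical(nrow(r2), 1L)
  expect_identical(r2$period, 2L)
  expect_identical(r2$copies, 5L)
})

test_that("every reported SSR re-validates as period x copies tandem", {
  set.seed(11)
  for (i in 1:20) {
    s <- rand_dna(600, c(A = .35, C = .15, G = .15, T = .35))
    r <- findSSRs(s)
    for (j in seq_len(nrow(r))) {
      seg <- substr(s, r$start[j], r$start[j] + r$length[j] - 1L)
      expect_identical(seg, strrep(r$motif[j], r$copies[j]))
    }
  }
})

test_that("the scanner agrees with the brute-force oracle", {
  set.seed(12)
  for (i in 1:60) {
    s <- rand_dna(400, c(A = .38, C = .12, G = .12, T = .38))
    got <- findSSRs(s)
    want <- oracle_ssrs(s)
    expect_identical(got[, c("start", "period", "copies", "motif")],
                     want[, c("start", "period", "copies", "motif")],
                     ignore_attr = TRUE)
  }
})

test_that("circular genomes find origin-spanning runs exactly once", {
  # 12 x A wrapped around the origin: 5 at the end, 7 at the start
  g <- AnnotatedGenome(paste0(strrep("A", 7), "GC", rand_dna(200),
                              "CG", strrep("A", 5)),
                       sampleId = "circ", circular = TRUE)
  set.seed(13)
  r <- findSSRs(g)
  wrapped <- r[r$motif == "A" & r$copies == 12L, ]
  expect_identical(nrow(wrapped), 1L)
  expect_identical(wrapped$start, nchar(genomeSequence(g)) - 4L)
  expect_identical(wrapped$end, 7L)

  # rotation shifts coordinates but preserves the call set
  s <- genomeSequence(g)
  g2 <- AnnotatedGenome(paste0(substr(s, 51, nchar(s)), substr(s, 1, 50)),
                        sampleId = "rot", circular = TRUE)
  r2 <- findSSRs(g2)
  expect_identical(sort(paste(r$motif, r$copies)),
                   sort(paste(r2$motif, r2$copies)))
})

test_that("composition statistics report documented percentages", {
  recs <- data.frame(at_only = c(rep(TRUE, 5), rep(FALSE, 4)),
                     region = c(rep("LSC", 7), "SSC", "IRa"),
                     context_kind = c(rep("IGS", 6), "CDS", "CDS", "IGS"),
                     period = c(1, 1, 1, 2, 2, 3, 4, 1, 1))
  st <- ssrCompositionStats(recs)
  expect_identical(st$percent_at_only, 55.56)   # 5 of 9
  expect_identical(st$percent_lsc, 77.78)       # 7 of 9
  expect_identical(st$percent_igs, 77.78)
  expect_identical(names(st$period_histogram)[1], "1")
  expect_error(ssrCompositionStats(recs[0, ]), "empty")

  all_a <- data.frame(at_only = TRUE, region = "LSC", context_kind = "IGS",
                      period = 1)
  expect_identical(ssrCompositionStats(all_a)$percent_at_only, 100)
})

test_that("planted SSR composition is recovered within sampling error", {
  cfg <- small_config(21, nSsrs = 40, ssrAtFraction = 0.6)
  anc <- buildAncestor(cfg)
  tr <- anc$truth$ssrs
  p_hat <- mean(tr$at_only)
  expect_lt(abs(p_hat - 0.6), 3 * sqrt(0.6 * 0.4 / nrow(tr)))
  # and the scanner labels planted records consistently with the truth
  qs <- detectInvertedRepeat(anc$genome)
  found <- findSSRs(anc$genome, structure = qs)
  for (i in seq_len(nrow(tr))) {
    hit <- found[found$start <= tr$start[i] & found$end >= tr$end[i] &
                   found$motif == tr$motif[i], ]
    expect_gte(nrow(hit), 1L)
  }
})

test_that("marker matrix and discriminating combinations match brute force", {
  m <- rbind(a = c(x1 = 10, x2 = 5, x3 = NA, x4 = 3),
             b = c(x1 = 10, x2 = 5, x3 = NA, x4 = 3),
             c = c(x1 = 10, x2 = 6, x3 = NA, x4 = 3),
             d = c(x1 = 10, x2 = 5, x3 = 4, x4 = 2))
  out <- discriminatingCombinations(m)
  expect_identical(nrow(out$inseparable), 1L)
  expect_identical(out$inseparable$sample_a, "a")
  expect_identical(out$inseparable$sample_b, "b")
  ac <- out$combinations[out$combinations$sample_a == "a" &
                           out$combinations$sample_b == "c", ]
  expect_identical(ac$size, 1L)
  expect_identical(ac$markers, "x2")

  # brute-force subset enumeration over a random 6-sample matrix
  set.seed(14)
  m2 <- matrix(sample(c(NA, 3:6), 6 * 5, TRUE), 6, 5,
               dimnames = list(letters[1:6], paste0("c", 1:5)))
  got <- discriminatingCombinations(m2)
  differs <- function(a, b) (is.na(a) != is.na(b)) |
    (!is.na(a) & !is.na(b) & a != b)
  for (i in 1:5) for (j in (i + 1):6) {
    d <- differs(m2[i, ], m2[j, ])
    row <- got$combinations[got$combinations$sample_a == letters[i] &
                              got$combinations$sample_b == letters[j], ]
    if (!any(d)) {
      expect_identical(nrow(row), 0L)
      expect_true(any(got$inseparable$sample_a == letters[i] &
                        got$inseparable$sample_b == letters[j]))
    } else {
      # oracle: smallest subset in lexicographic order whose columns differ
      found <- NULL
      for (size in 1:4) {
        cc <- utils::combn(1:5, size)
        ok <- which(apply(cc, 2, function(ix) any(d[ix])))
        if (length(ok)) { found <- cc[, ok[1]]; break }
      }
      expect_identical(row$markers,
                       paste(colnames(m2)[found], collapse = ";"))
    }
  }
  expect_error(discriminatingCombinations(m, maxSize = 0), "maxSize")
})
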