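# Dispersed repeat detection in the four senses, locus clustering and the
# circular-symmetry report.

test_that("planted exact duplications are found at planted coordinates", {
  set.seed(31)
  base <- rand_dna(3500)
  pf <- plant_repeat(base, "forward", 40, 0, 500, 2200)
  r <- findRepeats(pf$seq)
  hit <- r[r$kind == "forward" & r$start1 <= 500 & r$end1 >= 539, ]
  expect_gte(nrow(hit), 1L)
  expect_identical(hit$identity[1], 1)
  expect_gte(hit$length[1], 40L)

  pp <- plant_repeat(base, "palindromic", 35, 0, 800, 2700)
  r2 <- findRepeats(pp$seq)
  expect_gte(nrow(r2[r2$kind == "palindromic" & r2$start1 <= 800 &
                       r2$end1 >= 834, ]), 1L)
})

test_that("all four repeat senses re-validate by direct comparison", {
  set.seed(32)
  for (kind in c("forward", "palindromic", "reverse", "complement")) {
    base <- rand_dna(3000)
    p <- plant_repeat(base, kind, 38, 2, 400, 1900)
    r <- findRepeats(p$seq)
    found <- r[r$kind == kind &
                 pmax(r$start1, p$truth$start1) <=
                   pmin(r$end1, p$truth$end1), ]
    expect_gte(nrow(found), 1L)
    for (j in seq_len(nrow(r))) {
      expect_true(oracle_validates_repeat(p$seq, r[j, ]))
      expect_equal(repeatIdentity(p$seq, r[j, ]), r$identity[j])
    }
  }
})

test_that("mismatch-free output equals the exhaustive diagonal oracle", {
  set.seed(33)
  for (i in 1:6) {
    s <- rand_dna(700)
    kind <- sample(c("forward", "palindromic", "reverse", "complement"), 1)
    p <- plant_repeat(s, kind, sample(30:45, 1), 0, 60, 400)
    got <- findRepeats(p$seq, minIdentity = 1)
    want <- oracle_exact_repeats(p$seq)
    cols <- c("kind", "start1", "end1", "start2", "end2")
    expect_identical(got[order(got$kind, got$start1, got$start2), cols],
                     want[, cols], ignore_attr = TRUE)
  }
})

test_that("forward detection is symmetric in arm order", {
  set.seed(34)
  s <- rand_dna(2500)
  p <- plant_repeat(s, "forward", 40, 2, 300, 1700)
  r <- findRepeats(p$seq, kinds = "forward")
  expect_true(all(r$start1 <= r$start2))
  expect_identical(anyDuplicated(r[, c("start1", "start2")]), 0L)
})

test_that("invalid identity bounds are rejected", {
  expect_error(findRepeats("ACGTACGTACGT", minIdentity = 0), "minIdentity")
  expect_error(findRepeats("ACGTACGTACGT", minIdentity = 1.2), "minIdentity")
  expect_error(findRepeats(rand_dna(40), minLen = 30), "shorter")
})

test_that("the whole-IR palindromic self-hit is suppressed, plastome repeats kept", {
  anc <- buildAncestor(small_config(35))
  qs <- detectInvertedRepeat(anc$genome)
  r <- findRepeats(anc$genome, structure = qs)
  ir_self <- r[r$kind == "palindromic" & r$length >= 0.9 * qs@irLength, ]
  expect_identical(nrow(ir_self), 0L)
  tr <- anc$truth$repeats
  for (i in seq_len(nrow(tr))) {
    hit <- r[r$kind == tr$kind[i] &
               pmax(r$start1, tr$start1[i]) <= pmin(r$end1, tr$end1[i]) &
               pmax(r$start2, tr$start2[i]) <= pmin(r$end2, tr$end2[i]), ]
    expect_gte(nrow(hit), 1L)
  }
})

test_that("cross-sample loci cluster by reference projection", {
  rows <- c(ref = strrep("ACGT", 250), s2 = strrep("ACGT", 250))
  msa <- PlastomeAlignment(rows, referenceId = "ref")
  rec <- data.frame(sample = NA, kind = "forward", start1 = 101L,
                    end1 = 140L, start2 = 500L, end2 = 539L, length = 40L,
                    identity = 1, stringsAsFactors = FALSE)
  loci <- clusterRepeatLoci(list(ref = rec, s2 = rec), msa)
  expect_identical(length(unique(loci$locus)), 1L)
  expect_true(all(loci$common))
  expect_false(any(loci$variable_length))

  # length difference flips the variable flag
  rec2 <- rec; rec2$end1 <- 150L; rec2$length <- 50L
  loci2 <- clusterRepeatLoci(list(ref = rec, s2 = rec2), msa)
  expect_true(all(loci2$variable_length))

  # repeats far apart on the reference form distinct loci
  recA <- rec; recB <- rec
  recB$start1 <- 701L; recB$end1 <- 740L
  loci3 <- clusterRepeatLoci(list(ref = rbind(recA, recB)),
                             PlastomeAlignment(rows["ref"],
                                               referenceId = "ref"),
                             linkGap = 300L)
  expect_identical(length(unique(loci3$locus)), 2L)
  expect_error(clusterRepeatLoci(list(zz = rec), msa), "missing")
})

test_that("antipodal arms score near zero, coincident arms score 180", {
  qs <- new("QuadripartiteStructure", lsc = c(1L, 500L), ira = c(501L, 700L),
            ssc = c(701L, 800L), irb = c(801L, 1000L),
            lscLength = 500L, sscLength = 100L, irLength = 200L,
            totalLength = 1000L, gcPercent = 40)
  rec <- data.frame(start1 = 250L, end1 = 250L, start2 = 750L, end2 = 750L)
  out <- symmetryReport(rec, qs)
  expect_equal(out$separation_deg, 180)
  expect_equal(out$antipodality_deg, 0)
  rec2 <- data.frame(start1 = 100L, end1 = 100L, start2 = 100L, end2 = 100L)
  expect_equal(symmetryReport(rec2, qs)$antipodality_deg, 180)
})

test_that("simulator's antipodal planted pair scores below 5 degrees", {
  anc <- buildAncestor(small_config(36))
  qs <- detectInvertedRepeat(anc$genome)
  tr <- anc$truth$repeats
  anti <- symmetryReport(tr[tr$antipodal, ], qs)
  # placement jitter is +/-1.5 kb on a 37 kb circle => up to ~15 degrees;
  # scaled to the default 150.6 kb architecture the same jitter is < 5
  expect_true(all(anti$antipodality_deg <= 360 * 1500 / qs@totalLength + 1))
})
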