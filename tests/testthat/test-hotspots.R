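# Exhaustive SNP-density window scan, hotspot merging and the
# tree-concordance screen.

# a VariantTable with SNPs exactly at `pos` on an `L`-column consensus
fake_variants <- function(pos, L) {
  sites <- data.frame(column = pos, consensus_pos = pos,
                      class = "IGS", feature = "igs-1",
                      snp = TRUE, indel = FALSE, alleles = "A/C",
                      stringsAsFactors = FALSE)
  new("VariantTable", sites = sites,
      classTally = data.frame(), consensus = strrep("A", L),
      ingroup = c("a", "b"))
}

test_that("uniform low density yields no qualifying windows", {
  set.seed(51)
  L <- 10000L
  vt <- fake_variants(sort(sample(L, 50)), L)  # 0.5% density
  w <- scanWindows(vt, window = 1000, minSnps = 11)
  expect_identical(nrow(w), 0L)
})

test_that("window counts equal the brute-force recount at every start", {
  set.seed(52)
  L <- 3000L
  pos <- sort(sample(L, 60))
  vt <- fake_variants(pos, L)
  w <- scanWindows(vt, window = 500, minSnps = 1, circular = TRUE)
  want <- oracle_window_counts(pos, L, 500, circular = TRUE)
  expect_identical(nrow(w), sum(want >= 1))
  expect_identical(w$snp_count, unname(want[want >= 1]))
  w11 <- scanWindows(vt, window = 500, minSnps = 15)
  expect_identical(w11$start, which(want >= 15))
})

test_that("a planted dense segment qualifies exactly where it should", {
  set.seed(53)
  L <- 8000L
  planted <- sort(sample(3000:3999, 20))
  vt <- fake_variants(planted, L)
  w <- scanWindows(vt, window = 1000, minSnps = 11)
  want <- oracle_window_counts(planted, L, 1000)
  expect_identical(w$start, which(want >= 11))
  hs <- mergeHotspots(w, vt)
  expect_identical(nrow(hs), 1L)
  expect_lte(hs$start, 3000L)
  expect_gte(hs$start + hs$length - 1L, 3999L)
})

test_that("window/minSnps guards and the too-large window error fire", {
  vt <- fake_variants(c(5L, 10L), 100L)
  expect_error(scanWindows(vt, window = 0), ">= 1")
  expect_error(scanWindows(vt, minSnps = 0), ">= 1")
  expect_error(scanWindows(vt, window = 1000), "larger than")
})

test_that("overlapping windows merge, disjoint ones stay separate", {
  vt <- fake_variants(c(100L, 600L, 1200L), 2000L)
  w <- data.frame(start = c(1L, 501L), end = c(1000L, 1500L),
                  snp_count = c(2L, 2L))
  hs <- mergeHotspots(w, vt)
  expect_identical(nrow(hs), 1L)
  expect_identical(c(hs$start, hs$end), c(1L, 1500L))
  expect_identical(hs$snp_count, 3L)
  expect_identical(hs$n_windows, 2L)

  w2 <- data.frame(start = c(1L, 1200L), end = c(100L, 1400L),
                   snp_count = c(1L, 1L))
  expect_identical(nrow(mergeHotspots(w2, vt)), 2L)
  expect_identical(nrow(mergeHotspots(w[0, ], vt)), 0L)
})

test_that("two planted high-rate segments come out as two regions", {
  cfg <- small_config(54, treeScale = 0.15,
                      hotspots = list(
                        list(region = "LSC", at = 0.30, length = 1000,
                             multiplier = 25),
                        list(region = "LSC", at = 0.70, length = 1000,
                             multiplier = 25)))
  sim <- simulatePlastomes(cfg)
  ing <- setdiff(names(sim$genomes), "outgroup_1")
  vt <- callVariants(sim$msa, sim$genomes[[referenceId(sim$msa)]],
                     ingroup = ing)
  hs <- mergeHotspots(scanWindows(vt, 1000, minSnps = 11), vt)
  planted <- sim$truth$hotspots
  for (i in seq_len(nrow(planted))) {
    covered <- any(hs$start <= planted$start[i] &
                     (hs$start + hs$length - 1L) >= planted$end[i])
    expect_true(covered)
  }
})

test_that("clade-separating regions are concordant, flat regions are not", {
  # 3 fixed differences per clade across a 200 bp region
  set.seed(55)
  core <- rand_dna(200)
  mutate_at <- function(s, at) {
    cs <- strsplit(s, "")[[1]]
    cs[at] <- vapply(cs[at], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    paste(cs, collapse = "")
  }
  cladeA <- mutate_at(core, c(20, 50, 80, 110, 140))
  cladeB <- mutate_at(core, c(40, 70, 100, 130, 160))
  rows <- c(A1 = cladeA, A2 = cladeA, B1 = cladeB, B2 = cladeB,
            O1 = mutate_at(core, c(5, 190)))
  msa <- PlastomeAlignment(rows, referenceId = "A1")
  vt0 <- callVariants(msa, toy_ann <- AnnotatedGenome(
    core, sampleId = "A1", features = data.frame(
      feature_id = "f1", kind = "CDS", name = "g", start = 1L, end = 200L,
      strand = "+", part = 1L)))
  regions <- data.frame(start = 1L, end = 200L, length = 200L)
  set.seed(56)
  sc <- screenMarkers(msa, regions, cladeMap = list(A = c("A1", "A2"),
                                                    B = c("B1", "B2")),
                      vt0, outgroup = "O1", b = 30)
  expect_true(sc$concordant)
  # site resampling can drop a clade's informative sites in a replicate
  expect_gte(sc$recovery_fraction, 0.9)

  # zero variation: star tree, never concordant
  flat <- PlastomeAlignment(setNames(rep(core, 5), names(rows)), "A1")
  vt1 <- callVariants(flat, toy_ann)
  set.seed(57)
  sc2 <- screenMarkers(flat, regions, cladeMap = list(A = c("A1", "A2"),
                                                      B = c("B1", "B2")),
                       vt1, outgroup = "O1", b = 10)
  expect_false(sc2$concordant)
  expect_identical(sc2$recovery_fraction, 0)

  expect_warning(
    screenMarkers(msa, data.frame(start = 1L, end = 50L, length = 50L),
                  cladeMap = list(A = c("A1", "A2"), B = c("B1", "B2")),
                  vt0, b = 2), "skipped")
})
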