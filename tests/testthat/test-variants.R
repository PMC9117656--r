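# Consensus building, class-stratified variant calling, pairwise differences
# and indel-event extraction.

toy_annotation <- function(seq, genes) {
  ft <- do.call(rbind, lapply(seq_along(genes), function(i) {
    g <- genes[[i]]
    data.frame(feature_id = paste0("f", i), kind = g$kind, name = g$name,
               start = g$start, end = g$end, strand = "+", part = 1L,
               stringsAsFactors = FALSE)
  }))
  AnnotatedGenome(seq, sampleId = "ref", features = ft)
}

test_that("consensus takes the majority base, ties alphabetical, gaps ignored", {
  msa <- PlastomeAlignment(c(a = "ACGT", b = "ACGT", c = "ACGA"))
  expect_identical(buildConsensus(msa)$consensus, "ACGT")
  msa2 <- PlastomeAlignment(c(a = "A-", b = "AA"))
  expect_identical(buildConsensus(msa2)$consensus, "AA")
  # T vs G one each: alphabetical order -> G
  msa3 <- PlastomeAlignment(c(a = "AT", b = "AG"))
  expect_identical(buildConsensus(msa3)$consensus, "AG")
  # all-gap columns are dropped and the column map says so
  msa4 <- PlastomeAlignment(c(a = "A-C", b = "A-C"))
  cons <- buildConsensus(msa4)
  expect_identical(cons$consensus, "AC")
  expect_identical(cons$columnMap, c(1L, NA, 2L))
  expect_error(buildConsensus(PlastomeAlignment(c(a = "--", b = "--"))),
               "all-gap")
})

test_that("identical rows produce an all-zero variant table", {
  rows <- setNames(rep(strrep("ACGT", 30), 3), c("r1", "r2", "r3"))
  ann <- toy_annotation(strrep("ACGT", 30),
                        list(list(kind = "CDS", name = "g1", start = 10,
                                  end = 60)))
  ann <- methods::initialize(ann, sampleId = "r1")
  vt <- callVariants(PlastomeAlignment(rows, "r1"), ann)
  tal <- classTally(vt)
  expect_true(all(tal$snp_count == 0))
  expect_true(all(tal$indel_count == 0))
  expect_true(all(tal$snp_frequency == 0))
})

test_that("class lengths tile the consensus and counts are conserved", {
  sim <- simulatePlastomes(small_config(41))
  ing <- setdiff(names(sim$genomes), "outgroup_1")
  vt <- callVariants(sim$msa, sim$genomes[[referenceId(sim$msa)]],
                     ingroup = ing)
  tal <- classTally(vt)
  base <- tal[!(tal$class %in% c("Consensus", "Gene")), ]
  expect_identical(sum(base$region_length),
                   tal$region_length[tal$class == "Consensus"])
  expect_identical(sum(base$region_length),
                   nchar(consensusSequence(vt)))
  expect_identical(sum(base$snp_count),
                   tal$snp_count[tal$class == "Consensus"])
  expect_identical(sum(base$indel_count),
                   tal$indel_count[tal$class == "Consensus"])
  gene <- tal[tal$class == "Gene", ]
  sub <- base[base$class != "IGS", ]
  expect_identical(gene$region_length, sum(sub$region_length))
  expect_identical(gene$snp_count, sum(sub$snp_count))
})

test_that("variant calling is invariant to row order and duplicated rows", {
  sim <- simulatePlastomes(small_config(42))
  ing <- setdiff(names(sim$genomes), "outgroup_1")
  ref <- sim$genomes[[referenceId(sim$msa)]]
  vt <- callVariants(sim$msa, ref, ingroup = ing)
  rows <- alignmentRows(sim$msa)
  perm <- PlastomeAlignment(rows[rev(names(rows))],
                            referenceId = referenceId(sim$msa))
  vt2 <- callVariants(perm, ref, ingroup = ing)
  expect_identical(variantSites(vt)[, c("column", "class", "snp", "indel")],
                   variantSites(vt2)[, c("column", "class", "snp", "indel")])
  # adding a duplicate of an existing row leaves the site set unchanged
  dup <- rows
  dup[["dup_1"]] <- rows[[ing[1]]]
  vt3 <- callVariants(PlastomeAlignment(dup, referenceId(sim$msa)), ref,
                      ingroup = c(ing, "dup_1"))
  expect_identical(variantSites(vt)$column, variantSites(vt3)$column)
})

test_that("pairwise differences count SNPs and maximal indel runs", {
  msa <- PlastomeAlignment(c(x = "AACCGG", y = "AATC-G"))
  pd <- pairwiseDifferences(msa, "x", "y")
  expect_identical(pd$snp_count, 1L)
  expect_identical(pd$indel_event_count, 1L)
  expect_identical(pd$indel_events$length, 1L)
  expect_identical(pd$indel_events$carrier, "y")

  same <- PlastomeAlignment(c(x = "ACGT", y = "ACGT"))
  pd2 <- pairwiseDifferences(same, "x", "y")
  expect_identical(pd2$snp_count, 0L)
  expect_identical(pd2$indel_event_count, 0L)
  expect_error(pairwiseDifferences(msa, "x", "zz"), "unknown sample")

  # a two-sided example: gaps in both rows are separate events
  msa3 <- PlastomeAlignment(c(x = "AA--CCGGT", y = "AATTCC--T"))
  pd3 <- pairwiseDifferences(msa3, "x", "y")
  expect_identical(pd3$indel_event_count, 2L)
  expect_setequal(pd3$indel_events$carrier, c("x", "y"))
})

test_that("longest indels sort by length then coordinate and carry features", {
  ev <- data.frame(start_col = c(10L, 500L, 900L), end_col = c(12L, 886L,
                                                               1283L),
                   length = c(3L, 387L, 384L))
  top <- longestIndels(ev, 3)
  expect_identical(top$length, c(387L, 384L, 3L))
  expect_identical(longestIndels(ev, 1)$length, 387L)
  expect_error(longestIndels(ev, 0), "k must be")
  expect_error(longestIndels(ev[0, ], 1), "no events")

  # simulator: the planted clade-stem deletions surface as the longest events
  sim <- simulatePlastomes(small_config(43))
  ing <- setdiff(names(sim$genomes), "outgroup_1")
  evs <- indelEvents(sim$msa, sim$genomes[[referenceId(sim$msa)]],
                     ingroup = ing)
  top2 <- longestIndels(evs, 2)
  expect_setequal(top2$length, c(387L, 384L))
  expect_setequal(top2$feature, c("ycf2", "psbM-trnD"))
})
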