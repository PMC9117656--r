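# GenBank and aligned-FASTA I/O, coordinate conversion, IGS derivation.

make_toy_gb <- function(path, seq = strrep("ACGT", 125),
                        feats = c("     CDS             join(100..200,300..400)",
                                  '                     /gene="tester"')) {
  lines <- c(sprintf("LOCUS       toy %d bp DNA circular PLN 01-JAN-2026",
                     nchar(seq)),
             "FEATURES             Location/Qualifiers",
             sprintf("     source          1..%d", nchar(seq)),
             feats,
             "ORIGIN")
  s <- tolower(seq)
  for (i in seq(1, nchar(s), 60))
    lines <- c(lines, sprintf("%9d %s", i, substr(s, i, min(i + 59,
                                                            nchar(s)))))
  writeLines(c(lines, "//"), path)
  path
}

test_that("a CDS join is split into exon parts plus a derived intron", {
  tf <- make_toy_gb(tempfile(fileext = ".gb"))
  g <- readGenBank(tf)
  expect_true(isCircular(g))
  expect_identical(genomeSequence(g), strrep("ACGT", 125))
  ft <- features(g)
  cds <- ft[ft$kind == "CDS", ]
  expect_identical(cds$start, c(100L, 300L))
  expect_identical(cds$end, c(200L, 400L))
  expect_identical(cds$feature_id[1], cds$feature_id[2])
  intr <- ft[ft$kind == "intron", ]
  expect_identical(nrow(intr), 1L)
  # the gap between exon parts, in the file's 1-based closed coordinates
  expect_identical(c(intr$start, intr$end), c(201L, 299L))
})

test_that("minimal records round-trip through read -> write -> read", {
  tf <- make_toy_gb(tempfile(fileext = ".gb"),
                    feats = c("     gene            50..120",
                              '                     /gene="g1"',
                              "     tRNA            complement(200..272)",
                              '                     /gene="trnX"'))
  g <- readGenBank(tf)
  tf2 <- tempfile(fileext = ".gb")
  writeGenBank(g, tf2)
  g2 <- readGenBank(tf2)
  expect_identical(genomeSequence(g2), genomeSequence(g))
  f1 <- features(g); f2 <- features(g2)
  expect_identical(f1[order(f1$start), c("kind", "name", "start", "end",
                                         "strand")],
                   f2[order(f2$start), c("kind", "name", "start", "end",
                                         "strand")],
                   ignore_attr = TRUE)
  expect_identical(features(g2)$strand[features(g2)$kind == "tRNA"], "-")
})

test_that("malformed records raise parse errors naming the problem", {
  tf <- tempfile()
  writeLines(c("LOCUS       bad 10 bp", "FEATURES",
               "     CDS             nonsense..x", "ORIGIN",
               "        1 acgtacgtac", "//"), tf)
  expect_error(readGenBank(tf), "line")
  tf2 <- tempfile()
  writeLines(c("LOCUS       bad 0 bp", "ORIGIN", "//"), tf2)
  expect_error(readGenBank(tf2), "empty sequence")
  expect_error(readGenBank({
    tf3 <- tempfile(); writeLines("not genbank", tf3); tf3
  }), "LOCUS|ORIGIN")
})

test_that("deriveIgs names spacers after flanking genes and conserves length", {
  ft <- rbind(
    data.frame(feature_id = "f1", kind = "gene", name = "g1", start = 1L,
               end = 100L, strand = "+", part = 1L),
    data.frame(feature_id = "f2", kind = "gene", name = "g2", start = 201L,
               end = 300L, strand = "+", part = 1L))
  g <- AnnotatedGenome(strrep("ACGT", 100), sampleId = "toy", features = ft)
  g2 <- deriveIgs(g)
  igs <- features(g2)[features(g2)$kind == "IGS", ]
  expect_setequal(igs$name, c("g1-g2", "g2-g1"))
  expect_identical(igs$start[igs$name == "g1-g2"], 101L)
  expect_identical(igs$end[igs$name == "g1-g2"], 200L)
  # wrapping spacer: only the tail arc exists because g1 starts at base 1
  expect_identical(igs$start[igs$name == "g2-g1"], 301L)
  expect_identical(igs$end[igs$name == "g2-g1"], 400L)
  expect_identical(igsLength(g2) + 200L, genomeLength(g2))
})

test_that("overlapping genes are merged and produce no zero-length IGS", {
  ft <- rbind(
    data.frame(feature_id = "f1", kind = "gene", name = "g1", start = 10L,
               end = 100L, strand = "+", part = 1L),
    data.frame(feature_id = "f2", kind = "gene", name = "g2", start = 80L,
               end = 150L, strand = "+", part = 1L),
    data.frame(feature_id = "f3", kind = "gene", name = "g3", start = 151L,
               end = 200L, strand = "+", part = 1L))
  g <- AnnotatedGenome(strrep("AC", 150), sampleId = "toy", features = ft)
  igs <- features(deriveIgs(g))
  igs <- igs[igs$kind == "IGS", ]
  expect_true(all(igs$end >= igs$start))
  expect_false(any(igs$start >= 80 & igs$end <= 151))
  expect_error(deriveIgs(AnnotatedGenome("ACGT")), "no gene features")
})

test_that("IGS derivation agrees with the simulator's planted layout", {
  anc <- buildAncestor(small_config(5))
  stripped <- methods::initialize(
    anc$genome, features = features(anc$genome)[
      features(anc$genome)$kind != "IGS", ])
  g2 <- deriveIgs(stripped)
  expect_identical(igsLength(g2), as.integer(anc$truth$igs_total))
})

test_that("aligned FASTA reading validates shape and flags ragged rows", {
  tf <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "AC-T", ">c", "ACGT"), tf)
  msa <- readMsa(tf)
  expect_s4_class(msa, "PlastomeAlignment")
  expect_identical(names(alignmentRows(msa)), c("a", "b", "c"))
  m <- do.call(rbind, strsplit(alignmentRows(msa), ""))
  expect_identical(which(apply(m == "-", 2, any)), 3L)

  tf2 <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">bad", "ACGTT"), tf2)
  expect_error(readMsa(tf2), "bad")

  # identical rows: a valid alignment with zero variable columns downstream
  tf3 <- tempfile(fileext = ".fasta")
  writeLines(c(">r1", "ACGT", ">r2", "ACGT", ">r3", "ACGT"), tf3)
  msa3 <- readMsa(tf3)
  vt <- callVariants(msa3, AnnotatedGenome("ACGT", sampleId = "r1",
                                           features = data.frame(
      feature_id = "f1", kind = "gene", name = "g", start = 1L, end = 4L,
      strand = "+", part = 1L)))
  expect_identical(sum(variantSites(vt)$snp), 0L)
})

test_that("simulator-emitted files parse back with matching ids", {
  sim <- simulatePlastomes(small_config(9))
  dir <- tempfile()
  writeSimulation(sim, dir)
  msa <- readMsa(file.path(dir, "aligned.fasta"))
  expect_setequal(names(alignmentRows(msa)), names(sim$genomes))
  g <- readGenBank(file.path(dir, "Acnida_1.gb"))
  expect_identical(genomeSequence(g), genomeSequence(sim$genomes$Acnida_1))
})
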