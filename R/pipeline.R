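# Pipeline orchestration: run the full comparative workflow
# (partition -> ssr -> repeats -> variants -> hotspots -> tree) over a set of
# annotated genomes plus a whole-genome alignment, writing TSV/newick/JSON
# reports and a run manifest. A failure in one stage is recorded and the
# remaining stages still run; missing inputs abort before any stage starts.

PIPELINE_STAGES <- c("partition", "ssr", "repeats", "variants", "hotspots",
                     "tree")

#' Run the comparative plastome pipeline
#'
#' @param config a list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{genomes}{character vector of GenBank file paths, or a named
#'       list of [AnnotatedGenome-class] objects.}
#'     \item{msa}{aligned FASTA path or a [PlastomeAlignment-class]
#'       (required for the variants/hotspots/tree stages).}
#'     \item{reference}{sample id whose annotation is projected.}
#'     \item{outdir}{output directory (created if absent).}
#'     \item{ingroup}{sample ids for the variant tallies (default: all).}
#'     \item{cladeMap}{named list clade -> sample ids (tree/hotspot
#'       concordance).}
#'     \item{outgroup}{sample id to root the tree at.}
#'     \item{stages}{subset of `r toString(PIPELINE_STAGES)`.}
#'     \item{seed}{seed recorded in the manifest and used by the hotspot
#'       concordance resampling.}
#'     \item{subgenusMap}{named vector sample id -> subgenus (for the SSC
#'       summary).}
#'   }
#' @return the run manifest (also written to `manifest.json`), invisibly.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (is.list(config$genomes) &&
      all(vapply(config$genomes, is.character, TRUE)))
    config$genomes <- unlist(config$genomes)
  stages <- unlist(config$stages) %||% PIPELINE_STAGES
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stopf("unknown stage name(s): %s", paste(bad, collapse = ", "))
  outdir <- config$outdir %||% stopf("config$outdir is required")
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  # ---- inputs (validated before any stage runs) ----
  if (is.null(config$genomes)) stopf("config$genomes is required")
  input_hashes <- character()
  if (is.character(config$genomes)) {
    missing <- config$genomes[!file.exists(config$genomes)]
    if (length(missing))
      stopf("missing input file(s): %s", paste(missing, collapse = ", "))
    input_hashes <- tools::md5sum(config$genomes)
    genomes <- lapply(config$genomes, readGenBank)
    names(genomes) <- vapply(genomes, sampleId, "")
  } else {
    genomes <- config$genomes
    names(genomes) <- vapply(genomes, sampleId, "")
  }
  if (length(genomes) < 2L) stopf("need at least 2 genomes")
  if (!is.null(config$subgenusMap)) {
    for (id in names(genomes))
      if (id %in% names(config$subgenusMap))
        genomes[[id]]@subgenus <- config$subgenusMap[[id]]
  }
  msa <- NULL
  if (!is.null(config$msa)) {
    msa <- if (is.character(config$msa)) {
      if (!file.exists(config$msa)) stopf("missing MSA file: %s", config$msa)
      input_hashes <- c(input_hashes, tools::md5sum(config$msa))
      readMsa(config$msa, referenceId = config$reference)
    } else config$msa
  }
  reference <- config$reference %||% names(genomes)[1]
  if (!(reference %in% names(genomes)))
    stopf("reference '%s' is not among the genomes", reference)
  seed <- config$seed %||% 1L

  manifest <- list(
    tool = "plastcomp",
    version = as.character(utils::packageVersion("plastcomp")),
    seed = seed,
    config = config[setdiff(names(config), c("genomes", "msa"))],
    inputs = as.list(input_hashes),
    stages = list())
  outputs <- function(...) file.path(outdir, c(...))
  record <- function(stage, files, note = "ok") {
    rows <- vapply(files, function(f) {
      if (!file.exists(f)) return(NA_integer_)
      max(0L, length(readLines(f, warn = FALSE)) - 1L)
    }, 1L)
    manifest$stages[[stage]] <<- list(status = note,
                                      outputs = as.list(stats::setNames(rows,
                                                                        files)))
  }
  run_stage <- function(stage, fun) {
    if (!(stage %in% stages)) return(invisible())
    tryCatch(fun(), error = function(e) {
      warning(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
      manifest$stages[[stage]] <<- list(status = paste("error:",
                                                       conditionMessage(e)),
                                        outputs = list())
    })
  }

  structures <- list()
  str_of <- function(id) if (id %in% names(structures)) structures[[id]]
    else NULL
  run_stage("partition", function() {
    tab <- do.call(rbind, lapply(genomes, plastomeSummary))
    structures <<- lapply(genomes, detectInvertedRepeat)
    f <- outputs("table1.tsv")
    writeReportTsv(tab, f)
    fs <- f
    sg <- vapply(genomes, subgenus, "")
    if (all(nzchar(sg)) && length(unique(sg[sg != "outgroup"])) > 1L) {
      keep <- sg != "outgroup"
      t2 <- sscSummaryBySubgenus(data.frame(subgenus = sg[keep],
                                            ssc_bp = tab$ssc_bp[keep]))
      f2 <- outputs("table2.tsv")
      writeReportTsv(t2, f2)
      fs <- c(fs, f2)
    }
    record("partition", fs)
  })

  ssr_records <- NULL
  run_stage("ssr", function() {
    ssr_records <<- lapply(names(genomes), function(id)
      findSSRs(genomes[[id]], structure = str_of(id)))
    names(ssr_records) <<- names(genomes)
    all <- do.call(rbind, ssr_records)
    f1 <- outputs("ssrs.tsv"); writeReportTsv(all, f1)
    m <- ssrMarkerMatrix(ssr_records)
    f2 <- outputs("ssr_matrix.tsv")
    writeReportTsv(data.frame(sample = rownames(m), m, check.names = FALSE),
                   f2)
    dc <- discriminatingCombinations(m)
    f3 <- outputs("ssr_markers.tsv"); writeReportTsv(dc$combinations, f3)
    f4 <- outputs("ssr_inseparable.tsv"); writeReportTsv(dc$inseparable, f4)
    record("ssr", c(f1, f2, f3, f4))
  })

  run_stage("repeats", function() {
    recs <- lapply(names(genomes), function(id)
      findRepeats(genomes[[id]], structure = str_of(id)))
    names(recs) <- names(genomes)
    all <- do.call(rbind, recs)
    f1 <- outputs("repeats.tsv"); writeReportTsv(all, f1)
    fs <- f1
    if (!is.null(msa)) {
      loci <- clusterRepeatLoci(recs, msa, referenceId = reference)
      f2 <- outputs("repeat_loci.tsv"); writeReportTsv(loci, f2)
      if (length(structures)) {
        sym <- symmetryReport(loci, structures[[reference]])
        f3 <- outputs("repeat_symmetry.tsv"); writeReportTsv(sym, f3)
        fs <- c(fs, f2, f3)
      } else fs <- c(fs, f2)
    }
    record("repeats", fs)
  })

  vt <- NULL
  run_stage("variants", function() {
    if (is.null(msa)) stopf("variants stage requires an MSA")
    vt <<- callVariants(msa, genomes[[reference]],
                        ingroup = config$ingroup)
    f1 <- outputs("table3.tsv"); writeReportTsv(classTally(vt), f1)
    f2 <- outputs("variants.tsv"); writeReportTsv(variantSites(vt), f2)
    ev <- indelEvents(msa, genomes[[reference]], ingroup = config$ingroup)
    f3 <- outputs("indels.tsv"); writeReportTsv(ev, f3)
    fs <- c(f1, f2, f3)
    # pairwise species differences: requested pairs, or the only pair
    pairs <- config$pairs
    if (is.null(pairs) && length(genomes) == 2L)
      pairs <- list(names(genomes))
    if (!is.null(pairs)) {
      pw <- do.call(rbind, lapply(pairs, function(p) {
        d <- pairwiseDifferences(msa, p[1], p[2],
                                 annotation = genomes[[reference]])
        data.frame(sample_a = p[1], sample_b = p[2], snps = d$snp_count,
                   indel_events = d$indel_event_count,
                   longest_indel = if (nrow(d$indel_events))
                     max(d$indel_events$length) else 0L,
                   stringsAsFactors = FALSE)
      }))
      f4 <- outputs("pairwise.tsv"); writeReportTsv(pw, f4)
      fs <- c(fs, f4)
    }
    record("variants", fs)
  })

  run_stage("hotspots", function() {
    if (is.null(vt)) stopf("hotspots stage requires the variants stage")
    w <- scanWindows(vt, window = config$window %||% 1000L,
                     minSnps = config$minSnps %||% 11L)
    hs <- mergeHotspots(w, vt)
    f1 <- outputs("hotspots.tsv"); writeReportTsv(hs, f1)
    fs <- f1
    if (!is.null(config$cladeMap) && nrow(hs) &&
        length(alignmentRows(msa)) >= 3L) {
      set.seed(seed)
      sc <- screenMarkers(msa, hs, config$cladeMap, vt,
                          outgroup = config$outgroup,
                          b = config$bootstraps %||% 100L)
      f2 <- outputs("hotspot_concordance.tsv"); writeReportTsv(sc, f2)
      fs <- c(fs, f2)
    }
    record("hotspots", fs)
  })

  run_stage("tree", function() {
    if (is.null(msa)) stopf("tree stage requires an MSA")
    if (length(alignmentRows(msa)) < 3L) {
      warning("tree stage skipped: fewer than 3 taxa")
      manifest$stages[["tree"]] <<- list(status = "skipped: <3 taxa",
                                         outputs = list())
      return(invisible())
    }
    bt <- buildTree(msa, cladeMap = config$cladeMap %||% list(),
                    outgroup = config$outgroup)
    f1 <- outputs("tree.nwk"); writeNewick(bt$tree, f1)
    dm <- pDistance(msa)
    f2 <- outputs("distances.tsv")
    writeReportTsv(data.frame(sample = rownames(dm), dm,
                              check.names = FALSE), f2)
    fs <- c(f1, f2)
    if (length(bt$monophyly)) {
      f3 <- outputs("monophyly.tsv")
      writeReportTsv(data.frame(clade = names(bt$monophyly),
                                monophyletic = bt$monophyly), f3)
      fs <- c(fs, f3)
    }
    record("tree", fs)
  })

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Write simulator output to disk
#'
#' GenBank per leaf, the true aligned FASTA, the true tree and a truth
#' summary JSON — the on-disk layout [runPipeline()] consumes.
#'
#' @param sim result of [simulatePlastomes()].
#' @param outdir output directory.
#' @param unaligned also write ungapped per-leaf FASTA (for use with an
#'   external aligner).
#' @return named list of written paths, invisibly.
#' @export
writeSimulation <- function(sim, outdir, unaligned = FALSE) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- list()
  for (id in names(sim$genomes)) {
    p <- file.path(outdir, paste0(id, ".gb"))
    writeGenBank(sim$genomes[[id]], p)
    paths[[id]] <- p
  }
  paths$msa <- writeFasta(sim$msa, file.path(outdir, "aligned.fasta"))
  paths$tree <- writeNewick(sim$tree, file.path(outdir, "true_tree.nwk"))
  if (unaligned)
    paths$fasta <- writeFasta(vapply(sim$genomes, genomeSequence, ""),
                              file.path(outdir, "genomes.fasta"))
  truth <- list(
    ssrs = sim$truth$ssrs, repeats = sim$truth$repeats,
    hotspots = sim$truth$hotspots, regions = as.list(sim$truth$regions),
    planted_indels = lapply(sim$truth$planted_indels, function(p)
      p[c("feature", "length", "clade")]))
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  paths$truth <- file.path(outdir, "truth.json")
  invisible(paths)
}
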