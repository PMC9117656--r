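# Light distance-based phylogeny: p-distances from the alignment, a
# neighbor-joining tree, newick I/O and monophyly checks. The heavy model
# machinery (substitution model selection, likelihood, Bayesian inference)
# is deliberately out of scope; the testable surface of the published trees
# is which labelled clades are monophyletic, and NJ answers that.

#' Pairwise p-distance matrix from an alignment
#'
#' The p-distance of two rows is the fraction of mismatching columns among
#' the columns where both rows carry an unambiguous base (gap- or N-bearing
#' columns are excluded pairwise, not listwise).
#'
#' @param msa a [PlastomeAlignment-class] with >= 2 rows.
#' @return symmetric numeric matrix with zero diagonal and sample-id dimnames.
#' @export
pDistance <- function(msa) {
  rows <- alignmentRows(msa)
  if (length(rows) < 2L) stopf("pDistance: need >= 2 rows")
  bin <- ape::as.DNAbin(do.call(rbind,
                                strsplit(tolower(rows), "", fixed = TRUE)))
  d <- ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE)
  m <- as.matrix(d)
  if (any(!is.finite(m)))
    stopf("pDistance: a sample pair shares no comparable columns")
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining; negative branch lengths (an NJ
#' artefact on noisy matrices) are clamped to zero.
#'
#' @param dm symmetric distance matrix with sample-id dimnames.
#' @return an unrooted `ape::phylo` tree.
#' @export
neighborJoining <- function(dm) {
  if (nrow(as.matrix(dm)) < 3L) stopf("neighborJoining: need >= 3 taxa")
  tr <- ape::nj(as.matrix(dm))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Is a set of leaves monophyletic?
#'
#' When an outgroup is given the tree is rooted at it first; otherwise
#' monophyly is tested on the unrooted tree.
#'
#' @param tree an `ape::phylo` tree.
#' @param leafSet character vector of tip labels.
#' @param outgroup optional tip label to root at.
#' @return TRUE/FALSE.
#' @export
isMonophyletic <- function(tree, leafSet, outgroup = NULL) {
  miss <- setdiff(leafSet, tree$tip.label)
  if (length(miss))
    stopf("leaves not in tree: %s", paste(miss, collapse = ", "))
  if (!is.null(outgroup)) {
    if (!(outgroup %in% tree$tip.label))
      stopf("outgroup '%s' not in tree", outgroup)
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  }
  ape::is.monophyletic(tree, leafSet)
}

#' Read / write trees in newick format
#'
#' @param path file path.
#' @return `readNewick` returns an `ape::phylo`; `writeNewick` returns
#'   `path` invisibly.
#' @export
readNewick <- function(path) ape::read.tree(path)

#' @rdname readNewick
#' @param tree an `ape::phylo` tree.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Whole-alignment NJ tree with subgenus monophyly report
#'
#' Convenience wrapper used by the pipeline: p-distances, NJ, optional
#' rooting, and a monophyly verdict per labelled clade.
#'
#' @param msa a [PlastomeAlignment-class].
#' @param cladeMap named list: clade -> sample ids.
#' @param outgroup optional sample id to root at.
#' @return list with `tree` (phylo) and `monophyly` (named logical).
#' @export
buildTree <- function(msa, cladeMap = list(), outgroup = NULL) {
  tr <- neighborJoining(pDistance(msa))
  mono <- vapply(cladeMap, function(ids)
    isMonophyletic(tr, ids, outgroup = outgroup), TRUE)
  list(tree = tr, monophyly = mono)
}
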