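# Low-level sequence helpers shared across modules. Sequences are handled as
# uppercase character scalars at the module boundaries and as character
# vectors (one element per base) inside the scanning loops.

#' @importFrom Biostrings DNAString reverseComplement
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

complement_seq <- function(x) chartr("ACGTN", "TGCAN", x)

reverse_seq <- function(x) {
  paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
}

seq_to_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

chars_to_seq <- function(x) paste(x, collapse = "")

# circular coordinate normalisation: map to 1..len
wrap1 <- function(pos, len) ((pos - 1) %% len) + 1

#' Round half away from zero, the convention of printed report tables
#' (base round() rounds half to even).
#' @noRd
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# population (divide-by-n) standard deviation
sd_pop <- function(x) {
  x <- x[!is.na(x)]
  sqrt(mean((x - mean(x))^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Random DNA sequence with a target GC content
#'
#' Bases are drawn independently; G and C each with probability `gc / 2`.
#' Uses the session RNG (call `set.seed()` for reproducibility).
#'
#' @param n sequence length.
#' @param gc target GC fraction in [0, 1].
#' @return a DNA string of length `n`.
#' @export
randomDna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# random DNA with exact base composition (a shuffled fixed multiset), so the
# simulated ancestor hits its GC target regardless of genome size
random_dna_exact <- function(n, gc = 0.5) {
  ng <- round(n * gc / 2); nc <- round(n * gc) - ng
  na_ <- round(n * (1 - gc) / 2); nt <- n - ng - nc - na_
  paste(sample(c(rep("A", na_), rep("C", nc), rep("G", ng), rep("T", nt))),
        collapse = "")
}

#' Reverse complement of a DNA string
#'
#' @param x DNA string.
#' @return the reverse complement string.
#' @export
reverseComplementSeq <- function(x) revcomp(toupper(x))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
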