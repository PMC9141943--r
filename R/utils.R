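# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC nucleotide code expansion sets; motifs may use any of these, subject
# sequences must be plain ACGT.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reverse complement of a DNA string
#'
#' @param seq A character vector of DNA strings (`A`/`C`/`G`/`T`).
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("ACGT")
#' @export
revcomp <- function(seq) {
  vapply(seq, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

assert_dna <- function(seq, what = "sequence") {
  bad <- grepl("[^ACGT]", seq)
  if (any(bad)) {
    stop("invalid ", what, ": contains non-ACGT characters", call. = FALSE)
  }
  invisible(seq)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random number stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Translate a vector of codons with the standard genetic code; stops are "*".
translate_codons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  aa
}

# Round half away from zero, to `digits` decimals.
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Whole-percent display used in cohort summaries (62/270 -> 23).
percent_display <- function(num, den) {
  ifelse(den > 0, round_half_away(100 * num / den), NA_real_)
}

# Split a string into single characters.
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
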