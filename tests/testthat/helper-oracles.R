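# Independent oracles used by the test-suite. These deliberately do not share
# code with the package implementation: the aligner oracle is an exhaustive
# Smith-Waterman recurrence in plain R, the impact oracle applies the edit to
# the whole CDS and compares translations, and the identity oracle delegates
# to Biostrings::pairwiseAlignment.

# Exhaustive local alignment score, affine gaps
# (gap of length L costs open + (L-1) * ext).
sw_score_oracle <- function(q, r, match = 2, mismatch = -3,
                            gap_open = -5, gap_extend = -2) {
  qc <- strsplit(q, "")[[1]]
  rc <- strsplit(r, "")[[1]]
  m <- length(qc); n <- length(rc)
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  Fm <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] + gap_open, E[i, j - 1] + gap_extend)
      Fm[i, j] <- max(H[i - 1, j] + gap_open, Fm[i - 1, j] + gap_extend)
      s <- if (qc[i - 1] == rc[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], Fm[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Full-CDS translate-and-compare impact oracle for a single CDS-interior edit
# given as (start = first affected CDS position, del_len, ins).
impact_oracle <- function(loc, cds_start_pos, del_len, ins) {
  cds <- substr(loc$seq, loc$cds_start, loc$cds_end)
  alt <- paste0(substr(cds, 1, cds_start_pos - 1), ins,
                substr(cds, cds_start_pos + del_len, nchar(cds)))
  if (nchar(alt) %% 3 != 0) return("HIGH")
  tr <- function(s) {
    n <- nchar(s) %/% 3
    aa <- unname(Biostrings::GENETIC_CODE[substring(s, 3 * seq_len(n) - 2,
                                                    3 * seq_len(n))])
    aa[is.na(aa)] <- "X"
    aa
  }
  aa_ref <- tr(cds); aa_alt <- tr(alt)
  if (aa_alt[1] != "M") return("HIGH")                    # start lost
  stops <- which(aa_alt == "*")
  if (!length(stops)) return("HIGH")                      # stop lost
  if (stops[1] != length(aa_alt)) return("HIGH")          # premature stop
  if (identical(aa_ref, aa_alt)) "LOW" else "MODERATE"
}

# Pairwise identity of the shorter sequence fitted onto the longer,
# via Biostrings (overlap = free end gaps); matches / alignment columns.
identity_oracle <- function(a, b) {
  shorter <- if (nchar(a) <= nchar(b)) a else b
  longer <- if (nchar(a) <= nchar(b)) b else a
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(shorter), Biostrings::DNAString(longer),
    type = "global-local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = TRUE),
    gapOpening = 3, gapExtension = 2)
  Biostrings::nmatch(pa) / nchar(as.character(Biostrings::alignedPattern(pa)))
}

# Tiny deterministic read extractor: error-free reads tiling a sequence.
tile_reads <- function(seq, read_len, step, prefix = "r") {
  starts <- seq(1, nchar(seq) - read_len + 1, by = step)
  data.frame(id = sprintf("%s%04d", prefix, seq_along(starts)),
             seq = substring(seq, starts, starts + read_len - 1),
             stringsAsFactors = FALSE)
}

# Shared small fixtures (built once per test run).
toy_locus <- function() {
  # 60-codon CDS, 60 bp flanks
  make_locus(cds_length_codons = 90, flank_bp = 60, seed = 11)
}

table1_path <- function() {
  system.file("extdata", "slayer_table1.tsv", package = "pulascreen")
}
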