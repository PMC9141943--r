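#' Scan a DNA sequence for an IUPAC degenerate motif
#'
#' Slides the motif over both strands of the subject and reports every window
#' whose per-position mismatch count is at most `max_mismatch`. A position
#' matches when the subject base is a member of the motif character's IUPAC
#' expansion set (e.g. `W` = \{A, T\}, `N` = any). When a window matches on both
#' strands -- as happens for palindromic motifs such as the catabolite
#' responsive element (cre) consensus `TGWAANCGNTNWCA` -- only the forward
#' strand hit is reported, so palindromic operators are not double counted.
#'
#' @param seq Subject DNA string (`A`/`C`/`G`/`T` only).
#' @param motif Motif string over the IUPAC nucleotide alphabet.
#' @param max_mismatch Maximum mismatches allowed per window (default 0). The
#'   canonical cre scan uses 1: the published cre operator `TGTTATCGATAACA`
#'   differs from the consensus at one position.
#' @return A data.frame with columns `position` (1-based start on the forward
#'   strand), `strand` (`+`/`-`) and `mismatches`, sorted by position then
#'   strand.
#' @examples
#' scan_motif("GGTGTTATCGATAACAGG", "TGWAANCGNTNWCA", max_mismatch = 1)
#' @export
scan_motif <- function(seq, motif, max_mismatch = 0) {
  seq <- toupper(seq); motif <- toupper(motif)
  if (nchar(seq) == 0) stop("empty subject sequence", call. = FALSE)
  assert_dna(seq, "subject sequence")
  if (grepl(sprintf("[^%s]", paste(names(IUPAC_SETS), collapse = "")), motif)) {
    stop("invalid motif: contains non-IUPAC characters", call. = FALSE)
  }
  if (nchar(motif) > nchar(seq)) {
    stop("motif longer than subject sequence", call. = FALSE)
  }
  hits_one <- function(pat, strand) {
    m <- Biostrings::matchPattern(
      Biostrings::DNAString(pat), Biostrings::DNAString(seq),
      max.mismatch = max_mismatch, fixed = c(pattern = FALSE, subject = TRUE))
    st <- Biostrings::start(m)
    # drop windows extending past either end (matchPattern treats
    # out-of-bounds positions as mismatches at high max.mismatch)
    st <- st[st >= 1 & st <= nchar(seq) - nchar(pat) + 1L]
    if (!length(st)) {
      return(data.frame(position = integer(0), strand = character(0),
                        mismatches = integer(0), stringsAsFactors = FALSE))
    }
    mm <- vapply(st, function(p) {
      iupac_mismatches(substr(seq, p, p + nchar(pat) - 1L), pat)
    }, integer(1))
    data.frame(position = st, strand = strand, mismatches = mm,
               stringsAsFactors = FALSE)
  }
  fwd <- hits_one(motif, "+")
  rev <- hits_one(revcomp_iupac(motif), "-")
  # palindromic-motif dedup: a window hit on both strands is reported once (+)
  rev <- rev[!(rev$position %in% fwd$position), , drop = FALSE]
  out <- rbind(fwd, rev)
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Mismatch count of an ACGT window against an IUPAC pattern of equal length.
iupac_mismatches <- function(window, pattern) {
  w <- chars(window); p <- chars(pattern)
  sum(!mapply(function(b, code) b %in% IUPAC_SETS[[code]], w, p))
}

# Reverse complement over the full IUPAC alphabet (for minus-strand scans).
revcomp_iupac <- function(motif) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(unname(comp[chars(motif)])), collapse = "")
}

#' Test whether a DNA sequence is palindromic
#'
#' A DNA palindrome equals its own reverse complement, the hallmark of
#' protein-binding operators such as the cre site `TGTTATCGATAACA`. Sequences
#' of odd length cannot be palindromic and return `FALSE`.
#'
#' @param seq DNA string (`A`/`C`/`G`/`T` only).
#' @return `TRUE` iff `seq` equals its reverse complement.
#' @examples
#' is_palindromic("TGTTATCGATAACA")
#' is_palindromic("AAAA")
#' @export
is_palindromic <- function(seq) {
  seq <- toupper(seq)
  assert_dna(seq)
  if (nchar(seq) %% 2 == 1) return(FALSE)
  identical(seq, revcomp(seq))
}
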