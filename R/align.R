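#' Aligner parameters
#'
#' Scoring and reporting parameters of the single-target seed-and-extend
#' local aligner. Defaults: 15-mer seeds, +2/-3 match/mismatch, -5/-2 gap
#' open/extend (a gap of length L costs `gap_open + (L-1) * gap_extend`),
#' 32 bp band around seed diagonals, alignments below score 40 are reported
#' unmapped, and only terminal soft clips of at least 10 bp feed downstream
#' structural-variant evidence.
#'
#' @param seed_k Seed k-mer length (>= 8).
#' @param match,mismatch,gap_open,gap_extend Alignment scores; `match` must be
#'   positive and `mismatch` negative.
#' @param band_width Half-width of the extension window around seed diagonals;
#'   must be at least the largest indel expected within one read.
#' @param min_report_score Minimum local alignment score to report a mapping.
#' @param min_softclip_report Minimum soft-clip length that counts as
#'   breakpoint evidence.
#' @return A list of class `pula_aligner_params`.
#' @export
aligner_params <- function(seed_k = 15, match = 2, mismatch = -3,
                           gap_open = -5, gap_extend = -2, band_width = 32,
                           min_report_score = 40, min_softclip_report = 10) {
  if (seed_k < 8) stop("seed_k must be >= 8", call. = FALSE)
  if (!(match > 0 && mismatch < 0)) {
    stop("scores must satisfy match > 0 > mismatch", call. = FALSE)
  }
  structure(list(seed_k = as.integer(seed_k), match = as.integer(match),
                 mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 band_width = as.integer(band_width),
                 min_report_score = as.integer(min_report_score),
                 min_softclip_report = as.integer(min_softclip_report)),
            class = "pula_aligner_params")
}

#' Align reads to a single reference locus
#'
#' Seed-and-extend local alignment: exact k-mer seeds locate candidate
#' diagonals on either strand, each diagonal group is extended by banded
#' affine-gap Smith-Waterman, and read ends not covered by the best local
#' alignment become soft clips. When seeding is inconclusive the aligner falls
#' back to exhaustive Smith-Waterman against the whole locus, so the reported
#' score is the optimum of the scoring scheme. Ties break deterministically
#' (lowest reference start, then forward strand).
#'
#' @param reads data.frame with columns `id`, `seq` (and optionally `qual`),
#'   e.g. from [read_fastq()] or [simulate_reads()].
#' @param loc Reference [locus()] (or a plain DNA string).
#' @param params [aligner_params()].
#' @return A data.frame of class `pula_alignments`: `read_id`, `mapped`,
#'   `strand`, `ref_start` (1-based), `cigar` (M/I/D/S), `score`,
#'   `edit_distance`, `oriented_seq` (the read in reference orientation),
#'   `qual`.
#' @export
align_reads <- function(reads, loc, params = aligner_params()) {
  ref <- if (inherits(loc, "pula_locus")) loc$seq else toupper(loc)
  res <- align_batch_cpp(reads$seq, ref, params$seed_k, params$match,
                         params$mismatch, params$gap_open, params$gap_extend,
                         params$band_width, params$min_report_score)
  out <- data.frame(read_id = reads$id, mapped = res$mapped,
                    strand = res$strand, ref_start = res$ref_start,
                    cigar = res$cigar, score = res$score,
                    edit_distance = res$edit_distance,
                    oriented_seq = res$oriented_seq,
                    qual = if (!is.null(reads$qual)) reads$qual else
                      strrep("I", nchar(reads$seq)),
                    stringsAsFactors = FALSE)
  # minus-strand quality strings travel reversed, mirroring the sequence
  rev_needed <- which(out$mapped & out$strand == "-")
  if (length(rev_needed)) {
    out$qual[rev_needed] <- vapply(out$qual[rev_needed], function(q) {
      paste(rev(chars(q)), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  class(out) <- c("pula_alignments", "data.frame")
  out
}

# Parse a CIGAR string into (lengths, ops).
cigar_runs <- function(cigar) {
  if (is.na(cigar)) return(list(len = integer(0), op = character(0)))
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  op <- regmatches(cigar, gregexpr("[MIDS]", cigar))[[1]]
  list(len = len, op = op)
}

# Reference span consumed by a CIGAR (M + D).
cigar_ref_span <- function(cigar) {
  r <- cigar_runs(cigar)
  sum(r$len[r$op %in% c("M", "D")])
}

# Leading/trailing soft-clip lengths of a CIGAR.
cigar_clips <- function(cigar) {
  r <- cigar_runs(cigar)
  n <- length(r$op)
  left <- if (n > 0 && r$op[1] == "S") r$len[1] else 0L
  right <- if (n > 0 && r$op[n] == "S") r$len[n] else 0L
  c(left = left, right = right)
}

#' Write and read alignments in SAM format
#'
#' A minimal single-reference SAM 1.x dialect: `@HD`/`@SQ` header, flags 0/16
#' for forward/reverse mapped reads and 4 for unmapped, `POS`, `CIGAR`, `SEQ`,
#' `QUAL`, plus `NM:i` (edit distance) and `AS:i` (alignment score) tags.
#' `read_sam(write_sam(x))` is field-identical for everything the pipeline
#' uses.
#'
#' @param aln `pula_alignments` from [align_reads()].
#' @param loc The reference [locus()] (names and lengths the header).
#' @param path Output/input file path.
#' @return `read_sam` returns a `pula_alignments` data.frame.
#' @export
write_sam <- function(aln, loc, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", loc$id, locus_length(loc)))
  flag <- ifelse(!aln$mapped, 4L, ifelse(aln$strand == "-", 16L, 0L))
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tNM:i:%d\tAS:i:%d",
                 aln$read_id, flag,
                 ifelse(aln$mapped, loc$id, "*"),
                 ifelse(aln$mapped, aln$ref_start, 0L),
                 ifelse(aln$mapped, 60L, 0L),
                 ifelse(aln$mapped, aln$cigar, "*"),
                 aln$oriented_seq, aln$qual,
                 ifelse(aln$mapped, aln$edit_distance, 0L),
                 aln$score)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' @rdname write_sam
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 11)
  if (length(bad)) {
    stop(sprintf("malformed SAM record at line %d",
                 bad[1] + sum(startsWith(lines, "@"))), call. = FALSE)
  }
  get <- function(i) vapply(parts, `[[`, character(1), i)
  tagval <- function(tag) {
    vapply(parts, function(p) {
      hit <- grep(paste0("^", tag, ":i:"), p, value = TRUE)
      if (length(hit)) as.integer(sub(".*:", "", hit[1])) else NA_integer_
    }, integer(1))
  }
  flag <- as.integer(get(2))
  mapped <- bitwAnd(flag, 4L) == 0L
  out <- data.frame(
    read_id = get(1), mapped = mapped,
    strand = ifelse(!mapped, NA_character_,
                    ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")),
    ref_start = ifelse(mapped, as.integer(get(4)), NA_integer_),
    cigar = ifelse(mapped, get(6), NA_character_),
    score = tagval("AS"),
    edit_distance = ifelse(mapped, tagval("NM"), NA_integer_),
    oriented_seq = get(10), qual = get(11),
    stringsAsFactors = FALSE)
  class(out) <- c("pula_alignments", "data.frame")
  out
}
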