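#' Reference locus with a gene model
#'
#' A locus bundles the reference DNA sequence with the coding-sequence (CDS)
#' interval and optional named feature intervals (e.g. `signal_peptide`,
#' `cre_site`, `promoter`). All coordinates are 1-based inclusive; they are
#' converted to 0-based half-open only at BED boundaries.
#'
#' @param id Locus identifier.
#' @param seq DNA string over `A`/`C`/`G`/`T`.
#' @param cds_start,cds_end 1-based inclusive CDS interval. The CDS length must
#'   be a multiple of 3.
#' @param features Named list of `c(start, end)` integer pairs in locus
#'   coordinates.
#' @return An object of class `pula_locus`.
#' @examples
#' loc <- locus("toy", "AAATGACCTAAGGG", cds_start = 3, cds_end = 11)
#' loc
#' @export
locus <- function(id, seq, cds_start, cds_end, features = list()) {
  seq <- toupper(seq)
  assert_dna(seq, "locus sequence")
  n <- nchar(seq)
  if (!(cds_start >= 1 && cds_start < cds_end && cds_end <= n)) {
    stop("CDS interval must satisfy 1 <= cds_start < cds_end <= length(seq)",
         call. = FALSE)
  }
  if ((cds_end - cds_start + 1) %% 3 != 0) {
    stop("CDS length must be a multiple of 3", call. = FALSE)
  }
  if (length(features)) {
    ok <- vapply(features, function(f) {
      length(f) == 2 && f[1] >= 1 && f[1] <= f[2] && f[2] <= n
    }, logical(1))
    if (!all(ok)) stop("feature intervals out of range", call. = FALSE)
  }
  structure(
    list(id = id, seq = seq, cds_start = as.integer(cds_start),
         cds_end = as.integer(cds_end), features = features),
    class = "pula_locus")
}

#' @export
print.pula_locus <- function(x, ...) {
  cat(sprintf("<pula_locus> %s: %d bp, CDS %d-%d (%d codons)\n",
              x$id, nchar(x$seq), x$cds_start, x$cds_end,
              (x$cds_end - x$cds_start + 1L) %/% 3L))
  if (length(x$features)) {
    for (nm in names(x$features)) {
      cat(sprintf("  feature %-14s %d-%d\n", nm,
                  x$features[[nm]][1], x$features[[nm]][2]))
    }
  }
  invisible(x)
}

#' Length of a locus sequence
#' @param loc A `pula_locus`.
#' @return Integer length in bp.
#' @export
locus_length <- function(loc) nchar(loc$seq)

# CDS sequence as a single string.
cds_seq <- function(loc) substr(loc$seq, loc$cds_start, loc$cds_end)

#' Map locus positions into the gene coordinate system
#'
#' For each 1-based locus position reports whether it falls upstream of,
#' inside, or downstream of the CDS, and for CDS positions the 1-based codon
#' index and the offset (1, 2 or 3) within the codon.
#'
#' @param loc A [locus()].
#' @param pos Integer vector of 1-based locus positions.
#' @return A data.frame with columns `pos`, `region`
#'   (`upstream`/`CDS`/`downstream`), `codon_index`, `codon_offset` (NA outside
#'   the CDS), and `cds_pos` (1-based position within the CDS, NA outside).
#' @examples
#' loc <- locus("toy", "AAATGACCTAAGGG", 3, 11)
#' cds_coordinate(loc, c(2, 3, 7))
#' @export
cds_coordinate <- function(loc, pos) {
  pos <- as.integer(pos)
  if (any(pos < 1 | pos > locus_length(loc))) {
    stop("position out of locus range", call. = FALSE)
  }
  region <- ifelse(pos < loc$cds_start, "upstream",
                   ifelse(pos > loc$cds_end, "downstream", "CDS"))
  off0 <- pos - loc$cds_start
  codon_index <- ifelse(region == "CDS", off0 %/% 3L + 1L, NA_integer_)
  codon_offset <- ifelse(region == "CDS", off0 %% 3L + 1L, NA_integer_)
  cds_pos <- ifelse(region == "CDS", off0 + 1L, NA_integer_)
  data.frame(pos = pos, region = region, codon_index = codon_index,
             codon_offset = codon_offset, cds_pos = cds_pos,
             stringsAsFactors = FALSE)
}

#' Predicted PCR amplicon size from primer annealing offsets
#'
#' The forward primer's 5' end anneals `upstream_offset` bp upstream of the
#' gene start; the reverse primer's annealing ends `downstream_end` bp
#' downstream of the start. The spanned product is their sum: the standard
#' screening amplicon design of 42 bp upstream plus 257 bp downstream predicts
#' a 299 bp product.
#'
#' @param upstream_offset Non-negative bp upstream of the gene start.
#' @param downstream_end Non-negative bp position downstream of the start.
#' @return Amplicon length in bp.
#' @examples
#' amplicon_size(42, 257)
#' @export
amplicon_size <- function(upstream_offset, downstream_end) {
  if (any(upstream_offset < 0) || any(downstream_end < 0)) {
    stop("primer offsets must be non-negative", call. = FALSE)
  }
  upstream_offset + downstream_end
}

#' Read and write a locus as FASTA plus a gene-model sidecar
#'
#' The sequence travels as FASTA; the gene model as a JSON sidecar with
#' 1-based `cds_start`/`cds_end` and feature intervals, or as BED (0-based
#' half-open, converted on read).
#'
#' @param fasta Path to a single-record FASTA file.
#' @param gene_model Path to a JSON gene model (fields `cds_start`, `cds_end`,
#'   optional `features`) or a BED file (name column selects the feature; the
#'   `CDS` name sets the CDS interval).
#' @return A `pula_locus`.
#' @export
read_locus <- function(fasta, gene_model) {
  ss <- Biostrings::readDNAStringSet(fasta)
  if (length(ss) != 1) stop("expected a single-record FASTA", call. = FALSE)
  id <- sub("\\s.*$", "", names(ss)[1])
  seq <- as.character(ss[[1]])
  if (grepl("\\.json$", gene_model, ignore.case = TRUE)) {
    gm <- jsonlite::read_json(gene_model, simplifyVector = TRUE)
    feats <- lapply(gm$features, function(f) as.integer(unlist(f)))
    locus(id, seq, gm$cds_start, gm$cds_end, features = feats)
  } else {
    bed <- read.delim(gene_model, header = FALSE, stringsAsFactors = FALSE)
    names(bed)[1:4] <- c("chrom", "start", "end", "name")
    ivs <- lapply(seq_len(nrow(bed)), function(i) {
      c(bed$start[i] + 1L, bed$end[i]) # BED 0-based half-open -> 1-based incl.
    })
    names(ivs) <- bed$name
    if (!"CDS" %in% names(ivs)) stop("BED gene model needs a 'CDS' row",
                                     call. = FALSE)
    cds <- ivs[["CDS"]]
    locus(id, seq, cds[1], cds[2], features = ivs[names(ivs) != "CDS"])
  }
}

#' @rdname read_locus
#' @param loc A `pula_locus` to write.
#' @param gene_model_json Path for the JSON gene model.
#' @export
write_locus <- function(loc, fasta, gene_model_json) {
  ss <- Biostrings::DNAStringSet(setNames(loc$seq, loc$id))
  Biostrings::writeXStringSet(ss, fasta)
  gm <- list(cds_start = loc$cds_start, cds_end = loc$cds_end,
             features = loc$features)
  jsonlite::write_json(gm, gene_model_json, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(fasta, gene_model_json))
}
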