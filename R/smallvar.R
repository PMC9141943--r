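#' Variant-calling parameters
#'
#' Frequency-threshold calling in the pooled-continuous spirit: any
#' non-reference allele at a position with depth >= `min_coverage`, supported
#' by >= `min_alt_count` reads and >= `min_alt_fraction` of the reads, is
#' emitted as a per-sample observation (no genotype likelihoods; the allele
#' frequency is the continuous pooled read fraction). Across samples, a
#' variant is kept when it reaches `report_min_af` in at least
#' `min_prevalence_samples` samples. Observations at or above
#' `high_freq_threshold` are flagged as high-frequency (the threshold is
#' inclusive: exactly 0.7 is flagged). The coverage gate admits a sample when
#' at least `coverage_gate_fraction` of CDS positions reach `min_coverage`.
#'
#' @param min_coverage Minimum depth at a position (default 10).
#' @param min_alt_count Minimum alternate-supporting reads (default 2).
#' @param min_alt_fraction Minimum per-sample alternate fraction to observe
#'   (default 0.01).
#' @param report_min_af Alternate allele frequency a sample must reach to
#'   count towards prevalence (default 0.05).
#' @param min_prevalence_samples Minimum samples at `report_min_af`
#'   (default 3).
#' @param high_freq_threshold Inclusive high-frequency threshold
#'   (default 0.70).
#' @param coverage_gate_fraction Fraction of CDS positions that must reach
#'   `min_coverage` for a sample to enter the analysis (default 1.0).
#' @return A list of class `pula_calling_params`.
#' @export
calling_params <- function(min_coverage = 10, min_alt_count = 2,
                           min_alt_fraction = 0.01, report_min_af = 0.05,
                           min_prevalence_samples = 3,
                           high_freq_threshold = 0.70,
                           coverage_gate_fraction = 1.0) {
  if (!(min_alt_fraction >= 0 && min_alt_fraction <= report_min_af &&
        report_min_af <= high_freq_threshold && high_freq_threshold <= 1)) {
    stop("need 0 <= min_alt_fraction <= report_min_af <= high_freq_threshold <= 1",
         call. = FALSE)
  }
  structure(list(min_coverage = min_coverage, min_alt_count = min_alt_count,
                 min_alt_fraction = min_alt_fraction,
                 report_min_af = report_min_af,
                 min_prevalence_samples = min_prevalence_samples,
                 high_freq_threshold = high_freq_threshold,
                 coverage_gate_fraction = coverage_gate_fraction),
            class = "pula_calling_params")
}

#' Per-position pileup of aligned reads
#'
#' Walks each mapped read's CIGAR: `M` runs contribute the read base and
#' depth, `D` runs contribute depth plus a deletion observation anchored at
#' the base before the deleted run, `I` runs contribute an insertion
#' observation at their anchor, and soft clips contribute nothing to any
#' column.
#'
#' @param aln `pula_alignments` from [align_reads()].
#' @param loc Reference [locus()].
#' @return A list of class `pula_pileup`: `counts` (4 x L base-count matrix,
#'   rows A/C/G/T), `depth` (integer vector), `deletions` and `insertions`
#'   (data.frames `anchor`, `seq`, `count`).
#' @export
pileup <- function(aln, loc) {
  m <- aln[aln$mapped, , drop = FALSE]
  res <- pileup_cpp(m$ref_start, m$cigar, m$oriented_seq, loc$seq)
  rownames(res$counts) <- DNA_BASES
  structure(res, class = "pula_pileup")
}

#' Coverage gate over the coding sequence
#'
#' @param pu `pula_pileup`.
#' @param loc Reference [locus()].
#' @param params [calling_params()].
#' @return List with `included` (logical), `fraction_covered` (fraction of
#'   CDS positions at `min_coverage`), and `cds_depth` (per-base depth track
#'   over the CDS).
#' @export
coverage_gate <- function(pu, loc, params = calling_params()) {
  d <- pu$depth[loc$cds_start:loc$cds_end]
  frac <- mean(d >= params$min_coverage)
  list(included = frac >= params$coverage_gate_fraction - 1e-12,
       fraction_covered = frac, cds_depth = d)
}

# Left-align and minimally represent an anchored indel (pos, ref, alt) against
# the reference sequence; SNVs pass through unchanged.
normalize_variant <- function(ref_seq, pos, ref, alt) {
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1, nchar(ref) - 1)
    alt <- substr(alt, 1, nchar(alt) - 1)
  }
  repeat {
    if (nchar(ref) == 1 && nchar(alt) == 1) break
    last_ref <- substr(ref, nchar(ref), nchar(ref))
    last_alt <- substr(alt, nchar(alt), nchar(alt))
    if (pos > 1 && last_ref == last_alt) {
      prev <- substr(ref_seq, pos - 1, pos - 1)
      ref <- paste0(prev, substr(ref, 1, nchar(ref) - 1))
      alt <- paste0(prev, substr(alt, 1, nchar(alt) - 1))
      pos <- pos - 1L
    } else break
  }
  list(pos = as.integer(pos), ref = ref, alt = alt)
}

#' Call per-sample small-variant observations from a pileup
#'
#' Emits every position/allele passing the three per-sample minima (depth,
#' alternate count, alternate fraction). Indels are reported in anchored
#' variant-format style (one left reference base shared by `ref` and `alt`)
#' and left-aligned so identical planted events unify across samples.
#'
#' @param pu `pula_pileup`.
#' @param loc Reference [locus()].
#' @param params [calling_params()].
#' @return data.frame `pos`, `ref`, `alt`, `type`, `alt_count`, `depth`, `af`.
#' @export
call_sample_variants <- function(pu, loc, params = calling_params()) {
  L <- locus_length(loc)
  refc <- chars(loc$seq)
  depth <- pu$depth
  rows <- list()
  for (b in DNA_BASES) {
    cnt <- pu$counts[b, ]
    ok <- which(cnt >= params$min_alt_count & refc != b &
                  depth >= params$min_coverage &
                  cnt >= params$min_alt_fraction * depth)
    if (length(ok)) {
      rows[[b]] <- data.frame(pos = ok, ref = refc[ok], alt = b, type = "snv",
                              alt_count = cnt[ok], depth = depth[ok],
                              stringsAsFactors = FALSE)
    }
  }
  indel_rows <- function(df, is_del) {
    keep <- list()
    for (i in seq_len(nrow(df))) {
      anchor <- df$anchor[i]
      if (anchor < 1 || anchor > L) next
      dp <- depth[anchor]
      cnt <- df$count[i]
      if (dp < params$min_coverage || cnt < params$min_alt_count ||
          cnt < params$min_alt_fraction * dp) next
      anchor_base <- refc[anchor]
      if (is_del) {
        v <- normalize_variant(loc$seq, anchor,
                               paste0(anchor_base, df$seq[i]), anchor_base)
        ty <- "deletion"
      } else {
        v <- normalize_variant(loc$seq, anchor, anchor_base,
                               paste0(anchor_base, df$seq[i]))
        ty <- "insertion"
      }
      keep[[length(keep) + 1L]] <-
        data.frame(pos = v$pos, ref = v$ref, alt = v$alt, type = ty,
                   alt_count = cnt, depth = dp, stringsAsFactors = FALSE)
    }
    if (length(keep)) do.call(rbind, keep) else NULL
  }
  if (nrow(pu$deletions)) rows$del <- indel_rows(pu$deletions, TRUE)
  if (nrow(pu$insertions)) rows$ins <- indel_rows(pu$insertions, FALSE)
  rows <- Filter(Negate(is.null), rows)
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pos = integer(0), ref = character(0), alt = character(0),
               type = character(0), alt_count = integer(0), depth = integer(0),
               stringsAsFactors = FALSE)
  # identical normalized events observed via different anchors merge
  if (nrow(out)) {
    key <- paste(out$pos, out$ref, out$alt, sep = ":")
    agg_ac <- tapply(out$alt_count, key, sum)
    first <- !duplicated(key)
    out <- out[first, , drop = FALSE]
    out$alt_count <- as.integer(agg_ac[paste(out$pos, out$ref, out$alt,
                                             sep = ":")])
    out <- out[order(out$pos, out$ref, out$alt), , drop = FALSE]
  }
  out$af <- if (nrow(out)) out$alt_count / out$depth else numeric(0)
  rownames(out) <- NULL
  out
}

#' Multi-sample filtering of variant observations
#'
#' A variant is retained iff its per-sample allele frequency reaches
#' `report_min_af` in at least `min_prevalence_samples` samples; retained
#' variants carry the full per-sample AF/depth matrices (including
#' sub-threshold observations) for reporting.
#'
#' @param observations Named list (one per sample) of data.frames from
#'   [call_sample_variants()].
#' @param params [calling_params()].
#' @return A list of class `pula_varset`: `variants` (data.frame `pos`, `ref`,
#'   `alt`, `type`, `prevalence`), plus matrices `af`, `depth`, `alt_count`
#'   (variants x samples).
#' @export
joint_filter <- function(observations, params = calling_params()) {
  samples <- names(observations)
  all_obs <- do.call(rbind, lapply(samples, function(s) {
    o <- observations[[s]]
    if (!nrow(o)) return(NULL)
    o$sample <- s
    o
  }))
  empty <- list(variants = data.frame(pos = integer(0), ref = character(0),
                                      alt = character(0), type = character(0),
                                      prevalence = integer(0),
                                      stringsAsFactors = FALSE),
                af = matrix(0, 0, length(samples),
                            dimnames = list(NULL, samples)),
                depth = matrix(0L, 0, length(samples),
                               dimnames = list(NULL, samples)),
                alt_count = matrix(0L, 0, length(samples),
                                   dimnames = list(NULL, samples)))
  class(empty) <- "pula_varset"
  if (is.null(all_obs) || !nrow(all_obs)) return(empty)
  key <- paste(all_obs$pos, all_obs$ref, all_obs$alt, sep = ":")
  uk <- unique(key)
  af <- matrix(0, length(uk), length(samples), dimnames = list(uk, samples))
  dp <- matrix(0L, length(uk), length(samples), dimnames = list(uk, samples))
  ac <- matrix(0L, length(uk), length(samples), dimnames = list(uk, samples))
  af[cbind(match(key, uk), match(all_obs$sample, samples))] <- all_obs$af
  dp[cbind(match(key, uk), match(all_obs$sample, samples))] <- all_obs$depth
  ac[cbind(match(key, uk), match(all_obs$sample, samples))] <- all_obs$alt_count
  prevalence <- rowSums(af >= params$report_min_af - 1e-12)
  keep <- prevalence >= params$min_prevalence_samples
  first <- all_obs[match(uk, key), , drop = FALSE]
  variants <- data.frame(pos = first$pos, ref = first$ref, alt = first$alt,
                         type = first$type,
                         prevalence = as.integer(prevalence),
                         stringsAsFactors = FALSE)
  ord <- order(variants$pos, variants$ref, variants$alt)
  variants <- variants[ord, , drop = FALSE]; keep <- keep[ord]
  af <- af[ord, , drop = FALSE]; dp <- dp[ord, , drop = FALSE]
  ac <- ac[ord, , drop = FALSE]
  out <- list(variants = variants[keep, , drop = FALSE],
              af = af[keep, , drop = FALSE], depth = dp[keep, , drop = FALSE],
              alt_count = ac[keep, , drop = FALSE])
  rownames(out$variants) <- NULL
  class(out) <- "pula_varset"
  out
}

# ---------------------------------------------------------------------------
# Impact annotation
# ---------------------------------------------------------------------------

# Convert an anchored (pos, ref, alt) record into the internal edit triple
# (first affected position, deleted length, inserted sequence).
variant_to_edit <- function(pos, ref, alt) {
  if (nchar(ref) == 1 && nchar(alt) == 1) {
    list(start = pos, del_len = 1L, ins = alt, kind = "snv")
  } else if (nchar(alt) == 1) {
    list(start = pos + 1L, del_len = nchar(ref) - 1L, ins = "",
         kind = "deletion")
  } else if (nchar(ref) == 1) {
    list(start = pos + 1L, del_len = 0L, ins = substr(alt, 2, nchar(alt)),
         kind = "insertion")
  } else {
    stop("complex ref/alt pair not supported: ", ref, ">", alt, call. = FALSE)
  }
}

# Impact of one edit triple on the locus gene model.
impact_one <- function(loc, start, del_len, ins) {
  cs <- loc$cds_start; ce <- loc$cds_end
  net <- nchar(ins) - del_len
  if (del_len > 0) {
    a <- start; b <- start + del_len - 1L
    inside <- a >= cs && b <= ce
    outside <- b < cs || a > ce
    if (!inside && !outside) return("HIGH")     # straddles a CDS boundary
    if (outside) return("MODIFIER")
  } else {
    # pure insertion lands between start-1 and start
    if (start <= cs || start > ce) return("MODIFIER")
  }
  if (net %% 3L != 0L) return("HIGH")           # frameshift
  cds <- cds_seq(loc)
  ncds <- nchar(cds)
  q <- start - cs + 1L                          # CDS coordinate
  if (del_len > 0) {
    c1 <- (q - 1L) %/% 3L + 1L
    c2 <- (q + del_len - 2L) %/% 3L + 1L
  } else {
    c1 <- (max(q - 1L, 1L) - 1L) %/% 3L + 1L
    c2 <- (min(q, ncds) - 1L) %/% 3L + 1L
  }
  w0 <- (c1 - 1L) * 3L + 1L
  w1 <- c2 * 3L
  ref_win <- substr(cds, w0, w1)
  rel <- q - w0 + 1L
  alt_win <- paste0(substr(ref_win, 1, rel - 1L), ins,
                    substr(ref_win, rel + del_len, nchar(ref_win)))
  ref_aa <- translate_codons(codon_split(ref_win))
  alt_aa <- translate_codons(codon_split(alt_win))
  reaches_end <- (w1 == ncds)
  if (c1 == 1L && substr(alt_win, 1, 3) != "ATG") return("HIGH") # start lost
  stops <- which(alt_aa == "*")
  if (length(stops)) {
    premature <- any(stops < length(alt_aa)) || !reaches_end
    if (premature) return("HIGH")               # stop gained
  } else if (reaches_end && any(ref_aa == "*")) {
    return("HIGH")                              # stop lost
  }
  if (identical(ref_aa, alt_aa)) "LOW" else "MODERATE"
}

codon_split <- function(s) {
  n <- nchar(s) %/% 3L
  if (n == 0) return(character(0))
  substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# Impact of a simulator edit (pula_edit) -- used for ground truth.
edit_impact <- function(loc, e) {
  if (e$kind == "snv") return(impact_one(loc, e$position, 1L, e$alt))
  if (e$kind == "deletion") return(impact_one(loc, e$position, e$length, ""))
  ins <- if (e$kind == "insertion") e$seq else strrep("A", 1L) # length proxy
  impact_one(loc, e$position + 1L, 0L, ins)
}

#' Annotate variant impact on the encoded protein
#'
#' Classifies each variant against the locus gene model: `MODIFIER` outside
#' the CDS; inside the CDS, frameshift indels, stop-gain, start-loss and
#' stop-loss changes are `HIGH`; amino-acid-changing SNVs and in-frame indels
#' are `MODERATE` (unless the recoded codons introduce a premature stop,
#' which is `HIGH`); synonymous SNVs are `LOW`. Variants straddling a CDS
#' boundary are classified `HIGH`.
#'
#' @param variants data.frame with `pos`, `ref`, `alt` (anchored indel
#'   convention), or a `pula_varset`.
#' @param loc Reference [locus()].
#' @return The input with an `impact` column added (for a `pula_varset`, on
#'   its `variants` element).
#' @export
annotate_impact <- function(variants, loc) {
  vs <- if (inherits(variants, "pula_varset")) variants$variants else variants
  imp <- vapply(seq_len(nrow(vs)), function(i) {
    e <- variant_to_edit(vs$pos[i], vs$ref[i], vs$alt[i])
    impact_one(loc, e$start, e$del_len, e$ins)
  }, character(1))
  vs$impact <- imp
  if (inherits(variants, "pula_varset")) {
    variants$variants <- vs
    variants
  } else {
    vs
  }
}

#' High-frequency variant observations
#'
#' @param varset `pula_varset` (impact-annotated or not).
#' @param params [calling_params()]; the threshold is inclusive (`af >= 0.7`
#'   by default).
#' @return data.frame `pos`, `ref`, `alt`, `sample`, `af` (one row per
#'   flagged variant-sample pair), plus `impact` when available.
#' @export
high_frequency_flags <- function(varset, params = calling_params()) {
  vs <- varset$variants
  out <- list()
  for (s in colnames(varset$af)) {
    hit <- which(varset$af[, s] >= params$high_freq_threshold - 1e-12)
    if (length(hit)) {
      r <- data.frame(pos = vs$pos[hit], ref = vs$ref[hit], alt = vs$alt[hit],
                      sample = s, af = varset$af[hit, s],
                      stringsAsFactors = FALSE)
      if (!is.null(vs$impact)) r$impact <- vs$impact[hit]
      out[[s]] <- r
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(pos = integer(0), ref = character(0), alt = character(0),
               sample = character(0), af = numeric(0),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Write and read the variant set as VCF 4.2
#'
#' One record per alternate allele, 1-based positions, indels anchored on one
#' left reference base, impact and type in INFO, per-sample
#' `AF:DP:AD` in the genotype columns. `read_vcf(write_vcf(x))` is
#' field-identical.
#'
#' @param varset `pula_varset` (ideally impact-annotated).
#' @param loc Reference [locus()].
#' @param path File path.
#' @return `read_vcf` returns a `pula_varset` with an `impact` column.
#' @export
write_vcf <- function(varset, loc, path) {
  vs <- varset$variants
  samples <- colnames(varset$af)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", loc$id, locus_length(loc)),
           "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"Variant type\">",
           "##INFO=<ID=IMPACT,Number=1,Type=String,Description=\"Predicted impact\">",
           "##INFO=<ID=PREV,Number=1,Type=Integer,Description=\"Samples at reportable AF\">",
           "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Alternate allele frequency\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=AD,Number=1,Type=Integer,Description=\"Alternate-supporting reads\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  recs <- vapply(seq_len(nrow(vs)), function(i) {
    info <- sprintf("TYPE=%s;IMPACT=%s;PREV=%d", vs$type[i],
                    if (!is.null(vs$impact)) vs$impact[i] else ".",
                    vs$prevalence[i])
    gt <- vapply(samples, function(s) {
      sprintf("%s:%d:%d", format(varset$af[i, s], digits = 6),
              varset$depth[i, s], varset$alt_count[i, s])
    }, character(1))
    paste(c(loc$id, vs$pos[i], ".", vs$ref[i], vs$alt[i], ".", "PASS", info,
            "AF:DP:AD", gt), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' @rdname write_vcf
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  header <- body[1]
  if (!startsWith(header, "#CHROM")) stop("malformed VCF: missing #CHROM line",
                                          call. = FALSE)
  cols <- strsplit(sub("^#", "", header), "\t")[[1]]
  samples <- cols[-(1:9)]
  body <- body[-1]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != length(cols))
  if (length(bad)) {
    stop(sprintf("malformed VCF record at line %d",
                 bad[1] + sum(startsWith(lines, "#"))), call. = FALSE)
  }
  n <- length(parts)
  getf <- function(i) vapply(parts, `[[`, character(1), i)
  info_get <- function(info, key) {
    m <- regmatches(info, regexpr(paste0(key, "=[^;]+"), info))
    ifelse(lengths(regmatches(info, gregexpr(paste0(key, "=[^;]+"), info))) > 0,
           sub(paste0(key, "="), "", m), NA_character_)
  }
  info <- getf(8)
  af <- matrix(0, n, length(samples), dimnames = list(NULL, samples))
  dp <- matrix(0L, n, length(samples), dimnames = list(NULL, samples))
  ac <- matrix(0L, n, length(samples), dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    gt <- vapply(parts, `[[`, character(1), 9 + j)
    sp <- strsplit(gt, ":", fixed = TRUE)
    af[, j] <- as.numeric(vapply(sp, `[[`, character(1), 1))
    dp[, j] <- as.integer(vapply(sp, `[[`, character(1), 2))
    ac[, j] <- as.integer(vapply(sp, `[[`, character(1), 3))
  }
  variants <- data.frame(
    pos = as.integer(getf(2)), ref = getf(4), alt = getf(5),
    type = info_get(info, "TYPE"),
    prevalence = as.integer(info_get(info, "PREV")),
    impact = info_get(info, "IMPACT"), stringsAsFactors = FALSE)
  out <- list(variants = variants, af = af, depth = dp, alt_count = ac)
  class(out) <- "pula_varset"
  out
}
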