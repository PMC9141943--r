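#' Build a synthetic amylopullulanase-like reference locus
#'
#' Generates a random locus with an in-frame CDS (ATG start, single terminal
#' stop, no internal in-frame stop codons) flanked by random sequence, with a
#' catabolite-responsive-element-like palindrome (`TGTTATCGATAACA`) planted in
#' the upstream flank. Codons 52, 69 and 75 are fixed to TGG (Trp) so that a
#' single G->A substitution at CDS positions 156, 207 or 225 creates a
#' premature TGA stop -- the stop-gain archetypes used by the shipped cohort
#' presets. The defaults (1500 codons, 171 bp flanks) give the canonical
#' 4842 bp locus size.
#'
#' @param cds_length_codons Number of codons including start and stop
#'   (>= 40; default 1500).
#' @param flank_bp Flank length on each side (>= 50; default 171).
#' @param seed RNG seed; the same seed always returns the same locus.
#' @return A [locus()] with features `cre_site` and `signal_peptide`.
#' @examples
#' loc <- make_locus(cds_length_codons = 120, flank_bp = 60, seed = 1)
#' locus_length(loc)
#' @export
make_locus <- function(cds_length_codons = 1500, flank_bp = 171, seed = 1) {
  if (cds_length_codons < 40) stop("cds_length_codons must be >= 40", call. = FALSE)
  if (flank_bp < 50) stop("flank_bp must be >= 50", call. = FALSE)
  cre <- "TGTTATCGATAACA"
  with_seed(seed, {
    rand_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                                  collapse = "")
    up <- chars(rand_dna(flank_bp))
    cre_at <- max(1L, flank_bp - 130L)
    up[cre_at:(cre_at + nchar(cre) - 1L)] <- chars(cre)
    up <- paste(up, collapse = "")
    down <- rand_dna(flank_bp)
    all_codons <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0),
                                  DNA_BASES, paste0))
    sense <- setdiff(all_codons, STOP_CODONS)
    body <- sample(sense, cds_length_codons - 2L, replace = TRUE)
    trp_at <- c(52L, 69L, 75L) - 1L # body index of codons 52/69/75
    trp_at <- trp_at[trp_at <= length(body)]
    body[trp_at] <- "TGG"
    cds <- paste(c("ATG", body, "TAA"), collapse = "")
    seq <- paste0(up, cds, down)
    cds_start <- flank_bp + 1L
    cds_end <- flank_bp + 3L * cds_length_codons
    sp_end <- min(cds_end, cds_start + 180L - 1L)
    locus("synthetic_pulA_locus", seq, cds_start, cds_end,
          features = list(
            cre_site = c(cre_at, cre_at + nchar(cre) - 1L),
            signal_peptide = c(cds_start, sp_end)))
  })
}

#' Planted edits for haplotype construction
#'
#' Constructors for the four edit archetypes a haplotype may carry: a single
#' nucleotide variant, a deletion, a literal-sequence insertion, and a mobile
#' element (transposase) insertion referenced by id. Positions are 1-based
#' locus coordinates; a deletion's position is its first deleted base; an
#' insertion lands immediately after its anchor position.
#'
#' @param position 1-based locus position.
#' @param ref,alt Single reference/alternate bases (`edit_snv`).
#' @param length Number of deleted bases (`edit_deletion`).
#' @param seq Inserted sequence (`edit_insertion`).
#' @param element_id Identifier into the transposase set
#'   (`edit_element_insertion`).
#' @return A list describing the edit, class `pula_edit`.
#' @export
edit_snv <- function(position, ref, alt) {
  stopifnot(nchar(ref) == 1, nchar(alt) == 1, ref != alt)
  structure(list(kind = "snv", position = as.integer(position),
                 ref = toupper(ref), alt = toupper(alt)), class = "pula_edit")
}

#' @rdname edit_snv
#' @export
edit_deletion <- function(position, length) {
  stopifnot(length >= 1)
  structure(list(kind = "deletion", position = as.integer(position),
                 length = as.integer(length)), class = "pula_edit")
}

#' @rdname edit_snv
#' @export
edit_insertion <- function(position, seq) {
  assert_dna(seq, "inserted sequence")
  structure(list(kind = "insertion", position = as.integer(position),
                 seq = toupper(seq)), class = "pula_edit")
}

#' @rdname edit_snv
#' @export
edit_element_insertion <- function(position, element_id) {
  structure(list(kind = "element_insertion", position = as.integer(position),
                 element_id = element_id), class = "pula_edit")
}

#' Haplotype specification: an identifier plus non-overlapping edits
#'
#' @param id Haplotype identifier.
#' @param edits List of [edit_snv()]-family edits, non-overlapping; they are
#'   sorted by ascending position.
#' @return A `pula_haplotype_spec`.
#' @export
haplotype_spec <- function(id, edits = list()) {
  if (length(edits)) {
    pos <- vapply(edits, `[[`, integer(1), "position")
    edits <- edits[order(pos)]
    ends <- vapply(edits, function(e) {
      if (e$kind == "deletion") e$position + e$length - 1L else e$position
    }, integer(1))
    starts <- vapply(edits, `[[`, integer(1), "position")
    if (length(edits) > 1 && any(starts[-1] <= ends[-length(ends)])) {
      stop("haplotype edits overlap", call. = FALSE)
    }
  }
  structure(list(id = id, edits = edits), class = "pula_haplotype_spec")
}

# Resolve an edit to its inserted sequence (element insertions need the
# element set).
edit_inserted_seq <- function(edit, elements) {
  if (edit$kind == "insertion") return(edit$seq)
  if (edit$kind == "element_insertion") {
    if (is.null(elements) || is.null(elements[[edit$element_id]])) {
      stop("unknown element id: ", edit$element_id, call. = FALSE)
    }
    return(elements[[edit$element_id]])
  }
  stop("not an insertion edit", call. = FALSE)
}

#' Apply a haplotype's edits to the reference locus
#'
#' Returns the edited haplotype sequence together with a coordinate map from
#' locus positions to haplotype positions (NA for deleted bases). The length
#' change equals total inserted minus total deleted bases.
#'
#' @param loc A [locus()].
#' @param spec A [haplotype_spec()].
#' @param elements Named character vector (or list) of element sequences for
#'   `element_insertion` edits.
#' @return List with `seq` (haplotype DNA string) and `coord_map` (integer
#'   vector of length `locus_length(loc)`).
#' @export
apply_edits <- function(loc, spec, elements = NULL) {
  ref <- loc$seq
  L <- nchar(ref)
  pieces <- character(0)
  map <- integer(L)
  last <- 1L     # next un-consumed locus position
  hap_at <- 0L   # haplotype length emitted so far
  emit_ref <- function(from, to) {
    if (to >= from) {
      pieces[[length(pieces) + 1L]] <<- substr(ref, from, to)
      n <- to - from + 1L
      map[from:to] <<- hap_at + seq_len(n)
      hap_at <<- hap_at + n
    }
  }
  for (e in spec$edits) {
    p <- e$position
    if (p < last || p > L) stop("edit position out of range or overlapping",
                                call. = FALSE)
    if (e$kind == "snv") {
      if (substr(ref, p, p) != e$ref) {
        stop(sprintf("snv ref mismatch at %d: locus has %s, edit says %s",
                     p, substr(ref, p, p), e$ref), call. = FALSE)
      }
      emit_ref(last, p - 1L)
      pieces[[length(pieces) + 1L]] <- e$alt
      hap_at <- hap_at + 1L
      map[p] <- hap_at
      last <- p + 1L
    } else if (e$kind == "deletion") {
      if (p + e$length - 1L > L) stop("deletion runs past locus end", call. = FALSE)
      emit_ref(last, p - 1L)
      map[p:(p + e$length - 1L)] <- NA_integer_
      last <- p + e$length
    } else { # insertion / element_insertion
      ins <- edit_inserted_seq(e, elements)
      emit_ref(last, p)
      pieces[[length(pieces) + 1L]] <- ins
      hap_at <- hap_at + nchar(ins)
      last <- p + 1L
    }
  }
  emit_ref(last, L)
  list(seq = paste(pieces, collapse = ""), coord_map = map)
}

#' Per-sample simulation specification
#'
#' @param id Sample identifier.
#' @param mixture Named numeric vector of haplotype proportions (non-negative,
#'   summing to 1).
#' @param mean_depth Target mean read-bp coverage of the locus (default 50).
#' @param read_length Read length in bp (default 150).
#' @param sub_error_rate Per-base substitution error probability
#'   (default 0.001; must be < 0.25).
#' @param seed Sample RNG seed; fixes the FASTQ byte-for-byte.
#' @return A `pula_sample_spec`.
#' @export
sample_spec <- function(id, mixture, mean_depth = 50, read_length = 150,
                        sub_error_rate = 0.001, seed = 1) {
  if (any(mixture < 0) || abs(sum(mixture) - 1) > 1e-8) {
    stop("mixture proportions must be non-negative and sum to 1", call. = FALSE)
  }
  if (mean_depth <= 0) stop("mean_depth must be positive", call. = FALSE)
  if (sub_error_rate < 0 || sub_error_rate >= 0.25) {
    stop("sub_error_rate must be in [0, 0.25)", call. = FALSE)
  }
  structure(list(id = id, mixture = mixture, mean_depth = mean_depth,
                 read_length = as.integer(read_length),
                 sub_error_rate = sub_error_rate, seed = as.integer(seed)),
            class = "pula_sample_spec")
}

#' Simulate a shotgun read set for one sample
#'
#' Draws reads from a mixture of haplotypes: the total read count is Poisson
#' with mean `mean_depth * locus_length / read_length`, each read's haplotype
#' is drawn from the mixture, start positions are uniform over positions
#' admitting a full-length read, strands are uniform, and each base is
#' substituted with probability `sub_error_rate` (uniformly among the three
#' alternative bases). A fixed seed yields a byte-identical read set.
#'
#' Alongside the reads a machine-readable truth record is returned: every
#' planted edit with its expected allele frequency (the summed mixture
#' proportions of carrier haplotypes) and the expected sample classification.
#'
#' @param sample A [sample_spec()].
#' @param haplotypes Named list with one entry per haplotype id in the
#'   mixture; each entry needs `seq` (from [apply_edits()]) and `spec` (the
#'   [haplotype_spec()]).
#' @param loc The reference [locus()] (for truth annotation).
#' @param elements Element set for resolving element insertions in the truth.
#' @param high_freq_threshold Disruption threshold on expected allele
#'   frequency (default 0.7).
#' @return List with `reads` (data.frame `id`, `seq`, `qual`) and `truth`.
#' @export
simulate_reads <- function(sample, haplotypes, loc, elements = NULL,
                           high_freq_threshold = 0.7) {
  stopifnot(inherits(sample, "pula_sample_spec"))
  missing_h <- setdiff(names(sample$mixture), names(haplotypes))
  if (length(missing_h)) {
    stop("mixture references unknown haplotypes: ",
         paste(missing_h, collapse = ", "), call. = FALSE)
  }
  L <- locus_length(loc)
  rl <- sample$read_length
  for (h in names(sample$mixture)) {
    if (rl > nchar(haplotypes[[h]]$seq)) {
      stop("read_length exceeds haplotype length for ", h, call. = FALSE)
    }
  }
  reads <- with_seed(sample$seed, {
    n_total <- rpois(1, sample$mean_depth * L / rl)
    hap_ids <- names(sample$mixture)
    assign_h <- if (length(hap_ids) == 1) rep(hap_ids, n_total) else
      sample(hap_ids, n_total, replace = TRUE, prob = sample$mixture)
    seqs <- character(n_total)
    for (h in hap_ids) {
      idx <- which(assign_h == h)
      if (!length(idx)) next
      hs <- haplotypes[[h]]$seq
      starts <- sample.int(nchar(hs) - rl + 1L, length(idx), replace = TRUE)
      seqs[idx] <- substring(hs, starts, starts + rl - 1L)
    }
    minus <- runif(n_total) < 0.5
    seqs[minus] <- revcomp(seqs[minus])
    if (sample$sub_error_rate > 0 && n_total > 0) {
      mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                    nrow = rl)
      hit <- which(runif(length(mat)) < sample$sub_error_rate)
      if (length(hit)) {
        # substitute uniformly among the three alternatives
        shift <- sample.int(3L, length(hit), replace = TRUE)
        code <- match(mat[hit], DNA_BASES)
        mat[hit] <- DNA_BASES[((code - 1L + shift) %% 4L) + 1L]
      }
      seqs <- apply(mat, 2, paste, collapse = "")
    }
    data.frame(
      id = sprintf("%s_r%06d", sample$id, seq_len(n_total)),
      seq = seqs,
      qual = strrep("I", rl),
      stringsAsFactors = FALSE)
  })
  truth <- truth_record(sample, haplotypes, loc, elements, high_freq_threshold)
  list(reads = reads, truth = truth)
}

# Expected-truth record for a simulated sample.
truth_record <- function(sample, haplotypes, loc, elements,
                         high_freq_threshold = 0.7) {
  events <- list()
  for (h in names(sample$mixture)) {
    prop <- sample$mixture[[h]]
    if (prop <= 0) next
    for (e in haplotypes[[h]]$spec$edits) {
      key <- edit_key(e)
      if (is.null(events[[key]])) {
        events[[key]] <- list(edit = e, expected_af = 0)
      }
      events[[key]]$expected_af <- events[[key]]$expected_af + prop
    }
  }
  causes <- character(0)
  for (ev in events) {
    if (ev$expected_af + 1e-9 < high_freq_threshold) next
    causes <- union(causes, edit_causes(ev$edit, loc))
  }
  list(sample_id = sample$id,
       events = unname(lapply(events, function(ev) {
         list(kind = ev$edit$kind, position = ev$edit$position,
              expected_af = ev$expected_af)
       })),
       expected_status = if (length(causes)) "disrupted" else "intact",
       expected_causes = sort(causes))
}

edit_key <- function(e) {
  paste(e$kind, e$position,
        if (e$kind == "deletion") e$length
        else if (e$kind == "snv") paste0(e$ref, ">", e$alt)
        else if (e$kind == "insertion") e$seq
        else e$element_id,
        sep = ":")
}

# Which disruption causes a planted edit implies, if observed at high
# frequency. Large events surface as structural variants; small frameshift /
# stop-gain edits as high-impact small variants; neutral edits imply none.
SV_MIN_EVENT_BP <- 50L

edit_causes <- function(e, loc) {
  if (e$kind == "element_insertion") {
    return(c("structural_variant", "transposase_insertion"))
  }
  if (e$kind == "deletion" && e$length >= SV_MIN_EVENT_BP) {
    return("structural_variant")
  }
  if (e$kind == "insertion" && nchar(e$seq) >= SV_MIN_EVENT_BP) {
    return("structural_variant")
  }
  imp <- edit_impact(loc, e)
  if (imp == "HIGH") "high_impact_small_variant" else character(0)
}

#' Generate a toy transposase sequence set with family truth
#'
#' Emulates a redundant mobile-element database at toy scale: `n_families`
#' unrelated ancestor sequences, each copied `copies_per_family` times with
#' exactly `round(within_family_divergence * length_bp)` substitutions per
#' copy (drawn independently per copy). Any two same-family copies therefore
#' share identity of at least `1 - 2 * within_family_divergence`, so the
#' default divergence of 0.02 guarantees within-family identity >= 0.96 --
#' safely above the 95% clustering threshold -- while cross-family identity
#' stays near the random baseline.
#'
#' @param n_families Number of unrelated families (default 3).
#' @param copies_per_family Copies per family (default 4).
#' @param length_bp Element length (default 1000).
#' @param within_family_divergence Per-copy substitution fraction from the
#'   family ancestor (must be < 0.05; default 0.02).
#' @param seed RNG seed.
#' @return List with `sequences` (named character vector) and `families`
#'   (data.frame `id`, `family`).
#' @export
make_transposase_set <- function(n_families = 3, copies_per_family = 4,
                                 length_bp = 1000,
                                 within_family_divergence = 0.02, seed = 1) {
  if (within_family_divergence >= 0.05) {
    stop("within_family_divergence must be < 0.05 for distinguishable families",
         call. = FALSE)
  }
  if (n_families < 1 || copies_per_family < 1 || length_bp < 50) {
    stop("infeasible transposase set parameters", call. = FALSE)
  }
  k <- round(within_family_divergence * length_bp)
  with_seed(seed, {
    seqs <- character(0)
    fam <- character(0)
    for (f in seq_len(n_families)) {
      anc <- sample(DNA_BASES, length_bp, replace = TRUE)
      for (cc in seq_len(copies_per_family)) {
        cp <- anc
        if (k > 0) {
          at <- sample.int(length_bp, k)
          shift <- sample.int(3L, k, replace = TRUE)
          code <- match(cp[at], DNA_BASES)
          cp[at] <- DNA_BASES[((code - 1L + shift) %% 4L) + 1L]
        }
        id <- sprintf("tnp_f%02d_c%02d", f, cc)
        seqs[id] <- paste(cp, collapse = "")
        fam <- c(fam, sprintf("family_%02d", f))
      }
    }
    list(sequences = seqs,
         families = data.frame(id = names(seqs), family = fam,
                               stringsAsFactors = FALSE))
  })
}

#' Canonical haplotype presets mirroring the archetypal gene disruptions
#'
#' Builds the haplotype specifications used throughout testing: the intact
#' gene; a 2-nt frameshift deletion in the signal-peptide region (CDS position
#' 156 -- the exact in-gene position of the archetype is not published, so the
#' preset places it at the first of the three recurrent high-impact positions
#' and labels that an assumption); a stop-gain haplotype carrying G->A
#' substitutions at CDS positions 156, 207 and 225; N-terminal transposase
#' insertions of two different element families; and a 600 bp deletion
#' removing CDS positions 101-700.
#'
#' @param loc A locus from [make_locus()].
#' @param elements Transposase set from [make_transposase_set()] (its
#'   `sequences` field), needed for the element-insertion haplotypes.
#' @return Named list of [haplotype_spec()] objects.
#' @export
table_haplotypes <- function(loc, elements = NULL) {
  cs <- loc$cds_start
  gpos <- function(cds_pos) cs + cds_pos - 1L
  base_at <- function(p) substr(loc$seq, p, p)
  stop_snv <- function(cds_pos) {
    p <- gpos(cds_pos)
    edit_snv(p, base_at(p), "A") # TGG -> TGA
  }
  haps <- list(
    intact = haplotype_spec("intact"),
    del2_sp = haplotype_spec("del2_sp", list(edit_deletion(gpos(156L), 2L))),
    stopgain = haplotype_spec("stopgain", list(
      stop_snv(156L), stop_snv(207L), stop_snv(225L))),
    large_del = haplotype_spec("large_del",
                               list(edit_deletion(gpos(101L), 600L)))
  )
  if (!is.null(elements)) {
    ids <- names(elements)
    fam1 <- ids[grepl("_f01_", ids)][1]
    fam2 <- ids[grepl("_f02_", ids)][1]
    if (!is.na(fam1)) {
      haps$ins_tnp1 <- haplotype_spec(
        "ins_tnp1", list(edit_element_insertion(gpos(300L), fam1)))
    }
    if (!is.na(fam2)) {
      haps$ins_tnp2 <- haplotype_spec(
        "ins_tnp2", list(edit_element_insertion(gpos(250L), fam2)))
    }
  }
  haps
}

#' Assemble the standard 12-sample synthetic cohort
#'
#' The shipped study design: 2 intact samples, 3 samples homozygous for the
#' 2-nt signal-peptide deletion, 3 for the triple stop-gain haplotype, one for
#' each of two transposase-insertion variants, and 2 for the 600 bp deletion
#' -- every small variant is therefore carried by at least three samples,
#' matching the three-sample prevalence filter of the caller (structural
#' variants are called per sample and need no prevalence). All planted
#' genotypes are at allele frequency 1.0.
#'
#' @param seed Master seed; per-sample seeds are derived deterministically.
#' @param mean_depth,read_length,sub_error_rate Passed to [sample_spec()].
#' @return A cohort object (list) consumable by [simulate_cohort()] and
#'   [run_pipeline()]: locus, element set with family truth, haplotype specs,
#'   sample specs, and default parameters (`coverage_gate_fraction = 0.8`, so
#'   a high-frequency 600 bp deletion -- 13% of the CDS -- does not by itself
#'   fail the coverage gate).
#' @export
cohort_preset <- function(seed = 1, mean_depth = 50, read_length = 150,
                          sub_error_rate = 0.001) {
  loc <- make_locus(seed = seed)
  tnp <- make_transposase_set(seed = seed + 101L)
  haps <- table_haplotypes(loc, tnp$sequences)
  genotypes <- c(s01 = "intact", s02 = "intact",
                 s03 = "del2_sp", s04 = "del2_sp", s05 = "del2_sp",
                 s06 = "stopgain", s07 = "stopgain", s08 = "stopgain",
                 s09 = "ins_tnp1", s10 = "ins_tnp2",
                 s11 = "large_del", s12 = "large_del")
  samples <- lapply(seq_along(genotypes), function(i) {
    sample_spec(names(genotypes)[i],
                mixture = setNames(1, genotypes[[i]]),
                mean_depth = mean_depth, read_length = read_length,
                sub_error_rate = sub_error_rate,
                seed = (seed * 1000L + i * 37L) %% 2147483647L)
  })
  names(samples) <- names(genotypes)
  list(locus = loc, elements = tnp$sequences, element_families = tnp$families,
       haplotypes = haps, samples = samples,
       params = list(coverage_gate_fraction = 0.8))
}

#' Materialize a cohort on disk
#'
#' Writes the reference FASTA + JSON gene model, the transposase FASTA, one
#' FASTQ per sample, a BED of planted edit positions and a JSON truth file.
#'
#' @param cohort From [cohort_preset()] (or a hand-built list of the same
#'   shape).
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with `truth` (per-sample truth records) and
#'   `files`.
#' @export
simulate_cohort <- function(cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  loc <- cohort$locus
  files <- list(
    ref_fasta = file.path(outdir, "reference.fa"),
    gene_model = file.path(outdir, "gene_model.json"),
    transposase_fasta = file.path(outdir, "transposases.fa"),
    truth = file.path(outdir, "truth.json"),
    edits_bed = file.path(outdir, "planted_edits.bed"))
  write_locus(loc, files$ref_fasta, files$gene_model)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(cohort$elements),
                              files$transposase_fasta)
  built <- lapply(cohort$haplotypes, function(sp) {
    c(apply_edits(loc, sp, cohort$elements), list(spec = sp))
  })
  truth <- list(); fastqs <- character(0)
  bed <- character(0)
  for (sp in cohort$haplotypes) {
    for (e in sp$edits) {
      end <- if (e$kind == "deletion") e$position + e$length - 1L else e$position
      bed <- c(bed, sprintf("%s\t%d\t%d\t%s:%s", loc$id, e$position - 1L, end,
                            sp$id, e$kind))
    }
  }
  writeLines(unique(bed), files$edits_bed)
  for (sm in cohort$samples) {
    sim <- simulate_reads(sm, built, loc, cohort$elements)
    fq <- file.path(outdir, paste0(sm$id, ".fastq"))
    write_fastq(sim$reads, fq)
    fastqs[sm$id] <- fq
    truth[[sm$id]] <- sim$truth
  }
  files$fastq <- fastqs
  jsonlite::write_json(truth, files$truth, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(truth = truth, files = files))
}

#' FASTQ input/output
#'
#' Thin wrappers around Biostrings' FASTQ support, returning/consuming the
#' plain data.frame read layout used by the simulator and aligner.
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param path FASTQ file path.
#' @return `read_fastq` returns a data.frame with `id`, `seq`, `qual`.
#' @export
write_fastq <- function(reads, path) {
  q <- Biostrings::PhredQuality(reads$qual)
  ss <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(reads$seq, reads$id)), q)
  # the writer notes dropped metadata columns; nothing of ours is lost
  suppressWarnings(Biostrings::writeQualityScaledXStringSet(ss, path))
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  # the quality-scaled reader notes dropped metadata columns; none are ours
  ss <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  suppressWarnings(
    data.frame(id = names(ss), seq = as.character(ss),
               qual = as.character(Biostrings::quality(ss)),
               stringsAsFactors = FALSE, row.names = NULL))
}

#' Pipeline configuration for a simulated cohort
#'
#' Convenience glue between [simulate_cohort()] output and [run_pipeline()]:
#' points the pipeline at the materialized files and carries the cohort's
#' coverage-gate fraction into the calling parameters.
#'
#' @param cohort From [cohort_preset()].
#' @param sim Return value of [simulate_cohort()].
#' @param outdir Pipeline output directory.
#' @return A config list for [run_pipeline()].
#' @export
cohort_pipeline_config <- function(cohort, sim, outdir) {
  gate_frac <- cohort$params$coverage_gate_fraction
  if (is.null(gate_frac)) gate_frac <- 1.0
  list(ref_fasta = sim$files$ref_fasta,
       gene_model = sim$files$gene_model,
       transposase_fasta = sim$files$transposase_fasta,
       fastq = sim$files$fastq,
       params = list(calling = calling_params(coverage_gate_fraction = gate_frac)),
       outdir = outdir)
}
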