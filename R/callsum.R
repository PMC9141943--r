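#' Classify one sample as intact, disrupted, or insufficiently covered
#'
#' A sample that failed the coverage gate is `insufficient_coverage`.
#' Otherwise it is `disrupted` iff it carries a HIGH-impact small variant at
#' allele frequency >= `high_freq_threshold`, or a structural variant at
#' frequency >= the SV high-frequency threshold; the `causes` field records
#' which branch(es) fired, with `transposase_insertion` added when a firing
#' SV carries transposase evidence. Transposase read counts without a
#' supported SV never disrupt.
#'
#' @param sample_id Sample identifier.
#' @param gate From [coverage_gate()] (or `NULL` to assume coverage passed).
#' @param varset Impact-annotated `pula_varset` from
#'   [joint_filter()]/[annotate_impact()] covering this sample, or `NULL`.
#' @param svs Per-sample SV table from [call_structural_variants()] (after
#'   [attach_transposase_evidence()]), or `NULL`.
#' @param params [calling_params()].
#' @return A list of class `pula_sample_call`: `sample_id`, `status`,
#'   `causes`, `evidence` (data.frame `kind`, `description`, `frequency`).
#' @export
classify_sample <- function(sample_id, gate, varset, svs,
                            params = calling_params()) {
  mk <- function(status, causes = character(0),
                 evidence = data.frame(kind = character(0),
                                       description = character(0),
                                       frequency = numeric(0),
                                       stringsAsFactors = FALSE)) {
    structure(list(sample_id = sample_id, status = status, causes = causes,
                   evidence = evidence), class = "pula_sample_call")
  }
  if (!is.null(gate) && !isTRUE(gate$included)) {
    return(mk("insufficient_coverage"))
  }
  causes <- character(0)
  ev <- list()
  if (!is.null(varset) && nrow(varset$variants) &&
      sample_id %in% colnames(varset$af)) {
    vs <- varset$variants
    hi <- which(!is.na(vs$impact) & vs$impact == "HIGH" &
                  varset$af[, sample_id] >= params$high_freq_threshold - 1e-12)
    if (length(hi)) {
      causes <- c(causes, "high_impact_small_variant")
      ev[[length(ev) + 1L]] <- data.frame(
        kind = "small_variant",
        description = sprintf("%d:%s>%s", vs$pos[hi], vs$ref[hi], vs$alt[hi]),
        frequency = varset$af[hi, sample_id], stringsAsFactors = FALSE)
    }
  }
  if (!is.null(svs) && nrow(svs)) {
    hf <- which(svs$high_freq)
    if (length(hf)) {
      causes <- c(causes, "structural_variant")
      if (any(!is.na(svs$element[hf]))) {
        causes <- c(causes, "transposase_insertion")
      }
      ev[[length(ev) + 1L]] <- data.frame(
        kind = "structural_variant",
        description = sprintf("%s:%d-%d%s", svs$type[hf], svs$start[hf],
                              svs$end[hf],
                              ifelse(is.na(svs$element[hf]), "",
                                     paste0(":", svs$element[hf]))),
        frequency = svs$frequency[hf], stringsAsFactors = FALSE)
    }
  }
  if (!length(causes)) return(mk("intact"))
  evidence <- do.call(rbind, ev)
  rownames(evidence) <- NULL
  mk("disrupted", causes = unique(causes), evidence = evidence)
}

#' Summarize disruption prevalence over a cohort
#'
#' Union counting: a sample with several causes contributes once to
#' `n_disrupted`. Samples below the coverage gate are excluded from the
#' denominator. The display percentage rounds half away from zero to whole
#' percent (62/270 covered -> 23).
#'
#' @param calls List of `pula_sample_call` objects.
#' @return A list of class `pula_cohort_summary`: `n_samples_total`,
#'   `n_covered`, `n_disrupted`, `fraction_disrupted`, `percent_disrupted`,
#'   and `cause_counts` (named integer vector).
#' @export
summarize_cohort <- function(calls) {
  stopifnot(length(calls) >= 1)
  status <- vapply(calls, `[[`, character(1), "status")
  n_total <- length(calls)
  n_cov <- sum(status != "insufficient_coverage")
  n_dis <- sum(status == "disrupted")
  causes <- unlist(lapply(calls, `[[`, "causes"))
  cause_levels <- c("high_impact_small_variant", "structural_variant",
                    "transposase_insertion")
  cc <- vapply(cause_levels, function(x) sum(causes == x), integer(1))
  structure(list(n_samples_total = n_total, n_covered = n_cov,
                 n_disrupted = n_dis,
                 fraction_disrupted = if (n_cov > 0) n_dis / n_cov else NA_real_,
                 percent_disrupted = percent_display(n_dis, n_cov),
                 cause_counts = cc),
            class = "pula_cohort_summary")
}

#' @export
print.pula_cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort summary> %d samples, %d covered, %d disrupted (%s%%)\n",
              x$n_samples_total, x$n_covered, x$n_disrupted,
              format(x$percent_disrupted)))
  for (nm in names(x$cause_counts)) {
    cat(sprintf("  %-26s %d\n", nm, x$cause_counts[[nm]]))
  }
  invisible(x)
}

#' Stratify disruption prevalence by a sample grouping
#'
#' @param calls List of `pula_sample_call` objects.
#' @param groups Named character vector mapping sample id to group label;
#'   samples without a label fall into `"unknown"`. Groups with no covered
#'   samples are omitted.
#' @return data.frame `group`, `n_covered`, `n_disrupted`, `fraction`,
#'   `percent` (whole-percent display rounding).
#' @export
stratify <- function(calls, groups) {
  ids <- vapply(calls, `[[`, character(1), "sample_id")
  status <- vapply(calls, `[[`, character(1), "status")
  g <- groups[ids]
  g[is.na(g)] <- "unknown"
  rows <- lapply(sort(unique(g)), function(lab) {
    sel <- g == lab & status != "insufficient_coverage"
    n_cov <- sum(sel)
    if (n_cov == 0) return(NULL)
    n_dis <- sum(status[sel] == "disrupted")
    data.frame(group = lab, n_covered = n_cov, n_disrupted = n_dis,
               fraction = n_dis / n_cov,
               percent = percent_display(n_dis, n_cov),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) {
    out <- data.frame(group = character(0), n_covered = integer(0),
                      n_disrupted = integer(0), fraction = numeric(0),
                      percent = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Run the full screening pipeline on a cohort
#'
#' Orchestrates align -> pileup/coverage gate -> per-sample small-variant
#' observation -> cross-sample joint filter + impact annotation ->
#' breakpoint/SV scan with transposase classification -> per-sample
#' classification -> cohort summary. Fully deterministic given the input
#' files/objects; all stage outputs are written under `config$outdir`.
#'
#' @param config A list with either file paths (`ref_fasta` + `gene_model`,
#'   named `fastq` vector, `transposase_fasta`) or in-memory objects
#'   (`locus`, `samples` as a named list of read data.frames, `elements`);
#'   optional `groups` (named character vector) for stratification, optional
#'   `params` list with `calling`, `aligner`, `sv` overrides, and `outdir`.
#' @return A list: `calls`, `summary`, `varset`, `svs` (per sample),
#'   `gates`, `stratified` (if groups given), `files`.
#' @export
run_pipeline <- function(config) {
  outdir <- config$outdir
  if (is.null(outdir)) stop("config$outdir is required", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (f in c("ref_fasta", "gene_model", "transposase_fasta")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      stop("configuration error: missing input file ", config[[f]],
           call. = FALSE)
    }
  }
  if (!is.null(config$fastq)) {
    miss <- config$fastq[!file.exists(config$fastq)]
    if (length(miss)) {
      stop("configuration error: missing input file ", miss[1], call. = FALSE)
    }
  }
  loc <- if (!is.null(config$locus)) config$locus else
    read_locus(config$ref_fasta, config$gene_model)
  elements <- if (!is.null(config$elements)) config$elements else {
    ss <- Biostrings::readDNAStringSet(config$transposase_fasta)
    setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  }
  reads_by_sample <- if (!is.null(config$samples)) config$samples else
    lapply(config$fastq, read_fastq)
  p_call <- config$params$calling %||% calling_params()
  p_aln <- config$params$aligner %||% aligner_params()
  p_sv <- config$params$sv %||% sv_params()
  db <- cluster_sequences(elements, p_sv$identity_threshold, p_aln)
  sample_ids <- names(reads_by_sample)
  gates <- list(); obs <- list(); svs <- list(); counts_log <- list()
  for (s in sample_ids) {
    aln <- align_reads(reads_by_sample[[s]], loc, p_aln)
    write_sam(aln, loc, file.path(outdir, paste0(s, ".sam")))
    pu <- pileup(aln, loc)
    gates[[s]] <- coverage_gate(pu, loc, p_call)
    sv_s <- NULL
    if (gates[[s]]$included) {
      obs[[s]] <- call_sample_variants(pu, loc, p_call)
      clus <- detect_breakpoints(aln, p_sv, p_aln)
      sv_s <- call_structural_variants(clus, aln, loc, p_sv, p_aln)
      tails <- unlist(sv_s$tails)
      unmapped <- aln$oriented_seq[!aln$mapped]
      cls <- classify_clipped_reads(tails, unmapped, db, p_sv, p_aln)
      sv_s <- attach_transposase_evidence(sv_s, cls)
    }
    svs[[s]] <- sv_s
    counts_log[[s]] <- list(
      n_reads = nrow(reads_by_sample[[s]]),
      n_mapped = sum(aln$mapped),
      gate_included = gates[[s]]$included,
      n_sv = if (is.null(sv_s)) 0L else nrow(sv_s))
    sv_out <- if (is.null(sv_s)) {
      data.frame(type = character(0), start = integer(0), end = integer(0),
                 support_reads = integer(0), frequency = numeric(0),
                 high_freq = logical(0), element = character(0),
                 element_reads = integer(0), stringsAsFactors = FALSE)
    } else sv_s[, setdiff(names(sv_s), "tails")]
    write.table(sv_out, file.path(outdir, paste0(s, ".sv.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  varset <- joint_filter(obs, p_call)
  varset <- annotate_impact(varset, loc)
  write_vcf(varset, loc, file.path(outdir, "variants.vcf"))
  af_tsv <- file.path(outdir, "variant_af_matrix.tsv")
  af_df <- cbind(varset$variants, as.data.frame(varset$af))
  write.table(af_df, af_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  calls <- lapply(sample_ids, function(s) {
    classify_sample(s, gates[[s]], varset, svs[[s]], p_call)
  })
  names(calls) <- sample_ids
  summ <- summarize_cohort(calls)
  call_df <- data.frame(
    sample_id = sample_ids,
    status = vapply(calls, `[[`, character(1), "status"),
    causes = vapply(calls, function(x) paste(x$causes, collapse = ","),
                    character(1)),
    stringsAsFactors = FALSE)
  write.table(call_df, file.path(outdir, "sample_calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  summ_df <- data.frame(n_samples_total = summ$n_samples_total,
                        n_covered = summ$n_covered,
                        n_disrupted = summ$n_disrupted,
                        percent_disrupted = summ$percent_disrupted)
  write.table(summ_df, file.path(outdir, "cohort_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  stratified <- NULL
  if (!is.null(config$groups)) {
    stratified <- stratify(calls, config$groups)
    write.table(stratified, file.path(outdir, "stratified_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    reference = loc$id, reference_length = locus_length(loc),
    n_transposase_sequences = length(elements),
    n_transposase_representatives = length(db$representatives),
    params = list(calling = unclass(p_call), aligner = unclass(p_aln),
                  sv = unclass(p_sv)),
    stage_counts = counts_log)
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(calls = calls, summary = summ, varset = varset, svs = svs,
                 gates = gates, stratified = stratified, outdir = outdir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
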