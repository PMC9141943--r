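# Hand-built inputs for classification unit tests.
mk_varset <- function(impacts, afs, sample = "s1") {
  n <- length(impacts)
  vs <- list(variants = data.frame(pos = seq(10L, by = 10L, length.out = n),
                                   ref = "A", alt = "T", type = "snv",
                                   prevalence = 3L, impact = impacts,
                                   stringsAsFactors = FALSE),
             af = matrix(afs, n, 1, dimnames = list(NULL, sample)),
             depth = matrix(100L, n, 1, dimnames = list(NULL, sample)),
             alt_count = matrix(as.integer(afs * 100), n, 1,
                                dimnames = list(NULL, sample)))
  class(vs) <- "pula_varset"
  vs
}

mk_svs <- function(freqs = numeric(0), types = character(0),
                   elements = rep(NA_character_, length(freqs))) {
  df <- data.frame(type = types, start = 100L, end = 200L,
                   support_reads = 30L, frequency = freqs,
                   high_freq = freqs >= 0.7 - 1e-12, element = elements,
                   element_reads = ifelse(is.na(elements), NA_integer_, 25L),
                   stringsAsFactors = FALSE)
  df$tails <- rep(list(character(0)), nrow(df))
  df
}

gate_ok <- list(included = TRUE, fraction_covered = 1)
gate_bad <- list(included = FALSE, fraction_covered = 0.4)

test_that("sample classification follows the high-frequency disruption rule", {
  # HIGH-impact variant at af 0.8: disrupted by a small variant
  call <- classify_sample("s1", gate_ok, mk_varset("HIGH", 0.8), NULL)
  expect_equal(call$status, "disrupted")
  expect_equal(call$causes, "high_impact_small_variant")
  # MODERATE at af 0.95 alone: intact
  expect_equal(classify_sample("s1", gate_ok, mk_varset("MODERATE", 0.95),
                               NULL)$status, "intact")
  # HIGH at af 0.69: below the threshold, intact
  expect_equal(classify_sample("s1", gate_ok, mk_varset("HIGH", 0.69),
                               NULL)$status, "intact")
  # HIGH at exactly 0.7: inclusive boundary, disrupted
  expect_equal(classify_sample("s1", gate_ok, mk_varset("HIGH", 0.7),
                               NULL)$status, "disrupted")
  # failed gate wins over any evidence
  call_bad <- classify_sample("s1", gate_bad, mk_varset("HIGH", 0.9),
                              mk_svs(0.9, "insertion"))
  expect_equal(call_bad$status, "insufficient_coverage")
  expect_length(call_bad$causes, 0L)
})

test_that("SV evidence and transposase causes combine by union", {
  # high-frequency SV alone
  call_sv <- classify_sample("s1", gate_ok, NULL, mk_svs(0.9, "deletion"))
  expect_equal(call_sv$status, "disrupted")
  expect_equal(call_sv$causes, "structural_variant")
  # transposase-backed insertion adds the third cause
  call_tnp <- classify_sample("s1", gate_ok, NULL,
                              mk_svs(0.9, "insertion", "tnp_f01_c01"))
  expect_setequal(call_tnp$causes,
                  c("structural_variant", "transposase_insertion"))
  # sub-threshold SV disrupts nothing
  expect_equal(classify_sample("s1", gate_ok, NULL,
                               mk_svs(0.5, "insertion"))$status, "intact")
  # both branches firing still yield a single disrupted call
  both <- classify_sample("s1", gate_ok, mk_varset("HIGH", 0.8),
                          mk_svs(0.9, "insertion", "tnp_f01_c01"))
  expect_equal(both$status, "disrupted")
  expect_setequal(both$causes, c("high_impact_small_variant",
                                 "structural_variant",
                                 "transposase_insertion"))
})

test_that("cohort summary reproduces the published prevalence arithmetic", {
  mk_call <- function(id, status, causes = character(0)) {
    structure(list(sample_id = id, status = status, causes = causes,
                   evidence = NULL), class = "pula_sample_call")
  }
  calls <- c(lapply(1:62, function(i) mk_call(paste0("d", i), "disrupted",
                                              "structural_variant")),
             lapply(1:208, function(i) mk_call(paste0("i", i), "intact")),
             lapply(1:10, function(i) mk_call(paste0("u", i),
                                              "insufficient_coverage")))
  s <- summarize_cohort(calls)
  expect_equal(s$n_samples_total, 280L)
  expect_equal(s$n_covered, 270L)
  expect_equal(s$n_disrupted, 62L)
  expect_equal(s$percent_disrupted, 23) # 22.96 rounds half-away to 23
  # a sample with two causes still counts once
  multi <- c(calls[1:3],
             list(mk_call("m", "disrupted",
                          c("high_impact_small_variant",
                            "structural_variant"))))
  expect_equal(summarize_cohort(multi)$n_disrupted, 4L)
  # all intact: zero percent
  expect_equal(summarize_cohort(calls[63:80])$percent_disrupted, 0)
  # sample order does not change the fraction
  expect_equal(summarize_cohort(rev(calls))$fraction_disrupted,
               s$fraction_disrupted)
})

test_that("stratification reports per-group prevalence with display rounding", {
  mk_call <- function(id, status) {
    structure(list(sample_id = id, status = status, causes = character(0),
                   evidence = NULL), class = "pula_sample_call")
  }
  ids_a <- paste0("a", 1:102); ids_b <- paste0("b", 1:55)
  calls <- c(lapply(seq_along(ids_a), function(i) {
    mk_call(ids_a[i], if (i <= 12) "disrupted" else "intact")
  }),
  lapply(seq_along(ids_b), function(i) {
    mk_call(ids_b[i], if (i <= 19) "disrupted" else "intact")
  }))
  groups <- c(setNames(rep("groupA", 102), ids_a),
              setNames(rep("groupB", 55), ids_b))
  st <- stratify(calls, groups)
  expect_equal(st$n_covered, c(102L, 55L))
  expect_equal(st$n_disrupted, c(12L, 19L))
  expect_equal(st$percent[1], 12)  # 11.76 -> 12
  expect_equal(st$percent[2], 35)  # 34.5 -> 35 under round-half-away
  # unlabelled samples fall into "unknown"; empty groups are omitted
  st2 <- stratify(calls[1:3], groups[character(0)])
  expect_equal(st2$group, "unknown")
  expect_false("groupB" %in% stratify(calls[1:102], groups)$group)
})

test_that("the pipeline classifies a small planted cohort end to end", {
  loc <- make_locus(cds_length_codons = 300, flank_bp = 171, seed = 71)
  del_pos <- loc$cds_start + 155L
  haps <- list(
    intact = haplotype_spec("intact"),
    fs = haplotype_spec("fs", list(edit_deletion(del_pos, 2L))))
  genotypes <- c(p1 = "intact", p2 = "fs", p3 = "fs", p4 = "fs")
  cohort <- list(
    locus = loc,
    elements = make_transposase_set(n_families = 2, copies_per_family = 2,
                                    length_bp = 300, seed = 5)$sequences,
    haplotypes = haps,
    samples = lapply(seq_along(genotypes), function(i) {
      sample_spec(names(genotypes)[i], setNames(1, genotypes[[i]]),
                  mean_depth = 30, read_length = 100, seed = 700L + i)
    }),
    params = list(coverage_gate_fraction = 1.0))
  names(cohort$samples) <- names(genotypes)
  simdir <- tempfile("sim"); rundir <- tempfile("run")
  sim <- simulate_cohort(cohort, simdir)
  res <- run_pipeline(cohort_pipeline_config(cohort, sim, rundir))
  status <- vapply(res$calls, `[[`, character(1), "status")
  expect_equal(unname(status),
               c("intact", rep("disrupted", 3)))
  expect_equal(res$summary$n_disrupted, 3L)
  expect_equal(res$summary$percent_disrupted, 75)
  expect_true(file.exists(file.path(rundir, "variants.vcf")))
  expect_true(file.exists(file.path(rundir, "sample_calls.tsv")))
  expect_true(file.exists(file.path(rundir, "run_manifest.json")))
  # the planted frameshift is in the VCF with HIGH impact
  vcf <- read_vcf(file.path(rundir, "variants.vcf"))
  expect_true(any(vcf$variants$impact == "HIGH" &
                    vcf$variants$type == "deletion"))
})

test_that("a coverage-starved sample is excluded from the denominator", {
  loc <- make_locus(cds_length_codons = 200, flank_bp = 100, seed = 73)
  haps <- list(intact = haplotype_spec("intact"))
  cohort <- list(
    locus = loc, elements = c(el1 = strrep("ACGGTTCA", 40)),
    haplotypes = haps,
    samples = list(
      deep = sample_spec("deep", c(intact = 1), mean_depth = 25,
                         read_length = 100, seed = 81),
      shallow = sample_spec("shallow", c(intact = 1), mean_depth = 2,
                            read_length = 100, seed = 82)),
    params = list(coverage_gate_fraction = 1.0))
  simdir <- tempfile("sim"); rundir <- tempfile("run")
  sim <- simulate_cohort(cohort, simdir)
  res <- run_pipeline(cohort_pipeline_config(cohort, sim, rundir))
  expect_equal(res$calls$shallow$status, "insufficient_coverage")
  expect_equal(res$summary$n_covered, 1L)
  expect_equal(res$summary$n_disrupted, 0L)
})

test_that("a missing input file aborts before any stage runs", {
  cfg <- list(ref_fasta = tempfile("absent"), gene_model = tempfile("absent"),
              transposase_fasta = tempfile("absent"),
              fastq = c(s1 = tempfile("absent")), outdir = tempfile("out"))
  expect_error(run_pipeline(cfg), "configuration error")
  expect_false(file.exists(file.path(cfg$outdir, "run_manifest.json")))
})
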