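# Hand-built alignment tables double as pileup fixtures.
mk_aln <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  df$qual <- strrep("I", nchar(df$oriented_seq))
  if (is.null(df$score)) df$score <- 100L
  if (is.null(df$edit_distance)) df$edit_distance <- 0L
  if (is.null(df$strand)) df$strand <- "+"
  df$mapped <- TRUE
  class(df) <- c("pula_alignments", "data.frame")
  df
}

test_that("pileup counts match a hand-constructed alignment stack", {
  loc <- toy_locus()
  s100 <- substr(loc$seq, 1, 100)
  aln <- mk_aln(read_id = sprintf("r%02d", 1:10), ref_start = 1L,
                cigar = "100M", oriented_seq = s100)
  pu <- pileup(aln, loc)
  expect_true(all(pu$depth[1:100] == 10L))
  expect_true(all(pu$depth[101:locus_length(loc)] == 0L))
  ref_chars <- strsplit(s100, "")[[1]]
  for (p in c(1, 50, 100)) {
    expect_equal(unname(pu$counts[ref_chars[p], p]), 10L)
    expect_equal(sum(pu$counts[, p]), 10L)
  }
})

test_that("deletion-bearing and soft-clipped reads pile up correctly", {
  loc <- toy_locus()
  ref <- loc$seq
  span100 <- substr(ref, 1, 100)
  # one read skips reference bases 50-51 with a 2D run
  del_read <- paste0(substr(ref, 1, 49), substr(ref, 52, 102))
  clip_read <- paste0(substr(ref, 1, 80), strrep("G", 20))
  aln <- mk_aln(read_id = c(sprintf("n%02d", 1:9), "del", "clip"),
                ref_start = 1L,
                cigar = c(rep("100M", 9), "49M2D51M", "80M20S"),
                oriented_seq = c(rep(span100, 9), del_read, clip_read))
  pu <- pileup(aln, loc)
  expect_equal(pu$deletions$anchor, 49L)
  expect_equal(pu$deletions$seq, substr(ref, 50, 51))
  expect_equal(pu$deletions$count, 1L)
  expect_equal(pu$depth[50], 11L)  # M and D both cover the column
  expect_equal(pu$depth[85], 10L)  # the clipped tail adds nothing
  expect_equal(sum(pu$counts[, 85]), 10L)
})

test_that("coverage gate applies the per-position depth rule over the CDS", {
  loc <- toy_locus()
  full <- mk_aln(read_id = sprintf("f%02d", 1:12), ref_start = 1L,
                 cigar = sprintf("%dM", locus_length(loc)),
                 oriented_seq = loc$seq)
  pu <- pileup(full, loc)
  g <- coverage_gate(pu, loc, calling_params())
  expect_true(g$included)
  expect_equal(g$fraction_covered, 1)
  # drop coverage of one CDS position below 10: gate fraction 1.0 excludes
  part <- full
  part$cigar[1:3] <- sprintf("%dS%dM", loc$cds_start,
                             locus_length(loc) - loc$cds_start)
  part$ref_start[1:3] <- loc$cds_start + 1L
  pu2 <- pileup(part, loc)
  expect_equal(pu2$depth[loc$cds_start], 9L)
  g2 <- coverage_gate(pu2, loc, calling_params())
  expect_false(g2$included)
  # a relaxed gate fraction readmits the sample
  g3 <- coverage_gate(pu2, loc, calling_params(coverage_gate_fraction = 0.9))
  expect_true(g3$included)
})

test_that("per-sample calling enforces depth, count and fraction minima", {
  loc <- toy_locus()
  p <- loc$cds_start + 10L
  mut <- chars(loc$seq)
  alt <- setdiff(c("A", "C", "G", "T"), mut[p])[1]
  mut[p] <- alt
  mut_seq <- paste(mut, collapse = "")
  window <- function(s, n) substr(s, p - 20L, p + 20L)
  stack <- function(n_ref, n_alt) {
    mk_aln(read_id = sprintf("s%03d", seq_len(n_ref + n_alt)),
           ref_start = p - 20L, cigar = "41M",
           oriented_seq = c(rep(window(loc$seq), n_ref),
                            rep(window(mut_seq), n_alt)))
  }
  # depth 10, alt 2 (af 0.2): called
  v <- call_sample_variants(pileup(stack(8, 2), loc), loc, calling_params())
  expect_equal(nrow(v), 1L)
  expect_equal(v$pos, p)
  expect_equal(v$alt, alt)
  expect_equal(v$af, 0.2)
  # depth 9, alt 3: not called (coverage)
  v2 <- call_sample_variants(pileup(stack(6, 3), loc), loc, calling_params())
  expect_equal(nrow(v2), 0L)
  # alt 1 at depth 10: not called (count)
  v3 <- call_sample_variants(pileup(stack(9, 1), loc), loc, calling_params())
  expect_equal(nrow(v3), 0L)
  # af below min_alt_fraction: not called
  v4 <- call_sample_variants(pileup(stack(398, 2), loc), loc,
                             calling_params(min_alt_fraction = 0.01))
  expect_equal(nrow(v4), 0L)
})

test_that("indel observations are anchored and left-aligned", {
  # reference with a homopolymer so left-alignment has room to shift
  seqs <- paste0("ACGTT", "AAAAA", "CGATGACCTGACCTAAGTCTT")
  loc <- locus("hp", paste0(seqs, strrep("ACGTG", 20)), 11, 25)
  # delete two A's at the right edge of the homopolymer (positions 9-10)
  del_read <- paste0(substr(loc$seq, 1, 8), substr(loc$seq, 11, 40))
  aln <- mk_aln(read_id = sprintf("d%02d", 1:12), ref_start = 1L,
                cigar = "8M2D30M", oriented_seq = del_read)
  v <- call_sample_variants(pileup(aln, loc), loc, calling_params())
  expect_equal(v$type, "deletion")
  expect_equal(v$pos, 5L) # shifted left across the homopolymer
  expect_equal(v$ref, "TAA")
  expect_equal(v$alt, "T")
})

test_that("joint filtering applies the AF and prevalence rules", {
  obs_row <- function(af, depth = 100) {
    data.frame(pos = 50L, ref = "A", alt = "T", type = "snv",
               alt_count = as.integer(round(af * depth)), depth = depth,
               af = af, stringsAsFactors = FALSE)
  }
  none <- data.frame(pos = integer(0), ref = character(0), alt = character(0),
                     type = character(0), alt_count = integer(0),
                     depth = integer(0), af = numeric(0),
                     stringsAsFactors = FALSE)
  # af 0.04 everywhere: removed by the 0.05 rule
  vs <- joint_filter(list(a = obs_row(0.04), b = obs_row(0.04),
                          c = obs_row(0.04), d = obs_row(0.04)),
                     calling_params())
  expect_equal(nrow(vs$variants), 0L)
  # af 0.5 in exactly 2 samples: removed by the three-sample rule
  vs2 <- joint_filter(list(a = obs_row(0.5), b = obs_row(0.5), c = none,
                           d = none), calling_params())
  expect_equal(nrow(vs2$variants), 0L)
  # af 0.5 in 5 samples: retained with prevalence 5
  five <- setNames(rep(list(obs_row(0.5)), 5), letters[1:5])
  vs3 <- joint_filter(five, calling_params())
  expect_equal(nrow(vs3$variants), 1L)
  expect_equal(vs3$variants$prevalence, 5L)
  expect_equal(unname(vs3$af[1, ]), rep(0.5, 5))
  # sub-threshold observations ride along on retained variants
  mixed <- c(five, list(f = obs_row(0.02)))
  vs4 <- joint_filter(mixed, calling_params())
  expect_equal(vs4$af[1, "f"], 0.02)
  expect_equal(vs4$variants$prevalence, 5L)
})

test_that("joint filtering is monotone in its thresholds", {
  set.seed(31)
  obs <- lapply(1:6, function(i) {
    n <- sample(3:6, 1)
    data.frame(pos = sample(100, n), ref = "A", alt = "T", type = "snv",
               alt_count = 5L, depth = 50L,
               af = round(runif(n, 0.01, 0.9), 2), stringsAsFactors = FALSE)
  })
  names(obs) <- paste0("s", 1:6)
  strict <- joint_filter(obs, calling_params())
  key <- function(v) paste(v$variants$pos, v$variants$alt)
  loose_af <- joint_filter(obs, calling_params(report_min_af = 0.03,
                                               min_alt_fraction = 0.01))
  loose_n <- joint_filter(obs, calling_params(min_prevalence_samples = 2))
  expect_true(all(key(strict) %in% key(loose_af)))
  expect_true(all(key(strict) %in% key(loose_n)))
})

test_that("impact annotation follows the codon rules on curated cases", {
  # CDS codons (positions 6-26): ATG GAA TGG CAT CCT GGA TAA
  loc <- locus("imp", paste0("TTTTT", "ATGGAATGGCATCCTGGATAA", "CCCCC"),
               6, 26)
  imp <- function(pos, ref, alt) {
    annotate_impact(data.frame(pos = pos, ref = ref, alt = alt,
                               stringsAsFactors = FALSE), loc)$impact
  }
  expect_equal(imp(3L, "T", "A"), "MODIFIER")     # upstream
  expect_equal(imp(28L, "C", "G"), "MODIFIER")    # downstream
  expect_equal(imp(13L, "G", "A"), "HIGH")        # TGG -> TAG stop gain
  expect_equal(imp(11L, "A", "G"), "LOW")         # GAA -> GAG synonymous
  expect_equal(imp(10L, "A", "G"), "MODERATE")    # GAA -> GGA missense
  expect_equal(imp(9L, "G", "GTT"), "HIGH")       # 2-nt insertion frameshift
  expect_equal(imp(8L, "GGA", "G"), "HIGH")       # 2-nt deletion frameshift
  expect_equal(imp(7L, "T", "C"), "HIGH")         # start codon lost
  expect_equal(imp(24L, "T", "G"), "HIGH")        # TAA -> GAA stop lost
  expect_equal(imp(25L, "A", "G"), "LOW")         # TAA -> TGA stop kept
  expect_equal(imp(11L, "A", "AGGG"), "MODERATE") # in-frame codon insertion
  expect_equal(imp(11L, "ATGG", "A"), "MODERATE") # in-frame codon deletion
  expect_equal(imp(11L, "A", "ATAA"), "HIGH")     # in-frame stop insertion
  expect_equal(imp(3L, "TTTAT", "T"), "HIGH")     # deletion straddles CDS start
})

test_that("impact annotation agrees with the translate-and-compare oracle", {
  loc <- toy_locus()
  set.seed(17)
  n_cases <- 300
  ncds <- loc$cds_end - loc$cds_start + 1L
  mismatches <- 0
  for (i in seq_len(n_cases)) {
    kind <- sample(c("snv", "del", "ins"), 1)
    if (kind == "snv") {
      q <- sample(ncds, 1)
      p <- loc$cds_start + q - 1L
      ref <- substr(loc$seq, p, p)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      got <- annotate_impact(data.frame(pos = p, ref = ref, alt = alt),
                             loc)$impact
      want <- impact_oracle(loc, q, 1L, alt)
    } else if (kind == "del") {
      len <- sample(1:6, 1)
      q <- sample(ncds - len, 1) + 1L      # first deleted CDS base >= 2
      p <- loc$cds_start + q - 2L          # anchor
      ref <- substr(loc$seq, p, p + len)
      alt <- substr(loc$seq, p, p)
      got <- annotate_impact(data.frame(pos = p, ref = ref, alt = alt),
                             loc)$impact
      want <- impact_oracle(loc, q, len, "")
    } else {
      len <- sample(1:6, 1)
      ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = "")
      q <- sample(ncds - 1L, 1)            # anchor CDS position
      p <- loc$cds_start + q - 1L
      ref <- substr(loc$seq, p, p)
      got <- annotate_impact(data.frame(pos = p, ref = ref,
                                        alt = paste0(ref, ins)), loc)$impact
      want <- impact_oracle(loc, q + 1L, 0L, ins)
    }
    if (!identical(got, want)) mismatches <- mismatches + 1
  }
  expect_equal(mismatches, 0)
})

test_that("high-frequency flags use an inclusive 0.7 boundary", {
  vs <- list(variants = data.frame(pos = c(10L, 20L, 30L), ref = "A",
                                   alt = "T", type = "snv", prevalence = 3L,
                                   impact = c("HIGH", "HIGH", "MODERATE"),
                                   stringsAsFactors = FALSE),
             af = matrix(c(0.8, 0.69, 0.70), 3, 1,
                         dimnames = list(NULL, "s1")),
             depth = matrix(100L, 3, 1, dimnames = list(NULL, "s1")),
             alt_count = matrix(70L, 3, 1, dimnames = list(NULL, "s1")))
  class(vs) <- "pula_varset"
  fl <- high_frequency_flags(vs, calling_params())
  expect_setequal(fl$pos, c(10L, 30L)) # 0.8 and exactly 0.70; 0.69 is out
})

test_that("VCF round-trips the variant-by-sample matrices", {
  loc <- toy_locus()
  vs <- list(variants = data.frame(
    pos = c(155L, 200L), ref = c("CAG", "A"), alt = c("C", "T"),
    type = c("deletion", "snv"), prevalence = c(3L, 4L),
    impact = c("HIGH", "LOW"), stringsAsFactors = FALSE),
    af = matrix(c(0.9, 0.1, 0, 0.65), 2, 2,
                dimnames = list(NULL, c("s1", "s2"))),
    depth = matrix(c(50L, 60L, 45L, 70L), 2, 2,
                   dimnames = list(NULL, c("s1", "s2"))),
    alt_count = matrix(c(45L, 6L, 0L, 45L), 2, 2,
                       dimnames = list(NULL, c("s1", "s2"))))
  class(vs) <- "pula_varset"
  f <- tempfile(fileext = ".vcf")
  write_vcf(vs, loc, f)
  back <- read_vcf(f)
  expect_equal(back$variants$pos, vs$variants$pos)
  expect_equal(back$variants$ref, vs$variants$ref)
  expect_equal(back$variants$alt, vs$variants$alt)
  expect_equal(back$variants$impact, vs$variants$impact)
  expect_equal(back$af, vs$af)
  expect_equal(back$depth, vs$depth)
  expect_equal(back$alt_count, vs$alt_count)
  expect_error(read_vcf({
    g <- tempfile(); writeLines(c("##fileformat=VCFv4.2",
                                  "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
                                  "x\t1\t.\tA"), g); g
  }), "line 3")
})

test_that("error-free reads from the unedited locus call no variants", {
  loc <- toy_locus()
  reads <- tile_reads(loc$seq, 80, 3)
  aln <- align_reads(reads, loc)
  v <- call_sample_variants(pileup(aln, loc), loc, calling_params())
  expect_equal(nrow(v), 0L)
})
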