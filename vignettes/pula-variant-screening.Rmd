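---
title: "Screening metagenome reads for disruptive variants of a single gene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening metagenome reads for disruptive variants of a single gene}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The screen

`pulascreen` answers one question per metagenome sample: *does the dominant
strain in this sample carry a functional copy of the target gene?* The
motivating target is the *Lactobacillus crispatus* amylopullulanase gene
(*pulA*), whose product is anchored in the bacterial S-layer and initiates
glycogen degradation in the vaginal niche. Disruptions observed in natural
isolates fall into four archetypes: a 2-nt frameshift deletion in the
N-terminal signal-peptide region, stop-gain substitutions near the N
terminus, insertion of a transposase-family mobile element, and large
deletions. The screen detects all four from shotgun reads mapped to the one
gene of interest.

The pipeline is: align reads to the locus → coverage gate → per-sample
pooled variant observation → cross-sample filtering + impact annotation →
soft-clip breakpoint/SV scan with transposase classification → per-sample
classification → cohort summary.

## Model and decision rules

**Pooled-continuous allele frequencies.** A metagenome sample is a strain
pool, not a diploid individual, so no genotype-likelihood machinery is used.
The allele frequency of an event is simply the fraction of informative reads
supporting it: `alt_count / depth` at a pileup column for small variants,
`clipped / (clipped + cleanly spanning)` reads at a breakpoint for
structural variants (averaged over both breakpoints for deletions). All
downstream decisions are threshold rules on these frequencies.

**Per-sample observation thresholds** (`calling_params()`): depth ≥ 10,
alternate reads ≥ 2, alternate fraction ≥ 0.01. These minima suppress
sequencing-error singletons while keeping genuine minor strains visible.

**Cross-sample filter**: a variant is reported only when it reaches AF ≥
0.05 in at least 3 samples. Error-driven observations are essentially never
replicated at 5% in three samples, so this step does the heavy lifting of
false-positive control; sub-threshold AFs of retained variants are still
reported for inspection. Multi-allelic sites are decomposed one record per
alternate allele before filtering, and indels are left-normalized (anchored,
shifted across homopolymers) so identical planted events unify across
samples under the key (pos, ref, alt).

**Impact classes.** Inside the CDS: frameshift indels, stop gains, start
loss and stop loss are HIGH; amino-acid changes and in-frame indels are
MODERATE (an in-frame indel whose recoded codons introduce a premature stop
is HIGH); synonymous changes are LOW; everything outside the CDS is
MODIFIER. Variants straddling a CDS boundary are classified HIGH — a
deliberate conservative choice for events that remove the gene's start or
end. The implementation recodes only the affected codon window; the test
suite checks it against an independent oracle that rebuilds and translates
the whole CDS.

**Disruption rule.** A sample is `disrupted` when a HIGH-impact small
variant or a structural variant is present at frequency ≥ 0.7. The
threshold is applied inclusively (exactly 0.7 fires): of the two published
phrasings (">0.7" in the results narrative, "a minimum frequency of 0.7" in
the methods), the methods phrasing defines the classifier. The 0.7 cutoff
encodes the dominant-strain assumption: at lower frequencies the intact
strain may still dominate glycogen metabolism. Transposase read counts
alone never disrupt a sample — the evidence must localize to a supported
insertion breakpoint.

**Coverage gate.** Variant ascertainment is only attempted in samples whose
CDS is adequately covered; the gate requires a configurable fraction
(default 100%) of CDS positions at depth ≥ 10, and gated-out samples are
excluded from the prevalence denominator. The shipped cohort preset relaxes
the fraction to 0.8: a sample fixed for a large deletion has, by
construction, no coverage over the deleted interval (13% of the CDS for the
600 bp preset deletion), and a literal 100% gate would discard exactly the
samples the SV branch exists to find. This mirrors the fact that
deletion-bearing samples do pass coverage screening in practice.

**Percent display** rounds half away from zero (62/270 → 23%, 12/102 →
12%). For 19/55 this gives 35% where 34% has also been printed elsewhere
(plain truncation); the choice is documented here and applied consistently.

## The aligner

Mapping to a single 4.8 kb target does not need a general-purpose read
mapper, but it does need honest local-alignment semantics: reads crossing an
insertion or deletion junction must soft-clip rather than force-fit.
`align_reads()` is a seed-and-extend aligner: exact 15-mer seeds (both
strands) are grouped by diagonal within a 32 bp band, each group is extended
by affine-gap Smith–Waterman (+2 match, −3 mismatch, −5 gap open, −2 gap
extend; a length-L gap costs −5 − 2(L−1)) over a padded window, and the best
local alignment wins with deterministic tie-breaks (lowest reference start,
then forward strand). When seeding is inconclusive the aligner falls back to
exhaustive Smith–Waterman over the whole locus, so the reported score is the
scoring scheme's optimum — this is what makes the brute-force oracle test
exact rather than approximate. Alignments below score 40 are unmapped
(score 40 ≈ 20 perfectly matching bases). Soft clips shorter than 10 bp are
retained in the CIGAR but never feed SV evidence; clips of ≥ 10 bp are the
breakpoint currency. The hot loops live in `src/core.cpp` (Rcpp), as is
usual for alignment code in this ecosystem.

## Structural variants and transposase evidence

Clip positions on the same side within 5 bp merge into a breakpoint cluster
(position = modal clip point); clusters need ≥ 10 clipped reads. Typing is
by re-mapping clipped tails: a right-clip cluster whose tails re-map to the
locus downstream pairs with the corresponding left-clip cluster into a
*deletion* spanning the gap; adjacent right/left clusters whose tails do
not re-map locally become an *insertion*. Unpaired clusters are reported
`unresolved` — inversions, translocations and duplications are deliberately
never guessed at. For transposase evidence, clipped tails and unmapped
reads are aligned (same aligner, same scoring) against the representatives
of a transposase database built by greedy incremental clustering at 95%
identity — sequences sorted by length, each joining the first
representative whose identity (matching columns / alignment columns, on a
fit alignment of the shorter onto the longer) meets the threshold. A
sample's evidence flag fires when strictly more than 20 reads match the
database; the flag annotates supported insertion SVs and never disrupts a
sample on its own.

## The synthetic cohort

`make_locus()` emulates the study conditions at desk scale: a 4842 bp locus
(1500 codons + 171 bp flanks) with an ATG start, a single terminal stop, no
internal in-frame stops, a cre-like palindrome (`TGTTATCGATAACA`) planted in
the upstream flank, and tryptophan codons fixed at codons 52/69/75 so that
single G→A substitutions at CDS positions 156/207/225 create the recurrent
stop-gain archetypes. The exact in-gene position of the archetypal 2-nt
signal-peptide deletion is not published; the preset places it at CDS
position 156 — the first of the recurrent high-impact positions — and
treats that as an assumption, declaring a generous 60-codon signal-peptide
feature that covers all three positions.

`simulate_reads()` draws a Poisson read count at the target depth, assigns
each read a haplotype from the mixture, places single-end 150 bp reads
uniformly, and applies a substitution-only error model (default 0.001/base,
uniform among the three alternatives). Deliberately not modelled: indel
sequencing errors, quality-score structure, PCR duplicates, GC bias, paired
ends, and off-target (non-*L. crispatus*) reads. Passing tests on this
generator therefore demonstrate the logic of the screen — recovery of
planted events at their planted frequencies — not robustness to every
artefact of real sequencing; the per-sample thresholds adopted from the
real-data protocol are what carry that burden in practice. Read starts are
uniform over full-read positions, so coverage ramps down over the first and
last read-length of the locus; the 171 bp flanks exceed the 150 bp read
length precisely so the CDS sees no edge ramp and the coverage gate is
evaluated fairly.

The 12-sample preset (`cohort_preset()`): 2 intact, 3 × 2-nt deletion, 3 ×
triple stop-gain, 2 × transposase insertion (two different element
families), 2 × 600 bp deletion, all at allele frequency 1.0 and depth 50×.
Every small variant is thereby carried by ≥ 3 samples — the design must
respect the pipeline's own three-sample prevalence rule, just as the
recurrent variants in real cohorts do (structural variants are per-sample
calls and need no prevalence). `make_transposase_set()` gives each family
copy exactly `round(0.02 × length)` substitutions from its family ancestor,
so pairwise within-family identity is bounded below by 0.96 and the 95%
clustering threshold is cleared deterministically rather than
probabilistically.

## Numerical and design notes

- **Determinism.** Every stochastic step takes an explicit seed and restores
  the caller's RNG state; identical configs give byte-identical FASTQ, SAM,
  VCF and summary files. Ties everywhere break by fixed rules (position,
  then lexicographic).
- **Problem sizes.** The shipped validation runs at desk scale: 12 samples
  × ~1600 reads at depth 50 for the end-to-end checks, depth 200 for
  allele-frequency recovery (±0.05 at the binomial noise floor of ~0.035
  SD), 500 random instances for the aligner oracle, 1000 random coding
  edits for the impact oracle.
- **ND handling in the proteomics module.** "Not detected" is a distinct
  state, never imputed: ratios with an ND or zero input are ND, ND sorts
  last, and group sums simply omit ND rows. The shipped S-layer reference
  table reproduces its published log2 ratios from the printed quantities to
  within 0.1 for all but two cells, which are internally inconsistent in
  the source table itself (the published ratios were computed from a
  different label-free quantification series than the printed quantities);
  the two cells are pinned as known discrepancies in the test suite, and
  the headline amylopullulanase ratios reproduce at one decimal. The
  published whole-proteome totals behind the "fraction of total" row are
  not recoverable from the table, so `fraction_of_group()` takes the totals
  as an argument.
- **Known limitations.** Single-locus targets only (no multi-contig
  references, no mapping-quality model); breakpoint precision is the 5 bp
  cluster window; insertion SV content is not assembled — only classified
  against the element database; samples with several co-dominant variant
  strains are reported variant-by-variant rather than phased into strains.
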