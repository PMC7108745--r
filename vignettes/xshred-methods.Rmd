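---
title: "Methods: X-linked repeat target discovery and editing-outcome quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: X-linked repeat target discovery and editing-outcome quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xshred)
```

# Scope and model

Synthetic sex distorters bias the progeny of XY species toward males by
directing an endonuclease (here CRISPR/Cas9) against the X chromosome in
the male germline. Two mechanisms are distinguished:

* **X-shredding** — cleavage of X-linked multicopy repeats during
  spermatogenesis, acting pre-zygotically on X-bearing gametes;
* **X-poisoning** — cleavage of X-linked haplolethal genes (typically
  ribosomal protein genes), acting post-zygotically through female
  lethality.

`xshred` implements the computational workflow around both mechanisms:
discovery of X-linked repeat gRNA targets from raw sexed sequencing data,
screening of those targets, quantification of editing outcomes from
amplicon deep sequencing of the targeted repeat cluster (or coding
locus), and the genetics summary statistics of the resulting crosses. A
seeded synthetic-data generator reproduces the statistical structure of
every input, so the full pipeline is testable offline, with truth tables
for parameter-recovery checks.

# The synthetic-data generator

## Genome model

`genome_spec()`/`build_genome()` create a toy genome with an X, one or
more autosomes, a Y and a mitochondrion. Females are diploid
(2 X + 2 autosomes + mitochondria); males are hemizygous
(1 X + 1 Y + 2 autosomes + mitochondria). This copy-number asymmetry is
the entire signal exploited by sex-linkage inference.

The default scale is 500 kb X, 300 kb autosome, 500 kb Y, 16 kb
mitochondrion (tests use a 60/40/60/16 kb version). Two sizing choices
matter:

* The **Y is sized like the X**. Sequenced male and female genome sizes
  are then equal, so after per-library normalization the chromosome
  quotient (below) centres at 2 for X-linked, 1 for autosomal and 0 for
  Y-linked sequence. This mirrors *Drosophila melanogaster*, whose
  heterochromatic Y rivals the X in size. With a strongly asymmetric
  karyotype the CQ of every class shifts by the constant factor
  (male genome)/(female genome); the windows are configurable for such
  cases.
* The whole genome is small enough that a 30× sexed read simulation,
  census and binning run in seconds on one CPU. The methods scale to
  real genomes (streaming C-level k-mer census), but the test suite
  deliberately runs at toy scale; the vignette's numbers are properties
  of the generator's statistical structure, not of any real dataset.

A **repeat cluster** (`repeat_cluster()`) is a tandem array of
`n_units` (default 12) units of `unit_length` bp (default 271, which is
therefore also the spacing between successive target sites). Each unit
carries one copy of a consensus 23-nt Cas9 target (20-nt protospacer +
NGG PAM). Per-unit substitutions (rate 0.02/bp) are applied **outside**
a conserved core (the target window ± 15 bp, `conserved_flank`):

* flank heterogeneity mirrors real repeat arrays, where units are
  "slightly different" outside the target and an unedited cluster still
  shows ~90% intact target reads;
* the conserved core makes the target-bearing 25-mers literally shared
  across units — without it no k-mer would be abundant and
  abundance-based target selection would be meaningless.

One unit may be designated **cleavage-resistant**: it differs from the
consensus at protospacer position 5 and at the PAM's central G (so the
PAM is no longer NGG), and — mimicking a naturally pre-existing resistant
repeat variant — carries a linked 6-bp deletion marker 53 bp upstream of
the target window. The resistant unit is never cleaved.

A **coding locus** (`target_locus()`) embeds a toy single-copy gene
(random stop-free codons, one NGG target site) with a defined reading
frame, for the coding-effect branch of the allele pipeline.

## Read simulators

`simulate_short_reads()` draws reads from chromosomes in proportion to
length × copy number for the requested sex. `depth` is the expected
coverage of a two-copy locus, so X-linked positions are covered at
`depth` in females and `depth/2` in males. Errors are uniform
substitutions; qualities are a constant Q38 — the simplest model that
still exercises the Q30 mean-quality filter. The generator does **not**
model real-data features such as GC bias, quality decay along the read,
indel sequencing errors, adapter contamination or coverage waviness;
passing tests demonstrate correctness of the inference logic under the
stated statistical model, not robustness to every artefact of real
libraries.

`simulate_long_reads()` emulates an error-corrected long-read set:
chromosomes sampled proportional to length, lengths uniform between
configurable bounds (default 2–100 kb, truncated at the chromosome
length), low substitution error (0.2%).

## Editing model

`editing_model()` describes Cas9 activity on a cluster as sequential
cut-repair cycles. Per cycle, each unit with an intact target is cleaved
independently with probability `cleave_prob`; a cut is repaired either
imperfectly (probability `disrupt_prob`; an indel drawn from a size
spectrum is placed at the cut site, 3 bp 5′ of the PAM) or faithfully
(the unit returns to the cleavable pool). Optionally, adjacent cuts in
the same cycle collapse the units between them
(`intercut_deletion_prob`), with unit granularity: whole intervening
still-intact units are removed, so the truth bookkeeping stays exact
(`surviving = initial − deleted`, and no unit is ever both mutated and
deleted). The designated resistant unit is never cut and never deleted.

With no inter-cut deletions the closed form
`P(intact after c cycles) = (1 − cleave_prob × disrupt_prob)^c`
holds per cleavable unit, and the event log suffices to recompute it;
tests verify the Monte-Carlo agreement over ≥ 1000 units.

The two regimes contrasted in the study are encoded by
`regime_model()`:

* **meiotic** (Cas9 confined to meiosis): 1 cycle, cleavage 0.5,
  disrupting repair 0.9 → expected intact fraction 0.55, i.e. ~45%
  loss of cleavable target sites;
* **pre-meiotic** (Cas9 active from the stem-cell stages): 6 cycles,
  cleavage 0.3 per cycle, disrupting repair 0.95 → expected intact
  fraction 0.715⁶ ≈ 0.13, i.e. ~87% loss.

These choices reproduce the observed contrast — a moderate (> 40%)
reduction of cleavable sites under meiotic editing versus a much larger
(> 85%) reduction when repeats undergo repeated cleavage-repair rounds —
with 10 males per regime and one unedited control. The per-male variance
is dominated by the 11 cleavable units per haplotype (binomial, not
sequencing noise), so the mean reduction over 10 males carries a
standard error of ~3 percentage points in the pre-meiotic regime.

## Amplicon sequencing

`simulate_amplicon_reads()` emulates a proportion-preserving
(non-saturating) PCR over the cluster followed by deep sequencing: each
read is one surviving unit's amplicon (deleted units yield no reads),
unit choice is multinomial with equal weight per surviving copy,
substitution errors at the configured rate, constant Q38 qualities. PCR
bias, chimeras and UMI structure are out of scope. The default depth of
5,000 reads per male is a free choice at the scale of typical pooled
amplicon runs; allele-frequency standard errors at that depth
(≤ 0.7 percentage points) are negligible against the unit-level
variance.

# K-mer census and X-linkage

`kmer_census()` counts every 25-mer window of the male and female
libraries (C-level rolling 2-bit encoding; windows containing non-ACGT
characters are skipped). Counting is canonical by default — a k-mer and
its reverse complement share a record keyed by the lexicographically
smaller — because sequencing is unstranded; a stranded mode is exposed
as a flag. Counts are normalized per million sequenced bases per sex, a
stated normalization that makes libraries of unequal depth comparable.
Mitochondrial signal is removed by exact k-mer membership against the
mitochondrial reference (`filter_mitochondrial()`), and k-mers with a
combined male+female count below 4 are excluded (`apply_min_count()`).

The **chromosome quotient** (`compute_cq()`) is the ratio of normalized
female to normalized male evidence: ≈2 for X-linked, ≈1 for autosomal,
≈0 for Y-linked sequence. Division-by-zero contracts are explicit: zero
male evidence with nonzero female evidence caps the CQ at a configurable
value (default 10) with a flag — keeping downstream sorting total without
fabricating infinity — and zero evidence on both sides is an `NA`
sentinel, never a silent 0.

Long reads are filtered to an inclusive 2–100 kb window (the bounds are
documented as inclusive and configurable, since "between" is ambiguous)
and binned (`bin_long_reads()`) by the CQ of their summed constituent
k-mer counts — the sum, not the mean, so abundant repeats weigh as the
evidence they are. Default windows: X [1.5, 2.5], autosomal [0.7, 1.4],
Y ≤ 0.1; these are declared working defaults, not values inherited from
any publication, and they must be disjoint so binning is a partition.
Reads matching the mitochondrial reference (> 50% of windows in the
mitochondrial k-mer set) are binned mitochondrial regardless of CQ;
reads with no countable k-mers are ambiguous.

A k-mer is a **candidate X-kmer** (`call_x_kmers()`) iff its own CQ lies
in the X window and ≥ 99% of its exact long-read occurrences fall on
X-binned reads. Note the statistic is only meaningful for abundant
k-mers: a single-copy k-mer's CQ at 30× is a ratio of two small Poisson
counts (sd ≈ 0.7) and is expected to leave any reasonable window — the
recovery tests therefore score the abundant (≥ 8-copy) cluster k-mers,
which is also what the method is for.

# Target selection

`scan_pam_sites()` enumerates every [20-nt spacer][NGG] placement on
both strands of a candidate k-mer (a 25-mer has at most 3 per strand).
Off-target potential (`count_offtargets()`) is counted against exactly
the autosomal- and Y-binned long reads: occurrences of the spacer with
up to 4 mismatches (common Cas9 screening practice; configurable) where
the PAM remains NGG. Abundance metrics per k-mer
(`compute_abundance_metrics()`):

* `max_hits_per_long_read` — maximum exact occurrences in any single
  long read, estimating the local repeat array size;
* `n_long_reads_with_hit` — number of long reads containing the k-mer,
  estimating repeat abundance across the chromosome;
* log10-scaled coverages: log10 of the raw combined male+female
  short-read count, and log10 of the long-read count.

The shortlist filter (`apply_selection_filters()`) requires, with
defaults: log10 Illumina coverage > 2 (i.e. > 100 combined occurrences),
log10 long-read coverage > 1 (> 10 reads), maximum hits per long read
strictly > 7.5 (the non-integer cutoff applied to the raw per-read
maximum, unnormalized), ≥ 5 perfect assembly hits when an assembly is
available (otherwise the criterion is explicitly marked not-evaluated
rather than silently passed or failed), and 0 off-target hits. The
"coverage > log10(2)" phrasing is interpreted as a cutoff on the
log-scaled coverage axis (coverage > 10²); the literal reading
(coverage > 0.3) would exclude nothing. All cutoffs are configurable,
and tightening any threshold can only shrink the passing set (tested).

`assemble_contigs()` re-assembles candidate k-mers into longer contigs
by greedy longest-overlap merging with zero mismatches (minimum overlap
10), revealing higher-order repeat structure. Ties are broken toward the
lexicographically smaller merged sequence, making assembly deterministic;
a contained k-mer is absorbed; every input k-mer ends in exactly one
contig.

# Amplicon allele quantification

Reads are first filtered on mean base quality (Phred+33, inclusive
threshold 30 — a uniform Q30 read passes). Each read is globally aligned
to the reference amplicon (affine gaps, match 2 / mismatch −3 / gap open
5 / extend 2) and its **allele** is the aligned slice over the 23-nt
target window: deletions appear as `-` at deleted reference positions,
insertions are recorded against the reference position they follow and
**left-aligned** (an insertion is rotated leftward while the preceding
reference base equals its last base), so equivalent indels collapse to
one allele key regardless of the aligner's gap placement. Identical
reads are aligned once. Reads whose alignment identity outside the
window falls below 0.75 are unalignable and excluded from every
denominator — the intact-site fraction is reported over alignable reads,
the one defensible denominator when some reads cannot be attributed to
the amplicon at all.

* `intact_fraction()` — share of alignable reads whose window matches
  the reference protospacer + PAM exactly.
* `census_alleles()` — unique alleles at ≥ 1% frequency and with ≥ 10
  reads, reported both including and excluding the wild-type allele.
* `classify_alleles()` — an allele present in **every** control sample
  (above a noise floor of ≥ 2 reads and ≥ 0.1% of sample reads,
  separating sequencing error from real low-frequency alleles at the
  default error rate) is a pre-existing variant; absent from all
  controls but present in experimental samples, de-novo; the reference
  window, intact. An allele seen in some but not all controls has no
  class in this scheme and is labelled `ambiguous` — with a single
  control the pre-existing/de-novo split reduces to presence in that
  control.
* `flag_resistant()` — a window allele is predicted cleavage-resistant
  when its PAM is no longer NGG, when it carries a substitution in the
  PAM-proximal 10-nt seed region (configurable; standard Cas9 seed
  biology), or when it carries any indel. A substitution confined to the
  PAM-distal spacer with an intact PAM is tolerated.
* `allele_frequency_summary()` — per-sample frequencies with the median
  over experimental samples (controls reported separately).
* `linked_marker_dissociation()` — on a haplotype where the resistant
  allele is linked to an upstream marker, gene-conversion repair using
  the resistant repeat as template produces reads carrying the resistant
  window without the marker. The per-read marker call compares the
  *reconstructed* sequence over a ±10 bp context around the marker, so
  it is invariant to where the aligner places an ambiguous indel. The
  verdict is an exact binomial tail probability of the observed
  dissociated reads against the configured sequencing-error expectation.
* `classify_coding_effect()` — with a reading frame defined: net indel
  length ≢ 0 (mod 3) → frameshift; balanced indel → in-frame indel;
  substitutions are translated (standard code) and reported as
  synonymous or missense with predicted amino-acid changes.

# Cross statistics

`male_fraction()` computes per-cross male fractions with exact
Clopper–Pearson 95% intervals (brood sizes are small, so exact intervals
are preferred to the normal approximation). `welch_t_test()` is the
two-sided unequal-variance t-test with Satterthwaite degrees of freedom,
applied to per-replicate fractions — the replicate unit is the
single-male cross; a pooled cross contributes one observation, never
inflated to per-fly observations. Whether the original analyses used
fractions or counts per replicate is not recorded; fractions are used
here and stated. Degenerate inputs have explicit contracts: two constant
groups with equal means give t = 0, p = 1. `survival_rates()` converts
stage counts (embryos, hatched, pupae, adults by sex) into stage-wise
survival rates with invariant checks and `NA` sentinels for empty
denominators; `cross_summary()` aggregates replicates per genotype, the
pooled fraction equalling the count-weighted mean of replicate fractions.

# Numerical and design notes

* All generators are deterministic functions of their seed
  (`withr::with_seed`, so the caller's RNG state is untouched).
* k is limited to 31 so a k-mer fits one 64-bit word; the census uses
  `double` counts (exact to 2⁵³).
* `run_editing_regime()` derives per-male seeds as
  `(seed − 1) × 1000 + i`, so base seed 1 edits males with seeds 1–10;
  the control and the genome use fixed offsets in the same block.
* Problem sizes in the test suite: 30× short reads over a 176 kb toy
  genome, 350 long reads, amplicon depths of 800–2,000 (10 males per
  regime); the acceptance script uses the full 5,000 reads per male.
  These sizes keep a complete run in minutes on one CPU while leaving
  every statistical check at ≥ 3-SE resolution.

# Known limitations

* The CQ windows and the X-hit fraction cutoff are working defaults;
  they are not calibrated against any published pipeline's internals.
* The greedy zero-mismatch assembler is a deterministic reimplementation
  of the *idea* of strict-overlap reassembly, not of any particular
  assembler's algorithm.
* Allele extraction assumes single-end (or pre-merged), full-length
  amplicon reads; paired-end merging and UMI handling are out of scope.
* The amplicon reference is the cluster consensus; strongly diverged
  units would need per-unit references.
* Off-target screening counts mismatched occurrences; it does not score
  cleavage efficiency (no CFD/MIT-style scoring).
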