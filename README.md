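# xshred

Design and evaluation of synthetic CRISPR/Cas9 sex distorters in XY
species: bioinformatic discovery of X-linked repeat gRNA targets from raw
sexed sequencing reads, and quantification of editing outcomes and
genetic-cross phenotypes.

## Who this is for

Researchers developing genetic-control strategies that bias progeny
toward males — **X-shredding** (cleaving X-linked multicopy repeats
during spermatogenesis, a pre-zygotic effect on X-bearing gametes) and
**X-poisoning** (cleaving X-linked haplolethal genes, a post-zygotic
effect through female lethality). The package reimplements the
computational workflow around these experiments as a tested, reusable R
pipeline, with a seeded synthetic-data generator standing in for raw
data so everything runs offline.

## The statistics at the core

* **Chromosome quotient (CQ).** For a k-mer (k = 25) or long read with
  normalized female evidence $f$ and male evidence $m$,
  $CQ = f/m \approx 2$ for X-linked sequence (two female copies vs one
  hemizygous male copy), $\approx 1$ autosomal, $\approx 0$ Y-linked.
  Long reads are binned X/autosomal/Y by the CQ of their summed k-mer
  counts; a k-mer is a candidate X-kmer iff its own CQ lies in the X
  window and ≥ 99% of its long-read hits fall on X-binned reads.
* **Target shortlisting.** PAM (NGG) placements on both strands;
  off-target occurrences (≤ 4 spacer mismatches, PAM intact) against the
  autosomal/Y long-read bins; abundance cutoffs — log₁₀ combined
  short-read coverage > 2, log₁₀ long-read coverage > 1, max k-mer hits
  per long read > 7.5, ≥ 5 perfect assembly hits; greedy zero-mismatch
  contig reassembly.
* **Editing outcomes from amplicon deep sequencing.** Reads are
  quality-filtered (mean Q ≥ 30), globally aligned to the reference
  amplicon, and the aligned slice over the 23-nt protospacer+PAM window
  is the allele (indels left-aligned). Reported: intact-target fraction,
  unique-allele censuses (≥ 1% frequency / ≥ 10 reads), pre-existing vs
  de-novo classification against control samples, cleavage-resistance
  calls (PAM loss, seed substitutions, indels), linked-marker
  dissociation (evidence of gene-conversion repair) and coding effects
  (frameshift / in-frame / missense) for coding targets.
* **Cross statistics.** Per-cross male fractions with exact
  Clopper–Pearson intervals, Welch's unequal-variance t-test on replicate
  fractions, stage-wise developmental survival rates.

## Worked example

Simulate a genome with an X-linked 12-unit repeat cluster, sexed reads
at 30×, and run target discovery:

```r
library(xshred)

g <- build_genome(genome_spec(
  x_length = 6e4, autosome_lengths = 4e4, y_length = 6e4, mito_length = 16e3,
  clusters = list(repeat_cluster(chrom = "X", start = 10000, resistant_unit = 3)),
  seed = 41))
rs  <- read_sim_spec(depth = 30, n_long_reads = 350,
                     long_read_min = 2000, long_read_max = 8000, seed = 14)
cen <- kmer_census(simulate_short_reads(g, "male", rs),
                   simulate_short_reads(g, "female", rs))
cen <- apply_min_count(filter_mitochondrial(cen, g$seqs["MT"])$kept)
kept <- filter_long_reads(simulate_long_reads(g, rs))$kept
bins <- bin_long_reads(kept, cen, mito = g$seqs["MT"])
table(bins$bin)
#>     autosomal mitochondrial             X             Y
#>            91            29           109           121
```

Every retained long read lands in the bin of its source chromosome: the
CQ separates one-copy (Y, CQ ≈ 0), two-copy-in-both-sexes (autosome,
CQ ≈ 1) and two-vs-one-copy (X, CQ ≈ 2) sequence.

Quantify editing outcomes under the meiotic regime (one cut-repair
cycle, cleavage 0.5, disrupting repair 0.9), 10 males at 2,000 amplicon
reads each against an unedited control:

```r
res <- run_editing_regime(regime_model("meiotic"), n_males = 10,
                          depth = 2000, error_rate = 0.001, seed = 1)
round(res$control_intact, 3)
#> [1] 0.892
round(res$mean_reduction_pct, 1)
#> [1] 43.8
```

The control male keeps ~89% of reads with the complete unaltered target
site (the remainder is the cluster's pre-existing resistant repeat plus
sequencing error), and one meiotic cycle removes ~44% of cleavable
sites — matching the closed form
`1 − cleave_prob × disrupt_prob = 0.55` intact. The six-cycle
pre-meiotic regime (`regime_model("premeiotic")`) removes > 85%.

## Layout

| Path | Contents |
|---|---|
| `R/genome-sim.R`, `R/read-sim.R`, `R/editing-sim.R` | synthetic genomes, sexed/long reads, cut-repair editing, amplicons |
| `R/kmer-census.R`, `R/xlinkage.R` | k-mer census, mitochondrial/abundance filters, CQ, long-read binning, candidate X-kmers |
| `R/targets.R` | PAM scan, off-targets, abundance metrics, selection filters, contig assembly |
| `R/alleles.R`, `R/amplicon-spec.R` | amplicon allele extraction and all editing-outcome statistics |
| `R/cross-stats.R` | sex-ratio and survival statistics |
| `src/kmers.cpp` | 2-bit k-mer census / exact-match index / Hamming off-target scan |
| `vignettes/xshred-methods.Rmd` | the model, parameter choices and limitations |
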