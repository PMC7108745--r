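# Shared small-scale fixtures, built in code at test time.

# Toy genome small enough for 30x short-read simulation in seconds:
# X 60 kb with one 12-unit cluster, one 40 kb autosome, 60 kb Y (sized like
# the X so the sexes have equal sequenced genome sizes), 16 kb mito.
small_genome <- function(seed = 7, resistant_unit = 3L, decoy = FALSE) {
  clusters <- list(repeat_cluster(chrom = "X", start = 10000L,
                                  resistant_unit = resistant_unit))
  if (decoy) {
    clusters <- c(clusters, list(repeat_cluster(chrom = "A1", start = 5000L,
                                                n_units = 12L,
                                                resistant_unit = NA)))
  }
  build_genome(genome_spec(x_length = 60000, autosome_lengths = 40000,
                           y_length = 60000, mito_length = 16000,
                           clusters = clusters,
                           loci = list(target_locus(chrom = "X",
                                                    start = 40000L)),
                           seed = seed))
}

# Full sexed-read + census + long-read-binning dataset at 30x, built once
# per test run and shared by the X-linkage and acceptance suites.
xlink_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    g <- small_genome(seed = 41)
    spec <- read_sim_spec(depth = 30, error_rate = 0.001, n_long_reads = 350,
                          long_read_min = 2000, long_read_max = 8000,
                          long_error_rate = 0.002, seed = 14)
    males <- simulate_short_reads(g, "male", spec)
    females <- simulate_short_reads(g, "female", spec)
    cen <- kmer_census(males, females, k = 25)
    cen <- filter_mitochondrial(cen, g$seqs["MT"])$kept
    cen <- apply_min_count(cen, census_thresholds(4))
    long <- simulate_long_reads(g, spec)
    kept <- filter_long_reads(long)
    bins <- bin_long_reads(kept$kept, cen, mito = g$seqs["MT"])
    cache <<- list(genome = g, census = cen, long = long, kept = kept,
                   bins = bins)
    cache
  }
})

# Error-free constant-quality reads from given sequences.
plain_reads <- function(seqs, q = 38L) {
  ids <- sprintf("r%04d", seq_along(seqs))
  structure(list(reads = setNames(seqs, ids),
                 quals = setNames(xshred:::constant_quality(nchar(seqs), q), ids)),
            class = "sim_reads")
}
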