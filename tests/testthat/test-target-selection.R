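test_that("PAM scanning reports constructed placements and none when absent", {
  # 25-mer with TGG at positions 21-23: spacer = positions 1-20
  k <- paste0("ACGTACGTACGTACGTACGA", "TGG", "CA")
  sites <- scan_pam_sites(k)
  fwd <- sites[sites$strand == "+" & sites$offset == 1, ]
  expect_equal(fwd$spacer, "ACGTACGTACGTACGTACGA")
  expect_equal(fwd$pam, "TGG")
  # no GG (or CC) dinucleotide on either strand -> no sites
  expect_equal(nrow(scan_pam_sites(strrep("AT", 13))), 0)
})

test_that("PAM scan equals the exhaustive both-strand oracle on random 25-mers", {
  set.seed(55)
  kmers <- vapply(1:200, function(i) random_seq(25), "")
  got <- scan_pam_sites(kmers)
  for (km in kmers) {
    g <- got[got$kmer == km, ]
    f <- oracle_pam_scan_strand(km)
    r <- oracle_pam_scan_strand(oracle_revcomp(km))
    expect_equal(nrow(g[g$strand == "+", ]), if (is.null(f)) 0 else nrow(f))
    expect_equal(nrow(g[g$strand == "-", ]), if (is.null(r)) 0 else nrow(r))
    if (!is.null(f)) {
      expect_equal(g$spacer[g$strand == "+"], f$spacer)
      expect_equal(g$offset[g$strand == "+"], f$offset)
    }
  }
  # a 25-mer yields at most 3 placements per strand
  per <- table(got$kmer, got$strand)
  expect_true(all(per <= 3))
})

test_that("PAM scanning commutes with reverse complementation", {
  set.seed(56)
  kmers <- vapply(1:50, function(i) random_seq(25), "")
  a <- scan_pam_sites(kmers)
  b <- scan_pam_sites(oracle_revcomp(kmers))
  swap <- c("+" = "-", "-" = "+")
  expect_equal(sort(paste(a$spacer, a$pam, swap[a$strand])),
               sort(paste(b$spacer, b$pam, b$strand)))
})

test_that("off-target counting matches a Hamming-scan oracle", {
  set.seed(57)
  refs <- vapply(1:6, function(i) random_seq(400), "")
  spacer <- substr(refs[1], 50, 69)
  # plant the exact protospacer+PAM in a reference read
  refs[3] <- paste0(substr(refs[3], 1, 100), spacer, "TGG",
                    substr(refs[3], 104, 400))
  for (mm in c(0, 2, 4)) {
    expect_equal(count_offtargets(spacer, refs, mm),
                 oracle_offtargets(refs, spacer, mm))
  }
  expect_gte(count_offtargets(spacer, refs[3], 0), 1)
  # a spacer far from everything scores 0 at low tolerance
  expect_equal(count_offtargets(strrep("AC", 10), "TTTTGGTTTTGGTTTTTTTTTTTTTTT",
                                0), 0)
  expect_warning(z <- count_offtargets(spacer, character(), 4), "empty")
  expect_equal(z, 0L)
})

test_that("abundance metrics equal brute-force per-read occurrence counts", {
  g <- small_genome(seed = 61, resistant_unit = NA)
  kmer <- substr(g$units$unit_seq[1], 60, 84)  # 25-mer spanning the target
  long <- list(
    spanning = substr(g$seqs[["X"]], min(g$units$start) - 50,
                      max(g$units$end) + 50),
    off = substr(g$seqs[["A1"]], 1000, 5000))
  cen <- kmer_census(g$seqs[["X"]], g$seqs[["X"]], k = 25)
  met <- compute_abundance_metrics(c(kmer, strrep("A", 25)),
                                   unlist(long), cen)
  expect_equal(met$max_hits_per_long_read[1],
               max(oracle_kmer_hits(kmer, unlist(long))))
  expect_gte(met$max_hits_per_long_read[1], 12)  # one hit per unit
  expect_equal(met$n_long_reads_with_hit[1],
               sum(oracle_kmer_hits(kmer, unlist(long)) > 0))
  # absent k-mer: zero hits, -Inf log coverages
  expect_equal(met$max_hits_per_long_read[2], 0)
  expect_equal(met$n_long_reads_with_hit[2], 0)
  expect_equal(met$pacbio_log10_coverage[2], -Inf)
})

test_that("perfect assembly hits are exact both-strand counts", {
  set.seed(62)
  kmer <- random_seq(25)
  filler <- vapply(1:3, function(i) random_seq(300), "")
  assembly <- c(paste0(filler[1], kmer, filler[2], oracle_revcomp(kmer)),
                paste0(kmer, filler[3]))
  expect_equal(count_perfect_hits(kmer, assembly), 3)
  expect_equal(count_perfect_hits(random_seq(25), assembly), 0)
  # random k-mers against a toy assembly match the sliding-window oracle
  for (i in 1:20) {
    km <- random_seq(25)
    expect_equal(count_perfect_hits(km, assembly),
                 sum(oracle_kmer_hits(km, assembly)))
  }
  expect_message(na_hits <- count_perfect_hits(kmer, NULL), "not evaluated")
  expect_true(is.na(na_hits))
})

test_that("selection filters apply the printed cutoffs with their boundaries", {
  base <- data.frame(illumina_log10_coverage = 2.5,
                     pacbio_log10_coverage = 1.5,
                     max_hits_per_long_read = 12,
                     perfect_assembly_hits = 7, offtarget_hits = 0)
  expect_true(apply_selection_filters(base)$pass)
  # max hits per read exactly 7.5 fails (strict >)
  at_bound <- base; at_bound$max_hits_per_long_read <- 7.5
  v <- apply_selection_filters(at_bound)
  expect_false(v$pass_max_hits); expect_false(v$pass)
  # 4 perfect hits fails ("at least 5")
  few <- base; few$perfect_assembly_hits <- 4
  expect_false(apply_selection_filters(few)$pass)
  # perfect hits NA -> criterion not evaluated, others decide
  noasm <- base; noasm$perfect_assembly_hits <- NA
  vv <- apply_selection_filters(noasm)
  expect_true(is.na(vv$pass_perfect)); expect_true(vv$pass)
  # missing metric column is an explicit error
  expect_error(apply_selection_filters(base[, -1]), "incomplete")
  bad <- base; bad$offtarget_hits <- NA
  expect_error(apply_selection_filters(bad), "incomplete")
})

test_that("tightening any threshold never adds a passing target", {
  set.seed(63)
  targets <- data.frame(
    illumina_log10_coverage = runif(50, 0, 4),
    pacbio_log10_coverage = runif(50, 0, 3),
    max_hits_per_long_read = runif(50, 0, 20),
    perfect_assembly_hits = rpois(50, 5),
    offtarget_hits = rpois(50, 1))
  loose <- apply_selection_filters(targets, selection_thresholds())
  for (tight in list(selection_thresholds(illumina_log10 = 3),
                     selection_thresholds(pacbio_log10 = 2),
                     selection_thresholds(max_hits_per_read = 10),
                     selection_thresholds(min_perfect_hits = 8),
                     selection_thresholds(max_offtargets = 0))) {
    t2 <- apply_selection_filters(targets, tight)
    expect_true(all(loose$pass | !t2$pass))
  }
})

test_that("greedy contig assembly merges overlaps deterministically", {
  # two 25-mers overlapping by 24 -> one 26-bp contig
  a <- "ACGTACGTACGTACGTACGTACGTA"
  b <- paste0(substr(a, 2, 25), "G")
  out <- assemble_contigs(c(a, b), min_overlap = 10)
  expect_equal(nrow(out), 1)
  expect_equal(out$contig, paste0(a, "G"))
  expect_equal(out$length, 26)
  # two disjoint k-mers stay singletons
  set.seed(64)
  d1 <- strrep("AC", 13); d2 <- strrep("GT", 13)
  out2 <- assemble_contigs(c(d1, d2), min_overlap = 10)
  expect_equal(nrow(out2), 2)
  expect_setequal(out2$contig, c(d1, d2))
  # k-mers tiled from a 100-bp unit reassemble into the unit
  unit <- random_seq(100)
  tiles <- substring(unit, 1:(100 - 24), 25:100)
  out3 <- assemble_contigs(tiles, min_overlap = 20)
  expect_equal(nrow(out3), 1)
  expect_equal(out3$contig, unit)
  expect_equal(out3$n_members, length(unique(tiles)))
  # determinism
  expect_identical(assemble_contigs(sample(tiles), min_overlap = 20)$contig,
                   unit)
})

test_that("the designed cluster target passes all filters; autosomal decoys fail", {
  g <- small_genome(seed = 41, decoy = TRUE)
  spec <- read_sim_spec(depth = 30, error_rate = 0.001, n_long_reads = 350,
                        long_read_min = 2000, long_read_max = 8000, seed = 14)
  cen <- kmer_census(simulate_short_reads(g, "male", spec),
                     simulate_short_reads(g, "female", spec), k = 25)
  cen <- apply_min_count(filter_mitochondrial(cen, g$seqs["MT"])$kept)
  long <- simulate_long_reads(g, spec)
  kept <- filter_long_reads(long)$kept
  bins <- bin_long_reads(kept, cen, mito = g$seqs["MT"])
  offref <- kept[bins$bin %in% c("autosomal", "Y")]

  x_target <- g$targets[g$targets$chrom == "X", ]
  a_target <- g$targets[g$targets$chrom == "A1", ]
  # 25-mers spanning each cluster's target window
  xk <- substr(g$units$unit_seq[g$units$chrom == "X"][1],
               x_target$target_offset_in_unit - 1,
               x_target$target_offset_in_unit + 23)
  ak <- substr(g$units$unit_seq[g$units$chrom == "A1"][1],
               a_target$target_offset_in_unit - 1,
               a_target$target_offset_in_unit + 23)

  # the X k-mer is called candidate-X; the autosomal decoy is not
  called <- call_x_kmers(cen, kept, bins)
  expect_true(called$is_candidate[called$kmer == canonical_kmers(xk)])
  expect_false(isTRUE(called$is_candidate[called$kmer == canonical_kmers(ak)]))

  # and the X target passes all selection filters (no assembly stage)
  met <- compute_abundance_metrics(xk, kept, cen)
  met$perfect_assembly_hits <- count_perfect_hits(xk, unname(g$seqs))
  met$offtarget_hits <- count_offtargets(substr(x_target$spacer, 1, 20),
                                         offref, max_mismatches = 0)
  verdict <- apply_selection_filters(met, selection_thresholds())
  expect_true(verdict$pass)
  # the autosomal decoy shows off-target hits against its own bin
  expect_gt(count_offtargets(a_target$spacer, offref, 0), 0)
})
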