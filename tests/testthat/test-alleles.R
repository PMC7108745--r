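# Hand-built amplicon for exact-allele tests: 120 bp, window at 41-63.
toy_amplicon <- function() {
  set.seed(1234)
  left <- random_seq(40)
  spacer <- "GTAGATTATCCCGGCCCTCG"
  pam <- "CGG"
  right <- random_seq(57)
  amplicon_spec(paste0(left, spacer, pam, right), window_start = 41L,
                marker = list(start = 10L, end = 15L, alt = ""))
}

test_that("the mean-quality filter is inclusive at the threshold", {
  reads <- c(q29 = strrep("A", 50), q30 = strrep("C", 50),
             q38 = strrep("G", 50))
  quals <- c(strrep(intToUtf8(29 + 33), 50), strrep(intToUtf8(30 + 33), 50),
             strrep(intToUtf8(38 + 33), 50))
  out <- quality_filter(reads, 30, quals = quals)
  expect_setequal(names(out$reads), c("q30", "q38"))   # Q29 dropped, Q30 kept
  expect_equal(attr(out, "n_input"), 3L)
  # mixed qualities: mean decides
  mixed <- paste0(strrep(intToUtf8(20 + 33), 25), strrep(intToUtf8(40 + 33), 25))
  expect_length(quality_filter("A", 30, quals = mixed)$reads, 1)
  # empty input passes through
  expect_length(quality_filter(character(), 30, quals = character())$reads, 0)
  # non-ASCII quality is a parse error
  expect_error(quality_filter("ACGT", 30, quals = "é!!!"), "quality")
})

test_that("allele extraction recovers constructed indels at the cut site", {
  spec <- toy_amplicon()
  ref <- spec$reference
  refwin <- reference_window(spec)
  # error-free read identical to reference -> intact
  calls <- extract_alleles(c(r1 = ref), spec)
  expect_true(calls$intact)
  expect_equal(calls$allele, refwin)
  # 4-bp deletion at the cut site (cut after position 57 = 41+16)
  del4 <- paste0(substr(ref, 1, 55), substr(ref, 60, nchar(ref)))
  calls2 <- extract_alleles(c(r1 = del4), spec)
  expect_false(calls2$intact)
  core <- strsplit(substr(calls2$allele, 1, 23), "")[[1]]
  expect_equal(sum(core == "-"), 4)
  gap_pos <- which(core == "-")
  expect_true(all(abs(gap_pos - 17) <= 4))   # gaps at the expected offset
  # insertion at the cut site is anchored and reported
  ins <- paste0(substr(ref, 1, 57), "TTT", substr(ref, 58, nchar(ref)))
  calls3 <- extract_alleles(c(r1 = ins), spec)
  expect_match(calls3$allele, "\\+17:TTT")
  # an unrelated sequence is unalignable
  calls4 <- extract_alleles(c(r1 = random_seq(120)), spec)
  expect_false(calls4$alignable)
})

test_that("alleles of simulated edited haplotypes match the truth table", {
  g <- small_genome(seed = 77, resistant_unit = 3L)
  spec <- amplicon_spec_from_genome(g)
  em <- editing_model(cycles = 1, cleave_prob = 0.5, disrupt_prob = 0.9)
  coh <- simulate_editing(g, em, n_individuals = 2, seed = 5)
  amps <- simulate_amplicon_reads(coh, depth = 1500, error_rate = 0.001,
                                  seed = 6)
  ind1 <- coh$individuals[coh$individuals$individual == 1, ]
  calls <- extract_alleles(quality_filter(amps[[1]], 30), spec)
  truth <- amps[[1]]$truth
  # intact calls agree with the source unit being unedited (>= 99% at 0.1%
  # base error; errors inside the window legitimately break "intact")
  truth_intact <- truth$state == "intact" & !ind1$is_resistant[truth$unit]
  agree <- mean((calls$allele == reference_window(spec)) ==
                  truth_intact)
  # a 0.1% per-base error corrupts ~2.3% of 23-nt windows; calls must agree
  # with truth up to that expectation
  expect_gte(agree, 0.96)
  # at zero sequencing error agreement is exact
  amps0 <- simulate_amplicon_reads(coh, depth = 800, error_rate = 0, seed = 7)
  calls0 <- extract_alleles(quality_filter(amps0[[1]], 30), spec)
  truth0 <- amps0[[1]]$truth
  expect_equal(calls0$allele == reference_window(spec),
               truth0$state == "intact" & !ind1$is_resistant[truth0$unit])
  # and the resistant unit's reads all carry one shared allele with marker
  res_reads <- calls0[truth0$unit == which(ind1$is_resistant), ]
  expect_equal(length(unique(res_reads$allele)), 1)
  expect_true(all(res_reads$marker_state == "alt"))
})

test_that("intact fraction follows its arithmetic contract", {
  spec <- toy_amplicon()
  ref <- spec$reference
  mut <- paste0(substr(ref, 1, 50), "A", substr(ref, 52, nchar(ref)))
  mut <- if (substr(ref, 51, 51) == "A")
    paste0(substr(ref, 1, 50), "C", substr(ref, 52, nchar(ref))) else mut
  calls <- extract_alleles(setNames(c(rep(ref, 90), rep(mut, 10)),
                                    sprintf("r%03d", 1:100)), spec)
  expect_equal(intact_fraction(calls), 0.9)
  expect_equal(intact_fraction(tally_alleles(calls)), 0.9)
  all_in <- extract_alleles(setNames(rep(ref, 5), paste0("i", 1:5)), spec)
  expect_equal(intact_fraction(all_in), 1.0)
  none <- extract_alleles(setNames(rep(mut, 5), paste0("n", 1:5)), spec)
  expect_equal(intact_fraction(none), 0.0)
  # zero alignable reads -> undefined sentinel
  junk <- extract_alleles(c(r1 = random_seq(120)), spec)
  expect_true(is.na(intact_fraction(junk)))
})

test_that("the allele census applies the 1% and 10-read criteria", {
  spec <- toy_amplicon()
  ref <- spec$reference
  v1 <- paste0(substr(ref, 1, 56), substr(ref, 60, nchar(ref)))  # 3-bp del
  v2 <- paste0(substr(ref, 1, 57), "GTC", substr(ref, 58, nchar(ref)))
  # 1000 reads: 950 wild type, 41 v1, 9 v2 (0.9%, 9 reads: fails both)
  reads <- c(rep(ref, 950), rep(v1, 41), rep(v2, 9))
  calls <- extract_alleles(setNames(reads, sprintf("r%04d", seq_along(reads))),
                           spec)
  tal <- tally_alleles(calls)
  cen <- census_alleles(tal)
  expect_equal(cen$n_incl_wildtype[cen$criterion == "freq"], 2)
  expect_equal(cen$n_excl_wildtype[cen$criterion == "freq"], 1)
  expect_equal(cen$n_incl_wildtype[cen$criterion == "reads"], 2)
  # single allele at 100%
  single <- tally_alleles(extract_alleles(setNames(rep(ref, 50),
                                                   paste0("s", 1:50)), spec))
  cs <- census_alleles(single)
  expect_true(all(cs$n_incl_wildtype == 1))
  expect_true(all(cs$n_excl_wildtype == 0))
  # counts equal a direct tally oracle
  expect_equal(sum(tal$count), 1000)
  expect_equal(sort(tal$count, decreasing = TRUE), c(950, 41, 9))
  expect_equal(sum(tal$freq), 1, tolerance = 1e-9)
})

test_that("allele classification separates pre-existing from de-novo", {
  spec <- toy_amplicon()
  ref <- spec$reference
  refwin <- reference_window(spec)
  pre <- paste0(substr(ref, 1, 60), "A", substr(ref, 62, nchar(ref)))
  if (substr(ref, 61, 61) == "A")
    pre <- paste0(substr(ref, 1, 60), "G", substr(ref, 62, nchar(ref)))
  novo <- paste0(substr(ref, 1, 55), substr(ref, 58, nchar(ref)))
  mk <- function(seqs, sample) {
    tally_alleles(extract_alleles(
      setNames(seqs, sprintf("%s_%03d", sample, seq_along(seqs))), spec),
      sample)
  }
  tallies <- list(
    mk(c(rep(ref, 95), rep(pre, 5)), "ctrl1"),
    mk(c(rep(ref, 93), rep(pre, 7)), "ctrl2"),
    mk(c(rep(ref, 60), rep(pre, 15), rep(novo, 25)), "exp1"),
    mk(c(rep(ref, 70), rep(novo, 30)), "exp2"))
  cls <- classify_alleles(tallies, controls = c("ctrl1", "ctrl2"))
  get <- function(seqs) {
    key <- extract_alleles(c(r = seqs), spec)$allele
    cls$class[cls$allele == key]
  }
  expect_equal(get(ref), "intact")
  expect_equal(get(pre), "pre-existing-variant")
  expect_equal(get(novo), "de-novo")
  expect_error(classify_alleles(tallies, controls = character()), "control")
})

test_that("classification recovers truth exactly at zero sequencing error", {
  g <- small_genome(seed = 88, resistant_unit = 3L)
  spec <- amplicon_spec_from_genome(g)
  em <- editing_model(cycles = 2, cleave_prob = 0.5, disrupt_prob = 0.9)
  coh <- simulate_editing(g, em, n_individuals = 3, seed = 21)
  ctrl_coh <- simulate_editing(g, editing_model(cleave_prob = 0),
                               n_individuals = 2, seed = 22)
  amps <- simulate_amplicon_reads(coh, depth = 1200, error_rate = 0, seed = 2)
  ctrl <- simulate_amplicon_reads(ctrl_coh, depth = 1200, error_rate = 0,
                                  seed = 3)
  tallies <- c(
    lapply(seq_along(ctrl), function(i)
      tally_alleles(extract_alleles(ctrl[[i]], spec), paste0("ctrl", i))),
    lapply(seq_along(amps), function(i)
      tally_alleles(extract_alleles(amps[[i]], spec), paste0("exp", i))))
  cls <- classify_alleles(tallies, controls = c("ctrl1", "ctrl2"),
                          spec = spec)
  # truth: the resistant-unit allele pre-exists in all controls; disrupted
  # units give de-novo alleles; unedited flank-polymorphic units pre-exist
  res_allele <- extract_alleles(
    setNames(g$units$amp_seq[g$units$is_resistant], "r"), spec)$allele
  expect_equal(cls$class[cls$allele == res_allele], "pre-existing-variant")
  novo_seqs <- coh$individuals$amp_seq[coh$individuals$state == "disrupted"]
  novo_keys <- extract_alleles(
    setNames(novo_seqs, paste0("n", seq_along(novo_seqs))), spec)$allele
  novo_cls <- cls$class[cls$allele %in% novo_keys]
  expect_gt(length(novo_cls), 0)
  expect_true(all(novo_cls == "de-novo"))
  # all unedited non-resistant units carry the intact target window
  pre_seqs <- g$units$amp_seq[!g$units$is_resistant]
  pre_keys <- unique(extract_alleles(
    setNames(pre_seqs, paste0("p", seq_along(pre_seqs))), spec)$allele)
  expect_equal(pre_keys, reference_window(spec))
})

test_that("resistance calling follows the PAM/seed/indel rule", {
  spec <- toy_amplicon()
  refwin <- reference_window(spec)
  # the reference window itself is not resistant
  expect_false(flag_resistant(refwin, spec)$resistant)
  # a known pre-existing resistant pattern: substitutions at a PAM-distal
  # protospacer position AND at the PAM's central G
  chars <- strsplit(refwin, "")[[1]]
  chars[5] <- if (chars[5] == "A") "G" else "A"   # protospacer position 5
  chars[22] <- "A"                                 # PAM CGG -> CAG
  paper_like <- paste(chars, collapse = "")
  fr <- flag_resistant(paper_like, spec)
  expect_true(fr$resistant)
  expect_true(fr$pam_mutated)
  # a single PAM-distal substitution with intact PAM is not resistant
  distal <- strsplit(refwin, "")[[1]]
  distal[1] <- if (distal[1] == "A") "C" else "A"
  expect_false(flag_resistant(paste(distal, collapse = ""), spec)$resistant)
  # a seed-region substitution alone is resistant
  seedmut <- strsplit(refwin, "")[[1]]
  seedmut[15] <- if (seedmut[15] == "A") "C" else "A"
  fs <- flag_resistant(paste(seedmut, collapse = ""), spec)
  expect_true(fs$resistant)
  expect_equal(fs$seed_substitutions, 1)
  # any indel is resistant
  del <- sub("^(.{16}).", "\\1-", refwin)
  expect_true(flag_resistant(del, spec)$has_indel)
  expect_true(flag_resistant(paste0(refwin, "+17:TT"), spec)$resistant)
})

test_that("frequency summaries report per-sample values and experimental medians", {
  tallies <- data.frame(
    sample = c("c1", "e1", "e2", "e3"),
    allele = "AAA", count = 10,
    freq = c(0.05, 0.1, 0.2, 0.3), stringsAsFactors = FALSE)
  out <- allele_frequency_summary(tallies, controls = "c1")
  expect_equal(out$median_experimental, 0.2)
  expect_equal(out$c1, 0.05)
  one <- allele_frequency_summary(tallies[tallies$sample == "e1", ],
                                  controls = character())
  expect_equal(one$median_experimental, 0.1)
})

test_that("resistant-allele median frequency rises with cluster collapse", {
  g <- small_genome(seed = 99, resistant_unit = 3L)
  spec <- amplicon_spec_from_genome(g)
  res_allele <- extract_alleles(
    setNames(g$units$amp_seq[g$units$is_resistant], "r"), spec)$allele
  median_at <- function(del_prob, seed0) {
    em <- editing_model(cycles = 4, cleave_prob = 0.6, disrupt_prob = 0.3,
                        intercut_deletion_prob = del_prob)
    coh <- simulate_editing(g, em, n_individuals = 6, seed = seed0)
    amps <- simulate_amplicon_reads(coh, depth = 600, error_rate = 0,
                                    seed = seed0 + 1)
    tallies <- lapply(seq_along(amps), function(i)
      tally_alleles(extract_alleles(amps[[i]], spec), paste0("m", i)))
    fs <- allele_frequency_summary(tallies)
    fs$median_experimental[fs$allele == res_allele]
  }
  low <- median_at(0, 301)
  high <- median_at(0.8, 302)
  expect_gt(high, low)
  # with no deletions the resistant copy share stays ~1/12
  expect_lt(abs(low - 1 / 12), 0.03)
})

test_that("marker dissociation is detected when linkage is broken", {
  g <- small_genome(seed = 55, resistant_unit = 3L)
  spec <- amplicon_spec_from_genome(g)
  units <- g$units
  res_amp <- units$amp_seq[units$is_resistant]
  wt_amp <- units$amp_seq[!units$is_resistant][1]
  res_allele <- extract_alleles(setNames(res_amp, "r"), spec)$allele
  # perfect linkage: every resistant-allele read carries the marker
  reads <- setNames(c(rep(res_amp, 50), rep(wt_amp, 450)),
                    sprintf("r%03d", 1:500))
  calls <- extract_alleles(reads, spec)
  out <- linked_marker_dissociation(calls, res_allele)
  expect_false(out$dissociated)
  expect_equal(out$n_dissociated, 0)
  # gene conversion: resistant window copied onto a marker-less unit
  conv <- wt_amp
  # paste the resistant target window into the wild-type amplicon
  w0 <- spec$window_start
  res_win_seq <- substr(res_amp, w0 - 6L, w0 + 16L)  # resistant unit is 6 bp shorter
  conv <- paste0(substr(wt_amp, 1, w0 - 1), res_win_seq,
                 substr(wt_amp, spec$window_end + 1, nchar(wt_amp)))
  reads2 <- setNames(c(rep(res_amp, 25), rep(conv, 25), rep(wt_amp, 450)),
                     sprintf("r%03d", 1:500))
  calls2 <- extract_alleles(reads2, spec)
  out2 <- linked_marker_dissociation(calls2, res_allele)
  expect_true(out2$dissociated)
  expect_equal(out2$n_dissociated, 25)
  expect_lt(out2$p_value, 1e-6)
})

test_that("coding effects are classified by net indel and translation", {
  g <- small_genome(seed = 31)
  spec <- amplicon_spec_from_locus(g)
  refwin <- reference_window(spec)
  # 2-bp deletion -> frameshift
  del2 <- sub("^(.{15})..", "\\1--", refwin)
  expect_equal(classify_coding_effect(del2, spec)$coding_effect, "frameshift")
  # 3-bp deletion -> in-frame indel
  del3 <- sub("^(.{15})...", "\\1---", refwin)
  expect_equal(classify_coding_effect(del3, spec)$coding_effect,
               "in-frame indel")
  # 3-bp insertion -> in-frame; 1-bp insertion -> frameshift
  expect_equal(classify_coding_effect(paste0(refwin, "+17:TAC"),
                                      spec)$coding_effect, "in-frame indel")
  expect_equal(classify_coding_effect(paste0(refwin, "+17:T"),
                                      spec)$coding_effect, "frameshift")
  # substitution changing a codon's first base -> missense, with the change
  # verified against a direct translation oracle
  lo <- g$loci
  codon_start <- spec$window_start + (3 - (spec$window_start - 1) %% 3) %% 3
  pos_in_win <- codon_start - spec$window_start + 1
  chars <- strsplit(refwin, "")[[1]]
  old_codon <- substr(spec$reference, codon_start, codon_start + 2)
  chars[pos_in_win] <- setdiff(c("A", "C", "G", "T"), chars[pos_in_win])[1]
  new_codon <- paste0(chars[pos_in_win], substr(old_codon, 2, 3))
  mut <- paste(chars, collapse = "")
  res <- classify_coding_effect(mut, spec)
  aa_old <- as.character(Biostrings::translate(Biostrings::DNAString(old_codon)))
  aa_new <- as.character(Biostrings::translate(Biostrings::DNAString(new_codon),
                                               no.init.codon = TRUE))
  if (aa_old == aa_new) {
    expect_equal(res$coding_effect, "synonymous")
  } else {
    expect_equal(res$coding_effect, "missense")
    expect_match(res$protein_change, paste0("^", aa_old, "\\d+>", aa_new, "$"))
  }
  # no reading frame -> effect none with warning
  nospec <- toy_amplicon()
  expect_warning(none <- classify_coding_effect(refwin, nospec), "frame")
  expect_equal(none$coding_effect, "none")
})

test_that("per-sample allele frequencies sum to one after normalization", {
  g <- small_genome(seed = 12, resistant_unit = 3L)
  spec <- amplicon_spec_from_genome(g)
  coh <- simulate_editing(g, editing_model(cycles = 2, cleave_prob = 0.4),
                          n_individuals = 2, seed = 9)
  amps <- simulate_amplicon_reads(coh, depth = 800, error_rate = 0.001,
                                  seed = 10)
  for (i in seq_along(amps)) {
    tal <- tally_alleles(extract_alleles(quality_filter(amps[[i]], 30), spec))
    expect_equal(sum(tal$freq), 1, tolerance = 1e-9)
  }
})
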