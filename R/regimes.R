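#' Run a cut-repair editing regime end to end and quantify intact-site loss
#'
#' The full simulation-to-quantification loop used to compare editing
#' regimes: build a genome with one X-linked 12-unit repeat cluster
#' (271-bp units, one designated cleavage-resistant unit), edit one
#' haplotype per male under the given model (independent seeds per male,
#' emulating sons that each inherit one paternally edited X), sequence
#' each male's cluster amplicon, and run the allele pipeline
#' (quality filter at Q30, global alignment, target-window allele calls).
#' The per-male percentage reduction in reads carrying the complete
#' unaltered target site is computed against an unedited control male
#' processed identically.
#'
#' @param model an [editing_model()]; e.g. one cycle at cleavage 0.5 with
#'   disrupting-repair 0.9 for a meiotic regime, six cycles at cleavage
#'   0.3 with disrupting-repair 0.95 for a pre-meiotic regime.
#' @param n_males number of edited males.
#' @param depth amplicon reads per male.
#' @param error_rate per-base sequencing error rate.
#' @param seed base seed; male `i` is edited with seed
#'   `(seed - 1) * 1000 + i`, so base seed 1 gives males seeded 1..10.
#' @param n_units,resistant_unit cluster composition.
#' @return list with `control_intact`, `male_intact` (per-male intact
#'   fractions), `reduction_pct` (per-male percentage reductions relative
#'   to control) and `mean_reduction_pct`.
#' @export
run_editing_regime <- function(model, n_males = 10L, depth = 5000L,
                               error_rate = 0.001, seed = 1L,
                               n_units = 12L, resistant_unit = 3L) {
  base <- (as.integer(seed) - 1L) * 1000L
  genome <- build_genome(genome_spec(
    x_length = 2e4, autosome_lengths = 1e4, y_length = 2e4,
    mito_length = 4e3,
    clusters = list(repeat_cluster(chrom = "X", start = 5000L,
                                   n_units = n_units,
                                   resistant_unit = resistant_unit)),
    seed = base + 500L))
  spec <- amplicon_spec_from_genome(genome)

  measure <- function(cohort, amp_seed) {
    amps <- simulate_amplicon_reads(cohort, depth = depth,
                                    error_rate = error_rate,
                                    seed = amp_seed)
    calls <- extract_alleles(quality_filter(amps[[1]], 30), spec)
    intact_fraction(calls)
  }

  control_cohort <- simulate_editing(genome, editing_model(cleave_prob = 0),
                                     n_individuals = 1, seed = base + 999L)
  control_intact <- measure(control_cohort, base + 998L)

  male_intact <- vapply(seq_len(n_males), function(i) {
    s <- base + i
    cohort <- simulate_editing(genome, model, n_individuals = 1, seed = s)
    measure(cohort, s + 500000L)
  }, 0.0)

  reduction <- (control_intact - male_intact) / control_intact * 100
  list(control_intact = control_intact, male_intact = male_intact,
       reduction_pct = reduction, mean_reduction_pct = mean(reduction))
}

#' The two editing regimes contrasted by the sex-distorter study
#'
#' Meiotic editing (Cas9 restricted to meiosis): one cut-repair cycle at
#' high cleavage; pre-meiotic editing (Cas9 active from the stem-cell
#' stages): several sequential cycles at moderate per-cycle cleavage, each
#' disrupting cut being repaired before the next round.
#'
#' @param regime `"meiotic"` or `"premeiotic"`.
#' @return an [editing_model()].
#' @export
regime_model <- function(regime = c("meiotic", "premeiotic")) {
  regime <- match.arg(regime)
  if (regime == "meiotic") {
    editing_model(cycles = 1, cleave_prob = 0.5, disrupt_prob = 0.9)
  } else {
    editing_model(cycles = 6, cleave_prob = 0.3, disrupt_prob = 0.95)
  }
}
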