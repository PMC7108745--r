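#' Specify a Cas9 cut-repair editing model
#'
#' Editing of a tandem repeat cluster is modelled as a number of sequential
#' cut-repair cycles. In each cycle every unit whose target site is still
#' intact is cleaved independently with probability `cleave_prob`; a
#' cleaved unit is repaired either imperfectly (probability `disrupt_prob`,
#' leaving an indel at the cut site) or faithfully (restoring the intact
#' site, available for re-cutting in later cycles). Optionally, a pair of
#' units cut in the same cycle collapses the units lying between them
#' (probability `intercut_deletion_prob` per adjacent cut pair), removing
#' whole intervening units. A designated resistant unit is never cleaved
#' and never deleted. One cycle with high cleavage emulates the meiotic
#' editing regime; several cycles emulate pre-meiotic activity in which
#' repeats undergo multiple cleavage-repair rounds.
#'
#' @param cycles number of sequential cut-repair cycles (>= 0).
#' @param cleave_prob per-cycle cleavage probability of an intact unit.
#' @param disrupt_prob probability that repair of a cut leaves a disrupting
#'   indel (otherwise the site is restored faithfully).
#' @param indel_sizes,indel_size_probs indel size spectrum (sizes >= 1).
#' @param insertion_prob probability that a disrupting indel is an
#'   insertion rather than a deletion.
#' @param intercut_deletion_prob probability, per adjacent pair of units cut
#'   in the same cycle, that the intervening units are deleted.
#' @return an object of class `editing_model`.
#' @export
editing_model <- function(cycles = 1L, cleave_prob = 0.5, disrupt_prob = 0.9,
                          indel_sizes = 1:10,
                          indel_size_probs = 0.6 ^ (0:9),
                          insertion_prob = 0.2,
                          intercut_deletion_prob = 0) {
  stopifnot(cycles >= 0,
            cleave_prob >= 0, cleave_prob <= 1,
            disrupt_prob >= 0, disrupt_prob <= 1,
            insertion_prob >= 0, insertion_prob <= 1,
            intercut_deletion_prob >= 0, intercut_deletion_prob <= 1,
            all(indel_sizes >= 1),
            length(indel_sizes) == length(indel_size_probs),
            all(indel_size_probs >= 0), sum(indel_size_probs) > 0)
  structure(list(cycles = as.integer(cycles), cleave_prob = cleave_prob,
                 disrupt_prob = disrupt_prob,
                 indel_sizes = as.integer(indel_sizes),
                 indel_size_probs = indel_size_probs / sum(indel_size_probs),
                 insertion_prob = insertion_prob,
                 intercut_deletion_prob = intercut_deletion_prob),
            class = "editing_model")
}

#' Analytic expected intact-unit fraction under an editing model
#'
#' For a model without inter-cut deletions, a cleavable unit is intact
#' after `cycles` rounds with probability `(1 - cleave_prob *
#' disrupt_prob)^cycles` (a faithfully repaired cut returns the unit to the
#' intact pool). Returns `NA` when inter-cut deletions are enabled, where
#' no simple closed form holds.
#'
#' @param model an [editing_model()].
#' @return expected fraction of cleavable units left intact.
#' @export
expected_intact_fraction <- function(model) {
  stopifnot(inherits(model, "editing_model"))
  if (model$intercut_deletion_prob > 0) return(NA_real_)
  (1 - model$cleave_prob * model$disrupt_prob) ^ model$cycles
}

# Apply one disrupting indel to an amplicon sequence at the cut position
# (cut_after = last base 5' of the cut). Returns list(seq, net).
apply_indel <- function(seq, cut_after, model) {
  size <- sample(model$indel_sizes, 1, prob = model$indel_size_probs)
  if (runif(1) < model$insertion_prob) {
    ins <- random_dna(size)
    list(seq = paste0(substr(seq, 1, cut_after), ins,
                      substr(seq, cut_after + 1, nchar(seq))),
         net = size)
  } else {
    # deletion straddling the cut site
    start <- max(1L, cut_after - as.integer(ceiling(size / 2)) + 1L)
    end <- min(nchar(seq), start + size - 1L)
    list(seq = paste0(substr(seq, 1, start - 1),
                      substr(seq, end + 1, nchar(seq))),
         net = -(end - start + 1L))
  }
}

#' Simulate Cas9 editing of a repeat cluster across individuals
#'
#' For each individual (one haplotype, as in sons inheriting a single
#' paternal X), runs the cut-repair cycles of the model over the cluster's
#' units and records every event, so the expected intact fraction can be
#' recomputed analytically from the log. Unit states are `intact`,
#' `disrupted` (carries a repair indel), `deleted` (lost to an inter-cut
#' collapse) or `resistant` (the designated resistant unit, never touched).
#'
#' @param genome a `sim_genome`.
#' @param model an [editing_model()].
#' @param n_individuals number of independent haplotypes to edit.
#' @param cluster cluster id within the genome (default 1).
#' @param seed integer seed.
#' @return an object of class `edited_cohort`: `individuals` (one row per
#'   individual x unit: state, post-editing amplicon sequence, cut count,
#'   net indel length), `events` (per cut/repair/deletion event log),
#'   `model`, and the cluster's amplicon reference.
#' @export
simulate_editing <- function(genome, model, n_individuals, cluster = 1L,
                             seed = 1L) {
  stopifnot(inherits(genome, "sim_genome"), inherits(model, "editing_model"),
            n_individuals >= 1)
  units <- genome$units[genome$units$cluster == cluster, ]
  if (nrow(units) == 0) stop("no such cluster in genome: ", cluster)
  tg <- genome$targets[genome$targets$cluster == cluster, ]
  # cut site falls between protospacer positions 17 and 18 (3 bp 5' of PAM)
  cut_in_amp <- units$target_offset - units$amp_start + 1L + 16L

  withr::with_seed(seed, {
    indiv_rows <- vector("list", n_individuals)
    event_rows <- list()
    ev <- function(individual, cycle, unit, event) {
      event_rows[[length(event_rows) + 1L]] <<- data.frame(
        individual = individual, cycle = cycle, unit = unit, event = event,
        stringsAsFactors = FALSE)
    }
    n_units <- nrow(units)
    for (ind in seq_len(n_individuals)) {
      state <- ifelse(units$is_resistant, "resistant", "intact")
      amp <- units$amp_seq
      cuts <- integer(n_units)
      net <- integer(n_units)
      for (cyc in seq_len(model$cycles)) {
        cut <- which(state == "intact" & runif(n_units) < model$cleave_prob)
        if (length(cut) == 0) next
        for (u in cut) ev(ind, cyc, units$unit[u], "cut")
        cuts[cut] <- cuts[cut] + 1L
        if (model$intercut_deletion_prob > 0 && length(cut) >= 2) {
          for (p in seq_len(length(cut) - 1)) {
            a <- cut[p]; b <- cut[p + 1]
            if (b - a > 1 && runif(1) < model$intercut_deletion_prob) {
              # unit-granular collapse; only still-intact units are removed,
              # so no unit is ever both mutated and deleted, and the
              # resistant unit survives any intensity
              between <- seq(a + 1L, b - 1L)
              between <- between[state[between] == "intact"]
              for (u in between) ev(ind, cyc, units$unit[u], "deleted_intercut")
              state[between] <- "deleted"
            }
          }
        }
        for (u in cut) {
          if (state[u] == "deleted") next
          if (runif(1) < model$disrupt_prob) {
            res <- apply_indel(amp[u], cut_in_amp[u], model)
            amp[u] <- res$seq
            net[u] <- net[u] + res$net
            state[u] <- "disrupted"
            ev(ind, cyc, units$unit[u], "repair_disrupt")
          } else {
            ev(ind, cyc, units$unit[u], "repair_faithful")
          }
        }
      }
      indiv_rows[[ind]] <- data.frame(
        individual = ind, cluster = cluster, unit = units$unit,
        is_resistant = units$is_resistant, state = state, n_cuts = cuts,
        net_indel = net, amp_seq = amp, stringsAsFactors = FALSE)
    }
    out <- list(
      individuals = do.call(rbind, indiv_rows),
      events = if (length(event_rows)) do.call(rbind, event_rows) else
        data.frame(individual = integer(), cycle = integer(),
                   unit = integer(), event = character(),
                   stringsAsFactors = FALSE),
      model = model, cluster = cluster,
      reference = amplicon_spec_from_genome(genome, cluster))
    class(out) <- "edited_cohort"
    out
  })
}

#' @export
print.edited_cohort <- function(x, ...) {
  n <- length(unique(x$individuals$individual))
  cat("edited_cohort:", n, "individual(s),",
      nrow(x$individuals) / n, "units each;",
      nrow(x$events), "events\n")
  invisible(x)
}

#' Simulate amplicon sequencing of edited haplotypes
#'
#' Emulates a proportion-preserving (non-saturating) PCR over the repeat
#' cluster followed by deep sequencing: each read is drawn from the
#' surviving (non-deleted) units of one individual with equal probability
#' per unit copy, so read counts per unit are multinomial with
#' probabilities proportional to surviving unit copies. Deleted units
#' produce no reads. Base-call errors are uniform substitutions; qualities
#' are a constant Phred score.
#'
#' @param cohort an `edited_cohort` from [simulate_editing()].
#' @param depth reads per individual.
#' @param error_rate per-base substitution error rate.
#' @param quality_q constant Phred quality of simulated bases.
#' @param seed integer seed.
#' @return named list (one `sim_reads` per individual); each `truth`
#'   records the source unit and its state for every read.
#' @export
simulate_amplicon_reads <- function(cohort, depth = 5000L, error_rate = 0.001,
                                    quality_q = 38L, seed = 1L) {
  stopifnot(inherits(cohort, "edited_cohort"), depth >= 0)
  withr::with_seed(seed, {
    inds <- unique(cohort$individuals$individual)
    out <- vector("list", length(inds))
    names(out) <- paste0("male", inds)
    for (i in seq_along(inds)) {
      df <- cohort$individuals[cohort$individuals$individual == inds[i], ]
      surviving <- df[df$state != "deleted", ]
      if (nrow(surviving) == 0 || depth == 0) {
        out[[i]] <- structure(list(reads = character(), quals = character(),
                                   truth = data.frame()), class = "sim_reads")
        next
      }
      pick <- sample.int(nrow(surviving), depth, replace = TRUE)
      reads <- add_substitution_errors(surviving$amp_seq[pick], error_rate)
      ids <- sprintf("%s_amp%05d", names(out)[i], seq_len(depth))
      names(reads) <- ids
      out[[i]] <- structure(
        list(reads = reads,
             quals = setNames(constant_quality(nchar(reads), quality_q), ids),
             truth = data.frame(id = ids, unit = surviving$unit[pick],
                                state = surviving$state[pick],
                                stringsAsFactors = FALSE)),
        class = "sim_reads")
    }
    out
  })
}
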