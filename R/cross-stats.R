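#' Male fraction of a cross with exact binomial confidence interval
#'
#' `n_males / (n_males + n_females)` with a Clopper-Pearson interval
#' (exact intervals are preferred because single-cross brood sizes are
#' small). Undefined (`NA` sentinels) when the total is zero. Vectorized.
#'
#' @param n_males,n_females non-negative progeny counts.
#' @param conf_level confidence level (default 0.95).
#' @return data frame: `n_males`, `n_females`, `total`, `fraction`,
#'   `ci_lower`, `ci_upper`.
#' @export
male_fraction <- function(n_males, n_females, conf_level = 0.95) {
  stopifnot(all(n_males >= 0), all(n_females >= 0), length(n_males) ==
              length(n_females))
  total <- n_males + n_females
  frac <- ifelse(total > 0, n_males / total, NA_real_)
  ci <- t(mapply(function(x, n) {
    if (n == 0) return(c(NA_real_, NA_real_))
    stats::binom.test(x, n, conf.level = conf_level)$conf.int
  }, n_males, total))
  data.frame(n_males = n_males, n_females = n_females, total = total,
             fraction = frac, ci_lower = ci[, 1], ci_upper = ci[, 2])
}

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t-test with Satterthwaite degrees of freedom, applied
#' to per-replicate fractions (each single-male cross is one observation).
#' When both groups are constant with equal means the contract is `t = 0,
#' p = 1`; constant groups with different means give `p = 0` with
#' infinite `t`.
#'
#' @param a,b numeric vectors of replicate values (each of length >= 2).
#' @return list: `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
welch_t_test <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = NA_real_, p_value = 1,
                  mean_a = mean(a), mean_b = mean(b)))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = NA_real_,
                p_value = 0, mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Stage-wise developmental survival rates
#'
#' Survival through embryo, pupa and adult stages of one collection:
#' embryo-to-pupa rate, pupa-to-adult rate, and the sex fractions among
#' adults. Invariants (`hatched <= embryos`, `adults <= pupae <=
#' embryos`) are enforced; zero denominators yield `NA` sentinels.
#'
#' @param embryos,hatched,pupae,adult_females,adult_males stage counts.
#' @return list: `embryo_to_pupa`, `pupa_to_adult`, `hatch_rate`,
#'   `adult_male_fraction`, `adult_female_fraction`.
#' @export
survival_rates <- function(embryos, hatched, pupae, adult_females,
                           adult_males) {
  adults <- adult_females + adult_males
  if (hatched > embryos) stop("invariant violation: hatched > embryos")
  if (pupae > embryos) stop("invariant violation: pupae > embryos")
  if (adults > pupae) stop("invariant violation: adults > pupae")
  list(embryo_to_pupa = if (embryos > 0) pupae / embryos else NA_real_,
       pupa_to_adult = if (pupae > 0) adults / pupae else NA_real_,
       hatch_rate = if (embryos > 0) hatched / embryos else NA_real_,
       adult_male_fraction = if (adults > 0) adult_males / adults else NA_real_,
       adult_female_fraction = if (adults > 0) adult_females / adults else
         NA_real_)
}

#' Summarize replicated crosses per genotype
#'
#' Replicate unit is the single-male cross; a pooled cross contributes one
#' observation (never inflated to per-fly observations). The pooled
#' fraction per genotype equals the count-weighted mean of replicate
#' fractions.
#'
#' @param crosses data frame with columns `genotype`, `replicate`,
#'   `n_males`, `n_females` (e.g. read with [read_cross_table()]).
#' @param conf_level confidence level for the pooled exact interval.
#' @return data frame, one row per genotype: `n_replicates`, `n_total`,
#'   `mean_fraction` (unweighted mean over replicates), `sd_fraction`,
#'   `pooled_fraction`, `ci_lower`, `ci_upper`.
#' @export
cross_summary <- function(crosses, conf_level = 0.95) {
  need <- c("genotype", "replicate", "n_males", "n_females")
  stopifnot(all(need %in% names(crosses)))
  rows <- lapply(split(crosses, crosses$genotype), function(g) {
    per <- male_fraction(g$n_males, g$n_females, conf_level)
    pooled <- male_fraction(sum(g$n_males), sum(g$n_females), conf_level)
    data.frame(genotype = g$genotype[1], n_replicates = nrow(g),
               n_total = sum(per$total),
               mean_fraction = mean(per$fraction, na.rm = TRUE),
               sd_fraction = stats::sd(per$fraction[!is.na(per$fraction)]),
               pooled_fraction = pooled$fraction,
               ci_lower = pooled$ci_lower, ci_upper = pooled$ci_upper,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a cross-count table
#'
#' Expects a TSV with columns `genotype`, `replicate`, `n_males`,
#' `n_females` (additional columns are kept).
#'
#' @param path TSV path.
#' @return data frame.
#' @export
read_cross_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("genotype", "replicate", "n_males", "n_females")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cross table is missing column(s): ", paste(miss, collapse = ", "))
  df
}
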