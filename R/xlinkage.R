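#' X-linkage thresholds
#'
#' Cutoffs for long-read length filtering, chromosome-quotient (CQ)
#' binning and candidate X-kmer calling. The CQ of a sequence is the ratio
#' of normalized female to normalized male evidence: about 2 for X-linked
#' sequence (two female X copies vs one male copy), about 1 for autosomal
#' and about 0 for Y-linked sequence. The length window (2-100 kb by
#' default, both bounds inclusive) restricts the long-read set to reads
#' long enough for a stable CQ. The CQ windows themselves are working
#' defaults, configurable rather than canonical.
#'
#' @param long_read_min,long_read_max inclusive long-read length window (bp).
#' @param cq_x CQ window calling a read or k-mer X-linked.
#' @param cq_autosomal CQ window calling a read autosomal.
#' @param cq_y_max CQ ceiling calling a read Y-linked.
#' @param x_hit_fraction minimum fraction of a k-mer's long-read hits that
#'   must fall on X-binned reads for the k-mer to be a candidate X-kmer.
#' @param cq_cap CQ value reported (with a flag) when male evidence is zero
#'   but female evidence is not.
#' @param mito_fraction minimum fraction of a read's k-mer windows matching
#'   the mitochondrial reference for the read to be binned mitochondrial.
#' @return an object of class `linkage_thresholds`.
#' @export
linkage_thresholds <- function(long_read_min = 2000L, long_read_max = 100000L,
                               cq_x = c(1.5, 2.5), cq_autosomal = c(0.7, 1.4),
                               cq_y_max = 0.1, x_hit_fraction = 0.99,
                               cq_cap = 10, mito_fraction = 0.5) {
  stopifnot(long_read_min < long_read_max, long_read_min > 0,
            length(cq_x) == 2, length(cq_autosomal) == 2,
            cq_x[1] < cq_x[2], cq_autosomal[1] < cq_autosomal[2],
            cq_y_max >= 0, x_hit_fraction >= 0, x_hit_fraction <= 1,
            cq_cap > 0, mito_fraction >= 0, mito_fraction <= 1)
  # the three CQ windows must not overlap, or binning is not a partition
  if (cq_autosomal[2] >= cq_x[1] || cq_y_max >= cq_autosomal[1])
    stop("CQ windows must be disjoint (Y < autosomal < X)")
  structure(list(long_read_min = as.integer(long_read_min),
                 long_read_max = as.integer(long_read_max),
                 cq_x = cq_x, cq_autosomal = cq_autosomal,
                 cq_y_max = cq_y_max, x_hit_fraction = x_hit_fraction,
                 cq_cap = cq_cap, mito_fraction = mito_fraction),
            class = "linkage_thresholds")
}

#' Filter long reads by length
#'
#' Retains reads whose length lies inside the inclusive window
#' `[long_read_min, long_read_max]`.
#'
#' @param reads a `sim_reads` object, `DNAStringSet`, character vector or
#'   FASTA/FASTQ path.
#' @param thresholds a [linkage_thresholds()].
#' @return list with `kept` (named character vector of sequences) and
#'   `rejected` (data frame: id, length, reason).
#' @export
filter_long_reads <- function(reads, thresholds = linkage_thresholds()) {
  stopifnot(inherits(thresholds, "linkage_thresholds"))
  seqs <- as_sequences(reads)
  if (is.null(names(seqs)) && length(seqs))
    names(seqs) <- paste0("read", seq_along(seqs))
  lens <- nchar(seqs)
  ok <- lens >= thresholds$long_read_min & lens <= thresholds$long_read_max
  rejected <- data.frame(
    id = names(seqs)[!ok], length = lens[!ok],
    reason = ifelse(lens[!ok] < thresholds$long_read_min,
                    "too_short", "too_long"),
    stringsAsFactors = FALSE)
  rownames(rejected) <- NULL
  list(kept = seqs[ok], rejected = rejected)
}

#' Chromosome quotient
#'
#' `cq = (female_evidence / female_norm) / (male_evidence / male_norm)`.
#' When male evidence is zero but female evidence is not, the quotient is
#' capped at `cap` and flagged; when both evidences are zero the CQ is
#' undefined (`NA` with the `undefined` flag), never silently 0.
#'
#' @param female_evidence,male_evidence non-negative evidence (counts or
#'   summed counts); vectorized.
#' @param female_norm,male_norm normalization factors (e.g. library sizes);
#'   defaults of 1 assume pre-normalized evidence.
#' @param cap CQ value reported when male evidence is zero.
#' @return data frame with `cq`, `female_evidence`, `male_evidence`,
#'   `capped`, `undefined`.
#' @export
compute_cq <- function(female_evidence, male_evidence,
                       female_norm = 1, male_norm = 1, cap = 10) {
  stopifnot(all(female_evidence >= 0), all(male_evidence >= 0),
            female_norm > 0, male_norm > 0)
  f <- female_evidence / female_norm
  m <- male_evidence / male_norm
  undefined <- female_evidence == 0 & male_evidence == 0
  capped <- !undefined & male_evidence == 0
  cq <- ifelse(undefined, NA_real_, ifelse(capped, cap, f / m))
  data.frame(cq = cq, female_evidence = female_evidence,
             male_evidence = male_evidence, capped = capped,
             undefined = undefined)
}

#' Bin long reads by chromosome quotient
#'
#' Computes each read's CQ from the summed normalized sex counts of its
#' constituent k-mers (abundant repeats thereby weigh as the evidence they
#' are) and assigns a bin: `X`, `autosomal`, `Y`, `mitochondrial` (reads
#' matching the mitochondrial reference, regardless of CQ) or `ambiguous`
#' (no countable k-mers, undefined CQ, or CQ outside every window).
#'
#' @param reads retained long reads (`sim_reads`, character vector,
#'   `DNAStringSet` or file path); apply [filter_long_reads()] first.
#' @param census a [kmer_census()] table (after mitochondrial and
#'   minimum-count filtering).
#' @param mito optional mitochondrial reference sequence(s) or path.
#' @param thresholds a [linkage_thresholds()].
#' @return data frame of class `long_read_bins`: `id`, `length`, `cq`,
#'   `bin`, `n_kmers_hit`, `female_evidence`, `male_evidence`.
#' @export
bin_long_reads <- function(reads, census, mito = NULL,
                           thresholds = linkage_thresholds()) {
  stopifnot(inherits(census, "kmer_census"),
            inherits(thresholds, "linkage_thresholds"))
  seqs <- as_sequences(reads)
  if (is.null(names(seqs)) && length(seqs))
    names(seqs) <- paste0("read", seq_along(seqs))
  k <- attr(census, "k") %||% 25L
  canonical <- attr(census, "canonical") %||% TRUE
  ev <- cpp_read_evidence(unname(seqs), census$kmer,
                          census$female_norm, census$male_norm,
                          as.integer(k), canonical)
  cq <- compute_cq(ev$female_evidence, ev$male_evidence,
                   cap = thresholds$cq_cap)
  bin <- rep("ambiguous", length(seqs))
  bin[!is.na(cq$cq) & cq$cq >= thresholds$cq_x[1] &
        cq$cq <= thresholds$cq_x[2] & !cq$capped] <- "X"
  bin[!is.na(cq$cq) & cq$cq >= thresholds$cq_autosomal[1] &
        cq$cq <= thresholds$cq_autosomal[2]] <- "autosomal"
  bin[!is.na(cq$cq) & cq$cq <= thresholds$cq_y_max] <- "Y"
  if (!is.null(mito)) {
    mito_kmers <- cpp_count_kmers(unname(as_sequences(mito)),
                                  as.integer(k), TRUE)$kmer
    mfrac <- cpp_kmerset_fraction(unname(seqs), mito_kmers, as.integer(k))
    bin[!is.na(mfrac) & mfrac >= thresholds$mito_fraction] <- "mitochondrial"
  }
  out <- data.frame(id = names(seqs), length = nchar(seqs), cq = cq$cq,
                    bin = bin, n_kmers_hit = ev$n_kmers_hit,
                    female_evidence = ev$female_evidence,
                    male_evidence = ev$male_evidence,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("long_read_bins", "data.frame")
  out
}

#' Call candidate X-linked k-mers
#'
#' A k-mer is a candidate X-kmer iff its own CQ lies inside the X window
#' and at least `x_hit_fraction` of its exact long-read occurrences fall
#' on X-binned reads. K-mers with no long-read occurrence are never
#' candidates (no positional evidence).
#'
#' @param census a filtered [kmer_census()] table.
#' @param reads the retained long reads (same set that was binned).
#' @param bins the [bin_long_reads()] output for `reads`.
#' @param thresholds a [linkage_thresholds()].
#' @return data frame: `kmer`, `cq`, `n_hits`, `n_hits_x`, `x_fraction`,
#'   `is_candidate`, plus the census count columns.
#' @export
call_x_kmers <- function(census, reads, bins,
                         thresholds = linkage_thresholds()) {
  stopifnot(inherits(census, "kmer_census"),
            inherits(bins, "long_read_bins"))
  seqs <- as_sequences(reads)
  if (length(seqs) != nrow(bins))
    stop("reads and bins disagree in length; pass the same read set")
  k <- attr(census, "k") %||% 25L
  cq <- compute_cq(census$female_norm, census$male_norm,
                   cap = thresholds$cq_cap)
  in_x_window <- !is.na(cq$cq) & !cq$capped &
    cq$cq >= thresholds$cq_x[1] & cq$cq <= thresholds$cq_x[2]
  pool <- census$kmer[in_x_window]
  n_hits <- n_hits_x <- setNames(numeric(length(pool)), pool)
  if (length(pool) && length(seqs)) {
    hits <- cpp_kmer_read_hits(unname(seqs), pool, as.integer(k))
    if (nrow(hits)) {
      on_x <- bins$bin[hits$seq] == "X"
      n_hits <- n_hits +
        tapply_sum(hits$count, pool[hits$kmer], pool)
      n_hits_x <- n_hits_x +
        tapply_sum(hits$count * on_x, pool[hits$kmer], pool)
    }
  }
  out <- census[, c("kmer", "male_count", "female_count", "combined_count")]
  out$cq <- cq$cq
  out$n_hits <- 0
  out$n_hits_x <- 0
  idx <- match(pool, out$kmer)
  out$n_hits[idx] <- n_hits
  out$n_hits_x[idx] <- n_hits_x
  out$x_fraction <- ifelse(out$n_hits > 0, out$n_hits_x / out$n_hits, NA)
  out$is_candidate <- in_x_window & out$n_hits > 0 &
    !is.na(out$x_fraction) & out$x_fraction >= thresholds$x_hit_fraction
  rownames(out) <- NULL
  out
}

# sum `values` grouped by `groups`, returned in the order of `levels`
# (0 for absent levels)
tapply_sum <- function(values, groups, levels) {
  s <- tapply(values, groups, sum)
  out <- setNames(numeric(length(levels)), levels)
  out[names(s)] <- s
  out
}
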