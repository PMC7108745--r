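#' Specify read simulation parameters
#'
#' Covers both the sexed short-read libraries (Illumina-like) and the
#' long-read set (error-corrected PacBio-like, 2-100 kb by default).
#' `depth` is the expected per-base coverage of a diploid (two-copy) locus,
#' so an X-linked position is covered at `depth` in females and `depth/2`
#' in hemizygous males -- the copy-number signal the chromosome quotient
#' measures.
#'
#' @param depth expected short-read coverage of a two-copy locus (> 0).
#' @param read_length short-read length in bp.
#' @param error_rate per-base substitution error rate of short reads.
#' @param n_long_reads number of long reads to simulate.
#' @param long_read_min,long_read_max bounds of the uniform long-read length
#'   distribution (bp); `min < max` required (or equal for fixed length).
#' @param long_error_rate per-base substitution error rate of long reads.
#' @param mito_copies mitochondrial copy number relative to one nuclear
#'   chromosome copy (applied in both sexes).
#' @param quality_q constant Phred score assigned to simulated bases.
#' @param seed integer seed.
#' @return an object of class `read_sim_spec`.
#' @export
read_sim_spec <- function(depth = 30, read_length = 100L, error_rate = 0.001,
                          n_long_reads = 300L, long_read_min = 2000L,
                          long_read_max = 100000L, long_error_rate = 0.002,
                          mito_copies = 2, quality_q = 38L, seed = 1L) {
  stopifnot(depth >= 0, read_length >= 20, error_rate >= 0, error_rate <= 1,
            n_long_reads >= 0, long_read_min <= long_read_max,
            long_read_min > 0, mito_copies >= 0)
  structure(list(depth = depth, read_length = as.integer(read_length),
                 error_rate = error_rate,
                 n_long_reads = as.integer(n_long_reads),
                 long_read_min = as.integer(long_read_min),
                 long_read_max = as.integer(long_read_max),
                 long_error_rate = long_error_rate,
                 mito_copies = mito_copies, quality_q = as.integer(quality_q),
                 seed = as.integer(seed)),
            class = "read_sim_spec")
}

# Per-chromosome copy numbers for one individual of the given sex.
chromosome_copies <- function(genome, sex, mito_copies) {
  chroms <- names(genome$seqs)
  copies <- setNames(rep(2, length(chroms)), chroms)
  copies["MT"] <- mito_copies
  if (sex == "male") {
    copies["X"] <- 1
    copies["Y"] <- 1
  } else {
    copies["Y"] <- 0
  }
  copies
}

#' Simulate a sexed short-read library
#'
#' Females contribute two X copies, two copies of each autosome and the
#' mitochondrion; males one X, one Y, two autosome copies and the
#' mitochondrion. Expected per-base coverage is proportional to copy
#' number, so female:male k-mer count ratios converge to 2 for X-linked,
#' 1 for autosomal and 0 for Y-linked sequence as depth grows.
#'
#' @param genome a `sim_genome` from [build_genome()].
#' @param sex `"male"` or `"female"`.
#' @param spec a [read_sim_spec()].
#' @return an object of class `sim_reads`: `reads` and `quals` (named
#'   character vectors) plus a `truth` data frame with the source
#'   chromosome, start and strand of every read.
#' @export
simulate_short_reads <- function(genome, sex = c("male", "female"),
                                 spec = read_sim_spec()) {
  sex <- match.arg(sex)
  stopifnot(inherits(genome, "sim_genome"), inherits(spec, "read_sim_spec"))
  withr::with_seed(spec$seed + ifelse(sex == "male", 0L, 1L), {
    copies <- chromosome_copies(genome, sex, spec$mito_copies)
    lens <- nchar(genome$seqs)
    usable <- copies > 0 & lens >= spec$read_length
    w <- lens[usable] * copies[usable]
    total_bases <- spec$depth * sum(lens * copies) / 2
    n_reads <- round(total_bases / spec$read_length)
    if (n_reads == 0) {
      warning("depth produces zero reads; returning an empty read set")
      out <- list(reads = character(), quals = character(),
                  truth = data.frame(id = character(), chrom = character(),
                                     start = integer(), strand = character(),
                                     stringsAsFactors = FALSE),
                  sex = sex, spec = spec)
      class(out) <- "sim_reads"
      return(out)
    }
    chrom <- sample(names(w), n_reads, replace = TRUE, prob = w)
    start <- floor(runif(n_reads) *
                     (lens[chrom] - spec$read_length + 1)) + 1L
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    reads <- substr(genome$seqs[chrom], start, start + spec$read_length - 1L)
    minus <- strand == "-"
    if (any(minus)) reads[minus] <- revcomp(reads[minus])
    reads <- add_substitution_errors(unname(reads), spec$error_rate)
    ids <- sprintf("%s_read%06d", sex, seq_len(n_reads))
    names(reads) <- ids
    out <- list(reads = reads,
                quals = setNames(constant_quality(nchar(reads), spec$quality_q), ids),
                truth = data.frame(id = ids, chrom = unname(chrom),
                                   start = unname(start), strand = strand,
                                   stringsAsFactors = FALSE),
                sex = sex, spec = spec)
    class(out) <- "sim_reads"
    out
  })
}

#' Simulate a long-read set
#'
#' Reads are drawn from chromosomes in proportion to chromosome length
#' (restricted to chromosomes at least `long_read_min` bp long), with
#' lengths uniform between the configured bounds and truncated at the
#' chromosome length. The source chromosome of every read is recorded in
#' the truth table.
#'
#' @inheritParams simulate_short_reads
#' @return a `sim_reads` object; `truth` records the provenance chromosome.
#' @export
simulate_long_reads <- function(genome, spec = read_sim_spec()) {
  stopifnot(inherits(genome, "sim_genome"), inherits(spec, "read_sim_spec"))
  withr::with_seed(spec$seed + 2L, {
    lens <- nchar(genome$seqs)
    usable <- lens >= spec$long_read_min
    if (!any(usable)) stop("no chromosome is as long as long_read_min")
    w <- lens[usable]
    n <- spec$n_long_reads
    chrom <- sample(names(w), n, replace = TRUE, prob = w)
    want <- floor(runif(n) *
                    (spec$long_read_max - spec$long_read_min + 1)) +
      spec$long_read_min
    rlen <- pmin(want, lens[chrom])
    start <- floor(runif(n) * (lens[chrom] - rlen + 1)) + 1L
    strand <- sample(c("+", "-"), n, replace = TRUE)
    reads <- substr(genome$seqs[chrom], start, start + rlen - 1L)
    minus <- strand == "-"
    if (any(minus)) reads[minus] <- revcomp(reads[minus])
    reads <- add_substitution_errors(unname(reads), spec$long_error_rate)
    ids <- sprintf("long_read%05d", seq_len(n))
    names(reads) <- ids
    out <- list(reads = reads, quals = NULL,
                truth = data.frame(id = ids, chrom = unname(chrom),
                                   start = unname(start),
                                   length = nchar(reads), strand = strand,
                                   stringsAsFactors = FALSE),
                sex = "male", spec = spec)
    class(out) <- "sim_reads"
    out
  })
}

#' @export
print.sim_reads <- function(x, ...) {
  cat("sim_reads:", length(x$reads), "reads,",
      sum(nchar(x$reads)), "bases\n")
  invisible(x)
}
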