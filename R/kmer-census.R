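#' Census thresholds
#'
#' Minimum-abundance rule of the k-mer census: a k-mer is retained only if
#' its combined count over the male and female libraries is at least
#' `min_combined_count` (default 4, i.e. k-mers occurring fewer than 4
#' times in the combined data are excluded).
#'
#' @param min_combined_count minimum combined male+female count (>= 1).
#' @param k k-mer length (default 25).
#' @return an object of class `census_thresholds`.
#' @export
census_thresholds <- function(min_combined_count = 4L, k = 25L) {
  stopifnot(min_combined_count >= 1, k >= 11)
  structure(list(min_combined_count = as.integer(min_combined_count),
                 k = as.integer(k)),
            class = "census_thresholds")
}

#' Count k-mers of a read set
#'
#' Every k-length window of every read is counted exactly once; windows
#' containing non-ACGT characters are skipped. In canonical mode (the
#' default) a k-mer and its reverse complement share one record, keyed by
#' the lexicographically smaller of the two -- appropriate for unstranded
#' sequencing.
#'
#' @param reads a `sim_reads` object, `DNAStringSet`, character vector of
#'   sequences, or a FASTQ/FASTA file path.
#' @param k k-mer length (>= 11, <= 31).
#' @param canonical merge a k-mer with its reverse complement.
#' @return data frame with columns `kmer` and `count`, sorted by `kmer`.
#' @export
count_kmers <- function(reads, k = 25L, canonical = TRUE) {
  stopifnot(k >= 11, k <= 31)
  seqs <- as_sequences(reads)
  tab <- cpp_count_kmers(unname(seqs), as.integer(k), canonical)
  out <- data.frame(kmer = tab$kmer, count = tab$count,
                    stringsAsFactors = FALSE)
  out <- out[order(out$kmer), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Joint male/female k-mer census
#'
#' Counts k-mers in each sexed library and joins them into one table with
#' per-sex raw counts, the combined count, and per-sex normalized counts
#' (occurrences per million sequenced bases, so libraries of unequal depth
#' are comparable and the chromosome quotient has a stated normalization).
#'
#' @param male_reads,female_reads read sets (see [count_kmers()]).
#' @param k k-mer length.
#' @param canonical merge reverse complements (default `TRUE`).
#' @return data frame of class `kmer_census` with columns `kmer`,
#'   `male_count`, `female_count`, `combined_count`, `male_norm`,
#'   `female_norm`; library sizes are kept in attributes `male_bases` and
#'   `female_bases`.
#' @export
kmer_census <- function(male_reads, female_reads, k = 25L, canonical = TRUE) {
  mseq <- as_sequences(male_reads)
  fseq <- as_sequences(female_reads)
  m <- count_kmers(mseq, k, canonical)
  f <- count_kmers(fseq, k, canonical)
  names(m)[2] <- "male_count"
  names(f)[2] <- "female_count"
  tab <- merge(m, f, by = "kmer", all = TRUE)
  tab$male_count[is.na(tab$male_count)] <- 0
  tab$female_count[is.na(tab$female_count)] <- 0
  tab$combined_count <- tab$male_count + tab$female_count
  male_bases <- sum(nchar(mseq))
  female_bases <- sum(nchar(fseq))
  tab$male_norm <- tab$male_count / (male_bases / 1e6)
  tab$female_norm <- tab$female_count / (female_bases / 1e6)
  tab <- tab[order(tab$kmer), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "male_bases") <- male_bases
  attr(tab, "female_bases") <- female_bases
  attr(tab, "k") <- as.integer(k)
  attr(tab, "canonical") <- canonical
  class(tab) <- c("kmer_census", "data.frame")
  tab
}

#' Remove mitochondrial signal
#'
#' Removes any k-mer (or any read containing a k-mer) that exactly matches
#' the mitochondrial reference on either strand.
#'
#' @param x a `kmer_census` table, a plain k-mer count table, or a read set
#'   (`sim_reads`, `DNAStringSet`, character vector, file path).
#' @param mito mitochondrial reference: sequence(s) or FASTA path.
#' @param k k-mer length; defaults to the census attribute or 25.
#' @return list with `kept` (same type as `x`), `removed` and `n_removed`.
#' @export
filter_mitochondrial <- function(x, mito, k = NULL) {
  if (is.character(mito) && length(mito) == 1 && !file.exists(mito) &&
      grepl("\\.(fa|fasta|fna)(\\.gz)?$", mito))
    stop("mitochondrial reference file not found: ", mito)
  mito_seqs <- as_sequences(mito)
  if (length(mito_seqs) == 0 || all(nchar(mito_seqs) == 0))
    stop("mitochondrial reference is empty")
  if (is.data.frame(x)) {
    if (is.null(k)) k <- attr(x, "k") %||% 25L
    mito_kmers <- cpp_count_kmers(unname(mito_seqs), as.integer(k), TRUE)$kmer
    hit <- canonical_kmers(x$kmer) %in% mito_kmers
    kept <- x[!hit, , drop = FALSE]
    attributes(kept) <- c(attributes(kept),
                          attributes(x)[setdiff(names(attributes(x)),
                                                names(attributes(kept)))])
    list(kept = kept, removed = x[hit, , drop = FALSE], n_removed = sum(hit))
  } else {
    if (is.null(k)) k <- 25L
    seqs <- as_sequences(x)
    mito_kmers <- cpp_count_kmers(unname(mito_seqs), as.integer(k), TRUE)$kmer
    frac <- cpp_kmerset_fraction(unname(seqs), mito_kmers, as.integer(k))
    hit <- !is.na(frac) & frac > 0
    list(kept = seqs[!hit], removed = seqs[hit], n_removed = sum(hit))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply the minimum-abundance filter
#'
#' Retains a k-mer iff its combined male+female count is at least the
#' census threshold.
#'
#' @param census a `kmer_census` table.
#' @param thresholds a [census_thresholds()].
#' @return the filtered census table.
#' @export
apply_min_count <- function(census, thresholds = census_thresholds()) {
  stopifnot(inherits(thresholds, "census_thresholds"),
            "combined_count" %in% names(census))
  out <- census[census$combined_count >= thresholds$min_combined_count, ,
                drop = FALSE]
  rownames(out) <- NULL
  out
}
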