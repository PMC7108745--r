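#' Selection thresholds for shortlisting gRNA target k-mers
#'
#' Cutoffs of the final target shortlist: abundance in the combined
#' male+female short-read data above `10^illumina_log10` occurrences,
#' abundance in the long-read data above `10^pacbio_log10` reads, maximum
#' exact k-mer hits per long read strictly greater than
#' `max_hits_per_read` (an estimate of local repeat size; the non-integer
#' default 7.5 is applied to the raw per-read maximum), at least
#' `min_perfect_hits` perfect hits to an assembled genome (when an
#' assembly is available), and at most `max_offtargets` off-target hits in
#' the autosomal/Y long-read bins.
#'
#' @param illumina_log10 cutoff on log10 combined Illumina count (strict >).
#' @param pacbio_log10 cutoff on log10 number of long reads containing the
#'   k-mer (strict >).
#' @param max_hits_per_read cutoff on the maximum exact hits in any single
#'   long read (strict >).
#' @param min_perfect_hits minimum perfect assembly hits (>=).
#' @param max_offtargets maximum allowed off-target hits (<=).
#' @return an object of class `selection_thresholds`.
#' @export
selection_thresholds <- function(illumina_log10 = 2, pacbio_log10 = 1,
                                 max_hits_per_read = 7.5,
                                 min_perfect_hits = 5L, max_offtargets = 0L) {
  stopifnot(illumina_log10 >= 0, pacbio_log10 >= 0, max_hits_per_read >= 0,
            min_perfect_hits >= 0, max_offtargets >= 0)
  structure(list(illumina_log10 = illumina_log10,
                 pacbio_log10 = pacbio_log10,
                 max_hits_per_read = max_hits_per_read,
                 min_perfect_hits = as.integer(min_perfect_hits),
                 max_offtargets = as.integer(max_offtargets)),
            class = "selection_thresholds")
}

#' Scan a k-mer for Cas9 PAM placements
#'
#' Reports every window of the form \[20-nt spacer\]\[NGG\] on either
#' strand of each input sequence. A 25-mer yields at most 3 forward and 3
#' reverse placements. Offsets are 1-based spacer starts in the scanned
#' orientation (the reverse complement for `strand == "-"`).
#'
#' @param kmers character vector of sequences (each >= 23 nt).
#' @return data frame: `kmer`, `spacer`, `pam`, `strand`, `offset`.
#' @export
scan_pam_sites <- function(kmers) {
  kmers <- toupper(kmers)
  stopifnot(all(nchar(kmers) >= 23))
  scan_one_strand <- function(seq, strand) {
    n <- nchar(seq)
    starts <- seq_len(n - 22L)
    pam <- substring(seq, starts + 20L, starts + 22L)
    ok <- substring(pam, 2, 3) == "GG"
    if (!any(ok)) return(NULL)
    data.frame(spacer = substring(seq, starts[ok], starts[ok] + 19L),
               pam = pam[ok], strand = strand, offset = starts[ok],
               stringsAsFactors = FALSE)
  }
  out <- lapply(seq_along(kmers), function(i) {
    fwd <- scan_one_strand(kmers[i], "+")
    rev <- scan_one_strand(revcomp(kmers[i]), "-")
    res <- rbind(fwd, rev)
    if (is.null(res)) return(NULL)
    cbind(data.frame(kmer = kmers[i], stringsAsFactors = FALSE), res)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(kmer = character(), spacer = character(),
                      pam = character(), strand = character(),
                      offset = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Count off-target hits of a protospacer
#'
#' Counts occurrences of \[spacer\]\[NGG\] with at most `max_mismatches`
#' mismatches in the spacer (the PAM must remain NGG) on either strand of
#' the off-target reference -- by construction the autosomal- and Y-binned
#' long reads, so a hit is evidence the target is not X-confined.
#'
#' @param spacers character vector of 20-nt protospacers.
#' @param reference off-target reference sequences (character,
#'   `DNAStringSet`, `sim_reads` or file path).
#' @param max_mismatches spacer mismatch tolerance (default 4).
#' @return integer vector of hit counts, one per spacer.
#' @export
count_offtargets <- function(spacers, reference, max_mismatches = 4L) {
  seqs <- as_sequences(reference)
  if (length(seqs) == 0) {
    warning("empty off-target reference; reporting 0 hits")
    return(integer(length(spacers)))
  }
  vapply(spacers, function(sp) {
    sum(cpp_offtarget_hits(unname(seqs), sp, as.integer(max_mismatches)))
  }, 0L, USE.NAMES = FALSE)
}

#' Abundance metrics of candidate k-mers
#'
#' For each k-mer: the maximum number of exact occurrences (both strands)
#' in any single long read (`max_hits_per_long_read`, estimating local
#' repeat array size), the number of long reads containing the k-mer at
#' least once (`n_long_reads_with_hit`, estimating repeat abundance across
#' the chromosome), and log10-scaled coverages -- log10 of the combined
#' male+female short-read count and log10 of the long-read count.
#'
#' @param kmers character vector of k-mers (equal length).
#' @param long_reads the retained long-read set.
#' @param census a [kmer_census()] table providing combined counts.
#' @return data frame: `kmer`, `max_hits_per_long_read`,
#'   `n_long_reads_with_hit`, `illumina_log10_coverage`,
#'   `pacbio_log10_coverage`.
#' @export
compute_abundance_metrics <- function(kmers, long_reads, census) {
  stopifnot(length(unique(nchar(kmers))) <= 1)
  seqs <- as_sequences(long_reads)
  k <- unique(nchar(kmers))
  maxh <- setNames(numeric(length(kmers)), kmers)
  nread <- setNames(numeric(length(kmers)), kmers)
  if (length(kmers) && length(seqs)) {
    hits <- cpp_kmer_read_hits(unname(seqs), kmers, as.integer(k))
    if (nrow(hits)) {
      mx <- tapply(hits$count, kmers[hits$kmer], max)
      nr <- tapply(rep(1L, nrow(hits)), kmers[hits$kmer], sum)
      maxh[names(mx)] <- mx
      nread[names(nr)] <- nr
    }
  }
  comb <- census$combined_count[match(canonical_kmers(kmers),
                                      canonical_kmers(census$kmer))]
  comb[is.na(comb)] <- 0
  data.frame(kmer = kmers,
             max_hits_per_long_read = unname(maxh),
             n_long_reads_with_hit = unname(nread),
             illumina_log10_coverage = log10(comb),
             pacbio_log10_coverage = log10(unname(nread)),
             stringsAsFactors = FALSE)
}

#' Count perfect assembly hits
#'
#' Exact-match occurrences of each k-mer (both strands) across all
#' sequences of a genome assembly. This validation stage is optional: with
#' `assembly = NULL` it returns `NA` so the criterion can be marked
#' not-evaluated.
#'
#' @param kmers character vector of equal-length k-mers.
#' @param assembly assembly sequences (character, `DNAStringSet` or FASTA
#'   path), or `NULL`.
#' @return numeric vector of perfect-hit counts (`NA` if no assembly).
#' @export
count_perfect_hits <- function(kmers, assembly) {
  if (is.null(assembly)) {
    message("no assembly configured; perfect-hit criterion not evaluated")
    return(rep(NA_real_, length(kmers)))
  }
  seqs <- as_sequences(assembly)
  k <- unique(nchar(kmers))
  stopifnot(length(k) == 1)
  out <- setNames(numeric(length(kmers)), kmers)
  hits <- cpp_kmer_read_hits(unname(seqs), kmers, as.integer(k))
  if (nrow(hits)) {
    s <- tapply(hits$count, kmers[hits$kmer], sum)
    out[names(s)] <- s
  }
  unname(out)
}

#' Apply the target-selection filters
#'
#' The verdict is the conjunction of per-criterion checks: log10 Illumina
#' coverage and log10 long-read coverage above their cutoffs (strict >),
#' maximum hits per long read strictly above its cutoff, perfect assembly
#' hits at least the minimum (skipped with a not-evaluated flag when the
#' metric is `NA` because no assembly was configured), and off-target
#' count at most the maximum. A missing (`NA`) value in any other metric
#' is an error, never a silent fail.
#'
#' @param targets data frame with columns `illumina_log10_coverage`,
#'   `pacbio_log10_coverage`, `max_hits_per_long_read`,
#'   `perfect_assembly_hits`, `offtarget_hits` (e.g. assembled from
#'   [compute_abundance_metrics()], [count_perfect_hits()] and
#'   [count_offtargets()]).
#' @param thresholds a [selection_thresholds()].
#' @return `targets` with per-criterion logical columns `pass_illumina`,
#'   `pass_pacbio`, `pass_max_hits`, `pass_perfect` (`NA` when not
#'   evaluated), `pass_offtarget` and the overall `pass`.
#' @export
apply_selection_filters <- function(targets,
                                    thresholds = selection_thresholds()) {
  stopifnot(inherits(thresholds, "selection_thresholds"))
  need <- c("illumina_log10_coverage", "pacbio_log10_coverage",
            "max_hits_per_long_read", "perfect_assembly_hits",
            "offtarget_hits")
  miss <- setdiff(need, names(targets))
  if (length(miss))
    stop("incomplete target records; missing metric(s): ",
         paste(miss, collapse = ", "))
  for (col in setdiff(need, "perfect_assembly_hits"))
    if (anyNA(targets[[col]]))
      stop("incomplete target records; NA in metric: ", col)
  targets$pass_illumina <-
    targets$illumina_log10_coverage > thresholds$illumina_log10
  targets$pass_pacbio <-
    targets$pacbio_log10_coverage > thresholds$pacbio_log10
  targets$pass_max_hits <-
    targets$max_hits_per_long_read > thresholds$max_hits_per_read
  targets$pass_perfect <- ifelse(
    is.na(targets$perfect_assembly_hits), NA,
    targets$perfect_assembly_hits >= thresholds$min_perfect_hits)
  targets$pass_offtarget <- targets$offtarget_hits <= thresholds$max_offtargets
  evaluated <- cbind(targets$pass_illumina, targets$pass_pacbio,
                     targets$pass_max_hits, targets$pass_offtarget)
  targets$pass <- apply(evaluated, 1, all) &
    (is.na(targets$pass_perfect) | targets$pass_perfect)
  targets
}

#' Greedy zero-mismatch contig assembly of k-mers
#'
#' Re-assembles a candidate k-mer set into longer contigs to reveal
#' higher-order repeat structure: repeatedly merges the pair of contigs
#' with the longest exact suffix-prefix overlap (at least `min_overlap`,
#' zero mismatches), breaking ties toward the lexicographically smaller
#' merged sequence, until no pair overlaps. A contig fully contained in
#' another is absorbed. Every input k-mer ends up in exactly one contig
#' (singletons allowed).
#'
#' @param kmers character vector of k-mers (duplicates are collapsed).
#' @param min_overlap minimum exact overlap (>= 10, <= k).
#' @return data frame: `contig`, `length`, `n_members`, `members`
#'   (comma-separated input k-mers).
#' @export
assemble_contigs <- function(kmers, min_overlap = 10L) {
  kmers <- unique(toupper(kmers))
  stopifnot(length(kmers) >= 1, min_overlap >= 10,
            min_overlap <= min(nchar(kmers)))
  contigs <- kmers
  members <- as.list(kmers)

  best_overlap <- function(a, b) {
    # longest ov with suffix(a, ov) == prefix(b, ov); containment counts as
    # an overlap of nchar(b)
    if (a != b && grepl(b, a, fixed = TRUE)) return(nchar(b))
    top <- min(nchar(a), nchar(b)) - 1L
    if (top < min_overlap) return(0L)
    for (ov in seq(top, min_overlap, by = -1L)) {
      if (substr(a, nchar(a) - ov + 1L, nchar(a)) == substr(b, 1L, ov))
        return(ov)
    }
    0L
  }

  repeat {
    n <- length(contigs)
    if (n < 2) break
    best <- list(ov = 0L, i = 0L, j = 0L, merged = "")
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      ov <- best_overlap(contigs[i], contigs[j])
      if (ov < min_overlap) next
      merged <- if (ov == nchar(contigs[j]) &&
                    grepl(contigs[j], contigs[i], fixed = TRUE))
        contigs[i]
      else paste0(contigs[i], substr(contigs[j], ov + 1L, nchar(contigs[j])))
      if (ov > best$ov || (ov == best$ov && merged < best$merged)) {
        best <- list(ov = ov, i = i, j = j, merged = merged)
      }
    }
    if (best$ov < min_overlap) break
    keep <- setdiff(seq_len(n), c(best$i, best$j))
    members <- c(members[keep],
                 list(c(members[[best$i]], members[[best$j]])))
    contigs <- c(contigs[keep], best$merged)
  }
  out <- data.frame(contig = contigs, length = nchar(contigs),
                    n_members = lengths(members),
                    members = vapply(members, paste, "", collapse = ","),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$length, out$contig), , drop = FALSE]
  rownames(out) <- NULL
  out
}
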