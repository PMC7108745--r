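#' Allele-calling thresholds
#'
#' @param min_mean_quality minimum mean read quality (Phred+33; reads with
#'   mean quality below 30 are dropped by default, inclusive at 30).
#' @param min_freq minimum allele frequency for the allele census
#'   (default 1\%).
#' @param min_reads minimum read count for the allele census (default 10).
#' @return an object of class `allele_thresholds`.
#' @export
allele_thresholds <- function(min_mean_quality = 30, min_freq = 0.01,
                              min_reads = 10L) {
  stopifnot(min_mean_quality >= 0, min_freq >= 0, min_reads >= 0)
  structure(list(min_mean_quality = min_mean_quality, min_freq = min_freq,
                 min_reads = as.integer(min_reads)),
            class = "allele_thresholds")
}

#' Mean-quality read filter
#'
#' Retains reads whose mean base quality (Phred+33) is at least the
#' threshold (inclusive: a uniform Q30 read passes at threshold 30).
#'
#' @param reads a `sim_reads` object (with `quals`), or a character vector
#'   of sequences with `quals` supplied.
#' @param min_mean_quality minimum mean Phred score.
#' @param quals quality strings, if `reads` is a plain character vector.
#' @return a `sim_reads`-style list (`reads`, `quals`) with attributes
#'   `n_input` and `n_retained`.
#' @export
quality_filter <- function(reads, min_mean_quality = 30, quals = NULL) {
  if (inherits(reads, "sim_reads")) {
    quals <- reads$quals
    seqs <- reads$reads
  } else {
    seqs <- reads
  }
  if (is.null(quals)) stop("quality strings required")
  stopifnot(length(seqs) == length(quals))
  if (length(seqs) == 0) {
    out <- structure(list(reads = seqs, quals = quals), class = "sim_reads")
    attr(out, "n_input") <- 0L
    attr(out, "n_retained") <- 0L
    return(out)
  }
  keep <- phred_means(quals) >= min_mean_quality
  out <- structure(list(reads = seqs[keep], quals = quals[keep]),
                   class = "sim_reads")
  attr(out, "n_input") <- length(seqs)
  attr(out, "n_retained") <- sum(keep)
  out
}

# Global alignment parameters shared by allele extraction.
align_params <- function() {
  list(mat = Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                      mismatch = -3),
       gap_open = 5, gap_ext = 2)
}

# Slice the aligned pattern over reference positions [from, to].
# p, s: equal-length character vectors of aligned pattern/subject chars.
# refpos: reference position per column (0 before the first subject char).
# Returns list(core = window with '-' for deletions,
#              ins = data.frame(rel, seq) of insertions anchored inside).
aligned_slice <- function(p, s, refpos, from, to) {
  in_win <- s != "-" & refpos >= from & refpos <= to
  core <- paste(p[in_win], collapse = "")
  ins_cols <- which(s == "-" & refpos >= from & refpos <= to - 1L)
  ins <- NULL
  if (length(ins_cols)) {
    anchors <- refpos[ins_cols]
    split_seq <- split(p[ins_cols], anchors)
    ins <- data.frame(rel = as.integer(names(split_seq)) - from + 1L,
                      seq = vapply(split_seq, paste, "", collapse = ""),
                      stringsAsFactors = FALSE)
  }
  list(core = core, ins = ins)
}

# Rebuild the literal subsequence of a slice: kept bases with insertions
# inlined at their anchors (gap characters dropped).
slice_sequence <- function(slice) {
  core <- strsplit(slice$core, "", fixed = TRUE)[[1]]
  out <- character(0)
  for (r in seq_along(core)) {
    if (core[r] != "-") out <- c(out, core[r])
    if (!is.null(slice$ins)) {
      hit <- slice$ins$rel == r
      if (any(hit)) out <- c(out, slice$ins$seq[hit])
    }
  }
  paste(out, collapse = "")
}

# Left-align insertion anchors within the window: inserting S after position
# a is the same haplotype as inserting rotate(S) after a-1 whenever the
# reference base at a equals the last base of S. Normalizing makes the
# allele key invariant to the aligner's gap placement.
left_align_insertions <- function(slice, ref_chars) {
  if (is.null(slice$ins) || nrow(slice$ins) == 0) return(slice)
  for (i in seq_len(nrow(slice$ins))) {
    rel <- slice$ins$rel[i]
    seq <- strsplit(slice$ins$seq[i], "", fixed = TRUE)[[1]]
    while (rel >= 1 && ref_chars[rel] == seq[length(seq)]) {
      seq <- c(seq[length(seq)], seq[-length(seq)])
      rel <- rel - 1L
    }
    slice$ins$rel[i] <- rel
    slice$ins$seq[i] <- paste(seq, collapse = "")
  }
  agg <- stats::aggregate(seq ~ rel, data = slice$ins,
                          FUN = paste, collapse = "")
  slice$ins <- agg[order(agg$rel), , drop = FALSE]
  slice
}

# Canonical allele key: window slice (with '-' for deleted positions)
# followed by "+<rel>:<seq>" for each insertion, ordered by position.
allele_key <- function(slice) {
  key <- slice$core
  if (!is.null(slice$ins) && nrow(slice$ins)) {
    ins <- slice$ins[order(slice$ins$rel), , drop = FALSE]
    key <- paste0(key, paste0("+", ins$rel, ":", ins$seq, collapse = ""))
  }
  key
}

split_allele_key <- function(key) {
  parts <- strsplit(key, "+", fixed = TRUE)[[1]]
  core <- parts[1]
  ins <- NULL
  if (length(parts) > 1) {
    kv <- strsplit(parts[-1], ":", fixed = TRUE)
    ins <- data.frame(rel = as.integer(vapply(kv, `[`, "", 1)),
                      seq = vapply(kv, `[`, "", 2),
                      stringsAsFactors = FALSE)
  }
  list(core = core, ins = ins)
}

#' Extract target-window alleles from amplicon reads
#'
#' Globally aligns each read to the reference amplicon (affine gaps) and
#' reports the aligned slice over the target window as the read's allele:
#' deletions appear as `-` at the deleted reference positions and
#' insertions are recorded against the reference position they follow
#' (left-aligned by the alignment, so equivalent indels collapse to one
#' allele). Reads whose alignment identity outside the window falls below
#' `min_flank_identity` are flagged unalignable and excluded from all
#' denominators. When the spec defines a linked marker locus, each read's
#' marker state (`ref`, `alt` or `other`) is called from the same
#' alignment.
#'
#' Identical reads are aligned once and the result reused, which makes
#' deep amplicon data cheap to process.
#'
#' @param reads quality-filtered reads (`sim_reads` or character vector).
#' @param spec an [amplicon_spec()].
#' @param min_flank_identity minimum identity of the alignment outside the
#'   target window for a read to count as alignable.
#' @return data frame of class `allele_calls`: `id`, `allele`,
#'   `alignable`, `flank_identity`, `intact` and (if a marker is defined)
#'   `marker_state`; the spec is kept as attribute `spec`.
#' @export
extract_alleles <- function(reads, spec, min_flank_identity = 0.75) {
  stopifnot(inherits(spec, "amplicon_spec"))
  seqs <- if (inherits(reads, "sim_reads")) reads$reads else reads
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("read", seq_along(seqs))
  empty <- data.frame(id = character(), allele = character(),
                      alignable = logical(), flank_identity = numeric(),
                      intact = logical(), stringsAsFactors = FALSE)
  if (length(seqs) == 0) {
    attr(empty, "spec") <- spec
    class(empty) <- c("allele_calls", "data.frame")
    return(empty)
  }
  uniq <- unique(unname(seqs))
  par <- align_params()
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(uniq), Biostrings::DNAString(spec$reference),
    type = "global", substitutionMatrix = par$mat,
    gapOpening = par$gap_open, gapExtension = par$gap_ext)
  pat <- as.character(Biostrings::alignedPattern(aln))
  sub <- as.character(Biostrings::alignedSubject(aln))
  refwin <- reference_window(spec)
  refwin_chars <- strsplit(refwin, "", fixed = TRUE)[[1]]
  has_marker <- !is.null(spec$marker)
  if (has_marker) {
    # compare reconstructed sequence over a padded marker context, so the
    # call is invariant to where the aligner places an ambiguous indel
    pad <- 10L
    m_from <- max(1L, spec$marker$start - pad)
    m_to <- min(nchar(spec$reference), spec$marker$end + pad)
    exp_ref <- substr(spec$reference, m_from, m_to)
    exp_alt <- paste0(substr(spec$reference, m_from, spec$marker$start - 1L),
                      spec$marker$alt,
                      substr(spec$reference, spec$marker$end + 1L, m_to))
  }

  n <- length(uniq)
  allele <- character(n)
  flank_id <- numeric(n)
  marker_state <- character(n)
  for (i in seq_len(n)) {
    p <- strsplit(pat[i], "", fixed = TRUE)[[1]]
    s <- strsplit(sub[i], "", fixed = TRUE)[[1]]
    refpos <- cumsum(s != "-")
    slice <- aligned_slice(p, s, refpos, spec$window_start, spec$window_end)
    slice <- left_align_insertions(slice, refwin_chars)
    allele[i] <- allele_key(slice)
    out_cols <- s != "-" & (refpos < spec$window_start |
                              refpos > spec$window_end)
    flank_id[i] <- if (any(out_cols)) mean(p[out_cols] == s[out_cols]) else 0
    if (has_marker) {
      m <- aligned_slice(p, s, refpos, m_from, m_to)
      obs <- slice_sequence(m)
      marker_state[i] <- if (obs == exp_ref) "ref" else
        if (obs == exp_alt) "alt" else "other"
    }
  }
  idx <- match(unname(seqs), uniq)
  out <- data.frame(id = ids, allele = allele[idx],
                    alignable = flank_id[idx] >= min_flank_identity,
                    flank_identity = flank_id[idx],
                    intact = allele[idx] == refwin,
                    stringsAsFactors = FALSE)
  out$intact <- out$intact & out$alignable
  if (has_marker) out$marker_state <- marker_state[idx]
  rownames(out) <- NULL
  attr(out, "spec") <- spec
  class(out) <- c("allele_calls", "data.frame")
  out
}

#' Tally alleles of one sample
#'
#' @param calls an `allele_calls` data frame from [extract_alleles()].
#' @param sample sample identifier.
#' @return data frame of class `allele_tally`: `sample`, `allele`,
#'   `count`, `freq` (normalized over alignable reads, summing to 1).
#' @export
tally_alleles <- function(calls, sample = "sample") {
  ok <- calls[calls$alignable, , drop = FALSE]
  if (nrow(ok) == 0) {
    out <- data.frame(sample = character(), allele = character(),
                      count = integer(), freq = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    tab <- table(ok$allele)
    out <- data.frame(sample = sample, allele = names(tab),
                      count = as.integer(tab),
                      freq = as.integer(tab) / nrow(ok),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$count, out$allele), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "spec") <- attr(calls, "spec")
  class(out) <- c("allele_tally", "data.frame")
  out
}

#' Intact-target fraction
#'
#' Fraction of alignable reads whose target window matches the reference
#' protospacer + PAM exactly (no substitution, no indel). Undefined (`NA`)
#' when there are no alignable reads.
#'
#' @param x an `allele_calls` or `allele_tally` object.
#' @param spec the [amplicon_spec()]; defaults to the attribute carried by
#'   `x`.
#' @return a single fraction in \[0, 1\], or `NA`.
#' @export
intact_fraction <- function(x, spec = attr(x, "spec")) {
  stopifnot(inherits(spec, "amplicon_spec"))
  refwin <- reference_window(spec)
  if (inherits(x, "allele_tally")) {
    if (nrow(x) == 0) return(NA_real_)
    return(sum(x$freq[x$allele == refwin]))
  }
  ok <- x[x$alignable, , drop = FALSE]
  if (nrow(ok) == 0) return(NA_real_)
  mean(ok$allele == refwin)
}

#' Unique-allele census
#'
#' Counts unique alleles under the two census criteria: alleles at
#' frequency >= `min_freq` of all reads, and alleles represented by
#' >= `min_reads` reads. Reported both including and excluding the
#' wild-type (reference-window) allele.
#'
#' @param tally an `allele_tally`.
#' @param thresholds an [allele_thresholds()].
#' @param spec the [amplicon_spec()]; defaults to the attribute of `tally`.
#' @return data frame with one row per criterion (`freq`, `reads`) and
#'   counts `n_incl_wildtype`, `n_excl_wildtype`.
#' @export
census_alleles <- function(tally, thresholds = allele_thresholds(),
                           spec = attr(tally, "spec")) {
  stopifnot(inherits(thresholds, "allele_thresholds"),
            inherits(spec, "amplicon_spec"))
  refwin <- reference_window(spec)
  wt <- tally$allele == refwin
  by_freq <- tally$freq >= thresholds$min_freq
  by_reads <- tally$count >= thresholds$min_reads
  data.frame(criterion = c("freq", "reads"),
             threshold = c(thresholds$min_freq, thresholds$min_reads),
             n_incl_wildtype = c(sum(by_freq), sum(by_reads)),
             n_excl_wildtype = c(sum(by_freq & !wt), sum(by_reads & !wt)),
             stringsAsFactors = FALSE)
}

#' Classify alleles as intact, pre-existing or de-novo
#'
#' An allele present (above the noise floor) in every control sample is a
#' pre-existing variant; an allele absent from all controls but present in
#' at least one experimental sample is de-novo (putatively
#' CRISPR-induced); the reference window is intact. Alleles seen in some
#' but not all controls, or nowhere above the floor, are labelled
#' ambiguous.
#'
#' @param tallies a list of `allele_tally` objects, or one combined tally
#'   data frame with a `sample` column.
#' @param controls character vector of control sample ids (>= 1 required).
#' @param spec the [amplicon_spec()]; defaults to the attribute of the
#'   first tally.
#' @param noise_min_reads,noise_min_frac presence floor: an allele counts
#'   as observed in a sample when it has at least `noise_min_reads` reads
#'   and at least `noise_min_frac` of the sample's reads.
#' @return data frame: `allele`, `class`, `n_controls_present`,
#'   `n_experimental_present`.
#' @export
classify_alleles <- function(tallies, controls, spec = NULL,
                             noise_min_reads = 2L, noise_min_frac = 0.001) {
  if (inherits(tallies, "allele_tally")) tallies <- list(tallies)
  if (is.list(tallies) && !is.data.frame(tallies)) {
    if (is.null(spec)) spec <- attr(tallies[[1]], "spec")
    tallies <- do.call(rbind, lapply(tallies, as.data.frame))
  }
  stopifnot(is.data.frame(tallies), "sample" %in% names(tallies))
  if (length(controls) < 1 || !any(tallies$sample %in% controls))
    stop("allele classification requires at least one designated control sample")
  stopifnot(inherits(spec, "amplicon_spec"))
  refwin <- reference_window(spec)
  samples <- unique(tallies$sample)
  ctrl <- intersect(samples, controls)
  expt <- setdiff(samples, controls)
  present <- tallies$count >= noise_min_reads & tallies$freq >= noise_min_frac
  alleles <- unique(tallies$allele)
  n_ctrl <- vapply(alleles, function(a) {
    length(unique(tallies$sample[tallies$allele == a & present &
                                   tallies$sample %in% ctrl]))
  }, 0L)
  n_expt <- vapply(alleles, function(a) {
    length(unique(tallies$sample[tallies$allele == a & present &
                                   tallies$sample %in% expt]))
  }, 0L)
  cls <- ifelse(alleles == refwin, "intact",
                ifelse(n_ctrl == length(ctrl) & n_ctrl > 0,
                       "pre-existing-variant",
                       ifelse(n_ctrl == 0 & n_expt > 0, "de-novo",
                              "ambiguous")))
  data.frame(allele = alleles, class = unname(cls),
             n_controls_present = unname(n_ctrl),
             n_experimental_present = unname(n_expt),
             stringsAsFactors = FALSE)
}

#' Flag cleavage-resistant alleles
#'
#' An allele is predicted cleavage-resistant when its PAM is no longer
#' NGG, when it carries at least one substitution in the seed region (the
#' PAM-proximal `seed_length` protospacer positions), or when the window
#' carries an indel. A substitution confined to the PAM-distal spacer with
#' an intact PAM is tolerated by Cas9 and not flagged.
#'
#' @param alleles character vector of allele keys (from
#'   [extract_alleles()]).
#' @param spec the [amplicon_spec()].
#' @param seed_length PAM-proximal seed length (default 10 nt).
#' @return data frame: `allele`, `resistant`, `pam_mutated`,
#'   `seed_substitutions`, `has_indel`, `substitution_positions`
#'   (protospacer coordinates 1-20, comma-separated).
#' @export
flag_resistant <- function(alleles, spec, seed_length = 10L) {
  stopifnot(inherits(spec, "amplicon_spec"))
  refwin <- reference_window(spec)
  orient <- function(x) {
    # protospacer orientation: spacer positions 1..20, PAM 21..23
    if (spec$strand == "+") return(x)
    chars <- rev(strsplit(x, "", fixed = TRUE)[[1]])
    comp <- c(A = "T", C = "G", G = "C", T = "A", `-` = "-")
    paste(comp[chars], collapse = "")
  }
  ref_o <- strsplit(orient(refwin), "", fixed = TRUE)[[1]]
  one <- function(key) {
    parts <- split_allele_key(key)
    has_ins <- !is.null(parts$ins) && nrow(parts$ins) > 0
    core <- parts$core
    if (nchar(core) != 23)
      stop("allele core must cover the 23-nt window: ", key)
    a <- strsplit(orient(core), "", fixed = TRUE)[[1]]
    has_del <- any(a == "-")
    subs <- which(a != ref_o & a != "-")
    spacer_subs <- subs[subs <= 20]
    pam_ok <- !any(a[21:23] == "-") && a[22] == "G" && a[23] == "G"
    seed_region <- (20 - seed_length + 1):20
    seed_subs <- spacer_subs[spacer_subs %in% seed_region]
    data.frame(allele = key,
               resistant = !pam_ok || length(seed_subs) > 0 ||
                 has_del || has_ins,
               pam_mutated = !pam_ok,
               seed_substitutions = length(seed_subs),
               has_indel = has_del || has_ins,
               substitution_positions = paste(spacer_subs, collapse = ","),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(alleles, one))
  rownames(out) <- NULL
  out
}

#' Per-sample allele frequencies with experimental-sample medians
#'
#' @param tallies list of `allele_tally` objects or a combined data frame
#'   with a `sample` column.
#' @param controls control sample ids (reported separately, excluded from
#'   the median).
#' @return data frame: `allele`, `median_experimental`, then one frequency
#'   column per sample (0 where unobserved).
#' @export
allele_frequency_summary <- function(tallies, controls = character()) {
  if (inherits(tallies, "allele_tally")) tallies <- list(tallies)
  if (is.list(tallies) && !is.data.frame(tallies))
    tallies <- do.call(rbind, lapply(tallies, as.data.frame))
  stopifnot("sample" %in% names(tallies))
  samples <- unique(tallies$sample)
  expt <- setdiff(samples, controls)
  alleles <- unique(tallies$allele)
  wide <- matrix(0, nrow = length(alleles), ncol = length(samples),
                 dimnames = list(alleles, samples))
  wide[cbind(match(tallies$allele, alleles),
             match(tallies$sample, samples))] <- tallies$freq
  med <- if (length(expt)) apply(wide[, expt, drop = FALSE], 1, median) else
    rep(NA_real_, length(alleles))
  out <- data.frame(allele = alleles, median_experimental = unname(med),
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- cbind(out, as.data.frame(wide, check.names = FALSE))
  rownames(out) <- NULL
  out
}

#' Test for dissociation of a resistant allele from its linked marker
#'
#' On a haplotype where the resistant target allele is physically linked
#' to a marker (e.g. a 6-bp indel upstream of the target), gene-conversion
#' repair using the resistant repeat as template would produce reads that
#' carry the resistant target allele but lack the marker. Dissociation is
#' reported when such reads exceed the sequencing-error expectation, with
#' an exact binomial tail probability.
#'
#' @param calls an `allele_calls` data frame with `marker_state` (the spec
#'   must define a marker).
#' @param resistant_allele the allele key of the resistant target allele.
#' @param expected_marker marker state expected on the resistant haplotype
#'   (default `"alt"`).
#' @param error_rate probability that sequencing error alone makes a
#'   resistant-allele read appear to lack the marker.
#' @param alpha significance level of the dissociation verdict.
#' @return list: `n_resistant`, `n_dissociated`, `p_value`, `dissociated`
#'   (verdict), and the `table` of allele-by-marker read counts.
#' @export
linked_marker_dissociation <- function(calls, resistant_allele,
                                       expected_marker = "alt",
                                       error_rate = 0.001, alpha = 0.01) {
  if (!"marker_state" %in% names(calls))
    stop("no marker locus defined in the amplicon spec")
  ok <- calls[calls$alignable, , drop = FALSE]
  res <- ok[ok$allele == resistant_allele, , drop = FALSE]
  n_res <- nrow(res)
  n_dis <- sum(res$marker_state != expected_marker)
  p <- if (n_res == 0) NA_real_ else
    pbinom(n_dis - 1L, n_res, error_rate, lower.tail = FALSE)
  tab <- table(allele = ifelse(ok$allele == resistant_allele,
                               "resistant", "other"),
               marker = ok$marker_state)
  list(n_resistant = n_res, n_dissociated = n_dis, p_value = p,
       dissociated = !is.na(p) && p < alpha, table = tab)
}

#' Classify the coding effect of alleles
#'
#' For amplicons with a defined reading frame: a net indel length not
#' divisible by 3 is a frameshift; a balanced indel is an in-frame indel;
#' substitutions are translated (standard genetic code) and reported as
#' synonymous or missense with the predicted amino-acid changes.
#'
#' @param alleles character vector of allele keys.
#' @param spec an [amplicon_spec()] with `frame_start` defined (otherwise
#'   every effect is `none`, with a warning).
#' @return data frame: `allele`, `coding_effect` (`none`, `synonymous`,
#'   `missense`, `in-frame indel`, `frameshift`), `protein_change`,
#'   `net_indel`.
#' @export
classify_coding_effect <- function(alleles, spec) {
  stopifnot(inherits(spec, "amplicon_spec"))
  if (is.na(spec$frame_start)) {
    warning("no reading frame defined; reporting coding effect 'none'")
    return(data.frame(allele = alleles, coding_effect = "none",
                      protein_change = "", net_indel = NA_integer_,
                      stringsAsFactors = FALSE))
  }
  refwin <- reference_window(spec)
  translate_cds <- function(seq) {
    cds_len <- 3L * ((nchar(seq) - spec$frame_start + 1L) %/% 3L)
    if (cds_len < 3) return("")
    as.character(Biostrings::translate(Biostrings::DNAString(
      substr(seq, spec$frame_start, spec$frame_start + cds_len - 1L)),
      no.init.codon = TRUE))
  }
  ref_aa <- translate_cds(spec$reference)
  one <- function(key) {
    parts <- split_allele_key(key)
    core_chars <- strsplit(parts$core, "", fixed = TRUE)[[1]]
    # rebuild the mutant window: kept bases plus insertions at their anchors
    out_chars <- character(0)
    for (r in seq_len(23L)) {
      if (core_chars[r] != "-") out_chars <- c(out_chars, core_chars[r])
      if (!is.null(parts$ins)) {
        hit <- parts$ins$rel == r
        if (any(hit)) out_chars <- c(out_chars, strsplit(
          paste(parts$ins$seq[hit], collapse = ""), "", fixed = TRUE)[[1]])
      }
    }
    mutant_window <- paste(out_chars, collapse = "")
    net <- nchar(mutant_window) - 23L
    has_indel <- net != 0L || any(core_chars == "-") ||
      (!is.null(parts$ins) && nrow(parts$ins) > 0)
    mutant <- paste0(substr(spec$reference, 1, spec$window_start - 1L),
                     mutant_window,
                     substr(spec$reference, spec$window_end + 1L,
                            nchar(spec$reference)))
    if (mutant == spec$reference)
      return(data.frame(allele = key, coding_effect = "none",
                        protein_change = "", net_indel = 0L,
                        stringsAsFactors = FALSE))
    if (net %% 3L != 0L)
      return(data.frame(allele = key, coding_effect = "frameshift",
                        protein_change = "", net_indel = net,
                        stringsAsFactors = FALSE))
    if (has_indel)
      return(data.frame(allele = key, coding_effect = "in-frame indel",
                        protein_change = "", net_indel = net,
                        stringsAsFactors = FALSE))
    mut_aa <- translate_cds(mutant)
    ra <- strsplit(ref_aa, "", fixed = TRUE)[[1]]
    ma <- strsplit(mut_aa, "", fixed = TRUE)[[1]]
    len <- min(length(ra), length(ma))
    diff <- which(ra[seq_len(len)] != ma[seq_len(len)])
    change <- paste(sprintf("%s%d>%s", ra[diff], diff, ma[diff]),
                    collapse = ",")
    data.frame(allele = key,
               coding_effect = if (length(diff)) "missense" else "synonymous",
               protein_change = change, net_indel = 0L,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(alleles, one))
  rownames(out) <- NULL
  out
}
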