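#' Define a reference amplicon and its Cas9 target window
#'
#' Describes the amplified region used for editing-outcome quantification:
#' the reference amplicon sequence, the coordinates of the 23-nt target
#' window (20-nt protospacer + NGG PAM), the strand the protospacer lies
#' on, the expected blunt cut site (between protospacer positions 17 and
#' 18, i.e. 3 bp 5' of the PAM), an optional reading frame for coding
#' targets and an optional linked marker locus.
#'
#' @param reference reference amplicon sequence (character).
#' @param window_start 1-based start of the 23-nt target window on the
#'   reference (for `strand == "-"` the window still runs left to right in
#'   reference coordinates, with the PAM at its left end).
#' @param strand `"+"` or `"-"`: strand carrying the protospacer.
#' @param frame_start reference position at which a codon begins, for
#'   coding targets; `NA` disables coding-effect calling.
#' @param marker optional linked marker: `list(start, end, alt)` in
#'   reference coordinates, where `alt` is the alternate form (`""` for a
#'   deletion allele).
#' @return an object of class `amplicon_spec`.
#' @export
amplicon_spec <- function(reference, window_start, strand = "+",
                          frame_start = NA_integer_, marker = NULL) {
  reference <- toupper(reference)
  stopifnot(is.character(reference), length(reference) == 1,
            !grepl("[^ACGT]", reference), strand %in% c("+", "-"))
  window_start <- as.integer(window_start)
  window_end <- window_start + 22L
  if (window_start < 1 || window_end > nchar(reference))
    stop("target window must lie inside the amplicon")
  # cut between protospacer positions 17 and 18 (3 bp 5' of the PAM)
  cut_after <- if (strand == "+") window_start + 16L else window_start + 5L
  if (cut_after < window_start || cut_after >= window_end)
    stop("cut site must fall inside the target window")
  if (strand == "+") {
    pam <- substr(reference, window_start + 20L, window_end)
    if (substr(pam, 2, 3) != "GG")
      stop("reference PAM is not NGG on the + strand")
  } else {
    pam5 <- substr(reference, window_start, window_start + 2L)
    if (substr(pam5, 1, 2) != "CC")
      stop("reference PAM is not NGG on the - strand")
  }
  if (!is.null(marker)) {
    stopifnot(is.list(marker), all(c("start", "end", "alt") %in% names(marker)))
    if (marker$start < 1 || marker$end > nchar(reference) ||
        marker$start > marker$end)
      stop("marker locus lies outside the amplicon")
  }
  structure(list(reference = reference, window_start = window_start,
                 window_end = window_end, strand = strand,
                 cut_after = cut_after,
                 frame_start = as.integer(frame_start), marker = marker),
            class = "amplicon_spec")
}

#' Reference window sequence of an amplicon spec
#' @param spec an [amplicon_spec()].
#' @return the 23-nt reference target window (reference orientation).
#' @export
reference_window <- function(spec) {
  stopifnot(inherits(spec, "amplicon_spec"))
  substr(spec$reference, spec$window_start, spec$window_end)
}

#' Amplicon spec of a simulated repeat cluster
#'
#' Builds the [amplicon_spec()] of a cluster's consensus amplicon,
#' including the linked marker of the resistant unit when the genome
#' carries one.
#'
#' @param genome a `sim_genome`.
#' @param cluster cluster id.
#' @return an `amplicon_spec`.
#' @export
amplicon_spec_from_genome <- function(genome, cluster = 1L) {
  tg <- genome$targets[genome$targets$cluster == cluster, ]
  if (nrow(tg) != 1) stop("no such cluster in genome: ", cluster)
  marker <- NULL
  if (isTRUE(tg$marker_present)) {
    marker <- list(start = tg$marker_start_in_amp,
                   end = tg$marker_start_in_amp + tg$marker_length - 1L,
                   alt = "")
  }
  amplicon_spec(tg$consensus_amp, tg$target_offset_in_amp, strand = "+",
                marker = marker)
}

#' Amplicon spec of a simulated single-copy coding locus
#'
#' Uses the whole coding sequence as the reference amplicon, with the
#' reading frame starting at position 1.
#'
#' @param genome a `sim_genome`.
#' @param locus locus id.
#' @return an `amplicon_spec` with a defined reading frame.
#' @export
amplicon_spec_from_locus <- function(genome, locus = 1L) {
  lo <- genome$loci[genome$loci$locus == locus, ]
  if (nrow(lo) != 1) stop("no such locus in genome: ", locus)
  amplicon_spec(lo$cds, lo$target_offset, strand = "+", frame_start = 1L)
}
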