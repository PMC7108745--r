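#' Define an X-linked (or decoy) tandem repeat cluster
#'
#' A cluster is a tandem array of near-identical units, each carrying one
#' occurrence of a consensus Cas9 target site (20-nt protospacer + NGG PAM)
#' unless the unit is designated cleavage-resistant. Per-unit substitutions
#' are placed outside the target window, emulating repeat arrays that are
#' heterogeneous in their flanks while retaining an intact target site.
#' The designated resistant unit instead differs from the consensus inside
#' the window (at least one protospacer and one PAM position) and, when
#' there is room, carries a linked 6-bp deletion marker upstream of the
#' target, mirroring a pre-existing cleavage-resistant repeat variant.
#'
#' @param chrom chromosome name the cluster sits on (default `"X"`).
#' @param start 1-based start of the cluster on the chromosome.
#' @param n_units number of repeat units (>= 2).
#' @param unit_length consensus unit length in bp (>= 30); 271 by default,
#'   the spacing between successive target sites in the tandem array.
#' @param sub_rate per-base substitution rate applied independently to each
#'   unit outside the target window.
#' @param target_offset 1-based offset of the 23-nt target window within the
#'   unit; computed to fit the amplicon when `NULL`.
#' @param conserved_flank number of bases on each side of the target window
#'   kept free of per-unit substitutions (default 15), so the target-bearing
#'   k-mers are shared across units as in a real repeat array.
#' @param amplicon_length length of the amplicon window used by the amplicon
#'   simulator (default 153 bp, capped at the unit length).
#' @param resistant_unit index of the designated cleavage-resistant unit, or
#'   `NA` for none.
#' @param resistant_marker if `TRUE` (default) the resistant unit also
#'   carries a linked 6-bp deletion 53 bp upstream of the target window,
#'   when the amplicon window has room for it.
#' @param target_seq optional fixed 23-nt protospacer+PAM sequence (must end
#'   in GG); randomly generated per genome seed when `NULL`.
#' @return an object of class `repeat_cluster`.
#' @export
repeat_cluster <- function(chrom = "X", start = 1000L, n_units = 12L,
                           unit_length = 271L, sub_rate = 0.02,
                           target_offset = NULL, conserved_flank = 15L,
                           amplicon_length = NULL,
                           resistant_unit = NA_integer_,
                           resistant_marker = TRUE, target_seq = NULL) {
  stopifnot(unit_length >= 30, n_units >= 2, start >= 1,
            sub_rate >= 0, sub_rate <= 1, conserved_flank >= 0)
  if (is.null(amplicon_length)) amplicon_length <- min(153L, unit_length)
  amplicon_length <- as.integer(amplicon_length)
  if (amplicon_length < 23 || amplicon_length > unit_length)
    stop("amplicon_length must be between 23 and the unit length")
  if (is.null(target_offset)) {
    target_offset <- if (unit_length >= 160L) 65L else
      as.integer(floor((unit_length - 23) / 2) + 1)
  }
  target_offset <- as.integer(target_offset)
  if (target_offset < 1 || target_offset + 22 > unit_length)
    stop("target window must lie inside the repeat unit")
  # amplicon window within the unit, required to contain the target window
  amp_start <- max(1L, min(target_offset - 64L,
                           unit_length - amplicon_length + 1L))
  if (amp_start + amplicon_length - 1L < target_offset + 22L)
    stop("amplicon window cannot contain the target window; increase amplicon_length")
  if (!is.na(resistant_unit) &&
      (resistant_unit < 1 || resistant_unit > n_units))
    stop("resistant_unit out of range")
  if (!is.null(target_seq)) {
    target_seq <- toupper(target_seq)
    if (nchar(target_seq) != 23 || grepl("[^ACGT]", target_seq) ||
        substr(target_seq, 22, 23) != "GG")
      stop("target_seq must be 23 nt of ACGT ending in GG (NGG PAM)")
  }
  structure(list(chrom = chrom, start = as.integer(start),
                 n_units = as.integer(n_units),
                 unit_length = as.integer(unit_length),
                 sub_rate = sub_rate, target_offset = target_offset,
                 conserved_flank = as.integer(conserved_flank),
                 amplicon_length = amplicon_length, amp_start = amp_start,
                 resistant_unit = as.integer(resistant_unit),
                 resistant_marker = isTRUE(resistant_marker),
                 target_seq = target_seq),
            class = "repeat_cluster")
}

#' Define an embedded single-copy coding target locus
#'
#' A toy protein-coding gene (for example an X-linked ribosomal protein
#' gene) with a defined reading frame and one Cas9 target site, used to
#' exercise the coding-effect branch of the amplicon pipeline.
#'
#' @param chrom chromosome the locus sits on.
#' @param start 1-based start of the coding sequence on the chromosome.
#' @param cds_length length of the coding sequence (multiple of 3).
#' @param target_offset 1-based offset of the 23-nt target window within the
#'   coding sequence.
#' @param name locus name.
#' @return an object of class `target_locus`.
#' @export
target_locus <- function(chrom = "X", start = 200000L, cds_length = 300L,
                         target_offset = 121L, name = "toyRpS") {
  stopifnot(cds_length %% 3 == 0, cds_length >= 60,
            target_offset >= 1, target_offset + 22 <= cds_length)
  structure(list(chrom = chrom, start = as.integer(start),
                 cds_length = as.integer(cds_length),
                 target_offset = as.integer(target_offset), name = name),
            class = "target_locus")
}

#' Specify a toy genome for the sex-distorter pipeline
#'
#' The simulated species has a diploid-female / hemizygous-male XY karyotype:
#' an X chromosome, one or more autosomes, a Y chromosome and a
#' mitochondrial genome. Repeat clusters and single-copy coding loci are
#' embedded at stated coordinates. The default scale (500 kb X, 300 kb
#' autosome, 500 kb Y, 16 kb mitochondrion) keeps full pipeline runs fast
#' on one CPU while preserving the copy-number structure every downstream
#' stage relies on. The Y is sized like the X -- as in *Drosophila*, whose
#' heterochromatic Y rivals the X in size -- so male and female sequenced
#' genome sizes match and per-library-size normalization centres the
#' chromosome quotient at 2 (X), 1 (autosome) and 0 (Y).
#'
#' @param x_length,y_length,mito_length chromosome lengths in bp.
#' @param autosome_lengths numeric vector of autosome lengths in bp.
#' @param clusters list of [repeat_cluster()] definitions.
#' @param loci list of [target_locus()] definitions.
#' @param seed integer random seed; the genome is a deterministic function
#'   of the spec including the seed.
#' @return an object of class `genome_spec`.
#' @export
genome_spec <- function(x_length = 5e5, autosome_lengths = 3e5,
                        y_length = 5e5, mito_length = 16e3,
                        clusters = list(repeat_cluster()),
                        loci = list(), seed = 1L) {
  stopifnot(x_length > 0, all(autosome_lengths > 0), y_length > 0,
            mito_length > 0)
  if (inherits(clusters, "repeat_cluster")) clusters <- list(clusters)
  if (inherits(loci, "target_locus")) loci <- list(loci)
  stopifnot(all(vapply(clusters, inherits, TRUE, "repeat_cluster")),
            all(vapply(loci, inherits, TRUE, "target_locus")))
  chrom_lengths <- c(X = as.integer(x_length),
                     setNames(as.integer(autosome_lengths),
                              paste0("A", seq_along(autosome_lengths))),
                     Y = as.integer(y_length), MT = as.integer(mito_length))
  spec <- structure(list(chrom_lengths = chrom_lengths, clusters = clusters,
                         loci = loci, seed = as.integer(seed)),
                    class = "genome_spec")
  validate_genome_spec(spec)
  spec
}

# Footprint intervals of clusters/loci per chromosome; errors on overlap or
# out-of-chromosome coordinates.
validate_genome_spec <- function(spec) {
  feats <- data.frame(chrom = character(), start = integer(), end = integer(),
                      what = character(), stringsAsFactors = FALSE)
  for (i in seq_along(spec$clusters)) {
    cl <- spec$clusters[[i]]
    feats <- rbind(feats, data.frame(
      chrom = cl$chrom, start = cl$start,
      end = cl$start + cl$n_units * cl$unit_length - 1L,
      what = paste0("cluster", i), stringsAsFactors = FALSE))
  }
  for (i in seq_along(spec$loci)) {
    lo <- spec$loci[[i]]
    feats <- rbind(feats, data.frame(
      chrom = lo$chrom, start = lo$start,
      end = lo$start + lo$cds_length - 1L,
      what = paste0("locus", i), stringsAsFactors = FALSE))
  }
  for (i in seq_len(nrow(feats))) {
    f <- feats[i, ]
    if (!f$chrom %in% names(spec$chrom_lengths))
      stop(f$what, " references unknown chromosome '", f$chrom, "'")
    if (f$end > spec$chrom_lengths[[f$chrom]])
      stop(f$what, " extends beyond the end of chromosome ", f$chrom)
  }
  if (nrow(feats) > 1) {
    for (i in seq_len(nrow(feats) - 1)) for (j in (i + 1):nrow(feats)) {
      if (feats$chrom[i] == feats$chrom[j] &&
          feats$start[i] <= feats$end[j] && feats$start[j] <= feats$end[i])
        stop("overlapping definitions: ", feats$what[i], " and ", feats$what[j])
    }
  }
  invisible(spec)
}

# Random 23-nt protospacer+PAM with an NGG PAM (uses the current RNG stream).
random_target_site <- function() {
  paste0(random_dna(21), "GG")
}

# Build one cluster: returns list(units = per-unit data frame, seqs = per-unit
# sequences, consensus = consensus unit, target = consensus window).
build_cluster <- function(cl, cluster_id) {
  target <- if (is.null(cl$target_seq)) random_target_site() else cl$target_seq
  win <- cl$target_offset:(cl$target_offset + 22L)
  consensus <- strsplit(random_dna(cl$unit_length), "")[[1]]
  consensus[win] <- strsplit(target, "")[[1]]
  consensus_str <- paste(consensus, collapse = "")

  marker_start <- cl$target_offset - 59L   # 6 bp ending 53 bp upstream of the window
  marker_ok <- cl$resistant_marker && !is.na(cl$resistant_unit) &&
    marker_start >= cl$amp_start && marker_start >= 1L

  unit_seqs <- character(cl$n_units)
  offsets <- integer(cl$n_units)   # target offset within each unit sequence
  amp_starts <- integer(cl$n_units)
  marker_del <- logical(cl$n_units)
  for (u in seq_len(cl$n_units)) {
    chars <- consensus
    conserved <- max(1L, min(win) - cl$conserved_flank):
      min(cl$unit_length, max(win) + cl$conserved_flank)
    outside <- setdiff(seq_len(cl$unit_length), conserved)
    hit <- outside[runif(length(outside)) < cl$sub_rate]
    for (p in hit) {
      alt <- DNA_BASES[DNA_BASES != chars[p]]
      chars[p] <- alt[sample.int(3, 1)]
    }
    t_off <- cl$target_offset
    a_start <- cl$amp_start
    if (!is.na(cl$resistant_unit) && u == cl$resistant_unit) {
      # >=1 protospacer and >=1 PAM substitution: spacer position 5 flipped,
      # PAM central G -> A (pattern of a naturally pre-existing resistant repeat)
      chars[win[5]] <- flip_base(chars[win[5]])
      chars[win[22]] <- "A"
      if (marker_ok) {
        chars <- chars[-(marker_start:(marker_start + 5L))]
        t_off <- t_off - 6L
        marker_del[u] <- TRUE
      }
    }
    unit_seqs[u] <- paste(chars, collapse = "")
    offsets[u] <- t_off
    amp_starts[u] <- a_start
  }
  # a marker deletion shortens that unit's amplicon (primer positions fixed)
  amp_len <- pmin(cl$amplicon_length - ifelse(marker_del, 6L, 0L),
                  nchar(unit_seqs) - amp_starts + 1L)

  units <- data.frame(
    cluster = cluster_id, chrom = cl$chrom, unit = seq_len(cl$n_units),
    is_resistant = !is.na(cl$resistant_unit) &
      seq_len(cl$n_units) == cl$resistant_unit,
    unit_length = nchar(unit_seqs), target_offset = offsets,
    amp_start = amp_starts, amp_length = amp_len,
    unit_seq = unit_seqs, stringsAsFactors = FALSE)
  units$amp_seq <- substr(unit_seqs, units$amp_start,
                          units$amp_start + units$amp_length - 1L)

  consensus_amp <- substr(consensus_str, cl$amp_start,
                          cl$amp_start + cl$amplicon_length - 1L)
  target_row <- data.frame(
    cluster = cluster_id, chrom = cl$chrom,
    target = target, spacer = substr(target, 1, 20),
    pam = substr(target, 21, 23),
    target_offset_in_unit = cl$target_offset,
    target_offset_in_amp = cl$target_offset - cl$amp_start + 1L,
    consensus_amp = consensus_amp,
    marker_present = marker_ok,
    marker_start_in_amp = if (marker_ok) marker_start - cl$amp_start + 1L else NA_integer_,
    marker_length = if (marker_ok) 6L else NA_integer_,
    stringsAsFactors = FALSE)
  list(units = units, consensus = consensus_str, target = target_row)
}

# Random coding sequence without stop codons, with a forced NGG at the
# target window's PAM position.
build_locus_cds <- function(lo) {
  codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste,
                  collapse = "")
  codons <- codons[!codons %in% c("TAA", "TAG", "TGA")]
  cds <- paste(sample(codons, lo$cds_length / 3, replace = TRUE),
               collapse = "")
  chars <- strsplit(cds, "")[[1]]
  pam <- lo$target_offset + 20L
  chars[pam + 1L] <- "G"
  chars[pam + 2L] <- "G"
  # forcing the PAM may have created a stop codon; repair it in-frame
  for (ci in seq(1, lo$cds_length - 2, by = 3)) {
    cod <- paste(chars[ci:(ci + 2)], collapse = "")
    if (cod %in% c("TAA", "TAG", "TGA")) chars[ci] <- "C"
  }
  paste(chars, collapse = "")
}

#' Build a toy genome with truth annotation
#'
#' Deterministically (for a fixed seed) generates chromosome sequences,
#' inserts the repeat clusters and coding loci of the spec, and returns the
#' sequences together with a truth table of every repeat unit (coordinates,
#' resistant-unit identity, per-unit amplicon windows) and the consensus
#' target site of each cluster.
#'
#' @param spec a [genome_spec()].
#' @return an object of class `sim_genome`: a list with `seqs` (named
#'   character vector of chromosome sequences), `units` (per-unit truth
#'   table), `targets` (per-cluster consensus target table), `loci`
#'   (per-locus truth table) and `spec`.
#' @export
build_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  validate_genome_spec(spec)
  withr::with_seed(spec$seed, {
    seqs <- vapply(spec$chrom_lengths, random_dna, "")
    units_all <- list()
    targets_all <- list()
    for (i in seq_along(spec$clusters)) {
      cl <- spec$clusters[[i]]
      built <- build_cluster(cl, i)
      block <- paste(built$units$unit_seq, collapse = "")
      s <- seqs[[cl$chrom]]
      # replace the cluster footprint; marker deletions shorten the block,
      # the chromosome shrinks accordingly
      footprint <- cl$n_units * cl$unit_length
      seqs[[cl$chrom]] <- paste0(substr(s, 1, cl$start - 1), block,
                                 substr(s, cl$start + footprint, nchar(s)))
      u <- built$units
      ends <- cl$start - 1L + cumsum(u$unit_length)
      u$start <- ends - u$unit_length + 1L
      u$end <- ends
      u$target_start <- u$start + u$target_offset - 1L
      u$target_end <- u$target_start + 22L
      units_all[[i]] <- u
      targets_all[[i]] <- built$target
    }
    loci_all <- list()
    for (i in seq_along(spec$loci)) {
      lo <- spec$loci[[i]]
      cds <- build_locus_cds(lo)
      s <- seqs[[lo$chrom]]
      seqs[[lo$chrom]] <- paste0(substr(s, 1, lo$start - 1), cds,
                                 substr(s, lo$start + lo$cds_length, nchar(s)))
      loci_all[[i]] <- data.frame(
        locus = i, name = lo$name, chrom = lo$chrom, start = lo$start,
        end = lo$start + lo$cds_length - 1L,
        target_offset = lo$target_offset, cds = cds,
        target = substr(cds, lo$target_offset, lo$target_offset + 22L),
        stringsAsFactors = FALSE)
    }
    out <- list(
      seqs = seqs,
      units = if (length(units_all)) do.call(rbind, units_all) else
        data.frame(),
      targets = if (length(targets_all)) do.call(rbind, targets_all) else
        data.frame(),
      loci = if (length(loci_all)) do.call(rbind, loci_all) else data.frame(),
      spec = spec)
    class(out) <- "sim_genome"
    out
  })
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("sim_genome:", paste0(names(x$seqs), " (", nchar(x$seqs), " bp)",
                            collapse = ", "), "\n")
  cat("  ", nrow(x$units), "repeat units in",
      length(unique(x$units$cluster)), "cluster(s);",
      nrow(x$loci), "coding locus/loci\n")
  invisible(x)
}

#' Truth tables of a simulated genome as TSV
#'
#' Writes the per-unit and per-cluster truth annotation alongside the FASTA.
#'
#' @param genome a `sim_genome`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
write_genome_truth <- function(genome, dir, prefix = "genome") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, paste0(prefix, ".fasta")),
    units = file.path(dir, paste0(prefix, "_units.tsv")),
    targets = file.path(dir, paste0(prefix, "_targets.tsv")))
  write_fasta(genome, paths[["fasta"]])
  write_tsv(genome$units, paths[["units"]])
  write_tsv(genome$targets, paths[["targets"]])
  invisible(paths)
}
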