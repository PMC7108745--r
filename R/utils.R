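#' @useDynLib xshred, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rbinom runif median pbinom qbeta setNames complete.cases
#' @importFrom utils write.table read.delim head
NULL

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonical form of k-mer strings
#'
#' The canonical form of a k-mer is the lexicographically smaller of the
#' k-mer and its reverse complement, so that one key represents both strands.
#'
#' @param x character vector of equal-length DNA strings.
#' @return character vector of canonical k-mers.
#' @export
canonical_kmers <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

# Substitute a different base at `pos` (deterministic flip used for designated
# resistant-unit mutations): A<->G, C<->T transitions.
flip_base <- function(b) {
  c(A = "G", G = "A", C = "T", T = "C")[b]
}

# Apply uniform substitution errors to a character vector of reads.
# Returns the mutated vector; expected per-base error rate = `rate`.
add_substitution_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0) return(reads)
  lens <- nchar(reads)
  n_err <- rbinom(length(reads), lens, rate)
  idx <- which(n_err > 0)
  for (i in idx) {
    pos <- sample.int(lens[i], n_err[i])
    chars <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    for (p in pos) {
      cur <- chars[p]
      alt <- DNA_BASES[DNA_BASES != cur]
      chars[p] <- if (length(alt) == 3) alt[sample.int(3, 1)] else sample(DNA_BASES, 1)
    }
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

constant_quality <- function(lens, q) {
  vapply(lens, function(n) strrep(intToUtf8(q + 33L), n), "")
}

# Mean Phred score (Phred+33) per quality string.
phred_means <- function(quals) {
  vapply(quals, function(s) {
    v <- utf8ToInt(s)
    if (any(v < 33L | v > 126L)) stop("non-ASCII or out-of-range quality string")
    mean(v) - 33
  }, 0.0, USE.NAMES = FALSE)
}

# Coerce the various read containers used in the package to a plain named
# character vector of sequences.
as_sequences <- function(x) {
  if (is.character(x) && length(x) == 1 && !is.na(x) && nchar(x) < 1000 && file.exists(x)) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", x)) "fastq" else "fasta"
    ss <- Biostrings::readDNAStringSet(x, format = fmt)
    return(setNames(as.character(ss), names(ss)))
  }
  if (inherits(x, "sim_reads")) return(x$reads)
  if (inherits(x, "XStringSet")) return(setNames(as.character(x), names(x)))
  if (is.character(x)) return(x)
  stop("cannot interpret object of class '", paste(class(x), collapse = "/"),
       "' as sequences")
}

#' Write sequences to FASTA
#'
#' @param x named character vector, `DNAStringSet`, or a `sim_reads` /
#'   `sim_genome` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "sim_genome")) x <- x$seqs
  seqs <- as_sequences(x)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write simulated reads to FASTQ (Phred+33)
#'
#' @param x a `sim_reads` object, or a named character vector of sequences.
#' @param path output file path.
#' @param quals quality strings; taken from `x` when it is a `sim_reads`
#'   object.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path, quals = NULL) {
  if (inherits(x, "sim_reads")) {
    quals <- x$quals
    x <- x$reads
  }
  if (is.null(quals)) quals <- constant_quality(nchar(x), 38L)
  if (is.null(names(x))) names(x) <- paste0("read", seq_along(x))
  ss <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(ss, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals))
  invisible(path)
}

#' Read a FASTQ file into the package's read container
#'
#' @param path FASTQ file (optionally gzipped).
#' @return a `sim_reads`-style list with `reads` and `quals`.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  out <- list(reads = setNames(as.character(ss), names(ss)),
              quals = setNames(as.character(S4Vectors::mcols(ss)$qualities), names(ss)),
              truth = NULL)
  class(out) <- "sim_reads"
  out
}

#' Write a data frame as TSV
#'
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
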