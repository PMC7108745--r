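# Independent brute-force oracles, deliberately naive: every implementation
# they check uses a different code path (C-level hashing / vectorized scans).

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

# Sliding-window k-mer census over plain string operations.
oracle_count_kmers <- function(reads, k, canonical = TRUE) {
  words <- unlist(lapply(reads, function(r) {
    n <- nchar(r)
    if (n < k) return(character())
    substring(r, 1:(n - k + 1), k:n)
  }))
  words <- words[!grepl("[^ACGT]", words)]
  if (canonical) {
    rc <- oracle_revcomp(words)
    words <- ifelse(words <= rc, words, rc)
  }
  tab <- table(words)
  out <- data.frame(kmer = names(tab), count = as.numeric(tab),
                    stringsAsFactors = FALSE)
  out[order(out$kmer), , drop = FALSE]
}

# Exhaustive window scan for [20-nt spacer][NGG] placements on one strand.
oracle_pam_scan_strand <- function(seq) {
  out <- NULL
  n <- nchar(seq)
  if (n < 23) return(out)
  for (i in 1:(n - 22)) {
    pam <- substr(seq, i + 20, i + 22)
    if (substr(pam, 2, 3) == "GG") {
      out <- rbind(out, data.frame(spacer = substr(seq, i, i + 19),
                                   pam = pam, offset = i,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

# Hamming scan for spacer+NGG occurrences with <= max_mm spacer mismatches.
oracle_offtargets <- function(refs, spacer, max_mm) {
  count_one <- function(ref) {
    total <- 0L
    for (s in c(ref, oracle_revcomp(ref))) {
      n <- nchar(s)
      if (n < 23) next
      for (i in 1:(n - 22)) {
        if (substr(s, i + 21, i + 22) != "GG") next
        a <- strsplit(substr(s, i, i + 19), "")[[1]]
        b <- strsplit(spacer, "")[[1]]
        if (sum(a != b) <= max_mm) total <- total + 1L
      }
    }
    total
  }
  sum(vapply(refs, count_one, 0L))
}

# Exact occurrences of a k-mer on both strands of each sequence.
oracle_kmer_hits <- function(kmer, seqs) {
  vapply(seqs, function(s) {
    n <- nchar(s)
    k <- nchar(kmer)
    if (n < k) return(0L)
    wins <- substring(s, 1:(n - k + 1), k:n)
    sum(wins == kmer | wins == oracle_revcomp(kmer))
  }, 0L, USE.NAMES = FALSE)
}

# Closed-form Welch statistic with Satterthwaite degrees of freedom.
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Closed-form Clopper-Pearson interval via beta quantiles.
oracle_clopper_pearson <- function(x, n, conf = 0.95) {
  alpha <- 1 - conf
  lower <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower, upper)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
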