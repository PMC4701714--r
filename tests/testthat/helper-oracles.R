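# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles deliberately share no code with the implementation.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc_oracle <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

# all exact placements of tag on ref, both strands, by scanning every window
oracle_occurrences <- function(tag, ref) {
  m <- nchar(tag); L <- nchar(ref)
  out <- data.frame(start = integer(0), strand = character(0))
  if (m > L || m == 0) return(out)
  windows <- substring(ref, 1:(L - m + 1), m:L)
  plus <- which(windows == tag) - 1L
  minus <- which(windows == rc_oracle(tag)) - 1L
  out <- rbind(data.frame(start = plus, strand = rep("+", length(plus))),
               data.frame(start = minus, strand = rep("-", length(minus))))
  out[order(out$start, out$strand), , drop = FALSE]
}

# minimum Hamming distance over all same-length windows, both strands
oracle_min_mismatch <- function(tag, ref) {
  m <- nchar(tag); L <- nchar(ref)
  if (m > L) return(Inf)
  tags <- c(tag, rc_oracle(tag))
  best <- m
  for (t in tags) {
    tc <- strsplit(t, "")[[1]]
    for (s in 1:(L - m + 1)) {
      wc <- strsplit(substr(ref, s, s + m - 1), "")[[1]]
      best <- min(best, sum(tc != wc))
    }
  }
  best
}

# phase/cycle by explicit enumeration of phased positions around the anchor
oracle_phase_cycle <- function(anchor, cleavage, period = 21L) {
  for (k in -300:300) {
    for (p in 1:period) {
      if (anchor == cleavage + (k - 1L) * period + (p - 1L))
        return(c(phase = p, cycle = k))
    }
  }
  stop("anchor not found in enumeration range")
}

# hit data.frame builder in the package's column layout
make_hits <- function(start, strand, length = 21L, count = 1L,
                      sequence = NULL, ref_name = "ref") {
  n <- length(start)
  if (is.null(sequence)) sequence <- replicate(n, rand_dna(21))
  data.frame(ref_name = rep_len(ref_name, n), start = as.integer(start),
             strand = rep_len(strand, n),
             length = rep_len(as.integer(length), n),
             count = rep_len(as.integer(count), n),
             sequence = rep_len(sequence, n), stringsAsFactors = FALSE)
}

write_fastq <- function(path, reads) {
  lines <- as.vector(rbind(sprintf("@r%d", seq_along(reads)), reads, "+",
                           strrep("I", nchar(reads))))
  writeLines(lines, path)
}
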