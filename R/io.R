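#' Small RNA library container
#'
#' An `srna_library` holds a collapsed small RNA library: one row per unique
#' tag sequence with its redundant read count. Sequences are uppercase DNA;
#' RNA input (`U`) is normalized to `T` at construction.
#'
#' @param sequences Character vector of read or tag sequences.
#' @param counts Optional integer vector of redundant read counts, one per
#'   element of `sequences` (defaults to 1 each). Identical sequences are
#'   collapsed and their counts summed.
#' @param name Library label.
#'
#' @return An object of class `srna_library`: a list with elements `tags`
#'   (data.frame with columns `sequence`, `length`, `count`, sorted by
#'   decreasing count then sequence), `total_reads` and `name`.
#' @export
srna_library <- function(sequences, counts = NULL, name = "library") {
  sequences <- normalize_dna(sequences)
  if (is.null(counts)) counts <- rep(1L, length(sequences))
  if (length(counts) != length(sequences))
    stop("'counts' must have one entry per sequence")
  counts <- as.integer(counts)
  if (length(counts) && any(counts < 1L))
    stop("tag counts must be >= 1")
  if (length(sequences) == 0L) {
    tags <- data.frame(sequence = character(0), length = integer(0),
                       count = integer(0), stringsAsFactors = FALSE)
  } else {
    agg <- rowsum(counts, group = sequences)
    tags <- data.frame(sequence = rownames(agg),
                       length = nchar(rownames(agg)),
                       count = as.integer(agg[, 1L]),
                       stringsAsFactors = FALSE)
    tags <- tags[order(-tags$count, tags$sequence), , drop = FALSE]
    rownames(tags) <- NULL
  }
  structure(list(tags = tags,
                 total_reads = sum(tags$count),
                 name = name),
            class = "srna_library")
}

#' @export
print.srna_library <- function(x, ...) {
  cat(sprintf("srna_library '%s': %d unique tags, %d reads\n",
              x$name, nrow(x$tags), x$total_reads))
  if (nrow(x$tags)) {
    rng <- range(x$tags$length)
    cat(sprintf("  tag lengths %d-%d nt; top tag %s (%d reads)\n",
                rng[1], rng[2], x$tags$sequence[1], x$tags$count[1]))
  }
  invisible(x)
}

#' @export
summary.srna_library <- function(object, ...) {
  h <- size_histogram(object,
                      min_len = if (nrow(object$tags)) min(object$tags$length) else 18L,
                      max_len = if (nrow(object$tags)) max(object$tags$length) else 26L)
  cat(sprintf("srna_library '%s'\n  total reads : %d\n  unique tags : %d\n",
              object$name, object$total_reads, nrow(object$tags)))
  print(h[h$read_count > 0L, , drop = FALSE], row.names = FALSE)
  invisible(h)
}

# Uppercase, U -> T, validate strict ACGT. Reports the first offending tag.
normalize_dna <- function(x) {
  x <- chartr("u", "U", toupper(as.character(x)))
  x <- chartr("U", "T", x)
  bad <- grep("[^ACGT]", x)
  if (length(bad))
    stop(sprintf("non-ACGTU character in sequence '%s' (record %d)",
                 x[bad[1]], bad[1]))
  x
}

#' Read a small RNA library and collapse identical reads
#'
#' Reads plain FASTA, 4-line FASTQ, or collapsed FASTA (deduplicated tags with
#' the read count encoded in the header, either `>t{i}_x{count}` or
#' `>{id} count={n}`). Identical sequences are collapsed into one tag whose
#' count is the number of occurrences (times any encoded count).
#'
#' @param path Path to the sequence file.
#' @param format One of `"auto"`, `"fasta"`, `"fastq"`, `"collapsed_fasta"`.
#'   `"auto"` guesses from the file extension (`.fq`/`.fastq` vs `.fa` etc.);
#'   collapsed counts are honoured whenever a FASTA header matches a known
#'   dialect.
#' @param name Library label; defaults to the file's base name.
#'
#' @return An [srna_library()].
#' @export
read_srna_library <- function(path, format = c("auto", "fasta", "fastq",
                                               "collapsed_fasta"),
                              name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is.null(name)) name <- sub("\\.(fa|fasta|fq|fastq|txt)$", "",
                                 basename(path), ignore.case = TRUE)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE))
      "fastq" else "collapsed_fasta"
  }
  biofmt <- if (format == "fastq") "fastq" else "fasta"
  if (format == "fastq") validate_fastq_structure(path)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = biofmt),
    error = function(e) stop(sprintf("parse error in %s [%s]: %s",
                                     path, biofmt, conditionMessage(e))))
  seqs <- as.character(set)
  headers <- names(set)
  counts <- rep(1L, length(seqs))
  if (format %in% c("fasta", "collapsed_fasta") && length(seqs)) {
    counts <- parse_collapsed_counts(headers)
  }
  srna_library(seqs, counts, name = name)
}

# 4-line FASTQ sanity check with line numbers in the error message
validate_fastq_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L)
    stop(sprintf("parse error in %s: truncated FASTQ record near line %d",
                 path, length(lines)))
  heads <- seq(1L, length(lines), by = 4L)
  bad_h <- heads[!startsWith(lines[heads], "@")]
  bad_p <- (heads + 2L)[!startsWith(lines[heads + 2L], "+")]
  if (length(bad_h) || length(bad_p))
    stop(sprintf("parse error in %s: malformed FASTQ record at line %d",
                 path, min(bad_h, bad_p)))
  invisible(TRUE)
}

# ">t{i}_x{count}" and ">{id} count={n}" dialects; plain headers count as 1.
parse_collapsed_counts <- function(headers) {
  counts <- rep(1L, length(headers))
  m <- regmatches(headers, regexec("_x(\\d+)\\s*$", headers))
  hit <- lengths(m) == 2L
  counts[hit] <- as.integer(vapply(m[hit], `[`, "", 2L))
  m2 <- regmatches(headers, regexec("\\bcount=(\\d+)\\b", headers))
  hit2 <- lengths(m2) == 2L & !hit
  counts[hit2] <- as.integer(vapply(m2[hit2], `[`, "", 2L))
  counts
}

#' Write a library as collapsed FASTA
#'
#' Headers follow the `>t{index}_x{count}` dialect, so that
#' [read_srna_library()] round-trips tags and counts exactly.
#'
#' @param library An [srna_library()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_collapsed_fasta <- function(library, path) {
  stopifnot(inherits(library, "srna_library"))
  tags <- library$tags
  if (nrow(tags)) {
    lines <- as.vector(rbind(sprintf(">t%d_x%d", seq_len(nrow(tags)), tags$count),
                             tags$sequence))
  } else lines <- character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Transcripts-per-million abundance
#'
#' TPM of a tag is its read count per million total clean reads of the
#' library: `count * 1e6 / total_reads`.
#'
#' @param count Read count(s) of the tag(s); `0 <= count <= total_reads`.
#' @param total_reads Total clean reads of the library (denominator).
#' @return Numeric TPM value(s).
#' @export
tpm <- function(count, total_reads) {
  if (any(total_reads == 0)) stop("undefined TPM: total_reads is 0")
  if (any(count < 0) || any(count > total_reads))
    stop("count must satisfy 0 <= count <= total_reads")
  count * 1e6 / total_reads
}

#' Size distribution of a small RNA library
#'
#' Tallies reads and unique species per tag length over a length window.
#'
#' @param library An [srna_library()].
#' @param min_len,max_len Inclusive length bounds of the histogram (nt).
#' @return data.frame with columns `length`, `read_count`, `species_count`,
#'   one row per length in `[min_len, max_len]`.
#' @export
size_histogram <- function(library, min_len = 18L, max_len = 26L) {
  stopifnot(inherits(library, "srna_library"), min_len <= max_len)
  lens <- seq.int(min_len, max_len)
  tags <- library$tags
  reads <- integer(length(lens))
  species <- integer(length(lens))
  idx <- match(tags$length, lens)
  keep <- !is.na(idx)
  if (any(keep)) {
    reads <- as.integer(rowsum_at(tags$count[keep], idx[keep], length(lens)))
    species <- as.integer(rowsum_at(rep(1L, sum(keep)), idx[keep], length(lens)))
  }
  data.frame(length = lens, read_count = reads, species_count = species)
}

rowsum_at <- function(values, index, n) {
  out <- numeric(n)
  agg <- rowsum(values, group = index)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' Ratio of focal-length to other-length reads
#'
#' For hits on a single reference, computes (reads of the focal length) /
#' (reads of other lengths within the window), e.g. the 21-nt : non-21-nt
#' (20-24 nt) read ratio of a MIGS cassette.
#'
#' @param hits Hit data.frame (see [map_library()]) restricted to one
#'   reference; only the `length` and `count` columns are used.
#' @param focal_len Focal length in nt; must lie inside `window`.
#' @param window Inclusive length window `c(lo, hi)`.
#' @return A list with `ratio` (numeric; `Inf` when no other-length reads
#'   exist, `NA` when the window is empty), `focal_reads`, `other_reads`, and
#'   `flag` (`"ok"`, `"infinite"`, or `"undefined"`).
#' @export
length_class_ratio <- function(hits, focal_len = 21L, window = c(20L, 24L)) {
  stopifnot(focal_len >= window[1], focal_len <= window[2])
  inwin <- hits$length >= window[1] & hits$length <= window[2]
  focal <- sum(hits$count[inwin & hits$length == focal_len])
  other <- sum(hits$count[inwin & hits$length != focal_len])
  if (focal + other == 0)
    return(list(ratio = NA_real_, focal_reads = 0L, other_reads = 0L,
                flag = "undefined"))
  if (other == 0)
    return(list(ratio = Inf, focal_reads = focal, other_reads = 0L,
                flag = "infinite"))
  list(ratio = focal / other, focal_reads = focal, other_reads = other,
       flag = "ok")
}

#' Export a size histogram as TSV
#'
#' @param histogram Output of [size_histogram()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_size_histogram <- function(histogram, path) {
  write_tsv_commented(histogram, path,
                      "# small RNA size distribution (length, read_count, species_count)")
}

write_tsv_commented <- function(df, path, comment) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comment, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
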