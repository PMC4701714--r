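#' Exact occurrences of a tag on a reference
#'
#' Finds all windows of the reference where the tag matches perfectly on the
#' forward strand, or where the tag equals the reverse complement of the
#' window (minus strand). No mismatches or gaps are tolerated; ambiguity
#' codes in the reference never match.
#'
#' @param tag Tag sequence (DNA; `U` normalized to `T`).
#' @param reference Reference sequence (character scalar).
#' @param strands Strands to search, subset of `c("+", "-")`.
#' @param ref_name Label recorded in the `ref_name` column.
#' @param count Read count to attach to each hit (a multi-mapping tag carries
#'   its full count at every matching window).
#' @return Hit data.frame with columns `ref_name`, `start` (0-based, forward
#'   strand), `strand`, `length`, `count`, `sequence`, sorted by
#'   `(start, strand)` with `+` before `-`. Zero rows if the tag is absent or
#'   longer than the reference.
#' @export
find_occurrences <- function(tag, reference, strands = c("+", "-"),
                             ref_name = "ref", count = 1L) {
  tag <- normalize_dna(tag)
  stopifnot(length(tag) == 1L, length(reference) == 1L)
  strands <- match.arg(strands, c("+", "-"), several.ok = TRUE)
  if (nchar(tag) > nchar(reference) || nchar(tag) == 0L)
    return(empty_hits())
  subject <- Biostrings::DNAString(reference)
  starts <- integer(0); strand <- character(0)
  if ("+" %in% strands) {
    s <- Biostrings::start(Biostrings::matchPattern(tag, subject, fixed = TRUE)) - 1L
    starts <- c(starts, s); strand <- c(strand, rep("+", length(s)))
  }
  if ("-" %in% strands) {
    s <- Biostrings::start(Biostrings::matchPattern(revcomp(tag), subject,
                                                    fixed = TRUE)) - 1L
    starts <- c(starts, s); strand <- c(strand, rep("-", length(s)))
  }
  hits <- data.frame(ref_name = rep(ref_name, length(starts)),
                     start = starts, strand = strand,
                     length = rep(nchar(tag), length(starts)),
                     count = rep(as.integer(count), length(starts)),
                     sequence = rep(tag, length(starts)),
                     stringsAsFactors = FALSE)
  sort_hits(hits)
}

empty_hits <- function() {
  data.frame(ref_name = character(0), start = integer(0), strand = character(0),
              length = integer(0), count = integer(0), sequence = character(0),
              stringsAsFactors = FALSE)
}

sort_hits <- function(hits) {
  if (nrow(hits))
    hits <- hits[order(hits$start, hits$strand, hits$sequence), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Reverse complement of DNA strings
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Map a collapsed library onto a reference by perfect matching
#'
#' Every tag passing the length filter is placed at all of its exact
#' occurrences on both strands; a tag matching k windows yields k hits, each
#' carrying the tag's full read count.
#'
#' @param library An [srna_library()].
#' @param reference Reference sequence (character scalar).
#' @param length_filter Optional integer set of tag lengths to map (e.g. `21`
#'   for the phasing analysis); `NULL` maps all.
#' @param strands Strands to search.
#' @param ref_name Label for the `ref_name` column.
#' @return Hit data.frame as in [find_occurrences()].
#' @export
map_library <- function(library, reference, length_filter = NULL,
                        strands = c("+", "-"), ref_name = "ref") {
  stopifnot(inherits(library, "srna_library"), nchar(reference) > 0L)
  strands <- match.arg(strands, c("+", "-"), several.ok = TRUE)
  tags <- library$tags
  if (!is.null(length_filter))
    tags <- tags[tags$length %in% as.integer(length_filter), , drop = FALSE]
  tags <- tags[tags$length <= nchar(reference), , drop = FALSE]
  if (!nrow(tags)) return(empty_hits())
  subject <- Biostrings::DNAString(reference)
  pieces <- list()
  for (len in sort(unique(tags$length))) {
    grp <- tags[tags$length == len, , drop = FALSE]
    for (st in strands) {
      seqs <- if (st == "+") grp$sequence else revcomp(grp$sequence)
      m <- Biostrings::matchPDict(Biostrings::PDict(seqs), subject)
      starts <- Biostrings::startIndex(m)
      nhit <- lengths(starts)
      if (sum(nhit) == 0L) next
      pieces[[length(pieces) + 1L]] <- data.frame(
        ref_name = ref_name,
        start = unlist(starts, use.names = FALSE) - 1L,
        strand = st,
        length = len,
        count = rep(grp$count, nhit),
        sequence = rep(grp$sequence, nhit),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(pieces)) return(empty_hits())
  sort_hits(do.call(rbind, pieces))
}

#' Minimal ungapped mismatch count of a tag against a reference
#'
#' Minimum Hamming distance between the tag and any same-length reference
#' window, over both strands. Returns 0 iff an exact occurrence exists. A tag
#' longer than the reference has no alignment and returns `Inf` (treated as
#' "at least one mismatch" by specificity calls).
#'
#' @param tag Tag sequence.
#' @param reference Reference sequence.
#' @return Integer mismatch count (or `Inf`).
#' @export
min_mismatch <- function(tag, reference) {
  tag <- normalize_dna(tag)
  m <- nchar(tag); L <- nchar(reference)
  if (m > L || m == 0L) return(Inf)
  subject <- Biostrings::DNAString(reference)
  at <- seq_len(L - m + 1L)
  d_fwd <- Biostrings::neditStartingAt(Biostrings::DNAString(tag), subject,
                                       starting.at = at, with.indels = FALSE)
  d_rev <- Biostrings::neditStartingAt(Biostrings::DNAString(revcomp(tag)),
                                       subject, starting.at = at,
                                       with.indels = FALSE)
  min(min(d_fwd), min(d_rev))
}

#' Homolog-specific tag test
#'
#' A tag is specific to the target when it matches the target reference
#' perfectly (either strand) and has no exact occurrence on the homolog —
#' i.e. every candidate homolog window carries at least one mismatched
#' nucleotide.
#'
#' @param tag Tag sequence.
#' @param target_ref Target gene sequence the tag must match perfectly.
#' @param homolog_ref Homologous gene sequence the tag must mismatch.
#' @return Logical scalar.
#' @export
is_specific <- function(tag, target_ref, homolog_ref) {
  nrow(find_occurrences(tag, target_ref)) > 0L &&
    min_mismatch(tag, homolog_ref) >= 1
}

#' Export hits as BED6
#'
#' BED columns: reference, 0-based start, end, tag sequence, read count,
#' strand.
#'
#' @param hits Hit data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hits_bed <- function(hits, path) {
  bed <- data.frame(hits$ref_name, hits$start, hits$start + hits$length,
                    hits$sequence, hits$count, hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export strand-specific per-position read coverage as bedGraph
#'
#' Sums read counts of hits covering each position, separately per strand
#' (two output files, suffixed `.plus.bedgraph` / `.minus.bedgraph`),
#' mirroring above/below-axis abundance bar tracks.
#'
#' @param hits Hit data.frame restricted to one reference.
#' @param ref_length Reference length (nt).
#' @param path_prefix Output path prefix.
#' @return Invisibly, character vector of the two paths written.
#' @export
write_coverage_bedgraph <- function(hits, ref_length, path_prefix) {
  paths <- character(2)
  for (i in seq_along(c("+", "-"))) {
    st <- c("+", "-")[i]
    suffix <- c(".plus.bedgraph", ".minus.bedgraph")[i]
    cov <- numeric(ref_length)
    h <- hits[hits$strand == st, , drop = FALSE]
    for (j in seq_len(nrow(h)))
      cov[(h$start[j] + 1L):(h$start[j] + h$length[j])] <-
        cov[(h$start[j] + 1L):(h$start[j] + h$length[j])] + h$count[j]
    run <- rle(cov)
    ends <- cumsum(run$lengths)
    starts <- ends - run$lengths
    keep <- run$values != 0
    bg <- data.frame(ref = hits$ref_name[1] %||% "ref",
                     start = starts[keep], end = ends[keep],
                     value = run$values[keep])
    paths[i] <- paste0(path_prefix, suffix)
    utils::write.table(bg, paths[i], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a
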