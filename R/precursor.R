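#' miRNA precursor annotation
#'
#' Holds a stem-loop sequence with the annotated mature miRNA and star
#' (passenger) intervals, 0-based half-open on the stem-loop.
#'
#' @param stemloop Stem-loop (precursor) sequence.
#' @param mature Integer `c(start, end)` of the mature miRNA (22 nt for
#'   miR173).
#' @param star Integer `c(start, end)` of the miRNA* (21 nt for miR173*).
#' @return List of class `precursor_annotation` with `stemloop`, `mature`,
#'   `star` intervals and the extracted `mature_seq` / `star_seq`.
#' @export
precursor_annotation <- function(stemloop, mature, star) {
  stemloop <- normalize_dna(stemloop)
  mature <- as.integer(mature); star <- as.integer(star)
  L <- nchar(stemloop)
  for (iv in list(mature, star))
    if (!(iv[1] >= 0L && iv[1] < iv[2] && iv[2] <= L))
      stop("mature/star interval out of stem-loop bounds")
  if (max(mature[1], star[1]) < min(mature[2], star[2]))
    stop("mature and star intervals must not overlap")
  structure(list(stemloop = stemloop, mature = mature, star = star,
                 mature_seq = substr(stemloop, mature[1] + 1L, mature[2]),
                 star_seq = substr(stemloop, star[1] + 1L, star[2])),
            class = "precursor_annotation")
}

#' Read a precursor annotation from FASTA plus a BED-style interval file
#'
#' The interval file has two whitespace-separated lines naming the intervals
#' `mature` and `star`: `name start end` with 0-based half-open coordinates.
#'
#' @param stemloop_fasta FASTA file holding the stem-loop sequence (first
#'   record used).
#' @param annotation_file Two-line interval file as above.
#' @return A [precursor_annotation()].
#' @export
read_precursor_annotation <- function(stemloop_fasta, annotation_file) {
  set <- Biostrings::readBStringSet(stemloop_fasta)
  if (length(set) == 0L) stop("empty stem-loop FASTA")
  ann <- utils::read.table(annotation_file, header = FALSE,
                           col.names = c("name", "start", "end"),
                           stringsAsFactors = FALSE)
  get <- function(nm) {
    row <- ann[ann$name == nm, , drop = FALSE]
    if (nrow(row) != 1L) stop(sprintf("annotation must name '%s' exactly once", nm))
    c(row$start, row$end)
  }
  precursor_annotation(as.character(set[[1L]]), get("mature"), get("star"))
}

#' Precursor processing profile
#'
#' Catalogues library tags matching the stem-loop perfectly on its forward
#' strand (hairpin products are sense to the precursor transcript), with
#' signed 5'-end offsets relative to the annotated mature and star species
#' (negative = shifted toward the stem-loop 5' end). Species are sorted by
#' descending read count, ties broken by ascending (start, length). A species
#' occurring at several stem-loop positions (pathological) is assigned its
#' leftmost start and flagged `multi_hit`.
#'
#' @param library An [srna_library()].
#' @param annotation A [precursor_annotation()].
#' @param min_count Minimum read count for a species to be listed (a display
#'   threshold: the reported total of matched reads always covers all
#'   matches).
#' @return data.frame of class `precursor_profile` with columns `sequence`,
#'   `start`, `length`, `count`, `offset_vs_mature`, `offset_vs_star`,
#'   `multi_hit`; attribute `total_matched_reads` holds the read total over
#'   all stem-loop-matched tags.
#' @export
precursor_profile <- function(library, annotation, min_count = 1L) {
  stopifnot(inherits(library, "srna_library"),
            inherits(annotation, "precursor_annotation"))
  tags <- library$tags
  tags <- tags[tags$length <= nchar(annotation$stemloop), , drop = FALSE]
  if (nrow(tags)) {
    subject <- Biostrings::DNAString(annotation$stemloop)
    starts <- vector("list", nrow(tags))
    for (len in unique(tags$length)) {
      sel <- which(tags$length == len)
      m <- Biostrings::matchPDict(Biostrings::PDict(tags$sequence[sel]), subject)
      starts[sel] <- Biostrings::startIndex(m)
    }
    nhit <- lengths(starts)
    matched <- nhit > 0L
    prof <- data.frame(
      sequence = tags$sequence[matched],
      start = vapply(starts[matched], min, 0L) - 1L,
      length = tags$length[matched],
      count = tags$count[matched],
      stringsAsFactors = FALSE)
    prof$offset_vs_mature <- prof$start - annotation$mature[1]
    prof$offset_vs_star <- prof$start - annotation$star[1]
    prof$multi_hit <- nhit[matched] > 1L
  } else {
    prof <- data.frame(sequence = character(0), start = integer(0),
                       length = integer(0), count = integer(0),
                       offset_vs_mature = integer(0),
                       offset_vs_star = integer(0), multi_hit = logical(0),
                       stringsAsFactors = FALSE)
  }
  total <- sum(prof$count)
  prof <- prof[prof$count >= min_count, , drop = FALSE]
  prof <- prof[order(-prof$count, prof$start, prof$length), , drop = FALSE]
  rownames(prof) <- NULL
  attr(prof, "total_matched_reads") <- total
  class(prof) <- c("precursor_profile", "data.frame")
  prof
}

#' Top-k precursor species
#'
#' First `k` entries of the sorted profile (descending count, ties by
#' ascending start then length). If the profile holds fewer than `k` species
#' all are returned with attribute `shortfall` set to the deficit.
#'
#' @param profile A [precursor_profile()].
#' @param k Number of species requested (>= 1).
#' @return The top-k rows, with attribute `shortfall` (0 when the profile was
#'   large enough).
#' @export
dominant_species <- function(profile, k) {
  stopifnot(k >= 1L)
  out <- utils::head(profile, k)
  attr(out, "shortfall") <- max(0L, as.integer(k) - nrow(profile))
  out
}

#' Processing fidelity of a precursor profile
#'
#' Fraction of stem-loop-matched reads carried by species exactly equal to
#' the annotated mature or star sequence. A perfectly diced precursor gives
#' 1; accumulation of shifted species drives it toward 0.
#'
#' @param profile A [precursor_profile()] (built with `min_count = 1` so the
#'   mature/star species are present if cloned at all).
#' @param annotation The matching [precursor_annotation()].
#' @return Numeric fraction in `[0, 1]`; `NA` (with a warning) when no reads
#'   matched the stem-loop.
#' @export
processing_fidelity <- function(profile, annotation) {
  total <- attr(profile, "total_matched_reads")
  if (is.null(total) || total == 0L) {
    warning("no stem-loop-matched reads; fidelity undefined")
    return(NA_real_)
  }
  annotated <- profile$sequence %in% c(annotation$mature_seq,
                                       annotation$star_seq)
  sum(profile$count[annotated]) / total
}

#' Export a precursor profile as TSV
#'
#' @param profile A [precursor_profile()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_precursor_profile <- function(profile, path) {
  write_tsv_commented(
    as.data.frame(profile), path,
    sprintf("# precursor processing profile; 0-based starts; total matched reads = %d",
            attr(profile, "total_matched_reads")))
}
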