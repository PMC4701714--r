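#' Assemble a MIGS expression cassette from ordered elements
#'
#' Concatenates named elements (e.g. 35S promoter, viral translational leader,
#' 22-nt miR173 target site, target gene fragment, terminator) into one
#' transcript-strand reference, records each element as a half-open region,
#' and derives the predicted miRNA cleavage coordinate from the target site.
#'
#' All coordinates are 0-based, half-open, on the forward (transcript) strand.
#'
#' @param elements Named character vector (or named list of single sequences)
#'   in transcript order. Names become region names.
#' @param target_site_name Name of the element holding the miRNA target site;
#'   must occur exactly once. Default `"miR173ts"`.
#' @param mirna_length Length of the triggering miRNA (nt). Defaults to the
#'   length of the target-site element (end-to-end antiparallel pairing).
#' @param cleavage_override Optional explicit 0-based cleavage coordinate
#'   (first nucleotide of the 3' cleavage fragment), overriding the 10/11 rule.
#'
#' @return An object of class `migs_cassette`: list with `sequence`,
#'   `regions` (data.frame `name`,`start`,`end`), `target_site` (one-row
#'   region), and `cleavage_coord`.
#' @seealso [predicted_cleavage_coord()], [region_of()]
#' @export
assemble_cassette <- function(elements, target_site_name = "miR173ts",
                              mirna_length = NULL, cleavage_override = NULL) {
  if (is.list(elements)) elements <- unlist(elements)
  if (is.null(names(elements)) || any(!nzchar(names(elements))))
    stop("all cassette elements must be named")
  seqs <- normalize_dna(elements)
  hits <- which(names(elements) == target_site_name)
  if (length(hits) != 1L)
    stop(sprintf("target-site element '%s' must be present exactly once (found %d)",
                 target_site_name, length(hits)))
  lens <- nchar(seqs)
  ends <- cumsum(lens)
  starts <- ends - lens
  regions <- data.frame(name = names(elements), start = starts, end = ends,
                        stringsAsFactors = FALSE, row.names = NULL)
  target_site <- regions[hits, , drop = FALSE]
  if (is.null(mirna_length)) mirna_length <- lens[hits]
  cleavage <- if (!is.null(cleavage_override)) {
    as.integer(cleavage_override)
  } else {
    predicted_cleavage_coord(target_site, mirna_length)
  }
  if (cleavage <= target_site$start || cleavage >= target_site$end)
    stop("cleavage coordinate must fall strictly inside the target site")
  structure(list(sequence = paste(seqs, collapse = ""),
                 regions = regions,
                 target_site = target_site,
                 cleavage_coord = as.integer(cleavage)),
            class = "migs_cassette")
}

#' @export
print.migs_cassette <- function(x, ...) {
  cat(sprintf("migs_cassette: %d nt, %d regions; target site '%s' [%d,%d); cleavage at %d\n",
              nchar(x$sequence), nrow(x$regions), x$target_site$name,
              x$target_site$start, x$target_site$end, x$cleavage_coord))
  print(x$regions, row.names = FALSE)
  invisible(x)
}

#' Predicted miRNA-guided cleavage coordinate
#'
#' Plant miRNA-guided cleavage cuts the target between the nucleotides that
#' pair with miRNA positions 10 and 11 (counting from the miRNA 5' end). With
#' antiparallel end-to-end pairing over a target site of the miRNA's length,
#' the first nucleotide of the 3' cleavage fragment — the "phase 1" anchor of
#' the downstream phasiRNA register — sits at
#' `target_site$start + (mirna_length - 10)`.
#'
#' @param target_site A region: list or one-row data.frame with 0-based
#'   half-open `start`/`end`.
#' @param mirna_length Length of the miRNA in nt; must equal the target-site
#'   length (supply an explicit override to [assemble_cassette()] for
#'   non-canonical sites).
#' @return Integer 0-based coordinate of the first nucleotide of the 3'
#'   fragment.
#' @export
predicted_cleavage_coord <- function(target_site, mirna_length) {
  start <- as.integer(target_site$start)
  end <- as.integer(target_site$end)
  if (end - start != mirna_length)
    stop("target-site length differs from miRNA length; supply an explicit cleavage coordinate override")
  start + (as.integer(mirna_length) - 10L)
}

#' Region lookup for cassette coordinates
#'
#' @param coord Integer vector of 0-based coordinates;
#'   `0 <= coord < nchar(sequence)`.
#' @param cassette A [assemble_cassette()] object.
#' @return Character vector of region names; `"intergenic"` for coordinates
#'   covered by no region (cannot occur for assembled cassettes, whose regions
#'   tile the sequence).
#' @export
region_of <- function(coord, cassette) {
  stopifnot(inherits(cassette, "migs_cassette"))
  coord <- as.integer(coord)
  if (any(coord < 0L) || any(coord >= nchar(cassette$sequence)))
    stop("coordinate out of range for the cassette sequence")
  reg <- cassette$regions
  idx <- findInterval(coord, reg$start)
  out <- rep("intergenic", length(coord))
  ok <- idx >= 1L & coord < reg$end[pmax(idx, 1L)]
  out[ok] <- reg$name[idx[ok]]
  out
}

#' Export cassette regions as BED
#'
#' Coordinates are 0-based half-open (BED convention).
#'
#' @param cassette A [assemble_cassette()] object.
#' @param path Output BED path.
#' @param ref_name Reference name for the BED chrom column.
#' @return Invisibly, `path`.
#' @export
write_cassette_bed <- function(cassette, path, ref_name = "cassette") {
  bed <- data.frame(chrom = ref_name,
                    start = cassette$regions$start,
                    end = cassette$regions$end,
                    name = cassette$regions$name)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
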