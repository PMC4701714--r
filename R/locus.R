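#' Region-wise tallies of cassette hits
#'
#' For each cassette region: total reads, distinct species, and species above
#' a display threshold. A hit's region is that of its 5' reference start.
#'
#' @param hits Hit data.frame on the cassette (see [map_library()]).
#' @param cassette A [assemble_cassette()] object.
#' @param threshold Read-count display threshold (default 5).
#' @param strict If `TRUE` (default) a species must exceed the threshold
#'   (`> threshold`) to be counted in `species_over_threshold`; `FALSE`
#'   counts `>= threshold`.
#' @return data.frame with one row per region: `region`, `reads`, `species`,
#'   `species_over_threshold`.
#' @export
coverage_by_region <- function(hits, cassette, threshold = 5L, strict = TRUE) {
  stopifnot(inherits(cassette, "migs_cassette"))
  regions <- cassette$regions$name
  out <- data.frame(region = regions, reads = 0L, species = 0L,
                    species_over_threshold = 0L, stringsAsFactors = FALSE)
  if (nrow(hits)) {
    reg <- region_of(hits$start, cassette)
    idx <- match(reg, regions)
    out$reads <- as.integer(rowsum_at(hits$count, idx, length(regions)))
    # species per region: distinct tag sequences among hits starting there
    key <- paste(reg, hits$sequence)
    first <- !duplicated(key)
    out$species <- as.integer(rowsum_at(rep(1L, sum(first)), idx[first],
                                        length(regions)))
    over <- if (strict) hits$count > threshold else hits$count >= threshold
    firstov <- first & over
    out$species_over_threshold <-
      as.integer(rowsum_at(rep(1L, sum(firstov)), idx[firstov],
                           length(regions)))
  }
  out
}

#' Transitivity summary around an anchor interval
#'
#' Splits hits into strictly 5' of, overlapping/within, and strictly 3' of an
#' anchor interval (the cleavage site for the cassette, or the target
#' fragment's homologous segment for an endogenous gene), and issues a
#' directionality verdict: `"5'->3'"` when downstream reads exceed upstream
#' reads by `factor`, `"3'->5'"` for the reverse, otherwise
#' `"not directional"`.
#'
#' @param hits Hit data.frame on one reference.
#' @param anchor_interval Integer `c(start, end)`, 0-based half-open.
#' @param factor Directionality factor (default 10).
#' @return List with `upstream`, `within`, `downstream` (each
#'   `c(reads, species)`), `verdict`, and `max_downstream_count` /
#'   `max_upstream_count` (largest single-species read count on each side).
#' @export
transitivity_summary <- function(hits, anchor_interval, factor = 10) {
  a <- as.integer(anchor_interval)
  stopifnot(length(a) == 2L, a[1] <= a[2])
  end <- hits$start + hits$length
  side <- ifelse(end <= a[1], "upstream",
                 ifelse(hits$start >= a[2], "downstream", "within"))
  tally <- function(s) {
    h <- hits[side == s, , drop = FALSE]
    c(reads = sum(h$count), species = length(unique(h$sequence)))
  }
  up <- tally("upstream"); dn <- tally("downstream"); wi <- tally("within")
  verdict <- if (dn["reads"] > factor * up["reads"] && dn["reads"] > 0)
    "5'->3'"
  else if (up["reads"] > factor * dn["reads"] && up["reads"] > 0)
    "3'->5'"
  else "not directional"
  list(upstream = up, within = wi, downstream = dn, verdict = verdict,
       max_upstream_count = if (any(side == "upstream"))
         max(hits$count[side == "upstream"]) else 0L,
       max_downstream_count = if (any(side == "downstream"))
         max(hits$count[side == "downstream"]) else 0L)
}

#' Catalogue of homolog-specific siRNAs
#'
#' Tags of the stated length with at least one perfect occurrence on the
#' target gene (either strand) and no exact occurrence on the homolog — i.e.
#' at least one mismatched nucleotide at every candidate homolog window.
#'
#' @param library An [srna_library()].
#' @param target_ref Target gene sequence (the gene the tags are specific
#'   to).
#' @param homolog_ref Homologous gene sequence tags must mismatch.
#' @param length Tag length in nt (default 21).
#' @param target_name,homolog_name Labels used in printing.
#' @return Object of class `specific_catalog`: data.frame with columns
#'   `sequence`, `count`, `n_target_hits`, sorted by decreasing count;
#'   attributes `n_species`, `max_count`, `target_name`, `homolog_name`.
#' @export
specific_sirna_catalog <- function(library, target_ref, homolog_ref,
                                   length = 21L, target_name = "target",
                                   homolog_name = "homolog") {
  stopifnot(inherits(library, "srna_library"))
  on_target <- map_library(library, target_ref, length_filter = length,
                           ref_name = target_name)
  cand <- unique(on_target$sequence)
  if (length(cand)) {
    cand_lib <- srna_library(cand, rep(1L, length(cand)))
    on_homolog <- map_library(cand_lib, homolog_ref, length_filter = length,
                              ref_name = homolog_name)
    specific <- setdiff(cand, on_homolog$sequence)
  } else specific <- character(0)
  keep <- on_target[on_target$sequence %in% specific, , drop = FALSE]
  if (length(specific)) {
    nhits <- table(keep$sequence)
    counts <- library$tags$count[match(specific, library$tags$sequence)]
    cat_df <- data.frame(sequence = specific, count = counts,
                         n_target_hits = as.integer(nhits[specific]),
                         stringsAsFactors = FALSE)
    cat_df <- cat_df[order(-cat_df$count, cat_df$sequence), , drop = FALSE]
  } else {
    cat_df <- data.frame(sequence = character(0), count = integer(0),
                         n_target_hits = integer(0), stringsAsFactors = FALSE)
  }
  rownames(cat_df) <- NULL
  attr(cat_df, "n_species") <- nrow(cat_df)
  attr(cat_df, "max_count") <- if (nrow(cat_df)) max(cat_df$count) else 0L
  attr(cat_df, "target_name") <- target_name
  attr(cat_df, "homolog_name") <- homolog_name
  class(cat_df) <- c("specific_catalog", "data.frame")
  cat_df
}

#' @export
print.specific_catalog <- function(x, ...) {
  cat(sprintf("specific_catalog: %d %s-specific species (vs %s), max count %d\n",
              attr(x, "n_species"), attr(x, "target_name"),
              attr(x, "homolog_name"), attr(x, "max_count")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 10L), row.names = FALSE)
  invisible(x)
}

#' Export region tallies or a specific catalog as TSV
#'
#' @param df A data.frame ([coverage_by_region()] or
#'   [specific_sirna_catalog()] output).
#' @param path Output TSV path.
#' @param comment Header comment line.
#' @return Invisibly, `path`.
#' @export
write_locus_tsv <- function(df, path, comment = "# locus summary") {
  write_tsv_commented(as.data.frame(df), path, comment)
}
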