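#' Run the full MIGS analysis and write a report bundle
#'
#' Orchestrates every stage over one library: size distribution, precursor
#' processing profile, cassette phase report (21-nt) plus 22-nt map, region
#' tallies, per-gene transitivity summaries, the homolog-specific siRNA
#' catalogue, and a JSON summary of every headline statistic. All tables are
#' TSV with header comments; coordinates follow BED conventions (0-based,
#' half-open). Any stage failure stops with the stage name and leaves a
#' `FAILED` marker beside the partial outputs.
#'
#' @param library An [srna_library()], or a path to a library file (read via
#'   [read_srna_library()]).
#' @param cassette A [assemble_cassette()] object (optional).
#' @param precursor A [precursor_annotation()] (optional).
#' @param genes Named list of genes (`sequence`, `frag_interval`) as in
#'   [simulate_migs_system()] (optional). When two genes are supplied the
#'   second is catalogued as specific against the first.
#' @param outdir Output directory (created).
#' @param report_threshold Display threshold for region tallies (reads).
#' @param strict_threshold Whether the display threshold is strict (`>`).
#' @param period,overhang Phasing parameters.
#' @param size_range Length window `c(lo, hi)` for the size histogram.
#' @return Invisibly, the summary list (also written as `summary.json`).
#' @export
run_report <- function(library, cassette = NULL, precursor = NULL,
                       genes = NULL, outdir, report_threshold = 5L,
                       strict_threshold = TRUE, period = 21L, overhang = 2L,
                       size_range = c(18L, 26L)) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- "setup"
  on.exit({
    writeLines(sprintf("stage failed: %s", stage), file.path(outdir, "FAILED"))
  })
  fail <- function(s) stage <<- s

  fail("read_library")
  if (is.character(library)) library <- read_srna_library(library)
  stopifnot(inherits(library, "srna_library"))
  summary <- list(library = library$name,
                  total_reads = library$total_reads,
                  unique_tags = nrow(library$tags))

  fail("size_histogram")
  hist <- size_histogram(library, size_range[1], size_range[2])
  write_size_histogram(hist, file.path(outdir, "size_histogram.tsv"))
  peak <- hist$length[order(-hist$read_count)]
  summary$size_peaks <- peak[seq_len(min(2L, sum(hist$read_count > 0)))]

  if (!is.null(precursor)) {
    fail("precursor_profile")
    prof <- precursor_profile(library, precursor, min_count = 1L)
    write_precursor_profile(prof, file.path(outdir, "precursor_profile.tsv"))
    top <- dominant_species(prof, 2L)
    summary$precursor_matched_reads <- attr(prof, "total_matched_reads")
    summary$mature_reads <- sum(prof$count[prof$sequence == precursor$mature_seq])
    summary$star_reads <- sum(prof$count[prof$sequence == precursor$star_seq])
    summary$top_precursor_counts <- top$count
    summary$processing_fidelity <-
      if (attr(prof, "total_matched_reads") > 0)
        processing_fidelity(prof, precursor) else NA
  }

  if (!is.null(cassette)) {
    fail("map_cassette")
    stopifnot(inherits(cassette, "migs_cassette"))
    hits_all <- map_library(library, cassette$sequence,
                            length_filter = seq.int(size_range[1], size_range[2]),
                            ref_name = "cassette")
    hits21 <- hits_all[hits_all$length == period, , drop = FALSE]
    hits22 <- hits_all[hits_all$length == period + 1L, , drop = FALSE]
    write_hits_bed(hits21, file.path(outdir, "cassette_21nt.bed"))
    write_hits_bed(hits22, file.path(outdir, "cassette_22nt.bed"))
    write_coverage_bedgraph(hits21, nchar(cassette$sequence),
                            file.path(outdir, "cassette_21nt"))

    fail("phase_report")
    config <- phasing_config(cassette$cleavage_coord, period = period,
                             overhang = overhang)
    phased <- phase_assign(hits21, config)
    report <- phase_report(phased)
    write_phase_table(phased, file.path(outdir, "phase_table.tsv"))
    write_cycle_summary(report, file.path(outdir, "cycle_summary.tsv"))
    ratio <- length_class_ratio(hits_all, focal_len = period,
                                window = c(period - 1L, period + 3L))
    summary$cassette_reads_21nt <- sum(hits21$count[!duplicated(hits21$sequence)])
    summary$cassette_reads_22nt <- sum(hits22$count[!duplicated(hits22$sequence)])
    summary$max_22nt_count <- if (nrow(hits22)) max(hits22$count) else 0L
    summary$inphase_reads <- report$inphase_reads
    summary$outphase_reads <- report$outphase_reads
    summary$in_out_ratio <- report$in_out_ratio
    summary$in_out_ratio_species <- report$in_out_ratio_species
    summary$ratio_flag <- report$ratio_flag
    summary$out_of_phase_reads <- report$outphase_reads
    summary$phase_occupancy <- length(report$occupancy)
    summary$populated_inphase_cycles <- populated_inphase_cycles(report)
    summary$ratio_21_vs_non21 <- ratio$ratio
    summary$upstream_reads <- report$upstream_reads

    fail("region_tallies")
    tallies <- coverage_by_region(hits21, cassette,
                                  threshold = report_threshold,
                                  strict = strict_threshold)
    write_locus_tsv(tallies, file.path(outdir, "region_tallies.tsv"),
                    "# per-region 21-nt hit tallies")
    summary$region_reads <- stats::setNames(as.list(tallies$reads),
                                            tallies$region)

    fail("cassette_transitivity")
    trans <- transitivity_summary(hits21, c(cassette$cleavage_coord,
                                            cassette$cleavage_coord))
    summary$cassette_transitivity <- trans$verdict
  }

  if (!is.null(genes) && length(genes)) {
    for (gname in names(genes)) {
      fail(paste0("transitivity_", gname))
      g <- genes[[gname]]
      ghits <- map_library(library, g$sequence, length_filter = period,
                           ref_name = gname)
      trans <- transitivity_summary(ghits, g$frag_interval)
      write_locus_tsv(
        data.frame(side = c("upstream", "within", "downstream"),
                   reads = c(trans$upstream["reads"], trans$within["reads"],
                             trans$downstream["reads"]),
                   species = c(trans$upstream["species"],
                               trans$within["species"],
                               trans$downstream["species"])),
        file.path(outdir, sprintf("transitivity_%s.tsv", gname)),
        sprintf("# transitivity around fragment interval; verdict: %s",
                trans$verdict))
      summary[[paste0("transitivity_", gname)]] <- trans$verdict
      summary[[paste0("max_downstream_count_", gname)]] <-
        trans$max_downstream_count
      summary[[paste0("max_upstream_count_", gname)]] <-
        trans$max_upstream_count
    }
    if (length(genes) >= 2L) {
      fail("specific_catalog")
      tn <- names(genes)[2L]; hn <- names(genes)[1L]
      catalog <- specific_sirna_catalog(library, genes[[tn]]$sequence,
                                        genes[[hn]]$sequence, length = period,
                                        target_name = tn, homolog_name = hn)
      write_locus_tsv(catalog, file.path(outdir, "specific_catalog.tsv"),
                      sprintf("# %s-specific 21-nt siRNA catalogue (vs %s)",
                              tn, hn))
      summary$specific_species <- attr(catalog, "n_species")
      summary$specific_max_count <- attr(catalog, "max_count")
    }
  }

  fail("write_summary")
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  on.exit()  # success: clear FAILED handler
  invisible(summary)
}
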