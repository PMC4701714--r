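#' Phasing configuration
#'
#' Parameters of the phase-register analysis: the processing period (21 nt
#' for DCL4 products), the Dicer duplex 3' overhang (2 nt), and the cleavage
#' coordinate anchoring the register (first nucleotide of the 3' cleavage
#' fragment, i.e. phase 1 of cycle 1).
#'
#' @param cleavage_coord 0-based cleavage coordinate on the reference.
#' @param period Processing period in nt (default 21).
#' @param overhang Duplex 3' overhang in nt (default 2); antisense-strand
#'   hits are anchored `overhang` nt 3' of their reference start so that both
#'   strands of one duplex share a phase.
#' @param n_cycles_report Optional cap on the number of downstream cycles
#'   reported; `NULL` reports to the reference end.
#' @return List of class `phasing_config`.
#' @export
phasing_config <- function(cleavage_coord, period = 21L, overhang = 2L,
                           n_cycles_report = NULL) {
  period <- as.integer(period); overhang <- as.integer(overhang)
  if (!(period > overhang && overhang >= 0L))
    stop("need period > overhang >= 0")
  structure(list(cleavage_coord = as.integer(cleavage_coord),
                 period = period, overhang = overhang,
                 n_cycles_report = n_cycles_report),
            class = "phasing_config")
}

#' Assign hits to phases and processing cycles
#'
#' Each period-length hit gets a duplex anchor `a` (its start for sense hits;
#' start + overhang for antisense hits, undoing the 2-nt 3' overhang), a
#' phase `p = ((a - c) mod period) + 1` and a processing cycle
#' `k = floor((a - c) / period) + 1`, where `c` is the cleavage coordinate.
#' Phase 1 is in-phase with the cleavage register; cycle 1 is the first
#' period-length window downstream of the cleavage site; cycles <= 0 lie
#' upstream. Hits whose length differs from the period are excluded from
#' phasing and returned separately with a reason code.
#'
#' @param hits Hit data.frame (see [map_library()]).
#' @param config A [phasing_config()].
#' @return List of class `phased_hits` with elements `phased` (hits plus
#'   `anchor`, `phase`, `cycle` columns), `excluded` (non-period-length hits
#'   plus `reason`), and `config`.
#' @export
phase_assign <- function(hits, config) {
  stopifnot(inherits(config, "phasing_config"))
  ok <- hits$length == config$period
  phased <- hits[ok, , drop = FALSE]
  excluded <- hits[!ok, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- "length_ne_period"
  a <- ifelse(phased$strand == "+", phased$start,
              phased$start + config$overhang)
  d <- a - config$cleavage_coord
  phased$anchor <- as.integer(a)
  phased$phase <- as.integer((d %% config$period) + 1L)
  phased$cycle <- as.integer(floor(d / config$period) + 1L)
  rownames(phased) <- rownames(excluded) <- NULL
  structure(list(phased = phased, excluded = excluded, config = config),
            class = "phased_hits")
}

#' Consolidate sense/antisense duplex partners
#'
#' Paired sense and antisense period-length RNAs with the configured 3'
#' overhang share one duplex anchor; this merges hits by anchor into one
#' small RNA unit carrying sense and antisense read counts.
#'
#' @param phased A [phase_assign()] result, or its `phased` data.frame.
#' @return data.frame with one row per anchor: `anchor`, `phase`, `cycle`,
#'   `sense_reads`, `antisense_reads`, `total_reads`.
#' @export
consolidate_duplexes <- function(phased) {
  df <- if (inherits(phased, "phased_hits")) phased$phased else phased
  if (!nrow(df))
    return(data.frame(anchor = integer(0), phase = integer(0),
                      cycle = integer(0), sense_reads = integer(0),
                      antisense_reads = integer(0), total_reads = integer(0)))
  sense <- rowsum(df$count * (df$strand == "+"), group = df$anchor)
  anti <- rowsum(df$count * (df$strand == "-"), group = df$anchor)
  anchors <- as.integer(rownames(sense))
  first <- df[!duplicated(df$anchor), , drop = FALSE]
  first <- first[match(anchors, first$anchor), , drop = FALSE]
  out <- data.frame(anchor = anchors,
                    phase = first$phase, cycle = first$cycle,
                    sense_reads = as.integer(sense[, 1L]),
                    antisense_reads = as.integer(anti[, 1L]))
  out$total_reads <- out$sense_reads + out$antisense_reads
  out[order(out$anchor), , drop = FALSE]
}

#' Phase-register report
#'
#' Tallies phased reads per phase (1..period) and per processing cycle over a
#' downstream cycle range, computes the in-phase (phase 1) : out-of-phase
#' (phases 2..period) read and species ratios, phase occupancy, a near-phase
#' (phase 2 and phase `period`, i.e. register +/-1) diagnostic, and which
#' cycles have a populated in-phase position. Upstream hits (cycle <= 0) are
#' excluded from all ratios and reported separately.
#'
#' @param phased A [phase_assign()] result.
#' @param cycle_range Integer `c(lo, hi)` of downstream cycles to tally;
#'   default cycle 1 through the last populated cycle (capped by the config's
#'   `n_cycles_report`).
#' @return Object of class `phase_report`: list with `per_phase` (named
#'   integer vector of length `period`), `per_cycle` (data.frame `cycle`,
#'   `inphase_reads`, `outphase_reads`, `inphase_species`, `outphase_species`,
#'   `inphase_populated`), `in_out_ratio`, `in_out_ratio_species`,
#'   `ratio_flag` (`"ok"`, `"all_in_phase"`, `"undefined"`), `occupancy`,
#'   `near_phase_reads`, read totals, and the cycle range used.
#' @export
phase_report <- function(phased, cycle_range = NULL) {
  stopifnot(inherits(phased, "phased_hits"))
  config <- phased$config
  df <- phased$phased
  period <- config$period
  max_cycle <- if (nrow(df) && any(df$cycle >= 1L)) max(df$cycle) else 1L
  if (!is.null(config$n_cycles_report))
    max_cycle <- min(max_cycle, config$n_cycles_report)
  if (is.null(cycle_range)) cycle_range <- c(1L, max_cycle)
  cycle_range <- as.integer(cycle_range)
  if (cycle_range[1] < 1L) stop("cycle_range must start at cycle >= 1")

  upstream <- df[df$cycle <= 0L, , drop = FALSE]
  down <- df[df$cycle >= cycle_range[1] & df$cycle <= cycle_range[2], , drop = FALSE]

  per_phase <- integer(period)
  names(per_phase) <- as.character(seq_len(period))
  if (nrow(down))
    per_phase <- as.integer(rowsum_at(down$count, down$phase, period))
  names(per_phase) <- as.character(seq_len(period))

  cycles <- seq.int(cycle_range[1], cycle_range[2])
  per_cycle <- data.frame(cycle = cycles, inphase_reads = 0L,
                          outphase_reads = 0L, inphase_species = 0L,
                          outphase_species = 0L)
  if (nrow(down)) {
    idx <- match(down$cycle, cycles)
    inph <- down$phase == 1L
    per_cycle$inphase_reads <- as.integer(rowsum_at(down$count * inph, idx,
                                                    length(cycles)))
    per_cycle$outphase_reads <- as.integer(rowsum_at(down$count * !inph, idx,
                                                     length(cycles)))
    sp <- down[!duplicated(down[c("sequence", "cycle", "phase")]), , drop = FALSE]
    idx2 <- match(sp$cycle, cycles)
    per_cycle$inphase_species <- as.integer(
      rowsum_at(as.integer(sp$phase == 1L), idx2, length(cycles)))
    per_cycle$outphase_species <- as.integer(
      rowsum_at(as.integer(sp$phase != 1L), idx2, length(cycles)))
  }
  per_cycle$inphase_populated <- per_cycle$inphase_reads >= 1L

  in_reads <- sum(per_cycle$inphase_reads)
  out_reads <- sum(per_cycle$outphase_reads)
  ratio_flag <- if (in_reads + out_reads == 0L) "undefined"
    else if (out_reads == 0L) "all_in_phase" else "ok"
  in_sp <- if (nrow(down)) length(unique(down$sequence[down$phase == 1L])) else 0L
  out_sp <- if (nrow(down)) length(unique(down$sequence[down$phase != 1L])) else 0L

  occupancy <- sort(unique(down$phase))
  near <- sum(per_phase[c(2L, period)])

  structure(list(per_phase = per_phase,
                 per_cycle = per_cycle,
                 in_out_ratio = if (ratio_flag == "ok") in_reads / out_reads
                                else NA_real_,
                 in_out_ratio_species = if (out_sp > 0L) in_sp / out_sp
                                        else NA_real_,
                 ratio_flag = ratio_flag,
                 inphase_reads = in_reads, outphase_reads = out_reads,
                 inphase_species = in_sp, outphase_species = out_sp,
                 occupancy = occupancy,
                 near_phase_reads = as.integer(near),
                 upstream_reads = sum(upstream$count),
                 excluded_reads = sum(phased$excluded$count),
                 phased_reads = sum(down$count),
                 cycle_range = cycle_range,
                 period = period),
            class = "phase_report")
}

#' Count cycles with a populated in-phase position
#'
#' @param report A [phase_report()].
#' @param cycle_range Optional `c(lo, hi)` restriction within the report's
#'   cycle range.
#' @return Integer: number of cycles whose phase-1 position holds at least
#'   one read.
#' @export
populated_inphase_cycles <- function(report, cycle_range = NULL) {
  stopifnot(inherits(report, "phase_report"))
  pc <- report$per_cycle
  if (!is.null(cycle_range))
    pc <- pc[pc$cycle >= cycle_range[1] & pc$cycle <= cycle_range[2], ,
             drop = FALSE]
  sum(pc$inphase_populated)
}

#' Phase occupancy
#'
#' The set of phases (1..period) holding at least one downstream read.
#'
#' @param phased A [phase_assign()] result.
#' @return Sorted integer vector, subset of `1:period`.
#' @export
phase_occupancy <- function(phased) {
  stopifnot(inherits(phased, "phased_hits"))
  df <- phased$phased
  sort(unique(df$phase[df$cycle >= 1L & df$count >= 1L]))
}

#' @export
print.phase_report <- function(x, ...) {
  cat(sprintf("phase_report (period %d, cycles %d-%d)\n", x$period,
              x$cycle_range[1], x$cycle_range[2]))
  cat(sprintf("  phased reads: %d (in-phase %d, out-of-phase %d)\n",
              x$phased_reads, x$inphase_reads, x$outphase_reads))
  if (x$ratio_flag == "ok") {
    cat(sprintf("  in:out read ratio = 1:%.2f\n",
                x$outphase_reads / x$inphase_reads))
  } else cat(sprintf("  in:out read ratio: %s\n", x$ratio_flag))
  cat(sprintf("  phases occupied: %d of %d; in-phase cycles populated: %d of %d\n",
              length(x$occupancy), x$period,
              populated_inphase_cycles(x), nrow(x$per_cycle)))
  cat(sprintf("  upstream reads (excluded from ratios): %d; non-period-length reads: %d\n",
              x$upstream_reads, x$excluded_reads))
  invisible(x)
}

#' @export
plot.phase_report <- function(x, which = c("phase", "cycle"), ...) {
  which <- match.arg(which)
  if (which == "phase") {
    cols <- rep("grey60", x$period); cols[1] <- "firebrick"
    graphics::barplot(x$per_phase, col = cols, border = NA,
                      xlab = "phase", ylab = "reads",
                      main = "Phase distribution (phase 1 = in-phase)", ...)
  } else {
    m <- t(as.matrix(x$per_cycle[, c("inphase_reads", "outphase_reads")]))
    graphics::barplot(m, names.arg = x$per_cycle$cycle, border = NA,
                      col = c("firebrick", "grey60"), xlab = "processing cycle",
                      ylab = "reads", legend.text = c("in-phase", "out-of-phase"),
                      main = "Reads per processing cycle", ...)
  }
  invisible(x)
}

#' Export a phase table as TSV
#'
#' One row per phased hit (anchor, phase, cycle, strand, reads); coordinates
#' 0-based half-open.
#'
#' @param phased A [phase_assign()] result.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_phase_table <- function(phased, path) {
  df <- phased$phased[, c("anchor", "phase", "cycle", "strand", "count",
                          "sequence")]
  names(df)[5] <- "reads"
  write_tsv_commented(df, path,
                      "# phased hits; anchor is 0-based duplex anchor on the forward strand")
}

#' Export a per-cycle summary as TSV
#'
#' Mirrors a phase-distribution panel: per processing cycle, in-phase and
#' out-of-phase read counts and whether the in-phase position is populated.
#'
#' @param report A [phase_report()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_cycle_summary <- function(report, path) {
  write_tsv_commented(report$per_cycle, path,
                      "# per-cycle phasing summary; inphase_populated = phase-1 position holds >=1 read")
}
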