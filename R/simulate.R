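#' Simulation parameters for synthetic MIGS libraries
#'
#' Defaults emulate the study conditions of a MIGS-silenced transgenic line:
#' phased 21-nt duplexes decaying geometrically over processing cycles with a
#' cumulative register-slip random walk, a minority of 22-nt products at the
#' same anchors, unphased transitive secondary siRNAs downstream of the
#' target fragment in two endogenous homologs at 86% identity, a miRNA
#' precursor processed mostly into 5'-shifted species, and uniform background
#' degradation reads.
#'
#' @param seed Integer RNG seed; identical params + seed give byte-identical
#'   libraries.
#' @param n_cycles Number of downstream processing cycles generated (capped
#'   to fit the cassette).
#' @param duplex_mean Mean duplex reads of cycle 1; cycle k draws
#'   `Poisson(duplex_mean * decay^(k-1))` reads.
#' @param decay Per-cycle geometric abundance decay (default 0.7).
#' @param slip_prob Probability per cycle boundary of a +/-1 nt register slip
#'   that propagates to all later cycles.
#' @param strand_bias Fraction of duplex reads sampled from the sense strand.
#' @param frac_22nt Fraction of cassette-derived reads emitted as 22-mers at
#'   the same anchors.
#' @param secondary_rate Expected secondary siRNA reads per endogenous-gene
#'   position downstream of the fragment.
#' @param background_rate Expected uniform degradation reads per reference.
#' @param identity Pairwise identity of the simulated homolog pair.
#' @param precursor_reads Total precursor-derived reads.
#' @param precursor_profile data.frame describing the precursor processing
#'   profile; see [default_precursor_profile()]. Proportions must sum to
#'   <= 1; the remainder is emitted as random stem-loop fragments.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(seed = 1L, n_cycles = 25L, duplex_mean = 1000,
                       decay = 0.7, slip_prob = 0.15, strand_bias = 0.5,
                       frac_22nt = 0.2, secondary_rate = 5,
                       background_rate = 50, identity = 0.86,
                       precursor_reads = 3190,
                       precursor_profile = default_precursor_profile()) {
  probs <- c(slip_prob, strand_bias, frac_22nt)
  if (any(probs < 0) || any(probs > 1))
    stop("slip_prob, strand_bias and frac_22nt must lie in [0, 1]")
  if (identity <= 0 || identity > 1) stop("identity must lie in (0, 1]")
  if (n_cycles < 1L) stop("n_cycles must be >= 1")
  if (!is.null(precursor_profile) && sum(precursor_profile$proportion) > 1 + 1e-9)
    stop("precursor profile proportions must sum to <= 1")
  structure(list(seed = as.integer(seed), n_cycles = as.integer(n_cycles),
                 duplex_mean = duplex_mean, decay = decay,
                 slip_prob = slip_prob, strand_bias = strand_bias,
                 frac_22nt = frac_22nt, secondary_rate = secondary_rate,
                 background_rate = background_rate, identity = identity,
                 precursor_reads = as.integer(precursor_reads),
                 precursor_profile = precursor_profile),
            class = "sim_params")
}

#' Default precursor processing profile
#'
#' The processing pattern observed for the heterologous miR173 precursor in
#' MIGS petunia: the mature 22-mer is rare, the star 21-mer is almost absent,
#' and two species shifted 4 nt toward the precursor 5' end of the star
#' (20-nt and 21-nt) dominate. Proportions follow the printed read counts
#' 98 : 3 : 2047 : 876 of a 3,190-read precursor-matched total; the remaining
#' ~5% is emitted as random degradation fragments of the stem-loop.
#'
#' @return data.frame with columns `anchor` (`"mature"` or `"star"`),
#'   `offset` (signed nt shift of the 5' end vs the anchor), `length`, and
#'   `proportion`.
#' @export
default_precursor_profile <- function() {
  data.frame(anchor = c("mature", "star", "star", "star"),
             offset = c(0L, 0L, -4L, -4L),
             length = c(22L, 21L, 20L, 21L),
             proportion = c(98, 3, 2047, 876) / 3190,
             stringsAsFactors = FALSE)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a homolog pair at a given identity
#'
#' Gene A is uniform random DNA; gene B carries i.i.d. substitutions at rate
#' `1 - identity` (each substituted site becomes one of the three other
#' bases).
#'
#' @param seed Integer RNG seed.
#' @param length Gene length in nt (>= 100).
#' @param identity Target pairwise identity in (0, 1].
#' @return List with `geneA`, `geneB`, `subst_pos` (0-based substituted
#'   positions), and `realized_identity`.
#' @export
simulate_homolog_pair <- function(seed, length, identity = 0.86) {
  stopifnot(length >= 100L, identity > 0, identity <= 1)
  set.seed(as.integer(seed))
  mutate_gene(random_dna(length), identity)
}

mutate_gene <- function(geneA, identity) {
  length <- nchar(geneA)
  a <- strsplit(geneA, "")[[1L]]
  hit <- which(stats::runif(length) < (1 - identity))
  b <- a
  for (i in hit) b[i] <- sample(setdiff(c("A", "C", "G", "T"), a[i]), 1L)
  list(geneA = geneA, geneB = paste(b, collapse = ""),
       subst_pos = hit - 1L,
       realized_identity = 1 - length(hit) / length)
}

#' Simulate a complete MIGS reference system
#'
#' Builds, from one seed: a random endogenous gene pair at the requested
#' identity sharing a target-fragment interval; a MIGS cassette (35S
#' promoter, viral translational leader, 22-nt miR173 target site, the
#' fragment cut from gene A, 35S terminator); and a stem-loop precursor with
#' annotated mature (22 nt) and star (21 nt) intervals.
#'
#' @param seed Integer RNG seed.
#' @param gene_length,frag_start,frag_length Geometry of the endogenous genes
#'   and the fragment cloned into the cassette (0-based `frag_start`).
#' @param identity Pairwise identity of the homolog pair.
#' @param promoter_length,tl_length,terminator_length Lengths of the
#'   non-fragment cassette elements.
#' @param target_site 22-nt miR173 target-site sequence (default: the shared
#'   primer-encoded site used in MIGS constructs).
#' @return List of class `migs_system`: `cassette` ([assemble_cassette()]),
#'   `genes` (named list, each with `sequence`, `frag_interval`,
#'   `subst_pos`), `precursor` ([precursor_annotation()]),
#'   `realized_identity`.
#' @export
simulate_migs_system <- function(seed = 1L, gene_length = 1600L,
                                 frag_start = 400L, frag_length = 463L,
                                 identity = 0.86, promoter_length = 300L,
                                 tl_length = 140L, terminator_length = 200L,
                                 target_site = "GTGATTTTTCTCTACAAGCGAA") {
  set.seed(as.integer(seed))
  stopifnot(frag_start + frag_length <= gene_length)
  pair <- mutate_gene(random_dna(gene_length), identity)
  fragment <- substr(pair$geneA, frag_start + 1L, frag_start + frag_length)
  cassette <- assemble_cassette(c(
    promoter_35S = random_dna(promoter_length),
    TL = random_dna(tl_length),
    miR173ts = target_site,
    target_fragment = fragment,
    terminator_35S = random_dna(terminator_length)))
  frag_iv <- c(frag_start, frag_start + frag_length)
  genes <- list(
    geneA = list(sequence = pair$geneA, frag_interval = frag_iv,
                 subst_pos = pair$subst_pos),
    geneB = list(sequence = pair$geneB, frag_interval = frag_iv,
                 subst_pos = pair$subst_pos))
  stemloop <- random_dna(110L)
  precursor <- precursor_annotation(stemloop, mature = c(15L, 37L),
                                    star = c(62L, 83L))
  structure(list(cassette = cassette, genes = genes, precursor = precursor,
                 realized_identity = pair$realized_identity),
            class = "migs_system")
}

#' Simulate a small RNA library with ground-truth labels
#'
#' Emits, per the parameters: (i) phased 21-nt duplex reads at anchors
#' `c + (k-1)*21 + cumulative slip` for cycles k = 1..n_cycles, Poisson
#' counts with geometric decay, sense/antisense split by `strand_bias`,
#' antisense reads starting 2 nt 5' of the anchor (2-nt 3' overhang); (ii) a
#' `frac_22nt` share emitted as 22-mers at the same anchors; (iii) unphased
#' secondary siRNA reads at uniform positions strictly 3' of the fragment
#' interval of each endogenous gene, both strands; (iv) precursor reads per
#' the processing profile; (v) uniform background degradation reads
#' (18-26 nt) from every reference. Every read is truth-labelled with its
#' origin, position, strand, cycle and realized register offset, enabling
#' two-route (pipeline vs truth) parameter-recovery checks.
#'
#' @param cassette A [assemble_cassette()] object, or `NULL` to skip
#'   cassette-derived reads.
#' @param genes Named list of genes as in [simulate_migs_system()], or
#'   `NULL`.
#' @param precursor A [precursor_annotation()], or `NULL`.
#' @param params A [sim_params()].
#' @return List of class `migs_sim` with `library` ([srna_library()]),
#'   `truth` (data.frame with one row per distinct (origin, placement):
#'   `sequence`, `origin`, `ref`, `start`, `strand`, `length`, `cycle`,
#'   `offset`, `reads`, `shared_with_homolog`), `cycle_offsets` (realized
#'   register offset per cycle), and `params`.
#' @export
simulate_library <- function(cassette = NULL, genes = NULL, precursor = NULL,
                             params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  truth <- list()
  cycle_offsets <- integer(0)

  if (!is.null(cassette)) {
    stopifnot(inherits(cassette, "migs_cassette"))
    cs <- cassette$sequence
    cc <- cassette$cleavage_coord
    L <- nchar(cs)
    # cap cycles so every anchor (with worst-case slip) fits a 22-mer duplex
    nc <- params$n_cycles
    while (nc > 1L && cc + (nc - 1L) * 21L + (nc - 1L) + 22L > L) nc <- nc - 1L
    slips <- stats::rbinom(max(nc - 1L, 0L), 1L, params$slip_prob) *
      sample(c(-1L, 1L), max(nc - 1L, 0L), replace = TRUE)
    off <- cumsum(c(0L, slips))
    cycle_offsets <- off
    anchors <- cc + (seq_len(nc) - 1L) * 21L + off
    n_k <- stats::rpois(nc, params$duplex_mean * params$decay^(seq_len(nc) - 1L))
    n22 <- stats::rbinom(nc, n_k, params$frac_22nt)
    n21 <- n_k - n22
    s21 <- stats::rbinom(nc, n21, params$strand_bias)
    s22 <- stats::rbinom(nc, n22, params$strand_bias)
    duplex_rows <- function(len, sense_n, anti_n) {
      sense_seq <- substr_many(cs, anchors, anchors + len)
      anti_seq <- revcomp_many(substr_many(cs, anchors - 2L, anchors + len - 2L))
      rbind(
        data.frame(sequence = sense_seq, start = anchors, strand = "+",
                   length = len, cycle = seq_len(nc), offset = off,
                   reads = sense_n, stringsAsFactors = FALSE),
        data.frame(sequence = anti_seq, start = anchors - 2L, strand = "-",
                   length = len, cycle = seq_len(nc), offset = off,
                   reads = anti_n, stringsAsFactors = FALSE))
    }
    dup <- rbind(duplex_rows(21L, s21, n21 - s21),
                 duplex_rows(22L, s22, n22 - s22))
    dup <- dup[dup$reads > 0L, , drop = FALSE]
    if (nrow(dup)) {
      dup$origin <- ifelse(dup$offset == 0L, "phased_primary", "slipped")
      dup$ref <- "cassette"
      dup$shared_with_homolog <- NA
      truth[[length(truth) + 1L]] <- dup
    }
  }

  if (!is.null(genes)) {
    for (gname in names(genes)) {
      g <- genes[[gname]]
      Lg <- nchar(g$sequence)
      lo <- g$frag_interval[2]          # first start strictly 3' of fragment
      hi <- Lg - 21L
      if (hi < lo) next
      n_pos <- hi - lo + 1L
      n_sec <- stats::rpois(1L, params$secondary_rate * n_pos)
      if (n_sec > 0L) {
        pos <- sample(seq.int(lo, hi), n_sec, replace = TRUE)
        strand <- sample(c("+", "-"), n_sec, replace = TRUE)
        agg <- stats::aggregate(list(reads = rep(1L, n_sec)),
                                by = list(start = pos, strand = strand), sum)
        seqs <- substr_many(g$sequence, agg$start, agg$start + 21L)
        seqs[agg$strand == "-"] <- revcomp_many(seqs[agg$strand == "-"])
        truth[[length(truth) + 1L]] <- data.frame(
          sequence = seqs, start = agg$start, strand = agg$strand,
          length = 21L, cycle = NA_integer_, offset = NA_integer_,
          reads = agg$reads, origin = paste0("secondary:", gname),
          ref = gname,
          shared_with_homolog = !window_has_subst(agg$start, 21L, g$subst_pos),
          stringsAsFactors = FALSE)
      }
    }
  }

  if (!is.null(precursor)) {
    stopifnot(inherits(precursor, "precursor_annotation"))
    prof <- params$precursor_profile
    sl <- precursor$stemloop
    Ls <- nchar(sl)
    props <- prof$proportion
    rest <- max(0, 1 - sum(props))
    n_sp <- as.integer(stats::rmultinom(1L, params$precursor_reads,
                                        c(props, rest)))
    starts <- ifelse(prof$anchor == "mature", precursor$mature[1],
                     precursor$star[1]) + prof$offset
    if (any(starts < 0L) || any(starts + prof$length > Ls))
      stop("precursor profile species fall outside the stem-loop")
    keep <- which(n_sp[seq_len(nrow(prof))] > 0L)
    if (length(keep)) {
      truth[[length(truth) + 1L]] <- data.frame(
        sequence = substr_many(sl, starts[keep], starts[keep] + prof$length[keep]),
        start = starts[keep], strand = "+", length = prof$length[keep],
        cycle = NA_integer_, offset = NA_integer_, reads = n_sp[keep],
        origin = sprintf("precursor:%s%+d/%d", prof$anchor[keep],
                         prof$offset[keep], prof$length[keep]),
        ref = "precursor", shared_with_homolog = NA,
        stringsAsFactors = FALSE)
    }
    n_rest <- n_sp[length(n_sp)]
    if (n_rest > 0L) {
      lens <- sample(19:24, n_rest, replace = TRUE)
      pos <- vapply(lens, function(l) sample.int(Ls - l + 1L, 1L) - 1L, 0L)
      agg <- stats::aggregate(list(reads = rep(1L, n_rest)),
                              by = list(start = pos, length = lens), sum)
      truth[[length(truth) + 1L]] <- data.frame(
        sequence = substr_many(sl, agg$start, agg$start + agg$length),
        start = agg$start, strand = "+", length = agg$length,
        cycle = NA_integer_, offset = NA_integer_, reads = agg$reads,
        origin = "precursor:other", ref = "precursor",
        shared_with_homolog = NA, stringsAsFactors = FALSE)
    }
  }

  refs <- c(if (!is.null(cassette)) list(cassette = cassette$sequence),
            if (!is.null(genes)) lapply(genes, `[[`, "sequence"),
            if (!is.null(precursor)) list(precursor = precursor$stemloop))
  if (params$background_rate > 0 && length(refs)) {
    for (rname in names(refs)) {
      rs <- refs[[rname]]
      Lr <- nchar(rs)
      n_bg <- stats::rpois(1L, params$background_rate)
      if (n_bg == 0L) next
      lens <- sample(18:26, n_bg, replace = TRUE)
      lens <- pmin(lens, Lr)
      pos <- vapply(lens, function(l) sample.int(Lr - l + 1L, 1L) - 1L, 0L)
      strand <- sample(c("+", "-"), n_bg, replace = TRUE)
      agg <- stats::aggregate(list(reads = rep(1L, n_bg)),
                              by = list(start = pos, length = lens,
                                        strand = strand), sum)
      seqs <- substr_many(rs, agg$start, agg$start + agg$length)
      seqs[agg$strand == "-"] <- revcomp_many(seqs[agg$strand == "-"])
      shared <- rep(NA, nrow(agg))
      if (!is.null(genes) && rname %in% names(genes)) {
        sp <- genes[[rname]]$subst_pos
        shared <- ifelse(agg$length == 21L,
                         !window_has_subst(agg$start, 21L, sp), NA)
      }
      truth[[length(truth) + 1L]] <- data.frame(
        sequence = seqs, start = agg$start, strand = agg$strand,
        length = agg$length, cycle = NA_integer_, offset = NA_integer_,
        reads = agg$reads, origin = paste0("background:", rname),
        ref = rname, shared_with_homolog = shared, stringsAsFactors = FALSE)
    }
  }

  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(sequence = character(0), start = integer(0),
               strand = character(0), length = integer(0),
               cycle = integer(0), offset = integer(0), reads = integer(0),
               origin = character(0), ref = character(0),
               shared_with_homolog = logical(0), stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  lib <- srna_library(truth$sequence, truth$reads, name = "simulated")
  structure(list(library = lib, truth = truth,
                 cycle_offsets = cycle_offsets, params = params),
            class = "migs_sim")
}

# substr over vectors of 0-based half-open [from, to) coordinates
substr_many <- function(x, from, to) {
  substring(x, from + 1L, to)
}

revcomp_many <- function(x) if (length(x)) revcomp(x) else x

window_has_subst <- function(starts, len, subst_pos) {
  if (!length(subst_pos)) return(rep(FALSE, length(starts)))
  vapply(starts, function(p) any(subst_pos >= p & subst_pos < p + len),
         logical(1))
}

#' Truth-labelled homolog-specific tag set
#'
#' From a simulation's ground truth: the unique 21-nt tag sequences derived
#' from the target gene (secondary siRNAs or background degradation) whose
#' window carries at least one substituted site, i.e. tags not shared with
#' the homolog. This is the truth counterpart of
#' [specific_sirna_catalog()].
#'
#' @param sim A [simulate_library()] result.
#' @param target_name Name of the target gene in the simulation's reference
#'   set.
#' @return Character vector of tag sequences (sorted).
#' @export
specific_truth_set <- function(sim, target_name) {
  t <- sim$truth
  rows <- t$ref == target_name & t$length == 21L &
    !is.na(t$shared_with_homolog) & !t$shared_with_homolog
  sort(unique(t$sequence[rows]))
}

#' Truth-route in-phase read fraction
#'
#' Fraction of cassette-derived 21-nt duplex reads whose realized register
#' offset is 0 modulo the period — the ground-truth counterpart of the
#' phase-1 read fraction computed by the phasing engine.
#'
#' @param sim A [simulate_library()] result.
#' @param period Processing period (default 21).
#' @return Numeric fraction, or `NA` if no such reads exist.
#' @export
truth_inphase_fraction <- function(sim, period = 21L) {
  t <- sim$truth
  rows <- t$ref == "cassette" & t$length == period & !is.na(t$offset)
  if (!any(rows)) return(NA_real_)
  sum(t$reads[rows & t$offset %% period == 0L]) / sum(t$reads[rows])
}

#' Write a simulation to disk
#'
#' Library as collapsed FASTA, truth as TSV, parameters as a JSON manifest.
#'
#' @param sim A [simulate_library()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_collapsed_fasta(sim$library, file.path(dir, "library.fa"))
  write_tsv_commented(sim$truth, file.path(dir, "truth.tsv"),
                      "# per-read-group ground truth; 0-based starts")
  params <- sim$params
  params$precursor_profile <- NULL
  jsonlite::write_json(c(unclass(params),
                         list(cycle_offsets = sim$cycle_offsets)),
                       file.path(dir, "params.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
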