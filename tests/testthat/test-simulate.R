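test_that("homolog pair generation hits the requested identity", {
  same <- simulate_homolog_pair(seed = 1, length = 500, identity = 1.0)
  expect_equal(same$geneA, same$geneB)
  expect_equal(same$realized_identity, 1.0)

  pair <- simulate_homolog_pair(seed = 2, length = 1200, identity = 0.86)
  aligned <- mean(strsplit(pair$geneA, "")[[1]] ==
                    strsplit(pair$geneB, "")[[1]])
  expect_equal(aligned, pair$realized_identity)
  expect_lt(abs(pair$realized_identity - 0.86), 0.02)
  # substituted positions are exactly where the strings differ
  diffs <- which(strsplit(pair$geneA, "")[[1]] !=
                   strsplit(pair$geneB, "")[[1]]) - 1L
  expect_equal(sort(pair$subst_pos), diffs)
})

test_that("simulation is deterministic for identical seed and parameters", {
  sys <- simulate_migs_system(seed = 5)
  p <- sim_params(seed = 7, duplex_mean = 300)
  a <- simulate_library(sys$cassette, sys$genes, sys$precursor, p)
  b <- simulate_library(sys$cassette, sys$genes, sys$precursor, p)
  expect_identical(a$library, b$library)
  expect_identical(a$truth, b$truth)
  # same seed twice for the system builder too
  expect_identical(simulate_migs_system(seed = 5)$cassette$sequence,
                   sys$cassette$sequence)
})

test_that("truth labels partition the library and conserve reads", {
  sys <- simulate_migs_system(seed = 6)
  sim <- simulate_library(sys$cassette, sys$genes, sys$precursor,
                          sim_params(seed = 8, duplex_mean = 500))
  expect_equal(sum(sim$truth$reads), sim$library$total_reads)
  by_cat <- tapply(sim$truth$reads, sub(":.*$", "", sim$truth$origin), sum)
  expect_equal(sum(by_cat), sim$library$total_reads)
  expect_true(all(c("phased_primary", "secondary", "precursor",
                    "background") %in% names(by_cat)))
  # per-sequence truth totals equal library tag counts
  per_seq <- tapply(sim$truth$reads, sim$truth$sequence, sum)
  tags <- sim$library$tags
  expect_equal(as.integer(per_seq[tags$sequence]), tags$count)
})

test_that("slip-free simulation places every cassette 21-mer in phase 1", {
  sys <- simulate_migs_system(seed = 9)
  sim <- simulate_library(sys$cassette, genes = NULL, precursor = NULL,
                          sim_params(seed = 10, slip_prob = 0,
                                     secondary_rate = 0, background_rate = 0,
                                     duplex_mean = 400))
  hits <- map_library(sim$library, sys$cassette$sequence, length_filter = 21,
                      ref_name = "cassette")
  ph <- phase_assign(hits, phasing_config(sys$cassette$cleavage_coord))
  expect_true(all(ph$phased$phase == 1L))
  rep <- phase_report(ph)
  expect_equal(rep$outphase_reads, 0L)
  expect_equal(rep$ratio_flag, "all_in_phase")
  expect_equal(truth_inphase_fraction(sim), 1.0)
})

test_that("pipeline and truth routes agree exactly on the in-phase fraction", {
  sys <- simulate_migs_system(seed = 11)
  sim <- simulate_library(sys$cassette, genes = NULL, precursor = NULL,
                          sim_params(seed = 12, slip_prob = 0.15,
                                     n_cycles = 25, secondary_rate = 0,
                                     background_rate = 0,
                                     duplex_mean = 2000))
  hits <- map_library(sim$library, sys$cassette$sequence, length_filter = 21,
                      ref_name = "cassette")
  rep <- phase_report(phase_assign(hits,
                                   phasing_config(sys$cassette$cleavage_coord)))
  engine <- rep$inphase_reads / rep$phased_reads
  expect_equal(engine, truth_inphase_fraction(sim))
})

test_that("antisense duplex reads carry the 2-nt 3' overhang geometry", {
  sys <- simulate_migs_system(seed = 13)
  sim <- simulate_library(sys$cassette, genes = NULL, precursor = NULL,
                          sim_params(seed = 14, duplex_mean = 200,
                                     secondary_rate = 0, background_rate = 0))
  t21 <- sim$truth[sim$truth$length == 21L, ]
  anti <- t21[t21$strand == "-", ]
  sense <- t21[t21$strand == "+", ]
  # antisense starts sit 2 nt 5' of the sense anchors of the same cycle
  common <- intersect(anti$cycle, sense$cycle)
  expect_gt(length(common), 5)
  m <- match(common, sense$cycle)
  a <- match(common, anti$cycle)
  expect_true(all(anti$start[a] == sense$start[m] - 2L))
  # antisense sequences are reverse complements of the cassette window
  i <- which(anti$cycle == 1L)[1]
  win <- substr(sys$cassette$sequence, anti$start[i] + 1L, anti$start[i] + 21L)
  expect_equal(anti$sequence[i], revcomp(win))
})

test_that("secondary reads land strictly downstream of the fragment interval", {
  sys <- simulate_migs_system(seed = 15)
  sim <- simulate_library(cassette = NULL, genes = sys$genes,
                          precursor = NULL,
                          sim_params(seed = 16, secondary_rate = 2,
                                     background_rate = 0))
  sec <- sim$truth[grepl("^secondary:", sim$truth$origin), ]
  expect_gt(nrow(sec), 0)
  expect_true(all(sec$start >= sys$genes$geneA$frag_interval[2]))
  # unphased by construction: many distinct registers at this density
  ph <- unique(sec$start %% 21L)
  expect_gt(length(ph), 10)
})

test_that("precursor profile proportions are recovered from a simulated library", {
  sys <- simulate_migs_system(seed = 17)
  sim <- simulate_library(cassette = NULL, genes = NULL,
                          precursor = sys$precursor,
                          sim_params(seed = 18, precursor_reads = 3000,
                                     background_rate = 0))
  prof <- precursor_profile(sim$library, sys$precursor)
  expect_equal(attr(prof, "total_matched_reads"), sim$library$total_reads)
  top <- dominant_species(prof, 1)
  expect_equal(top$offset_vs_star, -4L)
  expect_equal(top$length, 20L)
})

test_that("in-phase fraction is monotone in slip and specificity grows with divergence", {
  # parameter recovery in miniature (the full grid runs in the acceptance suite)
  fractions <- vapply(c(0, 0.3), function(slip) {
    sys <- simulate_migs_system(seed = 19)
    sim <- simulate_library(sys$cassette, NULL, NULL,
                            sim_params(seed = 20, slip_prob = slip,
                                       secondary_rate = 0,
                                       background_rate = 0,
                                       duplex_mean = 1500))
    truth_inphase_fraction(sim)
  }, 0)
  expect_lt(fractions[2], fractions[1])

  species <- vapply(c(0.95, 0.80), function(id) {
    sys <- simulate_migs_system(seed = 21, identity = id)
    sim <- simulate_library(NULL, sys$genes, NULL,
                            sim_params(seed = 22, secondary_rate = 3,
                                       background_rate = 0))
    length(specific_truth_set(sim, "geneB"))
  }, 0)
  expect_gt(species[2], species[1])
})
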