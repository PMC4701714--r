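cfg <- phasing_config(cleavage_coord = 100L)

test_that("phase and cycle assignment follows the cleavage register", {
  hits <- make_hits(start = c(100, 121, 98, 102),
                    strand = c("+", "+", "-", "+"))
  ph <- phase_assign(hits, cfg)$phased
  # sense 21-mer at the cleavage coordinate: phase 1, cycle 1
  expect_equal(ph$phase[1], 1L); expect_equal(ph$cycle[1], 1L)
  # one period downstream: phase 1, cycle 2
  expect_equal(ph$phase[2], 1L); expect_equal(ph$cycle[2], 2L)
  # antisense starting at c-2 (2-nt 3' overhang): anchor c, phase 1, cycle 1
  expect_equal(ph$anchor[3], 100L)
  expect_equal(ph$phase[3], 1L); expect_equal(ph$cycle[3], 1L)
  # sense at c+2: phase 3
  expect_equal(ph$phase[4], 3L); expect_equal(ph$cycle[4], 1L)
})

test_that("non-period-length hits are excluded with a reason code", {
  hits <- make_hits(c(100, 100), "+", length = c(21L, 22L))
  ph <- phase_assign(hits, cfg)
  expect_equal(nrow(ph$phased), 1L)
  expect_equal(nrow(ph$excluded), 1L)
  expect_equal(ph$excluded$reason, "length_ne_period")
  expect_equal(ph$excluded$length, 22L)
})

test_that("duplex geometry: a constructed antisense partner shares the sense phase", {
  set.seed(12)
  for (a in sample(50:400, 25)) {
    hits <- make_hits(c(a, a - 2L), c("+", "-"))
    ph <- phase_assign(hits, cfg)$phased
    expect_equal(ph$phase[1], ph$phase[2])
    expect_equal(ph$cycle[1], ph$cycle[2])
    expect_equal(ph$anchor[1], ph$anchor[2])
  }
})

test_that("phase/cycle agree with brute-force enumeration of phased positions", {
  set.seed(13)
  starts <- sample(0:2000, 400, replace = TRUE)
  strands <- sample(c("+", "-"), 400, replace = TRUE)
  ph <- phase_assign(make_hits(starts, strands), cfg)$phased
  anchors <- ifelse(strands == "+", starts, starts + 2L)
  for (i in seq_len(60)) {
    want <- oracle_phase_cycle(anchors[i], 100L)
    expect_equal(ph$phase[i], unname(want["phase"]))
    expect_equal(ph$cycle[i], unname(want["cycle"]))
  }
})

test_that("register equivariance: shifting cleavage by one period shifts cycles only", {
  set.seed(14)
  hits <- make_hits(sample(200:1000, 100, replace = TRUE),
                    sample(c("+", "-"), 100, replace = TRUE))
  a <- phase_assign(hits, phasing_config(100L))$phased
  b <- phase_assign(hits, phasing_config(121L))$phased
  expect_equal(a$phase, b$phase)
  expect_equal(a$cycle, b$cycle + 1L)
})

test_that("duplex consolidation merges anchors and keeps off-by-one apart", {
  hits <- make_hits(c(100, 98), c("+", "-"), count = c(10L, 4L),
                    sequence = c("S1", "S2"))
  hits$sequence <- c(strrep("A", 21), strrep("C", 21))
  units <- consolidate_duplexes(phase_assign(hits, cfg))
  expect_equal(nrow(units), 1L)
  expect_equal(units$sense_reads, 10L)
  expect_equal(units$antisense_reads, 4L)

  # antisense off by one nucleotide anchors elsewhere, never merged
  hits2 <- make_hits(c(100, 97), c("+", "-"), count = c(10L, 4L))
  units2 <- consolidate_duplexes(phase_assign(hits2, cfg))
  expect_equal(nrow(units2), 2L)
  expect_equal(sort(units2$anchor), c(99L, 100L))

  # sense-only hit yields a unit with zero antisense reads
  units3 <- consolidate_duplexes(phase_assign(make_hits(100, "+"), cfg))
  expect_equal(units3$antisense_reads, 0L)
})

test_that("phase report arithmetic: 1:1 hand-built case and occupancy", {
  hits <- make_hits(c(100, 121, 102), "+", count = c(5L, 5L, 10L),
                    sequence = c("A1", "A2", "A3"))
  hits$sequence <- vapply(1:3, function(i) rand_dna(21), "")
  rep <- phase_report(phase_assign(hits, cfg))
  expect_equal(rep$inphase_reads, 10L)
  expect_equal(rep$outphase_reads, 10L)
  expect_equal(rep$in_out_ratio, 1.0)
  expect_equal(unname(rep$per_phase[1]), 10L)
  expect_equal(unname(rep$per_phase[3]), 10L)
  expect_equal(rep$occupancy, c(1L, 3L))
  expect_equal(populated_inphase_cycles(rep), 2L)
  expect_equal(populated_inphase_cycles(rep, c(1, 1)), 1L)
})

test_that("empty and all-in-phase inputs are flagged, not crashed", {
  empty <- phase_report(phase_assign(make_hits(integer(0), character(0)), cfg))
  expect_equal(empty$ratio_flag, "undefined")
  expect_true(is.na(empty$in_out_ratio))

  allin <- phase_report(phase_assign(make_hits(c(100, 142), "+",
                                               count = c(2L, 3L)), cfg))
  expect_equal(allin$ratio_flag, "all_in_phase")
})

test_that("report conserves reads: phased + upstream + excluded reconcile", {
  set.seed(15)
  hits <- make_hits(sample(0:900, 300, replace = TRUE),
                    sample(c("+", "-"), 300, replace = TRUE),
                    length = sample(c(20L, 21L, 22L), 300, replace = TRUE,
                                    prob = c(.1, .8, .1)),
                    count = sample(1:50, 300, replace = TRUE))
  ph <- phase_assign(hits, cfg)
  rep <- phase_report(ph)
  expect_equal(sum(rep$per_phase), rep$phased_reads)
  expect_equal(rep$inphase_reads + rep$outphase_reads, rep$phased_reads)
  expect_equal(sum(rep$per_cycle$inphase_reads + rep$per_cycle$outphase_reads),
               rep$phased_reads)
  expect_equal(rep$phased_reads + rep$upstream_reads + rep$excluded_reads,
               sum(hits$count))
  expect_true(all(rep$occupancy %in% 1:21))
})

test_that("uniform random anchors populate all 21 phases at n = 10000", {
  set.seed(16)
  hits <- make_hits(sample(100:5000, 10000, replace = TRUE),
                    sample(c("+", "-"), 10000, replace = TRUE))
  ph <- phase_assign(hits, cfg)
  expect_equal(phase_occupancy(ph), 1:21)
})
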