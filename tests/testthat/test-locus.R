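make_cassette <- function(seed = 40) {
  set.seed(seed)
  assemble_cassette(c(promoter_35S = rand_dna(120), TL = rand_dna(40),
                      miR173ts = rand_dna(22), target_fragment = rand_dna(300),
                      terminator_35S = rand_dna(80)))
}

test_that("region tallies reproduce a hand-built promoter/TL fixture", {
  cs <- make_cassette()
  # three promoter species (7, 5, 5 reads), nothing in TL, rest downstream
  hits <- rbind(
    make_hits(c(10, 40, 80), "+", count = c(7L, 5L, 5L),
              sequence = c("P1", "P2", "P3")),
    make_hits(c(200, 250), "+", count = c(100L, 60L),
              sequence = c("D1", "D2")))
  tl <- coverage_by_region(hits, cs, threshold = 5, strict = TRUE)
  expect_equal(tl$species[tl$region == "promoter_35S"], 3L)
  expect_equal(tl$reads[tl$region == "promoter_35S"], 17L)
  expect_equal(tl$species[tl$region == "TL"], 0L)
  # with the strict > 5 reading only the 7-read clone clears the threshold
  expect_equal(tl$species_over_threshold[tl$region == "promoter_35S"], 1L)
  # with >= 5 all three do (the threshold strictness is configurable)
  tl2 <- coverage_by_region(hits, cs, threshold = 5, strict = FALSE)
  expect_equal(tl2$species_over_threshold[tl2$region == "promoter_35S"], 3L)
})

test_that("hits entirely downstream of cleavage leave upstream regions empty", {
  cs <- make_cassette()
  hits <- make_hits(c(200, 300, 400), "+", count = c(1L, 2L, 3L))
  tl <- coverage_by_region(hits, cs)
  expect_equal(tl$reads[tl$region %in% c("promoter_35S", "TL")], c(0L, 0L))
})

test_that("region tallies match a per-hit lookup loop and reconcile totals", {
  cs <- make_cassette()
  set.seed(41)
  n <- 250
  hits <- make_hits(sample(0:(nchar(cs$sequence) - 21L), n, replace = TRUE),
                    sample(c("+", "-"), n, replace = TRUE),
                    count = sample(1:30, n, replace = TRUE),
                    sequence = replicate(n, rand_dna(21)))
  tl <- coverage_by_region(hits, cs, threshold = 5)
  loop <- sapply(cs$regions$name, function(r)
    sum(hits$count[region_of(hits$start, cs) == r]))
  expect_equal(tl$reads, unname(loop))
  expect_equal(sum(tl$reads), sum(hits$count))
  # threshold monotonicity of species_over_threshold
  t0 <- coverage_by_region(hits, cs, threshold = 0)
  t10 <- coverage_by_region(hits, cs, threshold = 10)
  expect_true(all(t10$species_over_threshold <= t0$species_over_threshold))
  expect_true(all(tl$species_over_threshold <= tl$species))
})

test_that("transitivity summary partitions hits and calls direction", {
  iv <- c(400, 600)
  down <- make_hits(c(700, 800, 900), "+", count = c(50L, 30L, 20L))
  s <- transitivity_summary(down, iv)
  expect_equal(unname(s$upstream["reads"]), 0)
  expect_equal(s$verdict, "5'->3'")

  sym <- rbind(make_hits(100, "+", count = 10L),
               make_hits(700, "+", count = 10L))
  expect_equal(transitivity_summary(sym, iv)$verdict, "not directional")

  mixed <- rbind(make_hits(c(50, 390), "+", count = c(3L, 2L)),   # upstream
                 make_hits(450, "+", count = 7L),                  # within
                 make_hits(c(650, 900), "+", count = c(80L, 40L))) # downstream
  m <- transitivity_summary(mixed, iv)
  expect_equal(unname(m$upstream["reads"] + m$within["reads"] +
                        m$downstream["reads"]), sum(mixed$count))
  expect_equal(m$verdict, "5'->3'")
  expect_equal(m$max_downstream_count, 80L)
  expect_equal(m$max_upstream_count, 3L)
  # a hit overlapping the interval boundary counts as within, not upstream
  expect_equal(unname(m$within["reads"]), 7 + 2)
})

test_that("specific catalog is sound and empty for identical homologs", {
  set.seed(42)
  gene <- rand_dna(600)
  lib <- srna_library(vapply(sample(1:570, 40), function(s)
    substr(gene, s, s + 20), ""))
  none <- specific_sirna_catalog(lib, gene, gene)
  expect_equal(attr(none, "n_species"), 0L)

  pair <- simulate_homolog_pair(seed = 43, length = 900, identity = 0.86)
  lib2 <- srna_library(vapply(sample(1:870, 120, replace = TRUE), function(s)
    substr(pair$geneB, s, s + 20), ""))
  cat2 <- specific_sirna_catalog(lib2, pair$geneB, pair$geneA)
  # soundness re-checked by the brute-force scanner
  for (tag in cat2$sequence) {
    expect_gte(oracle_min_mismatch(tag, pair$geneA), 1)
    expect_equal(nrow(oracle_occurrences(tag, pair$geneB)) > 0, TRUE)
  }
  expect_equal(attr(cat2, "max_count"),
               if (nrow(cat2)) max(cat2$count) else 0L)
})
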