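---
title: "Methods: phase-register analysis of MIGS small RNA libraries"
author: "migsphase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase-register analysis of MIGS small RNA libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migsphase)
```

## The biological model

miRNA-induced gene silencing (MIGS) exploits the tasiRNA pathway: a
transgene transcript carries a 22-nt miR173 target site fused upstream of a
fragment of the gene to be silenced. miR173-loaded RISC cleaves the
transcript between the target nucleotides pairing miRNA positions 10 and 11;
RDR6 converts the 3′ cleavage fragment to dsRNA, and DCL4 processes it from
the cleaved end in successive 21-nt increments. The resulting phasiRNAs are
therefore *phased*: their duplex 5′ ends sit at 21-nt intervals from the
cleavage position. Each duplex has the Dicer signature 2-nt 3′ overhang, so
on reference coordinates the antisense strand of a duplex starts 2 nt
5′ of the sense strand. The phasiRNAs cleave endogenous homologs and, via
RDR6, trigger *transitive* secondary siRNAs downstream of the targeted
region.

The package quantifies this process from a collapsed small RNA library and a
set of reference sequences. Its core quantities are:

* the **cleavage coordinate** `c = target_site_start + (m − 10)` for a
  miRNA of length `m` paired end-to-end and antiparallel over a same-length
  target site. For the canonical 22-nt miR173 site this is 12 nt into the
  site; `c` is the first nucleotide of the 3′ fragment and the anchor of
  phase 1, cycle 1. The rule can be overridden with an explicit coordinate
  for non-canonical sites (e.g. bulged pairing), because the arithmetic
  assumes perfect end-to-end pairing.
* the **duplex anchor** of a 21-nt hit: `a = start` for sense hits,
  `a = start + overhang` for antisense hits. The +2 antisense shift is the
  only convention under which both strands of one Dicer duplex share a
  phase; the package treats it as definitional, not tunable biology.
* **phase** `p = ((a − c) mod 21) + 1` and **cycle**
  `k = ⌊(a − c)/21⌋ + 1`. "In-phase" means `p == 1` exactly. Positions one
  nucleotide off the register (`p ∈ {2, 21}`) are reported as a separate
  near-phase diagnostic but never counted as in-phase, keeping the in/out
  dichotomy sharp.

## Mapping model and its assumptions

All placement is ungapped perfect matching on both strands; a tag with no
exact occurrence is unmapped. This is deliberately conservative: with 18–26
nt tags, a single mismatch usually means a different locus (or a sequencing
error, which we do not model), and it makes the homolog-specificity rule
computable without an alignment-scoring choice. A tag is *specific* to a
target gene when it occurs perfectly in the target and has at least one
mismatched nucleotide at every same-length window of the homolog — which is
operationally "no exact occurrence on either strand of the homolog".
Multi-mapping tags contribute their full read count at every matching
window of a reference; species-level tables count each tag once. Ambiguity
codes (`N`) in references never match.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `period` | 21 | nt | DCL4 processing increment; 24 would model DCL3-type loci |
| `overhang` | 2 | nt | Dicer duplex 3′ overhang; fixes the antisense anchor shift |
| `cleavage_override` | — | coord | replaces the 10/11 rule for non-canonical pairing |
| `report_threshold` | 5 | reads | display threshold for region tallies |
| `strict_threshold` | TRUE | — | whether the threshold reads `>` or `≥` |
| transitivity `factor` | 10 | — | fold difference calling a 5′→3′ verdict |
| `min_count` (profiles) | 1 | reads | display threshold; matched-read totals ignore it |

The report threshold is presentational; no ratio or statistic applies it.
Both a strict (`>`) and inclusive (`≥`) reading are supported because usage
of such thresholds is genuinely ambiguous in practice, and the two readings
differ for species sitting exactly at the threshold.

The in:out ratio is computed on read counts over all downstream cycles to
the reference end; a species-based ratio is emitted alongside, since
which of the two a given study reports is often unclear. Upstream hits
(cycle ≤ 0) are excluded from ratios — the register is only defined
downstream of cleavage — and surface in region tallies and a separate
upstream read count, so totals always reconcile.

## The synthetic data generator

`simulate_migs_system()` builds a reference system: a random endogenous gene
pair whose second member carries i.i.d. substitutions at rate
`1 − identity` (default identity 0.86, typical of close paralogs such as
chalcone synthase family members), a cassette of
promoter (300 nt) / leader (140 nt) / 22-nt target site / 463-nt fragment
cut from gene A / terminator (200 nt), and a 110-nt stem-loop with a 22-nt
mature and 21-nt star annotation. The fragment length mirrors the scale of
fragments typically cloned into MIGS vectors; the flanking element lengths
are plausible round numbers, and nothing downstream depends on them beyond
providing upstream/downstream room.

`simulate_library()` then emits, with a single seed controlling everything:

* **Phased duplexes**: cycle `k` draws `Poisson(duplex_mean · decay^(k−1))`
  reads at anchor `c + (k−1)·21 + offset_k`, split sense/antisense by
  `strand_bias`, antisense reads starting 2 nt 5′ of the anchor. The
  register offset is a cumulative ±1 random walk: at each cycle boundary a
  slip occurs with probability `slip_prob` and propagates downstream. This
  is the simplest mechanism producing accurate early-cycle phasing with
  growing late-cycle drift, consistent with the idea that Dicer
  misprocessing accumulates over cycles; no quantitative drift rate is
  claimed, so `slip_prob` (default 0.15/boundary) and `decay` (default
  0.7/cycle) are calibration knobs, not biological estimates.
* **22-nt products**: a `frac_22nt` share of cassette reads emitted as
  22-mers at the same anchors (default 0.2, i.e. a visible minority class).
* **Secondary siRNAs**: Poisson reads at uniform positions strictly 3′ of
  the fragment interval of each gene, both strands — deliberately
  *unphased*, modelling transitive spread that populates all 21 phases.
* **Precursor species**: a multinomial over a configurable processing
  profile. The default profile places 3.1% of reads on the mature species,
  0.1% on the star, 64% and 27% on 20-nt and 21-nt species shifted 4 nt 5′
  of the star (proportions taken from the 98 : 3 : 2047 : 876 read-count
  pattern of a 3,190-read profile of a heterologously processed miR173
  precursor), and the ~5% remainder on random stem-loop fragments.
* **Background**: Poisson degradation reads (18–26 nt, uniform position and
  strand) from every reference.

Every emitted read group carries a truth label (origin, position, strand,
cycle, realized offset, and — for gene-derived 21-mers — whether its window
is substitution-free and hence shared with the homolog). Truth read totals
partition the library exactly.

What the generator does **not** emulate: sequencing errors, adapter
remnants, non-uniform Dicer position preferences, RNA secondary structure,
cis-acting siRNA re-triggering (new registers), expression differences
between strands beyond a global bias, and multi-locus gene families.
Passing the parameter-recovery suite therefore shows the *analysis* is
correct and internally consistent; it does not show that real libraries
satisfy the generator's assumptions.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere, so mod-21 arithmetic needs
  no ±1 corrections; exported BED/bedGraph inherit the convention natively.
* Profiles sort by descending count with ties broken by ascending
  (start, length), making outputs order-independent and deterministic; a
  species occurring at several stem-loop positions is assigned the leftmost
  and flagged.
* Ratios with zero denominators are flagged (`"infinite"`, `"undefined"`,
  `"all_in_phase"`) rather than returned as bare `NaN`/`Inf` surprises.
* A hit's region is that of its 5′ start; transitivity classifies a hit as
  upstream/downstream only when it lies entirely on that side of the anchor
  interval, boundary-overlapping hits counting as "within", so the three
  sides always partition the hit set.
* Empty libraries, empty hit sets, and tags longer than the reference are
  legal inputs returning empty/zero/flagged results, not errors; genuinely
  malformed files and non-ACGTU letters are errors naming the offending
  record.
* RNA input (`U`) is normalized to DNA (`T`) at ingestion; all matching is
  DNA-vs-DNA, since references are customarily DNA (GenBank) sequences.
* Length bounds are not imposed at ingestion; size windows are analysis
  parameters (histogram 18–26 nt by default, ratio window 20–24 nt).

## Validation strategy and problem sizes

The test suite checks each stage against an independent route: brute-force
window scans for occurrence and Hamming-distance search (1,000 tags over a
5-kb reference), explicit enumeration of phased positions for phase/cycle
assignment, truth labels for the simulator (in-phase fractions computed by
the engine and from realized offsets must agree exactly; specificity
catalogues must equal the truth-labelled non-shared sets over 10 seeds),
and multinomial 3σ bounds for precursor-profile recovery at 3,000 reads.
Slip-rate recovery uses 10 seeds × ~50,000 reads per slip value on a
4-point grid — sizes chosen so the whole suite runs in a couple of minutes
on one CPU while keeping binomial noise far below the effects tested.

## Known limitations

* Perfect-match mapping understates abundance in error-prone libraries;
  there is no mismatch-tolerant mode by design.
* The cleavage rule assumes canonical 10/11 slicing over an end-to-end
  paired site; non-canonical sites need an explicit coordinate.
* Phasing statistics are descriptive tallies and ratios; the package does
  not compute phasing P-values or scan genomes for PHAS loci.
* The precursor profiler considers only hairpin-sense species and does not
  predict secondary structure or model DCL cut-site thermodynamics.
* With several references sharing sequence (cassette fragment vs the source
  gene), reads are intentionally counted on every reference they are mapped
  to; overlap sets are reported rather than resolved by count splitting.
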