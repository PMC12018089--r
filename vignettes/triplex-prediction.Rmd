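---
title: "Predicting DNA-RNA triplexes with triplexr: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting DNA-RNA triplexes with triplexr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triplexr)
```

## The biological model and its assumptions

A DNA–RNA triplex forms when an RNA third strand occupies the major groove of
an intact DNA duplex and hydrogen-bonds (Hoogsteen or reverse-Hoogsteen) with
the purine bases of one duplex strand. `triplexr` implements the canonical
subset of this chemistry:

* exactly four triplet codes — TA:U, CG:C, CG:G and TA:A — distributed over
  four motif/orientation frames (parallel pyrimidine, parallel mixed,
  antiparallel purine, antiparallel mixed). Each frame fixes one third-strand
  base per duplex pair, so deciding a position is a constant-time lookup on
  the purine-strand base;
* the target site is a pure A/G tract on one duplex strand. Even where the
  error budget would tolerate a mismatch, a C or T on the purine strand ends
  the tract — mismatches are allowed on the RNA side only;
* the CG:C code is treated as a plain pairing rule; protonation chemistry
  (C+ at low pH) is not modelled;
* frames are searched independently and a hit records its frame. The two
  mixed frames share the same code table and differ only in orientation, so
  palindromic situations can legitimately be reported twice, once per
  orientation;
* non-canonical and reverse-Hoogsteen extensions (24-code schemes) are out of
  scope, as are genome-scale searches and any hit-scoring or ranking system.

## Parameters

| Parameter         | Default | Units    | Meaning |
|-------------------|---------|----------|---------|
| `min_consecutive` | 7       | triplets | minimum total triplex length *and* minimum error-free run; 7 accommodates both long and short noncoding RNAs |
| `max_error_rate`  | 0.20    | fraction | maximum fraction of code-violating triplets in a hit |
| `core_run_floor`  | 7       | triplets | hard floor under `min_consecutive`; only lowered for small didactic examples |
| `cpg_step_score`  | +17     | score    | running-sum increment for a CpG dinucleotide |
| `other_step_score`| −1      | score    | decrement for any other dinucleotide |
| island length     | > 200   | bp       | exclusive span-length bound |
| island GC         | > 50    | %        | exclusive GC-content bound |
| island obs/exp    | > 0.6   | ratio    | exclusive observed/expected CpG bound |

`min_consecutive` deliberately plays both roles (minimum length and minimum
clean run): a single threshold matches how the tool's stricter presets are
described (e.g. requiring 16 consecutive pairs for a long lncRNA probe), and
at the default of 7 the two roles coincide anyway. The command-line interface
accepts the error rate as a percentage and refuses `--min-consecutive`
below 7.

## The search algorithm

For each DNA strand, maximal purine tracts of at least `min_consecutive`
bases are extracted (minus-strand tracts are maximal C/T runs of the input,
reported in plus coordinates). Each tract is scanned against the RNA in each
frame along every alignment diagonal; antiparallel frames reverse the RNA
(reverse, not complement — the third strand contacts the purine strand
directly).

On a diagonal with match mask $v$, the scanner emits, for every mismatch
count $k = 0 \dots \lfloor \text{rate} \cdot L \rfloor$, the
containment-maximal windows that start and end on a match and contain at
most $k$ mismatches. With a zero budget this is exactly the set of maximal
perfect runs — matching restarts immediately after each mismatch. With a
nonzero budget the maximal window at the highest level bridges mismatches
while the running mismatch fraction stays within budget, and the lower-level
windows (down to the pure runs) are emitted alongside it. Emitting every
level is what makes the engine provably equivalent to exhaustive placement
enumeration after filtering: any placement that can survive the region rule
is containment-maximal at its own mismatch level, and any placement that can
eliminate another is dominated by a containment-maximal window with equal or
lower error; a brute-force reference implementation
(`brute_force_triplexes()`) checks this equivalence on thousands of
randomized instances in the test suite.

Candidates then pass the filter chain, in this order:

1. **end trimming** — leading/trailing mismatches are stripped (both the TTS
   and TFO intervals shrink symmetrically);
2. **validity** — length ≥ `min_consecutive`, a clean run of
   `min_consecutive`, mismatch count within budget;
3. **region domination** — candidate $x$ is removed if some candidate $y$ is
   strictly longer, has error rate ≤ that of $x$ (compared by integer
   cross-multiplication, so the 20% boundary never hinges on floating
   point), and overlaps $x$ on *both* the TTS and TFO intervals by at least
   half of the shorter candidate. Equal-length candidates never remove each
   other. This operationalizes "the same TTS/TFO region", which the
   underlying method leaves undefined; 50% reciprocal overlap is the
   standard interval-deduplication choice. The rule is idempotent and
   order-independent;
4. **sliding-tie resolution** — placements with identical frame, strand,
   mask and sequences whose diagonals form a contiguous range (a repeat
   being slid across) are reduced to the central placement when their count
   is odd, or the two central placements when it is even. This reproduces
   the midpoint convention: equal-parity TTS/TFO lengths give an odd number
   of placements (one centre), mixed parity an even number (two centres).

Hits are sorted by length (descending), then error rate, TTS start, frame
name, strand and TFO start — the trailing keys exist purely to make output
deterministic.

## CpG island detection

The island scan is a running-sum heuristic, not an exhaustive search: a span
opens at the first positive-scoring step (+17, a CpG), accumulates the sum,
and closes where the sum returns to zero or at the sequence end; the closed
span is tested against the three strict criteria and reported if it
qualifies. After a report the scan resumes past the island (reported islands
are therefore non-overlapping and sorted); after a failed span it resumes
just after the position of the span's maximum running sum, or past the span
when the maximum sits at its first step (this also guarantees progress).
Every report is re-verifiable from the sequence — the tests recompute GC and
obs/exp independently for each island — but completeness over all
criterion-satisfying substrings is not claimed; that is inherent to the
running-sum formulation.

One scale consequence worth knowing: a lone CpG followed by AT-rich sequence
closes its span after exactly 17 unit decrements, i.e. a 19-bp span. More
generally the span around a CpG-dense segment extends into downstream
background by roughly 17 steps per island CpG before the sum reaches zero,
so a dense island followed by a long AT tail is assessed *together with part
of that tail*. Boundary probes in the tests and the acceptance script
therefore place constructed spans flush at the 3′ end of the sequence, where
the span closes exactly at the designed boundary and each criterion can be
isolated.

## The synthetic fixture generator

`plant_triplex()` and `plant_cpg_island()` define the study conditions for
all tests:

* DNA background (default 200 nt) is ~70% pyrimidine, generated as
  pyrimidine runs of 1–4 bases separated by single purines. This structure,
  rather than i.i.d. sampling, guarantees that *no* background purine tract
  on either strand reaches the 7-base hosting length — with i.i.d.
  pyrimidine-rich sequence, the minus strand is purine-rich and spurious
  tracts are common. The RNA background (default 150 nt) is uniform over
  A/C/G/U;
* the planted tract mixes A and G (redrawn if single-letter) so that slide
  groups and cross-frame coincidences stay rare; planted mismatches are
  interior, keep the ends matched, use third bases that match no frame at
  all, and preserve a clean 7-run unless `break_runs = TRUE` plants an
  intended negative (mismatches every 7th position);
* after generation the default search is run: a positive fixture is redrawn
  (deterministically, from the seed) if any hit falls outside the planted
  alignment; an intended negative is redrawn until no hit remains anywhere —
  chance off-diagonal self-alignments inside the planted region are genuine
  matches, not artifacts, so they must be excluded by redraw rather than
  ignored;
* planted islands (alternating CG, default 250 bp in 2000 bp of ~30% GC
  background) are placed within the final few hundred bases so the
  running-sum span closes before background dilution can drag the span's GC
  below 50% (see the scale note above).

What passing these tests shows — and does not show: recovery of planted
signal under controlled composition demonstrates the correctness of the
matching, budgeting and filtering machinery, not performance on genomic
sequence, where repeat structure, composition bias and the absence of ground
truth are entirely different. The external validation (a known lncRNA
against its target promoter) requires sequences that are not redistributed
with the package; the corresponding test documents exactly which files to
supply.

## Numerical and degenerate-input choices

* error budgets are tested as `mismatches <= rate * length + 1e-9`; the
  epsilon absorbs binary-representation artifacts of decimal rates at exact
  boundaries (4 mismatches in 20 at rate 0.2 must pass, 5 must fail).
  Candidate-to-candidate error comparisons avoid floating point entirely via
  integer cross-multiplication;
* all three island thresholds are strict inequalities, exactly as worded
  (a 200-bp span, a 50.0% GC span, and a 0.6 obs/exp span are all rejected);
  obs/exp is `#CpG × N / (#C × #G)`, defined as 0 when the span lacks C or G;
* RNA `T` is normalized to `U` on input; any other character (including `N`)
  is a hard error naming the first offending position — silent skipping
  would shift every downstream coordinate;
* empty inputs, inputs shorter than `min_consecutive`, and alphabet-violating
  tracts produce empty results or early errors, never partial output;
* coordinates are 0-based half-open internally and 1-based inclusive in all
  reports; BED output converts back to 0-based half-open.

## Problem sizes used by the test suite

The equivalence test runs 1000 randomized instances (sequences up to 50 nt,
error budgets 0/0.1/0.2, all four frames exercised) against the brute-force
reference; the detection-boundary sweeps use 50 fixtures per planted length
5–10 and 5 per mismatch count 0–6 at length 20; island boundary probes use
2000-bp backgrounds. These sizes were chosen to exercise every code path and
boundary with comfortable margins while keeping the default suite quick to
run.

## Known limitations

* the region rule keeps equal-length overlapping candidates from different
  diagonals unless they form a contiguous slide group; when *both* sequences
  can slide inside one long homopolymer the diagonal coordinate degenerates
  and the group is left unresolved (all placements kept). Region domination
  collapses almost all such cases first, so this arises only in contrived
  inputs;
* the CpG scan inherits the running-sum heuristic's incompleteness and its
  sensitivity to what follows an island (see above);
* no statistical significance, thermodynamic stability, or ranking is
  attached to hits; the error rate and G+U content are descriptive only;
* the search is designed for promoter/transcript-scale inputs, not
  chromosomes; cost grows with (tract length × RNA length) per frame.
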