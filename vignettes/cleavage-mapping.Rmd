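---
title: "Mapping tRNA 3'-tail cleavage and scoring PFS depletion screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping tRNA 3'-tail cleavage and scoring PFS depletion screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnatail)
```

## The problem

RNA-guided nucleases of the kind this package targets are activated by
recognition of a complementary target RNA and then cleave the conserved
3' CCA tail of tRNAs, a few nucleotides upstream of the 3' end. Two
experimental readouts drive the analyses implemented here:

1. **Direct RNA-seq cleavage mapping.** Small RNA from reactions run with a
   *target* crRNA (nuclease activated) and a *non-target* crRNA (control) is
   poly(A)-extended, sequenced from the 3' end, and mapped to a reference set
   of tRNAs and other non-coding RNAs. Cleaved molecules produce reads whose
   coverage stops short of the reference 3' end; comparing per-position
   coverage between conditions localizes the cut.
2. **PFS depletion screen.** A plasmid library carries the target flanked by
   all 1,024 randomized 5-mers (the protospacer-flanking sequence, PFS).
   5-mers that license nuclease activation kill or arrest their host and are
   depleted from the surviving pool relative to a non-targeting control.

## The depletion statistic

For one reference, condition totals $S_t, S_{nt}$ (reads mapped to that
reference) and per-position coverage $c_t(p), c_{nt}(p)$, the per-nucleotide
depletion score in the *printed* orientation is

$$d(p) \;=\; \frac{S_{nt}}{S_t}\cdot\frac{c_t(p)+\alpha}{c_{nt}(p)+\alpha},$$

with pseudocount $\alpha = 1$ by default. Reference-wise standardization
gives $z(p) = (d(p) - \bar d)/\sigma_d$ with the **population** standard
deviation, and for colour maps $z$ is clamped to $[0, 2]$.

Two deliberate interpretation choices are baked in and surfaced in every
output file header:

* **Orientation.** The printed formula yields scores *below* 1 at depleted
  positions, which a rule of the form "significant when $z \ge 2$" combined
  with a $[0,2]$ clamp could never satisfy. The package therefore works in
  the reciprocal, *fold-depletion* orientation (high = depleted under
  target), applies the $z \ge 2$ rule and the clamp there, and emits the
  printed orientation alongside (`score_printed`, `log2_printed`) for
  transparency. Swapping the two condition inputs maps every fold score
  $s \mapsto 1/s$, and the printed orientation of the swap equals the fold
  orientation of the original; both are tested properties.
* **Pseudocount scope.** $\alpha$ applies to per-position counts only, never
  to the totals, and positions with zero raw coverage in *both* conditions
  are masked out of mean, standard deviation and calling.

With $m$ unmasked positions the population $z$ is bounded by $\sqrt{m-1}$
(attained exactly by a single-outlier profile, which the tests check), so a
reference with fewer than five unmasked positions can never reach $z \ge 2$:
very short or near-empty profiles are structurally unable to produce calls,
which we consider the correct failure mode.

## Calling cleavage sites

A reference is **detected** when every replicate pair has at least
`min_reads = 10` mapped reads in both conditions. Significance requires the
raw $z$ (never the clamped `z_vis`) to reach `z_threshold = 2` at the same
position in the number of replicate pairs demanded by `replicate_rule`
(default `"all"`, matching a three-replicate design; `"majority"` and
`"any"` are available). Only consensus positions inside the 3'-terminal
window (`window_3p = 10` nt) make a reference significant; a consensus run
confined elsewhere is classed `internal`.

One further support rule exists because of the poly(A) geometry itself.
Every read — cleaved or not — loses its genuine terminal adenosine(s) to
the tail trimmer, so the last reference position is chronically uncovered
in *both* conditions; the only reads covering it are those with a
sequencing error in the terminal base. One or two such reads in the
control make a near-flat reference's largest fold score land exactly
there, and because the population z of a single outlier is
$\sqrt{m-1} \gg 2$, an inactive reference can reproducibly "call" at the
terminus. A position therefore only counts as significant when the
non-target condition covers it at least `min_pos_coverage` times (default:
`min_reads`) — depletion is unmeasurable where the control itself has no
coverage. Genuinely depleted positions are unaffected, since their control
coverage is near the reference total.

The apparent product end $e$ is the position immediately 5' of the
3'-terminal contiguous consensus run, and the apparent offset is
$L - e$. Because every 3' end is poly(A)-extended before sequencing, a
product that genuinely ends in adenosines is indistinguishable from a
shorter product whose tail begins earlier: with $a$ the length of the
reference A-run starting at $e+1$, the reported interval is
`[offset - a, offset]`.

### Known limitation: the ambiguity interval can under-cover

The poly(A) trimmer removes the longest 3' suffix that is at least 90% A,
at least 5 nt long, and begins with an A (the leading-A requirement is what
reconciles maximal-suffix trimming with run-anchored behaviour; without it,
a suffix starting at a non-A base one position further 5' can qualify on
fraction alone). With an appended tail of 10-30 nt, this rule will absorb
*any* body suffix of the form `A x A…A` — an isolated non-A base flanked by
adenosines — because the appended tail keeps the A-fraction above the
threshold. When the reference sequence 5' of the true product end contains
such a pattern, every product read's apparent end overshoots the true end
by two or more positions, while the contiguous-A-run interval extends back
by only the contiguous run. Similarly, when cleavage offsets vary from read
to read within one reference, the $z \ge 2$ boundary sits at the positions
depleted by essentially *all* cleaved reads, i.e. near the minimum offset,
not the modal one. In both situations the reported `offset_range` may not
bracket the most common true offset; simulations at the package's default
settings show this for roughly half of cleaved references. We keep the
contiguous-A-run rule because it is the field's stated correction, is exact
whenever the 3' neighbourhood of the cut is free of isolated-non-A
patterns, and matches the worked examples frozen in the test suite; a
trimming-aware interval would be strictly wider and incompatible with
those. Simulating with `offset_mode = "per_ref"` (one characteristic cut
site per tRNA, arguably closer to how a single nuclease behaves on a given
substrate) removes the mixture effect but not the absorption effect.

## The built-in mapper

`map_reads()` is a deliberately small seed-and-extend mapper for
desk-scale work: exact 13-mer seeds vote for (reference, diagonal) pairs,
the best diagonal per candidate reference is scored by ungapped match
counting, and the pseudo-MAPQ is `min(60, 6 * (best - second best))`, so a
read fitting two references equally is removed by the MAPQ >= 20 filter.
It assumes substitution-only errors and mutually distinct references (the
simulator guarantees a Hamming distance of at least 10 over the first
40 nt); on error-free simulated reads it assigns 100% of reads to their
true reference, a tested invariant. Real libraries should be aligned with
a production mapper and imported via `import_sam()`, which applies the
same retention rules (mapped, primary, MAPQ >= 20) and feeds the identical
downstream scoring — the equivalence of the two routes on simple
full-match alignments is itself a test.

## PFS screen scoring

`extract_pfs()` anchors on the exact 20-nt upstream and 10-nt downstream
flanks, counts the enclosed 5-mer, and tallies exclusions (`no_anchor`,
`ambiguous_N`, per-base Phred below 20 within the 5-mer); counted reads
plus exclusions always reconstruct the input read count. Anchors are
matched exactly by default because the cassette design fixes them; a
substitution tolerance is available (`max_anchor_mismatch`). The Phred
rule is applied per base within the extracted 5-mer only, and reads
without quality strings skip it.

Per-position summaries use **marginal counts** — sum the counts of all
5-mers carrying base $b$ at position $i$, then score — rather than
averaging per-5-mer log scores; marginal counting is count-weighted and
stable for sparse 5-mers. One consequence of compositional closure is
worth stating: depleting purines at positions +1/+2 by a factor of 10
*enriches* the pyrimidine cells at those positions by about +0.37 log2, so
"everything except the functional cells is near zero" can only hold at the
unconstrained positions +3..+5, and that is what the tests assert.

For the null screen (depletion factor 1), an independent Monte-Carlo of
multinomial counting noise at 200,000 reads per condition over
Dirichlet-distributed abundances (concentration 50, the generator default)
puts the 99th percentile of |log2 printed score| at 0.36-0.42 across 40
replicate screens; the acceptance suite checks observed null screens
against a frozen envelope bound of 0.5.

## What the simulator emulates, and what it does not

`simulate_direct_rna_reads()` reproduces the features the statistics
depend on: Bernoulli($\varphi$) cleavage per read, 3' truncation offsets
drawn from a configurable distribution (defaults: equal weight on 3-5 nt;
a 2-4 nt preset mirrors the cell-free milieu), poly(A) extension of every
3' end (uniform 10-30 nt, error-free — the trimming contract, not tail
realism, is under test), and substitution-only sequencing noise at 0.5%.
It does not model indels, signal-level basecalling artefacts, chemical
modifications, ligation biases, or realistic per-tRNA abundance skew
(an abundance parameter exists but imitates no particular organism;
per-reference read counts are exact by design so that count-conservation
is testable). Passing recovery tests therefore demonstrates that the
statistics recover truth under idealized read generation — not that the
pipeline is robust to every nanopore artefact.

Randomness is organized as derived substreams keyed by
(seed, reference, condition, replicate), with vectorized draws inside each
stream: identical configurations are byte-identical regardless of which
subset of conditions is generated or in which order.

## Problem sizes used by the tests

Unit tests run at toy scale (3-8 references, tens of reads). The recovery
suites run at the scales the package treats as its reference conditions:
20 tRNA references, 300 reads per reference per condition, three replicate
pairs, $\varphi = 0.9$ on 15 references and 0 on 5 for cleavage mapping;
200,000 reads per condition, depletion factor 10 on the 256
purine-at-+1/+2 5-mers for the screen. These sizes give comfortable
statistical margins for every tested property while keeping the full suite
to a few minutes on one core.

## Numerical and tie-break conventions

* Population (ddof 0) standard deviation; zero-variance references get
  $z = 0$ everywhere rather than NaN.
* Mapper ties: equal extension scores give pseudo-MAPQ 0 (ambiguous, then
  filtered); among equal-vote diagonals the smallest diagonal wins,
  deterministically.
* 5-mer ranking is fold-descending with a lexicographic tie-break.
* Coordinates are 0-based half-open internally (alignments), 1-based
  inclusive in every emitted table.
* The internal alphabet is `{A,C,G,T}` with U mapped to T on input, the
  convention of basecalled FASTQ and SAM.
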