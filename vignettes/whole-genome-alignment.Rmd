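---
title: "Aligning intra-species genomes and reading variants off the alignment"
author: "wgalignr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning intra-species genomes and reading variants off the alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Two assemblies of the same species are typically > 97% identical: long
stretches of exact agreement separated by isolated differences (SNVs and
small indels) and occasional larger rearrangements. `wgalignr` exploits that
structure with a seed–chain–align pipeline:

1. **Seed.** An FM-index (suffix array + Burrows–Wheeler transform + rank
   structure) is built over the reference *P* concatenated with its reverse
   complement *P′*. The query *Q* is scanned left to right; from each start
   position the match is extended as far as it goes — a *local maximal exact
   match* (LMEM). Extending forward on *Q* is one backward-search step with
   the complement of the next residue, which is why *P′* is indexed: hits in
   the *P′* half are forward-strand seeds, hits in the *P* half are
   reverse-strand seeds. An LMEM of length ≥ *k* with fewer than *f*
   occurrences becomes one *simple pair* (i1, i2, j1, j2) per occurrence,
   with `P[i1..i2] = Q[j1..j2]`. The scan restarts after the match, or 5 bp
   after its start in sensitive mode.
2. **Chain.** Co-linear seeds share a similar *PosDiff* = i1 − j1. Seeds are
   sorted by PosDiff and clustered with a break wherever adjacent sorted
   values differ by more than *MaxDiff*; within a cluster, seeds are
   re-sorted by query position, duplicated query positions are resolved
   toward the nearest unique seed, non-co-linear outliers are removed, long
   dissimilar gaps split the cluster, overlaps between adjacent seeds (from
   tandem repeats) are trimmed off the preceding seed, and the remaining
   gaps are filled with *normal pairs* — the non-identical fragment pairs
   between seeds. Each chained cluster is a *similar region* yielding one
   local alignment.
3. **Align.** Normal pairs are classified: equal-sized pairs with few
   mismatches are aligned by a linear scan (Type I), pairs with one empty
   side are a pure insertion or deletion (Type II), everything else gets
   global affine-gap dynamic programming (Type III). The region alignment is
   the concatenation of the per-pair alignments, and variants are read off
   it: one SNV per mismatch column, one left-anchored indel per gap run.

The package also contains the benchmark apparatus: `mutate_genome()` plants
variants at fixed per-Mbp rates and keeps the exact edit script, and
`evaluate_calls()` scores calls against that truth set, so the correctness
of the *alignment* is measured as variant-detection accuracy.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 30 bp | minimum LMEM length kept as a seed |
| `f` | 5 | seeds occurring ≥ f times are discarded |
| `stride` | 5 bp | scan restart offset in sensitive mode |
| `max_diff` | 25 bp | PosDiff break threshold; bounds the indel size between adjacent seeds |
| `outlier_tol` | 5 bp | PosDiff deviation from both neighbours that marks an outlier |
| `terminal_tol` | = `max_diff` | tolerance for the single neighbour of a cluster's first/last seed |
| `gap_break` | 300 bp | query gap length that triggers the similarity test |
| `sim_kmer`, `kmer_divisor` | 8, 3 | gap fragments sharing < gap/3 distinct 8-mers are dissimilar |
| `match`, `mismatch` | +2, −4 | substitution scores |
| `gap_open`, `gap_extend` | 8, 1 | affine gap penalty: a gap of length L costs 8 + L |
| `type1_max_mismatch_frac` | 0.3 | mismatch fraction cap for the un-gapped path |

Seed-length and occurrence thresholds barely move the result on
intra-species data — the chaining recovers dropped seeds as normal pairs —
so `k` and `f` are exposed but rarely worth touching. `sim_kmer = 8` is
small enough that 8-mers survive realistic substitution densities (at 1%
substitutions an 8-mer is intact with probability ≈ 0.92) and large enough
that two random 600 bp fragments share almost none.

### Why these gap penalties

The scoring scheme is not a free cosmetic choice: it decides how the
optimal alignment *represents* variation, and the variant calls inherit
that representation. Two inequalities matter.

* `gap_open > mismatch + match`. Otherwise the DP strictly prefers to
  re-represent a substitution adjacent to an indel as two separate gaps
  (the split earns `mismatch + match − gap_open` per event), fabricating
  indel calls that exist in no edit script.
* `gap_extend` well below `mismatch`. Two nearby opposite-sign indels
  (an insertion and a deletion a few bases apart) cost
  `2·gap_open + (s1+s2)·gap_extend` when represented faithfully; collapsing
  them into one net indel plus a mismatch run saves extension costs and
  wins whenever extension is expensive relative to mismatches.

BWA's defaults satisfy both inequalities; ours (+2/−4, open 8, extend 1)
are the same family scaled to a +2 match. No affine scheme can suppress
every representation ambiguity: when randomly inserted content happens to
align well against neighbouring sequence, an alternative representation is
*genuinely* score-optimal, and any score-maximising aligner will report it.
At the default mutation rates this affects a handful of events per 5 Mbp
and is visible in the fourth decimal of indel precision/recall.

### The Type I shortcut is exact, not heuristic

An equal-sized normal pair is aligned un-gapped only when
`nmis · (match + mismatch) ≤ 2 · (gap_open + gap_extend)` (and the mismatch
fraction is below the cap). Under that bound no gapped alignment can beat
the linear scan — a net-zero length change needs at least one insertion and
one deletion, costing `2·(gap_open + gap_extend)`, while re-aligning can
recover at most `match + mismatch` per mismatch column. Equal-sized pairs
above the bound go to the DP, which simply reproduces the un-gapped
alignment whenever that is best; the only cost is compute. Without the
bound, equal-sized pairs concealing a crossing insertion/deletion pair
would be force-aligned un-gapped and their indels lost.

## What the simulator emulates — and what it does not

`mutate_genome()` reproduces the benchmark's study conditions: 20,000 SNVs,
350 small indels (1–10 bp) and 100 large indels (11–20 bp) per Mbp (the 3x
and 5x presets triple or quintuple only the SNV rate), positions uniform
over non-N sites, events non-overlapping with ≥ 1 bp separation, indel
sizes uniform within their ranges. Under the uniform size draws the
expected mismatch burden is 20,000 + 350·5.5 + 100·15.5 per Mbp, an
average sequence identity of ≈ 97.66% for 1x.

It deliberately does **not** emulate: biased base composition, repeat
families and segmental duplications, clustered/hotspot mutation, large
structural variants, or inversions. Passing the round-trip benchmark
therefore demonstrates that seeding, chaining, gap alignment and variant
extraction are mutually consistent and near-exact on point-like variation —
it does not certify behaviour on repeat-rich real genomes, where seed
multiplicity and duplicate resolution carry much more weight.

## Evaluation semantics

SNV calls must match the truth exactly (chromosome, coordinate, alleles).
Indel calls match a truth event of the same kind whose anchor is within 10
bp (inclusive); this absorbs representation shifts inside tandem repeats
and homopolymers, where an indel placed at either end of the repeat is the
same event. Two countings are available:

* `counting = "per_event"` (default, the benchmark definition): TP/FP are
  counted over predictions and FN over truths, each side independently.
* `counting = "one_to_one"`: greedy nearest-first matching, ties to the
  left; every truth is creditable once.

`indel_match = "equivalent"` additionally requires that call and truth give
the same local haplotype when applied to the reference
(`variants_equivalent()`), a stricter representation-aware score useful
when the calls will feed downstream consumers that take alleles literally.

## Numerical and degenerate-input choices

* **Coordinates** are 1-based inclusive internally; MAF output converts to
  0-based starts (strand-relative for reverse-strand rows) and VCF is
  1-based with left-anchored indels.
* **N handling**: N is encoded as a separator symbol that never matches, so
  seeds cannot span or start in N runs; an all-N query yields no seeds.
  Lowercase (soft-masked) residues are uppercased and not treated specially.
* **DP tie-breaks** are fixed for determinism: diagonal over deletion over
  insertion, and gap runs prefer to extend (left-most opening).
* **Banding**: fragments whose DP matrix would exceed `max_cells`
  (default 6.4e7) fall back to a banded matrix of half-width
  `|n − m| + 2048` and say so via `message()`; chained fragments are
  bounded by the 300 bp gap-splitting rule, so this path is exceptional.
* **Blocked scanning**: `partition_query()` tiles each query record;
  blocks after the first discard the leading partial LMEM chain up to its
  first restart, each block may extend past its right edge and emit one
  LMEM starting beyond it, and the union is deduplicated by
  (j1, i1, strand). In sensitive mode the chain visits fixed positions
  (1, 1+stride, ...), so blocks are aligned to the stride and agree
  trivially. The block count never changes the output; it exists so the
  scan can be partitioned without a shared cursor.
* **Region ends are seed boundaries**: alignments start at the first and
  end at the last simple pair of a region. Variants in the few dozen bases
  of query before the first seed or after the last are therefore not
  recoverable (a handful of events per genome end at benchmark rates).
* **Reverse strand**: seeds and regions are chained per strand in the
  reverse-complement query frame; reverse-strand regions are reported in
  MAF/dot-plot form but yield no variant calls, since an inverted segment
  has no small-variant representation against the forward reference.
* **Duplicate/tie determinism**: duplicate seeds tie-break toward the
  nearest unique seed (then the cluster median PosDiff, then first in
  sorted order); all sorts use explicit secondary keys.

## Problem sizes used by the tests

The test suite exercises unit behaviour on strings of tens to hundreds of
bases against brute-force oracles (naive scans, a brute-force suffix sort,
an exhaustive affine DP), property checks on 3–100 kb simulated genome
pairs, and one full benchmark at 5 Mbp — the scale at which per-Mbp event
statistics are stable to the third decimal while a full run (index, scan,
chain, align, call, evaluate) stays around a minute. `scripts/acceptance.R`
re-runs the 5 Mbp benchmark from scratch with a caller-supplied seed.

## Known limitations

* No inversion or translocation *calling*: independent similar regions
  naturally express them as separate (possibly reverse-strand) alignments,
  but they are not reconciled into variant records.
* The full suffix array is stored unsampled; memory is linear in genome
  size with a sizeable constant (fine for bacterial-to-small-plant scale,
  not for mammalian genomes in modest RAM).
* Score-equivalent representation ambiguities near coincidentally similar
  inserted content are resolved by the scoring scheme, not by biological
  knowledge; a handful of indels per 5 Mbp are reported in a shifted or
  re-split form.
* The simulator's uniform-random genomes contain essentially no repeats;
  the duplicate-resolution and overlap-trimming paths are exercised by
  dedicated repeat fixtures in the tests instead.
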