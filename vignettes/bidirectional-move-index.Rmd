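---
title: "A bidirectional move-structure index: model, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A bidirectional move-structure index: model, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bimove)
```

## The problem

Pan-genomes — concatenations of many closely related genome sequences —
are highly repetitive, so the Burrows–Wheeler transform (BWT) of such a
text compresses into far fewer character runs `r` than the text length
`n`. Run-length compressed full-text indexes exploit this: they occupy
`O(r)` rather than `O(n)` space. `bimove` implements such an index in the
*move structure* style, in which the two permutations that drive
searching and locating — the LF mapping and the ϕ / ϕ⁻¹ suffix-array
neighbour maps — are evaluated by table jumps over run-indexed rows
rather than by rank/select queries on compressed bitvectors. On top of
the forward and reverse LF tables the package keeps the two suffix-array
intervals of a pattern synchronized, so the pattern can be extended by
one character on either end in any order. That bidirectionality is what
search schemes need, and search schemes are what make *lossless*
approximate pattern matching practical: every occurrence of a read within
a chosen Hamming or edit distance is guaranteed to be reported.

## The core structures

**Text.** All input fragments (chromosomes, strains) are concatenated and
terminated by a single sentinel `$`, lexicographically smaller than every
nucleotide; symbol order is `$ < A < C < G < T` with internal codes 0–4.
`N` characters are removed at ingestion; any other non-ACGT symbol is
rejected. All published indices are 0-based; suffix-array (SA) intervals
are closed `[s, e]`; text spans are half-open.

**Move tables.** One row per BWT run: the run character `c`, the input
interval start `p`, the output interval start `π = LF(p)`, and the row
index `ξ` whose input interval contains `π`. Because LF maps the
positions of one run to consecutive positions, `LF(i)` for any `i` is
`π + (i − p)` of the containing row, followed by a short *fast-forward*
scan from row `ξ` to find the row containing the result. A sentinel
bottom row with `p = n` keeps that scan in bounds. The same construction
works for ϕ (input intervals start at text positions `SA[i]` where `i`
starts a BWT run) and for ϕ⁻¹ (input starts at `SA[i]` for `i` a BWT run
*end*, equivalently the sorted ϕ output starts).

**Bidirectional state.** A matched string `Q` is represented by its SA
interval `[s, e]`, the SA interval of `Q` reversed in the reverse-text
index `[srev, erev]`, the run indices bracketing both intervals, the
matched length `m`, and a *toehold*: the text position of one occurrence
of `Q`. Extending left updates the forward interval with two
`move_step`s and shrinks the reverse interval arithmetically
(`srev' = srev + x`, width preserved), where `x` counts interval
positions whose BWT character precedes the new character (the sentinel
included). One memoized walk over the runs of the interval collects the
subinterval boundaries and all per-character counts at once, so an
extension costs a single `O(r)` pass rather than one per alphabet
character; the test suite checks that this memoized form is byte-identical
to the naive per-character reference. Run indices of the passive side go
stale but keep bracketing their interval; they are recovered by binary
search only when the search direction actually switches.

**Toehold maintenance.** After each extension the toehold is updated so
locating can start without any stored SA: if the pre-extension interval
lies inside a single BWT run, the old toehold simply shifts (left
extension) or stays (right extension); otherwise a per-run suffix-array
sample at a run boundary of the extension character inside the interval
is taken. For right extensions the sample lives in reverse-text
coordinates and is mapped back through `i = n − 1 − j − |Q|`. The
package stores four samples per run pair (run-start and run-end SA values
for both directions) — the simplest scheme satisfying the update rule;
sample subsampling is deliberately out of scope. The update rule is
pinned down by an oracle-backed invariant exercised over randomized
extension/switch sequences rather than trusted from derivation.

## Locating

Locating a final state starts from the toehold and recovers the rest of
the interval with ϕ (previous SA value) and ϕ⁻¹ (next SA value),
evaluated on *balanced* move tables. The stop rule uses the permuted LCP
array: `PLCP[SA[i]] ≥ m` exactly for the interior entries of the
interval of an `m`-long match. PLCP is stored sparsely at the ϕ
input-interval starts — the irreducible positions — and recovered as
`PLCP[p] − (i − p)` from the predecessor sample `p`; this recovery rule
is re-verified in full at construction time for every desk-scale build,
and by property tests always. The backward walk stops via PLCP; the
forward walk then performs exactly the remaining number of steps, which
is known from the interval width, so a width-`w` interval costs exactly
`w − 1` ϕ/ϕ⁻¹ operations. The predecessor structure is a binary search
over the sorted sample positions (`O(log r)`); the contract, not the
particular predecessor implementation, is what matters at desk scale.

An index can also be built without ϕ tables (`with_phi_tables = FALSE`):
it then retains the dense SA/ISA from construction and offers
`locate_all_no_tables()`, the lower-memory configuration; `locate_all()`
refuses to run on such an index.

## Balancing

BWT runs of a pan-genome have comparable sizes, so LF tables are kept
unbalanced (maximal runs). ϕ run sizes are heavily right-tailed, which
makes unbalanced fast-forward scans long; the ϕ and ϕ⁻¹ tables are
therefore balanced: any input interval whose output interval contains
more than `d` later input-interval starts is split at the `(d+1)`-th
contained start (both its input and output side), left-to-right with
rescan, until a fixed point. This caps every fast-forward at `d` steps —
asserted by instrumentation in the locate tests — never changes the
computed mapping, and at most doubles the row count (property-tested over
random and pan-genome-like texts). The default `d = 2` is the tightest
admissible threshold and is exposed as `balance_d`.

## Search schemes and approximate matching

A search scheme is a set of searches `(π, L, U)`: `π` a connected
processing order over the pattern pieces, `L`/`U` cumulative error
bounds. The pigeonhole scheme for `k` errors uses `k + 1` pieces and
`k + 1` searches, each anchoring one piece error-free. Patterns are
partitioned uniformly (remainder to the leftmost pieces); the first piece
is matched leftward from its right edge, later pieces extend the span
left or right as `π` dictates. `validate_scheme()` checks connectivity,
bound monotonicity, and — exhaustively for small `k` — that every error
distribution is covered; custom schemes can be loaded from JSON.

**Hamming distance** counts mismatches per extension; upper bounds prune
each step and lower bounds are enforced exactly at piece boundaries.

**Edit distance** maintains one dynamic-programming row per side
(left/right of the anchor), extended by one text character per character
extension. Rows saturate at `k + 1`, which realizes the ±`k` band. A
piece can close at any text length whose cut value
`D[i][boundary] + d_other` is within the piece's upper bound — this is
where text/pattern length slack from indels enters — and closing the
final piece reports the state with the exact total distance of that cut.
Two deliberate design choices: (i) intermediate *lower* bounds are not
enforced under edit distance — they only suppress duplicate finds across
searches, and duplicates are removed by the shared reduction rule, so
losslessness is unaffected; (ii) the locate stop criterion uses the exact
matched substring length of each final state (`m` of the state), not the
read length.

**Redundancy rule.** Under edit distance several substrings with
different lengths and distances can begin at the same text position. The
package collapses occurrences by `(strand, start)`, keeping the minimum
distance and, among ties, the shortest length. The exhaustive oracle
applies the identical rule, making index-vs-oracle set equality a
meaningful test even though other tools may resolve redundancy
differently. Occurrences are reported per strand (a read and its reverse
complement are both searched), and SAM output resolves concatenated
coordinates back to fragments, discarding occurrences that span a
fragment boundary — concatenation artifacts, not biological matches.

## Bit-packing and serialization

Move tables come in two observationally equivalent representations. The
full form stores plain integer vectors. The bit-packed form gives every
field its dedicated width — `⌈log₂(n+1)⌉` bits for `p` and `π`,
`⌈log₂(rows)⌉` for `ξ`, 3 bits for the run character — padded to whole
bytes per row so a row access reads a fixed byte range of one block. The
width of the position fields uses `n + 1` rather than `n` values because
the sentinel row stores `p = n`; for texts whose `n` is not a power of
two this is the same width the plain `⌈log₂ n⌉` rule gives (17 bits and
3 bytes per LF row for the 19-character example). Field widths are
floored at one bit so degenerate tables still encode. All primitives run
directly on packed tables through shared row accessors, and the property
suite runs on both forms. Serialization writes a little-endian container
(magic, version, header, fragment table, packed tables, SA samples, PLCP
samples) and loading reproduces bit-identical behavior; no compatibility
with any external tool's file format is attempted.

## Synthetic data: what it emulates and what it does not

`synth_pangenome()` generates one random base sequence plus independently
mutated near-copies — substitutions at 1% and indels at 0.1% per base by
default, the order of intra-species divergence in a bacterial pan-genome.
This reproduces the property that matters for a run-length compressed
index: `r/n` falls as copies are added (tested as a monotone trend). It
does not emulate large-scale rearrangements, horizontal transfer,
mobile elements, or real base composition, so passing tests demonstrate
correctness of the index machinery on repetitive collections, not
biological fidelity. `synth_reads()` samples reads from both strands with
planted substitutions (optionally indels) and carries the truth — origin,
strand, planted edit count — in the read names.

## Numerical and procedural choices

* Suffix arrays are built by deterministic prefix doubling over a radix
  sort; output is byte-identical across runs. LCP uses Kasai's
  algorithm. Construction is in-memory and targets desk-scale texts;
  compressed construction is out of scope.
* Construction-time verification (`verify`): for texts up to 100 kb every
  built table is checked row-for-row against the dense LF/ϕ/ϕ⁻¹ oracles
  and the PLCP recovery rule is checked at every position.
* Degenerate inputs: the smallest valid text is one symbol plus sentinel;
  single-run BWTs, width-one intervals (located with zero ϕ calls), and
  empty extensions (`NULL`, not an error) are all exercised in tests.
* Reads containing `N` or shorter than `k + 1` are reported unmapped
  rather than rejected.
* Ties and orders are fixed everywhere (leftmost offending row in
  balancing, remainder-left partitioning, radix sorting), so identical
  inputs and seeds give byte-identical indexes and SAM output.

## Problem sizes used by the test suite

The randomized suites run at sizes chosen to exercise the structures
thoroughly while keeping the suite quick on one core: oracle equivalence
of `move_step` on 200 random texts up to `n = 2000` (every position, all
table kinds, full and bit-packed, balanced and unbalanced); balancing
bounds on 100 further texts; lossless-alignment equality against the
exhaustive-scan oracle on texts up to `n ≈ 5000` with read lengths
20–151 and `k ∈ {0,…,3}` under both metrics and both strands; and
randomized extension/switch sequences for the toehold and locate
invariants. The worked 19-character example is verified value-for-value.

## Known limitations

* Pure R: throughput is suited to method validation and desk-scale
  collections, not production read mapping of multi-gigabase pan-genomes.
* The packed row width is limited to 52 bits (double-precision exactness),
  which bounds packed tables to texts well beyond desk scale but below
  the 64-bit regime a compiled implementation would support.
* No CIGAR strings: the index does not store the text, so alignment paths
  are not reconstructed; SAM records carry `CIGAR *` and an `NM` tag.
* One sentinel terminates the whole concatenation; matches spanning
  fragment boundaries are possible in the text and are filtered only at
  SAM reporting.
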