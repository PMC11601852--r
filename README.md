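# bimove

A run-length compressed, **bidirectional full-text index** for DNA
sequence collections, with **lossless approximate pattern matching**.

## Who this is for and what it does

Pan-genomes — many closely related genomes concatenated into one text —
are too large for classical FM-index tools, whose memory grows linearly
with the text length *n*. Their Burrows–Wheeler transform (BWT),
however, compresses into *r* ≪ *n* character runs, and a family of
run-length compressed indexes works in *O(r)* space. `bimove` implements
the *move structure* flavour of this idea in R, for method development,
teaching, and desk-scale analyses:

* **LF as a table jump.** The BWT's LF mapping sends each run's
  positions to consecutive positions, so a table with one row
  `(c, p, π, ξ)` per run — run character, input-interval start,
  output-interval start `π = LF(p)`, and the row `ξ` containing `π` —
  evaluates `LF(i) = π + (i − p)` followed by a short linear
  *fast-forward* to the row containing the result.
* **Bidirectional search.** Forward and reverse LF tables are kept
  synchronized: extending a matched string `Q` to `cQ` updates `[s, e]`
  by move steps and shrinks the reverse interval to
  `[srev + x, srev + x + y − 1]`, where `x` counts interval positions
  with BWT character ≺ `c` and `y` is the new width; `Q → Qc` is the
  mirror image. Arbitrary left/right extension orders are what search
  schemes require.
* **Lossless matching.** A search scheme (piece order π with cumulative
  error bounds L, U — the pigeonhole scheme by default) guarantees every
  occurrence of a read within Hamming or edit distance *k* is found.
* **Locating.** A *toehold* — the SA value of one occurrence — is
  maintained across extensions; the rest of the interval is recovered
  with ϕ/ϕ⁻¹ move tables (balanced, so every fast-forward is capped) and
  a sparse permuted-LCP stop rule, using exactly width − 1 operations.
* Bit-packed table encodings, binary index serialization, SAM output,
  and deterministic synthetic pan-genome/read generators round out the
  package.

## Worked example

The 19-character text `CTATGTCATATGTTGGTC$` is small enough to print
whole index structures:

```r
library(bimove)
idx <- move_index(bm_text("CTATGTCATATGTTGGTC$"))
idx
#> <bmove_index 'text': n = 19, r = 12, r_rev = 13, phi rows = 13/13 (balanced, d = 2)>
#>   fragments: 1

inspect_table(idx$mlf)
#>     j c  p pi xi
#> 1   0 C  0  4  1
#> 2   1 T  2 11  6
#> 3   2 $  6  0  0
#> ...
#> 13 12   19 19 12
```

Row 1 says: the second BWT run holds `T`s, starts at BWT index 2, its
positions map under LF to 11, 12, … and LF(2) = 11 falls in run 6. The
final row is the sentinel row (`p = n = 19`) that keeps fast-forwarding
in bounds. `move_step(idx$mlf, 5, 1)` returns position 14 and landing
row 8: LF(5) = 14.

Approximate matching, one substitution allowed:

```r
run_search_scheme(idx, "TATGA", 1, "hamming")
#>   start length distance strand
#> 1     1      5        1      +
#> 2     8      5        1      +
```

Both occurrences of `TATGT` match `TATGA` with one mismatch. A
pan-genome scale-up with planted-error reads:

```r
frags <- synth_pangenome(base_length = 2000, copies = 4, seed = 7)
pidx <- move_index(frags)
pidx
#> <bmove_index 'index': n = 8001, r = 1811, r_rev = 1832, phi rows = 2528/2519 (balanced, d = 2)>
#>   fragments: 4

reads <- synth_reads(concat_with_sentinel(frags), count = 3, length = 60,
                     error_rate = 0.02, indels = TRUE, seed = 7)
hits <- align_reads(pidx, setNames(reads$seq, reads$name), k = 2, metric = "edit")
head(hits, 3)
#>          read start length distance strand
#> 1 r1:7465:-:1  1464     61        2      -
#> 2 r1:7465:-:1  1465     60        1      -
#> 3 r1:7465:-:1  1466     59        2      -
```

Further down the full table, the same read also hits `start = 7465,
length = 60, distance = 1` on the minus strand.

Note `r = 1811` for `n = 8001`: four near-identical copies compress to
roughly the run count of one. Read `r1` was sampled at position 7465 on
the minus strand with one planted edit (the truth rides in its name);
the aligner recovers that occurrence at distance 1 together with the
homologous positions in the other copies and the distance-2 shifted
alignments an edit-distance search legitimately reports. `write_sam(pidx, hits, reads, "out.sam")`
emits one SAM line per occurrence (`NM` tag = distance; occurrences
spanning fragment boundaries are dropped; `CIGAR *` since the index does
not store the text).

A thin command-line wrapper ships in `inst/cli/bmove.R`:

```sh
Rscript inst/cli/bmove.R build --fasta genomes.fa --out genomes.idx
Rscript inst/cli/bmove.R align --index genomes.idx --reads reads.fq \
    --k 2 --metric edit --out hits.sam --report
Rscript inst/cli/bmove.R inspect --index genomes.idx --table lf
Rscript inst/cli/bmove.R selftest
```

## Scope

Construction is in-memory from dense suffix structures (deterministic
prefix doubling), aimed at desk-scale texts; compressed construction,
SA-sample subsampling, CIGAR reconstruction, and multi-threaded I/O are
out of scope. See the methods vignette
(`vignettes/bidirectional-move-index.Rmd`) for the model, parameter and
design discussion.
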