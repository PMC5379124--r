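---
title: "ltrnest: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ltrnest: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

An LTR retrotransposon copy is born as `5'LTR – internal region –
3'LTR`, flanked by a short target-site duplication (TSD), with both
LTRs identical. Afterwards the copy decays: unequal recombination
between its LTRs leaves a solo-LTR; deletions truncate either end;
recombination between adjacent copies yields shared-LTR complex
elements (`LTR-IN-LTR-IN-LTR`); and younger elements insert inside
older ones, splitting the host into pieces. `ltrnest` assumes the
input is a table of local alignments of per-family `_LTR` and `_IN`
consensus sequences against a genome (RepeatMasker `.out` layout) and
reconstructs whole elements from those pieces. It does not discover
families de novo and does not run an aligner: the computation starts,
deliberately, at the alignment table.

Coordinates are 1-based inclusive everywhere (RepeatMasker and GFF3
convention). Minus-strand hits are normalised at parse time so
consensus coordinates are always in forward consensus orientation;
downstream code only ever branches on a `strand` field.

## Linking rules

After overlap resolution and defragmentation, candidates on one
contig are scanned left to right. For an ordered pair (x, y) the
discriminating tree answers: are these pieces of *one* element?

* **Continuation** (LTR–LTR, IN–IN branches): same family, part and
  strand, and y resumes within `cons_tol` of where x's consensus
  coverage stopped. On the minus strand the genome-later piece
  carries the consensus-earlier interval, so the test is applied to
  the element-ordered pair (y, x).
* **Transition** (LTR–IN, IN–LTR branches): same family and strand,
  the element-earlier part reaches within `end_tol` of its consensus
  end, and the element-later part starts within `end_tol` of
  consensus position 1. This is what stitches `LTR`+`IN`+`LTR` into
  a full-length element, and lets a middle LTR serve two internal
  regions in a shared-LTR complex element.

Either test also requires the *unexplained* genomic gap — the gap
between x and y minus every base covered by candidates lying between
them — to be at most `g_direct`, and the total span to be at most
`g_insert`. Bounding the unexplained rather than the raw gap is
forced by the worked three-fragment example the linker is validated
against: the two halves of an interrupted internal region are linked
(state 1) even though 300 bp of inserted LTR sit between them, which
a raw-gap bound of 200 bp would forbid. It also generalises: a host
should reconnect across an insert of any size provided the insert
itself is annotated, while genuinely empty gaps stay tightly bounded.

State 2 ("inserted") is assigned to (x, y) when y fails its own test
but some later z within `g_insert` passes it, with one guard we found
necessary in practice (simulator seed 9): **z must not be claimed by
a nearer partner.** If any candidate between x and z is itself
state-1 linked to z, the intervening material is the front of a
distinct neighbouring element of the same family — e.g. element B's
own 5'LTR preceding B's internal region — not an insertion into x's
element, and the lookahead keeps scanning. A genuine nested insertion
never triggers the claim, because an insert aligns to its own
consensus ends while the host's continuation resumes mid-consensus.

Chains are built greedily, consuming left to right; when state 2
fires, everything between x and the nearest unclaimed continuation z
goes to the inserted pool, and the pool is re-chained as layer k+1
until a pass inserts nothing. The greedy sequential scan (rather than
score-optimal chaining) mirrors the sequential dynamic-link-list
construction the method describes, and makes output order — and hence
every output file — fully deterministic. Cross-strand links are never
made: the figures we reconstruct from draw both orientations but
never join them, and equal strand is the conservative reading.

## Tolerances

| parameter | default | unit | why |
|---|---|---|---|
| `gap_tol` (defrag) | 100 | bp | absorbs split-hit jitter without bridging real insertions (those are ≥ a few hundred bp and handled by state 2) |
| `cons_tol` | 30 | bp | consensus slack for split hits; also covers the ≤ 6 bp double-counting a TSD causes at a split point |
| `end_tol` | 20 | bp | how frayed an LTR/IN end may be at a junction |
| `g_direct` | 200 | bp | max unexplained gap within one element |
| `g_insert` | 20 000 | bp | lookahead bound; keeps distant same-family copies apart while comfortably spanning nested stacks of a few elements |
| `-D`/`-C`/`-L`/`-I` | 20 / 600 / 100 / 80 | %, score, bp, % | classic masking defaults, applied as parse- and fragment-level filters |

The source method names no linking tolerances; these values are the
package's own choices, fixed before any acceptance measurement and
exposed on the CLI.

The `-s` flag (80% "similar sequence length ... of query") is *not*
applied as a candidate coverage filter: dropping candidates below 80%
consensus coverage would delete every truncated and fragmented
element the method explicitly reports. It is instead the minimum
overlap of the optional greedy library-deduplication pre-step
(`dedupe_library()`), matching the flag's own wording about BLAST
searches of library queries. Completeness is still computed and
reported per element for users who want to filter.

## Structural taxonomy

Type strings are read in element (5'→3') order and collapse
continuation pieces, so a split internal region is still `IN`.
Categories are a pure function of the string: `LTR-IN-LTR` → Normal;
`LTR` → Solo-LTR (no completeness threshold — the taxonomy equates
the bare-LTR type with solo-LTRs); alternating strings with ≥ 3 LTR
labels → Complex; all other alternating forms → Truncated;
non-alternating strings → Others. "Nested" is an overlay (layer ≥ 2),
not a fifth category, so the four-plus-Others categories always sum
to the total. A `table1_compat` switch folds Others into Truncated to
reproduce the headline four-category rollup whose printed arithmetic
includes them there. What populated "Others" in the original runs is
undocumented; our grammar-based fallback is a guess and is labelled
as such.

## Dating

For every element whose type has ≥ 2 LTR labels, adjacent LTR copies
are globally aligned (match +1, mismatch −1, linear gap −2; verified
against an independent dynamic-programming oracle) and the K2P
distance K = −½·ln((1 − 2P − Q)·√(1 − 2Q)) is computed over columns
free of gaps and ambiguity codes. Ages are reported as T = K/2r for
both commonly used plant rates, 1.3×10⁻⁸ and 7×10⁻⁹
substitutions/site/year — applying synonymous-site rates to
non-coding LTRs replicates standard practice rather than endorsing
it. Shared-LTR complex elements are dated per adjacent pair (5'–mid,
mid–3'); interpretation is left to the user. Saturated pairs
(2P + Q ≥ 1 or 2Q ≥ 1) are reported undated rather than clamped.

## The simulator

`simulate_genome()` emulates exactly the stated world the annotator
targets: an i.i.d.-uniform background; per-family LTR (200–600 bp)
and IN (1–4 kb) consensi; planted full-length, solo, three-LTR
complex, 5'/3'-truncated and internal-only copies (defaults 6/4/1/2/2/2
in 200 kb); per-copy substitutions at 2%/site; TSDs of 4–6 bp
duplicated at every insertion; nesting depths drawn from weights
(0.60, 0.25, 0.10, 0.04, 0.01) over layers 1–5, each nested element
splitting a host segment of the layer above. Insertion points keep
120 bp of margin from segment boundaries, so every split piece clears
the default `-L`/`-C` filters and breakpoint ownership is
unambiguous; top-level elements are separated by ≥ 500 bp of
background, well beyond `g_direct`. `emit_alignments()` converts the
ground truth into exact `.out` records (score = 10× length,
divergence = realised mismatch fraction) and can split records into
abutting halves with probability `noise` to exercise defragmentation.

What the simulator does *not* emulate: indels (so emitted coordinates
map exactly), realistic base composition or gene content, families
with internal similarity to each other, solo-LTR formation *in situ*
(solos are planted, not recombined from planted full-lengths), and
alignment noise beyond clean splits (no spurious or missing hits).
A green recovery test therefore establishes that the chaining logic
inverts the generative structure exactly; it does not establish
robustness to aligner artefacts outside that model.

## Determinism and degenerate inputs

All randomness flows from explicit seeds; ties are broken
deterministically (overlap ties by lower genome start; several
continuation candidates by genome proximity), so identical inputs
give byte-identical output trees. Empty files, empty fragment sets
and all-state-0 inputs yield empty-but-valid outputs. Fragments
overrunning their consensus length are reported, never silently
clamped. When overlap trimming splinters a fragment's remainder, the
largest piece survives.

## Known limitations

* Elements never span contigs.
* The greedy scan is order-dependent by design; pathological
  interleavings of same-family copies closer than `g_direct` can
  still be mis-chained as complex elements — that ambiguity is
  intrinsic to shared-LTR detection.
* TSDs are generated but not used algorithmically (the reconstructed
  method never consumes them); they exist so TSD-aware extensions
  have fixtures.
* The external-aligner adapter flags (`-P`, `-p`) are accepted for
  interface parity but untested here; the hermetic path consumes a
  precomputed `.out` table.
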