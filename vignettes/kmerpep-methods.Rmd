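---
title: "Deterministic k-mer peptide matching: model, guarantees and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deterministic k-mer peptide matching: model, guarantees and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmerpep)
```

## The problem

Short peptides — T-cell epitopes, MHC ligands, neoepitopes, allergen
fragments — need to be located inside large protein sets under a purely
substitutional notion of similarity: two equal-length strings are compared
by Hamming distance, the number of positions where they differ. Insertions,
deletions and similarity scoring are deliberately out of scope; what
matters to the downstream immunology is *every* window of the proteome
within a given substitution budget, with none missed. That completeness
requirement is what rules out heuristic aligners for this task and shapes
the whole design.

## The index

A proteome is a list of protein records (accession, optional UniProt
metadata, sequence). Sequences are concatenated in file order into a single
0-based global coordinate space; an offset table maps any global position
back to (protein, local offset). K-mers are enumerated *per protein* and
then shifted by the protein's global start, so no indexed k-mer ever spans
a protein boundary — boundary safety is structural rather than checked at
query time. For every protein of length L ≥ k, exactly L − k + 1 positions
are indexed.

The map itself is stored as two parallel vectors: the distinct k-mer
strings and, for each, the ascending list of its global start offsets.
Lookups batch all k-mers needed by a search call into a single `match()`
probe of the key table. An earlier design used a hashed environment keyed
by k-mer; R interns every binding name as a permanent symbol, so streams
of transient indexes (each with tens of thousands of distinct random
k-mers) grow the symbol table without bound. The vector layout has no such
leak and serializes directly.

Persistence writes a versioned container (format magic, version, k, a
digest of the concatenated sequences, payload). Loading verifies the magic
and version, and — when the caller supplies an expected k or proteome —
refuses a stale artifact instead of silently answering queries for the
wrong data. One serialized single-file format serves all search modes; the
save/load contract (round-trip identity on query behaviour, staleness
detection) is what the rest of the package depends on, not the encoding.

## Exact matching

A query of length l is split into the minimum covering set of ⌈l/k⌉
k-mers at offsets 0, k, 2k, …, the final one moved flush with the right
end when k does not divide l. Each piece's lookup results are translated
to *implied window starts* (proteome offset minus query offset); a window
is a hit iff every piece implies it. Intersection of implied starts is
equivalent to the "count votes per start" formulation and needs only the
covering pieces, not all l − k + 1 of them. Candidates whose window would
cross a protein boundary are discarded; all occurrences of each query are
reported. When a query set mixes lengths, the index k defaults to the
shortest query length and longer peptides are min-cover split against it.

## Mismatch matching and the pigeonhole bound

For an allowance of m substitutions the seed size is k = ⌊l/(m+1)⌋
(`optimal_k()`): split the query into m + 1 disjoint seeds of that size
and any window within Hamming distance m must agree with at least one seed
exactly — m substitutions cannot touch all m + 1 pieces. Seeds sit at
query offsets 0, k, …, mk; residues beyond (m+1)·k take part in
verification but not seeding, which preserves the guarantee. Every seed
hit proposes a candidate window start; candidates are deduplicated,
boundary-filtered, and verified by a full-length comparison against the
stored residue vector. The per-neighbour bookkeeping one could do k-mer by
k-mer accepts exactly the same windows as full-window verification; the
tests assert this equivalence rather than assume it (mismatch results are
checked against an oracle that never looks at k-mers).

`mismatch_search()` refuses an index whose k exceeds ⌊l/(m+1)⌋ for any
query rather than under-report: completeness violations are errors, not
degraded results. The inverse bound m = ⌊l/k − 1⌋ (`max_mismatches()`)
gives the largest allowance a given seed size can guarantee.

## Best-match searching

The best match is the window with the globally minimal substitution count.
The schedule starts at k = l (exact matching) and floor-halves to 2,
clamping values below 2 and collapsing duplicates — for l = 15:
k = 15, 7, 3, 2 searched at m = 0, 1, 4, 6. A k of 1 would degenerate to
brute force, so the cascade stops after k = 2. Because each stage is
complete up to its bound, the first stage at which a query finds any match
already contains that query's global minimum; the query keeps its
minimal-count rows (all ties) and is retired from later stages. Queries
whose true minimum exceeds ⌊l/2⌋ − 1 are reported as unmatched; an
optional `fallback = TRUE` resolves them by exhaustive scan, a deliberate
escape hatch rather than a default, since the cascade bound is the
documented contract.

## Reference implementations and what the tests show

`brute_exact()` (window-equality scan), `brute_hamming()` (per-position
disagreement accumulation over all windows) and `brute_best()` share no
logic with the index or the seeding — no k-mers anywhere — so set equality
between the two routes is a meaningful check. The acceptance suite runs 52
seeded synthetic proteomes (200 proteins of 100–500 residues each, about
60,000 residues per proteome) cycling a grid of query lengths 8–17 and
allowances 0–3, with peptides planted at Hamming distances 0..m+1 and
shuffled decoys planted nowhere; exact, mismatch and best-match results
must equal the corresponding oracle's exactly. These sizes keep the whole
suite under a minute on a single core while exercising every (l, m)
regime, including distances just beyond the allowance.

## The synthetic fixture generator

`make_proteome()` draws proteins uniformly over the 20 canonical residues
(uniform background keeps the expected number of spurious hits
analytically estimable; an alternative alphabet/frequency can be supplied),
then overwrites non-overlapping windows with copies of query peptides
mutated at exactly the requested Hamming distance — distinct positions,
never substituting a residue for itself. The manifest records every
planted site, giving ground truth for recall. Decoys are residue shuffles
of the planted peptides, re-shuffled until absent from the proteome
verbatim. What the generator does *not* emulate: real amino-acid
composition bias, homologous repeat families, and the heavy self-similarity
of real proteomes. Passing tests therefore demonstrate algorithmic
completeness and soundness, not performance or hit-rate statistics on real
data; on real proteomes the guarantee is the same but candidate volumes
and timings will differ.

`make_benchmark_dataset()` emits a drop-in benchmark triple
(proteome.fasta, peptides.txt, expected.csv, the latter produced by the
oracle) in three flavours mirroring common study designs: exact 9-mers
plus shuffled decoys, mixed 8–15-mers at m = 2, and 15-mers at distances
0–6 for best-match.

## Benchmark harness

`run_benchmark()` times three phases with the elapsed-time clock —
proteome preprocessing, query preprocessing, search — for any method
wrapped in the `benchmark_adapter()` contract (only `search` is required;
absent phases report NA and contribute nothing to the total). Recall is
the percentage of expected rows matched on the key (query sequence,
matched sequence, accession, start): order-invariant, duplicate-tolerant,
and unrewarding of spurious extras. Timings are reported, never asserted:
they are hardware facts, not correctness facts. Adapters for external
aligners can be plugged in by users; none are shipped, because a wrapper
that the test suite cannot exercise is untestable surface.

## Conventions and numerical choices

- Coordinates are 0-based internally (match rows included); the
  writer/reader boundary converts to 1-based inclusive `start`/`end`, the
  convention of protein databases. `mismatch_positions` are 1-based
  positions within the peptide, semicolon-joined.
- Sequences are uppercased on input, trailing `*` stripped; the residue
  alphabet is the 20 canonical amino acids plus X, B, Z, U, O, matched
  literally (X matches only X — no wildcard semantics, preserving
  determinism). Any other character is a parse error.
- Duplicate accessions are rejected at parse time; duplicate query
  sequences are legitimate and each input row is reported independently.
- Output rows are sorted by (query input order, accession, start), making
  identical inputs produce byte-identical files.
- Ties in best-match mode are all reported; callers who need one row can
  take the first under the deterministic ordering.

## Known limitations

No insertions or deletions; no substitution-matrix scoring or ranking of
co-optimal matches; no nucleotide sequences. Indexes live in memory — a
human-proteome-scale index fits comfortably, but domain-scale collections
(hundreds of millions of proteins) would need an out-of-core backend
behind the same save/load contract.
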