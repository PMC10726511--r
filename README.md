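# kmerpep

Deterministic k-mer matching of short peptides in large protein sets.

Immunologists routinely need to locate short peptides — MHC class I ligands
(8–11 residues), class II epitopes (13–17), neoepitopes, allergen-derived
peptides — inside whole proteomes: exactly, within a fixed number of residue
substitutions, or as the *best match* (the proteome window with the fewest
substitutions). General-purpose aligners are tuned for long sequences and
routinely miss short, substitution-only matches. kmerpep instead preprocesses
the proteome once into a k-mer → position index and resolves every query by
table lookups, with completeness guaranteed by a pigeonhole argument.

## Method

The proteome is concatenated in file order (0-based global coordinates,
k-mers never span protein boundaries) and every k-mer is stored with its
start offsets. For a query of length *l*:

- **Exact matching** splits the query into the fewest covering k-mers
  (offsets 0, k, 2k, …, with the last k-mer flush right). A window is a hit
  iff every piece is found and the differences (proteome offset − query
  offset) agree — i.e. all pieces vote for the same window start.
- **Mismatch matching** with allowance *m* uses seeds of size

  **k = ⌊ l / (m + 1) ⌋**

  If a window differs from the query by at most *m* substitutions, at least
  one of the m + 1 disjoint seeds must match it exactly (pigeonhole), so
  seed lookups propose every true window; each candidate is then verified by
  a full-length Hamming comparison. Every window at distance ≤ m is found —
  100% recall by construction, not heuristically.
- **Best-match searching** runs a cascade of indexes at k = l, ⌊l/2⌋, … down
  to 2, each stage searched at its guaranteed bound **m = ⌊ l/k − 1 ⌋**
  (for l = 15: stages k = 15, 7, 3, 2 with m = 0, 1, 4, 6). Queries
  satisfied at an earlier stage skip later ones; all minimal-distance ties
  are reported.

Brute-force reference implementations (`brute_exact()`, `brute_hamming()`,
`brute_best()`), a seeded synthetic fixture generator and a pluggable
benchmark harness (phase timings + recall scoring) are part of the package,
so the completeness guarantee is continuously tested against an independent
oracle on generated data.

## Worked example

`proteome.fasta` holds two demo proteins; `peptides.txt` three epitopes, one
exact, one with two substitutions, one exact in the other protein:

```text
ep1	YTKDISFEA
ep2	YTKDISAEV
ep3	WAAVPGKTF
```

```sh
kmerpep search proteome.fasta peptides.txt --mismatches 2 --format csv
```

```text
[kmerpep] mode=mismatch m=2: 3 queries against 2 proteins
[kmerpep] k values used: 3
[kmerpep] 3 matches for 3 queries
"query_id","query_sequence","matched_sequence","accession","protein_name","gene","mismatch_count","mismatch_positions","species","taxon_id","start","end","existence_level"
"ep1","YTKDISFEA","YTKDISFEA","P88888","Demo protein two","DEM2",0,"","synthetic construct",32630,17,25,5
"ep2","YTKDISAEV","YTKDISFEA","P88888","Demo protein two","DEM2",2,"7;9","synthetic construct",32630,17,25,5
"ep3","WAAVPGKTF","WAAVPGKTF","P99999","Demo protein one","DEM1",0,"","synthetic construct",32630,32,40,5
```

Each row is one hit: the query, the matched proteome window, the protein's
accession/name/gene, the substitution count with the 1-based peptide
positions where they occur (`7;9` for ep2), and the 1-based inclusive
start/end of the window within the protein. Log lines go to stderr; with
9-mers and m = 2 the engine picks seeds of size k = ⌊9/3⌋ = 3.

The same operations are available in R (`build_index()`, `exact_search()`,
`mismatch_search()`, `best_match_search()`, `search_peptides()`), and
`kmerpep benchmark --generate exact` times the preprocessing/search phases
and scores recall against oracle-generated expected output.

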