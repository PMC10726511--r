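# Shared test helpers: tiny proteome constructors and match-set comparison.

make_prot <- function(seqs, acc = sprintf("P%d", seq_along(seqs))) {
  tibble::tibble(
    accession = acc,
    name = paste("protein", acc),
    gene = paste0("G", seq_along(seqs)),
    species = "synthetic construct",
    taxon_id = 32630L,
    existence_level = 5L,
    sequence = toupper(seqs)
  )
}

make_queries <- function(seqs, ids = sprintf("q%d", seq_along(seqs))) {
  tibble::tibble(query_id = ids, sequence = toupper(seqs))
}

# identity key of a match row: query, window and its location
match_key <- function(x) {
  paste(x$query_id, x$query_sequence, x$accession, x$start, x$matched_sequence,
        x$mismatch_count, sep = "|")
}

expect_same_matches <- function(got, want) {
  expect_setequal(match_key(got), match_key(want))
  expect_equal(nrow(got), nrow(want))
}

# recompute each row's Hamming bookkeeping from its stored sequences
expect_match_invariants <- function(m) {
  for (i in seq_len(nrow(m))) {
    h <- hamming_distance(m$query_sequence[i], m$matched_sequence[i])
    expect_identical(m$mismatch_count[i], h$count)
    expect_identical(m$mismatch_positions[i], paste(h$positions, collapse = ";"))
    expect_identical(m$end[i], m$start[i] + nchar(m$query_sequence[i]) - 1L)
  }
  invisible(m)
}

empty_matches_for_tests <- function() kmerpep:::empty_matches()

random_prot_seq <- function(n) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y"), n, replace = TRUE), collapse = "")
}
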