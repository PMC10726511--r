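# Peptide splitting, seed-size arithmetic and the three search protocols.

test_that("rolling split enumerates all overlapping k-mers in order", {
  sp <- split_rolling("YLLDLHSYL", 5)
  expect_identical(sp$qoffset, 0:4)
  expect_identical(sp$kmer, c("YLLDL", "LLDLH", "LDLHS", "DLHSY", "LHSYL"))
  expect_identical(split_rolling("PEPTIDE", 7),
                   tibble::tibble(qoffset = 0L, kmer = "PEPTIDE"))
  for (l in 5:12) for (k in 2:l) {
    expect_identical(nrow(split_rolling(strrep("A", l), k)), l - k + 1L)
  }
  expect_error(split_rolling("PEP", 4), class = "kmerpep_invalid_parameter")
})

test_that("min-cover split uses ceiling(l/k) k-mers and covers every residue", {
  sp <- split_min_cover("YLLDLHSYL", 5)
  expect_identical(sp$qoffset, c(0L, 4L))
  expect_identical(sp$kmer, c("YLLDL", "LHSYL"))
  # divisible length: non-overlapping tiling
  sp9 <- split_min_cover("ABCDEFGHI", 3)
  expect_identical(sp9$qoffset, c(0L, 3L, 6L))
  set.seed(21)
  for (rep in 1:30) {
    l <- sample(4:20, 1); k <- sample(2:l, 1)
    pep <- random_prot_seq(l)
    sp <- split_min_cover(pep, k)
    expect_identical(nrow(sp), as.integer(ceiling(l / k)))
    covered <- sort(unique(unlist(lapply(sp$qoffset, function(o) o + 1:k))))
    expect_identical(covered, 1:l)
    expect_true(all(sp$kmer == substring(pep, sp$qoffset + 1, sp$qoffset + k)))
  }
})

test_that("seed size and mismatch bound follow the pigeonhole arithmetic", {
  expect_identical(optimal_k(9, 2), 3L)
  expect_identical(optimal_k(15, 1), 7L)
  for (l in 2:20) expect_identical(optimal_k(l, 0), as.integer(l))
  expect_error(optimal_k(3, 5), class = "kmerpep_infeasible")

  expect_identical(max_mismatches(15, 2), 6L)
  expect_identical(max_mismatches(15, 7), 1L)
  for (l in 2:20) expect_identical(max_mismatches(l, l), 0L)
  expect_error(max_mismatches(5, 6), class = "kmerpep_invalid_parameter")

  # the bound is consistent: seeding at optimal_k(l, m) always tolerates >= m
  for (l in 2:25) for (m in 0:5) {
    if (l %/% (m + 1) < 1) next
    expect_gte(max_mismatches(l, optimal_k(l, m)), m)
  }
})

test_that("hamming_distance agrees with a character-by-character oracle", {
  expect_identical(hamming_distance("PEPTIDE", "PEPTIDE"),
                   list(count = 0L, positions = integer(0)))
  expect_identical(hamming_distance("AAA", "ABA"),
                   list(count = 1L, positions = 2L))
  expect_error(hamming_distance("AA", "AAA"), class = "kmerpep_invalid_parameter")
  set.seed(22)
  for (rep in 1:50) {
    l <- sample(2:20, 1)
    a <- random_prot_seq(l); b <- random_prot_seq(l)
    h <- hamming_distance(a, b)
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    expect_identical(h$count, sum(ca != cb))
    expect_identical(h$positions, which(ca != cb))
  }
})

test_that("exact search reports every occurrence and nothing else", {
  # planted twice in one protein and once in another: all three reported
  pep <- "YLLDLHSYL"
  prot <- make_prot(c(paste0("AAAA", pep, "CCCC", pep, "DD"),
                      paste0(pep, "WWWWW"),
                      random_prot_seq(40)))
  idx <- build_index(prot, 5)
  res <- exact_search(idx, make_queries(pep))
  expect_identical(res$start, c(4L, 17L, 0L))
  expect_identical(res$accession, c("P1", "P1", "P2"))
  expect_true(all(res$mismatch_count == 0L))
  expect_true(all(res$matched_sequence == pep))
  expect_match_invariants(res)
})

test_that("a peptide straddling two proteins is not matched", {
  prot <- make_prot(c("AAAAPEPT", "IDESSSS"))
  idx <- build_index(prot, 4)
  res <- exact_search(idx, make_queries("PEPTIDES"))
  expect_identical(nrow(res), 0L)
})

test_that("queries shorter than k yield per-query errors, others proceed", {
  idx <- build_index(make_prot("YLLDLHSYLAAAA"), 5)
  res <- exact_search(idx, make_queries(c("YLL", "YLLDLHSYL")))
  expect_identical(nrow(res), 1L)
  errs <- attr(res, "query_errors")
  expect_identical(errs$query_id, "q1")
})

test_that("exact search equals the brute-force oracle on planted fixtures", {
  for (seed in 1:4) {
    fx <- make_proteome(fixture_spec(
      n_proteins = 40, min_len = 60, max_len = 150, n_planted = 50,
      planted_lengths = 9L, planted_distances = 0L, n_decoys = 10, seed = seed))
    qs <- rbind(fx$queries, fx$decoys)
    got <- search_peptides(fx$proteome, qs, "exact")
    want <- brute_exact(fx$proteome, qs)
    expect_same_matches(got, want)
    # decoys are constructed absent: zero exact matches
    expect_identical(sum(got$query_id %in% fx$decoys$query_id), 0L)
  }
})

test_that("the worked mismatch example accepts at exactly the threshold", {
  # query of length 9, m = 2, k = 3: the planted window differs in the
  # right-hand seed's neighborhood by exactly 2 residues
  query <- "YLLDLHSYL"
  window <- "YLLDLHAYV"  # mismatches at peptide positions 7 and 9
  prot <- make_prot(paste0("GGGG", window, "GGGG"))
  idx <- build_index(prot, optimal_k(9, 2))
  res <- mismatch_search(idx, make_queries(query), 2)
  expect_identical(nrow(res), 1L)
  expect_identical(res$start, 4L)
  expect_identical(res$mismatch_count, 2L)
  expect_identical(res$mismatch_positions, "7;9")
  # one fewer allowance rejects the same window
  idx3 <- build_index(prot, optimal_k(9, 1))
  expect_identical(nrow(mismatch_search(idx3, make_queries(query), 1)), 0L)
})

test_that("mismatch search at m = 0 reduces to exact search", {
  fx <- make_proteome(fixture_spec(n_proteins = 30, min_len = 50, max_len = 120,
                                   n_planted = 20, planted_lengths = 9L,
                                   planted_distances = 0L, seed = 31))
  idx <- build_index(fx$proteome, 9)
  em <- mismatch_search(idx, fx$queries, 0)
  ex <- exact_search(idx, fx$queries)
  expect_same_matches(em, ex)
})

test_that("an index too coarse for the requested allowance is refused", {
  idx <- build_index(make_prot(random_prot_seq(50)), 5)
  expect_error(mismatch_search(idx, make_queries("YLLDLHSYL"), 2),
               class = "kmerpep_infeasible")
})

test_that("mismatch search equals the brute-force Hamming oracle on a grid", {
  for (seed in 1:3) {
    for (m in 0:3) {
      l <- sample(8:17, 1)
      fx <- make_proteome(fixture_spec(
        n_proteins = 30, min_len = 60, max_len = 150, n_planted = 12,
        planted_lengths = l, planted_distances = 0:(m + 1), seed = seed * 10 + m))
      idx <- build_index(fx$proteome, optimal_k(l, m))
      got <- mismatch_search(idx, fx$queries, m)
      want <- brute_hamming(fx$proteome, fx$queries, m)
      expect_same_matches(got, want)
      expect_match_invariants(got)
      # a window planted beyond the allowance is never its query's report
      beyond <- fx$manifest[fx$manifest$distance == m + 1, ]
      for (i in seq_len(nrow(beyond))) {
        expect_false(any(got$query_id == beyond$query_id[i] &
                         got$accession == beyond$accession[i] &
                         got$start == beyond$start[i]))
      }
    }
  }
})

test_that("match sets grow monotonically with the allowance", {
  fx <- make_proteome(fixture_spec(n_proteins = 25, min_len = 60, max_len = 120,
                                   n_planted = 10, planted_lengths = 9L,
                                   planted_distances = 0:3, seed = 41))
  prev <- NULL
  for (m in 0:3) {
    idx <- build_index(fx$proteome, optimal_k(9, m))
    cur <- mismatch_search(idx, fx$queries, m)
    if (!is.null(prev)) {
      expect_true(all(match_key(prev) %in% match_key(cur)))
    }
    prev <- cur
  }
})

test_that("the best-match cascade halves k down to 2 with growing bounds", {
  expect_identical(best_match_schedule(15), c(15L, 7L, 3L, 2L))
  expect_identical(vapply(best_match_schedule(15), max_mismatches, integer(1),
                          l = 15), c(0L, 1L, 4L, 6L))
  expect_identical(best_match_schedule(2), 2L)
  expect_identical(best_match_schedule(9), c(9L, 4L, 2L))
  # thresholds never decrease as k shrinks
  for (l in 2:25) {
    ks <- best_match_schedule(l)
    ms <- vapply(ks, max_mismatches, integer(1), l = l)
    expect_identical(ks, unique(ks))
    expect_true(all(diff(ms) >= 0))
    expect_identical(ks[length(ks)], 2L)
  }
})

test_that("an exactly present peptide is resolved at the first stage", {
  pep <- strrep("LYDHS", 3)
  prot <- make_prot(c(paste0("AAAA", pep, "AAAA"), random_prot_seq(60)))
  res <- best_match_search(prot, make_queries(pep))
  expect_identical(res$mismatch_count, 0L)
  expect_identical(res$start, 4L)
  expect_identical(nrow(attr(res, "unmatched")), 0L)
})

test_that("best-match search recovers the oracle's minimum distance", {
  for (seed in 5:7) {
    fx <- make_proteome(fixture_spec(
      n_proteins = 30, min_len = 60, max_len = 150, n_planted = 14,
      planted_lengths = 15L, planted_distances = 0:6, seed = seed))
    got <- best_match_search(fx$proteome, fx$queries)
    want <- brute_best(fx$proteome, fx$queries)
    expect_same_matches(got, want)
    expect_match_invariants(got)
  }
})

test_that("queries beyond the cascade bound are unmatched unless fallback is on", {
  # in a single-letter proteome an all-W 8-mer query has distance 8 > bound 3
  prot <- make_prot(strrep("A", 60))
  q <- make_queries("WWWWWWWW")
  res <- best_match_search(prot, q)
  expect_identical(nrow(res), 0L)
  expect_identical(attr(res, "unmatched")$query_id, "q1")
  res2 <- best_match_search(prot, q, fallback = TRUE)
  expect_true(all(res2$mismatch_count == 8L))
  expect_identical(nrow(res2), 53L)  # every window ties at distance 8
})

test_that("search output is deterministic and sorted by query, protein, start", {
  fx <- make_proteome(fixture_spec(n_proteins = 30, min_len = 60, max_len = 120,
                                   n_planted = 10, planted_lengths = 9L,
                                   planted_distances = 0:2, seed = 51))
  a <- search_peptides(fx$proteome, fx$queries, "mismatch", m = 2)
  b <- search_peptides(fx$proteome, fx$queries, "mismatch", m = 2)
  expect_identical(a, b)
  qi <- match(a$query_id, fx$queries$query_id)
  expect_false(is.unsorted(qi))
  for (q in unique(a$query_id)) {
    sub <- a[a$query_id == q, ]
    expect_false(is.unsorted(order(sub$accession, sub$start)))
  }
})

test_that("mixed-length query sets are handled per length group", {
  fx <- make_proteome(fixture_spec(n_proteins = 30, min_len = 60, max_len = 150,
                                   n_planted = 16, planted_lengths = 8:15,
                                   planted_distances = 0:2, seed = 61))
  got <- search_peptides(fx$proteome, fx$queries, "mismatch", m = 2)
  want <- brute_hamming(fx$proteome, fx$queries, 2)
  expect_same_matches(got, want)
})
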