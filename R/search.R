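# Exact, fixed-mismatch and best-match peptide search over a k-mer index,
# plus the seed-size arithmetic that makes mismatch search complete.

#' Split a peptide into all overlapping k-mers
#'
#' Rolling window of one residue: a peptide of length l yields l - k + 1
#' k-mers at query offsets 0, 1, ..., l - k.
#'
#' @param peptide Peptide string.
#' @param k K-mer size, `k <= nchar(peptide)`.
#' @return Tibble with columns `qoffset` (0-based) and `kmer`.
#' @examples
#' split_rolling("YLLDLHSYL", 5)
#' @export
split_rolling <- function(peptide, k) {
  l <- nchar(peptide)
  if (k < 1 || k > l) {
    abort_kmerpep("k must satisfy 1 <= k <= peptide length",
                  "kmerpep_invalid_parameter")
  }
  n <- l - k + 1L
  tibble::tibble(qoffset = 0:(n - 1L), kmer = substring(peptide, 1:n, k:l))
}

#' Split a peptide into the fewest k-mers that cover it
#'
#' K-mers at query offsets 0, k, 2k, ...; when k does not divide the length
#' the final k-mer is shifted left to end flush with the peptide, so the
#' last two k-mers overlap.  The count is always `ceiling(l / k)` and every
#' residue is covered.
#'
#' @inheritParams split_rolling
#' @return Tibble with columns `qoffset` and `kmer`.
#' @examples
#' split_min_cover("YLLDLHSYL", 5)  # YLLDL at 0, LHSYL at 4
#' @export
split_min_cover <- function(peptide, k) {
  l <- nchar(peptide)
  if (k < 1 || k > l) {
    abort_kmerpep("k must satisfy 1 <= k <= peptide length",
                  "kmerpep_invalid_parameter")
  }
  offs <- seq(0L, by = k, length.out = ceiling(l / k))
  offs[length(offs)] <- l - k  # flush right when k does not divide l
  tibble::tibble(qoffset = as.integer(offs),
                 kmer = substring(peptide, offs + 1L, offs + k))
}

#' Optimal seed k-mer size for a mismatch search
#'
#' By the pigeonhole principle, a peptide of length `l` split into `m + 1`
#' pieces of length `floor(l / (m + 1))` must share at least one exactly
#' matching piece with any window within Hamming distance `m`, so
#' `k = floor(l / (m + 1))` is the largest seed size that guarantees
#' completeness.
#'
#' @param l Peptide length (>= 1).
#' @param m Allowed mismatches (>= 0).
#' @return The seed size `k` as an integer.
#' @examples
#' optimal_k(9, 2)  # 3
#' @export
optimal_k <- function(l, m) {
  if (l < 1 || m < 0) {
    abort_kmerpep("require l >= 1 and m >= 0", "kmerpep_invalid_parameter")
  }
  k <- as.integer(l) %/% (as.integer(m) + 1L)
  if (k < 1) {
    abort_kmerpep(sprintf(
      "infeasible parameters: %d mismatches need %d pieces but the peptide has only %d residues",
      m, m + 1, l), "kmerpep_infeasible")
  }
  k
}

#' Maximum mismatches guaranteed findable at a given seed size
#'
#' The inverse of [optimal_k()]: with seeds of size `k`, every match with
#' up to `floor(l / k - 1)` substitutions is guaranteed to be found.
#'
#' @param l Peptide length.
#' @param k Seed k-mer size, `1 <= k <= l`.
#' @return Mismatch bound `m` as an integer.
#' @examples
#' max_mismatches(15, 2)  # 6
#' @export
max_mismatches <- function(l, k) {
  if (k < 1 || k > l) {
    abort_kmerpep("require 1 <= k <= l", "kmerpep_invalid_parameter")
  }
  as.integer(l) %/% as.integer(k) - 1L
}

#' Hamming distance between two equal-length strings
#'
#' @param a,b Strings of equal length.
#' @return A list with `count` (number of differing positions) and
#'   `positions` (1-based positions of the differences, ascending).
#' @export
hamming_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    abort_kmerpep("Hamming distance requires equal-length strings",
                  "kmerpep_invalid_parameter")
  }
  pos <- which(utf8ToInt(a) != utf8ToInt(b))
  list(count = length(pos), positions = as.integer(pos))
}

# --- match assembly -------------------------------------------------------

# Build match rows for verified windows.  g0: global window starts, q: one
# row of the query set, mism_pos: list of integer vectors (1-based).
assemble_matches <- function(index, query_id, query_sequence, g0, mism_pos) {
  if (length(g0) == 0) return(empty_matches())
  l <- nchar(query_sequence)
  ord <- protein_ordinal(index, g0)
  local <- as.integer(g0 - index$starts[ord])
  rec <- index$records[ord, ]
  tibble::tibble(
    query_id = query_id,
    query_sequence = query_sequence,
    matched_sequence = substring(rec$sequence, local + 1L, local + l),
    accession = rec$accession,
    protein_name = rec$name,
    gene = rec$gene,
    mismatch_count = vapply(mism_pos, length, integer(1)),
    mismatch_positions = vapply(mism_pos, paste, character(1), collapse = ";"),
    species = rec$species,
    taxon_id = rec$taxon_id,
    start = local,
    end = local + l - 1L,
    existence_level = rec$existence_level
  )
}

# candidate window starts that lie entirely within one protein
window_in_protein <- function(index, g0, l) {
  ok <- g0 >= 0 & g0 + l <= index$total
  ord <- rep(NA_integer_, length(g0))
  ord[ok] <- protein_ordinal(index, g0[ok])
  ok[ok] <- g0[ok] + l <= index$starts[ord[ok]] + index$lengths[ord[ok]]
  ok
}

sort_matches <- function(matches, query_order) {
  if (nrow(matches) == 0) return(matches)
  qi <- match(matches$query_id, query_order)
  matches[order(qi, matches$accession, matches$start), ]
}

# --- exact search ---------------------------------------------------------

#' Exact peptide search
#'
#' Each query is split into the minimal covering set of index-k k-mers;
#' a window is a match iff every k-mer is found at its expected offset,
#' i.e. the difference (proteome offset - query offset) agrees across all
#' k-mers.  All occurrences of each peptide are reported.  Queries shorter
#' than `index$k` are recorded in the `query_errors` attribute and the
#' remaining queries proceed.
#'
#' @param index A `proteome_index`.
#' @param queries Query tibble (`query_id`, `sequence`), see [read_peptides()].
#' @return Match tibble sorted by (query input order, accession, start),
#'   with attribute `query_errors` (tibble of `query_id`, `message`).
#' @export
exact_search <- function(index, queries) {
  k <- index$k
  res <- vector("list", nrow(queries))
  errs <- list()
  too_short <- nchar(queries$sequence) < k
  for (i in which(too_short)) {
    errs[[length(errs) + 1]] <- tibble::tibble(
      query_id = queries$query_id[i],
      message = sprintf("query length %d < index k %d",
                        nchar(queries$sequence[i]), k))
  }
  valid <- which(!too_short)
  pieces_list <- lapply(queries$sequence[valid], split_min_cover, k = k)
  hits_list <- kmer_lookup_many(index, unlist(lapply(pieces_list, `[[`, "kmer")))
  cursor <- 0L
  for (v in seq_along(valid)) {
    i <- valid[v]
    pep <- queries$sequence[i]
    l <- nchar(pep)
    pieces <- pieces_list[[v]]
    cand <- hits_list[[cursor + 1L]] - pieces$qoffset[1]
    for (j in seq_len(nrow(pieces))[-1]) {
      if (length(cand) == 0) break
      cand <- intersect(cand, hits_list[[cursor + j]] - pieces$qoffset[j])
    }
    cursor <- cursor + nrow(pieces)
    cand <- cand[window_in_protein(index, cand, l)]
    res[[i]] <- assemble_matches(index, queries$query_id[i], pep, cand,
                                 rep(list(integer(0)), length(cand)))
  }
  out <- do.call(rbind, c(res[!vapply(res, is.null, logical(1))],
                          list(empty_matches())))
  out <- sort_matches(out, queries$query_id)
  attr(out, "query_errors") <- if (length(errs) > 0) do.call(rbind, errs) else
    tibble::tibble(query_id = character(), message = character())
  out
}

# --- mismatch search ------------------------------------------------------

# Core seed-and-verify pass for one query against one index, threshold m.
# Seeds are the m + 1 non-overlapping k-mers at query offsets 0, k, ..., mk;
# the pigeonhole principle guarantees an exact seed for every true match.
# Surviving candidate windows are verified by full-length Hamming
# comparison against the stored residues.  seed_hits, when supplied, are
# the pre-batched lookup results for the m + 1 seeds.
seed_verify_one <- function(index, pep, m, seed_hits = NULL) {
  k <- index$k
  l <- nchar(pep)
  qoffs <- (0:m) * k
  if (is.null(seed_hits)) {
    seed_hits <- kmer_lookup_many(index, substring(pep, qoffs + 1L, qoffs + k))
  }
  cand <- unique(unlist(lapply(seq_along(seed_hits), function(j) {
    seed_hits[[j]] - qoffs[j]
  })))
  if (length(cand) == 0) return(list(g0 = integer(0), pos = list()))
  cand <- sort(cand[window_in_protein(index, cand, l)])
  if (length(cand) == 0) return(list(g0 = integer(0), pos = list()))
  qi <- utf8ToInt(pep)
  pos <- vector("list", length(cand))
  keep <- logical(length(cand))
  for (j in seq_along(cand)) {
    w <- index$residues[(cand[j] + 1L):(cand[j] + l)]
    p <- which(w != qi)
    if (length(p) <= m) {
      keep[j] <- TRUE
      pos[[j]] <- as.integer(p)
    }
  }
  list(g0 = cand[keep], pos = pos[keep])
}

#' Mismatch (Hamming) peptide search
#'
#' Finds every window within a single protein whose Hamming distance to a
#' query is at most `m`, exact matches included.  Completeness requires
#' `index$k <= floor(l / (m + 1))` for every query length `l` (see
#' [optimal_k()]); violating lengths raise an infeasible-parameters error
#' rather than silently under-reporting.
#'
#' @param index A `proteome_index`.
#' @param queries Query tibble.
#' @param m Allowed mismatches, an integer >= 0.
#' @return Match tibble sorted by (query input order, accession, start).
#' @export
mismatch_search <- function(index, queries, m) {
  if (!is.numeric(m) || length(m) != 1 || is.na(m) || m < 0) {
    abort_kmerpep("m must be a single integer >= 0", "kmerpep_invalid_parameter")
  }
  m <- as.integer(m)
  k <- index$k
  bad <- nchar(queries$sequence) %/% (m + 1L) < k
  if (any(bad)) {
    abort_kmerpep(sprintf(
      "index k=%d cannot guarantee completeness for length-%d queries at m=%d (need k <= %d)",
      k, nchar(queries$sequence[bad][1]), m,
      nchar(queries$sequence[bad][1]) %/% (m + 1L)), "kmerpep_infeasible")
  }
  res <- vector("list", nrow(queries))
  # one batched key-table probe for every query's m + 1 seeds
  qoffs <- (0:m) * k
  all_seeds <- unlist(lapply(queries$sequence, substring,
                             first = qoffs + 1L, last = qoffs + k))
  all_hits <- kmer_lookup_many(index, all_seeds)
  for (i in seq_len(nrow(queries))) {
    hit <- seed_verify_one(index, queries$sequence[i], m,
                           seed_hits = all_hits[(i - 1L) * (m + 1L) + seq_len(m + 1L)])
    res[[i]] <- assemble_matches(index, queries$query_id[i],
                                 queries$sequence[i], hit$g0, hit$pos)
  }
  out <- do.call(rbind, c(res, list(empty_matches())))
  sort_matches(out, queries$query_id)
}

# --- best match search ----------------------------------------------------

#' Seed-size schedule for the best-match cascade
#'
#' Starts at `k = l`, repeatedly halves (floor), clamps values below 2 up
#' to 2 and stops after the `k = 2` stage (a k of 1 would be brute force).
#' Duplicate k values are collapsed.
#'
#' @param l Peptide length (>= 2).
#' @return Integer vector of k values, decreasing.
#' @examples
#' best_match_schedule(15)  # 15 7 3 2
#' @export
best_match_schedule <- function(l) {
  if (l < 2) {
    abort_kmerpep("best-match search requires peptide length >= 2",
                  "kmerpep_invalid_parameter")
  }
  ks <- integer(0)
  k <- as.integer(l)
  repeat {
    ks <- c(ks, max(k, 2L))
    if (max(k, 2L) == 2L) break
    k <- k %/% 2L
  }
  unique(ks)
}

#' Best-match peptide search
#'
#' Finds, for each query, the match(es) with the globally minimal number
#' of substitutions.  The proteome is indexed at a cascade of seed sizes
#' (`k = l`, then floor-halving down to 2); each stage runs a mismatch
#' search at that stage's guaranteed bound `max_mismatches(l, k)`.  A query
#' satisfied at an earlier stage is retired and skips later stages, so an
#' exactly present peptide is resolved at the first (k = l) stage.  A query
#' whose true best distance exceeds `max_mismatches(l, 2) = floor(l/2) - 1`
#' is reported in the `unmatched` attribute unless `fallback = TRUE`, in
#' which case an exhaustive window scan resolves it.
#'
#' @param proteome Proteome tibble.
#' @param queries Query tibble.
#' @param fallback Resolve out-of-bound queries by exhaustive scan.
#' @param cache Optional index cache (internal reuse across calls).
#' @return Match tibble of minimal-distance hits (all ties reported),
#'   sorted by (query input order, accession, start), with attribute
#'   `unmatched`: tibble of queries with no match within the cascade bound.
#' @export
best_match_search <- function(proteome, queries, fallback = FALSE, cache = NULL) {
  validate_proteome(proteome)
  if (is.null(cache)) cache <- new_index_cache(proteome)
  res <- list()
  unmatched <- list()
  for (l in sort(unique(nchar(queries$sequence)))) {
    grp <- queries[nchar(queries$sequence) == l, ]
    remaining <- grp
    for (k in best_match_schedule(l)) {
      if (nrow(remaining) == 0) break
      m <- max_mismatches(l, k)
      idx <- cache_get_index(cache, k)
      hits <- mismatch_search(idx, remaining, m)
      if (nrow(hits) > 0) {
        # keep only each query's minimal-distance rows; retire those queries
        best <- tapply(hits$mismatch_count, hits$query_id, min)
        hits <- hits[hits$mismatch_count == best[hits$query_id], ]
        res[[length(res) + 1]] <- hits
        remaining <- remaining[!remaining$query_id %in% hits$query_id, ]
      }
    }
    if (nrow(remaining) > 0) {
      if (fallback) {
        res[[length(res) + 1]] <- brute_best(proteome, remaining)
      } else {
        unmatched[[length(unmatched) + 1]] <- remaining
      }
    }
  }
  out <- do.call(rbind, c(res, list(empty_matches())))
  out <- sort_matches(out, queries$query_id)
  attr(out, "unmatched") <- if (length(unmatched) > 0) do.call(rbind, unmatched) else
    queries[0, ]
  out
}

# --- umbrella -------------------------------------------------------------

#' Search peptides in a proteome (umbrella over the three modes)
#'
#' Groups queries by length, chooses k per group ([optimal_k()] in mismatch
#' mode; the shortest query length in exact mode), builds or reuses the
#' needed indexes and dispatches to the mode's search.
#'
#' @param proteome Proteome tibble.
#' @param queries Query tibble.
#' @param mode One of `"exact"`, `"mismatch"`, `"best"`.
#' @param m Allowed mismatches (mismatch mode only).
#' @param fallback Passed to [best_match_search()].
#' @param cache Optional index cache.
#' @return Match tibble (see the mode-specific functions for attributes).
#' @export
search_peptides <- function(proteome, queries, mode = c("exact", "mismatch", "best"),
                            m = 0L, fallback = FALSE, cache = NULL) {
  mode <- match.arg(mode)
  validate_proteome(proteome)
  if (is.null(cache)) cache <- new_index_cache(proteome)
  if (mode == "exact") {
    idx <- cache_get_index(cache, min(nchar(queries$sequence)))
    return(exact_search(idx, queries))
  }
  if (mode == "best") {
    return(best_match_search(proteome, queries, fallback = fallback, cache = cache))
  }
  res <- list()
  for (l in sort(unique(nchar(queries$sequence)))) {
    grp <- queries[nchar(queries$sequence) == l, ]
    idx <- cache_get_index(cache, optimal_k(l, m))
    res[[length(res) + 1]] <- mismatch_search(idx, grp, m)
  }
  out <- do.call(rbind, c(res, list(empty_matches())))
  sort_matches(out, queries$query_id)
}
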