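# Brute-force reference implementations.  These deliberately share no code
# with the k-mer index or the seed-and-verify search: exact matching is a
# direct window-equality scan and Hamming search accumulates per-position
# disagreement counts across all windows, so agreement between the two
# routes is a meaningful check rather than a tautology.

oracle_assemble <- function(rec, query_id, query_sequence, starts0, counts, pos_list) {
  l <- nchar(query_sequence)
  if (length(starts0) == 0) return(empty_matches())
  tibble::tibble(
    query_id = query_id,
    query_sequence = query_sequence,
    matched_sequence = substring(rec$sequence, starts0 + 1L, starts0 + l),
    accession = rec$accession,
    protein_name = rec$name,
    gene = rec$gene,
    mismatch_count = as.integer(counts),
    mismatch_positions = vapply(pos_list, paste, character(1), collapse = ";"),
    species = rec$species,
    taxon_id = rec$taxon_id,
    start = as.integer(starts0),
    end = as.integer(starts0) + l - 1L,
    existence_level = rec$existence_level
  )
}

# per-protein vector of Hamming distances of the query to every window
window_distances <- function(prot_int, q_int) {
  L <- length(prot_int)
  l <- length(q_int)
  if (L < l) return(integer(0))
  n <- L - l + 1L
  d <- integer(n)
  for (j in seq_len(l)) {
    d <- d + (prot_int[j:(j + n - 1L)] != q_int[j])
  }
  d
}

#' Brute-force exact search (reference implementation)
#'
#' Naive window-equality scan over every protein; complete by construction,
#' overlapping occurrences included.  Used as the ground truth in tests and
#' for generating benchmark expected output.
#'
#' @param proteome Proteome tibble.
#' @param queries Query tibble.
#' @return Match tibble sorted by (query input order, accession, start).
#' @export
brute_exact <- function(proteome, queries) {
  res <- list()
  lens <- unique(nchar(queries$sequence))
  for (p in seq_len(nrow(proteome))) {
    rec <- proteome[p, ]
    L <- nchar(rec$sequence)
    for (l in lens) {
      if (L < l) next
      # the window set depends only on the length, share it across queries
      wins <- substring(rec$sequence, 1:(L - l + 1L), l:L)
      for (i in which(nchar(queries$sequence) == l)) {
        pep <- queries$sequence[i]
        s0 <- which(wins == pep) - 1L
        if (length(s0) > 0) {
          res[[length(res) + 1]] <- oracle_assemble(
            rec, queries$query_id[i], pep, s0, rep(0L, length(s0)),
            rep(list(integer(0)), length(s0)))
        }
      }
    }
  }
  out <- do.call(rbind, c(res, list(empty_matches())))
  sort_matches(out, queries$query_id)
}

#' Brute-force Hamming search (reference implementation)
#'
#' Direct comparison of each query against every same-length window of
#' every protein; reports all windows at distance at most `m`.
#'
#' @param proteome Proteome tibble.
#' @param queries Query tibble.
#' @param m Allowed mismatches (>= 0).
#' @return Match tibble sorted by (query input order, accession, start).
#' @export
brute_hamming <- function(proteome, queries, m) {
  stopifnot(m >= 0)
  prot_ints <- lapply(proteome$sequence, utf8ToInt)
  res <- list()
  for (i in seq_len(nrow(queries))) {
    q_int <- utf8ToInt(queries$sequence[i])
    for (p in seq_len(nrow(proteome))) {
      d <- window_distances(prot_ints[[p]], q_int)
      s0 <- which(d <= m) - 1L
      if (length(s0) > 0) {
        pos <- lapply(s0, function(s) {
          which(prot_ints[[p]][(s + 1L):(s + length(q_int))] != q_int)
        })
        res[[length(res) + 1]] <- oracle_assemble(
          proteome[p, ], queries$query_id[i], queries$sequence[i],
          s0, d[s0 + 1L], pos)
      }
    }
  }
  out <- do.call(rbind, c(res, list(empty_matches())))
  sort_matches(out, queries$query_id)
}

#' Brute-force best-match search (reference implementation)
#'
#' Scans every window of every protein and returns, per query, the
#' window(s) at the global minimum Hamming distance, all ties included.
#'
#' @param proteome Proteome tibble.
#' @param queries Query tibble.
#' @return Match tibble sorted by (query input order, accession, start).
#' @export
brute_best <- function(proteome, queries) {
  prot_ints <- lapply(proteome$sequence, utf8ToInt)
  res <- list()
  for (i in seq_len(nrow(queries))) {
    q_int <- utf8ToInt(queries$sequence[i])
    dists <- lapply(prot_ints, window_distances, q_int = q_int)
    mins <- vapply(dists, function(d) if (length(d) == 0) NA_integer_ else min(d),
                   integer(1))
    if (all(is.na(mins))) next
    gmin <- min(mins, na.rm = TRUE)
    for (p in which(!is.na(mins) & mins == gmin)) {
      s0 <- which(dists[[p]] == gmin) - 1L
      pos <- lapply(s0, function(s) {
        which(prot_ints[[p]][(s + 1L):(s + length(q_int))] != q_int)
      })
      res[[length(res) + 1]] <- oracle_assemble(
        proteome[p, ], queries$query_id[i], queries$sequence[i],
        s0, rep(gmin, length(s0)), pos)
    }
  }
  out <- do.call(rbind, c(res, list(empty_matches())))
  sort_matches(out, queries$query_id)
}
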