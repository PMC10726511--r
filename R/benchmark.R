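# Pluggable benchmarking harness: times the proteome-preprocessing, query-
# preprocessing and search phases of a method and scores its recall against
# an expected-output file.  Wall-clock numbers are hardware-dependent and
# are reported, never asserted.

#' Score recall of reported matches against expected matches
#'
#' A reported row counts for an expected row iff the key
#' (query_sequence, matched_sequence, accession, start) matches exactly;
#' recall is the percentage of expected rows so covered.  Row order and
#' duplicate reported rows do not affect the score, and extra spurious rows
#' do not lower it (recall, not precision).
#'
#' @param reported Match tibble reported by a method.
#' @param expected Match tibble of ground-truth matches.
#' @return Recall percentage in `[0, 100]`.
#' @export
compare_results <- function(reported, expected) {
  if (nrow(expected) == 0) return(100)
  key <- function(x) paste(x$query_sequence, x$matched_sequence,
                           x$accession, x$start, sep = "\r")
  100 * mean(key(expected) %in% key(reported))
}

#' Define a benchmark adapter
#'
#' An adapter plugs a matching method into the harness.  `search` is
#' required; the two preprocessing hooks are optional (methods without a
#' preprocessing phase report `NA` for that phase's time).
#'
#' @param name Method name for the report.
#' @param search `function(proteome, queries, params, state)` returning a
#'   match tibble; `state` is the list of preprocessing results.
#' @param preprocess_proteome Optional `function(proteome, params)`.
#' @param preprocess_query Optional `function(queries, params)`.
#' @return A `benchmark_adapter`.
#' @export
benchmark_adapter <- function(name, search, preprocess_proteome = NULL,
                              preprocess_query = NULL) {
  stopifnot(is.character(name), is.function(search))
  structure(list(name = name, search = search,
                 preprocess_proteome = preprocess_proteome,
                 preprocess_query = preprocess_query),
            class = "benchmark_adapter")
}

#' Built-in k-mer engine as a benchmark adapter
#'
#' Proteome preprocessing builds the index(es) the mode needs; the search
#' phase then runs on the prebuilt cache.
#'
#' @return A `benchmark_adapter` wrapping [search_peptides()].
#' @export
kmer_engine_adapter <- function() {
  benchmark_adapter(
    name = "kmer-engine",
    preprocess_proteome = function(proteome, params) {
      cache <- new_index_cache(proteome)
      lens <- unique(params$query_lengths)
      ks <- switch(params$mode,
        exact = min(lens),
        mismatch = unique(vapply(lens, optimal_k, integer(1), m = params$m)),
        best = unique(unlist(lapply(lens, best_match_schedule)))
      )
      for (k in ks) cache_get_index(cache, k)
      cache
    },
    search = function(proteome, queries, params, state) {
      search_peptides(proteome, queries, mode = params$mode,
                      m = params$m %||% 0L, cache = state$proteome)
    }
  )
}

#' Run one method through the benchmark
#'
#' Each implemented phase is timed with the monotonic elapsed-time clock;
#' file parsing done by the harness itself is excluded from the timings.
#' An adapter that raises is recorded as a failed run (`status = "failed"`,
#' `NA` recall) rather than aborting the benchmark.
#'
#' @param adapter A [benchmark_adapter()].
#' @param proteome Proteome tibble or path to a FASTA file.
#' @param queries Query tibble or path to a peptide list.
#' @param params List with `mode` (`"exact"`, `"mismatch"`, `"best"`) and
#'   `m` (mismatch mode).
#' @param expected Match tibble or path to an expected-results file.
#' @return One-row tibble: `method`, `proteome_preprocess_s`,
#'   `query_preprocess_s`, `search_s`, `total_s`, `recall_pct`, `status`.
#' @export
run_benchmark <- function(adapter, proteome, queries, params, expected) {
  stopifnot(inherits(adapter, "benchmark_adapter"))
  if (is.character(proteome)) proteome <- read_proteome(proteome)
  if (is.character(queries)) queries <- read_peptides(queries)
  if (is.character(expected)) expected <- read_results(expected)
  params$query_lengths <- nchar(queries$sequence)

  clock <- function() proc.time()[["elapsed"]]
  state <- list()
  t_prot <- NA_real_; t_query <- NA_real_; t_search <- NA_real_
  result <- tryCatch({
    if (!is.null(adapter$preprocess_proteome)) {
      t0 <- clock()
      state$proteome <- adapter$preprocess_proteome(proteome, params)
      t_prot <- clock() - t0
    }
    if (!is.null(adapter$preprocess_query)) {
      t0 <- clock()
      state$query <- adapter$preprocess_query(queries, params)
      t_query <- clock() - t0
    }
    t0 <- clock()
    reported <- adapter$search(proteome, queries, params, state)
    t_search <- clock() - t0
    list(recall = compare_results(reported, expected), status = "ok")
  }, error = function(e) list(recall = NA_real_, status = "failed"))

  tibble::tibble(
    method = adapter$name,
    proteome_preprocess_s = t_prot,
    query_preprocess_s = t_query,
    search_s = t_search,
    total_s = sum(c(t_prot, t_query, t_search), na.rm = TRUE),
    recall_pct = result$recall,
    status = result$status
  )
}
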