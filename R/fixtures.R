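# Synthetic proteome / peptide generator.  Everything is produced from a
# seed, so every test and benchmark runs from code with no downloads; the
# manifest records where each planted peptide went and at what distance, as
# ground truth for recall checks.

#' Describe a synthetic fixture
#'
#' @param n_proteins Number of random proteins.
#' @param min_len,max_len Protein length range (uniform).
#' @param alphabet Residue alphabet; defaults to the 20 canonical amino
#'   acids with uniform frequencies (keeps spurious-hit probabilities
#'   analytically estimable).
#' @param n_planted Number of planted query peptides.
#' @param planted_lengths Lengths of planted peptides (recycled).
#' @param planted_distances Hamming distances at which planted windows
#'   differ from their query peptide (recycled).
#' @param n_decoys Number of shuffled decoy peptides, re-shuffled until
#'   absent verbatim from the proteome.
#' @param seed Integer seed; the same seed yields a byte-identical fixture.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_proteins = 200L, min_len = 100L, max_len = 500L,
                         alphabet = AA_CANONICAL, n_planted = 20L,
                         planted_lengths = 9L, planted_distances = 0L,
                         n_decoys = 0L, seed = 1L) {
  if (max(planted_lengths) > min_len) {
    abort_kmerpep("planted peptide longer than the shortest protein",
                  "kmerpep_invalid_parameter")
  }
  structure(list(
    n_proteins = as.integer(n_proteins), min_len = as.integer(min_len),
    max_len = as.integer(max_len), alphabet = alphabet,
    n_planted = as.integer(n_planted),
    planted_lengths = as.integer(planted_lengths),
    planted_distances = as.integer(planted_distances),
    n_decoys = as.integer(n_decoys), seed = as.integer(seed)
  ), class = "fixture_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_peptide <- function(l, alphabet) {
  paste(sample(alphabet, l, replace = TRUE), collapse = "")
}

# substitute exactly d residues at distinct positions, never to the same
# residue, so the mutated window is at Hamming distance exactly d
mutate_peptide <- function(pep, d, alphabet) {
  if (d == 0) return(pep)
  chars <- strsplit(pep, "")[[1]]
  pos <- sample(length(chars), d)
  for (p in pos) {
    chars[p] <- sample(setdiff(alphabet, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic proteome with planted peptides and decoys
#'
#' Random proteins are drawn from the spec's alphabet; each planted query
#' peptide is embedded by overwriting a non-overlapping window with a copy
#' mutated at exactly the requested Hamming distance.  Decoys are residue
#' shuffles of fresh random peptides, re-shuffled (or redrawn) until absent
#' verbatim from the proteome.
#'
#' @param spec A [fixture_spec()].
#' @return A list with `proteome` (tibble), `queries` (planted peptides as
#'   a query tibble), `decoys` (query tibble) and `manifest` (tibble of
#'   query_id, sequence, planted_sequence, accession, start, distance).
#' @export
make_proteome <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    lens <- sample(spec$min_len:spec$max_len, spec$n_proteins, replace = TRUE)
    seqs <- vapply(lens, random_peptide, character(1), alphabet = spec$alphabet)
    acc <- sprintf("SYN%04d", seq_len(spec$n_proteins))
    proteome <- tibble::tibble(
      accession = acc,
      name = sprintf("Synthetic protein %d", seq_len(spec$n_proteins)),
      gene = sprintf("SYNG%d", seq_len(spec$n_proteins)),
      species = "synthetic construct",
      taxon_id = 32630L,
      existence_level = 5L,
      sequence = seqs
    )

    manifest <- NULL
    if (spec$n_planted > 0) {
      pls <- rep_len(spec$planted_lengths, spec$n_planted)
      pds <- rep_len(spec$planted_distances, spec$n_planted)
      used <- vector("list", spec$n_proteins)  # occupied intervals per protein
      rows <- vector("list", spec$n_planted)
      for (i in seq_len(spec$n_planted)) {
        l <- pls[i]; d <- pds[i]
        pep <- random_peptide(l, spec$alphabet)
        win <- mutate_peptide(pep, d, spec$alphabet)
        placed <- FALSE
        for (try in 1:200) {
          p <- sample(spec$n_proteins, 1)
          if (lens[p] < l) next
          s0 <- sample(0:(lens[p] - l), 1)
          overlaps <- any(vapply(used[[p]], function(iv) {
            s0 < iv[2] && iv[1] < s0 + l
          }, logical(1)))
          if (overlaps) next
          substr(proteome$sequence[p], s0 + 1L, s0 + l) <- win
          used[[p]] <- c(used[[p]], list(c(s0, s0 + l)))
          rows[[i]] <- tibble::tibble(
            query_id = sprintf("plant%03d", i), sequence = pep,
            planted_sequence = win, accession = acc[p],
            start = as.integer(s0), distance = as.integer(d))
          placed <- TRUE
          break
        }
        if (!placed) {
          abort_kmerpep("could not place a planted peptide without overlap",
                        "kmerpep_invalid_parameter")
        }
      }
      manifest <- do.call(rbind, rows)
    } else {
      manifest <- tibble::tibble(query_id = character(), sequence = character(),
                                 planted_sequence = character(),
                                 accession = character(), start = integer(),
                                 distance = integer())
    }

    decoys <- tibble::tibble(query_id = character(), sequence = character())
    if (spec$n_decoys > 0) {
      # "#" separators prevent false containment across protein boundaries
      blob <- paste(proteome$sequence, collapse = "#")
      dseq <- character(spec$n_decoys)
      for (i in seq_len(spec$n_decoys)) {
        # decoys are residue shuffles of the planted peptides (or of fresh
        # random peptides when nothing was planted)
        base <- if (nrow(manifest) > 0) {
          manifest$sequence[(i - 1L) %% nrow(manifest) + 1L]
        } else {
          random_peptide(rep_len(spec$planted_lengths, spec$n_decoys)[i],
                         spec$alphabet)
        }
        cand <- paste(sample(strsplit(base, "")[[1]]), collapse = "")
        while (grepl(cand, blob, fixed = TRUE)) {
          cand <- paste(sample(strsplit(cand, "")[[1]]), collapse = "")
        }
        dseq[i] <- cand
      }
      decoys <- tibble::tibble(query_id = sprintf("decoy%03d", seq_len(spec$n_decoys)),
                               sequence = dseq)
    }

    list(
      proteome = proteome,
      queries = manifest[, c("query_id", "sequence")],
      decoys = decoys,
      manifest = manifest
    )
  })
}

#' Generate a complete benchmark dataset on disk
#'
#' Writes a drop-in benchmark instance: `proteome.fasta`, `peptides.txt`
#' and `expected.csv`, where the expected output is produced by the
#' brute-force oracle for the task's mode.  The three kinds mirror common
#' study designs: `exact` plants peptides verbatim alongside shuffled
#' decoys (MHC-ligand style), `mismatch` plants mixed-length peptides
#' (8-15) searched at m = 2 (viral-variant style), and `best` plants
#' 15-mers at distances 0-6 (allergen cross-reactivity style).
#'
#' @param kind One of `"exact"`, `"mismatch"`, `"best"`.
#' @param scale `"small"` (the default benchmark size) or `"tiny"` (quick
#'   smoke tests).
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return A list with the three file paths, the mode, `m`, and the fixture
#'   manifest.
#' @export
make_benchmark_dataset <- function(kind = c("exact", "mismatch", "best"),
                                   scale = c("small", "tiny"),
                                   dir = tempfile("benchmark"), seed = 1L) {
  kind <- match.arg(kind)
  scale <- match.arg(scale)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  np <- if (scale == "small") 200L else 20L
  n <- if (scale == "small") 100L else 10L

  spec <- switch(kind,
    exact = fixture_spec(n_proteins = np, n_planted = n, planted_lengths = 9L,
                         planted_distances = 0L, n_decoys = n, seed = seed),
    mismatch = fixture_spec(n_proteins = np, n_planted = n,
                            planted_lengths = 8:15, planted_distances = 0:2,
                            seed = seed),
    best = fixture_spec(n_proteins = np, n_planted = n, planted_lengths = 15L,
                        planted_distances = 0:6, seed = seed)
  )
  fx <- make_proteome(spec)
  queries <- rbind(fx$queries, fx$decoys)

  proteome_path <- file.path(dir, "proteome.fasta")
  peptides_path <- file.path(dir, "peptides.txt")
  expected_path <- file.path(dir, "expected.csv")
  write_proteome(fx$proteome, proteome_path)
  con <- file(peptides_path, open = "wb")
  writeLines(paste(queries$query_id, queries$sequence, sep = "\t"), con)
  close(con)

  m <- switch(kind, exact = 0L, mismatch = 2L, best = NA_integer_)
  expected <- switch(kind,
    exact = brute_exact(fx$proteome, queries),
    mismatch = brute_hamming(fx$proteome, queries, m),
    best = brute_best(fx$proteome, queries)
  )
  write_results(expected, expected_path, "csv")

  list(proteome = proteome_path, peptides = peptides_path,
       expected = expected_path, mode = kind, m = m, manifest = fx$manifest)
}
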