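# K-mer -> position index over a concatenated-coordinate proteome.
#
# Coordinates: a single 0-based global offset over the concatenation of all
# protein sequences in file order.  K-mers are generated per protein and
# shifted by the protein's global start, so no indexed k-mer ever spans a
# protein boundary.

INDEX_MAGIC <- "KMERPEP-INDEX"
INDEX_VERSION <- 1L

proteome_checksum <- function(proteome) {
  # digest of the concatenated sequences in file order; a rebuilt index on
  # the same FASTA is recognized as current regardless of header edits
  tmp <- tempfile()
  on.exit(unlink(tmp))
  con <- file(tmp, open = "wb")
  writeLines(paste(proteome$sequence, collapse = ""), con)
  close(con)
  unname(tools::md5sum(tmp))
}

validate_proteome <- function(proteome) {
  if (!is.data.frame(proteome) || nrow(proteome) == 0) {
    abort_kmerpep("proteome must be a nonempty record table",
                  "kmerpep_invalid_input")
  }
  if (anyDuplicated(proteome$accession)) {
    abort_kmerpep("duplicate accessions in proteome", "kmerpep_invalid_input")
  }
  if (any(nchar(proteome$sequence) < 1)) {
    abort_kmerpep("empty protein sequence in proteome", "kmerpep_invalid_input")
  }
  invisible(proteome)
}

#' Build a k-mer index over a proteome
#'
#' Breaks every protein into all overlapping k-mers and stores each k-mer's
#' global start offsets in a hash map.  This preprocessing is done once per
#' proteome and per k; subsequent queries are hash lookups.  Proteins
#' shorter than `k` contribute no k-mers but remain in the record table.
#'
#' @param proteome A proteome tibble (see [read_proteome()]).
#' @param k K-mer size, a single integer >= 1.
#' @return A `proteome_index` object.
#' @examples
#' prot <- tibble::tibble(accession = "P1", name = "", gene = "",
#'                        species = "", taxon_id = NA_integer_,
#'                        existence_level = NA_integer_, sequence = "YLLDLHSYL")
#' idx <- build_index(prot, k = 5)
#' kmer_lookup(idx, "YLLDL")  # 0
#' @export
build_index <- function(proteome, k) {
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1 || k != as.integer(k)) {
    abort_kmerpep("k must be a single integer >= 1", "kmerpep_invalid_parameter")
  }
  k <- as.integer(k)
  validate_proteome(proteome)

  lens <- nchar(proteome$sequence)
  starts <- c(0L, cumsum(lens))[seq_along(lens)]  # 0-based global starts

  kmers <- vector("list", nrow(proteome))
  offs <- vector("list", nrow(proteome))
  for (i in seq_len(nrow(proteome))) {
    L <- lens[i]
    if (L < k) next
    n <- L - k + 1L
    kmers[[i]] <- substring(proteome$sequence[i], 1:n, k:L)
    offs[[i]] <- starts[i] + 0:(n - 1L)
  }
  # key-value map as parallel vectors: keys are the distinct k-mers, pos the
  # ascending global offsets of each; lookups go through match(), batched
  # per search call (a hashed environment would intern every k-mer as a
  # permanent symbol, which does not scale across many proteomes)
  kmer_map <- split(as.integer(unlist(offs)), unlist(kmers))

  structure(
    list(
      k = k,
      keys = names(kmer_map),
      pos = unname(kmer_map),
      starts = starts,
      lengths = lens,
      total = sum(lens),
      records = proteome,
      residues = utf8ToInt(paste(proteome$sequence, collapse = "")),
      checksum = proteome_checksum(proteome)
    ),
    class = "proteome_index"
  )
}

#' @export
print.proteome_index <- function(x, ...) {
  cat(sprintf("proteome_index: k=%d, %d proteins, %d residues, %d distinct k-mers\n",
              x$k, nrow(x$records), x$total, length(x$keys)))
  invisible(x)
}

#' The distinct k-mers stored in an index
#'
#' @param index A `proteome_index`.
#' @return Character vector of all indexed k-mer strings.
#' @export
index_keys <- function(index) index$keys

#' Look up a k-mer in the index
#'
#' @param index A `proteome_index`.
#' @param kmer A string of length `index$k`.
#' @return Sorted integer vector of 0-based global offsets where the k-mer
#'   occurs within a single protein; `integer(0)` when absent.
#' @export
kmer_lookup <- function(index, kmer) {
  if (!is.character(kmer) || length(kmer) != 1 || nchar(kmer) != index$k) {
    abort_kmerpep(sprintf("k-mer must be a single string of length k = %d", index$k),
                  "kmerpep_invalid_parameter")
  }
  i <- match(kmer, index$keys)
  if (is.na(i)) integer(0) else index$pos[[i]]
}

# batched lookup: one match() over the key table for a whole k-mer vector
kmer_lookup_many <- function(index, kmers) {
  i <- match(kmers, index$keys)
  out <- vector("list", length(kmers))
  hit <- !is.na(i)
  out[hit] <- index$pos[i[hit]]
  out[!hit] <- list(integer(0))
  out
}

#' Map global offsets back to protein coordinates
#'
#' @param index A `proteome_index`.
#' @param g Vector of 0-based global offsets.
#' @return A tibble with columns `accession` and `local_start` (0-based
#'   offset within the protein).
#' @export
to_protein_coords <- function(index, g) {
  if (any(g < 0 | g >= index$total)) {
    abort_kmerpep("global offset out of range", "kmerpep_range_error")
  }
  i <- findInterval(g, index$starts)
  tibble::tibble(
    accession = index$records$accession[i],
    local_start = as.integer(g - index$starts[i])
  )
}

# protein ordinal containing each global offset (internal)
protein_ordinal <- function(index, g) findInterval(g, index$starts)

#' Persist an index to disk
#'
#' The on-disk artifact is a versioned container recording the format
#' magic, version, `k` and the proteome checksum alongside the payload, so
#' a stale or foreign file is recognized at load time.
#'
#' @param index A `proteome_index`.
#' @param path Output path.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "proteome_index"))
  container <- list(
    magic = INDEX_MAGIC,
    version = INDEX_VERSION,
    k = index$k,
    checksum = index$checksum,
    payload = index
  )
  ok <- tryCatch({ saveRDS(container, path); TRUE }, error = function(e) FALSE)
  if (!ok) abort_kmerpep(sprintf("cannot write index to '%s'", path),
                         "kmerpep_io_error")
  invisible(path)
}

#' Load a persisted index
#'
#' When `k` or `proteome` is supplied the stored artifact is verified
#' against them: a mismatching k or proteome checksum raises a stale-index
#' error rather than silently answering queries for the wrong data.
#'
#' @param path Path written by [save_index()].
#' @param k Optional expected k-mer size.
#' @param proteome Optional proteome tibble to verify the checksum against.
#' @return A `proteome_index`.
#' @export
load_index <- function(path, k = NULL, proteome = NULL) {
  container <- tryCatch(readRDS(path), error = function(e) NULL)
  if (is.null(container) || !is.list(container) ||
      !identical(container$magic, INDEX_MAGIC)) {
    abort_kmerpep(sprintf("'%s' is not a kmerpep index file", path),
                  "kmerpep_format_error")
  }
  if (!identical(container$version, INDEX_VERSION)) {
    abort_kmerpep(sprintf("unsupported index format version: %s",
                          container$version), "kmerpep_format_error")
  }
  if (!is.null(k) && container$k != k) {
    abort_kmerpep(sprintf("stale index: file has k=%d, requested k=%d",
                          container$k, as.integer(k)), "kmerpep_stale_index")
  }
  if (!is.null(proteome) &&
      !identical(container$checksum, proteome_checksum(proteome))) {
    abort_kmerpep("stale index: proteome checksum mismatch",
                  "kmerpep_stale_index")
  }
  container$payload
}

# Per-proteome cache of indexes keyed by k; avoids re-preprocessing when a
# query set spans several lengths or the best-match cascade reuses a k.
new_index_cache <- function(proteome) {
  validate_proteome(proteome)
  structure(
    list(proteome = proteome,
         store = new.env(hash = TRUE, parent = emptyenv())),
    class = "index_cache"
  )
}

cache_get_index <- function(cache, k) {
  key <- as.character(k)
  idx <- get0(key, envir = cache$store, ifnotfound = NULL)
  if (is.null(idx)) {
    idx <- build_index(cache$proteome, k)
    assign(key, idx, envir = cache$store)
  }
  idx
}
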