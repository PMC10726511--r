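# FASTA / peptide-list input and tabular result output.

# Fixed column order of the result table.  query_id leads so that duplicate
# input peptides stay distinguishable; the remaining columns are the report
# schema (matched sequence, protein ID, name, gene, mismatch bookkeeping,
# then the optional organism/position/evidence columns, emitted empty when
# unknown but never omitted).
RESULT_COLUMNS <- c(
  "query_id", "query_sequence", "matched_sequence", "accession",
  "protein_name", "gene", "mismatch_count", "mismatch_positions",
  "species", "taxon_id", "start", "end", "existence_level"
)

empty_matches <- function() {
  tibble::tibble(
    query_id = character(), query_sequence = character(),
    matched_sequence = character(), accession = character(),
    protein_name = character(), gene = character(),
    mismatch_count = integer(), mismatch_positions = character(),
    species = character(), taxon_id = integer(),
    start = integer(), end = integer(), existence_level = integer()
  )
}

extract_tag <- function(x, tag) {
  # UniProt header tags: value runs until the next "XX=" tag or end of line
  pat <- paste0(tag, "=(.*?)(?= [A-Z]{2}=|$)")
  m <- regmatches(x, regexpr(pat, x, perl = TRUE))
  if (length(m) == 0) "" else sub(paste0(tag, "="), "", m, fixed = TRUE)
}

#' Parse a FASTA header into protein metadata
#'
#' Understands the UniProt dialect
#' `db|ACCESSION|ENTRY Protein name OS=Species OX=taxon GN=gene PE=level`.
#' Any other header falls back to the first whitespace-delimited token as
#' the accession with all other fields empty.
#'
#' @param header Header line without the leading `>`.
#' @return A list with fields `accession`, `name`, `gene`, `species`,
#'   `taxon_id`, `existence_level`.
#' @export
parse_fasta_header <- function(header) {
  header <- trimws(header)
  out <- list(accession = "", name = "", gene = "", species = "",
              taxon_id = NA_integer_, existence_level = NA_integer_)
  if (grepl("^[A-Za-z0-9]+\\|[^|]+\\|", header)) {
    parts <- strsplit(header, "|", fixed = TRUE)[[1]]
    out$accession <- parts[2]
    rest <- paste(parts[-(1:2)], collapse = "|")
    # drop the ENTRY_NAME token; the description runs up to the first tag
    desc <- sub("^\\S+\\s*", "", rest)
    desc <- sub("\\s*[A-Z]{2}=.*$", "", desc)
    out$name <- trimws(desc)
    out$species <- extract_tag(rest, "OS")
    out$gene <- extract_tag(rest, "GN")
    ox <- extract_tag(rest, "OX")
    pe <- extract_tag(rest, "PE")
    out$taxon_id <- if (nzchar(ox)) suppressWarnings(as.integer(ox)) else NA_integer_
    out$existence_level <- if (nzchar(pe)) suppressWarnings(as.integer(pe)) else NA_integer_
  } else {
    out$accession <- strsplit(header, "\\s+")[[1]][1]
  }
  out
}

#' Read a proteome from FASTA
#'
#' Sequences are uppercased and trailing `*` stop characters stripped; any
#' residue outside the 20 canonical amino acids plus `X B Z U O` is a parse
#' error.  Duplicate accessions are rejected.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A tibble with one row per protein: `accession`, `name`, `gene`,
#'   `species`, `taxon_id`, `existence_level`, `sequence`.
#' @export
read_proteome <- function(path) {
  if (!file.exists(path)) {
    abort_kmerpep(sprintf("FASTA file not found: %s", path), "kmerpep_io_error")
  }
  set <- withCallingHandlers(
    tryCatch(
      Biostrings::readAAStringSet(path),
      error = function(e) abort_kmerpep(
        sprintf("malformed FASTA '%s': %s", path, conditionMessage(e)),
        "kmerpep_parse_error")
    ),
    # the reader drops invalid residue codes with a warning; treat as fatal
    warning = function(w) abort_kmerpep(
      sprintf("malformed FASTA '%s': %s", path, conditionMessage(w)),
      "kmerpep_parse_error")
  )
  if (length(set) == 0) {
    abort_kmerpep(sprintf("FASTA '%s' contains no records", path),
                  "kmerpep_invalid_input")
  }
  headers <- names(set)
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*+$", "", seqs)
  meta <- lapply(headers, parse_fasta_header)
  bad <- which(!grepl(AA_REGEX, seqs))
  if (length(bad) > 0) {
    abort_kmerpep(sprintf(
      "record %d (%s): illegal residue character in sequence",
      bad[1], meta[[bad[1]]]$accession), "kmerpep_parse_error")
  }
  acc <- vapply(meta, `[[`, character(1), "accession")
  if (anyDuplicated(acc)) {
    abort_kmerpep(sprintf("duplicate accession in FASTA: %s",
                          acc[duplicated(acc)][1]), "kmerpep_parse_error")
  }
  tibble::tibble(
    accession = acc,
    name = vapply(meta, `[[`, character(1), "name"),
    gene = vapply(meta, `[[`, character(1), "gene"),
    species = vapply(meta, `[[`, character(1), "species"),
    taxon_id = vapply(meta, `[[`, integer(1), "taxon_id"),
    existence_level = vapply(meta, `[[`, integer(1), "existence_level"),
    sequence = unname(seqs)
  )
}

#' Write a proteome tibble to FASTA
#'
#' Records with UniProt-style metadata get a `sp|ACC|ACC` header carrying
#' the `OS=/OX=/GN=/PE=` tags so that a round-trip preserves metadata.
#'
#' @param proteome Tibble as returned by [read_proteome()].
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @export
write_proteome <- function(proteome, path, width = 60L) {
  hdr <- vapply(seq_len(nrow(proteome)), function(i) {
    r <- proteome[i, ]
    tags <- character(0)
    if (nzchar(r$species)) tags <- c(tags, paste0("OS=", r$species))
    if (!is.na(r$taxon_id)) tags <- c(tags, paste0("OX=", r$taxon_id))
    if (nzchar(r$gene)) tags <- c(tags, paste0("GN=", r$gene))
    if (!is.na(r$existence_level)) tags <- c(tags, paste0("PE=", r$existence_level))
    if (nzchar(r$name) || length(tags) > 0) {
      paste0(">sp|", r$accession, "|", r$accession,
             if (nzchar(r$name)) paste0(" ", r$name) else "",
             if (length(tags) > 0) paste0(" ", paste(tags, collapse = " ")) else "")
    } else {
      paste0(">", r$accession)
    }
  }, character(1))
  con <- file(path, open = "wb")  # "wb": fixed \n line endings on all platforms
  on.exit(close(con))
  for (i in seq_len(nrow(proteome))) {
    writeLines(hdr[i], con)
    s <- proteome$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read query peptides
#'
#' Accepts either FASTA or plain text with one peptide per line, optionally
#' `id<TAB>sequence`.  Missing ids are auto-generated `q1...qn`.  CRLF line
#' endings and trailing blank lines are tolerated.
#'
#' @param path Path to the peptide list.
#' @return A tibble with columns `query_id` and `sequence`, in input order.
#' @export
read_peptides <- function(path) {
  if (!file.exists(path)) {
    abort_kmerpep(sprintf("peptide file not found: %s", path), "kmerpep_io_error")
  }
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  nonempty <- lines[nzchar(trimws(lines))]
  if (length(nonempty) == 0) {
    abort_kmerpep(sprintf("peptide file '%s' is empty", path),
                  "kmerpep_invalid_input")
  }
  if (startsWith(nonempty[1], ">")) {
    set <- Biostrings::readAAStringSet(path)
    ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1)
    qs <- tibble::tibble(query_id = ids, sequence = toupper(as.character(set)))
  } else {
    has_tab <- grepl("\t", nonempty)
    ids <- ifelse(has_tab, vapply(strsplit(nonempty, "\t"), `[[`, character(1), 1), "")
    seqs <- ifelse(has_tab,
                   vapply(strsplit(nonempty, "\t"), function(x) x[2], character(1)),
                   nonempty)
    ids[!nzchar(ids)] <- paste0("q", which(!nzchar(ids)))
    qs <- tibble::tibble(query_id = ids, sequence = toupper(trimws(seqs)))
  }
  bad <- which(!grepl(AA_REGEX, qs$sequence))
  if (length(bad) > 0) {
    abort_kmerpep(sprintf("peptide %d ('%s'): illegal residue character",
                          bad[1], qs$sequence[bad[1]]), "kmerpep_parse_error")
  }
  short <- which(nchar(qs$sequence) < 2)
  if (length(short) > 0) {
    abort_kmerpep(sprintf("peptide %d is shorter than 2 residues", short[1]),
                  "kmerpep_invalid_input")
  }
  qs
}

#' Write search results
#'
#' Serializes a match table to CSV (default), TSV or JSON with a fixed
#' column order.  `start`/`end` are written 1-based inclusive within the
#' protein (internal coordinates are 0-based); `mismatch_positions` is a
#' semicolon-joined list of 1-based peptide positions.  Output bytes are
#' deterministic for identical input.
#'
#' @param matches Match tibble as returned by the search functions.
#' @param path Output path.
#' @param format One of `"csv"`, `"tsv"`, `"json"`.
#' @export
write_results <- function(matches, path, format = c("csv", "tsv", "json")) {
  format <- match.arg(format)
  out <- as.data.frame(matches[, RESULT_COLUMNS], stringsAsFactors = FALSE)
  out$start <- out$start + 1L
  out$end <- out$end + 1L
  ok <- tryCatch({
    if (format == "json") {
      jsonlite::write_json(out, path, dataframe = "rows", na = "null",
                           auto_unbox = TRUE, digits = NA)
    } else {
      sep <- if (format == "csv") "," else "\t"
      con <- file(path, open = "wb")
      on.exit(close(con))
      utils::write.table(out, con, sep = sep, row.names = FALSE,
                         quote = TRUE, qmethod = "double", na = "", eol = "\n")
    }
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    abort_kmerpep(sprintf("cannot write results to '%s'", path), "kmerpep_io_error")
  }
  invisible(path)
}

#' Read back a results file written by [write_results()]
#'
#' Restores internal 0-based coordinates and column types, so a
#' write -> read round-trip reconstructs the original match rows.
#'
#' @param path Path to a results file.
#' @param format File format; inferred from the extension by default.
#' @return A match tibble.
#' @export
read_results <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     tsv = "tsv", json = "json", "csv")
  }
  if (format == "json") {
    df <- jsonlite::fromJSON(path)
    if (length(df) == 0 || nrow(df) == 0) return(empty_matches())
    df <- as.data.frame(df, stringsAsFactors = FALSE)
  } else {
    sep <- if (format == "tsv") "\t" else ","
    df <- utils::read.table(path, sep = sep, header = TRUE, quote = "\"",
                            colClasses = "character", na.strings = NULL)
    if (nrow(df) == 0) return(empty_matches())
  }
  for (col in c("query_id", "query_sequence", "matched_sequence", "accession",
                "protein_name", "gene", "mismatch_positions", "species")) {
    v <- as.character(df[[col]])
    v[is.na(v)] <- ""
    df[[col]] <- v
  }
  for (col in c("mismatch_count", "taxon_id", "start", "end", "existence_level")) {
    v <- df[[col]]
    v[!nzchar(as.character(v)) | is.na(v)] <- NA
    df[[col]] <- suppressWarnings(as.integer(v))
  }
  df$start <- df$start - 1L
  df$end <- df$end - 1L
  tibble::as_tibble(df[, RESULT_COLUMNS])
}
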