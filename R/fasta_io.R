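#' Open a multi-FASTA alignment as a text stream
#'
#' Opens a plain-text or gzip-compressed file for sequential reading.
#' Compression is detected from the gzip magic bytes (`0x1f 0x8b`), never
#' from the file extension, so misnamed files are handled correctly. The
#' returned connection supports one sequential read; re-open (call again)
#' for a second pass.
#'
#' @param path Path to a multi-FASTA alignment, plain or gzipped.
#' @return An open read-mode text connection.
#' @examples
#' aln <- system.file("extdata", "example_alignment.fa", package = "polysites")
#' con <- open_alignment_stream(aln)
#' readLines(con, n = 2)
#' close(con)
#' @export
open_alignment_stream <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("alignment file not found: ", path, call. = FALSE)
  if (is_gzip_file(path)) gzfile(path, "rt") else file(path, "rt")
}

# gzip magic-byte sniff; a file shorter than two bytes is not gzip
is_gzip_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1L] == as.raw(0x1f) && magic[2L] == as.raw(0x8b)
}

# readLines with gzip-corruption warnings promoted to errors, so a
# truncated compressed stream is always a fatal, named failure
read_stream_lines <- function(con, n) {
  withCallingHandlers(
    readLines(con, n = n),
    warning = function(w) {
      if (grepl("compressed data", conditionMessage(w), fixed = TRUE))
        stop("cannot decompress input: ", conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    }
  )
}

#' Stream the records of a multi-FASTA alignment
#'
#' Reads an alignment record by record, calling `on_record(id, sequence,
#' index)` for each, so memory use is bounded by one record regardless of
#' how many sequences the file holds. Sequence lines are concatenated with
#' all line breaks removed; the record id is the header text after `>` up
#' to the first whitespace. Blank lines and Windows line endings are
#' tolerated; duplicate ids raise a warning (output is positional, so they
#' are not fatal).
#'
#' @param path Path to a plain or gzipped multi-FASTA file.
#' @param on_record Callback `function(id, sequence, index)`; its return
#'   value is discarded.
#' @param chunk_lines Number of lines fetched per read from the connection.
#' @return Invisibly, a list with `n_records` and `bytes_read` (line bytes
#'   plus one newline per line, i.e. the on-disk size of a plain file that
#'   ends in a newline).
#' @export
stream_alignment <- function(path, on_record, chunk_lines = 512L) {
  con <- open_alignment_stream(path)
  on.exit(close(con))

  bytes <- 0
  idx <- 0L
  id <- NULL
  parts <- list()
  ids_seen <- character()
  saw_any <- FALSE

  flush_record <- function() {
    if (is.null(id)) return(invisible())
    seq <- paste0(unlist(parts), collapse = "")
    if (!nzchar(seq))
      stop("malformed FASTA: record '", id, "' has an empty sequence",
           call. = FALSE)
    idx <<- idx + 1L
    on_record(id, seq, idx)
    invisible()
  }

  repeat {
    lines <- read_stream_lines(con, n = chunk_lines)
    if (length(lines) == 0L) break
    bytes <- bytes + sum(nchar(lines, type = "bytes")) + length(lines)
    cr <- endsWith(lines, "\r")
    if (any(cr)) lines[cr] <- substr(lines[cr], 1L, nchar(lines[cr]) - 1L)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      if (startsWith(ln, ">")) {
        flush_record()
        id <- sub("^>\\s*(\\S*).*$", "\\1", ln)
        if (!nzchar(id))
          stop("malformed FASTA: header with empty id", call. = FALSE)
        if (id %in% ids_seen)
          warning("duplicate sample id '", id, "' in alignment", call. = FALSE)
        ids_seen <- c(ids_seen, id)
        parts <- list()
        saw_any <- TRUE
      } else {
        if (!saw_any)
          stop("malformed FASTA: first non-blank line must start with '>'",
               call. = FALSE)
        parts[[length(parts) + 1L]] <- ln
      }
    }
  }
  flush_record()
  if (!saw_any)
    stop("malformed FASTA: no records found in ", path, call. = FALSE)
  invisible(list(n_records = idx, bytes_read = bytes))
}

#' Read a whole alignment into memory
#'
#' Convenience wrapper around [stream_alignment()] for small alignments;
#' validates that all sequences share one length.
#'
#' @param path Path to a plain or gzipped multi-FASTA file.
#' @return A list with `ids` (character), `seqs` (character), `s` and `g`.
#' @examples
#' aln <- system.file("extdata", "example_alignment.fa", package = "polysites")
#' read_alignment(aln)
#' @export
read_alignment <- function(path) {
  ids <- character()
  seqs <- character()
  stream_alignment(path, function(id, seq, i) {
    ids[i] <<- id
    seqs[i] <<- seq
  })
  dims <- validate_alignment(seqs, ids)
  list(ids = ids, seqs = seqs, s = dims$s, g = dims$g)
}

#' Validate that records form a proper alignment
#'
#' Checks that there is at least one record and that every sequence has the
#' same length, returning the alignment dimensions.
#'
#' @param seqs Character vector of sequences.
#' @param ids Optional ids, used to name the offending record in errors.
#' @return A list with `s` (number of samples) and `g` (alignment columns).
#' @export
validate_alignment <- function(seqs, ids = NULL) {
  if (length(seqs) < 1L)
    stop("alignment must contain at least one record", call. = FALSE)
  lens <- nchar(seqs, type = "chars")
  if (any(lens != lens[1L])) {
    bad <- which(lens != lens[1L])[1L]
    nm <- if (is.null(ids)) paste0("#", bad) else ids[bad]
    stop("unequal sequence lengths: record '", nm, "' has ", lens[bad],
         " columns, expected ", lens[1L], call. = FALSE)
  }
  list(s = length(seqs), g = lens[1L])
}
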