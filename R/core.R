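#' Classify an alignment character as informative or missing
#'
#' The missing-data rule: gaps and unknown bases -- `n`, `N`, `?`, `-` --
#' are regarded as non-variant. Every other character, including lowercase
#' nucleotides and IUPAC ambiguity codes other than N (R, Y, S, W, K, M, B,
#' D, H, V), counts as an informative allele. Comparison is
#' case-insensitive.
#'
#' @param x Character vector of single characters.
#' @return Character vector, `"informative"` or `"missing"` per element.
#' @examples
#' classify_base(c("A", "n", "?", "-", "R"))
#' @export
classify_base <- function(x) {
  ifelse(toupper(x) %in% c("N", "?", "-"), "missing", "informative")
}

#' Informative alleles present in one alignment column
#'
#' Uppercase-folds the column, drops the missing characters, and returns
#' the distinct alleles in order of first appearance down the column.
#'
#' @param column Character vector: the `s` characters of one column.
#' @return Character vector of distinct informative alleles (possibly empty).
#' @examples
#' column_alleles(c("-", "A", "a", "G"))
#' @export
column_alleles <- function(column) {
  fold <- toupper(column)
  unique(fold[!fold %in% c("N", "?", "-")])
}

#' Is an alignment column a variant (SNP) site?
#'
#' A column is polymorphic when it carries at least two distinct
#' informative alleles. A column holding one allele plus any mixture of
#' gaps or unknowns is monomorphic, as is an all-missing column.
#'
#' @param column Character vector: the `s` characters of one column.
#' @return `TRUE` if the column is a variant site.
#' @examples
#' is_variant_site(c("G", "G", "A"))  # TRUE
#' is_variant_site(c("-", "A", "A"))  # FALSE: gaps are non-variant
#' @export
is_variant_site <- function(column) {
  length(column_alleles(column)) >= 2L
}

#' Reference allele for a variant column
#'
#' The uppercase-folded character of the first record if informative,
#' otherwise the first informative character in record order. A variant
#' column always has one, so the result is always informative. Used as the
#' VCF REF allele.
#'
#' @param column Character vector: the `s` characters of one column.
#' @return Single uppercase informative character.
#' @export
reference_allele_for_site <- function(column) {
  fold <- toupper(column)
  inf <- !fold %in% c("N", "?", "-")
  if (!any(inf))
    stop("column has no informative allele", call. = FALSE)
  fold[which(inf)[1L]]
}

#' Brute-force per-column variant scan
#'
#' Declarative reference implementation: materializes every column of an
#' in-memory alignment and applies [is_variant_site()] to each. Quadratic
#' in care and linear in memory -- intended for small alignments and as a
#' cross-check of the streaming scanner, which must agree with it exactly.
#'
#' @param seqs Character vector of equal-length sequences.
#' @return Integer vector of 0-based variant column indices.
#' @export
variant_sites_bruteforce <- function(seqs) {
  dims <- validate_alignment(seqs)
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  nrow = dims$s, byrow = TRUE)
  which(apply(chars, 2L, is_variant_site)) - 1L
}

#' First pass: find variant sites by streaming consensus
#'
#' Reads the alignment once, maintaining one consensus character and one
#' variant flag per column (2 x g bytes of working storage). Each column's
#' consensus is set to the first informative base observed; the column is
#' flagged variant the first time a differing informative base appears.
#' This streaming procedure provably returns exactly the columns satisfying
#' [is_variant_site()].
#'
#' @param path Path to a plain or gzipped multi-FASTA alignment.
#' @return An object of class `variant_scan`: a list with `sites` (0-based
#'   integer indices, strictly increasing), `p`, `s`, `g`, `consensus`,
#'   `bytes_read`, and `aux_chars` (measured first-pass working storage).
#' @examples
#' aln <- system.file("extdata", "example_alignment.fa", package = "polysites")
#' find_variant_sites(aln)
#' @export
find_variant_sites <- function(path) {
  scan <- NULL
  g <- NULL
  ids <- character()
  io <- stream_alignment(path, function(id, seq, i) {
    if (is.null(g)) {
      g <<- nchar(seq, type = "bytes")
      if (g < 1L)
        stop("malformed FASTA: record '", id, "' has an empty sequence",
             call. = FALSE)
      scan <<- .scan_new(g)
    } else if (nchar(seq, type = "bytes") != g) {
      stop("unequal sequence lengths: record '", id, "' has ",
           nchar(seq), " columns, expected ", g, call. = FALSE)
    }
    .scan_add(scan, seq)
    ids[i] <<- id
  })
  structure(
    list(sites = .scan_sites(scan),
         p = length(.scan_sites(scan)),
         s = io$n_records,
         g = as.integer(g),
         ids = ids,
         consensus = .scan_consensus(scan),
         bytes_read = io$bytes_read,
         aux_chars = .scan_aux_chars(scan)),
    class = "variant_scan")
}

#' @export
print.variant_scan <- function(x, ...) {
  cat("Variant scan: s =", x$s, "samples, g =", x$g,
      "columns, p =", x$p, "variant sites\n")
  invisible(x)
}

#' Second pass: extract the variant columns
#'
#' Re-reads the alignment and pulls out the characters at the given sites
#' for every sample, preserving original case, gaps and unknowns verbatim.
#' Working storage is the p x s result itself. The source is re-validated
#' against the first pass: a changed record count or alignment length is a
#' fatal inconsistency.
#'
#' @param path Path to the same alignment the scan was computed from.
#' @param scan A `variant_scan` from [find_variant_sites()], or a bare
#'   integer vector of 0-based sites (then no consistency check is done).
#' @return An object of class `snp_matrix`: list with `ids`, `rows`
#'   (character vector, one string of length p per sample), `sites`
#'   (0-based), `s`, `g`, `p`, `bytes_read`, `aux_chars`.
#' @examples
#' aln <- system.file("extdata", "example_alignment.fa", package = "polysites")
#' scan <- find_variant_sites(aln)
#' extract_snp_matrix(aln, scan)
#' @export
extract_snp_matrix <- function(path, scan) {
  if (inherits(scan, "variant_scan")) {
    sites <- scan$sites
    expect_s <- scan$s
    expect_g <- scan$g
  } else {
    sites <- as.integer(scan)
    expect_s <- NA_integer_
    expect_g <- NA_integer_
  }
  ids <- character()
  rows <- character()
  io <- stream_alignment(path, function(id, seq, i) {
    if (!is.na(expect_g) && nchar(seq, type = "bytes") != expect_g)
      stop("input changed between passes: record '", id, "' now has ",
           nchar(seq), " columns, expected ", expect_g, call. = FALSE)
    ids[i] <<- id
    rows[i] <<- .extract_at(seq, sites)
  })
  if (!is.na(expect_s) && io$n_records != expect_s)
    stop("input changed between passes: ", io$n_records,
         " records found, expected ", expect_s, call. = FALSE)
  structure(
    list(ids = ids, rows = rows, sites = sites,
         s = length(ids), g = expect_g, p = length(sites),
         bytes_read = io$bytes_read,
         aux_chars = sum(nchar(rows, type = "bytes"))),
    class = "snp_matrix")
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat("SNP matrix:", x$s, "samples x", x$p, "variant sites\n")
  n <- min(x$s, 6L)
  for (i in seq_len(n))
    cat(" ", x$ids[i], " ",
        if (x$p > 20L) paste0(substr(x$rows[i], 1L, 20L), "...") else x$rows[i],
        "\n", sep = "")
  if (x$s > n) cat("  ... and", x$s - n, "more\n")
  invisible(x)
}

# per-site columns of a snp_matrix: p x s character matrix
snp_matrix_columns <- function(m) {
  if (m$p == 0L)
    return(matrix(character(), nrow = 0L, ncol = m$s))
  chars <- matrix(unlist(strsplit(m$rows, "", fixed = TRUE), use.names = FALSE),
                  nrow = m$p, ncol = m$s)
  chars  # column j of the alignment site i is chars[i, ]
}
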