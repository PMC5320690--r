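# open a writable text sink; NULL or "-" means standard output
open_sink <- function(path) {
  if (is.null(path) || identical(path, "-"))
    return(list(con = stdout(), close = FALSE))
  con <- if (is.character(path)) {
    if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  } else path
  list(con = con, close = is.character(path))
}

#' Write a SNP matrix as multi-FASTA
#'
#' One record per sample in input order, ids unchanged, the extracted
#' variant columns on a single unwrapped line. Byte-exact layout:
#' `>` + id + newline + row + newline.
#'
#' @param m An `snp_matrix` from [extract_snp_matrix()].
#' @param path Output file path, `"-"`/`NULL` for standard output, or an
#'   open connection.
#' @return Invisibly, the number of bytes written.
#' @export
write_snp_fasta <- function(m, path = NULL) {
  sink <- open_sink(path)
  if (sink$close) on.exit(close(sink$con))
  lines <- as.vector(rbind(paste0(">", m$ids), m$rows))
  writeLines(lines, sink$con, sep = "\n")
  invisible(sum(nchar(lines, type = "bytes")) + length(lines))
}

#' Write a SNP matrix in relaxed sequential PHYLIP format
#'
#' Header line `s p`, then one line per sample: id, a single space, the
#' extracted row. Names are not truncated to ten characters (the relaxed
#' dialect accepted by RAxML); ids containing whitespace would corrupt the
#' format and are a fatal error.
#'
#' @inheritParams write_snp_fasta
#' @return Invisibly, the number of bytes written.
#' @export
write_phylip <- function(m, path = NULL) {
  if (any(grepl("[[:space:]]", m$ids)))
    stop("PHYLIP output requires whitespace-free sample ids; offending id: '",
         m$ids[grepl("[[:space:]]", m$ids)][1L], "'", call. = FALSE)
  sink <- open_sink(path)
  if (sink$close) on.exit(close(sink$con))
  body <- ifelse(nzchar(m$rows), paste(m$ids, m$rows), m$ids)
  lines <- c(paste(m$s, m$p), body)
  writeLines(lines, sink$con, sep = "\n")
  invisible(sum(nchar(lines, type = "bytes")) + length(lines))
}

#' Build VCF site records from a SNP matrix
#'
#' One record per variant site, ascending position (1-based alignment
#' column). REF is chosen by [reference_allele_for_site()]; ALT holds the
#' remaining distinct informative alleles in order of first appearance down
#' the column, with `*` appended when any sample carries a gap at the site.
#' Genotypes are haploid allele indices into `c(REF, ALT)`; samples with an
#' unknown base (`N`/`?`) are no-calls (`NA`).
#'
#' @param m An `snp_matrix` from [extract_snp_matrix()].
#' @param chrom Contig label for the CHROM column; the alignment has a
#'   single unnamed coordinate system, so this defaults to `"1"`.
#' @return List of records, each a list with `chrom`, `pos`, `ref`, `alts`
#'   (character vector) and `gt` (integer vector length s, `NA` = no-call).
#' @export
build_vcf_records <- function(m, chrom = "1") {
  cols <- snp_matrix_columns(m)
  lapply(seq_len(m$p), function(j) {
    column <- cols[j, ]
    fold <- toupper(column)
    inf <- !fold %in% c("N", "?", "-")
    ref <- fold[which(inf)[1L]]
    alts <- setdiff(unique(fold[inf]), ref)
    has_gap <- any(fold == "-")
    if (has_gap) alts <- c(alts, "*")
    alleles <- c(ref, alts)
    gt <- ifelse(fold %in% c("N", "?"), NA_integer_,
                 match(ifelse(fold == "-", "*", fold), alleles) - 1L)
    list(chrom = chrom, pos = m$sites[j] + 1L, ref = ref,
         alts = alts, gt = as.integer(gt))
  })
}

#' Write VCF 4.1
#'
#' Emits a `##fileformat=VCFv4.1` document: meta lines, the `#CHROM`
#' header declaring one genotype column per sample, then one tab-delimited
#' data line per site with placeholder `.` for ID, QUAL, FILTER and INFO
#' and FORMAT `GT` carrying haploid single-index calls (`.` = no-call).
#'
#' @param records List of site records from [build_vcf_records()].
#' @param sample_ids Ordered sample identifiers for the genotype columns.
#' @param path Output file path, `"-"`/`NULL` for standard output, or an
#'   open connection.
#' @return Invisibly, the number of bytes written.
#' @export
write_vcf <- function(records, sample_ids, path = NULL) {
  sink <- open_sink(path)
  if (sink$close) on.exit(close(sink$con))
  header <- c(
    "##fileformat=VCFv4.1",
    paste0("##source=polysites-", as.character(utils::packageVersion("polysites"))),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t"))
  body <- vapply(records, function(r) {
    gt <- ifelse(is.na(r$gt), ".", as.character(r$gt))
    alt <- if (length(r$alts)) paste(r$alts, collapse = ",") else "."
    paste(c(r$chrom, r$pos, ".", r$ref, alt, ".", ".", ".", "GT", gt),
          collapse = "\t")
  }, character(1L))
  lines <- c(header, body)
  writeLines(lines, sink$con, sep = "\n")
  invisible(sum(nchar(lines, type = "bytes")) + length(lines))
}
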