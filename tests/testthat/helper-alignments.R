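# Shared fixtures and an implementation-independent oracle.

worked_example_path <- function() {
  system.file("extdata", "example_alignment.fa", package = "polysites")
}

# the printed input/output of the three-sequence example
worked_example_ids <- c("sample1", "sample2", "sample3")
worked_example_seqs <- c("AG-CACAGTCAC", "AGACAC----AC", "AAACGCATTCAN")
worked_example_rows <- c("GAG", "GA-", "AGT")
worked_example_fasta_out <- ">sample1\nGAG\n>sample2\nGA-\n>sample3\nAGT\n"

write_fasta <- function(ids, seqs, path = tempfile(fileext = ".fa")) {
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

gzip_copy <- function(path, gz = tempfile(fileext = ".fa.gz")) {
  src <- file(path, "rb")
  dst <- gzfile(gz, "wb")
  writeBin(readBin(src, "raw", file.size(path)), dst)
  close(src); close(dst)
  gz
}

# mixed-case alphabet with gaps, unknowns and ambiguity codes
test_alphabet <- c("A", "C", "G", "T", "a", "c", "g", "t",
                   "N", "n", "?", "-", "R", "Y")

random_seqs <- function(s, g, alphabet = test_alphabet) {
  vapply(seq_len(s),
         function(k) paste(sample(alphabet, g, replace = TRUE), collapse = ""),
         character(1L))
}

# Independent oracle for the variant predicate, written from the
# missing-data rule itself: fold case, drop {N, ?, -}, a site is variant
# iff >= 2 distinct characters remain. Shares no code with the package's
# predicate or streaming paths.
oracle_sites <- function(seqs) {
  g <- nchar(seqs[1L])
  chars <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  keep <- vapply(seq_len(g), function(j) {
    col <- chars[, j]
    length(unique(col[!(col %in% c("N", "?", "-"))])) >= 2L
  }, logical(1L))
  which(keep) - 1L
}
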