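test_that("the missing-data rule classifies characters case-insensitively", {
  expect_identical(classify_base(c("N", "n", "?", "-")), rep("missing", 4L))
  expect_identical(classify_base("A"), "informative")
  # IUPAC ambiguity codes other than N are ordinary alleles
  expect_identical(classify_base(c("R", "y", "S", "W", "K", "M",
                                   "B", "D", "H", "V", ".")),
                   rep("informative", 11L))
})

test_that("column_alleles folds case and drops missing characters", {
  expect_identical(column_alleles(c("A", "A", "A")), "A")
  expect_identical(column_alleles(c("-", "A", "A")), "A")
  expect_identical(column_alleles(c("a", "G", "N")), c("A", "G"))
  expect_identical(column_alleles(c("N", "?", "-")), character(0))
})

test_that("a site is variant iff it has two distinct informative alleles", {
  expect_false(is_variant_site(c("A", "A", "A")))
  expect_true(is_variant_site(c("G", "G", "A")))
  expect_false(is_variant_site(c("-", "A", "A")))
  expect_false(is_variant_site(c("N", "?", "-")))    # all-missing column
  expect_true(is_variant_site(c("a", "G", "N")))     # case-folded pair
  expect_true(is_variant_site(c("A", "R", "A")))     # ambiguity code counts
})

test_that("reference allele is the first informative character, folded", {
  expect_identical(reference_allele_for_site(c("G", "G", "A")), "G")
  expect_identical(reference_allele_for_site(c("-", "T", "C")), "T")
  expect_identical(reference_allele_for_site(c("a", "G", "G")), "A")
  expect_error(reference_allele_for_site(c("-", "N", "?")), "no informative")
})

test_that("streaming scan finds the worked-example sites", {
  scan <- find_variant_sites(worked_example_path())
  expect_identical(scan$sites, c(1L, 4L, 7L))
  expect_identical(scan$p, 3L)
  expect_identical(scan$s, 3L)
  expect_identical(scan$g, 12L)
})

test_that("identical or single sequences yield no variant sites", {
  f <- write_fasta(c("a", "b", "c"), rep("ACGTACGT", 3L))
  expect_identical(find_variant_sites(f)$sites, integer(0))
  f1 <- write_fasta("solo", "ACGTNNRY")
  expect_identical(find_variant_sites(f1)$sites, integer(0))
})

test_that("streaming scan equals brute force and the independent oracle", {
  set.seed(4242)
  for (i in 1:200) {
    s <- sample(2:20, 1)
    g <- sample(1:200, 1)
    seqs <- random_seqs(s, g)
    f <- write_fasta(paste0("t", seq_len(s)), seqs)
    streamed <- find_variant_sites(f)$sites
    expect_identical(streamed, as.integer(variant_sites_bruteforce(seqs)))
    expect_identical(streamed, as.integer(oracle_sites(seqs)))
    unlink(f)
  }
})

test_that("extraction preserves original characters at the variant columns", {
  aln <- worked_example_path()
  m <- extract_snp_matrix(aln, find_variant_sites(aln))
  expect_identical(m$rows, worked_example_rows)
  expect_identical(m$ids, worked_example_ids)
  expect_identical(m$p, 3L)
})

test_that("extraction with no sites yields empty rows", {
  f <- write_fasta(c("a", "b"), c("ACGT", "ACGT"))
  m <- extract_snp_matrix(f, find_variant_sites(f))
  expect_identical(m$rows, c("", ""))
  expect_identical(m$p, 0L)
})

test_that("every column of an extracted matrix is variant by construction", {
  set.seed(7)
  for (i in 1:25) {
    f <- write_fasta(paste0("t", 1:8), random_seqs(8, 120))
    m <- extract_snp_matrix(f, find_variant_sites(f))
    if (m$p > 0L) {
      cols <- do.call(rbind, strsplit(m$rows, "", fixed = TRUE))
      expect_true(all(apply(cols, 2L, is_variant_site)))
    }
    unlink(f)
  }
})

test_that("extraction is idempotent on its own FASTA output", {
  aln <- worked_example_path()
  m1 <- extract_snp_matrix(aln, find_variant_sites(aln))
  out <- tempfile(fileext = ".fa")
  write_snp_fasta(m1, out)
  m2 <- extract_snp_matrix(out, find_variant_sites(out))
  expect_identical(m2$rows, m1$rows)
  expect_identical(m2$ids, m1$ids)
})

test_that("permuting record order permutes rows and leaves sites unchanged", {
  set.seed(31)
  seqs <- random_seqs(6, 80)
  ids <- paste0("t", 1:6)
  f1 <- write_fasta(ids, seqs)
  perm <- sample(6)
  f2 <- write_fasta(ids[perm], seqs[perm])
  m1 <- extract_snp_matrix(f1, find_variant_sites(f1))
  m2 <- extract_snp_matrix(f2, find_variant_sites(f2))
  expect_identical(m2$sites, m1$sites)
  expect_identical(m2$rows, m1$rows[perm])
  expect_identical(m2$ids, m1$ids[perm])
})

test_that("exactly two complete reads of the input are performed", {
  aln <- worked_example_path()
  f <- file.size(aln)
  res <- run_pipeline(aln, "fasta", tempfile(), quiet = TRUE)
  expect_identical(res$bytes_read, as.numeric(2 * f))
})

test_that("a source changed between passes is a fatal inconsistency", {
  f <- write_fasta(c("a", "b"), c("ACGT", "ACGA"))
  scan <- find_variant_sites(f)
  write_fasta(c("a", "b", "c"), c("ACGT", "ACGA", "ACGC"), path = f)
  expect_error(extract_snp_matrix(f, scan), "changed between passes")
  write_fasta(c("a", "b"), c("ACGTA", "ACGAA"), path = f)
  expect_error(extract_snp_matrix(f, scan), "changed between passes")
})

test_that("unequal-length records abort the scan with the offending id", {
  f <- write_fasta(c("ok", "short"), c("ACGTACGTACGT", "ACGTACGTACG"))
  expect_error(find_variant_sites(f), "unequal sequence lengths.*'short'")
})

test_that("measured working storage matches the declared bounds", {
  f <- write_fasta(paste0("t", 1:10), {set.seed(5); random_seqs(10, 300)})
  scan <- find_variant_sites(f)
  expect_identical(scan$aux_chars, as.numeric(2 * scan$g))
  m <- extract_snp_matrix(f, scan)
  expect_identical(m$aux_chars, as.integer(scan$p * scan$s))
})
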