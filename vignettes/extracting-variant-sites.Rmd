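---
title: "Extracting variant sites from whole-genome alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting variant sites from whole-genome alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polysites)
```

## The problem

Prokaryotic population studies routinely produce whole-genome multiple
sequence alignments with thousands of taxa and megabase-scale columns —
files of many gigabytes. Downstream phylogenetic tools (FastTree, RAxML)
and variant-analysis tools (BCFtools, PLINK) only need the polymorphic
columns, which are typically a tiny fraction of the alignment. Extracting
them is conceptually trivial, but tools that load the whole alignment into
memory do not survive contact with an 8 GB input on a desktop machine.

`polysites` extracts the variant columns with a streaming two-pass
algorithm whose peak memory is bounded by

$$\max(p \times s,\; 2g)$$

characters, where $s$ is the number of samples, $g$ the alignment length
and $p$ the number of variant sites, and whose total file I/O is exactly
two sequential reads of the input plus one write of the (much smaller)
output: $2f \le \mathrm{I/O} \le 2f + o$ for input size $f$ and output
size $o$. Running time is linear in the total number of characters.

## The variant predicate

An alignment column is a **variant (SNP) site** when it carries at least
two distinct *informative* alleles. The missing-data rule is:

* `n`, `N`, `?` and `-` are *missing* — they never create variation;
* every other character is an informative allele, compared
  case-insensitively (`a` ≡ `A`). This deliberately includes IUPAC
  ambiguity codes other than N (`R`, `Y`, `S`, `W`, `K`, `M`, `B`, `D`,
  `H`, `V`): the missing set is exactly those four characters, so anything
  else counts as an allele. Non-IUPAC characters such as `.` are likewise
  treated as alleles rather than errors; the predicate is total over
  characters, and rejecting unusual characters would make the tool fail on
  legacy alignments it could otherwise serve.

Consequences worth spelling out: a column with one allele plus any mixture
of gaps and unknowns is monomorphic and excluded; an all-missing column is
excluded; a column distinguished only by case is monomorphic.

```{r predicate}
is_variant_site(c("G", "G", "A"))   # two alleles: variant
is_variant_site(c("-", "A", "a"))   # gap + one allele: monomorphic
is_variant_site(c("A", "R", "A"))   # ambiguity code is an allele
```

## The two-pass streaming algorithm

**Pass one** reads the alignment record by record and maintains two
$g$-length arrays: a *consensus* (one working reference character per
column, initialised to "nothing seen") and a *variant flag* per column.
For each informative character, the consensus is set if the column has
none yet; if the column already has a differing informative consensus, the
column is flagged variant. This is exactly $2g$ bytes of working storage,
and it provably computes the declarative predicate above: a column is
flagged iff at least two distinct informative alleles occur in it,
regardless of record order or of which allele happens to become the
consensus. The package keeps the declarative predicate
(`is_variant_site()` applied column by column, exposed as
`variant_sites_bruteforce()`) as an independent reference path, and the
test suite checks the two agree exactly on randomized alignments over the
full character set.

**Pass two** re-reads the file and copies the characters at the flagged
columns for every sample — original case, gaps and unknowns preserved
verbatim — into the $p \times s$ result. The input is never held in
memory; the two per-pass bounds give the overall $\max(ps, 2g)$ envelope.
Pass two re-checks the record count and alignment length, so an input file
replaced between passes is a fatal inconsistency rather than silent
corruption.

The per-column scan is implemented in C++ (via Rcpp); parsing, validation
and orchestration are R. The reader detects gzip input by its magic bytes
rather than the file extension, tolerates CRLF line endings and blank
lines, takes the sample id to be the header text up to the first
whitespace, and warns (rather than fails) on duplicate ids since output is
positional.

## Output formats

* **Multi-FASTA** (default): one unwrapped line per sample, byte-exact
  layout `>` id, newline, row, newline.
* **Relaxed sequential PHYLIP**: header `s p`, then `id row` lines. Names
  are not truncated to ten characters — the relaxed dialect accepted by
  RAxML — because strict truncation would collide typical modern sample
  ids. Whitespace inside an id would corrupt the format and is a fatal
  error.
* **VCF 4.1**, haploid. The alignment is a single unnamed coordinate
  system, so CHROM is the constant `1` and POS is the 1-based alignment
  column. REF is the first record's character at the site when
  informative, otherwise the first informative character down the column —
  a deterministic, order-stable rule. ALT lists the remaining distinct
  folded alleles in order of first appearance, with `*` appended when any
  sample carries `-` (VCF cannot express `-` as an allele string; `*` is
  the standard missing-due-to-overlap symbol, the closest encoding).
  Unknown bases (`N`/`?`) become no-call genotypes (`.`). Genotypes are
  single haploid indices, the natural ploidy for the prokaryotic
  alignments this serves. ID/QUAL/FILTER/INFO are `.` placeholders.

```{r formats}
aln <- system.file("extdata", "example_alignment.fa", package = "polysites")
scan <- find_variant_sites(aln)
scan$sites          # 0-based variant columns
m <- extract_snp_matrix(aln, scan)
m$rows
write_vcf(build_vcf_records(m), m$ids)
```

## The synthetic-alignment generator

`simulate_alignment()` emulates the benchmark design used to exercise the
tool: alignments parameterized by taxa count $s$, length $g$ and planted
variant-site count $p$. A monomorphic background is drawn uniformly over
A/C/G/T; $p$ distinct columns are chosen without replacement and each is
assigned a random bipartition of the samples between two distinct bases.
Missing characters (`-`, `N`, `n`, `?`) can be injected at a per-cell rate
(`gap_fraction`, default 0 — the plain benchmark condition), but never
into the one guaranteed carrier of each planted base, so the planted
count stays exact by construction: planted columns always retain two
informative alleles and monomorphic columns cannot gain one. Planted
columns are bi-allelic; real alignments also contain multi-allelic sites,
homoplasy and phylogenetic correlation among taxa, none of which the
generator models — recovery tests on planted alignments therefore verify
the detector's correctness contract, not its behaviour under any
particular evolutionary model (which it does not depend on: the predicate
is purely per-column).

`run_scaling_experiment()` runs the full pipeline over a parameter grid
and records found-versus-planted correctness, wall time, file sizes, the
bytes read by the two passes and the measured per-pass working storage.
The test suite uses it at $s$ up to 1000 and $g$ up to $10^5$ (up to
$10^8$ characters per alignment, minutes of total runtime on one CPU); the
published extremes of this experimental design (tens of gigabytes) scale
linearly from there and are out of desk scope.

## Numerical and degenerate-input choices

* A single-sequence alignment has no variant sites (variation needs two
  informative alleles), and extraction with zero sites yields valid empty
  outputs in every format (`s 0` PHYLIP, header-only VCF).
* I/O accounting counts line bytes plus one newline per line, which equals
  the on-disk size for plain newline-terminated files; for gzip input it
  measures decompressed volume, not disk I/O, so the $2f$ envelope is
  asserted on plain files.
* The generator restores the caller's RNG state, and the analysis path
  contains no randomness at all: identical input gives byte-identical
  output.
* A truncated gzip stream surfaces as a fatal decompression error; an
  empty file, a missing header, an empty sequence and unequal record
  lengths are each fatal with a diagnostic naming the offender.

## Limitations

* Alignments must be pre-computed; no alignment construction, no
  FASTQ/SAM/BAM, no SNP calling from reads.
* Monomorphic-site output and ACGT-only column filtering are not offered.
* VCF output is plain text (no BCF, bgzip or tabix indexing) and carries
  no INFO annotations.
* The memory envelope is a bound on the algorithm's working set in
  characters; R-level object overhead adds a constant factor on top.
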