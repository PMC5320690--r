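#' Generate a planted-SNP synthetic alignment
#'
#' Writes a multi-FASTA alignment of `s` sequences of length `g` in which
#' exactly `p` columns are polymorphic under the tool's own predicate, and
#' returns the planted positions. A monomorphic background sequence is
#' drawn uniformly over A/C/G/T; at each of `p` distinct columns the
#' samples are split by a random bipartition between two distinct bases,
#' so every planted column carries at least two informative alleles and
#' every other column at most one. Missing characters (`-`, `N`, `n`, `?`)
#' may be injected into cells at rate `gap_fraction`, but never into the
#' one guaranteed carrier of each planted base, so the planted count stays
#' exact. Generation is streamed row by row (memory bounded in `g`, plus
#' the p x s planted-base table) and fully reproducible from `seed`.
#'
#' @param path Output file path; a `.gz` suffix or `gzip = TRUE` writes
#'   gzip-compressed output.
#' @param s Number of samples (taxa); at least 2 when `p >= 1`.
#' @param g Alignment length in columns.
#' @param p Number of planted variant sites, `0 <= p <= g`.
#' @param seed Integer seed; same seed, same bytes.
#' @param gap_fraction Probability that a cell outside the protected
#'   carriers is replaced by a missing character. Default 0.
#' @param gzip Force gzip output regardless of the path suffix.
#' @return Integer vector of the planted 0-based column indices, sorted.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' planted <- simulate_alignment(f, s = 10, g = 200, p = 5, seed = 42)
#' identical(find_variant_sites(f)$sites, planted)
#' @export
simulate_alignment <- function(path, s, g, p, seed,
                               gap_fraction = 0, gzip = grepl("\\.gz$", path)) {
  if (p < 0L || p > g)
    stop("planted site count p must satisfy 0 <= p <= g", call. = FALSE)
  if (p >= 1L && s < 2L)
    stop("planting a variant site requires at least 2 samples", call. = FALSE)
  if (gap_fraction < 0 || gap_fraction >= 1)
    stop("gap_fraction must be in [0, 1)", call. = FALSE)

  if (exists(".Random.seed", globalenv()))
    old_seed <- get(".Random.seed", globalenv())
  else old_seed <- NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  bases <- charToRaw("ACGT")
  miss <- charToRaw("-Nn?")
  bg <- bases[sample.int(4L, g, replace = TRUE)]

  planted_cols <- integer(0)
  carrier1 <- carrier2 <- integer(0)
  P <- NULL
  if (p > 0L) {
    planted_cols <- sort(sample.int(g, p))
    b1 <- sample.int(4L, p, replace = TRUE)
    b2 <- ((b1 - 1L + sample.int(3L, p, replace = TRUE)) %% 4L) + 1L
    P <- matrix(as.raw(0L), nrow = s, ncol = p)
    carrier1 <- carrier2 <- integer(p)
    for (j in seq_len(p)) {
      perm <- sample.int(s)
      k <- if (s == 2L) 1L else sample.int(s - 1L, 1L)
      colv <- rep(bases[b2[j]], s)
      colv[perm[seq_len(k)]] <- bases[b1[j]]
      P[, j] <- colv
      carrier1[j] <- perm[1L]
      carrier2[j] <- perm[k + 1L]
    }
  }

  con <- if (gzip) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con), add = TRUE, after = FALSE)
  for (r in seq_len(s)) {
    row <- bg
    if (p > 0L) row[planted_cols] <- P[r, ]
    if (gap_fraction > 0) {
      mask <- stats::runif(g) < gap_fraction
      if (p > 0L)
        mask[planted_cols[carrier1 == r | carrier2 == r]] <- FALSE
      nm <- sum(mask)
      if (nm > 0L) row[mask] <- miss[sample.int(4L, nm, replace = TRUE)]
    }
    writeLines(c(paste0(">sample_", r), rawToChar(row)), con)
  }
  planted_cols - 1L
}

#' Run a scaling experiment over a grid of simulation parameters
#'
#' For each parameter combination, generates a planted-SNP alignment, runs
#' the full detection/extraction pipeline on it, and records correctness
#' (found sites versus planted sites), wall time, file sizes and the
#' measured I/O and working-storage figures. Any run whose found sites
#' differ from the planted ones is flagged with a warning.
#'
#' @param grid Data frame with columns `s`, `g`, `p` and optionally `seed`
#'   (default: the row number) and `gap_fraction` (default 0).
#' @param format Output format passed to [run_pipeline()].
#' @param dir Directory for the generated alignments and outputs
#'   (temporary files, removed afterwards).
#' @param report Optional path; when given, the result table is also
#'   written there as tab-delimited text.
#' @return Data frame, one row per run: the parameters plus `p_found`,
#'   `sites_match`, `elapsed` (seconds), `f` and `o` (input/output bytes
#'   on disk), `bytes_read` (both passes, as counted by the reader),
#'   `io_within_envelope` (`2f <= bytes_read <= 2f + o`), `aux_pass1` and
#'   `aux_pass2` (measured working storage in characters).
#' @export
run_scaling_experiment <- function(grid, format = "fasta",
                                   dir = tempdir(), report = NULL) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L,
            all(c("s", "g", "p") %in% names(grid)))
  if (is.null(grid$seed)) grid$seed <- seq_len(nrow(grid))
  if (is.null(grid$gap_fraction)) grid$gap_fraction <- 0

  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sp <- grid[i, ]
    aln <- tempfile("simaln_", tmpdir = dir, fileext = ".fa")
    out <- tempfile("simout_", tmpdir = dir)
    on.exit(unlink(c(aln, out)))
    planted <- simulate_alignment(aln, s = sp$s, g = sp$g, p = sp$p,
                                  seed = sp$seed,
                                  gap_fraction = sp$gap_fraction)
    f <- file.size(aln)
    elapsed <- system.time(
      res <- run_pipeline(aln, format = format, output = out, quiet = TRUE)
    )[["elapsed"]]
    o <- file.size(out)
    data.frame(
      s = sp$s, g = sp$g, p = sp$p, seed = sp$seed,
      gap_fraction = sp$gap_fraction,
      p_found = res$p,
      sites_match = identical(res$sites, planted),
      elapsed = elapsed, f = f, o = o,
      bytes_read = res$bytes_read,
      io_within_envelope =
        res$bytes_read >= 2 * f && res$bytes_read <= 2 * f + o,
      aux_pass1 = res$aux_pass1, aux_pass2 = res$aux_pass2)
  })
  tab <- do.call(rbind, rows)
  if (any(!tab$sites_match))
    warning("correctness failure: found sites differ from planted sites in ",
            sum(!tab$sites_match), " run(s)", call. = FALSE)
  if (!is.null(report))
    utils::write.table(tab, report, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  tab
}
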