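#' Count canonical k-mers into a multiplicity histogram
#'
#' Every window of k consecutive A/C/G/T bases contributes one count to the
#' canonical form of the k-mer (the lexicographically smaller of the k-mer
#' and its reverse complement); windows containing any other character are
#' skipped. Counting is exact and in memory (2-bit encoded hash), sized for
#' desk-scale read sets.
#'
#' @param x Reads: a character vector, `DNAStringSet`, or a FASTA/FASTQ
#'   file path (plain text).
#' @param k Odd k-mer length between 3 and 31; default 19.
#' @param cap Multiplicities above `cap` are pooled into the cap bin, so
#'   organelle and rDNA k-mers cannot dominate memory.
#' @return A `kmer_histogram`: list with `k`, `counts` (dense numeric vector,
#'   `counts[m]` = number of distinct canonical k-mers seen `m` times),
#'   `cap`, `total_kmers`, `distinct`.
#' @export
count_canonical_kmers <- function(x, k = 19, cap = 10000) {
  k <- as.integer(k); cap <- as.integer(cap)
  if (k < 3 || k > 31) stop("k must be in [3, 31]")
  if (k %% 2 == 0)
    stop("k must be odd (even k makes canonical palindromes ambiguous)")
  seqs <- kmer_input_seqs(x)
  if (length(seqs) == 0 || all(nchar(seqs) == 0)) stop("empty input")
  res <- cpp_kmer_histogram(seqs, k, cap)
  if (res$total_kmers == 0) stop("empty input: no valid k-mer window")
  h <- structure(list(k = k, counts = as.numeric(res$counts), cap = cap,
                      total_kmers = res$total_kmers,
                      distinct = res$distinct),
                 class = "kmer_histogram")
  # conservation: sum m*counts[m] must equal the windows ingested (exact
  # unless multiplicities were pooled into the cap bin)
  if (length(h$counts) < cap || h$counts[cap] == 0) {
    tot <- sum(seq_along(h$counts) * h$counts)
    stopifnot(isTRUE(all.equal(tot, h$total_kmers)))
  }
  h
}

kmer_input_seqs <- function(x) {
  if (inherits(x, "DNAStringSet")) return(as.character(x))
  if (inherits(x, "read_sim")) return(unname(x$reads))
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    first <- substr(readLines(x, n = 1L), 1, 1)
    fmt <- if (identical(first, "@")) "fastq" else "fasta"
    return(as.character(Biostrings::readDNAStringSet(x, format = fmt)))
  }
  as.character(x)
}

#' @export
print.kmer_histogram <- function(x, ...) {
  cat(sprintf("Canonical %d-mer histogram: %.0f k-mers, %.0f distinct, %d multiplicity bins\n",
              x$k, x$total_kmers, x$distinct, length(x$counts)))
  invisible(x)
}

#' Read/write a k-mer histogram in two-column text layout
#'
#' The layout (one `multiplicity count` pair per line, space separated) is
#' the one the jellyfish `histo` subcommand prints.
#'
#' @param hist A `kmer_histogram`.
#' @param path File path.
#' @param k,cap Metadata for the histogram being read (the text layout does
#'   not carry them).
#' @return `write_kmer_histogram`: `path` invisibly; `read_kmer_histogram`:
#'   a `kmer_histogram`.
#' @export
write_kmer_histogram <- function(hist, path) {
  nz <- which(hist$counts > 0)
  writeLines(sprintf("%d %.0f", nz, hist$counts[nz]), path)
  invisible(path)
}

#' @rdname write_kmer_histogram
#' @export
read_kmer_histogram <- function(path, k = 19, cap = 10000) {
  tab <- read.table(path, header = FALSE,
                    col.names = c("multiplicity", "count"))
  counts <- numeric(max(tab$multiplicity))
  counts[tab$multiplicity] <- tab$count
  structure(list(k = as.integer(k), counts = counts, cap = as.integer(cap),
                 total_kmers = sum(tab$multiplicity * tab$count),
                 distinct = sum(tab$count)),
            class = "kmer_histogram")
}

# centred moving average, window 3 (shrunk at the ends); raw histograms
# from low-coverage runs are too noisy for direct peak/valley detection
smooth_counts <- function(counts) {
  n <- length(counts)
  vapply(seq_len(n), function(i)
    mean(counts[max(1, i - 1):min(n, i + 1)]), numeric(1))
}

#' Locate the error/signal valley of a k-mer histogram
#'
#' Low-multiplicity k-mers derive from sequencing errors (and low-coverage
#' contamination); the cutoff is the first valley of the smoothed histogram:
#' the smallest multiplicity `m >= 2` whose smoothed count is below that of
#' `m + 1`.
#'
#' @param hist A `kmer_histogram`.
#' @return The cutoff multiplicity (integer).
#' @export
find_error_cutoff <- function(hist) {
  counts <- hist$counts
  if (length(counts) < 3) stop("histogram needs at least 3 bins")
  sm <- smooth_counts(counts)
  for (m in 2:(length(sm) - 1)) {
    if (sm[m] < sm[m + 1]) return(as.integer(m))
  }
  stop("no error/signal separation: histogram decreases monotonically")
}

#' Estimate haploid genome size from a diploid k-mer spectrum
#'
#' The homozygous (2n) peak is the argmax of the smoothed histogram at or
#' above the error cutoff (ties between smoothed bins resolved toward the
#' highest raw count); the haploid size is the total k-mer count above the
#' cutoff divided by the 2n peak multiplicity. A heterozygous (1n) peak is
#' reported when a local maximum exists between the cutoff and 0.75 x the
#' 2n peak.
#'
#' @param hist A `kmer_histogram`.
#' @return A `genome_size_estimate`: list with `haploid_size`,
#'   `homozygous_peak_coverage`, `heterozygous_peak_coverage` (`NA` when no
#'   1n peak is detectable), `error_cutoff`, `total_kmers_used`, `k`.
#' @export
estimate_genome_size <- function(hist) {
  cutoff <- find_error_cutoff(hist)
  counts <- hist$counts
  sm <- smooth_counts(counts)
  n <- length(counts)
  cand <- cutoff:n
  peak_sm <- max(sm[cand])
  ties <- cand[sm[cand] >= peak_sm * (1 - 1e-12)]
  homo <- ties[which.max(counts[ties])]
  total_used <- sum(cand * counts[cand])
  haploid <- total_used / homo

  het <- NA_integer_
  hi <- floor(0.75 * homo)
  if (hi > cutoff + 1) {
    rng <- (cutoff + 1):(hi - 1)
    is_max <- vapply(rng, function(m)
      sm[m] > 0 && sm[m] >= sm[m - 1] && sm[m] >= sm[m + 1], logical(1))
    if (any(is_max)) {
      mx <- rng[is_max]
      het <- mx[which.max(sm[mx])]
    }
  }
  structure(list(haploid_size = haploid,
                 homozygous_peak_coverage = as.integer(homo),
                 heterozygous_peak_coverage = as.integer(het),
                 error_cutoff = cutoff,
                 total_kmers_used = total_used,
                 k = hist$k),
            class = "genome_size_estimate")
}

#' @export
print.genome_size_estimate <- function(x, ...) {
  cat(sprintf("Haploid genome size estimate: %.2f Mbp\n",
              x$haploid_size / 1e6))
  cat(sprintf("  2n peak %d x, 1n peak %s, error cutoff %d, %.0f %d-mers used\n",
              x$homozygous_peak_coverage,
              ifelse(is.na(x$heterozygous_peak_coverage), "not detected",
                     paste0(x$heterozygous_peak_coverage, " x")),
              x$error_cutoff, x$total_kmers_used, x$k))
  invisible(x)
}
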