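#' Assembly summary statistics
#'
#' Contig count, total size, N50 (the length of the contig at which the
#' descending cumulative length first reaches half the assembly), and GC
#' percent over unambiguous A/C/G/T bases only.
#'
#' @param contigs Contig set.
#' @return An `assembly_stats` object: `n_contigs`, `total_bp`, `n50`,
#'   `gc_percent`.
#' @export
assembly_stats <- function(contigs) {
  contigs <- as_contigs(contigs)
  if (length(contigs) == 0) stop("empty assembly")
  w <- sort(as.numeric(Biostrings::width(contigs)), decreasing = TRUE)
  total <- sum(w)
  n50 <- w[which(cumsum(w) >= total / 2)[1]]
  gc <- sum(Biostrings::letterFrequency(contigs, "GC"))
  acgt <- sum(Biostrings::letterFrequency(contigs, "ACGT"))
  structure(list(n_contigs = length(contigs), total_bp = total,
                 n50 = n50, gc_percent = 100 * gc / acgt),
            class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf("%d contigs, %s bp, N50 %s bp, GC %.1f%%\n",
              x$n_contigs, format(x$total_bp, big.mark = ","),
              format(x$n50, big.mark = ","), x$gc_percent))
  invisible(x)
}

#' Fragment-based average nucleotide identity
#'
#' The query is cut into non-overlapping fragments; each fragment's best
#' location in the reference is found by shared-k-mer seeding (vote over
#' contig, strand and diagonal) and scored by banded gapped alignment of
#' the fragment against the seeded reference window. Fragments whose best
#' identity reaches `min_identity_orth` are called orthologous and their
#' mean identity is the (direction-specific) ANI.
#'
#' @param query,reference Contig sets.
#' @param fragment Fragment length in bases.
#' @param min_identity_orth Percent identity above which a fragment counts
#'   as orthologous.
#' @param seed_k,seed_stride K-mer length and query sampling stride of the
#'   seeding stage.
#' @param names Length-2 character vector naming the two assemblies.
#' @return An `ani_result`: `query`, `reference`, `ani_percent`,
#'   `n_fragments_used`, `n_fragments_total`.
#' @export
ani <- function(query, reference, fragment = 1000, min_identity_orth = 80,
                seed_k = 15, seed_stride = 7,
                names = c("query", "reference")) {
  query <- as_contigs(query); reference <- as_contigs(reference)
  if (length(query) == 0 || length(reference) == 0)
    stop("both assemblies must be non-empty")
  qseq <- as.character(query)
  frags <- character(0)
  for (s in qseq) {
    nf <- nchar(s) %/% fragment
    if (nf == 0) next
    st <- seq_len(nf) * fragment - fragment
    frags <- c(frags, substring(s, st + 1L, st + fragment))
  }
  n_total <- length(frags)
  if (n_total == 0) stop("query has no full fragment")

  hits <- cpp_seed_best(frags, as.character(reference),
                        as.integer(seed_k), as.integer(seed_stride), 20L)
  rseq <- as.character(reference)
  rlen <- nchar(rseq)
  margin <- 40L
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                     mismatch = -1)
  idents <- rep(NA_real_, n_total)
  for (i in seq_len(n_total)) {
    if (hits[i, 1] == 0) next
    ri <- hits[i, 1]; strand <- hits[i, 2]; diag <- hits[i, 3]
    flen <- nchar(frags[i])
    wstart <- if (strand > 0) diag else diag - flen + seed_k
    lo <- max(0L, wstart - margin)
    hi <- min(rlen[ri], wstart + flen + margin)
    if (hi - lo < seed_k) next
    win <- substr(rseq[ri], lo + 1L, hi)
    if (strand < 0) win <- revcomp(win)
    aln <- Biostrings::pairwiseAlignment(
      frags[i], win, type = "global-local", substitutionMatrix = submat,
      gapOpening = 5, gapExtension = 2)
    idents[i] <- Biostrings::pid(aln, type = "PID1")
  }
  orth <- !is.na(idents) & idents >= min_identity_orth
  if (!any(orth)) stop("assemblies too divergent: no orthologous fragment")
  structure(list(query = names[1], reference = names[2],
                 ani_percent = mean(idents[orth]),
                 n_fragments_used = sum(orth),
                 n_fragments_total = n_total),
            class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  cat(sprintf("ANI %s -> %s: %.2f%% over %d/%d fragments\n", x$query,
              x$reference, x$ani_percent, x$n_fragments_used,
              x$n_fragments_total))
  invisible(x)
}

#' Both-direction ANI
#'
#' @param a,b Contig sets.
#' @param ... Passed to [ani()].
#' @return List: `ab`, `ba` (the two `ani_result`s) and `mean_percent`.
#' @export
ani_both <- function(a, b, ...) {
  ab <- ani(a, b, names = c("A", "B"), ...)
  ba <- ani(b, a, names = c("B", "A"), ...)
  list(ab = ab, ba = ba,
       mean_percent = mean(c(ab$ani_percent, ba$ani_percent)))
}
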