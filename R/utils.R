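#' Coerce to a named DNAStringSet
#'
#' Contigs are handled throughout as a named [Biostrings::DNAStringSet].
#' Character vectors (named) and single file paths to FASTA are accepted
#' wherever a contig set is expected.
#'
#' @param x A named character vector, `DNAStringSet`, or FASTA file path.
#' @return A named `DNAStringSet`.
#' @export
as_contigs <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    if (length(x) > 0 && is.null(names(x))) stop("contig set must be named")
    return(x)
  }
  if (is.character(x) && length(x) == 1L && file.exists(x) &&
      !grepl("^[ACGTNacgtn]+$", x)) {
    return(Biostrings::readDNAStringSet(x))
  }
  if (is.character(x)) {
    if (is.null(names(x))) stop("contig set must be named")
    return(Biostrings::DNAStringSet(x))
  }
  stop("cannot interpret input as a contig set")
}

#' Write contigs as 80-column wrapped FASTA
#'
#' @param contigs Contig set (see [as_contigs()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(contigs, path) {
  Biostrings::writeXStringSet(as_contigs(contigs), path, width = 80L)
  invisible(path)
}

# random sequence with i.i.d. bases, P(G or C) = gc, G/C and A/T split evenly
random_dna <- function(n, gc) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# substitute `n_sub` random positions of a sequence string with a different
# base; returns the mutated string and the 0-based positions
substitute_bases <- function(seq, n_sub, exclude = NULL) {
  n <- nchar(seq)
  eligible <- seq_len(n)
  if (!is.null(exclude) && length(exclude))
    eligible <- eligible[!(eligible %in% exclude)]
  n_sub <- min(n_sub, length(eligible))
  if (n_sub == 0) return(list(seq = seq, pos0 = integer(0)))
  pos <- sort(sample(eligible, n_sub))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    alt <- setdiff(bases, chars[p])
    chars[p] <- alt[sample.int(3L, 1L)]
  }
  list(seq = paste(chars, collapse = ""), pos0 = pos - 1L)
}

# lower median: for even n the smaller of the two central order statistics
lower_median <- function(x) {
  n <- length(x)
  if (n == 0) return(NA_real_)
  sort(x, partial = floor((n + 1) / 2))[floor((n + 1) / 2)]
}

# merge possibly overlapping/adjacent 0-based half-open intervals
merge_intervals <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
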