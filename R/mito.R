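#' Identify the mitochondrial contig by k-mer containment
#'
#' Scores every contig by the fraction of the reference's distinct
#' canonical 21-mers it contains and returns the argmax. Containment (not
#' identity) is used so a mitochondrial contig with extra flanking sequence
#' still scores 1. Random nuclear contigs share essentially no 21-mers with
#' the reference, so the 0.5 floor cleanly separates hit from no-hit.
#'
#' @param assembly Contig set.
#' @param reference Mitochondrial reference sequence (contig set or single
#'   sequence).
#' @param k K-mer length for containment.
#' @param min_containment Minimum containment for a confident call.
#' @return List: `contig` (name), `containment` (score), `scores` (named
#'   vector over all contigs).
#' @export
identify_mito_contig <- function(assembly, reference, k = 21,
                                 min_containment = 0.5) {
  assembly <- as_contigs(assembly)
  reference <- if (is.character(reference) && length(reference) == 1L &&
                   !file.exists(reference) && is.null(names(reference)))
    reference else paste(as.character(as_contigs(reference)), collapse = "N")
  if (nchar(reference) == 0) stop("empty reference")
  scores <- cpp_kmer_containment(reference, as.character(assembly), k)
  names(scores) <- names(assembly)
  best <- which.max(scores)
  if (scores[best] < min_containment)
    stop("no mitochondrial contig (best containment ",
         sprintf("%.3f", scores[best]), " < ", min_containment, ")")
  list(contig = names(assembly)[best],
       containment = unname(scores[best]), scores = scores)
}

#' Trim the duplicated end overlap of a circular contig
#'
#' Assemblers emit a circular replicon as a linear contig whose ends
#' duplicate each other. The longest suffix aligning to a prefix with
#' identity at least `min_identity` and length at least `min_overlap`
#' (seed anchoring with 15-mers from the prefix, ungapped comparison) is
#' removed; ties in length are broken toward higher identity. With no
#' qualifying overlap the contig is returned unchanged. The operation is
#' idempotent.
#'
#' @param contig A single contig (`DNAString(Set)` or character).
#' @param min_overlap Minimum overlap length considered.
#' @param min_identity Minimum ungapped identity of the overlap.
#' @return List: `contig` (trimmed, `DNAStringSet`) and `curation`
#'   (`circular_curation` record: `contig`, `overlap_trimmed`,
#'   `rotation_offset`, `strand_flipped`, `final_length`).
#' @export
circ_trim <- function(contig, min_overlap = 50, min_identity = 0.95) {
  x <- single_contig(contig)
  s <- x$seq; n <- nchar(s); cn <- x$name
  if (n <= 2 * min_overlap)
    stop("contig must be longer than twice min_overlap")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]

  # seed 15-mers taken from several prefix offsets so a mismatch inside the
  # first seed cannot hide a true overlap
  seed_k <- 15L
  best_len <- 0L; best_id <- 0
  for (off in seq(0L, min(45L, n %/% 4L), by = 5L)) {
    seed <- substr(s, off + 1L, off + seed_k)
    if (nchar(seed) < seed_k) break
    hits <- Biostrings::start(Biostrings::matchPattern(
      seed, Biostrings::DNAString(s))) - 1L   # 0-based
    for (p in hits) {
      q <- p - off                            # 0-based overlap start
      L <- n - q
      if (L < min_overlap || L >= n || q <= 0) next
      ident <- mean(chars[(q + 1L):n] == chars[1:L])
      if (ident >= min_identity &&
          (L > best_len || (L == best_len && ident > best_id))) {
        best_len <- L; best_id <- ident
      }
    }
  }
  trimmed <- if (best_len > 0) substr(s, 1L, n - best_len) else s
  curation <- structure(list(contig = cn, overlap_trimmed = best_len,
                             rotation_offset = 0L, strand_flipped = FALSE,
                             final_length = nchar(trimmed)),
                        class = "circular_curation")
  list(contig = Biostrings::DNAStringSet(setNames(trimmed, cn)),
       curation = curation)
}

#' Rotate a circular contig to start at an anchor sequence
#'
#' Locates the best match of the anchor in the doubled sequence (so matches
#' spanning the linearisation origin are found) on both strands, reverse
#' complements the contig if the match lies on the reverse strand, and
#' rotates it so the anchor match starts at position 0. Any rotation or
#' strand presentation of the same circle therefore yields byte-identical
#' output.
#'
#' @param contig A single (already trimmed) circular contig.
#' @param anchor Anchor sequence (>= 20 bases), e.g. the start of the large
#'   subunit rRNA gene of a reference genome; character, `DNAString(Set)`,
#'   or FASTA path.
#' @param min_identity Minimum anchor identity.
#' @return List: `contig` (rotated `DNAStringSet`) and `curation`
#'   (`circular_curation` record).
#' @export
circ_restart <- function(contig, anchor, min_identity = 0.9) {
  x <- single_contig(contig)
  s <- x$seq; n <- nchar(s); cn <- x$name
  if (is.character(anchor) && length(anchor) == 1L && file.exists(anchor))
    anchor <- as.character(Biostrings::readDNAStringSet(anchor))[1]
  anchor <- single_contig(anchor)$seq
  m <- nchar(anchor)
  if (m < 20) stop("anchor must be at least 20 bases")
  max_mm <- floor((1 - min_identity) * m)

  best_for <- best_anchor_match(anchor, paste0(s, s), max_mm)
  src <- revcomp(s)
  best_rev <- best_anchor_match(anchor, paste0(src, src), max_mm)
  if (is.null(best_for) && is.null(best_rev))
    stop("anchor not found (identity < ", min_identity, " everywhere)")
  use_rev <- is.null(best_for) ||
    (!is.null(best_rev) && best_rev$mismatches < best_for$mismatches)
  seq_use <- if (use_rev) src else s
  p <- (if (use_rev) best_rev$start else best_for$start) %% n
  doubled <- paste0(seq_use, seq_use)
  rotated <- substr(doubled, p + 1L, p + n)
  curation <- structure(list(contig = cn, overlap_trimmed = 0L,
                             rotation_offset = p, strand_flipped = use_rev,
                             final_length = n),
                        class = "circular_curation")
  list(contig = Biostrings::DNAStringSet(setNames(rotated, cn)),
       curation = curation)
}

# best (fewest-mismatch, then leftmost) ungapped match of anchor in subject
best_anchor_match <- function(anchor, subject, max_mm) {
  mp <- Biostrings::matchPattern(anchor, Biostrings::DNAString(subject),
                                 max.mismatch = max_mm, with.indels = FALSE)
  if (length(mp) == 0) return(NULL)
  starts <- Biostrings::start(mp) - 1L   # 0-based
  achars <- strsplit(anchor, "", fixed = TRUE)[[1]]
  mm <- vapply(seq_along(starts), function(i) {
    sub <- substr(subject, starts[i] + 1L, starts[i] + nchar(anchor))
    sum(strsplit(sub, "", fixed = TRUE)[[1]] != achars)
  }, numeric(1))
  i <- which(mm == min(mm))[1]
  list(start = starts[i], mismatches = mm[i])
}

#' @export
print.circular_curation <- function(x, ...) {
  cat(sprintf("Circular curation of %s: trimmed %d bp overlap, rotated by %d, strand %s, final %d bp\n",
              x$contig, x$overlap_trimmed, x$rotation_offset,
              ifelse(x$strand_flipped, "flipped", "kept"), x$final_length))
  invisible(x)
}

single_contig <- function(x) {
  if (inherits(x, "DNAString"))
    return(list(seq = as.character(x), name = "contig"))
  if (inherits(x, "DNAStringSet")) {
    if (length(x) != 1) stop("expected a single contig")
    return(list(seq = as.character(x)[[1]],
                name = names(x) %||% "contig"))
  }
  if (is.character(x) && length(x) == 1L)
    return(list(seq = unname(x), name = names(x) %||% "contig"))
  stop("expected a single contig")
}
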