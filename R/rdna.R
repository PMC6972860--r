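#' rDNA operon annotation
#'
#' The operon interval (0-based half-open) on a contig, optionally with
#' named subregions (18S, ITS1, 5.8S, ITS2, 28S) nested inside it.
#'
#' @param contig Contig carrying the operon.
#' @param start,end Operon interval, 0-based half-open.
#' @param subregions Optional data.frame (`name`, `start`, `end`) of
#'   non-overlapping, ordered intervals inside the operon.
#' @return An `operon_annotation` object.
#' @export
operon_annotation <- function(contig, start, end, subregions = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (end <= start) stop("empty operon interval")
  if (!is.null(subregions)) {
    o <- order(subregions$start)
    subregions <- subregions[o, , drop = FALSE]
    if (any(subregions$start < start) || any(subregions$end > end))
      stop("subregions must be nested in the operon")
    if (any(subregions$end[-nrow(subregions)] >
            subregions$start[-1]))
      stop("subregions must not overlap")
  }
  structure(list(contig = contig, start = start, end = end,
                 subregions = subregions),
            class = "operon_annotation")
}

#' Read intervals from BED or GFF3
#'
#' BED is 0-based half-open and used as is; GFF3 (detected from the file
#' content) is 1-based closed and converted on read.
#'
#' @param path BED or GFF3 file.
#' @return Data.frame: `contig`, `start`, `end`, `name` (0-based half-open).
#' @export
read_intervals <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- vapply(fields, length, integer(1))
  if (all(ncol >= 8)) {  # GFF3: seqid source type start end ...
    grab <- function(i) vapply(fields, `[[`, character(1), i)
    attr9 <- if (all(ncol >= 9)) grab(9) else ""
    nm <- sub(".*(?:Name|ID)=([^;]+).*", "\\1", attr9)
    nm[nm == attr9] <- grab(3)[nm == attr9]
    data.frame(contig = grab(1), start = as.integer(grab(4)) - 1L,
               end = as.integer(grab(5)), name = nm)
  } else {
    grab <- function(i) vapply(fields, `[[`, character(1), i)
    data.frame(contig = grab(1), start = as.integer(grab(2)),
               end = as.integer(grab(3)),
               name = if (all(ncol >= 4)) grab(4) else "")
  }
}

#' Estimate rDNA operon haploid copy number from depth ratios
#'
#' The assembly collapses a tandem rDNA array into (near) one unit, so the
#' reads of all copies pile onto it: the copy number per haploid genome is
#' the median per-base depth across the operon divided by the median
#' per-base depth across the single-copy backbone, taken as the pooled
#' per-base depths of the 50 longest contigs (both operon and backbone are
#' diploid, so ploidy cancels in the ratio). With fewer than 50 contigs all
#' are used and a note is recorded.
#'
#' @param tracks A `depth_tracks` object.
#' @param annotation An [operon_annotation()].
#' @param n_backbone Number of longest contigs forming the baseline.
#' @return A `copy_number_estimate`: `operon_median_depth`,
#'   `backbone_median_depth`, `haploid_copies` (unrounded ratio),
#'   `haploid_copies_int`, `n_backbone_contigs`, `note`.
#' @export
operon_copy_number <- function(tracks, annotation, n_backbone = 50) {
  if (!annotation$contig %in% names(tracks))
    stop("annotation contig not in depth tracks: ", annotation$contig)
  d <- tracks[[annotation$contig]]
  if (annotation$end > length(d)) stop("operon interval exceeds contig")
  op <- d[(annotation$start + 1L):annotation$end]
  op_med <- as.numeric(lower_median(op))

  lens <- vapply(tracks, length, integer(1))
  note <- ""
  if (length(tracks) < n_backbone) {
    note <- sprintf("only %d contigs available for the %d-contig backbone",
                    length(tracks), n_backbone)
    n_backbone <- length(tracks)
  }
  longest <- names(sort(lens, decreasing = TRUE))[seq_len(n_backbone)]
  backbone <- unlist(tracks[longest], use.names = FALSE)
  bb_med <- as.numeric(lower_median(backbone))
  if (bb_med <= 0) stop("no coverage baseline (backbone median is 0)")
  structure(list(operon_median_depth = op_med,
                 backbone_median_depth = bb_med,
                 haploid_copies = op_med / bb_med,
                 haploid_copies_int = as.integer(round(op_med / bb_med)),
                 n_backbone_contigs = n_backbone, note = note),
            class = "copy_number_estimate")
}

#' @export
print.copy_number_estimate <- function(x, ...) {
  cat(sprintf("rDNA operon haploid copy number: %.2f (~%d)\n",
              x$haploid_copies, x$haploid_copies_int))
  cat(sprintf("  operon median depth %.1f / backbone median depth %.1f over %d contigs\n",
              x$operon_median_depth, x$backbone_median_depth,
              x$n_backbone_contigs))
  if (nzchar(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Count strain-unique substitutions per operon subregion
#'
#' Over an alignment of the operon across strains, a strain scores a
#' substitution in a column when its base differs from the base shared
#' unanimously by all other strains. Columns containing gaps, and columns
#' with any other variant pattern (e.g. two strains each carrying a
#' different base), are skipped and tallied separately.
#'
#' @param msa Aligned sequences (`DNAStringSet`, named character vector, or
#'   aligned-FASTA path); at least 3 sequences of equal aligned length.
#' @param regions Optional data.frame (`name`, `start`, `end`) of region
#'   intervals in 0-based half-open alignment coordinates; columns outside
#'   any region are counted under `"other"`.
#' @return List: `counts` (strains x regions integer matrix),
#'   `ambiguous_columns`, `gap_columns`, `variant_columns`.
#' @export
count_strain_substitutions <- function(msa, regions = NULL) {
  msa <- as_contigs(msa)
  if (length(msa) < 3) stop("need at least 3 aligned sequences")
  w <- Biostrings::width(msa)
  if (length(unique(w)) != 1) stop("aligned sequences have unequal lengths")
  mat <- do.call(rbind, strsplit(as.character(msa), "", fixed = TRUE))
  rownames(mat) <- names(msa)
  ncolumns <- ncol(mat)

  region_of <- rep("other", ncolumns)
  region_names <- "other"
  if (!is.null(regions) && nrow(regions) > 0) {
    region_names <- unique(c(regions$name, "other"))
    for (i in seq_len(nrow(regions))) {
      lo <- regions$start[i] + 1L; hi <- regions$end[i]
      region_of[lo:hi] <- regions$name[i]
    }
  }
  counts <- matrix(0L, nrow = nrow(mat), ncol = length(region_names),
                   dimnames = list(rownames(mat), region_names))
  ambiguous <- 0L; gaps <- 0L; variant <- 0L
  for (j in seq_len(ncolumns)) {
    col <- mat[, j]
    if (any(col == "-")) { gaps <- gaps + 1L; next }
    tab <- table(col)
    if (length(tab) == 1L) next
    variant <- variant + 1L
    if (length(tab) == 2L && min(tab) == 1L && nrow(mat) >= 3L) {
      strain <- names(col)[col == names(tab)[which.min(tab)]]
      counts[strain, region_of[j]] <- counts[strain, region_of[j]] + 1L
    } else {
      ambiguous <- ambiguous + 1L
    }
  }
  list(counts = counts, ambiguous_columns = ambiguous,
       gap_columns = gaps, variant_columns = variant)
}

#' Base counts and minor-allele fraction at given sites
#'
#' Pileup of primary, mapped alignment records at each site (bases at
#' reference positions consumed by CIGAR `M`/`=`/`X` only). For each site
#' the counts of A/C/G/T and the fraction of the most frequent
#' non-reference base are reported; a site with zero depth gets fraction
#' `NA` rather than an error.
#'
#' @param alignments SAM path or `sam_records` object (records must carry
#'   `SEQ`).
#' @param sites Data.frame: `contig`, `pos0` (0-based), `ref_base`.
#' @return Data.frame: `contig`, `pos0`, `ref_base`, `A`, `C`, `G`, `T`,
#'   `depth`, `minor_fraction`.
#' @export
allele_fraction_at_sites <- function(alignments, sites) {
  if (is.character(alignments)) alignments <- read_sam(alignments)
  r <- alignments$records
  keep <- r$rname != "*" & bitwAnd(r$flag, 4L) == 0L &
    bitwAnd(r$flag, 256L) == 0L & bitwAnd(r$flag, 2048L) == 0L
  r <- r[keep, , drop = FALSE]
  if (length(alignments$contigs) &&
      !all(sites$contig %in% names(alignments$contigs)))
    stop("site(s) on unknown contigs")
  out <- lapply(seq_len(nrow(sites)), function(i) {
    cn <- sites$contig[i]; p0 <- sites$pos0[i]
    rr <- r[r$rname == cn, , drop = FALSE]
    counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
    if (nrow(rr)) {
      for (j in seq_len(nrow(rr))) {
        b <- base_at(rr$cigar[j], rr$pos[j] - 1L, rr$seq[j], p0)
        if (!is.na(b) && b %in% names(counts))
          counts[b] <- counts[b] + 1L
      }
    }
    depth <- sum(counts)
    ref <- toupper(sites$ref_base[i])
    alt_counts <- counts[setdiff(names(counts), ref)]
    frac <- if (depth == 0) NA_real_ else max(alt_counts) / depth
    data.frame(contig = cn, pos0 = p0, ref_base = ref,
               A = counts[["A"]], C = counts[["C"]], G = counts[["G"]],
               T = counts[["T"]], depth = depth, minor_fraction = frac)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# query base aligned to reference position `at0`, or NA if the record does
# not cover it with an aligned (M/=/X) base
base_at <- function(cigar, pos0, seq, at0) {
  if (grepl("^[0-9]+M$", cigar)) {      # fast path: all-match
    len <- as.integer(sub("M$", "", cigar))
    off <- at0 - pos0
    if (off < 0 || off >= len) return(NA_character_)
    return(substr(seq, off + 1L, off + 1L))
  }
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  rp <- pos0; qp <- 0L
  for (op in ops) {
    n <- as.integer(substr(op, 1L, nchar(op) - 1L))
    o <- substr(op, nchar(op), nchar(op))
    if (o %in% c("M", "=", "X")) {
      if (at0 >= rp && at0 < rp + n)
        return(substr(seq, qp + (at0 - rp) + 1L, qp + (at0 - rp) + 1L))
      rp <- rp + n; qp <- qp + n
    } else if (o %in% c("D", "N")) {
      if (at0 >= rp && at0 < rp + n) return(NA_character_)
      rp <- rp + n
    } else if (o %in% c("I", "S")) {
      qp <- qp + n
    }
  }
  NA_character_
}
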