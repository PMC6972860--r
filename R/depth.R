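#' Read a SAM file into a record table
#'
#' A light text parser for the mandatory 11 SAM columns; `@SQ` header lines
#' supply contig lengths. BAM input is supported through Rsamtools when that
#' package is installed.
#'
#' @param path SAM (or BAM) file path.
#' @return A `sam_records` list: `records` data.frame (`qname`, `flag`,
#'   `rname`, `pos`, `mapq`, `cigar`, `seq`, `qual`), `contigs` (named
#'   lengths).
#' @export
read_sam <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) return(read_bam(path))
  lines <- readLines(path)
  is_header <- startsWith(lines, "@")
  sq <- lines[startsWith(lines, "@SQ")]
  contigs <- integer(0)
  if (length(sq)) {
    sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
    ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
    contigs <- setNames(ln, sn)
  }
  body <- lines[!is_header]
  if (length(body) == 0) {
    records <- data.frame(qname = character(0), flag = integer(0),
                          rname = character(0), pos = integer(0),
                          mapq = integer(0), cigar = character(0),
                          seq = character(0), qual = character(0))
  } else {
    fields <- strsplit(body, "\t", fixed = TRUE)
    grab <- function(i) vapply(fields, `[[`, character(1), i)
    records <- data.frame(qname = grab(1), flag = as.integer(grab(2)),
                          rname = grab(3), pos = as.integer(grab(4)),
                          mapq = as.integer(grab(5)), cigar = grab(6),
                          seq = grab(10), qual = grab(11))
  }
  structure(list(records = records, contigs = contigs, n_omitted = 0L),
            class = "sam_records")
}

read_bam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("BAM input requires the Rsamtools package")
  bf <- Rsamtools::BamFile(path)
  hdr <- Rsamtools::scanBamHeader(bf)
  contigs <- hdr$targets
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"))
  b <- Rsamtools::scanBam(bf, param = p)[[1]]
  keep <- !is.na(b$pos)
  records <- data.frame(qname = b$qname[keep], flag = b$flag[keep],
                        rname = as.character(b$rname[keep]),
                        pos = b$pos[keep], mapq = b$mapq[keep],
                        cigar = b$cigar[keep],
                        seq = as.character(b$seq)[keep],
                        qual = as.character(b$qual)[keep])
  structure(list(records = records, contigs = contigs, n_omitted = 0L),
            class = "sam_records")
}

#' Read a minimap2-style PAF file
#'
#' Columns 1-12 of the PAF dialect are required; extra tag columns are
#' ignored.
#'
#' @param path PAF file path.
#' @return A `paf_records` list: `records` data.frame with query/target
#'   fields (0-based half-open target interval), `contigs` (named target
#'   lengths).
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(fields, length, integer(1)) < 12))
    stop("PAF requires at least 12 columns")
  grab <- function(i) vapply(fields, `[[`, character(1), i)
  records <- data.frame(qname = grab(1), qlen = as.integer(grab(2)),
                        qstart = as.integer(grab(3)),
                        qend = as.integer(grab(4)), strand = grab(5),
                        tname = grab(6), tlen = as.integer(grab(7)),
                        tstart = as.integer(grab(8)),
                        tend = as.integer(grab(9)),
                        matches = as.integer(grab(10)),
                        alnlen = as.integer(grab(11)),
                        mapq = as.integer(grab(12)))
  contigs <- tapply(records$tlen, records$tname, `[`, 1)
  structure(list(records = records,
                 contigs = setNames(as.integer(contigs), names(contigs))),
            class = "paf_records")
}

#' Per-base read depth from alignments
#'
#' SAM records contribute depth at reference positions consumed by CIGAR
#' `M`/`=`/`X` (deletions and skips consume reference without depth; clips
#' and insertions consume none); only mapped, primary, non-supplementary
#' records count. PAF records add 1 over their whole target interval.
#' Malformed CIGARs are skipped and tallied in the `skipped` attribute.
#'
#' @param x A SAM/BAM/PAF path, or a `sam_records`/`paf_records` object.
#' @param contigs Optional named contig lengths; defaults to the lengths
#'   declared in the input (`@SQ` lines / PAF column 7). Required when the
#'   input declares none.
#' @return A `depth_tracks` object: named list of integer vectors, one
#'   per-base depth array per contig.
#' @export
depth_from_alignments <- function(x, contigs = NULL) {
  if (is.character(x) && length(x) == 1L) {
    x <- if (grepl("\\.paf$", x, ignore.case = TRUE)) read_paf(x)
         else read_sam(x)
  }
  if (inherits(x, "paf_records")) {
    r <- x$records
    contigs <- contigs %||% x$contigs
    tid <- match(r$tname, names(contigs))
    if (anyNA(tid))
      stop("alignment target(s) not in contig table: ",
           paste(unique(r$tname[is.na(tid)]), collapse = ", "))
    res <- cpp_depth(tid, r$tstart, paste0(r$tend - r$tstart, "M"),
                     as.integer(unname(contigs)))
  } else if (inherits(x, "sam_records")) {
    r <- x$records
    contigs <- contigs %||% x$contigs
    if (is.null(contigs) || length(contigs) == 0)
      stop("no contig lengths available (missing @SQ header?)")
    keep <- r$rname != "*" &
      bitwAnd(r$flag, 4L) == 0L &      # mapped
      bitwAnd(r$flag, 256L) == 0L &    # primary
      bitwAnd(r$flag, 2048L) == 0L     # non-supplementary
    r <- r[keep, , drop = FALSE]
    tid <- match(r$rname, names(contigs))
    if (anyNA(tid))
      stop("alignment target(s) not in contig table: ",
           paste(unique(r$rname[is.na(tid)]), collapse = ", "))
    res <- cpp_depth(tid, r$pos - 1L, r$cigar,
                     as.integer(unname(contigs)))
  } else {
    stop("unsupported alignment input")
  }
  if (res$skipped > 0)
    warning(res$skipped, " record(s) skipped (malformed CIGAR)")
  tracks <- setNames(res$depth, names(contigs))
  structure(tracks, class = "depth_tracks", skipped = res$skipped)
}

#' @export
print.depth_tracks <- function(x, ...) {
  cat("Per-base depth over", length(x), "contigs,",
      sum(vapply(x, length, integer(1))), "bp total\n")
  invisible(x)
}

#' Median per-contig coverage
#'
#' The median of the per-base depth array of each contig; even-length
#' arrays use the lower median.
#'
#' @param tracks A `depth_tracks` object (or plain named list of integer
#'   vectors).
#' @return Named numeric vector of per-contig median depth.
#' @export
median_contig_coverage <- function(tracks) {
  if (length(tracks) == 0) stop("no depth tracks")
  vapply(tracks, function(d) as.numeric(lower_median(d)), numeric(1))
}
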