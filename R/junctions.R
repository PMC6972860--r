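#' Parameters for coverage-drop junction detection
#'
#' The flag letters follow the original command line the procedure was run
#' with (`-a200 -b200 -c5 -d2 -f30 -e30`): `a`/`b` are the left/right flank
#' windows in bases, `c` the depth below which a position belongs to a
#' drop, `d` both the flank-to-threshold ratio (flanks must average at
#' least `d * c`) and the merge distance between nearby drops, and `e`/`f`
#' the start/end exclusion zones where contig-end coverage ramps are
#' expected.
#'
#' @param a,b Flank windows (bases).
#' @param c Drop depth threshold (fold).
#' @param d Flank-to-threshold ratio, also the run merge distance.
#' @param e,f Start/end exclusion zones (bases).
#' @return A `junction_params` object.
#' @export
junction_params <- function(a = 200, b = 200, c = 5, d = 2, e = 30, f = 30) {
  p <- list(a = as.integer(a), b = as.integer(b), c = as.numeric(c),
            d = as.numeric(d), e = as.integer(e), f = as.integer(f))
  if (p$a < 1 || p$b < 1) stop("flank windows a, b must be >= 1")
  if (p$c < 1) stop("drop threshold c must be >= 1")
  if (p$d < 1) stop("flank ratio d must be >= 1")
  if (p$e < 0 || p$f < 0) stop("exclusion zones e, f must be >= 0")
  structure(p, class = "junction_params")
}

#' Detect unexpected coverage drops (candidate misjoins)
#'
#' A junction call is a maximal run of positions with depth below `c` that
#' lies wholly inside `[e, length - f)` and whose `a`-base left flank and
#' `b`-base right flank (truncated at the exclusion zones) both average at
#' least `d * c`. Runs separated by fewer than `d` bases are merged before
#' the flanks are evaluated. Contigs shorter than `a + b + e + f` yield no
#' calls.
#'
#' @param tracks A `depth_tracks` object, or a single integer depth vector
#'   (then `contig` names the track).
#' @param params A [junction_params()].
#' @param contig Contig name when `tracks` is a bare vector.
#' @return Data.frame of calls: `contig`, `start`, `end` (0-based half-open
#'   low-coverage run), `left_mean`, `right_mean`, `min_depth`.
#' @export
detect_junctions <- function(tracks, params = junction_params(),
                             contig = "contig") {
  if (!inherits(tracks, "depth_tracks") && is.numeric(tracks))
    tracks <- structure(setNames(list(as.integer(tracks)), contig),
                        class = "depth_tracks")
  out <- lapply(names(tracks), function(cn)
    detect_junctions_one(tracks[[cn]], cn, params))
  do.call(rbind, c(out, list(empty_junction_calls())))
}

empty_junction_calls <- function() {
  data.frame(contig = character(0), start = integer(0), end = integer(0),
             left_mean = numeric(0), right_mean = numeric(0),
             min_depth = numeric(0))
}

detect_junctions_one <- function(depth, cn, p) {
  len <- length(depth)
  if (len <= p$a + p$b + p$e + p$f) return(empty_junction_calls())
  low <- depth < p$c
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths            # 0-based run starts
  rs <- starts[r$values]; re <- ends[r$values]
  if (length(rs) == 0) return(empty_junction_calls())
  # merge runs separated by < d bases
  if (length(rs) > 1) {
    gap <- rs[-1] - re[-length(re)]
    grp <- cumsum(c(0, as.integer(gap >= p$d)))
    rs <- unname(tapply(rs, grp, min)); re <- unname(tapply(re, grp, max))
    o <- order(rs); rs <- rs[o]; re <- re[o]
  }
  keep_s <- integer(0); keep_e <- integer(0)
  lm <- numeric(0); rm_ <- numeric(0); md <- numeric(0)
  for (i in seq_along(rs)) {
    s <- rs[i]; e <- re[i]
    if (s < p$e || e > len - p$f) next          # touches an exclusion zone
    lf_s <- max(p$e, s - p$a); lf_e <- s
    rf_s <- e; rf_e <- min(len - p$f, e + p$b)
    if (lf_e <= lf_s || rf_e <= rf_s) next
    left_mean <- mean(depth[(lf_s + 1):lf_e])
    right_mean <- mean(depth[(rf_s + 1):rf_e])
    if (min(left_mean, right_mean) < p$d * p$c) next
    keep_s <- c(keep_s, s); keep_e <- c(keep_e, e)
    lm <- c(lm, left_mean); rm_ <- c(rm_, right_mean)
    md <- c(md, min(depth[(s + 1):e]))
  }
  if (length(keep_s) == 0) return(empty_junction_calls())
  data.frame(contig = cn, start = as.integer(keep_s),
             end = as.integer(keep_e), left_mean = lm, right_mean = rm_,
             min_depth = md)
}

#' Break contigs at junction calls
#'
#' Each contig is cut at its calls with the low-coverage run itself removed
#' (bases with sub-threshold read support are unreliable); pieces are named
#' `<contig>.1`, `.2`, ... left to right. Pieces shorter than `min_piece`
#' are dropped and logged; contigs without calls pass through unchanged
#' under their original names. Overlapping calls on one contig are merged
#' before cutting.
#'
#' @param contigs Contig set.
#' @param calls Junction calls ([detect_junctions()]).
#' @param min_piece Minimum piece length retained.
#' @return List: `contigs` (`DNAStringSet` of pieces), `removed` (BED-style
#'   data.frame of the excised intervals), `dropped` (data.frame of pieces
#'   below `min_piece`: `piece`, `contig`, `start`, `end`).
#' @export
break_contigs <- function(contigs, calls, min_piece = 1000) {
  contigs <- as_contigs(contigs)
  if (nrow(calls) > 0 && !all(calls$contig %in% names(contigs)))
    stop("junction calls reference unknown contigs")
  out_names <- character(0); out_seqs <- character(0)
  removed <- list(); dropped <- list()
  for (cn in names(contigs)) {
    cc <- calls[calls$contig == cn, , drop = FALSE]
    if (nrow(cc) == 0) {
      out_names <- c(out_names, cn)
      out_seqs <- c(out_seqs, as.character(contigs[[cn]]))
      next
    }
    iv <- merge_intervals(cc$start, cc$end)
    removed[[cn]] <- data.frame(contig = cn, start = iv$start, end = iv$end)
    len <- Biostrings::width(contigs)[match(cn, names(contigs))]
    piece_s <- c(0L, iv$end)
    piece_e <- c(iv$start, len)
    seq_chr <- as.character(contigs[[cn]])
    for (i in seq_along(piece_s)) {
      pname <- paste0(cn, ".", i)
      ps <- piece_s[i]; pe <- piece_e[i]
      if (pe - ps >= min_piece) {
        out_names <- c(out_names, pname)
        out_seqs <- c(out_seqs, substr(seq_chr, ps + 1L, pe))
      } else {
        dropped[[length(dropped) + 1L]] <-
          data.frame(piece = pname, contig = cn, start = ps, end = pe)
      }
    }
  }
  list(contigs = Biostrings::DNAStringSet(setNames(out_seqs, out_names)),
       removed = do.call(rbind, c(removed, list(
         data.frame(contig = character(0), start = integer(0),
                    end = integer(0))))),
       dropped = do.call(rbind, c(dropped, list(
         data.frame(piece = character(0), contig = character(0),
                    start = integer(0), end = integer(0))))))
}

#' Write removed intervals as BED (0-based half-open)
#'
#' @param removed `removed` table from [break_contigs()].
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(removed, path) {
  writeLines(sprintf("%s\t%d\t%d", removed$contig, removed$start,
                     removed$end), path)
  invisible(path)
}

# split depth tracks the same way break_contigs splits sequences, so
# downstream stages can reuse coverage computed on the unbroken assembly
break_tracks <- function(tracks, calls, min_piece = 1000) {
  out <- list()
  for (cn in names(tracks)) {
    cc <- calls[calls$contig == cn, , drop = FALSE]
    d <- tracks[[cn]]
    if (nrow(cc) == 0) { out[[cn]] <- d; next }
    iv <- merge_intervals(cc$start, cc$end)
    piece_s <- c(0L, iv$end); piece_e <- c(iv$start, length(d))
    for (i in seq_along(piece_s)) {
      if (piece_e[i] - piece_s[i] >= min_piece)
        out[[paste0(cn, ".", i)]] <- d[(piece_s[i] + 1):piece_e[i]]
    }
  }
  structure(out, class = "depth_tracks")
}
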