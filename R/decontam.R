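#' Split contigs into consecutive classification windows
#'
#' Non-overlapping windows of `window` bases; a final remainder is kept as
#' a short fragment when it is at least `window / 2` long (enough sequence
#' to classify) and dropped otherwise. Contigs shorter than `window / 2`
#' yield no fragments. Fragment ids are `<contig>:<start0>-<end0>` in
#' 0-based half-open coordinates and are deterministic.
#'
#' @param contigs Contig set.
#' @param window Window size in bases (>= 100).
#' @return Data.frame: `fragment_id`, `contig`, `start`, `end`, `seq`.
#' @export
fragment_contigs <- function(contigs, window = 500) {
  window <- as.integer(window)
  if (window < 100) stop("window must be >= 100")
  contigs <- as_contigs(contigs)
  rows <- lapply(names(contigs), function(cn) {
    len <- Biostrings::width(contigs)[match(cn, names(contigs))]
    n_full <- len %/% window
    starts <- seq_len(n_full) * window - window
    ends <- starts + window
    rem <- len - n_full * window
    if (rem >= window / 2) {
      starts <- c(starts, n_full * window)
      ends <- c(ends, len)
    }
    if (length(starts) == 0) return(NULL)
    data.frame(fragment_id = sprintf("%s:%d-%d", cn, starts, ends),
               contig = cn, start = as.integer(starts),
               end = as.integer(ends))
  })
  frags <- do.call(rbind, rows)
  if (is.null(frags))
    return(data.frame(fragment_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      seq = character(0)))
  seqs <- as.character(contigs)
  frags$seq <- substring(seqs[frags$contig], frags$start + 1L, frags$end)
  rownames(frags) <- NULL
  frags
}

taxonomy_from_frame <- function(df) {
  taxid <- as.character(df$taxid)
  tree <- structure(list(parent = setNames(as.character(df$parent), taxid),
                         rank = setNames(as.character(df$rank), taxid),
                         name = setNames(as.character(df$name), taxid),
                         root = taxid[df$parent == df$taxid][1]),
                    class = "taxonomy_tree")
  if (is.na(tree$root)) stop("taxonomy has no root (self-parented node)")
  tree
}

#' Read a taxonomy tree
#'
#' Accepts either NCBI taxdump-style `nodes.dmp` (+ optional `names.dmp`,
#' pipe-delimited) or a simplified 4-column TSV
#' (`taxid  parent  rank  name`).
#'
#' @param nodes Path to `nodes.dmp` or the 4-column TSV.
#' @param names Optional path to `names.dmp` (scientific names).
#' @return A `taxonomy_tree`: list with named character maps `parent`,
#'   `rank`, `name` and the `root` taxid.
#' @export
read_taxonomy <- function(nodes, names = NULL) {
  first <- readLines(nodes, n = 1L)
  if (grepl("\\|", first)) {
    fields <- strsplit(readLines(nodes), "\t\\|\t?")
    taxid <- vapply(fields, `[[`, character(1), 1)
    parent <- vapply(fields, `[[`, character(1), 2)
    rank <- vapply(fields, `[[`, character(1), 3)
    nm <- taxid
    if (!is.null(names)) {
      nf <- strsplit(readLines(names), "\t\\|\t?")
      sci <- vapply(nf, function(x)
        if (length(x) >= 4 && grepl("scientific name", x[4])) x[1]
        else NA_character_, character(1))
      lbl <- vapply(nf, `[[`, character(1), 2)
      keep <- !is.na(sci)
      nm <- setNames(lbl[keep], sci[keep])[taxid]
      nm[is.na(nm)] <- taxid[is.na(nm)]
    }
    df <- data.frame(taxid = taxid, parent = parent, rank = trimws(rank),
                     name = trimws(unname(nm)))
  } else {
    df <- read.table(nodes, sep = "\t", header = FALSE, quote = "",
                     col.names = c("taxid", "parent", "rank", "name"),
                     colClasses = "character")
  }
  taxonomy_from_frame(df)
}

#' Write a taxonomy tree as simplified 4-column TSV
#'
#' @param tree A `taxonomy_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy_tsv <- function(tree, path) {
  ids <- names(tree$parent)
  writeLines(paste(ids, tree$parent[ids], tree$rank[ids], tree$name[ids],
                   sep = "\t"), path)
  invisible(path)
}

#' Resolve taxon ids to their superkingdom
#'
#' Walks parent links from each taxid to the root and returns the name of
#' the first ancestor (the taxid itself included) whose rank is
#' `superkingdom`. Unknown taxids, and lineages reaching the root without a
#' superkingdom (e.g. assignments at "cellular organisms" or the root),
#' resolve to `"unclassified"`.
#'
#' @param taxid Vector of taxon ids.
#' @param tree A `taxonomy_tree`.
#' @return Character vector in
#'   `{Bacteria, Archaea, Eukaryota, Viruses, unclassified}`.
#' @export
resolve_superkingdom <- function(taxid, tree) {
  cache <- new.env(parent = emptyenv())
  resolve_one <- function(id) {
    id <- as.character(id)
    if (!is.na(id) && !is.null(cache[[id]])) return(cache[[id]])
    chain <- character(0)
    cur <- id
    label <- "unclassified"
    while (!is.na(cur) && cur %in% names(tree$parent)) {
      if (cur %in% chain)
        stop("cyclic parent links in taxonomy at taxid ", cur)
      chain <- c(chain, cur)
      if (identical(tree$rank[[cur]], "superkingdom")) {
        label <- tree$name[[cur]]
        break
      }
      nxt <- tree$parent[[cur]]
      if (identical(nxt, cur)) break    # root self-loop
      cur <- nxt
    }
    for (c_ in chain) cache[[c_]] <- label
    label
  }
  vapply(taxid, resolve_one, character(1), USE.NAMES = FALSE)
}

#' Canonical tetranucleotide frequency profile
#'
#' Counts of the 136 canonical 4-mer classes (each 4-mer pooled with its
#' reverse complement) over A/C/G/T windows, normalised to sum 1; a
#' sequence and its reverse complement give identical profiles.
#'
#' @param sequence A `DNAString`, single-element `DNAStringSet`, or
#'   character string of length >= 4.
#' @return Named numeric vector of 136 canonical 4-mer frequencies.
#' @export
tetranucleotide_profile <- function(sequence) {
  if (inherits(sequence, "DNAStringSet")) sequence <- sequence[[1]]
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  if (length(sequence) < 4) stop("sequence shorter than 4 bases")
  counts <- Biostrings::oligonucleotideFrequency(sequence, width = 4)
  map <- tetra_canonical_map()
  v <- tapply(as.numeric(counts), map[names(counts)], sum)
  tot <- sum(v)
  if (tot == 0) stop("no valid A/C/G/T 4-mer window")
  v[] <- v / tot
  v[sort(names(v))]
}

tetra_canonical_map <- local({
  map <- NULL
  function() {
    if (!is.null(map)) return(map)
    kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 4)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(kmers)))
    map <<- setNames(pmin(kmers, rc), kmers)
    map
  }
})

#' Screen contigs against four contamination criteria
#'
#' Per contig: the fraction of classified fragments resolving to Bacteria
#' (the decisive criterion - a contig is dropped iff strictly more than
#' half of its classified fragments are bacterial), plus three
#' corroborative descriptors that never drive the verdict: GC content
#' (A/C/G/T only), median read coverage, and a tetranucleotide distance
#' z-score against the length-weighted mean profile of the whole set
#' (standardised robustly with median/MAD so a minority of outlying
#' contaminant profiles cannot inflate the scale they are judged against).
#' Viral assignments count as classified but never toward exclusion
#' (endogenous viral elements are expected in these genomes).
#'
#' @param contigs Contig set.
#' @param classifications Classifier table (data.frame `status`,
#'   `fragment_id`, `taxid`) or path to the 3-column TSV.
#' @param tree A `taxonomy_tree`.
#' @param coverage Optional named per-contig median coverage
#'   ([median_contig_coverage()]).
#' @return A `contig_screen` data.frame: `contig`, `n_fragments`,
#'   `n_classified`, `n_bacterial`, `frac_bacterial`, `gc`,
#'   `median_coverage`, `tetra_distance_z`, `verdict`, `reason`.
#' @export
screen_contigs <- function(contigs, classifications, tree,
                           coverage = NULL) {
  contigs <- as_contigs(contigs)
  if (is.character(classifications) && length(classifications) == 1L)
    classifications <- read.table(classifications, sep = "\t",
                                  header = FALSE,
                                  col.names = c("status", "fragment_id",
                                                "taxid"))
  cl <- classifications
  frag_contig <- sub(":[0-9]+-[0-9]+$", "", cl$fragment_id)
  if (!all(frag_contig %in% names(contigs)))
    stop("classified fragment(s) reference unknown contigs: ",
         paste(head(unique(frag_contig[!(frag_contig %in% names(contigs))])),
               collapse = ", "))
  sk <- rep("unclassified", nrow(cl))
  is_c <- cl$status == "C"
  sk[is_c] <- resolve_superkingdom(cl$taxid[is_c], tree)

  profiles <- lapply(seq_along(contigs), function(i)
    tetranucleotide_profile(contigs[[i]]))
  pm <- do.call(rbind, profiles)
  w <- as.numeric(Biostrings::width(contigs))
  centre <- colSums(pm * (w / sum(w)))
  dist <- sqrt(rowSums((pm - rep(centre, each = nrow(pm)))^2))
  # robust standard score: median/MAD so a minority of outlying
  # (contaminant) profiles cannot inflate the scale they are judged against
  scale_ <- stats::mad(dist)
  if (!is.finite(scale_) || scale_ == 0) scale_ <- sd(dist)
  z <- if (length(dist) > 1 && is.finite(scale_) && scale_ > 0)
    (dist - median(dist)) / scale_ else rep(0, length(dist))

  gc <- Biostrings::letterFrequency(contigs, "GC") /
    pmax(Biostrings::letterFrequency(contigs, "ACGT"), 1)

  rows <- lapply(seq_along(contigs), function(i) {
    cn <- names(contigs)[i]
    idx <- frag_contig == cn
    n_frag <- sum(idx)
    skc <- sk[idx]
    n_classified <- sum(skc %in% c("Bacteria", "Archaea", "Eukaryota",
                                   "Viruses"))
    n_bacterial <- sum(skc == "Bacteria")
    frac <- if (n_classified > 0) n_bacterial / n_classified else 0
    drop <- n_classified > 0 && frac > 0.5
    reason <- if (n_classified == 0) "unclassified"
      else sprintf("bacterial fraction %.2f %s 0.5", frac,
                   ifelse(drop, ">", "<="))
    data.frame(contig = cn, n_fragments = n_frag,
               n_classified = n_classified, n_bacterial = n_bacterial,
               frac_bacterial = frac, gc = as.numeric(gc[i]),
               median_coverage =
                 if (!is.null(coverage) && cn %in% names(coverage))
                   as.numeric(coverage[[cn]]) else NA_real_,
               tetra_distance_z = z[i],
               verdict = ifelse(drop, "drop", "keep"), reason = reason)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("contig_screen", class(out))
  out
}

#' Partition an assembly by screening verdict
#'
#' @param contigs Contig set.
#' @param screens A `contig_screen` table covering every contig.
#' @return List: `kept` and `dropped` (`DNAStringSet`s partitioning the
#'   input exactly) and `report` (the screen table).
#' @export
apply_decontamination <- function(contigs, screens) {
  contigs <- as_contigs(contigs)
  if (!all(names(contigs) %in% screens$contig))
    stop("screens do not cover all contigs")
  verdict <- screens$verdict[match(names(contigs), screens$contig)]
  list(kept = contigs[verdict == "keep"],
       dropped = contigs[verdict == "drop"],
       report = screens)
}

#' Write a screening report as TSV
#'
#' @param screens A `contig_screen` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen_tsv <- function(screens, path) {
  write.table(screens, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
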