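#' Built-in validation scenarios
#'
#' Each `benchmark_*` function generates a synthetic dataset at the design
#' conditions the pipeline was built for, runs the corresponding curation
#' stage end to end, and measures recovery against the planted truth.
#' They are used by the test suite and by `scripts/acceptance.R`; all
#' randomness flows from the single `seed` argument.
#'
#' @param seed Integer seed.
#' @name benchmarks
NULL

#' @describeIn benchmarks Haploid genome-size recovery from the 19-mer
#'   spectrum of a 5 Mbp diploid (het 0.005, GC 0.70) sequenced at 60x
#'   with error-free 300 bp reads.
#' @export
benchmark_genome_size <- function(seed = 1) {
  g <- generate_genome(genome_spec(haploid_size = 5e6, gc_target = 0.70,
                                   het_rate = 0.005, seed = seed))
  diploid <- c(g$haplotypes$A, g$haplotypes$B)
  sim <- simulate_reads(diploid, read_sim_spec(read_length = 300,
                                               coverage = 60,
                                               error_rate = 0,
                                               seed = seed + 1))
  hist <- count_canonical_kmers(sim$reads, k = 19)
  est <- estimate_genome_size(hist)
  list(estimate = est, true_haploid_size = g$truth$true_haploid_size,
       rel_error = abs(est$haploid_size - g$truth$true_haploid_size) /
         g$truth$true_haploid_size,
       peak_ratio = est$heterozygous_peak_coverage /
         est$homozygous_peak_coverage)
}

#' @describeIn benchmarks Junction recovery: 20 chimeras planted among 100
#'   clean 10 kb contigs, 30x simulated alignments, default parameters.
#' @export
benchmark_junctions <- function(seed = 1) {
  set.seed(seed)
  n_src <- 140L   # 40 become 20 chimeras, 100 stay clean
  seqs <- vapply(seq_len(n_src), function(i) random_dna(10000, 0.5),
                 character(1))
  sources <- Biostrings::DNAStringSet(setNames(
    seqs, sprintf("src%03d", seq_len(n_src))))
  ch <- make_chimeras(sources, 20, seed = seed + 1)
  sim <- simulate_reads(sources, read_sim_spec(read_length = 150,
                                               coverage = 30,
                                               seed = seed + 2))
  sam <- emit_alignments(sim, ch$contigs, liftover = ch$liftover)
  tracks <- depth_from_alignments(sam)
  calls <- detect_junctions(tracks)
  br <- break_contigs(ch$contigs, calls)

  hit <- vapply(seq_len(nrow(ch$junctions)), function(j) {
    rem <- br$removed[br$removed$contig == ch$junctions$contig[j], ,
                      drop = FALSE]
    any(rem$start <= ch$junctions$start[j] &
        rem$end >= ch$junctions$end[j])
  }, logical(1))
  false_calls <- sum(vapply(seq_len(nrow(calls)), function(i) {
    tj <- ch$junctions[ch$junctions$contig == calls$contig[i], ,
                       drop = FALSE]
    nrow(tj) == 0 || min(abs(tj$start - calls$start[i])) > 500
  }, logical(1)))
  conserved <- sum(Biostrings::width(br$contigs)) +
    sum(br$removed$end - br$removed$start) +
    sum(br$dropped$end - br$dropped$start) ==
    sum(Biostrings::width(ch$contigs))
  list(n_junctions = nrow(ch$junctions), n_calls = nrow(calls),
       recall = mean(hit), false_calls = false_calls,
       base_conserved = conserved)
}

#' @describeIn benchmarks Decontamination precision/recall on a host +
#'   20-contaminant assembly under a given classifier accuracy and
#'   unclassified rate.
#' @export
benchmark_decontam <- function(seed = 1, accuracy = 0.9,
                               unclassified_rate = 0.2) {
  g <- generate_genome(genome_spec(haploid_size = 6e5, n_chromosomes = 30,
                                   rdna_copies = 4,
                                   rdna_unit_length = 2000,
                                   contaminant_count = 20,
                                   contaminant_length = 10000,
                                   seed = seed))
  asm <- c(g$haplotypes$A, g$contaminants)
  frags <- fragment_contigs(asm)
  tab <- emit_classifier_table(frags, g$truth, accuracy = accuracy,
                               unclassified_rate = unclassified_rate,
                               seed = seed + 1)
  sc <- screen_contigs(asm, tab, synthetic_taxonomy())
  dec <- apply_decontamination(asm, sc)
  dropped <- names(dec$dropped)
  truth_pos <- g$truth$contaminant_ids
  tp <- length(intersect(dropped, truth_pos))
  precision <- if (length(dropped)) tp / length(dropped) else 1
  recall <- tp / length(truth_pos)
  list(precision = precision, recall = recall,
       n_dropped = length(dropped), n_contaminants = length(truth_pos))
}

#' @describeIn benchmarks Exact recovery of planted circular end overlaps
#'   (50-2000 bp) plus idempotence and rotation/strand invariance of the
#'   restart.
#' @export
benchmark_mito <- function(seed = 1) {
  set.seed(seed)
  circle <- random_dna(15000, 0.35)
  anchor <- substr(circle, 1, 200)
  overlaps <- c(50, 100, 250, 500, 1000, 2000)
  exact <- vapply(overlaps, function(L) {
    rot <- sample.int(15000, 1) - 1
    lin <- paste0(substr(circle, rot + 1, 15000), substr(circle, 1, rot))
    lin <- paste0(lin, substr(lin, 1, L))
    tr <- circ_trim(Biostrings::DNAStringSet(c(m = lin)))
    idem <- circ_trim(tr$contig)$curation$overlap_trimmed == 0
    rs <- circ_restart(tr$contig, anchor)
    tr$curation$overlap_trimmed == L && idem &&
      identical(as.character(rs$contig[[1]]), circle)
  }, logical(1))
  # strand invariance: flipped presentation normalises to the same bytes
  flipped <- revcomp(paste0(substr(circle, 3001, 15000),
                            substr(circle, 1, 3000)))
  rs <- circ_restart(Biostrings::DNAStringSet(c(m = flipped)), anchor)
  list(overlaps = overlaps, recovery_rate = mean(exact),
       strand_invariant = identical(as.character(rs$contig[[1]]), circle))
}

#' @describeIn benchmarks rDNA copy-number recovery for a planted tandem
#'   array of `copies` units under uniform 100x coverage of the true
#'   genome, aligned onto the collapsed (single-unit) assembly.
#' @export
benchmark_rdna <- function(seed = 1, copies = 20) {
  set.seed(seed)
  unit_len <- 3000L; flank <- 40000L
  unit <- random_dna(unit_len, 0.5)
  fl <- random_dna(flank, 0.5); fr <- random_dna(flank, 0.5)
  true_ctg <- Biostrings::DNAStringSet(c(
    arr = paste0(fl, paste(rep(unit, copies), collapse = ""), fr)))
  asm <- Biostrings::DNAStringSet(c(arr = paste0(fl, unit, fr)))
  lift <- rbind(
    data.frame(src = "arr", src_start = 0L, src_end = flank,
               dst = "arr", dst_start = 0L),
    data.frame(src = "arr",
               src_start = flank + (seq_len(copies) - 1L) * unit_len,
               src_end = flank + seq_len(copies) * unit_len,
               dst = "arr", dst_start = flank),
    data.frame(src = "arr", src_start = flank + copies * unit_len,
               src_end = flank + copies * unit_len + flank,
               dst = "arr", dst_start = flank + unit_len))
  sim <- simulate_reads(true_ctg, read_sim_spec(read_length = 150,
                                                coverage = 100,
                                                seed = seed + 1))
  sam <- emit_alignments(sim, asm, liftover = lift)
  tracks <- depth_from_alignments(sam)
  ann <- operon_annotation("arr", flank, flank + unit_len)
  est <- operon_copy_number(tracks, ann, n_backbone = 1)
  list(true_copies = copies, estimate = est$haploid_copies,
       rel_error = abs(est$haploid_copies - copies) / copies)
}

#' @describeIn benchmarks Self-ANI (must be exactly 100) and the ANI of a
#'   copy carrying 1% i.i.d. substitutions.
#' @export
benchmark_ani <- function(seed = 1) {
  set.seed(seed)
  g <- Biostrings::DNAStringSet(c(
    g1 = random_dna(100000, 0.7), g2 = random_dna(100000, 0.7)))
  self <- ani(g, g)
  mut <- Biostrings::DNAStringSet(setNames(vapply(
    as.character(g), function(s)
      substitute_bases(s, rbinom(1, nchar(s), 0.01))$seq, character(1)),
    names(g)))
  div <- ani(g, mut)
  list(self_ani = self$ani_percent, divergent_ani = div$ani_percent)
}
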