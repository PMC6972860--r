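#' Specification of a synthetic genome
#'
#' Describes the synthetic study system the curation pipeline assumes: a
#' diploid, high-GC nuclear genome with heterozygous substitutions, one
#' tandem rDNA array of known copy number, a circular mitochondrial replicon
#' emitted as a linear contig with duplicated ends, and AT-shifted bacterial
#' contaminant contigs. Defaults mirror the organism the toolkit was built
#' for: ~70% GC, diploid, heterozygosity 0.005, rDNA copy number within the
#' 18-83 range observed across strains.
#'
#' @param haploid_size Haploid nuclear genome size in bases.
#' @param gc_target Nuclear GC content as a fraction in `[0, 1]`.
#' @param het_rate Heterozygous substitutions per base between haplotypes.
#' @param rdna_unit_length Length in bases of one rDNA operon repeat unit.
#' @param rdna_copies Tandem copies of the unit per haploid genome.
#' @param mito_length Length of the circular mitochondrial genome.
#' @param mito_end_overlap Bases of the circle duplicated at the end of the
#'   emitted linear mitochondrial contig (must be `< mito_length`).
#' @param contaminant_count Number of bacterial contaminant contigs.
#' @param contaminant_length Length of each contaminant contig.
#' @param contaminant_gc GC fraction of contaminant contigs.
#' @param n_chromosomes Number of nuclear chromosomes the haploid genome is
#'   split into.
#' @param seed Integer seed; a fixed seed gives byte-identical outputs.
#' @return A `genome_spec` object (validated list).
#' @export
genome_spec <- function(haploid_size = 5e6, gc_target = 0.70,
                        het_rate = 0.005, rdna_unit_length = 5000,
                        rdna_copies = 20, mito_length = 40000,
                        mito_end_overlap = 500, contaminant_count = 10,
                        contaminant_length = 20000, contaminant_gc = 0.45,
                        n_chromosomes = 8, seed = 42) {
  spec <- list(haploid_size = as.numeric(haploid_size),
               gc_target = gc_target, het_rate = het_rate,
               rdna_unit_length = as.integer(rdna_unit_length),
               rdna_copies = as.integer(rdna_copies),
               mito_length = as.integer(mito_length),
               mito_end_overlap = as.integer(mito_end_overlap),
               contaminant_count = as.integer(contaminant_count),
               contaminant_length = as.integer(contaminant_length),
               contaminant_gc = contaminant_gc,
               n_chromosomes = as.integer(n_chromosomes),
               seed = as.integer(seed))
  if (spec$haploid_size <= 0) stop("haploid_size must be > 0")
  if (gc_target < 0 || gc_target > 1) stop("gc_target must be in [0, 1]")
  if (het_rate < 0 || het_rate >= 1) stop("het_rate must be in [0, 1)")
  if (spec$mito_end_overlap >= spec$mito_length)
    stop("mito_end_overlap must be smaller than mito_length")
  if (spec$rdna_copies * as.numeric(spec$rdna_unit_length) >
      spec$haploid_size)
    stop("contradictory spec: rDNA array larger than the haploid genome")
  if (spec$n_chromosomes < 1) stop("n_chromosomes must be >= 1")
  structure(spec, class = "genome_spec")
}

#' Generate a synthetic diploid genome with planted features
#'
#' Emits two nuclear haplotypes differing only by substitutions at
#' `het_rate`, a tandem rDNA array of identical units embedded at one locus
#' of chromosome 1 (shared by both haplotypes), the mitochondrial genome
#' both as its true circle and as a linear contig whose first
#' `mito_end_overlap` bases are duplicated at its end (at a random rotation),
#' bacterial contaminant contigs with distinct GC, and a truth table
#' recording every planted feature.
#'
#' @param spec A [genome_spec()].
#' @return A `synthetic_genome` list with elements `haplotypes` (list `A`,
#'   `B` of `DNAStringSet`), `mito` (linear contig, `DNAStringSet`),
#'   `mito_circle` (character, the true circle), `contaminants`
#'   (`DNAStringSet`) and `truth` (list: `contaminant_ids`, `junctions`,
#'   `true_haploid_size`, `true_rdna_copies`, `mito_overlap`,
#'   `mito_rotation_offset`, `rdna_locus`, `mito_anchor`).
#' @export
generate_genome <- function(spec = genome_spec()) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$seed)
  array_len <- spec$rdna_copies * spec$rdna_unit_length
  base_len <- floor(spec$haploid_size / spec$n_chromosomes)
  lens <- rep(base_len, spec$n_chromosomes)
  lens[1] <- spec$haploid_size - sum(lens[-1])
  if (lens[1] <= array_len + 2000)
    stop("contradictory spec: rDNA array does not fit on chromosome 1")

  # chromosome 1 carries the rDNA array: left flank + copies x unit + right
  unit <- random_dna(spec$rdna_unit_length, spec$gc_target)
  left_len <- floor((lens[1] - array_len) / 2)
  right_len <- lens[1] - array_len - left_len
  chrom1 <- paste0(random_dna(left_len, spec$gc_target),
                   paste(rep(unit, spec$rdna_copies), collapse = ""),
                   random_dna(right_len, spec$gc_target))
  chroms <- c(chrom1,
              vapply(lens[-1], random_dna, character(1), gc = spec$gc_target))
  names(chroms) <- paste0("chr", seq_len(spec$n_chromosomes))

  # haplotype B: substitutions at het_rate, sparing the rDNA array so its
  # units stay identical across haplotypes
  hap_b <- chroms
  for (i in seq_along(chroms)) {
    excl <- if (i == 1) seq(left_len + 1L, left_len + array_len) else NULL
    n_sub <- rbinom(1, nchar(chroms[i]) - length(excl), spec$het_rate)
    hap_b[i] <- substitute_bases(chroms[i], n_sub, exclude = excl)$seq
  }
  hap_a_set <- Biostrings::DNAStringSet(setNames(chroms, paste0(names(chroms), "_A")))
  hap_b_set <- Biostrings::DNAStringSet(setNames(hap_b, paste0(names(chroms), "_B")))

  # mitochondrion: AT-rich circle, emitted linearised at a random rotation
  # with the first `mito_end_overlap` bases duplicated at the end
  mito_circle <- random_dna(spec$mito_length, 0.35)
  rot <- sample.int(spec$mito_length, 1L) - 1L
  rotated <- paste0(substr(mito_circle, rot + 1L, spec$mito_length),
                    substr(mito_circle, 1L, rot))
  mito_linear <- paste0(rotated, substr(rotated, 1L, spec$mito_end_overlap))
  mito_set <- Biostrings::DNAStringSet(c(mito = mito_linear))

  contam <- character(0)
  if (spec$contaminant_count > 0) {
    contam <- vapply(seq_len(spec$contaminant_count), function(i)
      random_dna(spec$contaminant_length, spec$contaminant_gc), character(1))
    names(contam) <- sprintf("contam_%02d", seq_len(spec$contaminant_count))
  }
  contam_set <- Biostrings::DNAStringSet(contam)

  truth <- list(
    contaminant_ids = names(contam),
    junctions = data.frame(contig = character(0), start = integer(0),
                           end = integer(0)),
    true_haploid_size = spec$haploid_size,
    true_rdna_copies = spec$rdna_copies,
    mito_overlap = spec$mito_end_overlap,
    mito_rotation_offset = rot,
    rdna_locus = list(contig = "chr1", start = left_len,
                      unit_length = spec$rdna_unit_length,
                      copies = spec$rdna_copies),
    mito_anchor = substr(mito_circle, 1L, 200L)
  )
  structure(list(haplotypes = list(A = hap_a_set, B = hap_b_set),
                 mito = mito_set, mito_circle = mito_circle,
                 contaminants = contam_set, truth = truth, spec = spec),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("Synthetic genome:", length(x$haplotypes$A), "chromosomes x 2 haplotypes,",
      sum(Biostrings::width(x$haplotypes$A)), "bp haploid;",
      length(x$contaminants), "contaminants;",
      "mito", nchar(x$mito_circle), "bp circle\n")
  invisible(x)
}

#' Assemble the contig set a curation run would start from
#'
#' Concatenates one nuclear haplotype, the linearised mitochondrial contig
#' (with its duplicated ends) and the contaminant contigs, i.e. the state of
#' a raw assembly before curation.
#'
#' @param genome A [generate_genome()] result.
#' @param haplotype Which haplotype represents the assembled sequence.
#' @return A named `DNAStringSet`.
#' @export
synthetic_assembly <- function(genome, haplotype = "A") {
  c(genome$haplotypes[[haplotype]], genome$mito, genome$contaminants)
}

# identity liftover: every contig maps onto itself
identity_liftover <- function(contigs) {
  contigs <- as_contigs(contigs)
  data.frame(src = names(contigs), src_start = 0L,
             src_end = Biostrings::width(contigs),
             dst = names(contigs), dst_start = 0L)
}

#' Plant chimeric misjoins into a contig set
#'
#' Each chimera concatenates two whole source contigs drawn without
#' replacement; the join coordinate is recorded in the returned truth table.
#' Reads are later simulated from the *true* (non-chimeric) contigs, so no
#' read spans a join and planted misjoins manifest as genuine coverage gaps.
#'
#' @param contigs Source contig set.
#' @param n_chimeras Number of chimeras to plant.
#' @param seed Integer seed.
#' @return List with `contigs` (chimeras plus untouched contigs),
#'   `junctions` (data.frame `contig`, `start`, `end`: the join coordinate as
#'   a zero-width point interval), and `liftover` (block table mapping true
#'   contig coordinates onto the chimeric set, for [emit_alignments()]).
#' @export
make_chimeras <- function(contigs, n_chimeras, seed = 42) {
  contigs <- as_contigs(contigs)
  if (length(contigs) < 2) stop("need at least 2 source contigs")
  n_chimeras <- as.integer(n_chimeras)
  if (n_chimeras > floor(length(contigs) / 2))
    stop("n_chimeras exceeds available source contig pairs")
  empty <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0))
  if (n_chimeras == 0)
    return(list(contigs = contigs, junctions = empty,
                liftover = identity_liftover(contigs)))
  set.seed(seed)
  picked <- sample(names(contigs), 2L * n_chimeras)
  first <- picked[seq_len(n_chimeras)]
  second <- picked[n_chimeras + seq_len(n_chimeras)]
  keep <- setdiff(names(contigs), picked)

  chim_names <- sprintf("chimera_%02d", seq_len(n_chimeras))
  chim <- Biostrings::DNAStringSet(setNames(
    paste0(as.character(contigs[first]), as.character(contigs[second])),
    chim_names))
  w1 <- Biostrings::width(contigs)[match(first, names(contigs))]
  w2 <- Biostrings::width(contigs)[match(second, names(contigs))]
  junctions <- data.frame(contig = chim_names, start = w1, end = w1)
  liftover <- rbind(
    identity_liftover(contigs[keep]),
    data.frame(src = first, src_start = 0L, src_end = w1,
               dst = chim_names, dst_start = 0L),
    data.frame(src = second, src_start = 0L, src_end = w2,
               dst = chim_names, dst_start = w1)
  )
  list(contigs = c(contigs[keep], chim), junctions = junctions,
       liftover = liftover)
}

#' Read-simulation settings
#'
#' @param read_length Read length in bases.
#' @param coverage Fold coverage over the total bases of the supplied
#'   contig set.
#' @param error_rate I.i.d. substitution errors per base.
#' @param paired Emit synchronised mate pairs.
#' @param insert_size Outer distance between paired mates (only used when
#'   `paired = TRUE`).
#' @param seed Integer seed.
#' @return A `read_sim_spec` object.
#' @export
read_sim_spec <- function(read_length = 300, coverage = 30, error_rate = 0,
                          paired = FALSE, insert_size = NULL, seed = 42) {
  if (coverage <= 0) stop("coverage must be > 0")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  structure(list(read_length = as.integer(read_length), coverage = coverage,
                 error_rate = error_rate, paired = isTRUE(paired),
                 insert_size = as.integer(insert_size %||% (3 * read_length)),
                 seed = as.integer(seed)),
            class = "read_sim_spec")
}

#' Simulate uniform-coverage shotgun reads with known placements
#'
#' Read start positions are uniform over the supplied contigs (weighted by
#' length), strands are random, and substitution errors are i.i.d. at
#' `error_rate`. The placement table records each read's true origin, which
#' [emit_alignments()] turns into alignment records without an external
#' mapper. Base qualities are constant `I` (Q40); the curation pipeline
#' never uses them.
#'
#' @param genome Contig set reads are drawn from (the *true* genome).
#' @param spec A [read_sim_spec()].
#' @return A `read_sim` list: `reads` (named character vector, read
#'   orientation as sequenced), `placements` (data.frame `read_id`, `contig`,
#'   `start0`, `strand`, `length`, `mate`), and `spec`.
#' @export
simulate_reads <- function(genome, spec = read_sim_spec()) {
  genome <- as_contigs(genome)
  if (length(genome) == 0 || sum(Biostrings::width(genome)) == 0)
    stop("empty genome")
  rl <- spec$read_length
  if (rl > min(Biostrings::width(genome)))
    stop("read_length exceeds the shortest contig")
  set.seed(spec$seed)
  total <- sum(as.numeric(Biostrings::width(genome)))
  n_reads <- as.integer(ceiling(spec$coverage * total / rl))
  if (spec$paired) n_reads <- as.integer(2 * ceiling(n_reads / 2))

  w <- Biostrings::width(genome)
  if (spec$paired) {
    ins <- min(spec$insert_size, min(w))
    n_frag <- n_reads %/% 2L
    ci <- sample.int(length(genome), n_frag, replace = TRUE,
                     prob = pmax(w - ins + 1, 1))
    fs <- floor(runif(n_frag) * (w[ci] - ins + 1))
    start1 <- as.integer(fs)
    start2 <- as.integer(fs + ins - rl)
    contig <- rep(names(genome)[ci], each = 2)
    start0 <- as.integer(rbind(start1, start2))
    strand <- rep(c("+", "-"), n_frag)
    mate <- rep(c(1L, 2L), n_frag)
    read_id <- rep(sprintf("read%07d", seq_len(n_frag)), each = 2)
  } else {
    ci <- sample.int(length(genome), n_reads, replace = TRUE,
                     prob = pmax(w - rl + 1, 1))
    start0 <- as.integer(floor(runif(n_reads) * (w[ci] - rl + 1)))
    contig <- names(genome)[ci]
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    mate <- rep(0L, n_reads)
    read_id <- sprintf("read%07d", seq_len(n_reads))
  }

  seqs_by_contig <- as.character(genome)
  reads <- character(length(start0))
  for (cn in unique(contig)) {
    idx <- which(contig == cn)
    reads[idx] <- substring(seqs_by_contig[[cn]], start0[idx] + 1L,
                            start0[idx] + rl)
  }
  minus <- strand == "-"
  if (any(minus)) reads[minus] <- revcomp(reads[minus])
  if (spec$error_rate > 0) reads <- cpp_mutate(reads, spec$error_rate)
  names(reads) <- if (spec$paired)
    paste0(read_id, "/", mate) else read_id
  placements <- data.frame(read_id = names(reads), contig = contig,
                           start0 = start0, strand = strand,
                           length = rl, mate = mate)
  structure(list(reads = reads, placements = placements, spec = spec),
            class = "read_sim")
}

#' Write simulated reads as FASTQ
#'
#' Paired simulations are written as two synchronised files
#' (`<prefix>_1.fastq`, `<prefix>_2.fastq`); single-end as `<prefix>.fastq`.
#'
#' @param sim A [simulate_reads()] result.
#' @param prefix Output path prefix.
#' @return Character vector of the files written.
#' @export
write_fastq <- function(sim, prefix) {
  fq_block <- function(ids, seqs) {
    as.vector(rbind(paste0("@", ids), unname(seqs), "+",
                    strrep("I", nchar(seqs))))
  }
  if (sim$spec$paired) {
    m1 <- sim$placements$mate == 1L
    f1 <- paste0(prefix, "_1.fastq"); f2 <- paste0(prefix, "_2.fastq")
    writeLines(fq_block(names(sim$reads)[m1], sim$reads[m1]), f1)
    writeLines(fq_block(names(sim$reads)[!m1], sim$reads[!m1]), f2)
    c(f1, f2)
  } else {
    f <- paste0(prefix, ".fastq")
    writeLines(fq_block(names(sim$reads), sim$reads), f)
    f
  }
}

#' Turn true read placements into SAM alignment records
#'
#' Each placement whose interval lies wholly inside a single liftover block
#' yields one primary, all-match (`<len>M`) record on the corresponding
#' target contig. Reads that fit in no block - e.g. reads from the true
#' genome overlapping the boundary of a chimeric join - are omitted, which
#' is exactly how a misassembly manifests as a coverage gap in real data.
#'
#' @param placements Placement table from [simulate_reads()] (or a
#'   compatible data.frame with `read_id`, `contig`, `start0`, `strand`,
#'   `length`).
#' @param targets Target contig set the records refer to.
#' @param liftover Optional block table (`src`, `src_start`, `src_end`,
#'   `dst`, `dst_start`) mapping true-genome coordinates onto the targets;
#'   defaults to the identity on `targets`.
#' @param reads Optional named read sequences (as sequenced); when given,
#'   SAM `SEQ`/`QUAL` carry the reference-oriented sequence, otherwise `*`.
#' @return A `sam_records` list: `records` (data.frame of SAM fields),
#'   `contigs` (named lengths), `n_omitted`.
#' @export
emit_alignments <- function(placements, targets, liftover = NULL,
                            reads = NULL) {
  if (inherits(placements, "read_sim")) {
    reads <- reads %||% placements$reads
    placements <- placements$placements
  }
  targets <- as_contigs(targets)
  liftover <- liftover %||% identity_liftover(targets)
  if (!all(liftover$dst %in% names(targets)))
    stop("liftover refers to contigs absent from targets")
  known <- placements$contig %in% liftover$src
  if (!all(known))
    warning(sum(!known), " placements on contigs absent from the liftover")

  n <- nrow(placements)
  dst <- rep(NA_character_, n); dpos <- rep(NA_integer_, n)
  for (src in unique(placements$contig)) {
    blocks <- liftover[liftover$src == src, , drop = FALSE]
    if (nrow(blocks) == 0) next
    blocks <- blocks[order(blocks$src_start), , drop = FALSE]
    idx <- which(placements$contig == src)
    s <- placements$start0[idx]
    e <- s + placements$length[idx]
    bi <- findInterval(s, blocks$src_start)
    ok <- bi >= 1 & s >= blocks$src_start[bi] & e <= blocks$src_end[bi]
    hit <- idx[ok]
    dst[hit] <- blocks$dst[bi[ok]]
    dpos[hit] <- blocks$dst_start[bi[ok]] + s[ok] - blocks$src_start[bi[ok]]
  }
  mapped <- !is.na(dst)
  n_omitted <- sum(!mapped)
  p <- placements[mapped, , drop = FALSE]
  seq_field <- rep("*", nrow(p)); qual_field <- rep("*", nrow(p))
  if (!is.null(reads) && nrow(p) > 0) {
    r <- unname(reads[match(p$read_id, names(reads))])
    minus <- p$strand == "-"
    if (any(minus)) r[minus] <- revcomp(r[minus])
    seq_field <- r
    qual_field <- strrep("I", nchar(r))
  }
  k <- nrow(p)
  records <- data.frame(
    qname = p$read_id,
    flag = ifelse(p$strand == "-", 16L, 0L),
    rname = dst[mapped],
    pos = dpos[mapped] + 1L,
    mapq = rep(60L, k),
    cigar = if (k) paste0(p$length, "M") else character(0),
    rnext = rep("*", k), pnext = rep(0L, k), tlen = rep(0L, k),
    seq = seq_field, qual = qual_field)
  structure(list(records = records,
                 contigs = setNames(Biostrings::width(targets),
                                    names(targets)),
                 n_omitted = n_omitted),
            class = "sam_records")
}

#' Write SAM records to file
#'
#' @param sam A `sam_records` object (see [emit_alignments()]).
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(sam, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(sam$contigs),
                      sam$contigs))
  r <- sam$records
  body <- if (nrow(r) == 0) character(0) else
    paste(r$qname, r$flag, r$rname, r$pos, r$mapq, r$cigar, r$rnext,
          r$pnext, r$tlen, r$seq, r$qual, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Minimal taxonomy covering the four superkingdoms
#'
#' A small NCBI-style taxonomy tree with real superkingdom taxids
#' (Bacteria 2, Archaea 2157, Eukaryota 2759, Viruses 10239), a lineage of
#' intermediate ranks below Bacteria, and one representative species per
#' superkingdom, as used by [emit_classifier_table()].
#'
#' @return A `taxonomy_tree` (see [read_taxonomy()]).
#' @export
synthetic_taxonomy <- function() {
  df <- data.frame(
    taxid = c(1, 131567, 2, 1224, 543, 561, 562,
              2157, 2158, 2759, 2760, 10239, 10240),
    parent = c(1, 1, 131567, 2, 1224, 543, 561,
               131567, 2157, 131567, 2759, 1, 10239),
    rank = c("no rank", "no rank", "superkingdom", "phylum", "family",
             "genus", "species", "superkingdom", "species", "superkingdom",
             "species", "superkingdom", "species"),
    name = c("root", "cellular organisms", "Bacteria", "Proteobacteria",
             "Enterobacteriaceae", "Escherichia", "Escherichia coli",
             "Archaea", "Archaea sp.", "Eukaryota", "Eukaryota sp.",
             "Viruses", "Virus sp."))
  taxonomy_from_frame(df)
}

# representative species taxid per superkingdom in synthetic_taxonomy()
.sk_reps <- c(Bacteria = 562, Archaea = 2158, Eukaryota = 2760,
              Viruses = 10240)

#' Fabricate Kaiju-style per-fragment classifier output
#'
#' Each fragment is unclassified with probability `unclassified_rate`;
#' otherwise it receives the representative species of its *true*
#' superkingdom with probability `accuracy` and of a uniformly drawn wrong
#' superkingdom otherwise. True superkingdoms come from the truth table:
#' fragments of contaminant contigs are Bacteria, everything else Eukaryota.
#'
#' @param fragments Fragment table from [fragment_contigs()].
#' @param truth Truth table (list with `contaminant_ids`).
#' @param accuracy Probability a classified fragment gets its true
#'   superkingdom.
#' @param unclassified_rate Probability a fragment is unclassified.
#' @param seed Integer seed.
#' @return Data.frame with Kaiju-style columns `status` (`"C"`/`"U"`),
#'   `fragment_id`, `taxid` (0 for unclassified).
#' @export
emit_classifier_table <- function(fragments, truth, accuracy = 1,
                                  unclassified_rate = 0, seed = 42) {
  if (accuracy < 0 || accuracy > 1) stop("accuracy must be in [0, 1]")
  if (unclassified_rate < 0 || unclassified_rate >= 1 + 1e-12)
    stop("unclassified_rate must be in [0, 1]")
  set.seed(seed)
  n <- nrow(fragments)
  true_sk <- ifelse(fragments$contig %in% truth$contaminant_ids,
                    "Bacteria", "Eukaryota")
  uncl <- runif(n) < unclassified_rate
  correct <- runif(n) < accuracy
  sk <- true_sk
  wrong_idx <- which(!uncl & !correct)
  if (length(wrong_idx)) {
    sk[wrong_idx] <- vapply(true_sk[wrong_idx], function(s)
      sample(setdiff(names(.sk_reps), s), 1L), character(1))
  }
  taxid <- unname(.sk_reps[sk])
  taxid[uncl] <- 0L
  data.frame(status = ifelse(uncl, "U", "C"),
             fragment_id = fragments$fragment_id,
             taxid = as.integer(taxid))
}

#' Write a classifier table as 3-column TSV
#'
#' @param tab Classifier table ([emit_classifier_table()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_classifier_tsv <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a truth table as JSON
#'
#' @param truth Truth table list.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
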