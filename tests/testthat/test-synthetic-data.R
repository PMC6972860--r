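test_that("genome generation is seed-deterministic and honours the spec", {
  g1 <- small_genome(seed = 3)
  g2 <- small_genome(seed = 3)
  expect_identical(as.character(g1$haplotypes$A), as.character(g2$haplotypes$A))
  expect_identical(g1$mito_circle, g2$mito_circle)
  expect_identical(g1$truth, g2$truth)

  # het_rate = 0 gives identical haplotypes
  g0 <- small_genome(seed = 4, het_rate = 0)
  expect_identical(unname(as.character(g0$haplotypes$A)),
                   unname(as.character(g0$haplotypes$B)))

  # GC of the emitted nuclear sequence within +/- 0.02 of target
  g <- generate_genome(genome_spec(haploid_size = 5e5, gc_target = 0.70,
                                   n_chromosomes = 4, seed = 5))
  nuc <- g$haplotypes$A
  gc <- sum(Biostrings::letterFrequency(nuc, "GC")) /
    sum(Biostrings::width(nuc))
  expect_gt(gc, 0.68); expect_lt(gc, 0.72)

  # contradictory spec rejected
  expect_error(genome_spec(haploid_size = 1e4, rdna_copies = 10,
                           rdna_unit_length = 5000), "contradictory")
  expect_error(genome_spec(mito_length = 100, mito_end_overlap = 200),
               "mito_end_overlap")
})

test_that("planted genome features are verifiable in the emitted sequences", {
  g <- small_genome(seed = 8)
  tr <- g$truth
  # the tandem array really is rdna_copies identical units at the locus
  chr1 <- as.character(g$haplotypes$A[["chr1_A"]])
  unit_len <- tr$rdna_locus$unit_length
  units <- vapply(seq_len(tr$rdna_locus$copies), function(i)
    substr(chr1, tr$rdna_locus$start + (i - 1) * unit_len + 1,
           tr$rdna_locus$start + i * unit_len), character(1))
  expect_length(unique(units), 1L)
  # haplotype B shares the array exactly
  chr1b <- as.character(g$haplotypes$B[["chr1_B"]])
  expect_identical(substr(chr1b, tr$rdna_locus$start + 1,
                          tr$rdna_locus$start + unit_len * 4),
                   substr(chr1, tr$rdna_locus$start + 1,
                          tr$rdna_locus$start + unit_len * 4))
  # linear mito = rotated circle + duplicated start
  lin <- as.character(g$mito[[1]])
  n <- nchar(g$mito_circle)
  expect_identical(nchar(lin), n + tr$mito_overlap)
  expect_identical(substr(lin, n + 1, n + tr$mito_overlap),
                   substr(lin, 1, tr$mito_overlap))
  doubled <- paste0(g$mito_circle, g$mito_circle)
  expect_identical(substr(lin, 1, n),
                   substr(doubled, tr$mito_rotation_offset + 1,
                          tr$mito_rotation_offset + n))
  # haplotypes differ only by substitutions (equal lengths, ~het_rate)
  expect_identical(Biostrings::width(g$haplotypes$A),
                   Biostrings::width(g$haplotypes$B))
  diffs <- sum(vapply(seq_along(g$haplotypes$A), function(i) {
    a <- strsplit(as.character(g$haplotypes$A[[i]]), "")[[1]]
    b <- strsplit(as.character(g$haplotypes$B[[i]]), "")[[1]]
    sum(a != b)
  }, numeric(1)))
  expect_gt(diffs / 2e5, 0.003); expect_lt(diffs / 2e5, 0.007)
})

test_that("chimera planting records internal junctions and lifts coordinates", {
  contigs <- random_contigs(8, 5000, seed = 2)
  expect_identical(make_chimeras(contigs, 0)$contigs, contigs)
  expect_error(make_chimeras(contigs, 5), "exceeds")
  expect_error(make_chimeras(contigs[1], 1), "at least 2")

  ch <- make_chimeras(contigs, 3, seed = 6)
  expect_equal(nrow(ch$junctions), 3)
  w <- Biostrings::width(ch$contigs)[match(ch$junctions$contig,
                                           names(ch$contigs))]
  expect_true(all(ch$junctions$start > 0 & ch$junctions$start < w))
  # every chimera is the concatenation of its two liftover source blocks
  for (j in seq_len(3)) {
    cn <- ch$junctions$contig[j]
    blocks <- ch$liftover[ch$liftover$dst == cn, ]
    blocks <- blocks[order(blocks$dst_start), ]
    rebuilt <- paste0(as.character(contigs[[blocks$src[1]]]),
                      as.character(contigs[[blocks$src[2]]]))
    expect_identical(as.character(ch$contigs[[cn]]), rebuilt)
  }
})

test_that("read simulation hits coverage, placements and error model", {
  contigs <- random_contigs(1, 10000, seed = 3)
  sim <- simulate_reads(contigs, read_sim_spec(read_length = 300,
                                               coverage = 20, seed = 1))
  total <- sum(nchar(sim$reads))
  expect_gte(total, 0.98 * 20 * 10000)
  expect_lte(total, 1.02 * 20 * 10000)

  # error-free reads are exact substrings (modulo strand)
  seqchr <- as.character(contigs[[1]])
  p <- sim$placements[1:50, ]
  ref <- substring(seqchr, p$start0 + 1, p$start0 + p$length)
  obs <- unname(sim$reads[1:50])
  minus <- p$strand == "-"
  obs[minus] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(obs[minus])))
  expect_identical(obs, ref)

  # substitution errors appear at roughly the requested rate
  sim_e <- simulate_reads(contigs, read_sim_spec(read_length = 300,
                                                 coverage = 5,
                                                 error_rate = 0.02,
                                                 seed = 2))
  pe <- sim_e$placements
  refs <- substring(seqchr, pe$start0 + 1, pe$start0 + pe$length)
  obs <- unname(sim_e$reads)
  minus <- pe$strand == "-"
  obs[minus] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(obs[minus])))
  mm <- sum(mapply(function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]), obs, refs))
  rate <- mm / sum(nchar(obs))
  expect_gt(rate, 0.015); expect_lt(rate, 0.025)

  expect_error(simulate_reads(Biostrings::DNAStringSet(), read_sim_spec()),
               "empty")

  # paired mode: two synchronised files
  simp <- simulate_reads(contigs, read_sim_spec(read_length = 100,
                                                coverage = 2, paired = TRUE,
                                                seed = 3))
  files <- write_fastq(simp, file.path(tempdir(), "paired"))
  expect_length(files, 2)
  l1 <- readLines(files[1]); l2 <- readLines(files[2])
  expect_identical(length(l1), length(l2))
  expect_identical(sub("/[12]$", "", l1[c(TRUE, FALSE, FALSE, FALSE)]),
                   sub("/[12]$", "", l2[c(TRUE, FALSE, FALSE, FALSE)]))
})

test_that("emitted alignments follow SAM coordinate conventions", {
  target <- random_contigs(1, 1000, seed = 4, prefix = "c")
  pl <- data.frame(read_id = "r1", contig = "c01", start0 = 100,
                   strand = "+", length = 300)
  sam <- emit_alignments(pl, target)
  expect_equal(sam$records$pos, 101)          # 1-based POS
  expect_equal(sam$records$cigar, "300M")
  expect_equal(sam$records$flag, 0L)

  # empty placement table -> header-only SAM
  sam0 <- emit_alignments(pl[0, ], target)
  f <- tempfile(fileext = ".sam")
  write_sam(sam0, f)
  lines <- readLines(f)
  expect_true(all(startsWith(lines, "@")))
  expect_length(lines, 2)  # @HD + one @SQ

  # placements off the liftover blocks are omitted
  pl2 <- data.frame(read_id = c("ok", "off"), contig = "c01",
                    start0 = c(0, 900), strand = "+", length = 300)
  sam2 <- emit_alignments(pl2, target)
  expect_equal(nrow(sam2$records), 1)
  expect_equal(sam2$n_omitted, 1)
})

test_that("alignments round-trip through SAM text and depth agrees", {
  g <- random_contigs(2, 4000, seed = 5)
  sim <- simulate_reads(g, read_sim_spec(read_length = 200, coverage = 8,
                                         seed = 6))
  sam <- emit_alignments(sim, g)
  f <- tempfile(fileext = ".sam")
  write_sam(sam, f)
  back <- read_sam(f)
  expect_equal(nrow(back$records), nrow(sam$records))
  expect_identical(back$contigs,
                   setNames(Biostrings::width(g), names(g)))
  d1 <- depth_from_alignments(sam)
  d2 <- depth_from_alignments(f)
  expect_identical(lapply(d1, identity), lapply(d2, identity))
})

test_that("classifier table emulation matches its probability model", {
  g <- small_genome(seed = 12, contaminant_count = 10,
                    contaminant_length = 10000)
  frags <- fragment_contigs(g$contaminants)
  expect_gte(nrow(frags), 200)
  truth <- g$truth

  # perfect classifier: every contaminant fragment bacterial
  tab <- emit_classifier_table(frags, truth, accuracy = 1,
                               unclassified_rate = 0)
  expect_true(all(tab$status == "C"))
  tree <- toy_taxonomy()
  expect_true(all(resolve_superkingdom(tab$taxid, tree) == "Bacteria"))

  # all unclassified
  tabu <- emit_classifier_table(frags, truth, accuracy = 1,
                                unclassified_rate = 1 - 1e-12)
  expect_true(all(tabu$status == "U"))

  # accuracy 0.9 over n contaminant fragments: binomial 3-sigma band
  f1000 <- frags[rep(seq_len(nrow(frags)), length.out = 1000), ]
  f1000$fragment_id <- sprintf("%s#%d", f1000$fragment_id, seq_len(1000))
  tab9 <- emit_classifier_table(f1000, truth, accuracy = 0.9,
                                unclassified_rate = 0, seed = 21)
  nb <- sum(resolve_superkingdom(tab9$taxid, tree) == "Bacteria")
  expect_gte(nb, 870); expect_lte(nb, 930)
})
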