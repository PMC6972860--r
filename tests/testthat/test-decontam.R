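test_that("fragmentation windows and tail rule are exact", {
  ctg <- function(len) Biostrings::DNAStringSet(setNames(
    paste(rep("ACGT", ceiling(len / 4)), collapse = ""), "c"))
  f1 <- fragment_contigs(Biostrings::DNAStringSet(
    c(c = substr(paste(rep("ACGT", 320), collapse = ""), 1, 1250))))
  expect_equal(f1$start, c(0, 500, 1000))
  expect_equal(f1$end, c(500, 1000, 1250))     # 250 bp tail kept
  f2 <- fragment_contigs(Biostrings::DNAStringSet(
    c(c = substr(paste(rep("ACGT", 300), collapse = ""), 1, 1100))))
  expect_equal(nrow(f2), 2)                    # 100 bp tail dropped
  f3 <- fragment_contigs(Biostrings::DNAStringSet(
    c(c = substr(paste(rep("ACGT", 200), collapse = ""), 1, 499))))
  expect_equal(nrow(f3), 1)
  expect_equal(f3$end, 499)                    # whole short contig kept
  f4 <- fragment_contigs(Biostrings::DNAStringSet(
    c(c = substr(paste(rep("ACGT", 80), collapse = ""), 1, 200))))
  expect_equal(nrow(f4), 0)                    # < window/2: nothing
  expect_error(fragment_contigs(ctg(1000), window = 50), ">= 100")
  # fragment ids parse back to contig coordinates
  expect_equal(f1$fragment_id[2], "c:500-1000")
})

test_that("superkingdom resolution walks the lineage correctly", {
  tree <- toy_taxonomy()
  expect_equal(resolve_superkingdom(562, tree), "Bacteria")
  expect_equal(resolve_superkingdom(2, tree), "Bacteria")    # itself
  expect_equal(resolve_superkingdom(2760, tree), "Eukaryota")
  expect_equal(resolve_superkingdom(99999, tree), "unclassified")
  expect_equal(resolve_superkingdom(1, tree), "unclassified")      # root
  expect_equal(resolve_superkingdom(131567, tree), "unclassified") # above sk
  expect_equal(resolve_superkingdom(c(562, 10240, 1), tree),
               c("Bacteria", "Viruses", "unclassified"))

  # cyclic parent links are an error
  bad <- tree
  bad$parent[["543"]] <- "561"   # 561 -> 543 -> 561 cycle
  expect_error(resolve_superkingdom(562, bad), "cyclic")
})

test_that("taxonomy reads both taxdump and simplified TSV layouts", {
  tree <- toy_taxonomy()
  f <- tempfile()
  write_taxonomy_tsv(tree, f)
  tree2 <- read_taxonomy(f)
  expect_equal(resolve_superkingdom(562, tree2), "Bacteria")
  expect_equal(tree2$root, "1")

  nodes <- tempfile(); nms <- tempfile()
  writeLines(c("1\t|\t1\t|\tno rank\t|",
               "2\t|\t1\t|\tsuperkingdom\t|",
               "7\t|\t2\t|\tspecies\t|"), nodes)
  writeLines(c("1\t|\troot\t|\t\t|\tscientific name\t|",
               "2\t|\tBacteria\t|\t\t|\tscientific name\t|",
               "2\t|\teubacteria\t|\t\t|\tsynonym\t|",
               "7\t|\tBug\t|\t\t|\tscientific name\t|"), nms)
  tree3 <- read_taxonomy(nodes, nms)
  expect_equal(resolve_superkingdom(7, tree3), "Bacteria")
})

test_that("tetranucleotide profiles are canonical and normalised", {
  set.seed(19)
  s <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  p <- tetranucleotide_profile(s)
  expect_length(p, 136)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_equal(tetranucleotide_profile(rc), p)
  expect_error(tetranucleotide_profile("ACG"), "shorter")
})

test_that("screening applies the strict >50% bacterial rule", {
  tree <- toy_taxonomy()
  contigs <- random_contigs(2, 5000, seed = 20, prefix = "ctg")
  mk_cl <- function(cn, n_bact, n_euk) {
    n <- n_bact + n_euk
    data.frame(status = "C",
               fragment_id = sprintf("%s:%d-%d", cn, (0:(n - 1)) * 500,
                                     (1:n) * 500),
               taxid = c(rep(562, n_bact), rep(2760, n_euk)))
  }
  # 6/10 bacterial -> drop; exactly 5/10 -> keep (strict inequality)
  cl <- rbind(mk_cl("ctg01", 6, 4), mk_cl("ctg02", 5, 5))
  sc <- screen_contigs(contigs, cl, tree)
  expect_equal(setNames(sc$verdict, sc$contig),
               c(ctg01 = "drop", ctg02 = "keep"))
  expect_equal(sc$frac_bacterial, c(0.6, 0.5))

  # unclassified-only contig: keep, flagged
  sc0 <- screen_contigs(contigs[1], cl[0, ], tree)
  expect_equal(sc0$verdict, "keep")
  expect_equal(sc0$reason, "unclassified")
  expect_equal(sc0$n_classified, 0)

  # viral fragments count as classified but never toward exclusion
  clv <- mk_cl("ctg01", 4, 0)
  clv$taxid[1:2] <- 10240          # two of four now viral
  scv <- screen_contigs(contigs[1], clv, tree)
  expect_equal(scv$n_classified, 4)
  expect_equal(scv$n_bacterial, 2)
  expect_equal(scv$verdict, "keep")

  # unknown contig in a fragment id is an error
  expect_error(screen_contigs(contigs, mk_cl("ghost", 1, 1), tree),
               "unknown contigs")

  # monotonicity: converting eukaryotic fragments to bacterial can only
  # move a contig toward (never away from) exclusion
  for (nb in 0:9) {
    sc_a <- screen_contigs(contigs[1], mk_cl("ctg01", nb, 10 - nb), tree)
    sc_b <- screen_contigs(contigs[1], mk_cl("ctg01", nb + 1, 9 - nb), tree)
    expect_false(sc_a$verdict == "drop" && sc_b$verdict == "keep")
  }
})

test_that("contamination separates on composition, coverage and taxonomy", {
  g <- small_genome(seed = 21, n_chromosomes = 12,
                    haploid_size = 6e5, contaminant_count = 2,
                    contaminant_length = 20000)
  asm <- c(g$haplotypes$A, g$contaminants)
  frags <- fragment_contigs(asm)
  tab <- emit_classifier_table(frags, g$truth, accuracy = 1,
                               unclassified_rate = 0)
  cov <- setNames(c(rep(30, 12), rep(5, 2)), names(asm))
  sc <- screen_contigs(asm, tab, toy_taxonomy(), coverage = cov)

  is_contam <- sc$contig %in% g$truth$contaminant_ids
  # taxonomy: perfect classifier leads to perfect partition
  expect_true(all(sc$verdict[is_contam] == "drop"))
  expect_true(all(sc$verdict[!is_contam] == "keep"))
  # GC criterion agrees
  expect_true(all(sc$gc[is_contam] < 0.5))
  expect_true(all(sc$gc[!is_contam] > 0.65))
  # tetranucleotide criterion agrees (robust z over host-dominated set)
  expect_true(all(sc$tetra_distance_z[is_contam] > 3))
  expect_true(all(sc$tetra_distance_z[!is_contam] < 3))
  # coverage criterion agrees (4-fold separation preserved in the report)
  expect_true(all(sc$median_coverage[is_contam] * 4 <=
                  min(sc$median_coverage[!is_contam])))

  dec <- apply_decontamination(asm, sc)
  # partition property: kept + dropped = input exactly
  expect_setequal(c(names(dec$kept), names(dec$dropped)), names(asm))
  expect_equal(sum(Biostrings::width(dec$kept)) +
               sum(Biostrings::width(dec$dropped)),
               sum(Biostrings::width(asm)))
  expect_setequal(names(dec$dropped), g$truth$contaminant_ids)

  # an all-bacterial assembly keeps nothing
  sc_c <- screen_contigs(g$contaminants,
                         tab[grepl("^contam", tab$fragment_id), ],
                         toy_taxonomy())
  dec_c <- apply_decontamination(g$contaminants, sc_c)
  expect_length(dec_c$kept, 0)

  # no classifications at all: nothing dropped
  sc_u <- screen_contigs(asm, tab[0, ], toy_taxonomy())
  expect_length(apply_decontamination(asm, sc_u)$dropped, 0)
})
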