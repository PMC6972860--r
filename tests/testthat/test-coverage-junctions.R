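test_that("depth accumulation follows the per-base pileup conventions", {
  # single record POS=101, 300M on a 1000 bp contig
  sam <- structure(list(
    records = data.frame(qname = "r", flag = 0L, rname = "c", pos = 101L,
                         mapq = 60L, cigar = "300M", seq = "*", qual = "*"),
    contigs = c(c = 1000L)), class = "sam_records")
  d <- depth_from_alignments(sam)[["c"]]
  expect_equal(sum(d), 300)
  expect_true(all(d[101:400] == 1))
  expect_true(all(d[c(1:100, 401:1000)] == 0))

  # deletions consume reference without adding depth
  sam$records$cigar <- "50M10D50M"
  sam$records$pos <- 1L
  d <- depth_from_alignments(sam)[["c"]]
  expect_true(all(d[1:50] == 1))
  expect_true(all(d[51:60] == 0))
  expect_true(all(d[61:110] == 1))

  # soft clips consume query only
  sam$records$cigar <- "10S80M"
  d <- depth_from_alignments(sam)[["c"]]
  expect_equal(which(d == 1), 1:80)

  # secondary/supplementary/unmapped records do not contribute
  sam$records <- data.frame(qname = c("a", "b", "c"),
                            flag = c(256L, 2048L, 4L), rname = "c",
                            pos = 1L, mapq = 60L, cigar = "100M",
                            seq = "*", qual = "*")
  expect_equal(sum(depth_from_alignments(sam)[["c"]]), 0)

  # unknown targets are an error that names the contig
  sam$records <- data.frame(qname = "r", flag = 0L, rname = "nope",
                            pos = 1L, mapq = 60L, cigar = "10M",
                            seq = "*", qual = "*")
  expect_error(depth_from_alignments(sam), "nope")

  # malformed CIGARs are skipped with a warning, not counted
  sam$records <- data.frame(qname = c("ok", "bad"), flag = 0L, rname = "c",
                            pos = 1L, mapq = 60L,
                            cigar = c("100M", "10Q"), seq = "*", qual = "*")
  expect_warning(d <- depth_from_alignments(sam), "skipped")
  expect_equal(sum(d[["c"]]), 100)
})

test_that("PAF records add depth over their target interval", {
  f <- tempfile(fileext = ".paf")
  writeLines(paste("q1", 300, 0, 300, "+", "t1", 1000, 100, 400, 300, 300,
                   60, sep = "\t"), f)
  d <- depth_from_alignments(f)
  expect_true(all(d[["t1"]][101:400] == 1))
  expect_equal(sum(d[["t1"]]), 300)
})

test_that("median coverage uses the lower median", {
  expect_equal(unname(median_contig_coverage(as_tracks(
    a = rep(30L, 10)))), 30)
  expect_equal(unname(median_contig_coverage(as_tracks(
    a = c(0L, 0L, 10L, 10L)))), 0)
  expect_error(median_contig_coverage(list()), "no depth")
})

test_that("junction detection calls constructed drops and honours exclusions", {
  p <- junction_params()
  # uniform coverage: no calls
  expect_equal(nrow(detect_junctions(as_tracks(u = rep(30L, 10000)), p)), 0)

  # clean internal drop: exactly one call with the planted interval
  d <- rep(30L, 10000); d[5001:5010] <- 0L
  calls <- detect_junctions(as_tracks(x = d), p)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$start, 5000)
  expect_equal(calls$end, 5010)
  expect_equal(calls$left_mean, 30)
  expect_equal(calls$right_mean, 30)
  expect_equal(calls$min_depth, 0)

  # drop inside the start exclusion zone: no call
  d2 <- rep(30L, 10000); d2[11:20] <- 0L
  expect_equal(nrow(detect_junctions(as_tracks(x = d2), p)), 0)

  # weak flanks (below d*c) suppress the call
  d3 <- rep(8L, 10000); d3[5001:5010] <- 0L
  expect_equal(nrow(detect_junctions(as_tracks(x = d3), p)), 0)

  # nearby runs merge before flank evaluation (gap < d)
  d4 <- rep(30L, 10000); d4[5001:5005] <- 0L; d4[5007:5010] <- 0L
  calls4 <- detect_junctions(as_tracks(x = d4), p)
  expect_equal(nrow(calls4), 1)
  expect_equal(calls4$start, 5000); expect_equal(calls4$end, 5010)

  # short contigs yield no calls
  expect_equal(nrow(detect_junctions(as_tracks(s = rep(0L, 100)), p)), 0)
})

test_that("contig breaking removes calls, names pieces, conserves bases", {
  contigs <- random_contigs(1, 10000, seed = 7, prefix = "ctg")
  calls <- data.frame(contig = "ctg01", start = 5000L, end = 5010L)
  br <- break_contigs(contigs, calls)
  expect_equal(names(br$contigs), c("ctg01.1", "ctg01.2"))
  expect_equal(unname(Biostrings::width(br$contigs)), c(5000, 4990))
  s <- as.character(contigs[[1]])
  expect_identical(as.character(br$contigs[["ctg01.1"]]), substr(s, 1, 5000))
  expect_identical(as.character(br$contigs[["ctg01.2"]]),
                   substr(s, 5011, 10000))

  # no calls: byte-identical passthrough
  br0 <- break_contigs(contigs, calls[0, ])
  expect_identical(as.character(br0$contigs), as.character(contigs))

  # overlapping calls merge; small pieces are dropped and logged
  calls2 <- data.frame(contig = "ctg01",
                       start = c(400L, 450L, 9800L), end = c(500L, 600L, 9900L))
  br2 <- break_contigs(contigs, calls2, min_piece = 1000)
  expect_equal(nrow(br2$removed), 2)   # 400-600 merged, 9800-9900
  expect_equal(nrow(br2$dropped), 2)   # 0-400 and 9900-10000 too short
  total <- sum(Biostrings::width(br2$contigs)) +
    sum(br2$removed$end - br2$removed$start) +
    sum(br2$dropped$end - br2$dropped$start)
  expect_equal(total, 10000)
})

test_that("planted chimeras are recovered from simulated alignments", {
  truth_contigs <- random_contigs(14, 8000, seed = 8, prefix = "src")
  ch <- make_chimeras(truth_contigs, 4, seed = 9)
  sim <- simulate_reads(truth_contigs,
                        read_sim_spec(read_length = 150, coverage = 30,
                                      seed = 10))
  sam <- emit_alignments(sim, ch$contigs, liftover = ch$liftover)
  tracks <- depth_from_alignments(sam)

  # depth drops to ~0 at each planted junction
  for (j in seq_len(nrow(ch$junctions))) {
    d <- tracks[[ch$junctions$contig[j]]]
    expect_lte(d[ch$junctions$start[j] + 1], 2)
  }
  # median depth away from ends is near the simulated coverage
  meds <- median_contig_coverage(tracks)
  expect_true(all(meds >= 27 & meds <= 33))

  calls <- detect_junctions(tracks)
  br <- break_contigs(ch$contigs, calls)
  # recall: every truth junction inside a removed interval
  for (j in seq_len(nrow(ch$junctions))) {
    rem <- br$removed[br$removed$contig == ch$junctions$contig[j], ]
    expect_true(any(rem$start <= ch$junctions$start[j] &
                    rem$end >= ch$junctions$end[j]))
  }
  # precision: no cut further than 500 bp from a truth junction
  for (i in seq_len(nrow(br$removed))) {
    tj <- ch$junctions[ch$junctions$contig == br$removed$contig[i], ]
    expect_true(nrow(tj) > 0 &&
                min(abs(tj$start - br$removed$start[i])) <= 500)
  }
  # base conservation through the break
  total <- sum(Biostrings::width(br$contigs)) +
    sum(br$removed$end - br$removed$start) +
    sum(br$dropped$end - br$dropped$start)
  expect_equal(total, sum(Biostrings::width(ch$contigs)))
})
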