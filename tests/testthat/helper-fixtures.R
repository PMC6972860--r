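# small deterministic fixtures shared across test files

small_genome <- function(seed = 11, ...) {
  args <- list(haploid_size = 2e5, n_chromosomes = 4, rdna_copies = 4,
               rdna_unit_length = 2000, mito_length = 8000,
               mito_end_overlap = 200, contaminant_count = 3,
               contaminant_length = 8000, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  generate_genome(do.call(genome_spec, args))
}

random_contigs <- function(n, len, gc = 0.5, seed = 1, prefix = "c") {
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = ""),
    character(1))
  Biostrings::DNAStringSet(setNames(seqs, sprintf("%s%02d", prefix, 1:n)))
}

# depth track wrapper for hand-constructed depth vectors
as_tracks <- function(...) {
  structure(list(...), class = "depth_tracks")
}

toy_taxonomy <- function() synthetic_taxonomy()
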