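# crcurate

Curation toolkit for draft genome assemblies of small diploid eukaryotes —
built around the curation of a marine bacterivorous flagellate with a ~70%
GC, ~40 Mbp diploid nuclear genome assembled from MiSeq + PacBio reads of
non-axenic cultures. The raw assemblies of such organisms need a stack of
bespoke post-processing before they are publishable; crcurate implements
that stack as tested, reusable R functions:

* **Genome size from the k-mer spectrum** — canonical 19-mer histograms
  from reads; haploid size = (k-mers above the error valley) / (2n peak
  multiplicity), with detection of the heterozygous 1n peak at half the
  homozygous 2n peak.
* **Misjoin breaking from coverage** — per-base depth from SAM/BAM/PAF;
  junction calls are maximal runs of depth < c with both flanks averaging
  >= d·c (defaults `-a200 -b200 -c5 -d2 -e30 -f30`); contigs are cut with
  the unsupported run removed.
* **Taxonomic decontamination** — contigs split into 500 bp fragments,
  external (Kaiju-style) per-fragment classifications resolved to
  superkingdom through the taxonomy tree; a contig is dropped iff strictly
  more than 50% of its classified fragments are bacterial, with GC,
  coverage and tetranucleotide z-scores reported as corroborating
  evidence.
* **Mitochondrial curation** — organelle contig identification by 21-mer
  containment against a reference, trimming of the duplicated ends of the
  circular sequence, and rotation/strand normalisation to a reference
  anchor (the LSU rRNA gene).
* **rDNA copy number** — median operon depth over median backbone depth
  (50 longest contigs); plus strain-unique substitution counts over an
  operon alignment and allele-fraction summaries at given SNP sites.
* **Assembly statistics** — contig count, total size, N50, GC, and
  fragment-based two-direction average nucleotide identity (ANI).
* **Synthetic data** — a generator that plants every defect the pipeline
  must find (contaminants, chimeras, duplicated mito ends, tandem rDNA
  arrays, heterozygous SNPs) together with reads, alignments, classifier
  tables and a machine-readable truth table, so the whole pipeline is
  testable without downloading anything.

See `vignettes/curation-methods.Rmd` for the models, parameter choices and
limitations.

## Worked example

Generate a defective assembly (contaminants + chimeras + unmerged
mitochondrial ends), then curate it end to end:

```r
library(crcurate)

g  <- generate_genome(genome_spec(haploid_size = 4e5, n_chromosomes = 10,
                                  rdna_copies = 4, rdna_unit_length = 2000,
                                  mito_length = 12000, mito_end_overlap = 300,
                                  contaminant_count = 3,
                                  contaminant_length = 12000, seed = 80))
ch  <- make_chimeras(g$haplotypes$A, 2, seed = 81)          # plant 2 misjoins
asm <- c(ch$contigs, g$mito, g$contaminants)                 # the "raw" assembly

sim <- simulate_reads(c(g$haplotypes$A, g$mito, g$contaminants),
                      read_sim_spec(read_length = 150, coverage = 30,
                                    seed = 82))
sam <- emit_alignments(sim, asm,
                       liftover = rbind(ch$liftover,
                                        crcurate:::identity_liftover(
                                          c(g$mito, g$contaminants))))

tracks <- depth_from_alignments(sam)
calls  <- detect_junctions(tracks)                           # the 2 planted joins
broken <- break_contigs(asm, calls)

frags <- fragment_contigs(asm)
cls   <- emit_classifier_table(frags, g$truth, accuracy = 0.9,
                               unclassified_rate = 0.2, seed = 83)
sc    <- screen_contigs(asm, cls, synthetic_taxonomy(),
                        coverage = median_contig_coverage(tracks))
dec   <- apply_decontamination(asm, sc)                      # drops contam_01..03

mitoname <- identify_mito_contig(asm,
              Biostrings::DNAStringSet(c(r = g$mito_circle)))$contig
trim  <- circ_trim(asm[mitoname])
mito  <- circ_restart(trim$contig, g$truth$mito_anchor)

print(calls)
print(trim$curation)
print(assembly_stats(dec$kept))
```

which prints (numbers from this exact seed):

```
      contig start   end left_mean right_mean min_depth
1 chimera_01 39975 40030    15.255      20.70         0
2 chimera_02 39981 40023    23.075      26.54         0
Circular curation of mito: trimmed 300 bp overlap, rotated by 0, strand kept, final 12000 bp
9 contigs, 412,300 bp, N50 40,000 bp, GC 68.9%
```

The two junction calls bracket the planted joins at position 40,000 of
each chimera (each low-coverage run is removed when the contigs are cut);
the mitochondrial record shows the 300 bp duplicated end removed by
`circ_trim` before `circ_restart` rotates the circle onto the anchor; and
the kept assembly has lost exactly the three contaminants
(`names(dec$dropped)` is `contam_01 contam_02 contam_03`).
The same chain, driven by files, is available as the `run` subcommand of
the bundled CLI (`inst/scripts/crcurate`), configured by YAML
(`crcurate run config=pipeline.yaml`).

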