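Package: crcurate
Title: Curation Toolkit for Heterotrophic Protist Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Re-usable implementations of the bespoke curation steps behind
    a set of diploid, high-GC protist genome assemblies: canonical k-mer
    histograms and genome-size estimation from the diploid k-mer spectrum,
    coverage-based misassembly detection and contig breaking, fragment-wise
    taxonomic decontamination with a four-criterion screening report,
    circular mitochondrial contig trimming and rotation, rDNA operon
    copy-number estimation from read-depth ratios, and assembly comparison
    statistics (N50, GC, fragment-based average nucleotide identity).
    Includes a synthetic-data generator that emulates the statistical
    structure these procedures assume (diploid high-GC nuclear genome,
    tandem rDNA array, circular mitochondrion emitted with duplicated ends,
    compositionally distinct bacterial contaminants, chimeric contigs, and
    uniform-coverage reads) so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
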