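Package: homeophaser
Title: Homoeolog Phasing and Read Sorting for Collapsed Polyploid
    Transcriptome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-assembly separation of homoeologous gene copies in
    allopolyploid transcriptomes. Detects homoeo-SNPs on collapsed
    reference contigs from read pileups, partitions the SNPs into
    linkage blocks and assigns two haplotypes per block by
    minimum-error-correction local search, sorts paired-end read
    fragments into phase-specific sets, and reconstructs per-phase
    consensus sequences. Includes a synthetic tetraploid-transcriptome
    generator with full truth tracking (homoeolog pairs, chimeric merged
    contigs, paired-end reads, alignments) so every stage of the
    pipeline can be validated at desk scale, plus evaluation tools for
    phasing accuracy, switch errors, read-sorting precision/recall and
    consensus coverage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    data.table,
    igraph,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr,
    yaml
Config/testthat/edition: 3
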