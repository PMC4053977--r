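# homeophaser

Post-assembly separation of homoeologous gene copies in allopolyploid
transcriptomes.

## The problem

An allotetraploid (e.g. pasta wheat, genomes AABB) carries two copies of
most genes — one per parental genome — that are typically 96–99%
identical in coding sequence. De novo transcriptome assemblers collapse
such near-identical copies into single contigs, and often into
**chimeras** whose segments alternate between the A and B copy. Anyone
who needs genome-specific sequences (genome-specific primers, per-genome
expression, variant interpretation) needs them separated again.

homeophaser does this with a phasing pipeline run against the collapsed
assembly:

1. **homoeo-SNP calling** — reads aligned back to each contig produce
   apparently heterozygous pileup columns where the two homoeologs
   differ; sites are called at depth ≥ 4, alternate-allele count ≥ 2,
   allele fraction in [0.2, 0.8], after dropping fragments with more
   than 10 mismatches per 2×100 bp pair (the budget a 94%
   mapping-identity threshold implies, since 200 × (1 − 0.94) = 12);
2. **phasing** — sites linked by spanning fragments form blocks; each
   block gets two haplotypes by **minimum error correction** (MEC):
   find haplotype h ∈ {0,1}^k minimizing
   `Σ_fragments min(d(f, h), d(f, h̄))`, solved by restarted alternating
   local search with suffix-flip polishing, verified against an
   exhaustive oracle;
3. **read sorting** — every fragment is assigned to a phase of its
   block under strict unanimity, or set aside (out-of-phase or third
   alleles, low mapping quality, indels, duplicates), with exact
   conservation of counts;
4. **consensus** — per (block, phase), a reference-guided majority
   consensus reconstructs the homoeolog over every covered interval;
   per-phase FASTQ files are exported for users who prefer a de novo
   assembler.

A synthetic tetraploid-transcriptome generator (homoeolog identity ~
truncated Normal(97.26, 1.20), GC 0.49, chimeric merged references,
2×100 bp pairs with sequencing error, full truth tables) makes every
stage testable, and an evaluation module scores phasing accuracy, switch
errors, sorting precision/recall and consensus coverage against truth.

## Worked example

```r
library(homeophaser)

cfg <- sim_config(n_genes = 5L, seed = 11L)   # defaults = study conditions
bench <- end_to_end_benchmark(cfg)
print(bench$metrics, row.names = FALSE)
#>                       metric       value
#>               n_called_sites 133.0000000
#>                n_phased_snps 133.0000000
#>          phased_snp_fraction   1.0000000
#>             phasing_accuracy   1.0000000
#>                switch_errors   0.0000000
#>                 blocks_total   5.0000000
#>              blocks_chimeric   4.0000000
#>            sorting_precision   0.9987966
#>               sorting_recall   0.9562212
#>  consensus_coverage_fraction   0.9972946
#>              conservation_ok   1.0000000
```

Reading this: 133 homoeo-SNPs were called across the 5 simulated contigs
and all of them landed in phased blocks (`phased_snp_fraction` 1.0);
every phased SNP matched its true phase (`phasing_accuracy` 1.0, no
switch errors); 4 of the 5 contigs were chimeric in the merged
reference and were detected as such; 99.9% of phase-assigned read
fragments came from the homoeolog their phase represents, at the cost of
~4% of fragments excluded by the strict consistency rule
(`sorting_recall` 0.956); and the phased consensus sequences cover 99.7%
of the original contig length. `conservation_ok` confirms that every
input fragment was routed to exactly one output category.

Individual stages are plain functions (`call_variants()`,
`phase_contig()`, `sort_reads()`, `build_phase_consensus()`, ...) and a
command-line wrapper `exec/homeophaser` exposes them as subcommands
(`simulate`, `call`, `phase`, `sort`, `consensus`, `stats`, `evaluate`,
`run-all`) over FASTA/FASTQ/SAM/VCF and a HapCUT-style block format.

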