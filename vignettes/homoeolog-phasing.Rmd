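---
title: "Separating collapsed homoeologs: models, parameters, and design choices"
author: "homeophaser"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating collapsed homoeologs: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homeophaser)
```

## The problem

In an allotetraploid such as pasta wheat (genomes AABB), most genes exist
as a homoeologous pair: two copies, one per parental genome, typically
96–99% identical in coding sequence. De novo transcriptome assemblers were
designed for diploid levels of heterozygosity; at homoeolog-level
divergence they either collapse the two copies into one contig or, worse,
stitch together chimeras that alternate between the A and B copy along
their length. Downstream uses — primer design, expression partitioning
between genomes, variant interpretation — all need genome-specific
sequences.

homeophaser separates collapsed homoeologs after assembly, in four stages:

1. **Variant detection.** Reads are aligned back to the assembled contigs
   (in real mode the user supplies SAM; in synthetic mode the simulator
   emits truth alignments). Fixed differences between homoeologs appear as
   apparently heterozygous pileup columns with roughly balanced allele
   fractions; these homoeo-SNPs are called with coverage and allele-count
   thresholds.
2. **Phasing.** Called sites are partitioned into linkage blocks — two
   sites are linked when a read-pair fragment observes both — and each
   block is assigned two haplotypes by minimum error correction (MEC).
3. **Read sorting.** Every fragment is assigned to one haplotype of its
   block, or excluded, under a strict consistency rule.
4. **Consensus.** Each (block, phase) read set is reduced to a
   reference-guided majority consensus, yielding genome-specific
   sequences over every covered interval.

A synthetic tetraploid-transcriptome generator with complete truth
tracking makes all of this testable at desk scale, and the evaluation
module scores each stage against that truth.

## Divergence model and threshold arithmetic

Homoeolog percent identity in tetraploid wheat coding regions is well
described by a normal distribution with mean 97.26% and standard
deviation 1.20%. Two small functions expose the parameter arithmetic that
such a model implies:

```{r}
# mismatch budget per 2x100 bp fragment at a mapping-identity threshold
expected_snp_count(200, 94)
expected_snp_count(200, 95)
# expected substitutions for the mean curated gene
expected_snp_count(1199, 97.26)
# fraction of homoeolog pairs retained above a threshold
inclusion_fraction(97.26, 1.20, 94)
```

`expected_snp_count` is literally `L * (1 - id/100)`: an expected
substitution *count*. For these parameters its value (32.9 for the mean
1199 bp gene) is numerically close to the mean inter-SNP spacing, and it
is sometimes read that way, but the two are distinct quantities — the
docstring says so explicitly.

## The synthetic data generator

`sim_config()` fixes the study conditions; `generate_homoeolog_pair()`,
`build_merged_reference()`, `simulate_fragments()` and
`emit_alignments()` realize them. Defaults, with units and rationale:

| parameter | default | meaning |
|---|---|---|
| `gene_length_mean/sd/min` | 1199 / 300 / 300 bp | normal draw, clipped below |
| `identity_mean/sd` | 97.26 / 1.20 % | truncated normal on `identity_bounds` [90, 100] |
| `gc_content` | 0.49 | ancestral base composition |
| `chimera_switch_prob` | 0.3 | per-adjacent-variant origin switch in the merged reference |
| `coverage_per_homoeolog` | 30x | fragment count `round(cov * L / (2 * read_length))` |
| `read_length` | 100 bp | 2x100 paired-end geometry |
| `fragment_size_mean/sd` | 300 / 30 bp | overlapping mates allowed |
| `base_error_rate` | 0.002 | i.i.d. substitution errors; constant base quality `round(-10 log10(rate))` |

Design choices worth knowing:

* **All divergence on the B branch.** The A copy is the ancestral draw and
  B carries every substitution. Only the difference *pattern* matters to
  calling, phasing and sorting, and one-sided divergence keeps the truth
  bookkeeping exact.
* **Uniform variant placement.** Substitution positions are sampled
  uniformly without replacement, which makes inter-SNP gaps geometric
  (the discrete analogue of the exponential spacing seen between real
  homoeologs). Real homoeo-SNPs cluster somewhat — their empirical mean
  spacing exceeds the Poisson expectation — and the generator deliberately
  does not model that clustering; tests that pass here say nothing about
  clustered-SNP behaviour.
* **Truncation bias.** Because identity is drawn from a normal truncated
  to [90, 100], the upper tail is shaved and the generator's true mean
  identity is ≈97.22, about 0.04 below the nominal 97.26. Parameter-
  recovery tests therefore compare the sample mean against the closed-form
  truncated-normal mean, not the nominal value.
* **Pooled gap distributions are mixtures.** Each gene has its own SNP
  density, so inter-SNP gaps pooled across genes follow a *mixture* of
  exponentials, which a large-sample goodness-of-fit test rightly rejects.
  `snp_gap_exponential_test()` accepts a per-gap expected spacing
  (`L/(m+1)`) to standardize gaps to a common unit-mean law first, and
  applies a randomized continuity correction (each integer gap `k` spread
  uniformly over `(k-1, k]`) because raw integer gaps would otherwise fail
  against a continuous law on discreteness alone.
* **Chimera model.** The reference-allele origin follows a two-state
  Markov chain along the variants with switch probability 0.3. A
  consequence: a contig with `m` variants is chimeric with probability
  `1 - 0.7^(m-1)`, so SNP-rich simulated contigs are almost always
  chimeric. Real assemblies show a ~50/50 chimeric split only because
  many real contigs carry few SNPs.
* **Indels are off.** The read sorter discards indel-bearing records, so
  simulating indels would only exercise a filter; `indel_rate` is
  accepted but must be 0.
* **Reproducibility.** One master seed; every gene and stage derives its
  own substream via `derive_seed(seed, gene, stage)`, so gene sets are
  stable under any evaluation order.

## Variant calling

`build_pileup()` counts aligned bases passing mapping quality ≥ 20, base
quality ≥ 20, and no duplicate flag; overlapping mates of one fragment
contribute one vote where they agree and none where they disagree, so a
fragment is never double-counted. Upstream, `filter_fragments_by_nm()`
drops both mates when their summed NM exceeds 10 — the mismatch budget a
94% mapping-identity threshold implies for a 200 bp fragment.

`call_variants()` emits a site when depth ≥ 4, the second allele is seen
≥ 2 times, its fraction of depth lies in [0.2, 0.8], and exactly two
bases reach the count floor. The allele-fraction window replaces diploid
genotype likelihoods as the heterozygosity criterion: homoeo-SNPs on a
collapsed contig with balanced genome expression sit near 0.5, and the
window is configurable for skewed expression. Sites with three qualifying
alleles are excluded from the VCF but logged, because a third allele is
exactly the evidence the read sorter later uses to divert fragments from
recent paralogs. Only SNPs are called; adjacent substitutions stay
separate sites, since phasing treats sites independently and indel-bearing
reads never reach the phaser anyway.

## Phasing by minimum error correction

The MEC objective asks for the two-haplotype assignment minimizing the
number of allele observations that must be flipped so every fragment is
consistent with one haplotype. `phase_block()` solves it by restarted
alternating local search:

1. initialize haplotype 0;
2. assign each fragment to the haplotype it mismatches least (ties to
   haplotype 0);
3. reset each site to the majority allele among its assigned fragments
   (ties to allele 0);
4. iterate to a fixed point.

Alternating updates alone cannot perform the *coordinated* flip of a
weakly linked tail segment — the classic switch-type local optimum — so
each converged solution is polished with suffix flips (flip sites `j..k`,
re-descend, keep improvements). Starts are: all-reference, a
linkage-propagation start (relative phase of adjacent sites from the
majority of co-observing fragments), and 20 seeded random restarts. The
search is deterministic given its seed, and ties between equal-MEC optima
are broken toward the lexicographically smallest haplotype-0 vector,
whose first allele is always 0 by complement symmetry.

MEC is unweighted with a base-quality floor (bases under q20 become
missing) rather than quality-weighted: this keeps
`brute_force_phase()` — an exhaustive `2^(k-1)` enumeration used as the
test oracle — exact, and on transcript-scale blocks (tens of sites,
hundreds of fragments) the weighting adds nothing measurable. The test
suite requires the heuristic to match the brute-force optimum on every
noise-free random instance and on ≥95% of noisy ones.

Blocks are connected components of the site graph in which fragments with
≥2 non-missing observations contribute edges; single-site components are
emitted unphased (MEC 0). A block is *chimeric* when haplotype 0 changes
value between adjacent sites — i.e. when the reference contig alternates
origin within the block — and the switch count is reported.

## Read sorting

`assign_fragment()` restricts a fragment's observations to its block's
sites: no observation → uninformative; any third allele → inconsistent;
unanimity with one haplotype → that phase; anything mixed → inconsistent.
Strict unanimity deliberately trades recall for precision: an out-of-phase
fragment is more likely a sequencing error or a paralogous read than a
recombinant molecule, and excluding it keeps the downstream consensus
pure. A majority-vote mode exists behind a flag. Inconsistent fragments
are written to their own FASTQ with a reason sidecar since out-of-phase
variants can be biologically interesting. Filter categories are
fragment-level: a fragment counts as filtered only when *every* record of
it is filtered (duplicate, then indel, then mapping quality), because one
good mate still carries phase information. The category counts always sum
to the number of distinct input fragments — an exact conservation
invariant asserted on every run.

## Consensus

Because indel-bearing records are filtered upstream, phased reads are
colinear with the reference, and a reference-guided majority consensus
per (block, phase) reconstructs each homoeolog without de novo
re-assembly: per column the majority base among q ≥ 20 votes wins, ties
at phased sites resolve to the phased allele, ties elsewhere to the
reference base, and zero-coverage columns split the output into segments.
The per-phase FASTQ export remains the hook for users who want a real
assembler instead. `coverage_fraction()` — the union of segment intervals
over the contig length — quantifies how much of the original contig the
phased reconstruction recovers.

## Evaluation

`phasing_accuracy()` compares blocks to truth under per-block best-of-two
labeling (each block's phase labels may be swapped, mirroring how a
curated gene pair is compared to its phasing output), and reports switch
errors separately since accuracy alone hides switch structure. Single-site
blocks are excluded: best-of-two labeling makes them trivially correct.
`sorting_metrics()` maps phases to homoeologs per block by majority and
scores precision and recall against fragment origin truth.
`identity_distribution()` reproduces the before/after diagnostic: phased
consensus sequences against the two truth homoeologs cluster at ~100%
(own genome) and at the identity mean (other genome), a bimodal pattern
whose mode gap is ≈ `100 - identity_mean`, while chimeric unphased
contigs sit at intermediate identities with no such separation. In real
mode it falls back to best local alignment against a supplied reference
set.

## Problem sizes and runtime

The shipped tests and the acceptance script run entirely on simulated
data at sizes chosen to exercise every code path while staying
interactive: 30 genes at full defaults (~1,000 phased SNPs, about half a
minute) for the end-to-end accuracy benchmark, 500 genes for
parameter-recovery statistics (pair generation only), 100 random
instances for the MEC-oracle comparison, and 2–6 gene configurations for
noise-free exactness, filter, and coverage-sweep properties.

## Known limitations

* No indel handling anywhere: real homoeologs differ by indels too
  (especially in UTRs), and those regions will stay unresolved or
  unsegmented here.
* Alignment is taken as given; mapping-quality pathologies of real
  aligners (multi-mapping across alternative splice forms, soft
  clipping) are not simulated, only a configurable fraction of demoted
  records.
* The caller assumes roughly balanced homoeolog expression; strongly
  skewed genes need a wider allele-fraction window and will phase with
  lower power regardless.
* Consensus quality is bounded by the reference's colinearity with both
  homoeologs; structural divergence between copies calls for the FASTQ
  export plus a de novo assembler.
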