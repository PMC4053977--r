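#' Simulation configuration for synthetic homoeolog data
#'
#' Parameters controlling the synthetic tetraploid-transcriptome generator.
#' Defaults reflect the divergence statistics of curated A/B homoeolog
#' pairs in tetraploid wheat: percent identity approximately normal with
#' mean 97.26 and standard deviation 1.20, mean coding length 1199 bp,
#' GC content 49%, and a 2x100 bp paired-end read geometry.
#'
#' @param n_genes number of homoeolog pairs to simulate.
#' @param gene_length_mean,gene_length_sd,gene_length_min gene length model
#'   (bp); lengths are drawn from a normal distribution, rounded, and
#'   clipped below at `gene_length_min`.
#' @param identity_mean,identity_sd,identity_bounds percent-identity model
#'   between the two homoeologs; draws come from a normal truncated to
#'   `identity_bounds`.
#' @param gc_content GC fraction of the ancestral sequences.
#' @param chimera_switch_prob probability, at each consecutive variant,
#'   that the merged reference contig switches which homoeolog supplies
#'   the reference allele (Markov chain on variant origins).
#' @param coverage_per_homoeolog fold coverage per homoeolog.
#' @param read_length mate length in bp.
#' @param fragment_size_mean,fragment_size_sd sequenced-fragment length
#'   model (bp); overlapping mates are allowed.
#' @param base_error_rate per-base substitution sequencing-error
#'   probability.
#' @param indel_rate reserved; indels default off because downstream read
#'   sorting discards indel-bearing records.
#' @param seed master integer seed; per-gene substreams are derived from
#'   `(seed, gene_index)`.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 30L,
                       gene_length_mean = 1199,
                       gene_length_sd = 300,
                       gene_length_min = 300,
                       identity_mean = 97.26,
                       identity_sd = 1.20,
                       identity_bounds = c(90, 100),
                       gc_content = 0.49,
                       chimera_switch_prob = 0.3,
                       coverage_per_homoeolog = 30,
                       read_length = 100L,
                       fragment_size_mean = 300,
                       fragment_size_sd = 30,
                       base_error_rate = 0.002,
                       indel_rate = 0,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              gene_length_mean = gene_length_mean,
              gene_length_sd = gene_length_sd,
              gene_length_min = gene_length_min,
              identity_mean = identity_mean,
              identity_sd = identity_sd,
              identity_bounds = identity_bounds,
              gc_content = gc_content,
              chimera_switch_prob = chimera_switch_prob,
              coverage_per_homoeolog = coverage_per_homoeolog,
              read_length = as.integer(read_length),
              fragment_size_mean = fragment_size_mean,
              fragment_size_sd = fragment_size_sd,
              base_error_rate = base_error_rate,
              indel_rate = indel_rate,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (length(cfg$identity_bounds) != 2L ||
      cfg$identity_bounds[1] < 0 || cfg$identity_bounds[2] > 100 ||
      cfg$identity_bounds[1] > cfg$identity_bounds[2])
    stop("identity_bounds must be an ordered interval within [0, 100]",
         call. = FALSE)
  if (cfg$fragment_size_mean > cfg$gene_length_min)
    stop("fragment_size_mean must not exceed gene_length_min",
         call. = FALSE)
  stopifnot_scalar_prob(cfg$gc_content, "gc_content")
  stopifnot_scalar_prob(cfg$chimera_switch_prob, "chimera_switch_prob")
  stopifnot_scalar_prob(cfg$base_error_rate, "base_error_rate")
  stopifnot_scalar_prob(cfg$indel_rate, "indel_rate")
  if (cfg$indel_rate > 0)
    stop("indel simulation is not implemented; set indel_rate = 0",
         call. = FALSE)
  if (cfg$gene_length_min <= 0 || cfg$read_length <= 0 ||
      cfg$coverage_per_homoeolog <= 0)
    stop("lengths and coverage must be positive", call. = FALSE)
  invisible(cfg)
}

#' Variant-caller configuration
#'
#' Thresholds for pileup-based homoeo-SNP detection, mirroring the
#' FreeBayes parameter contract used for RNA-seq variant detection
#' (minimum coverage 4, minimum alternate-allele count 2) plus a
#' fragment-level mismatch cap of 10 per 2x100 bp paired-end fragment
#' (the >95% identity mapping criterion).
#'
#' @param min_coverage minimum pileup depth at a site.
#' @param min_alt_count minimum reads carrying the alternate allele.
#' @param min_baseq minimum base quality for a base to enter the pileup.
#' @param min_mapq minimum mapping quality for a record to enter the
#'   pileup.
#' @param min_alt_fraction,max_alt_fraction allele-fraction window used as
#'   the heterozygosity criterion (homoeo-SNPs in a balanced tetraploid
#'   look like ~50/50 heterozygous sites).
#' @param max_fragment_mismatches maximum summed NM over the two mates of
#'   a fragment.
#' @return an object of class `caller_config`.
#' @export
caller_config <- function(min_coverage = 4L,
                          min_alt_count = 2L,
                          min_baseq = 20L,
                          min_mapq = 20L,
                          min_alt_fraction = 0.2,
                          max_alt_fraction = 0.8,
                          max_fragment_mismatches = 10L) {
  cfg <- list(min_coverage = as.integer(min_coverage),
              min_alt_count = as.integer(min_alt_count),
              min_baseq = as.integer(min_baseq),
              min_mapq = as.integer(min_mapq),
              min_alt_fraction = min_alt_fraction,
              max_alt_fraction = max_alt_fraction,
              max_fragment_mismatches = as.integer(max_fragment_mismatches))
  if (cfg$min_alt_fraction < 0 || cfg$max_alt_fraction > 1 ||
      cfg$min_alt_fraction > cfg$max_alt_fraction)
    stop("need 0 <= min_alt_fraction <= max_alt_fraction <= 1",
         call. = FALSE)
  if (any(c(cfg$min_coverage, cfg$min_alt_count, cfg$min_baseq,
            cfg$min_mapq, cfg$max_fragment_mismatches) < 0))
    stop("caller thresholds must be non-negative", call. = FALSE)
  class(cfg) <- "caller_config"
  cfg
}
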