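#' Run the full phasing pipeline on a simulated dataset
#'
#' simulate -> fragment NM filter -> pileup -> variant calling -> block
#' phasing -> read sorting -> per-phase consensus, all under seeds
#' derived from the configuration seed.
#'
#' @param config a [sim_config()].
#' @param caller a [caller_config()].
#' @param phase_min_mapq mapping-quality floor for phasing and sorting.
#' @param restarts phasing restarts per block.
#' @param mapq_demote_frac,dup_frac passed to [simulate_dataset()].
#' @return list of class `pipeline_result`: `dataset`, `alignments`
#'   (NM-filtered), `pileup`, `sites`, `matrices`, `blocks` (flat list),
#'   `sort` (`sort_report`), `consensus` (list of `phased_consensus`).
#' @export
run_pipeline <- function(config, caller = caller_config(),
                         phase_min_mapq = 30L, restarts = 20L,
                         mapq_demote_frac = 0, dup_frac = 0) {
  ds <- simulate_dataset(config, mapq_demote_frac = mapq_demote_frac,
                         dup_frac = dup_frac)
  aln <- filter_fragments_by_nm(ds$alignments,
                                caller$max_fragment_mismatches)
  pile <- build_pileup(aln, ds$contigs, caller)
  sites <- call_variants(pile, ds$contigs, caller)
  mats <- extract_fragments_by_contig(aln, sites,
                                      min_mapq = phase_min_mapq)
  blocks <- list()
  for (ct in names(mats)) {
    bl <- phase_contig(mats[[ct]], restarts = restarts,
                       seed = derive_seed(config$seed, 5L,
                                          match(ct, names(mats))))
    blocks <- c(blocks, bl)
  }
  sorted <- sort_reads(aln, blocks, min_mapq = phase_min_mapq)
  contig_ids <- vapply(ds$contigs, `[[`, "", "contig_id")
  consensus <- list()
  for (b in blocks) {
    merged <- ds$contigs[[match(b$contig, contig_ids)]]
    for (ph in 0:1) {
      ids <- sorted$assignments$fragment_id[
        sorted$assignments$category == paste0("phase", ph) &
          sorted$assignments$contig == b$contig &
          sorted$assignments$block_id == b$block_id]
      if (!length(ids)) next
      sub <- aln[aln$qname %in% ids & aln$rname == b$contig, , drop = FALSE]
      consensus[[length(consensus) + 1L]] <-
        build_phase_consensus(sub, merged, b, ph)
    }
  }
  structure(list(dataset = ds, alignments = aln, pileup = pile,
                 sites = sites, matrices = mats, blocks = blocks,
                 sort = sorted, consensus = consensus),
            class = "pipeline_result")
}

#' End-to-end benchmark against simulation truth
#'
#' Runs [run_pipeline()] at the given configuration and scores every
#' stage against the recorded truth: phasing accuracy and switch errors,
#' phased-SNP fraction, chimeric-block counts, read-sorting precision
#' and recall, conservation, and mean per-contig consensus coverage.
#'
#' @param config a [sim_config()].
#' @param ... passed to [run_pipeline()].
#' @param outdir optional directory for a TSV report.
#' @return list of class `benchmark_report`: `metrics` (data.frame
#'   `metric`, `value`), plus the underlying `pipeline_result` as
#'   `"result"` attribute.
#' @export
end_to_end_benchmark <- function(config, ..., outdir = NULL) {
  res <- run_pipeline(config, ...)
  truth <- truth_phase_table(res$dataset)
  score <- phasing_accuracy(res$blocks, truth)
  sm <- sorting_metrics(res$sort$assignments, res$dataset$fragments)
  multi <- vapply(res$blocks, function(b) b$n_phased >= 2L, logical(1))
  phased_fraction <- if (nrow(res$sites))
    sum(vapply(res$blocks[multi], `[[`, 0L, "n_phased")) / nrow(res$sites)
  else NA_real_
  contig_ids <- vapply(res$dataset$contigs, `[[`, "", "contig_id")
  cov <- vapply(seq_along(contig_ids), function(i) {
    cs <- Filter(function(x) x$contig == contig_ids[i], res$consensus)
    coverage_fraction(cs, res$dataset$contigs[[i]])
  }, 0)
  conserved <- sum(res$sort$counts) == length(unique(res$alignments$qname))
  metrics <- data.frame(
    metric = c("n_called_sites", "n_phased_snps", "phased_snp_fraction",
               "phasing_accuracy", "switch_errors", "blocks_total",
               "blocks_chimeric", "sorting_precision", "sorting_recall",
               "consensus_coverage_fraction", "conservation_ok"),
    value = c(nrow(res$sites), score$n_phased_snps, phased_fraction,
              score$accuracy, score$switch_errors, score$blocks_total,
              score$blocks_chimeric, sm$precision, sm$recall,
              mean(cov), as.numeric(conserved)))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write.table(metrics, file.path(outdir, "benchmark_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  structure(list(metrics = metrics, phasing = score, sorting = sm),
            class = "benchmark_report", result = res)
}
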