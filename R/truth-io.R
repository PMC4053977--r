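#' Write a simulated dataset and its truth tables to disk
#'
#' Emits the merged-contig reference FASTA, the homoeolog truth FASTA
#' (`<gene>_A` / `<gene>_B`), paired FASTQ (`/1`, `/2`), SAM alignments,
#' a truth VCF of homoeo-variants on the merged contigs, a per-variant
#' phase table, and a per-fragment origin table. All file coordinates
#' are 1-based.
#'
#' @param dataset a `sim_dataset`.
#' @param dir output directory.
#' @param force overwrite existing files.
#' @return named character vector of paths, invisibly.
#' @export
write_truth <- function(dataset, dir, force = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(reference = file.path(dir, "reference.fasta"),
             homoeologs = file.path(dir, "homoeologs.fasta"),
             reads1 = file.path(dir, "reads_1.fastq"),
             reads2 = file.path(dir, "reads_2.fastq"),
             alignments = file.path(dir, "alignments.sam"),
             variants = file.path(dir, "truth_variants.vcf"),
             phase = file.path(dir, "truth_phase.tsv"),
             fragments = file.path(dir, "truth_fragments.tsv"))
  clash <- paths[file.exists(paths)]
  if (length(clash) && !force)
    stop("refusing to overwrite ", clash[1], " (use force = TRUE)",
         call. = FALSE)

  ref <- Biostrings::DNAStringSet(
    setNames(vapply(dataset$contigs, `[[`, "", "sequence"),
             vapply(dataset$contigs, `[[`, "", "contig_id")))
  Biostrings::writeXStringSet(ref, paths["reference"])

  hom <- unlist(lapply(dataset$pairs, function(p)
    setNames(c(p$seq_a, p$seq_b), paste0(p$gene_id, c("_A", "_B")))))
  if (is.null(hom)) hom <- setNames(character(0), character(0))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(hom),
                              paths["homoeologs"])

  q <- if (dataset$config$base_error_rate > 0)
    min(40L, as.integer(round(-10 * log10(dataset$config$base_error_rate))))
  else 40L
  for (mate in 1:2) {
    s <- dataset$fragments[[paste0("mate", mate, "_seq")]]
    nm <- if (length(s)) paste0(dataset$fragments$fragment_id, "/", mate)
          else character(0)
    sq <- Biostrings::DNAStringSet(setNames(s, nm))
    Biostrings::writeXStringSet(
      sq, paths[paste0("reads", mate)], format = "fastq",
      qualities = Biostrings::BStringSet(
        vapply(nchar(s), function(n) phred_char(rep(q, n)), "")))
  }

  write_sam(dataset$alignments, dataset$contigs, paths["alignments"])

  truth <- truth_phase_table(dataset)
  n <- nrow(truth)
  vcf_sites <- data.frame(
    contig = truth$contig, pos = truth$pos,
    ref = ifelse(truth$ref_origin == "A", truth$allele_a, truth$allele_b),
    alt = ifelse(truth$ref_origin == "A", truth$allele_b, truth$allele_a),
    ref_count = rep(0L, n), alt_count = rep(0L, n), depth = rep(0L, n),
    alt_fraction = rep(0, n), stringsAsFactors = FALSE)
  class(vcf_sites) <- c("variant_sites", "data.frame")
  write_variants(vcf_sites, paths["variants"], force = force)

  write.table(truth, paths["phase"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(dataset$fragments[, c("fragment_id", "gene_id", "source",
                                    "start", "frag_len")],
              paths["fragments"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' Read truth tables back from a [write_truth()] directory
#'
#' @param dir directory written by [write_truth()].
#' @return list: `phase` (truth phase table), `fragments` (origin
#'   table), `variants` (`variant_sites`), `reference`, `homoeologs`
#'   (named character vectors).
#' @export
read_truth <- function(dir) {
  phase <- read.delim(file.path(dir, "truth_phase.tsv"),
                      stringsAsFactors = FALSE)
  frags <- read.delim(file.path(dir, "truth_fragments.tsv"),
                      stringsAsFactors = FALSE)
  list(phase = phase, fragments = frags,
       variants = read_variants(file.path(dir, "truth_variants.vcf")),
       reference = ref_seqs(Biostrings::readDNAStringSet(
         file.path(dir, "reference.fasta"))),
       homoeologs = ref_seqs(Biostrings::readDNAStringSet(
         file.path(dir, "homoeologs.fasta"))))
}
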