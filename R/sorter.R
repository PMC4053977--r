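SORT_CATEGORIES <- c("phase0", "phase1", "inconsistent", "uninformative",
                     "filtered_mapq", "filtered_indel", "filtered_duplicate")

#' Assign one fragment to a phase or an excluded category
#'
#' Restricts the fragment's allele observations to the block's phased
#' sites. No observed site gives `uninformative`; a third (offsite)
#' allele at a phased site gives `inconsistent`; unanimity with one
#' haplotype gives `phase0`/`phase1`; mixed observations give
#' `inconsistent`. The default strict-unanimity rule removes any
#' out-of-phase fragment — trading recall for phase purity — while
#' `mode = "majority"` assigns by majority with ties inconsistent.
#'
#' @param obs integer vector of allele codes (0/1/NA) indexed like the
#'   contig's site list.
#' @param block a `phased_block`.
#' @param offsite logical vector marking third-allele observations,
#'   indexed like `obs`.
#' @param mode `"strict"` (default) or `"majority"`.
#' @return one of `"phase0"`, `"phase1"`, `"inconsistent"`,
#'   `"uninformative"`.
#' @export
assign_fragment <- function(obs, block, offsite = NULL,
                            mode = c("strict", "majority")) {
  mode <- match.arg(mode)
  idx <- block$site_indices
  o <- obs[idx]
  off <- if (is.null(offsite)) rep(FALSE, length(idx)) else offsite[idx]
  if (any(off)) return("inconsistent")
  seen <- which(!is.na(o))
  if (length(seen) == 0L) return("uninformative")
  m0 <- sum(o[seen] == block$hap0[seen])
  m1 <- length(seen) - m0
  if (mode == "strict") {
    if (m1 == 0L) return("phase0")
    if (m0 == 0L) return("phase1")
    return("inconsistent")
  }
  if (m0 > m1) "phase0" else if (m1 > m0) "phase1" else "inconsistent"
}

#' Sort read fragments into per-block phase sets
#'
#' Re-implements the readphaser contract: every fragment in the input
#' alignments lands in exactly one category. Fragments whose records are
#' all filtered are counted under the filter reason (duplicate, then
#' indel, then mapping quality); fragments covering no phased site are
#' uninformative; the rest are assigned by [assign_fragment()].
#' Phase fragments are written as paired FASTQ per (contig, block,
#' phase); inconsistent fragments go to a separate FASTQ with a reason
#' sidecar, since out-of-phase variants can be biologically interesting
#' (recent duplications, residual paralogy).
#'
#' @param alignments alignment data.frame.
#' @param blocks list of `phased_block` (possibly many contigs).
#' @param reads optional list with named character vectors `mate1`,
#'   `mate2`, `qual1`, `qual2` keyed by fragment ID; by default mates are
#'   reconstructed from the alignment records. IDs present in the
#'   alignments but absent here are a hard error.
#' @param outdir if non-NULL, FASTQ files and the report TSV are written
#'   here.
#' @param min_mapq,min_baseq filters, matching the phasing extraction.
#' @param mode passed to [assign_fragment()].
#' @return list of class `sort_report`: `counts` (named, conservation:
#'   sums to the number of distinct input fragments), `per_block`
#'   (data.frame), `assignments` (data.frame: `fragment_id`, `contig`,
#'   `block_id`, `category`, `reason`), `files` (written paths).
#' @export
sort_reads <- function(alignments, blocks, reads = NULL, outdir = NULL,
                       min_mapq = 30L, min_baseq = 20L,
                       mode = c("strict", "majority")) {
  mode <- match.arg(mode)
  frag_ids <- unique(alignments$qname)
  category <- setNames(rep(NA_character_, length(frag_ids)), frag_ids)
  reason <- setNames(rep(NA_character_, length(frag_ids)), frag_ids)
  frag_contig <- setNames(rep(NA_character_, length(frag_ids)), frag_ids)
  frag_block <- setNames(rep(NA_integer_, length(frag_ids)), frag_ids)

  # fragment-level filter categories: only when every record is filtered
  rec_dup <- is_dup(alignments$flag)
  rec_ind <- has_indel(alignments$cigar)
  rec_mapq <- alignments$mapq < min_mapq
  rec_filtered <- rec_dup | rec_ind | rec_mapq
  all_filtered <- tapply(rec_filtered, alignments$qname, all)
  any_dup <- tapply(rec_dup, alignments$qname, any)
  any_ind <- tapply(rec_ind, alignments$qname, any)
  gone <- names(all_filtered)[all_filtered]
  category[gone] <- ifelse(any_dup[gone], "filtered_duplicate",
                           ifelse(any_ind[gone], "filtered_indel",
                                  "filtered_mapq"))

  # per-contig observation matrices at the phased sites
  site_tables <- blocks_site_tables(blocks)
  for (ct in names(site_tables)) {
    st <- site_tables[[ct]]
    fm <- extract_fragments(alignments, st$sites, min_mapq, min_baseq)
    ct_blocks <- st$blocks
    for (fi in seq_along(fm$fragment_ids)) {
      id <- fm$fragment_ids[fi]
      if (!is.na(category[id])) next
      obs <- fm$mat[fi, ]
      off <- fm$offsite[fi, ]
      touched <- which(vapply(ct_blocks, function(b)
        any(!is.na(obs[b$site_indices])) || any(off[b$site_indices]),
        logical(1)))
      if (length(touched) == 0L) next
      if (length(touched) > 1L) {
        # observations straddling two blocks cannot be phased jointly
        category[id] <- "inconsistent"
        reason[id] <- "multi_block"
        frag_contig[id] <- ct
        next
      }
      b <- ct_blocks[[touched]]
      cat_i <- assign_fragment(obs, b, off, mode)
      if (cat_i == "uninformative") next
      category[id] <- cat_i
      frag_contig[id] <- ct
      frag_block[id] <- b$block_id
      if (cat_i == "inconsistent")
        reason[id] <- if (any(off[b$site_indices])) "third_allele"
                      else "out_of_phase"
    }
  }
  category[is.na(category)] <- "uninformative"

  counts <- setNames(integer(length(SORT_CATEGORIES)), SORT_CATEGORIES)
  tab <- table(category)
  counts[names(tab)] <- as.integer(tab)

  assignments <- data.frame(fragment_id = frag_ids,
                            contig = unname(frag_contig),
                            block_id = unname(frag_block),
                            category = unname(category),
                            reason = unname(reason),
                            stringsAsFactors = FALSE)
  phased <- assignments[assignments$category %in%
                          c("phase0", "phase1", "inconsistent"), , drop = FALSE]
  per_block <- if (nrow(phased)) {
    agg <- as.data.frame(table(contig = phased$contig,
                               block_id = phased$block_id,
                               category = phased$category))
    w <- stats::reshape(agg, idvar = c("contig", "block_id"),
                        timevar = "category", direction = "wide")
    names(w) <- sub("^Freq\\.", "", names(w))
    w[w$contig != "NA", , drop = FALSE]
  } else data.frame(contig = character(0), block_id = integer(0))

  files <- character(0)
  if (!is.null(outdir)) {
    files <- write_sorted_fastq(assignments, alignments, reads, outdir)
    report_path <- file.path(outdir, "sort_report.tsv")
    write.table(data.frame(category = names(counts),
                           fragments = as.integer(counts)),
                report_path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, report_path)
  }
  structure(list(counts = counts, per_block = per_block,
                 assignments = assignments, files = files),
            class = "sort_report")
}

# Ordered site table and blocks per contig, rebuilt from the block list
# so sorting can run directly from a HapCUT-style file.
blocks_site_tables <- function(blocks) {
  by_contig <- split(blocks, vapply(blocks, `[[`, "", "contig"))
  lapply(by_contig, function(bs) {
    sites <- data.frame(
      contig = unlist(lapply(bs, function(b) rep(b$contig, b$n_phased))),
      pos = unlist(lapply(bs, `[[`, "pos")),
      ref = unlist(lapply(bs, `[[`, "ref")),
      alt = unlist(lapply(bs, `[[`, "alt")),
      stringsAsFactors = FALSE)
    ord <- order(sites$pos)
    sites <- sites[ord, , drop = FALSE]
    class(sites) <- c("variant_sites", "data.frame")
    # re-index block sites against the rebuilt (position-sorted) table
    bs <- lapply(bs, function(b) {
      b$site_indices <- match(b$pos, sites$pos)
      b
    })
    list(sites = sites, blocks = bs)
  })
}

write_sorted_fastq <- function(assignments, alignments, reads, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(reads)) reads <- reads_from_alignments(alignments)
  missing <- setdiff(assignments$fragment_id, names(reads$mate1))
  if (length(missing))
    stop("read IDs in alignments absent from FASTQ input: ",
         paste(head(missing, 3), collapse = ", "), call. = FALSE)
  paths <- character(0)
  emit <- function(ids, stem) {
    if (!length(ids)) return(invisible(NULL))
    for (mate in 1:2) {
      p <- file.path(outdir, sprintf("%s_%d.fastq", stem, mate))
      sq <- Biostrings::DNAStringSet(reads[[paste0("mate", mate)]][ids])
      names(sq) <- paste0(ids, "/", mate)
      Biostrings::writeXStringSet(
        sq, p, format = "fastq",
        qualities = Biostrings::BStringSet(
          unname(reads[[paste0("qual", mate)]][ids])))
      paths <<- c(paths, p)
    }
  }
  ph <- assignments[assignments$category %in% c("phase0", "phase1"), ]
  if (nrow(ph)) {
    for (key in unique(paste(ph$contig, ph$block_id, ph$category))) {
      sel <- ph[paste(ph$contig, ph$block_id, ph$category) == key, ]
      emit(sel$fragment_id,
           sprintf("%s_block%d_%s", sel$contig[1], sel$block_id[1],
                   sel$category[1]))
    }
  }
  inc <- assignments[assignments$category == "inconsistent", ]
  emit(inc$fragment_id, "inconsistent")
  if (nrow(inc)) {
    p <- file.path(outdir, "inconsistent_reasons.tsv")
    write.table(inc[, c("fragment_id", "contig", "reason")], p,
                sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  paths
}

# Reconstruct original read orientation from the stored SAM records.
reads_from_alignments <- function(alignments) {
  first <- is_first_mate(alignments$flag)
  orient <- function(a) {
    s <- a$seq
    q <- a$qual
    rev_idx <- is_reverse(a$flag)
    s[rev_idx] <- revcomp(s[rev_idx])
    q[rev_idx] <- vapply(strsplit(q[rev_idx], ""), function(x)
      paste(rev(x), collapse = ""), "")
    list(seq = setNames(s, a$qname), qual = setNames(q, a$qname))
  }
  m1 <- orient(alignments[first, , drop = FALSE])
  m2 <- orient(alignments[!first, , drop = FALSE])
  list(mate1 = m1$seq, qual1 = m1$qual, mate2 = m2$seq, qual2 = m2$qual)
}
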