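#' Emit SAM-style alignment records for simulated fragments
#'
#' Places each mate at its known truth coordinate on the merged contig
#' (no aligner is involved), with all-match CIGARs, proper-pair flags,
#' signed TLEN, and NM/MD tags computed against the merged reference.
#' NM therefore counts homoeo-SNP sites where the source homoeolog
#' disagrees with the reference allele, plus surviving sequencing errors.
#'
#' @param fragments a `sim_fragments` data.frame for one gene.
#' @param merged the `merged_contig` for that gene.
#' @param config the [sim_config()] used for simulation.
#' @param mapq_demote_frac fraction of fragments demoted to mapping
#'   quality 20 (below the phasing threshold of 30).
#' @param dup_frac fraction of fragments flagged as duplicates (SAM flag
#'   0x400).
#' @param seed seed for the demotion/duplicate draws.
#' @return a data.frame of SAM records: `qname`, `flag`, `rname`, `pos`,
#'   `mapq`, `cigar`, `rnext`, `pnext`, `tlen`, `seq`, `qual`, `nm`, `md`.
#' @export
emit_alignments <- function(fragments, merged, config,
                            mapq_demote_frac = 0, dup_frac = 0,
                            seed = 1L) {
  ref <- seq_chars(merged$sequence)
  L <- length(ref)
  rl <- config$read_length
  if (any(fragments$start + fragments$frag_len - 1L > L))
    stop("fragment extends past the end of contig ", merged$contig_id,
         call. = FALSE)
  q <- if (config$base_error_rate > 0)
    min(40L, as.integer(round(-10 * log10(config$base_error_rate)))) else 40L
  qual <- phred_char(rep(q, rl))

  n <- nrow(fragments)
  draws <- with_seed(seed, list(demote = runif(n) < mapq_demote_frac,
                                dup = runif(n) < dup_frac))
  recs <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    fr <- fragments[i, ]
    p1 <- fr$start
    p2 <- fr$start + fr$frag_len - rl
    s1 <- seq_chars(fr$mate1_seq)
    s2 <- rev(chartr_vec(seq_chars(fr$mate2_seq)))  # reference orientation
    t1 <- tag_vs_ref(s1, ref, p1)
    t2 <- tag_vs_ref(s2, ref, p2)
    mapq <- if (draws$demote[i]) 20L else 60L
    dupbit <- if (draws$dup[i]) 1024L else 0L
    recs[[2L * i - 1L]] <- list(qname = fr$fragment_id,
                                flag = 99L + dupbit,
                                rname = merged$contig_id, pos = p1,
                                mapq = mapq, cigar = paste0(rl, "M"),
                                rnext = "=", pnext = p2,
                                tlen = fr$frag_len,
                                seq = fr$mate1_seq, qual = qual,
                                nm = t1$nm, md = t1$md)
    recs[[2L * i]] <- list(qname = fr$fragment_id,
                           flag = 147L + dupbit,
                           rname = merged$contig_id, pos = p2,
                           mapq = mapq, cigar = paste0(rl, "M"),
                           rnext = "=", pnext = p1,
                           tlen = -fr$frag_len,
                           seq = paste(s2, collapse = ""), qual = qual,
                           nm = t2$nm, md = t2$md)
  }
  data.table::rbindlist(recs) |> as.data.frame()
}

# NM and MD for an all-match alignment of `bases` at 1-based `pos`.
tag_vs_ref <- function(bases, ref, pos) {
  refbit <- ref[pos:(pos + length(bases) - 1L)]
  mm <- which(bases != refbit)
  if (length(mm) == 0L)
    return(list(nm = 0L, md = as.character(length(bases))))
  runs <- diff(c(0L, mm)) - 1L
  md <- paste0(paste0(runs, refbit[mm], collapse = ""),
               length(bases) - mm[length(mm)])
  list(nm = length(mm), md = md)
}

#' Write alignment records as SAM text
#'
#' @param alignments alignment data.frame from [emit_alignments()] or
#'   [read_sam()].
#' @param contigs named integer vector of reference lengths, or a list of
#'   `merged_contig` objects, for the `@SQ` header lines.
#' @param path output path.
#' @export
write_sam <- function(alignments, contigs, path) {
  if (is.list(contigs) && length(contigs) == 0L)
    contigs <- setNames(integer(0), character(0))
  if (is.list(contigs) && length(contigs) > 0L &&
      !is.null(contigs[[1]]$contig_id))
    contigs <- setNames(vapply(contigs, function(x) nchar(x$sequence), 0L),
                        vapply(contigs, `[[`, "", "contig_id"))
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs))
  a <- alignments[order(alignments$rname, alignments$pos), ]
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s\tNM:i:%d\tMD:Z:%s",
                  a$qname, a$flag, a$rname, a$pos, a$mapq, a$cigar,
                  a$rnext, a$pnext, a$tlen, a$seq, a$qual, a$nm, a$md)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read SAM text into an alignment data.frame
#'
#' Parses the eleven mandatory columns plus NM and MD tags. Headers are
#' returned in the `"header"` attribute. Only all-match or indel-bearing
#' CIGARs over A/C/G/T sequences are expected (the formats this package
#' emits and consumes); records are not otherwise validated.
#'
#' @param path SAM file path.
#' @return alignment data.frame as produced by [emit_alignments()].
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  get_tag <- function(fields, prefix) {
    hit <- fields[startsWith(fields, prefix)]
    if (length(hit)) sub(prefix, "", hit[1]) else NA_character_
  }
  out <- data.frame(
    qname = vapply(parts, `[[`, "", 1L),
    flag = as.integer(vapply(parts, `[[`, "", 2L)),
    rname = vapply(parts, `[[`, "", 3L),
    pos = as.integer(vapply(parts, `[[`, "", 4L)),
    mapq = as.integer(vapply(parts, `[[`, "", 5L)),
    cigar = vapply(parts, `[[`, "", 6L),
    rnext = vapply(parts, `[[`, "", 7L),
    pnext = as.integer(vapply(parts, `[[`, "", 8L)),
    tlen = as.integer(vapply(parts, `[[`, "", 9L)),
    seq = vapply(parts, `[[`, "", 10L),
    qual = vapply(parts, `[[`, "", 11L),
    stringsAsFactors = FALSE)
  out$nm <- as.integer(vapply(parts, get_tag, "", "NM:i:"))
  out$md <- vapply(parts, get_tag, "", "MD:Z:")
  attr(out, "header") <- hdr
  out
}

is_dup <- function(flag) bitwAnd(flag, 1024L) > 0L
is_reverse <- function(flag) bitwAnd(flag, 16L) > 0L
is_first_mate <- function(flag) bitwAnd(flag, 64L) > 0L
is_unmapped <- function(flag) bitwAnd(flag, 4L) > 0L
has_indel <- function(cigar) grepl("[ID]", cigar)
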