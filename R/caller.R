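#' Drop fragments exceeding the per-fragment mismatch budget
#'
#' Mirrors the mapping-identity criterion of at most 10 mismatches per
#' 2x100 bp paired-end fragment (>95% identity): the NM tags of the two
#' mates are summed and both mates are dropped when the sum exceeds the
#' budget. Unmapped mates contribute 0; singletons are judged on their
#' own NM.
#'
#' @param alignments alignment data.frame with `nm` present on mapped
#'   records.
#' @param max_fragment_mismatches mismatch budget per fragment.
#' @param missing_nm `"error"` (default) to fail on mapped records without
#'   NM, `"pass"` to treat missing NM as 0.
#' @return the filtered alignment data.frame.
#' @export
filter_fragments_by_nm <- function(alignments, max_fragment_mismatches = 10L,
                                   missing_nm = c("error", "pass")) {
  missing_nm <- match.arg(missing_nm)
  nm <- alignments$nm
  mapped <- !is_unmapped(alignments$flag)
  if (anyNA(nm[mapped])) {
    if (missing_nm == "error")
      stop("mapped records without NM tags; rerun with missing_nm = \"pass\" to treat them as 0",
           call. = FALSE)
    nm[is.na(nm)] <- 0L
  }
  nm[!mapped] <- 0L
  per_frag <- tapply(nm, alignments$qname, sum)
  keep <- names(per_frag)[per_frag <= max_fragment_mismatches]
  alignments[alignments$qname %in% keep, , drop = FALSE]
}

#' Build a per-position base-count pileup
#'
#' Counts aligned bases from records passing the mapping-quality floor,
#' not flagged as duplicates, at base quality at or above the floor.
#' Overlapping mates of one fragment contribute a single observation at a
#' column when they agree, and none when they disagree, so a fragment is
#' never double-counted. Records whose CIGAR contains indels are ignored
#' (downstream stages discard them anyway).
#'
#' @param alignments alignment data.frame (all-match CIGARs).
#' @param reference named character vector of contig sequences, or a list
#'   of `merged_contig` objects.
#' @param config a [caller_config()].
#' @return a data.frame of class `pileup`: `contig`, `pos`, `A`, `C`,
#'   `G`, `T`, `depth`.
#' @export
build_pileup <- function(alignments, reference, config = caller_config()) {
  reference <- ref_seqs(reference)
  a <- alignments[alignments$mapq >= config$min_mapq &
                    !is_dup(alignments$flag) &
                    !is_unmapped(alignments$flag) &
                    !has_indel(alignments$cigar), , drop = FALSE]
  if (!all(unique(a$rname) %in% names(reference)))
    stop("alignment contigs missing from reference: ",
         paste(setdiff(unique(a$rname), names(reference)), collapse = ", "),
         call. = FALSE)
  if (nrow(a) == 0L)
    return(empty_pileup())
  len <- nchar(a$seq)
  idx <- rep(seq_len(nrow(a)), len)
  off <- sequence(len)
  dt <- data.table::data.table(
    qname = a$qname[idx],
    contig = a$rname[idx],
    pos = a$pos[idx] + off - 1L,
    base = unlist(strsplit(a$seq, "", fixed = TRUE), use.names = FALSE),
    q = utf8ToInt(paste(a$qual, collapse = "")) - 33L)
  dt <- dt[dt$q >= config$min_baseq]
  if (nrow(dt) == 0L) return(empty_pileup())
  frag <- dedup_mate_votes(dt)
  base <- NULL; contig <- NULL; pos <- NULL  # NSE notes
  counts <- data.table::dcast(
    frag[, list(n = .N), by = list(contig, pos, base)],
    contig + pos ~ base, value.var = "n", fill = 0L)
  for (b in DNA_BASES) if (is.null(counts[[b]])) counts[[b]] <- 0L
  out <- as.data.frame(counts[, c("contig", "pos", DNA_BASES), with = FALSE])
  out$depth <- out$A + out$C + out$G + out$T
  out <- out[order(out$contig, out$pos), ]
  rownames(out) <- NULL
  class(out) <- c("pileup", "data.frame")
  out
}

# Overlapping-mate de-duplication at pileup columns: mates of one
# fragment contribute a single vote where they agree and none where they
# disagree. Exploits that a fragment has at most two records per column,
# so groups can be resolved by sorted neighbour comparison instead of a
# per-group aggregation.
dedup_mate_votes <- function(dt) {
  has_contig <- "contig" %in% names(dt)
  if (has_contig) data.table::setorder(dt, qname, contig, pos)
  else data.table::setorder(dt, qname, pos)
  n <- nrow(dt)
  if (n == 1L) return(dt)
  same_next <- dt$qname[-n] == dt$qname[-1] & dt$pos[-n] == dt$pos[-1]
  if (has_contig)
    same_next <- same_next & dt$contig[-n] == dt$contig[-1]
  first_of_pair <- c(same_next, FALSE)
  second_of_pair <- c(FALSE, same_next)
  singleton <- !first_of_pair & !second_of_pair
  agree <- first_of_pair & dt$base == c(dt$base[-1], "")
  dt[singleton | agree]
}

empty_pileup <- function() {
  out <- data.frame(contig = character(0), pos = integer(0),
                    A = integer(0), C = integer(0), G = integer(0),
                    T = integer(0), depth = integer(0))
  class(out) <- c("pileup", "data.frame")
  out
}

ref_seqs <- function(reference) {
  if (is.list(reference) && !is.null(reference[[1]]$contig_id))
    return(setNames(vapply(reference, `[[`, "", "sequence"),
                    vapply(reference, `[[`, "", "contig_id")))
  if (is.character(reference) && !is.null(names(reference)))
    return(reference)
  if (inherits(reference, "DNAStringSet"))
    return(setNames(as.character(reference), names(reference)))
  stop("reference must be a named character vector, DNAStringSet, or list of merged contigs",
       call. = FALSE)
}

#' Call biallelic homoeo-SNP sites from a pileup
#'
#' A site is emitted when depth meets `min_coverage`, the alternate
#' allele is seen at least `min_alt_count` times, its fraction of the
#' depth lies within the heterozygosity window, and exactly two bases
#' reach `min_alt_count` (one of them the reference base). Positions
#' where three or more bases qualify are skipped but logged, so read
#' sorting can still treat them as third-haplotype evidence; so are
#' positions where two non-reference bases qualify.
#'
#' @param pileup from [build_pileup()].
#' @param reference named character vector or list of `merged_contig`.
#' @param config a [caller_config()].
#' @return a data.frame of class `variant_sites`: `contig`, `pos`, `ref`,
#'   `alt`, `ref_count`, `alt_count`, `depth`, `alt_fraction`; skipped
#'   positions (with reasons) in the `"skipped"` attribute.
#' @export
call_variants <- function(pileup, reference, config = caller_config()) {
  reference <- ref_seqs(reference)
  if (nrow(pileup) == 0L) return(empty_sites())
  m <- as.matrix(pileup[, DNA_BASES])
  refbase <- substring(reference[pileup$contig], pileup$pos, pileup$pos)
  qual <- m >= config$min_alt_count
  nqual <- rowSums(qual)
  ref_idx <- match(refbase, DNA_BASES)
  ref_count <- m[cbind(seq_len(nrow(m)), ref_idx)]
  ref_qual <- qual[cbind(seq_len(nrow(m)), ref_idx)]

  multi <- nqual >= 3L
  noref <- nqual == 2L & !ref_qual
  cand <- nqual == 2L & ref_qual
  skipped <- data.frame(
    contig = pileup$contig[multi | noref],
    pos = pileup$pos[multi | noref],
    reason = ifelse(multi[multi | noref], "multiallelic", "ref_not_qualifying"),
    stringsAsFactors = FALSE)

  out <- empty_sites()
  if (any(cand)) {
    mm <- m[cand, , drop = FALSE]
    qq <- qual[cand, , drop = FALSE]
    ri <- ref_idx[cand]
    alt_idx <- vapply(seq_len(nrow(mm)), function(i) {
      j <- which(qq[i, ]); j[j != ri[i]][1L]
    }, 0L)
    alt_count <- mm[cbind(seq_len(nrow(mm)), alt_idx)]
    depth <- pileup$depth[cand]
    alt_fraction <- alt_count / depth
    keep <- depth >= config$min_coverage &
      alt_fraction >= config$min_alt_fraction &
      alt_fraction <= config$max_alt_fraction
    out <- data.frame(contig = pileup$contig[cand][keep],
                      pos = pileup$pos[cand][keep],
                      ref = refbase[cand][keep],
                      alt = DNA_BASES[alt_idx][keep],
                      ref_count = ref_count[cand][keep],
                      alt_count = alt_count[keep],
                      depth = depth[keep],
                      alt_fraction = alt_fraction[keep],
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    class(out) <- c("variant_sites", "data.frame")
  }
  attr(out, "skipped") <- skipped
  out
}

empty_sites <- function() {
  out <- data.frame(contig = character(0), pos = integer(0),
                    ref = character(0), alt = character(0),
                    ref_count = integer(0), alt_count = integer(0),
                    depth = integer(0), alt_fraction = numeric(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("variant_sites", "data.frame")
  out
}
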