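#' Write called sites as VCF v4.2
#'
#' One biallelic SNP record per site, genotype `0/1`, with depth and
#' allele counts in INFO (`DP`, `RO`, `AO`). Positions are 1-based.
#'
#' @param sites a `variant_sites` data.frame.
#' @param path output path.
#' @param force overwrite an existing file.
#' @return the path, invisibly.
#' @export
write_variants <- function(sites, path, force = FALSE) {
  if (file.exists(path) && !force)
    stop("refusing to overwrite ", path, " (use force = TRUE)",
         call. = FALSE)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=homeophaser",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total pileup depth\">",
           "##INFO=<ID=RO,Number=1,Type=Integer,Description=\"Reference allele observations\">",
           "##INFO=<ID=AO,Number=1,Type=Integer,Description=\"Alternate allele observations\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsample")
  body <- character(0)
  if (nrow(sites) > 0L)
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;RO=%d;AO=%d\tGT\t0/1",
                    sites$contig, sites$pos, sites$ref, sites$alt,
                    sites$depth, sites$ref_count, sites$alt_count)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a homeophaser VCF back into a `variant_sites` data.frame
#'
#' Inverse of [write_variants()]; malformed records are rejected with
#' their line number.
#'
#' @param path VCF path.
#' @return a `variant_sites` data.frame.
#' @export
read_variants <- function(path) {
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "#"))
  body_idx <- body_idx[nzchar(lines[body_idx])]
  if (length(body_idx) == 0L) return(empty_sites())
  parts <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 8L)
  if (length(bad))
    stop("malformed VCF record at line ", body_idx[bad[1]], call. = FALSE)
  info_field <- function(info, key, line) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([0-9]+)"), info))[[1]]
    if (length(m) < 2L)
      stop("malformed VCF record at line ", line, ": missing INFO ", key,
           call. = FALSE)
    as.integer(m[2])
  }
  pos <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  if (anyNA(pos))
    stop("malformed VCF record at line ", body_idx[which(is.na(pos))[1]],
         call. = FALSE)
  info <- vapply(parts, `[[`, "", 8L)
  out <- data.frame(
    contig = vapply(parts, `[[`, "", 1L),
    pos = pos,
    ref = vapply(parts, `[[`, "", 4L),
    alt = vapply(parts, `[[`, "", 5L),
    ref_count = mapply(info_field, info, "RO", body_idx),
    alt_count = mapply(info_field, info, "AO", body_idx),
    depth = mapply(info_field, info, "DP", body_idx),
    stringsAsFactors = FALSE)
  out$alt_fraction <- out$alt_count / out$depth
  rownames(out) <- NULL
  class(out) <- c("variant_sites", "data.frame")
  out
}
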