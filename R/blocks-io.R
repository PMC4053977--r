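#' Write phased blocks in HapCUT-style tabular format
#'
#' One header line per block (`BLOCK: contig=<id> block=<n> sites=<k>
#' mec=<m>`), one line per phased site (`<site_index> <hap0> <hap1>
#' <contig> <pos_1based> <ref_base> <alt_base>`), blocks terminated by a
#' line of eight asterisks.
#'
#' @param blocks list of `phased_block`.
#' @param path output path.
#' @export
write_blocks <- function(blocks, path) {
  lines <- unlist(lapply(blocks, function(b) {
    c(sprintf("BLOCK: contig=%s block=%d sites=%d mec=%d",
              b$contig, b$block_id, b$n_phased, b$mec),
      sprintf("%d %d %d %s %d %s %s",
              b$site_indices, b$hap0, b$hap1, b$contig, b$pos, b$ref,
              b$alt),
      "********")
  }))
  writeLines(if (is.null(lines)) character(0) else lines, path)
  invisible(path)
}

#' Read a HapCUT-style block file
#'
#' Inverse of [write_blocks()]; malformed lines are rejected with their
#' line number.
#'
#' @param path block file path.
#' @return list of `phased_block`.
#' @export
read_blocks <- function(path) {
  lines <- readLines(path)
  blocks <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(lines[i])) { i <- i + 1L; next }
    m <- regmatches(lines[i], regexec(
      "^BLOCK: contig=(\\S+) block=(\\d+) sites=(\\d+) mec=(\\d+)$",
      lines[i]))[[1]]
    if (length(m) != 5L)
      stop("malformed block header at line ", i, call. = FALSE)
    contig <- m[2]; block_id <- as.integer(m[3])
    k <- as.integer(m[4]); mec <- as.integer(m[5])
    site_lines <- lines[i + seq_len(k)]
    parts <- strsplit(site_lines, " ", fixed = TRUE)
    bad <- which(lengths(parts) != 7L)
    if (length(bad))
      stop("malformed site line at line ", i + bad[1], call. = FALSE)
    if (lines[i + k + 1L] != "********")
      stop("missing block terminator at line ", i + k + 1L, call. = FALSE)
    blocks[[length(blocks) + 1L]] <- new_phased_block(
      block_id, contig,
      site_indices = as.integer(vapply(parts, `[[`, "", 1L)),
      pos = as.integer(vapply(parts, `[[`, "", 5L)),
      ref = vapply(parts, `[[`, "", 6L),
      alt = vapply(parts, `[[`, "", 7L),
      hap0 = as.integer(vapply(parts, `[[`, "", 2L)),
      mec = mec)
    i <- i + k + 2L
  }
  blocks
}
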