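#' Extract per-fragment allele observations at called sites
#'
#' Builds the fragments x sites matrix that drives phasing. Records are
#' excluded (and tallied) when duplicate-flagged, when their CIGAR
#' contains indels, or when mapping quality is below `min_mapq`; bases
#' below `min_baseq` are treated as missing. The two mates of a fragment
#' are merged into one observation vector: when both mates cover a site
#' and disagree, the observation is missing. A base matching neither the
#' reference nor the alternate allele is recorded as offsite evidence —
#' it does not vote in phasing but flags possible third haplotypes for
#' the read sorter.
#'
#' @param alignments alignment data.frame for one contig (or containing
#'   it).
#' @param sites `variant_sites` for a single contig.
#' @param min_mapq mapping-quality floor (default 30, the read-sorting
#'   threshold).
#' @param min_baseq base-quality floor.
#' @return an object of class `fragment_matrix`: `contig`, `sites`,
#'   `fragment_ids`, `mat` (0 = ref allele, 1 = alt allele, NA =
#'   missing), `offsite` (logical matrix), `mapq` (per fragment),
#'   `excluded_counts` (named: mapq, indel, duplicate, offsite_allele).
#' @export
extract_fragments <- function(alignments, sites, min_mapq = 30L,
                              min_baseq = 20L) {
  contig <- unique(sites$contig)
  if (length(contig) > 1L)
    stop("sites span multiple contigs; use extract_fragments_by_contig()",
         call. = FALSE)
  excl <- c(mapq = 0L, indel = 0L, duplicate = 0L, offsite_allele = 0L)
  if (length(contig) == 0L || nrow(sites) == 0L) {
    return(structure(list(contig = if (length(contig)) contig else NA_character_,
                          sites = sites, fragment_ids = character(0),
                          mat = matrix(NA_integer_, 0, nrow(sites)),
                          offsite = matrix(FALSE, 0, nrow(sites)),
                          mapq = integer(0), excluded_counts = excl),
                     class = "fragment_matrix"))
  }
  a <- alignments[alignments$rname == contig &
                    !is_unmapped(alignments$flag), , drop = FALSE]
  dup <- is_dup(a$flag)
  excl["duplicate"] <- sum(dup)
  a <- a[!dup, , drop = FALSE]
  ind <- has_indel(a$cigar)
  excl["indel"] <- sum(ind)
  a <- a[!ind, , drop = FALSE]
  lowq <- a$mapq < min_mapq
  excl["mapq"] <- sum(lowq)
  a <- a[!lowq, , drop = FALSE]

  sites <- sites[order(sites$pos), , drop = FALSE]
  k <- nrow(sites)
  n_rec <- nrow(a)
  end <- a$pos + nchar(a$seq) - 1L
  # per (record, site) base observation, then mate-merged per fragment
  obs <- vector("list", k)
  for (j in seq_len(k)) {
    p <- sites$pos[j]
    cov <- which(a$pos <= p & end >= p)
    if (!length(cov)) { obs[[j]] <- NULL; next }
    o <- p - a$pos[cov] + 1L
    base <- substring(a$seq[cov], o, o)
    q <- utf8ToInt(paste(substring(a$qual[cov], o, o), collapse = "")) - 33L
    ok <- q >= min_baseq
    obs[[j]] <- data.frame(qname = a$qname[cov][ok], base = base[ok],
                           stringsAsFactors = FALSE)
  }
  frag_ids <- sort(unique(unlist(lapply(obs, function(d) d$qname))))
  n <- length(frag_ids)
  mat <- matrix(NA_integer_, n, k)
  offsite <- matrix(FALSE, n, k)
  for (j in seq_len(k)) {
    d <- obs[[j]]
    if (is.null(d) || nrow(d) == 0L) next
    agg <- tapply(d$base, d$qname, function(b) {
      u <- unique(b)
      if (length(u) == 1L) u else NA_character_  # mate disagreement
    })
    i <- match(names(agg), frag_ids)
    b <- unname(agg)
    code <- ifelse(is.na(b), NA_integer_,
                   ifelse(b == sites$ref[j], 0L,
                          ifelse(b == sites$alt[j], 1L, -1L)))
    off <- !is.na(code) & code == -1L
    excl["offsite_allele"] <- excl["offsite_allele"] + sum(off)
    code[off] <- NA_integer_
    mat[i, j] <- code
    offsite[i, j] <- off
  }
  keep <- rowSums(!is.na(mat)) > 0L | rowSums(offsite) > 0L
  mapq <- vapply(frag_ids, function(id) max(a$mapq[a$qname == id]), 0L)
  structure(list(contig = contig, sites = sites,
                 fragment_ids = frag_ids[keep],
                 mat = mat[keep, , drop = FALSE],
                 offsite = offsite[keep, , drop = FALSE],
                 mapq = unname(mapq[keep]),
                 excluded_counts = excl),
            class = "fragment_matrix")
}

#' Extract fragment matrices for every contig with called sites
#'
#' @inheritParams extract_fragments
#' @return named list of `fragment_matrix`, one per contig.
#' @export
extract_fragments_by_contig <- function(alignments, sites, min_mapq = 30L,
                                        min_baseq = 20L) {
  by_contig <- split(sites, sites$contig)
  lapply(by_contig, function(s) {
    class(s) <- c("variant_sites", "data.frame")
    extract_fragments(alignments, s, min_mapq, min_baseq)
  })
}

#' Partition sites into linkage blocks
#'
#' Two sites are linked when at least one fragment observes both (with
#' non-missing alleles); blocks are the connected components of this
#' co-observation graph. Sites no fragment links to another form
#' single-site blocks, which are unphasable but still reported.
#'
#' @param matrix a `fragment_matrix`.
#' @return list of strictly increasing integer vectors of site indices,
#'   ordered by first site.
#' @export
partition_blocks <- function(matrix) {
  k <- ncol(matrix$mat)
  if (k == 0L) return(list())
  edges <- integer(0)
  for (i in seq_len(nrow(matrix$mat))) {
    sites_i <- which(!is.na(matrix$mat[i, ]))
    if (length(sites_i) >= 2L)
      edges <- c(edges, rbind(sites_i[-length(sites_i)], sites_i[-1]))
  }
  g <- igraph::make_graph(edges, n = k, directed = FALSE)
  comp <- igraph::components(g)$membership
  blocks <- unname(split(seq_len(k), comp))
  blocks <- lapply(blocks, sort)
  blocks[order(vapply(blocks, `[[`, 0L, 1L))]
}

# Deterministic initialization: propagate relative phase between
# consecutive sites from the majority of co-observing fragments (equal
# allele codes on one fragment mean same phase).
linkage_init <- function(M) {
  k <- ncol(M)
  h <- integer(k)
  for (j in seq_len(k - 1L)) {
    both <- !is.na(M[, j]) & !is.na(M[, j + 1L])
    rel <- if (any(both)) {
      as.integer(sum(M[both, j] != M[both, j + 1L]) > sum(both) / 2)
    } else 0L
    h[j + 1L] <- bitwXor(h[j], rel)
  }
  h
}

# Mismatch counts of every fragment against hap h and its complement.
frag_distances <- function(M, h) {
  n <- nrow(M)
  Mh <- matrix(h, n, length(h), byrow = TRUE)
  matches <- rowSums(M == Mh, na.rm = TRUE)
  nobs <- rowSums(!is.na(M))
  list(d0 = nobs - matches, d1 = matches)
}

mec_of <- function(M, h) {
  d <- frag_distances(M, h)
  sum(pmin(d$d0, d$d1))
}

canonical_hap <- function(h) if (length(h) && h[1] == 1L) 1L - h else h

#' Phase one block by restarted alternating local search (minimum MEC)
#'
#' Finds a two-haplotype assignment minimizing the minimum-error
#' correction (MEC) score: starting from a random haplotype, alternately
#' (i) assign each fragment to the haplotype it mismatches least
#' (ties to haplotype 0) and (ii) reset each site's allele to the
#' majority among assigned fragments (ties to allele 0), until a fixed
#' point; the best of `restarts` seeded restarts (plus the all-reference
#' start) is kept. Results are deterministic given `seed`, with ties
#' between equal-MEC solutions broken toward the lexicographically
#' smallest haplotype-0 vector; haplotype 0 always starts with allele 0.
#'
#' @param matrix a `fragment_matrix`.
#' @param block integer vector of site indices (from
#'   [partition_blocks()]).
#' @param restarts,max_iter search effort.
#' @param seed integer seed.
#' @param block_id identifier stored on the result.
#' @return an object of class `phased_block`: `block_id`, `contig`,
#'   `site_indices`, `pos`, `ref`, `alt`, `hap0`, `hap1`, `mec`,
#'   `n_phased`, `chimeric`, `n_switches`.
#' @export
phase_block <- function(matrix, block, restarts = 20L, max_iter = 100L,
                        seed = 1L, block_id = 1L) {
  k <- length(block)
  M <- matrix$mat[, block, drop = FALSE]
  M <- M[rowSums(!is.na(M)) > 0L, , drop = FALSE]
  if (k == 1L) {
    best <- list(h = 0L, mec = 0L)
  } else {
    local_opt <- function(h) {
      for (iter in seq_len(max_iter)) {
        d <- frag_distances(M, h)
        assign0 <- d$d0 <= d$d1
        v1 <- colSums(M[assign0, , drop = FALSE] == 1L, na.rm = TRUE) +
          colSums(M[!assign0, , drop = FALSE] == 0L, na.rm = TRUE)
        v0 <- colSums(M[assign0, , drop = FALSE] == 0L, na.rm = TRUE) +
          colSums(M[!assign0, , drop = FALSE] == 1L, na.rm = TRUE)
        h_new <- as.integer(v1 > v0)
        if (identical(h_new, h)) break
        h <- h_new
      }
      h
    }
    # polish with suffix flips: alternating updates cannot perform the
    # coordinated segment flip that repairs switch-type local optima
    polish <- function(h) {
      h <- local_opt(h)
      repeat {
        m0 <- mec_of(M, h)
        improved <- FALSE
        for (j in 2:k) {
          h2 <- h
          h2[j:k] <- 1L - h2[j:k]
          if (mec_of(M, h2) < m0) {
            h <- local_opt(h2)
            improved <- TRUE
            break
          }
        }
        if (!improved) return(h)
      }
    }
    inits <- c(list(rep(0L, k), linkage_init(M)),
               lapply(seq_len(restarts), function(r)
                 with_seed(derive_seed(seed, r),
                           sample(c(0L, 1L), k, replace = TRUE))))
    best <- NULL
    for (h0 in inits) {
      h <- polish(h0)
      cand <- list(h = canonical_hap(h), mec = mec_of(M, h))
      if (is.null(best) || cand$mec < best$mec ||
          (cand$mec == best$mec &&
           paste(cand$h, collapse = "") < paste(best$h, collapse = "")))
        best <- cand
    }
  }
  hap0 <- canonical_hap(best$h)
  new_phased_block(block_id, matrix$contig, block,
                   matrix$sites$pos[block], matrix$sites$ref[block],
                   matrix$sites$alt[block], hap0, best$mec)
}

new_phased_block <- function(block_id, contig, site_indices, pos, ref, alt,
                             hap0, mec) {
  sw <- if (length(hap0) > 1L) sum(diff(hap0) != 0L) else 0L
  structure(list(block_id = as.integer(block_id), contig = contig,
                 site_indices = as.integer(site_indices),
                 pos = as.integer(pos), ref = ref, alt = alt,
                 hap0 = as.integer(hap0), hap1 = 1L - as.integer(hap0),
                 mec = as.integer(mec),
                 n_phased = length(hap0),
                 chimeric = sw >= 1L, n_switches = as.integer(sw)),
            class = "phased_block")
}

#' Exhaustive minimum-MEC phasing (test oracle)
#'
#' Enumerates all `2^(k-1)` haplotype vectors (first allele fixed at 0 by
#' complement symmetry) and returns the exact optimum, ties broken toward
#' the lexicographically smallest haplotype-0 vector. Guarded to blocks
#' of at most 20 sites.
#'
#' @inheritParams phase_block
#' @return list with `hap0` and `mec`.
#' @export
brute_force_phase <- function(matrix, block) {
  k <- length(block)
  if (k > 20L) stop("brute force guarded to blocks of <= 20 sites",
                    call. = FALSE)
  M <- matrix$mat[, block, drop = FALSE]
  M <- M[rowSums(!is.na(M)) > 0L, , drop = FALSE]
  best <- NULL
  for (code in 0:(2^(k - 1L) - 1L)) {
    # MSB-first bits make the enumeration lexicographic in hap0, so the
    # first strict minimum is the lexicographically smallest optimum
    h <- if (k == 1L) 0L else
      c(0L, rev(as.integer(intToBits(code))[seq_len(k - 1L)]))
    m <- mec_of(M, h)
    if (is.null(best) || m < best$mec) best <- list(hap0 = h, mec = m)
  }
  best
}

#' Chimerism of a phased block
#'
#' A block is chimeric when the reference-allele pattern alternates
#' between the two phases, i.e. when haplotype 0 changes value between
#' adjacent sites. Returns the switch count and the chimeric flag.
#'
#' @param block a `phased_block`.
#' @return list with `chimeric` and `n_switches`.
#' @export
classify_chimerism <- function(block) {
  sw <- if (length(block$hap0) > 1L) sum(diff(block$hap0) != 0L) else 0L
  list(chimeric = sw >= 1L, n_switches = as.integer(sw))
}

#' Phase every block of a contig
#'
#' Convenience wrapper: [partition_blocks()] then [phase_block()] per
#' block, numbering blocks along the contig.
#'
#' @inheritParams phase_block
#' @return list of `phased_block`.
#' @export
phase_contig <- function(matrix, restarts = 20L, max_iter = 100L,
                         seed = 1L) {
  blocks <- partition_blocks(matrix)
  lapply(seq_along(blocks), function(b)
    phase_block(matrix, blocks[[b]], restarts, max_iter,
                seed = derive_seed(seed, b), block_id = b))
}
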