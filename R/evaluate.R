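#' Truth phase table of a simulated dataset
#'
#' One row per homoeo-variant on each merged contig: the two alleles,
#' which homoeolog supplied the reference base, and the truth phase code
#' of homoeolog A (0 when A's allele is the reference allele).
#'
#' @param dataset a `sim_dataset`.
#' @return data.frame: `contig`, `pos`, `allele_a`, `allele_b`,
#'   `ref_origin`, `code_a`.
#' @export
truth_phase_table <- function(dataset) {
  rows <- lapply(seq_along(dataset$pairs), function(i) {
    p <- dataset$pairs[[i]]
    m <- dataset$contigs[[i]]
    if (length(p$variant_positions) == 0L) return(NULL)
    data.frame(contig = m$contig_id, pos = p$variant_positions,
               allele_a = p$allele_a, allele_b = p$allele_b,
               ref_origin = m$ref_origin,
               code_a = as.integer(m$ref_origin != "A"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(contig = character(0), pos = integer(0),
                                      allele_a = character(0),
                                      allele_b = character(0),
                                      ref_origin = character(0),
                                      code_a = integer(0))
  rownames(out) <- NULL
  out
}

#' Score phased blocks against truth
#'
#' Per block the label mapping (identity or complement) maximizing
#' agreement with truth is chosen, matching how curated genes are
#' compared to phasing output; switch errors — adjacent phased-site
#' pairs whose relative phase disagrees with truth — are reported
#' separately because accuracy alone hides switch structure. Only
#' multi-site blocks contribute: a single-site block is trivially
#' "correct" under best-of-two labeling and would inflate accuracy.
#' Phased sites absent from the truth table are excluded and tallied.
#'
#' @param blocks list of `phased_block`.
#' @param truth truth phase table from [truth_phase_table()].
#' @return an object of class `phasing_score`: `n_phased_snps`,
#'   `n_correct`, `accuracy`, `switch_errors`, `switch_opportunities`,
#'   `blocks_chimeric`, `blocks_total`, `n_untruthed`.
#' @export
phasing_accuracy <- function(blocks, truth) {
  if (length(blocks) == 0L) stop("no blocks to score", call. = FALSE)
  key <- paste(truth$contig, truth$pos)
  n_phased <- 0L; n_correct <- 0L
  sw_err <- 0L; sw_opp <- 0L; untruthed <- 0L
  for (b in blocks) {
    hit <- match(paste(b$contig, b$pos), key)
    known <- !is.na(hit)
    untruthed <- untruthed + sum(!known)
    if (sum(known) < 2L) next
    h <- b$hap0[known]
    t <- truth$code_a[hit[known]]
    agree <- sum(h == t)
    n <- length(h)
    n_phased <- n_phased + n
    n_correct <- n_correct + max(agree, n - agree)
    rel_h <- diff(h) != 0L
    rel_t <- diff(t) != 0L
    sw_err <- sw_err + sum(rel_h != rel_t)
    sw_opp <- sw_opp + n - 1L
  }
  structure(list(n_phased_snps = n_phased, n_correct = n_correct,
                 accuracy = if (n_phased) n_correct / n_phased else NA_real_,
                 switch_errors = sw_err, switch_opportunities = sw_opp,
                 blocks_chimeric = sum(vapply(blocks, `[[`, FALSE, "chimeric")),
                 blocks_total = length(blocks),
                 n_untruthed = untruthed),
            class = "phasing_score")
}

#' Precision and recall of read sorting against fragment-origin truth
#'
#' Phase labels are matched to homoeologs per block by majority vote
#' among the block's phase-assigned fragments, then fragments are scored
#' against their true source homoeolog. Recall is relative to all
#' fragments in the truth table, so upstream filtering and the strict
#' consistency rule both count against it.
#'
#' @param assignments the `assignments` data.frame of a `sort_report`.
#' @param fragment_truth data.frame with `fragment_id` and `source`
#'   ("A"/"B"), e.g. the simulator's fragment table.
#' @return list: `precision`, `recall`, `n_assigned`, `n_correct`,
#'   `confusion` (assigned phase x true source), or NA metrics when
#'   nothing was assigned.
#' @export
sorting_metrics <- function(assignments, fragment_truth) {
  unknown <- setdiff(assignments$fragment_id, fragment_truth$fragment_id)
  if (length(unknown))
    stop("fragments absent from truth: ", paste(head(unknown, 3),
                                                collapse = ", "),
         call. = FALSE)
  src <- setNames(fragment_truth$source, fragment_truth$fragment_id)
  ph <- assignments[assignments$category %in% c("phase0", "phase1"), ,
                    drop = FALSE]
  if (nrow(ph) == 0L)
    return(list(precision = NA_real_, recall = NA_real_, n_assigned = 0L,
                n_correct = 0L, confusion = NULL))
  ph$source <- src[ph$fragment_id]
  n_correct <- 0L
  for (key in unique(paste(ph$contig, ph$block_id))) {
    sel <- ph[paste(ph$contig, ph$block_id) == key, ]
    tab <- table(sel$category, sel$source)
    # best of the two phase->homoeolog label mappings for this block
    straight <- sum(tab[rownames(tab) == "phase0", colnames(tab) == "A"]) +
      sum(tab[rownames(tab) == "phase1", colnames(tab) == "B"])
    crossed <- sum(tab[rownames(tab) == "phase0", colnames(tab) == "B"]) +
      sum(tab[rownames(tab) == "phase1", colnames(tab) == "A"])
    n_correct <- n_correct + max(straight, crossed)
  }
  list(precision = n_correct / nrow(ph),
       recall = n_correct / nrow(fragment_truth),
       n_assigned = nrow(ph), n_correct = n_correct,
       confusion = table(assigned = ph$category, true_source = ph$source))
}

#' Percent-identity distribution diagnostics
#'
#' After successful phasing, consensus sequences compared against the
#' two truth homoeologs cluster at ~100% (own genome) and at the
#' homoeolog identity mean (other genome) — a bimodal distribution whose
#' mode gap is approximately `100 - identity_mean`. Chimeric unphased
#' contigs instead sit at intermediate identities and the gap collapses.
#'
#' @param queries data.frame with `contig`, `start`, `end`, `sequence`
#'   (e.g. consensus segments, or whole merged contigs with
#'   `start = 1`).
#' @param reference in `"truth"` mode, the list of `homoeolog_pair`
#'   objects (queries are compared to both homoeologs over their own
#'   coordinates); in `"align"` mode, a `DNAStringSet` against which the
#'   best local alignment identity is computed.
#' @param mode `"truth"` or `"align"`.
#' @return list: `identities` (data.frame `query`, `target`,
#'   `identity`), `mode_low`, `mode_high`, `mode_gap` (NA when the
#'   density has a single mode).
#' @export
identity_distribution <- function(queries, reference,
                                  mode = c("truth", "align")) {
  mode <- match.arg(mode)
  if (nrow(queries) == 0L) stop("no query sequences", call. = FALSE)
  if (mode == "truth") {
    gene_ids <- vapply(reference, `[[`, "", "gene_id")
    rows <- lapply(seq_len(nrow(queries)), function(i) {
      q <- queries[i, ]
      pair <- reference[[match(q$contig, gene_ids)]]
      data.frame(query = sprintf("%s:%d-%d", q$contig, q$start, q$end),
                 target = c("A", "B"),
                 identity = c(
                   gapless_identity(q$sequence,
                                    substr(pair$seq_a, q$start, q$end)),
                   gapless_identity(q$sequence,
                                    substr(pair$seq_b, q$start, q$end))),
                 stringsAsFactors = FALSE)
    })
    ids <- do.call(rbind, rows)
  } else {
    ref <- reference
    rows <- lapply(seq_len(nrow(queries)), function(i) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(rep(queries$sequence[i], length(ref))),
        ref, type = "local")
      best <- which.max(Biostrings::score(aln))
      data.frame(query = queries$contig[i],
                 target = names(ref)[best],
                 identity = Biostrings::pid(aln[best]),
                 stringsAsFactors = FALSE)
    })
    ids <- do.call(rbind, rows)
  }
  structure(c(list(identities = ids), density_modes(ids$identity)),
            class = "identity_distribution")
}

# Locate the two principal modes of an identity vector; gap is NA when
# the kernel density has a single local maximum.
density_modes <- function(x, bw = 0.5) {
  if (length(unique(round(x, 6))) == 1L)
    return(list(mode_low = x[1], mode_high = x[1], mode_gap = NA_real_))
  d <- density(x, bw = bw)
  peaks <- which(diff(sign(diff(d$y))) == -2) + 1L
  if (length(peaks) < 2L) {
    m <- d$x[which.max(d$y)]
    return(list(mode_low = m, mode_high = m, mode_gap = NA_real_))
  }
  top2 <- peaks[order(d$y[peaks], decreasing = TRUE)][1:2]
  list(mode_low = min(d$x[top2]), mode_high = max(d$x[top2]),
       mode_gap = abs(diff(d$x[top2])))
}
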