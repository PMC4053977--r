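#' Simulate one homoeolog pair with truth tracking
#'
#' Draws an ancestral coding sequence at the configured GC content and a
#' target percent identity from a truncated normal, then places the implied
#' number of substitutions uniformly without replacement on the B copy.
#' All divergence is carried by the B branch (A is the ancestor): only the
#' A/B difference pattern matters downstream, and one-sided divergence
#' keeps the truth bookkeeping exact. Uniform placement yields near
#' exponential inter-SNP spacing, the regime observed between wheat
#' homoeolog coding regions.
#'
#' @param config a [sim_config()].
#' @param gene_index 1-based gene index; the RNG substream is derived from
#'   `(config$seed, gene_index)` so gene sets are reproducible.
#' @return an object of class `homoeolog_pair` with fields `gene_id`,
#'   `seq_a`, `seq_b`, `length`, `target_identity`, `realized_identity`,
#'   `variant_positions` (1-based, strictly increasing), `allele_a`,
#'   `allele_b`.
#' @export
generate_homoeolog_pair <- function(config, gene_index) {
  validate_sim_config(config)
  with_seed(derive_seed(config$seed, gene_index, 1L), {
    L <- max(config$gene_length_min,
             round(rnorm(1, config$gene_length_mean, config$gene_length_sd)))
    L <- as.integer(L)
    gc <- config$gc_content
    anc <- sample(DNA_BASES, L, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    id <- rtrunc_norm(config$identity_mean, config$identity_sd,
                      config$identity_bounds)
    n_sub <- as.integer(round(L * (1 - id / 100)))
    if (n_sub < 0)
      stop("identity bounds imply a negative substitution count",
           call. = FALSE)
    n_sub <- min(n_sub, L)
    pos <- sort(sample.int(L, n_sub))
    allele_a <- anc[pos]
    allele_b <- vapply(allele_a,
                       function(b) sample(setdiff(DNA_BASES, b), 1L),
                       character(1), USE.NAMES = FALSE)
    seq_b <- anc
    seq_b[pos] <- allele_b
    structure(list(gene_id = sprintf("gene%04d", gene_index),
                   seq_a = paste(anc, collapse = ""),
                   seq_b = paste(seq_b, collapse = ""),
                   length = L,
                   target_identity = id,
                   realized_identity = 100 * (1 - n_sub / L),
                   variant_positions = as.integer(pos),
                   allele_a = allele_a,
                   allele_b = allele_b),
              class = "homoeolog_pair")
  })
}

# Truncated-normal draw by rejection; bounds are narrow relative to the
# bulk of the distribution so rejection is cheap.
rtrunc_norm <- function(mean, sd, bounds) {
  if (sd <= 0) return(min(max(mean, bounds[1]), bounds[2]))
  repeat {
    x <- rnorm(1, mean, sd)
    if (x >= bounds[1] && x <= bounds[2]) return(x)
  }
}

#' Collapse a homoeolog pair into a merged (possibly chimeric) reference
#'
#' Emulates an assembler collapsing two near-identical homoeologs into one
#' contig: at each variant position the merged sequence carries the allele
#' of one homoeolog, and the supplying homoeolog follows a two-state
#' Markov chain along the variants. A switch probability of 0 gives a pure
#' single-origin reference; any switch makes the contig chimeric.
#'
#' @param pair a `homoeolog_pair`.
#' @param switch_prob per-consecutive-variant probability of switching the
#'   reference-allele origin.
#' @param seed integer seed for the origin chain.
#' @return an object of class `merged_contig` with fields `contig_id`,
#'   `sequence`, `variant_positions`, `ref_origin` ("A"/"B" per variant),
#'   `n_switches`.
#' @export
build_merged_reference <- function(pair, switch_prob, seed = 1L) {
  stopifnot_scalar_prob(switch_prob, "switch_prob")
  nv <- length(pair$variant_positions)
  origin <- character(0)
  if (nv > 0) {
    origin <- with_seed(seed, {
      o <- character(nv)
      o[1] <- if (runif(1) < 0.5) "A" else "B"
      if (nv > 1) {
        flips <- runif(nv - 1) < switch_prob
        for (i in 2:nv) o[i] <- if (flips[i - 1]) setdiff(c("A", "B"), o[i - 1]) else o[i - 1]
      }
      o
    })
  }
  merged <- seq_chars(pair$seq_a)
  if (nv > 0) {
    b_sites <- pair$variant_positions[origin == "B"]
    merged[b_sites] <- pair$allele_b[origin == "B"]
  }
  structure(list(contig_id = pair$gene_id,
                 sequence = paste(merged, collapse = ""),
                 variant_positions = pair$variant_positions,
                 ref_origin = origin,
                 n_switches = if (nv > 1) sum(origin[-1] != origin[-nv]) else 0L),
            class = "merged_contig")
}

#' Simulate paired-end fragments from both homoeologs
#'
#' Per homoeolog the fragment count is `round(coverage * L / (2 *
#' read_length))`. Fragment lengths are normal draws resampled until they
#' fit within the gene; starts are uniform. Sequencing errors are
#' independent per-base substitutions at `base_error_rate`, replacing the
#' true base with a uniformly chosen different base; base qualities are
#' constant at `round(-10 * log10(base_error_rate))`.
#'
#' @param pair a `homoeolog_pair`.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return a `data.frame` (class `sim_fragments`) with one row per
#'   fragment: `fragment_id`, `gene_id`, `source` ("A"/"B"), `start`
#'   (1-based on the gene), `frag_len`, `mate1_seq`, `mate2_seq` (mate2 in
#'   sequencing orientation, i.e. reverse-complemented), and list-column
#'   `errors` of per-mate error offsets.
#' @export
simulate_fragments <- function(pair, config, seed = 1L) {
  validate_sim_config(config)
  L <- pair$length
  rl <- config$read_length
  n_frag <- as.integer(round(config$coverage_per_homoeolog * L / (2 * rl)))
  with_seed(seed, {
    out <- lapply(c("A", "B"), function(src) {
      src_seq <- seq_chars(if (src == "A") pair$seq_a else pair$seq_b)
      rows <- vector("list", n_frag)
      for (i in seq_len(n_frag)) {
        repeat {
          flen <- as.integer(round(rnorm(1, config$fragment_size_mean,
                                         config$fragment_size_sd)))
          if (flen >= rl && flen <= L) break
        }
        start <- sample.int(L - flen + 1L, 1L)
        frag <- src_seq[start:(start + flen - 1L)]
        m1 <- frag[1:rl]
        m2 <- rev(chartr_vec(frag[(flen - rl + 1L):flen]))
        e1 <- inject_errors(m1, config$base_error_rate)
        e2 <- inject_errors(m2, config$base_error_rate)
        rows[[i]] <- list(
          fragment_id = sprintf("%s_%s_f%05d", pair$gene_id, src, i),
          gene_id = pair$gene_id, source = src,
          start = start, frag_len = flen,
          mate1_seq = paste(e1$seq, collapse = ""),
          mate2_seq = paste(e2$seq, collapse = ""),
          errors = list(list(mate1 = e1$pos, mate2 = e2$pos)))
        rows[[i]]
      }
      rows
    })
    rows <- c(out[[1]], out[[2]])
    df <- data.frame(
      fragment_id = vapply(rows, `[[`, "", "fragment_id"),
      gene_id = vapply(rows, `[[`, "", "gene_id"),
      source = vapply(rows, `[[`, "", "source"),
      start = vapply(rows, `[[`, 0L, "start"),
      frag_len = vapply(rows, `[[`, 0L, "frag_len"),
      mate1_seq = vapply(rows, `[[`, "", "mate1_seq"),
      mate2_seq = vapply(rows, `[[`, "", "mate2_seq"),
      stringsAsFactors = FALSE)
    df$errors <- lapply(rows, function(r) r$errors[[1]])
    class(df) <- c("sim_fragments", class(df))
    df
  })
}

empty_fragments <- function() {
  df <- data.frame(fragment_id = character(0), gene_id = character(0),
                   source = character(0), start = integer(0),
                   frag_len = integer(0), mate1_seq = character(0),
                   mate2_seq = character(0), stringsAsFactors = FALSE)
  df$errors <- list()
  df
}

empty_alignments <- function() {
  data.frame(qname = character(0), flag = integer(0), rname = character(0),
             pos = integer(0), mapq = integer(0), cigar = character(0),
             rnext = character(0), pnext = integer(0), tlen = integer(0),
             seq = character(0), qual = character(0), nm = integer(0),
             md = character(0), stringsAsFactors = FALSE)
}

# Complement+reverse on a character vector of bases (mate2 orientation).
chartr_vec <- function(bases) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  unname(comp[bases])
}

inject_errors <- function(bases, rate) {
  if (rate <= 0) return(list(seq = bases, pos = integer(0)))
  hit <- which(runif(length(bases)) < rate)
  for (i in hit) bases[i] <- sample(setdiff(DNA_BASES, bases[i]), 1L)
  list(seq = bases, pos = hit)
}

#' Simulate a complete synthetic dataset
#'
#' Runs pair generation, reference merging, fragment simulation and
#' alignment emission for every gene in the configuration, under per-gene
#' derived seeds.
#'
#' @param config a [sim_config()].
#' @param mapq_demote_frac fraction of fragments whose records get mapping
#'   quality 20 instead of 60, to exercise the mapping-quality filters.
#' @param dup_frac fraction of fragments flagged as PCR/optical
#'   duplicates.
#' @return a list of class `sim_dataset`: `pairs` (list of
#'   `homoeolog_pair`), `contigs` (list of `merged_contig`), `fragments`
#'   (row-bound `sim_fragments`), `alignments` (SAM-record data.frame),
#'   `config`.
#' @export
simulate_dataset <- function(config, mapq_demote_frac = 0, dup_frac = 0) {
  validate_sim_config(config)
  pairs <- lapply(seq_len(config$n_genes),
                  function(i) generate_homoeolog_pair(config, i))
  contigs <- lapply(seq_len(config$n_genes), function(i)
    build_merged_reference(pairs[[i]], config$chimera_switch_prob,
                           seed = derive_seed(config$seed, i, 2L)))
  frags <- lapply(seq_len(config$n_genes), function(i)
    simulate_fragments(pairs[[i]], config,
                       seed = derive_seed(config$seed, i, 3L)))
  alns <- lapply(seq_len(config$n_genes), function(i)
    emit_alignments(frags[[i]], contigs[[i]], config,
                    mapq_demote_frac = mapq_demote_frac,
                    dup_frac = dup_frac,
                    seed = derive_seed(config$seed, i, 4L)))
  fragments <- if (length(frags)) do.call(rbind, frags) else
    empty_fragments()
  class(fragments) <- c("sim_fragments", "data.frame")
  alignments <- if (length(alns)) do.call(rbind, alns) else
    empty_alignments()
  structure(list(pairs = pairs, contigs = contigs,
                 fragments = fragments, alignments = alignments,
                 config = config),
            class = "sim_dataset")
}
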