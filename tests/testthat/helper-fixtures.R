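# Hand-built objects for unit tests, plus a memoised small pipeline run
# shared across test files.

make_pair <- function(seq_a, seq_b, gene_id = "gene0001") {
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  pos <- which(a != b)
  structure(list(gene_id = gene_id, seq_a = seq_a, seq_b = seq_b,
                 length = nchar(seq_a),
                 target_identity = 100 * (1 - length(pos) / nchar(seq_a)),
                 realized_identity = 100 * (1 - length(pos) / nchar(seq_a)),
                 variant_positions = as.integer(pos),
                 allele_a = a[pos], allele_b = b[pos]),
            class = "homoeolog_pair")
}

# Random pair at given length/variant count (ancestor unconstrained).
random_pair <- function(L, n_var, seed, gene_id = "gene0001") {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    a <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    pos <- sort(sample.int(L, n_var))
    b <- a
    for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), a[p]), 1)
    make_pair(paste(a, collapse = ""), paste(b, collapse = ""), gene_id)
  })
}

# Minimal alignment record data.frame; defaults give a mapped,
# properly-paired first mate with all-match CIGAR.
make_aln <- function(qname, seq, pos = 1L, flag = 99L, rname = "ctg1",
                     mapq = 60L, qual = NULL, cigar = NULL, nm = 0L) {
  n <- length(qname)
  if (is.null(qual)) qual <- strrep("I", nchar(seq))
  if (is.null(cigar)) cigar <- paste0(nchar(seq), "M")
  data.frame(qname = qname, flag = rep_len(flag, n),
             rname = rep_len(rname, n), pos = rep_len(pos, n),
             mapq = rep_len(mapq, n), cigar = rep_len(cigar, n),
             rnext = "=", pnext = rep_len(pos, n), tlen = 0L,
             seq = seq, qual = qual, nm = rep_len(nm, n),
             md = NA_character_, stringsAsFactors = FALSE)
}

# Fragment matrix straight from an observation matrix (rows fragments,
# columns sites; NA = missing).
make_fm <- function(mat, contig = "ctg1", pos = NULL, ref = NULL,
                    alt = NULL, offsite = NULL) {
  k <- ncol(mat)
  if (is.null(pos)) pos <- seq_len(k) * 10L
  if (is.null(ref)) ref <- rep("A", k)
  if (is.null(alt)) alt <- rep("C", k)
  sites <- data.frame(contig = contig, pos = as.integer(pos), ref = ref,
                      alt = alt, stringsAsFactors = FALSE)
  class(sites) <- c("variant_sites", "data.frame")
  structure(list(contig = contig, sites = sites,
                 fragment_ids = sprintf("f%03d", seq_len(nrow(mat))),
                 mat = mat,
                 offsite = if (is.null(offsite))
                   matrix(FALSE, nrow(mat), k) else offsite,
                 mapq = rep(60L, nrow(mat)),
                 excluded_counts = c(mapq = 0L, indel = 0L,
                                     duplicate = 0L, offsite_allele = 0L)),
            class = "fragment_matrix")
}

# Random phasing instance with known truth haplotype.
random_instance <- function(k, n_frag, noise, seed) {
  set.seed(seed)
  h <- c(0L, sample(c(0L, 1L), k - 1L, replace = TRUE))
  mat <- matrix(NA_integer_, n_frag, k)
  for (i in seq_len(n_frag)) {
    span <- sample(2:min(4L, k), 1L)
    start <- sample.int(k - span + 1L, 1L)
    sites <- start:(start + span - 1L)
    hap <- if (runif(1) < 0.5) h else 1L - h
    obs <- hap[sites]
    flip <- runif(span) < noise
    obs[flip] <- 1L - obs[flip]
    mat[i, sites] <- obs
  }
  list(fm = make_fm(mat), truth = h)
}

# Small pipeline runs are expensive; compute each configuration once.
.pipeline_cache <- new.env(parent = emptyenv())

cached_pipeline <- function(key, config, ...) {
  if (!exists(key, envir = .pipeline_cache))
    assign(key, run_pipeline(config, ...), envir = .pipeline_cache)
  get(key, envir = .pipeline_cache)
}

noise_free_config <- function() {
  sim_config(n_genes = 6L, coverage_per_homoeolog = 20,
             base_error_rate = 0, seed = 42L)
}

default_config_30 <- function() sim_config(n_genes = 30L, seed = 101L)
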