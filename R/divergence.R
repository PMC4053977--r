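#' Percent identity excluding gapped columns
#'
#' Identity between two aligned sequences computed over columns where
#' neither sequence has a gap. Case-insensitive; IUPAC ambiguity codes
#' never match anything (including themselves).
#'
#' @param aligned_a,aligned_b equal-length aligned sequences, gap symbol
#'   `-`.
#' @return percent identity in `[0, 100]`.
#' @export
gapless_identity <- function(aligned_a, aligned_b) {
  a <- toupper(seq_chars(aligned_a))
  b <- toupper(seq_chars(aligned_b))
  if (length(a) != length(b))
    stop("aligned sequences must have equal length", call. = FALSE)
  keep <- a != "-" & b != "-"
  if (!any(keep))
    stop("no gap-free columns to compare", call. = FALSE)
  a <- a[keep]; b <- b[keep]
  matches <- sum(a == b & a %in% DNA_BASES)
  100 * matches / length(a)
}

#' Distances between successive SNP positions
#'
#' @param variant_positions strictly increasing positions (bp).
#' @return integer vector of successive gaps; empty when fewer than two
#'   positions.
#' @export
inter_snp_distances <- function(variant_positions) {
  if (is.unsorted(variant_positions, strictly = TRUE))
    stop("variant positions must be strictly increasing", call. = FALSE)
  if (length(variant_positions) < 2L) return(integer(0))
  as.integer(diff(variant_positions))
}

#' Expected substitution count from length and percent identity
#'
#' `length * (1 - identity/100)`, rounded to one decimal. For a 200 bp
#' paired-end fragment this gives the mismatch budget implied by a
#' mapping identity threshold (12 at 94%, 10 at 95%); applied to the mean
#' coding length of curated homoeolog pairs (1199 bp at 97.26%) it gives
#' 32.9 — note this is an expected substitution *count*, even though it is
#' sometimes read as an average spacing, with which it happens to be
#' numerically close for these parameters.
#'
#' @param length sequence or fragment length in bp.
#' @param identity percent identity in `[0, 100]`.
#' @return expected substitutions, rounded to one decimal.
#' @export
expected_snp_count <- function(length, identity) {
  if (any(identity < 0 | identity > 100))
    stop("identity must be in [0, 100]", call. = FALSE)
  if (any(length <= 0)) stop("length must be positive", call. = FALSE)
  round(length * (1 - identity / 100), 1)
}

#' Fraction of homoeolog pairs above an identity threshold
#'
#' Under the normal model of homoeolog percent identity, the proportion
#' of pairs whose identity exceeds `threshold` is
#' `Phi((identity_mean - threshold) / identity_sd)`. At the wheat
#' parameters (mean 97.26, sd 1.20) a 94% threshold retains ~99.7% of
#' homoeolog pairs.
#'
#' @param identity_mean,identity_sd normal model parameters (percent).
#' @param threshold identity threshold (percent).
#' @return percentage of pairs above the threshold.
#' @export
inclusion_fraction <- function(identity_mean, identity_sd, threshold) {
  if (identity_sd <= 0) stop("identity_sd must be positive", call. = FALSE)
  100 * pnorm((identity_mean - threshold) / identity_sd)
}

#' Summarise divergence over a set of homoeolog pairs
#'
#' Computes the percent-identity mean/sd with a Shapiro-Wilk normality
#' p-value, and pooled inter-SNP gap statistics.
#'
#' @param pairs a list of `homoeolog_pair` objects (or any list whose
#'   elements have `realized_identity` and `variant_positions`).
#' @return a list of class `divergence_summary`: `n_pairs`,
#'   `identity_mean`, `identity_sd`, `normality_p` (NA when fewer than 3
#'   pairs or zero variance), `snp_gap_mean`, `snp_gap_sd` (0 when a
#'   single gap), `snp_gap_median`, `n_gaps`.
#' @export
summarize_divergence <- function(pairs) {
  ids <- vapply(pairs, `[[`, 0, "realized_identity")
  gaps <- unlist(lapply(pairs, function(p)
    inter_snp_distances(p$variant_positions)))
  if (is.null(gaps)) gaps <- integer(0)
  normality_p <- NA_real_
  if (length(ids) >= 3L && sd(ids) > 0)
    normality_p <- shapiro.test(ids)$p.value
  structure(list(
    n_pairs = length(ids),
    identity_mean = mean(ids),
    identity_sd = if (length(ids) > 1L) sd(ids) else 0,
    normality_p = normality_p,
    snp_gap_mean = if (length(gaps)) mean(gaps) else NA_real_,
    snp_gap_sd = if (length(gaps) > 1L) sd(gaps) else
      if (length(gaps) == 1L) 0 else NA_real_,
    snp_gap_median = if (length(gaps)) median(gaps) else NA_real_,
    n_gaps = length(gaps)),
    class = "divergence_summary")
}

#' Kolmogorov-Smirnov check of exponential inter-SNP spacing
#'
#' Uniform variant placement implies near-geometric integer gaps, the
#' discrete analogue of an exponential spacing law. Because the gaps are
#' integers, a raw KS test against a continuous exponential reports
#' spurious discreteness at large sample sizes, so a randomized
#' continuity correction is applied first: each integer gap `k` is spread
#' uniformly over `(k - 1, k]` by subtracting a U(0,1) draw. The
#' exponential rate is estimated from the corrected sample mean.
#'
#' When gaps are pooled across genes of differing divergence, each gene
#' contributes its own exponential rate and the pooled sample is a
#' mixture, which a large-sample KS test rightly rejects. Supplying
#' `expected_mean` (the per-gap expected spacing, `L / (m + 1)` for a
#' gene of length `L` with `m` variants) standardizes every gap to a
#' common unit-mean law before testing.
#'
#' @param gaps integer inter-SNP distances (pooled over genes).
#' @param seed seed for the continuity-correction draws.
#' @param expected_mean optional per-gap expected spacing (length 1 or
#'   `length(gaps)`) used to standardize gaps from heterogeneous genes.
#' @return the `ks.test` result (`htest`).
#' @export
snp_gap_exponential_test <- function(gaps, seed = 1L,
                                     expected_mean = NULL) {
  if (length(gaps) < 10L)
    stop("need at least 10 gaps for a meaningful test", call. = FALSE)
  x <- with_seed(seed, gaps - runif(length(gaps)))
  if (!is.null(expected_mean)) x <- x / expected_mean
  suppressWarnings(ks.test(x, "pexp", rate = 1 / mean(x)))
}
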