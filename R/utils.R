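#' @importFrom stats dnorm pnorm qnorm rbinom rnorm runif shapiro.test
#'   ks.test median sd setNames density
#' @importFrom utils read.delim write.table head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

# data.table is used via :: only; declare awareness so [.data.table
# keeps data.table semantics inside this namespace
.datatable.aware <- TRUE

#' Derive a reproducible sub-seed from a master seed and stream indices
#'
#' Gives each gene (and each stage within a gene) its own RNG substream so
#' that simulated gene sets are reproducible regardless of generation order.
#' The result always lies in `[1, 2^31 - 2]`.
#'
#' @param seed master integer seed.
#' @param ... one or more non-negative integer stream indices.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  x <- as.numeric(seed) %% 2147483647
  for (i in idx) {
    x <- (x * 48271 + as.numeric(i) * 8191 + 1) %% 2147483647
  }
  as.integer(x + 1)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Split a sequence string into a character vector of single bases.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

phred_char <- function(q) rawToChar(as.raw(33L + as.integer(q)))

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single probability in [0, 1]", name),
         call. = FALSE)
}
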