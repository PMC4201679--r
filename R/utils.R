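#' @useDynLib chickgp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats var sd cor rnorm runif rpois rbinom rbeta pnorm qnorm pt
#' @importFrom stats lm coef model.matrix aggregate setNames complete.cases
#' @importFrom utils read.table write.table head
NULL

#' Derive a reproducible substream seed from a root seed and a stream name
#'
#' All stochastic stages of the pipeline draw their seed from one root seed
#' through named substreams, so that any stage can be re-run in isolation
#' and still reproduce its output bit-for-bit.
#'
#' @param root integer root seed.
#' @param name character stream label, e.g. "population" or "fold2_lasso".
#' @return an integer seed in [0, 2^31 - 1).
#' @export
substream_seed <- function(root, name) {
  stopifnot(is.numeric(root), length(root) == 1L, is.character(name))
  h <- as.double(root %% 2147483647)
  for (b in utf8ToInt(paste0(name, ":"))) {
    h <- (h * 131 + b) %% 2147483647
  }
  as.integer(h)
}

# Set the RNG when a seed is supplied; NULL leaves the current RNG state alone.
set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# Cheap stable hash of an R object (for stage caching in run_pipeline).
# Polynomial rolling hash over the serialized bytes; collision risk is
# irrelevant at the scale of a handful of config stanzas.
object_hash <- function(x) {
  bytes <- serialize(x, connection = NULL, version = 2L)
  # drop the serialization header (R version stamp) so hashes are stable
  bytes <- bytes[-seq_len(14L)]
  h1 <- 0; h2 <- 0
  v <- as.double(bytes)
  for (i in seq_along(v)) {
    h1 <- (h1 * 257 + v[i]) %% 2147483629
    h2 <- (h2 * 263 + v[i]) %% 2147483587
  }
  sprintf("%08x%08x", as.integer(h1), as.integer(h2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
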