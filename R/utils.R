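#' Derive a per-replicate seed from a base seed
#'
#' Deterministic stream derivation so replicate batches are reproducible
#' and embarrassingly parallel: `seed = (base * 48271 + 262147 * i + j)`
#' reduced modulo the Mersenne prime `2^31 - 1` (never 0). `i` typically
#' indexes the grid point and `j` the replicate.
#'
#' @param baseSeed integer base seed.
#' @param i,j non-negative integer stream indices.
#' @return a single integer seed in `[1, 2^31 - 2]`.
#' @export
deriveSeed <- function(baseSeed, i = 0, j = 0) {
  m31 <- 2147483647
  s <- ((baseSeed %% m31) * 48271 + 262147 * i + j) %% m31
  as.integer(if (s == 0) 1 else s)
}
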