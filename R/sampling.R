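# Hybrid Poisson-Gaussian approximation to multinomial sampling.
#
# Wright-Fisher sampling at very large population sizes cannot use exact
# multinomial draws: cost grows with N and 32-bit totals overflow around
# 4e9. Categories with small expected count N*x_k are drawn as independent
# Poisson variables (drift acts on them almost independently), and the
# remaining common categories from a multivariate Gaussian with the
# multinomial mean and covariance, conditioned on the total left over after
# the rare draws, so the returned counts always sum exactly to N.

#' Draw approximately-multinomial category counts at arbitrary total
#'
#' Draws one vector of category counts summing exactly to `N` with
#' expected frequencies `x`. For `N <= exactCutoff` an exact
#' `stats::rmultinom()` draw is returned. Otherwise categories with
#' expected count `N * x_k <= threshold` are drawn as independent
#' Poisson(`N * x_k`) variables, and the remaining ("common") categories
#' from the multivariate Gaussian approximation to the multinomial with
#' total `N' = N - sum(rare draws)`, mean `N' x'` and covariance
#' `N' x'_i (delta_ij - x'_j)`, where `x'` renormalizes `x` over the common
#' set. The Gaussian is discretized by sampling all common categories but
#' the largest, rounding to integers, clamping negatives to zero, and
#' giving the largest category the exact remainder (decrementing the
#' largest counts in the astronomically rare event the remainder is
#' negative), so totals are conserved exactly.
#'
#' In the pathological case where the independent rare draws exceed `N`,
#' the rare block is redrawn (up to 100 times) rather than silently
#' truncated.
#'
#' Totals are handled as doubles; means remain exact up to about 2^53, and
#' the sampler is intended for totals up to ~1e15.
#'
#' @param N total count (non-negative; may far exceed 32-bit range).
#' @param x numeric vector of expected category frequencies; must be
#'   non-negative and sum to 1.
#' @param threshold rare-category expected-count threshold; default 10.
#' @param exactCutoff total at or below which exact multinomial sampling
#'   is used; default 1e6.
#' @return numeric vector of integer-valued counts, `sum == N`.
#' @examples
#' set.seed(1)
#' hybridMultinomial(1e12, c(0.5, 0.5 - 1e-11, 1e-11))
#' @export
hybridMultinomial <- function(N, x, threshold = 10, exactCutoff = 1e6) {
  if (length(N) != 1L || is.na(N) || N < 0 || N != floor(N))
    stop("N must be a single non-negative integer-valued number")
  if (any(is.na(x)) || any(x < 0))
    stop("x must be non-negative")
  if (abs(sum(x) - 1) > 1e-9)
    stop("x must sum to 1 (got ", format(sum(x)), ")")
  K <- length(x)
  if (N == 0) return(numeric(K))
  if (K == 1L) return(N)
  if (N <= exactCutoff)
    return(as.numeric(stats::rmultinom(1, as.integer(N), x)[, 1]))

  mu <- N * x
  rare <- which(mu <= threshold)
  common <- which(mu > threshold)
  if (!length(common))
    stop("all categories are rare at this threshold; ",
         "use a smaller threshold or the exact sampler")

  out <- numeric(K)
  if (length(rare)) {
    ok <- FALSE
    for (try in 1:100) {
      nr <- stats::rpois(length(rare), mu[rare])
      if (sum(nr) <= N) { ok <- TRUE; break }
    }
    if (!ok)
      stop("rare-category Poisson draws exceeded the total after 100 tries")
    out[rare] <- nr
  }
  Np <- N - sum(out)
  if (length(common) == 1L) {
    out[common] <- Np
    return(out)
  }
  xp <- x[common] / sum(x[common])
  drop <- which.max(xp)
  xs <- xp[-drop]
  mean <- Np * xs
  Sigma <- Np * (diag(xs, nrow = length(xs)) - outer(xs, xs))
  L <- chol(Sigma)
  v <- mean + drop(crossprod(L, stats::rnorm(length(xs))))
  n <- pmax(0, round(v))
  rem <- Np - sum(n)
  if (rem < 0) {
    deficit <- -rem
    while (deficit > 0) {
      k <- which.max(n)
      take <- min(deficit, n[k])
      n[k] <- n[k] - take
      deficit <- deficit - take
    }
    rem <- 0
  }
  idx <- common[-drop]
  out[idx] <- n
  out[common[drop]] <- rem
  out
}

# Poisson draw valid for arbitrarily large means (Gaussian approximation
# above 1e8, where rpois would overflow or lose nothing in accuracy).
.rpoisLarge <- function(lambda) {
  if (lambda <= 0) return(0)
  if (lambda < 1e8) return(as.numeric(stats::rpois(1, lambda)))
  max(0, round(stats::rnorm(1, lambda, sqrt(lambda))))
}
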