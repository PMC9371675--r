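# Closed-form critical population sizes, minimal gRNA numbers, the
# standing-variation amplification ratio, and binomial sigmoid fitting.
#
# The probability that resistance evolves before elimination follows
# p = 1 - exp(-N / N*): the population size N in units of a critical size
# N* set by the population-level rate at which fully resistant haplotypes
# are generated and establish against the drive background.

#' Probability of resistance at population size N
#'
#' `p = 1 - exp(-N / N*)`.
#'
#' @param N effective population size(s), non-negative.
#' @param NStar critical population size, positive.
#' @return probability vector.
#' @export
pResistance <- function(N, NStar) {
  if (any(NStar <= 0)) stop("NStar must be positive")
  if (any(N < 0)) stop("N must be non-negative")
  -expm1(-N / NStar)
}

#' Population size at a resistance-probability contour
#'
#' Inverts [pResistance()]: `N = N* ln(1 / (1 - p))`.
#'
#' @param p target probability of resistance, in (0, 1).
#' @param NStar critical population size.
#' @return population size at which the probability of resistance is `p`.
#' @export
contourN <- function(p, NStar) {
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly in (0, 1)")
  NStar * log(1 / (1 - p))
}

#' Critical population size: NHEJ-only resistance
#'
#' `N*_n = 1 / (4 gammaN (epsilon nu beta)^m)`. At `N = N*_n` the
#' population-level rate of generating functional NHEJ mutants at all m
#' sites, `2 N (epsilon nu beta)^m`, equals `1 / (2 gammaN)`.
#'
#' @param params a [DriveParams-class] object (uses epsilon, nu, beta, m).
#' @param consts a [TheoryConstants-class] object; default
#'   [theoryConstants()].
#' @return critical population size (`Inf` when the NHEJ functional-mutant
#'   rate is zero).
#' @export
criticalNNhej <- function(params, consts = theoryConstants()) {
  rate <- params@epsilon * params@nu * params@beta
  if (rate <= 0) return(Inf)
  1 / (4 * consts@gammaN * rate^params@m)
}

# gammaM for arbitrary m: fitted table for m <= length(gammaM), the
# product form sB * tau^m beyond it.
.gammaM <- function(consts, m) {
  if (m <= length(consts@gammaM)) consts@gammaM[m]
  else consts@sBDenovo * consts@tau^m
}

#' Critical population size: de novo SNP mutants only
#'
#' `N*_d = 1 / (4 gammaM (xi mu)^m)` where `gammaM = sB tau^m` reflects
#' sequential accumulation of resistant alleles over a timescale `tau`.
#'
#' @inheritParams criticalNNhej
#' @return critical population size (`Inf` when `xi mu = 0`).
#' @export
criticalNDenovo <- function(params, consts = theoryConstants()) {
  rate <- params@xi * params@mu
  if (rate <= 0) return(Inf)
  1 / (4 * .gammaM(consts, params@m) * rate^params@m)
}

#' Critical population size: standing variation (plus de novo) of SNPs
#'
#' `N*_s = 1 / (4 xi mu m (gamma xi mu / sigma)^(m-1) ln(1 + sB / (m sigma)))`.
#' For `m = 1` this is the single-site soft-sweep form (the establishment
#' probability averaged over the mutation-selection-balance frequency
#' distribution); for `m > 1` the power-law factor reflects the frequency
#' of haplotypes one mutation short of full resistance, amplifying weakly
#' deleterious standing variation.
#'
#' @inheritParams criticalNNhej
#' @return critical population size.
#' @export
criticalNStanding <- function(params, consts = theoryConstants()) {
  if (params@sigma <= 0)
    stop("standing-variation theory requires sigma > 0 ",
         "(mutation-selection balance)")
  rate <- params@xi * params@mu
  if (rate <= 0) return(Inf)
  m <- params@m
  1 / (4 * rate * m * (consts@gamma * rate / params@sigma)^(m - 1) *
         log(1 + consts@sB / (m * params@sigma)))
}

#' Critical population size: NHEJ and standing variation combined
#'
#' Treats the two resistance routes as independent:
#' `1 / N* = 1 / N*_n + 1 / N*_s`.
#'
#' @inheritParams criticalNNhej
#' @return combined critical population size.
#' @export
criticalNCombined <- function(params, consts = theoryConstants()) {
  1 / (1 / criticalNNhej(params, consts) +
         1 / criticalNStanding(params, consts))
}

#' Minimal gRNA number against NHEJ-only resistance
#'
#' Smallest integer `m` keeping the NHEJ-only probability of resistance at
#' or below `p` for population size `N`:
#' `m > (ln(ln(1 / (1 - p)) / (4 gammaN)) - ln N) / ln(epsilon nu beta)`.
#' The closed form is cross-validated against brute-force search over the
#' critical size; the brute-force answer is authoritative and returned,
#' with the closed-form value attached as attribute `"closedForm"`.
#'
#' @param N target population size.
#' @param p maximum acceptable probability of resistance; default 0.05.
#' @param params a [DriveParams-class] object (its `m` is ignored).
#' @param consts a [TheoryConstants-class] object.
#' @param mMax search limit for the brute force; default 100.
#' @return integer minimal m.
#' @export
minGuidesNhej <- function(N, p = 0.05, params, consts = theoryConstants(),
                          mMax = 100L) {
  rate <- params@epsilon * params@nu * params@beta
  if (rate <= 0 || rate >= 1)
    stop("epsilon * nu * beta must lie in (0, 1)")
  rhs <- (log(log(1 / (1 - p)) / (4 * consts@gammaN)) - log(N)) / log(rate)
  closed <- as.integer(floor(rhs) + 1)
  brute <- NA_integer_
  for (m in seq_len(mMax)) {
    pm <- params; pm@m <- as.integer(m)
    if (contourN(p, criticalNNhej(pm, consts)) >= N) { brute <- m; break }
  }
  if (is.na(brute)) stop("no m <= ", mMax, " keeps resistance below p")
  out <- as.integer(brute)
  attr(out, "closedForm") <- closed
  out
}

#' Minimal gRNA number against standing-variation resistance
#'
#' Smallest integer `m` keeping the probability of resistance from
#' standing (plus de novo) variation at or below `p`. The `"brute"`
#' method searches [criticalNStanding()] directly and is authoritative;
#' the `"lambert"` method evaluates the closed form
#' `m > W_{-1}(gamma ln(1/(1-p)) ln(gamma xi mu / sigma) /
#' (4 N sigma ln(1 + sB / sigma))) / ln(gamma xi mu / sigma)`
#' (valid for `sigma >> xi mu`, with the weak m-dependence of the
#' logarithm frozen at `m = 1`), falling back to brute force with a
#' warning when the Lambert argument leaves the W_{-1} domain.
#' Both are computed; the brute-force value is returned with the
#' closed form attached as attribute `"closedForm"`.
#'
#' @inheritParams minGuidesNhej
#' @param method `"brute"` (authoritative) or `"lambert"`.
#' @return integer minimal m.
#' @export
minGuidesStanding <- function(N, p = 0.05, params,
                              consts = theoryConstants(),
                              method = c("brute", "lambert"),
                              mMax = 100L) {
  method <- match.arg(method)
  if (params@sigma <= 0) stop("sigma must be positive")
  rate <- params@xi * params@mu
  if (rate <= 0) stop("xi * mu must be positive")

  brute <- NA_integer_
  for (m in seq_len(mMax)) {
    pm <- params; pm@m <- as.integer(m)
    if (contourN(p, criticalNStanding(pm, consts)) >= N) {
      brute <- m; break
    }
  }
  if (is.na(brute)) stop("no m <= ", mMax, " keeps resistance below p")

  lgr <- log(consts@gamma * rate / params@sigma)
  arg <- consts@gamma / (4 * N * params@sigma) * log(1 / (1 - p)) * lgr /
    log(1 + consts@sB / params@sigma)
  closed <- NA_integer_
  if (is.finite(arg) && arg < 0 && arg >= -exp(-1)) {
    w <- pracma::lambertWn(arg)
    closed <- as.integer(floor(w / lgr) + 1)
  } else if (method == "lambert") {
    warning("Lambert W_{-1} argument outside (-1/e, 0); ",
            "falling back to brute-force search")
  }
  out <- as.integer(brute)
  attr(out, "closedForm") <- closed
  out
}

#' Standing-variation amplification ratio N*_d / N*_s
#'
#' How much smaller the critical population size is with preexisting
#' variation than with de novo mutation alone:
#' `N*_d / N*_s = m gamma^(m-1) ln(1 + sB / (m sigma)) / (sigma^(m-1) gammaM)`.
#'
#' @param m number of gRNAs.
#' @param sigma heterozygous fitness cost of functional resistance before
#'   drive release.
#' @param consts a [TheoryConstants-class] object.
#' @return amplification ratio (dimensionless).
#' @examples
#' amplificationRatio(2, 0.01)  # about 217
#' @export
amplificationRatio <- function(m, sigma, consts = theoryConstants()) {
  m <- .checkM(m)
  if (sigma <= 0) stop("sigma must be positive")
  m * consts@gamma^(m - 1) * log(1 + consts@sB / (m * sigma)) /
    (sigma^(m - 1) * .gammaM(consts, m))
}

#' Fit the resistance sigmoid p(N) = 1 - exp(-N / N*)
#'
#' One-parameter maximum-binomial-likelihood fit of the critical
#' population size over `log N*`, with a 95% profile-likelihood
#' confidence interval. Replicate outcomes are Bernoulli, so the binomial
#' likelihood (not least squares) is the appropriate objective.
#'
#' @param outcomes data.frame with columns `N`, `nResistance`, `nReps`
#'   (e.g. the summary returned by [resistanceProbability()]).
#' @return a [SigmoidFit-class] object. When every replicate (or none)
#'   was resistant the likelihood is monotone in N*, and the fit reports
#'   the corresponding search-bracket bound with a `boundary` flag.
#' @export
fitSigmoid <- function(outcomes) {
  need <- c("N", "nResistance", "nReps")
  if (!all(need %in% names(outcomes)))
    stop("outcomes must have columns N, nResistance, nReps")
  if (nrow(outcomes) < 1L) stop("no data to fit")
  N <- outcomes$N; k <- outcomes$nResistance; n <- outcomes$nReps
  if (any(k < 0 | k > n)) stop("nResistance must lie in [0, nReps]")

  nll <- function(logNs) {
    pr <- pmin(pmax(-expm1(-N / exp(logNs)), 1e-15), 1 - 1e-15)
    -sum(k * log(pr) + (n - k) * log1p(-pr))
  }
  lo <- log(min(N)) - log(1e8)
  hi <- log(max(N)) + log(1e8)
  boundary <- "none"
  if (all(k == n)) boundary <- "lower"     # N* only bounded from above
  if (all(k == 0)) boundary <- "upper"     # N* only bounded from below
  opt <- stats::optimize(nll, c(lo, hi), tol = 1e-10)
  logNs <- opt$minimum
  if (boundary == "lower") logNs <- lo
  if (boundary == "upper") logNs <- hi

  # profile-likelihood 95% interval
  cut <- nll(logNs) + stats::qchisq(0.95, 1) / 2
  ciLo <- if (boundary == "upper" || nll(lo) <= cut) exp(lo) else
    exp(stats::uniroot(function(z) nll(z) - cut, c(lo, logNs))$root)
  ciHi <- if (boundary == "lower" || nll(hi) <= cut) exp(hi) else
    exp(stats::uniroot(function(z) nll(z) - cut, c(logNs, hi))$root)

  new("SigmoidFit", NStar = exp(logNs), logLik = -nll(logNs),
      ci = c(ciLo, ciHi), boundary = boundary)
}

#' Fit constant implied by a fitted critical population size
#'
#' Converts a fitted `N*` back to the mechanism's fit constant:
#' `gammaN = 1 / (4 N* (epsilon nu beta)^m)` for NHEJ-only dynamics, or
#' `gammaM = 1 / (4 N* (xi mu)^m)` for de novo SNP dynamics.
#'
#' @param fit a [SigmoidFit-class] object (or a numeric N*).
#' @param params a [DriveParams-class] object.
#' @param mechanism `"nhej"` or `"denovo"`.
#' @return implied fit constant.
#' @export
impliedGamma <- function(fit, params, mechanism = c("nhej", "denovo")) {
  mechanism <- match.arg(mechanism)
  NStar <- if (is(fit, "SigmoidFit")) fit@NStar else as.numeric(fit)
  rate <- switch(mechanism,
                 nhej = params@epsilon * params@nu * params@beta,
                 denovo = params@xi * params@mu)
  1 / (4 * NStar * rate^params@m)
}
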