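#' @import methods
NULL

.ALLELES <- c("W", "R", "N", "D")

#' DriveParams: parameters of the multiplexed suppression-drive model
#'
#' Container for all rates, fitness parameters and demographic constants of
#' the model. All rates are per generation, per individual, per target site,
#' in an independent-sites model.
#'
#' @slot epsilon per-site cleavage probability in W/D germlines.
#' @slot nu fraction of cleavage events resolved by NHEJ (rather than homing).
#' @slot beta fraction of NHEJ repair products that are functional (R);
#'   the remaining fraction `1 - beta` is nonfunctional (N).
#' @slot xi fraction of de novo single-nucleotide mutations that are
#'   functional.
#' @slot mu target-site mutation rate per generation; default
#'   `18 * 3e-9 = 5.4e-8` (18 bp target, Drosophila base-pair rate).
#' @slot sigma heterozygous fitness cost of a functional resistant allele R
#'   (in females, in the absence of drive).
#' @slot s homozygous fitness cost of nonfunctional alleles (D or N);
#'   default 1 (female sterility/death).
#' @slot h dominance coefficient of D over W (somatic cost of leaky
#'   Cas9 expression in W/D females); default 0.3.
#' @slot hN dominance coefficient of N over W; default 0.02.
#' @slot m number of gRNAs / multiplexed target sites.
#' @slot Rm intrinsic growth rate of the Beverton-Holt recruitment model
#'   (low-density offspring multiplier per individual); default 6.
#' @slot K carrying capacity, identified with the effective population
#'   size N of the analytic theory.
#' @slot releaseFreq drive allele frequency introduced among male
#'   chromosomes at release (D/D homozygous males); default 0.1.
#' @slot resistanceThreshold summed frequency of fully resistant haplotypes
#'   at which a replicate is classified resistant; default 0.95.
#' @slot maxGenerations censoring horizon of a replicate; default 1000.
#' @slot burnIn logical; run a pre-release burn-in of
#'   `ceiling(burnInMultiplier / sigma)` generations so resistant standing
#'   variation equilibrates at mutation-selection balance.
#' @slot burnInMultiplier multiplier on the `1/sigma` burn-in duration.
#' @slot samplerThreshold expected-count threshold below which a category is
#'   drawn as Poisson in the hybrid sampler; default 10.
#' @slot exactCutoff total count at or below which exact multinomial
#'   sampling is used instead of the hybrid approximation; default 1e6.
#' @slot deterministicOffspring logical; if TRUE the offspring total is the
#'   rounded Beverton-Holt expectation instead of a Poisson draw (pure
#'   Wright-Fisher mode used in drift checks).
#' @slot fitnessOverrides named list overriding individual site-pair fitness
#'   factors; names are unordered allele pairs such as "RR", "RN", "RD", "ND".
#' @export
setClass("DriveParams", representation(
  epsilon = "numeric", nu = "numeric", beta = "numeric", xi = "numeric",
  mu = "numeric", sigma = "numeric", s = "numeric", h = "numeric",
  hN = "numeric", m = "integer", Rm = "numeric", K = "numeric",
  releaseFreq = "numeric", resistanceThreshold = "numeric",
  maxGenerations = "integer", burnIn = "logical",
  burnInMultiplier = "numeric", samplerThreshold = "numeric",
  exactCutoff = "numeric", deterministicOffspring = "logical",
  fitnessOverrides = "list"))

setValidity("DriveParams", function(object) {
  msg <- character()
  p01 <- c(epsilon = object@epsilon, nu = object@nu, beta = object@beta,
           xi = object@xi, mu = object@mu, sigma = object@sigma,
           s = object@s, h = object@h, hN = object@hN,
           resistanceThreshold = object@resistanceThreshold)
  bad <- names(p01)[is.na(p01) | p01 < 0 | p01 > 1]
  if (length(bad))
    msg <- c(msg, paste0("parameters must lie in [0, 1]: ",
                         paste(bad, collapse = ", ")))
  if (object@releaseFreq < 0 || object@releaseFreq >= 1)
    msg <- c(msg, "releaseFreq must lie in [0, 1)")
  if (is.na(object@m) || object@m < 1L)
    msg <- c(msg, "m must be a positive integer")
  if (object@Rm <= 1) msg <- c(msg, "Rm must exceed 1")
  if (object@K < 1) msg <- c(msg, "K must be at least 1")
  if (object@maxGenerations < 1L) msg <- c(msg, "maxGenerations must be >= 1")
  if (object@burnInMultiplier <= 0) msg <- c(msg, "burnInMultiplier must be > 0")
  if (object@samplerThreshold < 0) msg <- c(msg, "samplerThreshold must be >= 0")
  ov <- object@fitnessOverrides
  if (length(ov) && (is.null(names(ov)) || any(!nzchar(names(ov)))))
    msg <- c(msg, "fitnessOverrides must be a named list")
  if (length(msg)) msg else TRUE
})

#' Construct a DriveParams object
#'
#' Defaults follow the model's standard parameterization: cleavage
#' `epsilon = 0.95` and NHEJ rate `nu = 0.05` (doublesex-like target site),
#' mutation rate `mu = 5.4e-8` (18 bp site at 3e-9 per bp), homozygous
#' nonfunctional cost `s = 1`, dominance `h = 0.3` (W/D) and `hN = 0.02`
#' (W/N), release at drive frequency 0.1 in males, and a resistance
#' criterion of 0.95 on the summed frequency of fully resistant haplotypes.
#'
#' @param m number of gRNAs / target sites (required).
#' @param K carrying capacity = effective population size (required).
#' @param epsilon,nu,beta,xi,mu,sigma,s,h,hN,Rm,releaseFreq model rates and
#'   fitness parameters; see the class documentation.
#' @param resistanceThreshold,maxGenerations outcome classification controls.
#' @param burnIn,burnInMultiplier standing-variation burn-in controls.
#' @param samplerThreshold,exactCutoff hybrid multinomial sampler controls.
#' @param deterministicOffspring use a deterministic offspring total.
#' @param fitnessOverrides named list of site-pair fitness overrides.
#' @return A validated [DriveParams-class] object.
#' @examples
#' driveParams(m = 2, K = 1e6, beta = 0.01, sigma = 0.01)
#' @export
driveParams <- function(m, K, epsilon = 0.95, nu = 0.05, beta = 1, xi = 1,
                        mu = 5.4e-8, sigma = 0.01, s = 1, h = 0.3,
                        hN = 0.02, Rm = 6, releaseFreq = 0.1,
                        resistanceThreshold = 0.95, maxGenerations = 1000L,
                        burnIn = FALSE, burnInMultiplier = 1,
                        samplerThreshold = 10, exactCutoff = 1e6,
                        deterministicOffspring = FALSE,
                        fitnessOverrides = list()) {
  new("DriveParams", epsilon = epsilon, nu = nu, beta = beta, xi = xi,
      mu = mu, sigma = sigma, s = s, h = h, hN = hN, m = as.integer(m),
      Rm = Rm, K = as.numeric(K), releaseFreq = releaseFreq,
      resistanceThreshold = resistanceThreshold,
      maxGenerations = as.integer(maxGenerations), burnIn = burnIn,
      burnInMultiplier = burnInMultiplier,
      samplerThreshold = samplerThreshold, exactCutoff = exactCutoff,
      deterministicOffspring = deterministicOffspring,
      fitnessOverrides = fitnessOverrides)
}

setMethod("show", "DriveParams", function(object) {
  cat("DriveParams: m =", object@m, "gRNAs, K =",
      format(object@K, big.mark = ","), "\n")
  cat("  cleavage epsilon =", object@epsilon, " NHEJ nu =", object@nu,
      " beta =", object@beta, "\n")
  cat("  mutation mu =", object@mu, " xi =", object@xi,
      " sigma =", object@sigma, "\n")
  cat("  fitness s =", object@s, " h =", object@h, " hN =", object@hN, "\n")
  cat("  demography Rm =", object@Rm, " release =", object@releaseFreq,
      if (object@burnIn) " (with burn-in)" else "", "\n")
})

#' TheoryConstants: fitted constants of the critical-population-size theory
#'
#' Constants calibrated against replicate simulations that enter the
#' closed-form expressions for the critical population size N*.
#'
#' @slot gammaN NHEJ fit constant (independent of m); default 0.2.
#' @slot gammaM de novo fit constants for m = 1, 2, 3; default
#'   `c(0.76, 6, 55)`. For larger m the product form
#'   `sBDenovo * tau^m` is used.
#' @slot sBDenovo effective beneficial coefficient in `gammaM = sB * tau^m`;
#'   default 0.09.
#' @slot tau accumulation timescale (generations) in the same product form;
#'   default 8.5.
#' @slot gamma standing-variation scaling constant; default 2.
#' @slot sB effective establishment advantage of a fully resistant
#'   haplotype against the drive background; default 0.5.
#' @export
setClass("TheoryConstants", representation(
  gammaN = "numeric", gammaM = "numeric", sBDenovo = "numeric",
  tau = "numeric", gamma = "numeric", sB = "numeric"))

setValidity("TheoryConstants", function(object) {
  vals <- c(object@gammaN, object@gammaM, object@sBDenovo, object@tau,
            object@gamma, object@sB)
  if (any(!is.finite(vals)) || any(vals <= 0))
    "all theory constants must be positive and finite"
  else TRUE
})

#' Construct a TheoryConstants object
#'
#' @param gammaN,gammaM,sBDenovo,tau,gamma,sB see
#'   [TheoryConstants-class]; defaults are the values fitted from
#'   500-replicate simulation batches.
#' @return A [TheoryConstants-class] object.
#' @examples
#' theoryConstants()
#' @export
theoryConstants <- function(gammaN = 0.2, gammaM = c(0.76, 6, 55),
                            sBDenovo = 0.09, tau = 8.5, gamma = 2,
                            sB = 0.5) {
  new("TheoryConstants", gammaN = gammaN, gammaM = gammaM,
      sBDenovo = sBDenovo, tau = tau, gamma = gamma, sB = sB)
}

setMethod("show", "TheoryConstants", function(object) {
  cat("TheoryConstants: gammaN =", object@gammaN, " gammaM =",
      paste(object@gammaM, collapse = ", "), "\n")
  cat("  de novo sB =", object@sBDenovo, " tau =", object@tau,
      "; standing gamma =", object@gamma, " sB =", object@sB, "\n")
})

#' PopulationState: adult counts by sex and diploid genotype
#'
#' @slot generation generation index (0 at drive release).
#' @slot counts numeric matrix with rows `male`, `female` and one column
#'   per diploid genotype (labels from [enumerateGenotypes()]). Counts are
#'   stored as doubles because totals can exceed the 32-bit integer range.
#' @slot m number of target sites the genotype columns refer to.
#' @export
setClass("PopulationState", representation(
  generation = "integer", counts = "matrix", m = "integer"))

setValidity("PopulationState", function(object) {
  msg <- character()
  if (nrow(object@counts) != 2L ||
      !identical(rownames(object@counts), c("male", "female")))
    msg <- c(msg, "counts must have rows 'male' and 'female'")
  if (any(object@counts < 0) || any(!is.finite(object@counts)))
    msg <- c(msg, "counts must be finite and non-negative")
  if (any(object@counts != floor(object@counts)))
    msg <- c(msg, "counts must be integer-valued")
  if (ncol(object@counts) != nGenotypes(object@m))
    msg <- c(msg, "number of genotype columns inconsistent with m")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PopulationState", function(object) {
  tot <- sum(object@counts)
  cat("PopulationState: generation", object@generation, "- m =", object@m,
      "\n  total", format(tot, big.mark = ","), "adults (",
      format(sum(object@counts["male", ]), big.mark = ","), "male /",
      format(sum(object@counts["female", ]), big.mark = ","), "female )\n")
  occ <- which(colSums(object@counts) > 0)
  cat("  occupied genotypes:", length(occ), "of", ncol(object@counts), "\n")
})

#' Total number of adults in a state
#' @param state a [PopulationState-class] object.
#' @return numeric scalar.
#' @export
populationSize <- function(state) sum(state@counts)

#' Genotype counts of a state
#' @param state a [PopulationState-class] object.
#' @return the sex-by-genotype count matrix.
#' @export
genotypeCounts <- function(state) state@counts

#' ReplicateOutcome: classified endpoint of one replicate
#'
#' @slot outcome one of `"resistance"`, `"elimination"`, `"censored"`.
#' @slot tResistance generation of first crossing of the resistance
#'   criterion (NA if resistance did not arise).
#' @slot tElimination generation of population elimination (NA otherwise).
#' @slot finalFreqs named haplotype frequency vector at the endpoint
#'   (over all adult chromosomes of both sexes).
#' @slot trajectory optional per-generation summary matrix (columns:
#'   generation, total, resistantFreq, then haplotype frequencies).
#' @export
setClass("ReplicateOutcome", representation(
  outcome = "character", tResistance = "numeric", tElimination = "numeric",
  finalFreqs = "numeric", trajectory = "ANY"))

setValidity("ReplicateOutcome", function(object) {
  msg <- character()
  if (!object@outcome %in% c("resistance", "elimination", "censored"))
    msg <- c(msg, "outcome must be resistance, elimination or censored")
  if (object@outcome == "resistance" && is.na(object@tResistance))
    msg <- c(msg, "resistance outcome requires tResistance")
  if (object@outcome == "elimination" && is.na(object@tElimination))
    msg <- c(msg, "elimination outcome requires tElimination")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ReplicateOutcome", function(object) {
  cat("ReplicateOutcome:", object@outcome)
  if (!is.na(object@tResistance))
    cat(" (t_resistance =", object@tResistance, ")")
  if (!is.na(object@tElimination))
    cat(" (t_elimination =", object@tElimination, ")")
  cat("\n")
  top <- sort(object@finalFreqs[object@finalFreqs > 0], decreasing = TRUE)
  if (length(top))
    cat("  final haplotype frequencies:",
        paste(names(top), signif(top, 3), sep = "=", collapse = " "), "\n")
})

#' SigmoidFit: maximum-likelihood fit of p(N) = 1 - exp(-N / N*)
#'
#' @slot NStar fitted critical population size.
#' @slot logLik binomial log-likelihood at the optimum.
#' @slot ci 95% profile-likelihood confidence interval for N*.
#' @slot boundary `"none"`, or `"lower"`/`"upper"` when all outcomes were
#'   resistant / none were, so N* is only bounded on one side.
#' @export
setClass("SigmoidFit", representation(
  NStar = "numeric", logLik = "numeric", ci = "numeric",
  boundary = "character"))

setMethod("show", "SigmoidFit", function(object) {
  cat("SigmoidFit: N* =", signif(object@NStar, 4), "\n")
  cat("  95% CI [", signif(object@ci[1], 4), ",", signif(object@ci[2], 4),
      "] logLik =", round(object@logLik, 2),
      if (object@boundary != "none")
        paste0(" (boundary: ", object@boundary, ")") else "", "\n")
})

#' Fitted critical population size
#' @param fit a [SigmoidFit-class] object.
#' @return numeric scalar N*.
#' @export
criticalN <- function(fit) fit@NStar
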