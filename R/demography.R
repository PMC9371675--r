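# Density-dependent Beverton-Holt demography with separate sexes.
# Fitness costs are manifest as reduced female survival to adulthood;
# males of all genotypes survive equally.

#' Expected Beverton-Holt offspring total
#'
#' Mean recruitment `M = 2 Rm F / (1 + (Rm - 1) N_t / K)` where `F` is the
#' number of adult females, `N_t` the total adult count and `K` the
#' carrying capacity. An all-wild-type population at `N_t = K` with
#' `F = K / 2` reproduces itself exactly (`M = K`); at low density each
#' female contributes `2 Rm` offspring, i.e. per-capita growth `Rm`.
#'
#' @param state a [PopulationState-class] object.
#' @param params a [DriveParams-class] object.
#' @return expected offspring total (non-negative real).
#' @export
expectedOffspringTotal <- function(state, params) {
  Ft <- sum(state@counts["female", ])
  Nt <- sum(state@counts)
  2 * params@Rm * Ft / (1 + (params@Rm - 1) * Nt / params@K)
}

#' All-wild-type population state at carrying capacity
#'
#' @param params a [DriveParams-class] object.
#' @return a [PopulationState-class] with `floor(K / 2)` males and
#'   `ceiling(K / 2)` females, all homozygous wild type, at generation 0.
#' @export
wildTypeState <- function(params) {
  G <- nGenotypes(params@m)
  counts <- matrix(0, 2, G,
                   dimnames = list(c("male", "female"),
                                   enumerateGenotypes(params@m)$label))
  counts["male", 1] <- floor(params@K / 2)
  counts["female", 1] <- ceiling(params@K / 2)
  new("PopulationState", generation = 0L, counts = counts, m = params@m)
}

# One generation transition on a raw 2 x G count matrix. Returns the new
# count matrix, or NULL when the population is eliminated (either sex
# empty, or zero offspring drawn). `model` is a .buildModel() list.
.stepCounts <- function(counts, model, params) {
  maleCounts <- counts[1L, ]
  femCounts <- counts[2L, ]
  Mt <- sum(maleCounts); Ft <- sum(femCounts)
  if (Mt == 0 || Ft == 0) return(NULL)

  malePool <- drop(maleCounts %*% model$gameteM) / Mt
  femPool <- drop(femCounts %*% model$gameteM) / Ft

  outer <- malePool %o% femPool
  S <- outer + t(outer)
  pg <- S[cbind(model$gi, model$gj)]
  hom <- model$gi == model$gj
  pg[hom] <- pg[hom] / 2

  Nt <- Mt + Ft
  Mexp <- 2 * params@Rm * Ft / (1 + (params@Rm - 1) * Nt / params@K)
  Toff <- if (params@deterministicOffspring) round(Mexp)
          else .rpoisLarge(Mexp)
  if (Toff <= 0) return(NULL)

  # categories: male genotypes, surviving-female genotypes, nonsurvivors
  pSurvF <- 0.5 * pg * model$wFem
  probs <- c(0.5 * pg, pSurvF, max(0, 0.5 - sum(pSurvF)))
  probs <- probs / sum(probs)
  draw <- hybridMultinomial(Toff, probs,
                            threshold = params@samplerThreshold,
                            exactCutoff = params@exactCutoff)
  G <- model$G
  newCounts <- rbind(draw[seq_len(G)], draw[G + seq_len(G)])
  if (sum(newCounts) == 0) return(NULL)
  dimnames(newCounts) <- dimnames(counts)
  newCounts
}

#' Advance a population by one generation
#'
#' Forms the sex-specific mean gamete pools (weighting each adult's
#' [gameteDistribution()] by its genotype count), combines them into
#' offspring genotype probabilities, draws the offspring total from the
#' Beverton-Holt expectation (Poisson, or deterministic in pure
#' Wright-Fisher mode), and allocates offspring to (sex, genotype)
#' categories with [hybridMultinomial()]: a sex ratio of 1/2 at birth, and
#' female survival to adulthood weighted by [femaleFitness()].
#'
#' @param state a [PopulationState-class] object with at least one adult
#'   of each sex.
#' @param params a [DriveParams-class] object.
#' @return the next [PopulationState-class], or `NULL` when the population
#'   is eliminated (a sex with zero adults, or zero offspring).
#' @export
nextGeneration <- function(state, params) {
  if (state@m != params@m)
    stop("state and params disagree on m")
  model <- .buildModel(params)
  counts <- .stepCounts(state@counts, model, params)
  if (is.null(counts)) return(NULL)
  new("PopulationState", generation = state@generation + 1L,
      counts = counts, m = params@m)
}
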