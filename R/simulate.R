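# Replicate orchestration: burn-in to mutation-selection balance, drive
# release in males, the generation loop, outcome classification, and
# resistance-probability estimation over a grid of population sizes.

#' Haplotype frequencies of a state
#'
#' Frequencies of each haplotype among all adult chromosomes of both
#' sexes (two chromosomes per adult).
#'
#' @param state a [PopulationState-class] object.
#' @return named numeric vector over the haplotypes of
#'   [enumerateHaplotypes()]; sums to 1 for a non-empty state.
#' @export
haplotypeFrequencies <- function(state) {
  model <- .hapDosageFor(state@m)
  tot <- sum(state@counts)
  f <- drop(colSums(state@counts) %*% model) / (2 * tot)
  f
}

# cached genotype -> haplotype dosage matrices, keyed by m
.hapDosageCache <- new.env(parent = emptyenv())
.hapDosageFor <- function(m) {
  key <- as.character(m)
  if (is.null(.hapDosageCache[[key]])) {
    geno <- enumerateGenotypes(m)
    haps <- enumerateHaplotypes(m)
    inc <- matrix(0, nrow(geno), nrow(haps),
                  dimnames = list(geno$label, haps$label))
    inc[cbind(seq_len(nrow(geno)), geno$i)] <-
      inc[cbind(seq_len(nrow(geno)), geno$i)] + 1
    inc[cbind(seq_len(nrow(geno)), geno$j)] <-
      inc[cbind(seq_len(nrow(geno)), geno$j)] + 1
    .hapDosageCache[[key]] <- inc
  }
  .hapDosageCache[[key]]
}

#' Equilibrate standing variation before drive release
#'
#' Runs `ceiling(burnInMultiplier / sigma)` generations from an
#' all-wild-type population at carrying capacity, with de novo mutation
#' and viability selection but no drive, so that resistant standing
#' variation settles towards mutation-selection balance. The default
#' multiplier of 1 gives the canonical `1 / sigma` generations; larger
#' multipliers allow longer equilibration checks.
#'
#' @param params a [DriveParams-class] object with `sigma > 0`.
#' @return the equilibrated [PopulationState-class] (generation reset
#'   to 0, ready for [introduceDrive()]).
#' @export
burnIn <- function(params) {
  if (params@sigma <= 0)
    stop("burn-in requires sigma > 0 (its duration is 1 / sigma generations)")
  nGen <- ceiling(params@burnInMultiplier / params@sigma)
  model <- .buildModel(params)
  state <- wildTypeState(params)
  counts <- state@counts
  for (t in seq_len(nGen)) {
    counts <- .stepCounts(counts, model, params)
    if (is.null(counts))
      stop("population eliminated during burn-in; ",
           "check the demographic parameters")
  }
  new("PopulationState", generation = 0L, counts = counts, m = params@m)
}

#' Release drive homozygote males into a population
#'
#' Replaces males, sampled proportionally across genotypes (largest
#' remainder allocation), with drive homozygote (D/D) males so that the
#' drive allele frequency among male chromosomes equals
#' `params@releaseFreq`. Females are untouched and the total population
#' size is preserved.
#'
#' @param state a [PopulationState-class] object with at least one male.
#' @param params a [DriveParams-class] object.
#' @return the post-release [PopulationState-class].
#' @export
introduceDrive <- function(state, params) {
  f <- params@releaseFreq
  if (f < 0 || f >= 1) stop("releaseFreq must lie in [0, 1)")
  if (f == 0) return(state)
  counts <- state@counts
  maleCounts <- counts["male", ]
  Mt <- sum(maleCounts)
  if (Mt == 0) stop("cannot release drive into a population with no males")
  nD <- round(f * Mt)
  if (nD > 0) {
    quota <- nD * maleCounts / Mt
    takes <- floor(quota)
    shortfall <- nD - sum(takes)
    if (shortfall > 0) {
      frac <- quota - takes
      frac[takes >= maleCounts] <- -1  # cannot take beyond the class size
      ord <- order(frac, decreasing = TRUE)
      takes[ord[seq_len(shortfall)]] <- takes[ord[seq_len(shortfall)]] + 1
    }
    ddIdx <- .genotypePairIndex(params@m)[nHaplotypes(params@m),
                                          nHaplotypes(params@m)]
    counts["male", ] <- maleCounts - takes
    counts["male", ddIdx] <- counts["male", ddIdx] + nD
  }
  new("PopulationState", generation = state@generation, counts = counts,
      m = params@m)
}

#' Run one replicate of the drive-release experiment
#'
#' Optional burn-in, drive release at generation 0, then the generation
#' loop. After each generation the summed frequency of fully resistant
#' haplotypes among all adult chromosomes is compared against
#' `resistanceThreshold` (default 0.95): the replicate is classified
#' `resistance` at the first crossing, `elimination` when the population
#' (or either sex) reaches zero, and `censored` at `maxGenerations`.
#'
#' @param params a [DriveParams-class] object.
#' @param seed optional integer seed for this replicate.
#' @param keepTrajectory record a per-generation summary matrix.
#' @param initialState optional pre-release [PopulationState-class] (e.g.
#'   a shared [burnIn()] state); by default a fresh burn-in is run when
#'   `params@burnIn` is TRUE, else the all-wild-type state is used.
#' @return a [ReplicateOutcome-class] object.
#' @export
runReplicate <- function(params, seed = NULL, keepTrajectory = FALSE,
                         initialState = NULL) {
  if (!is.null(seed)) set.seed(seed)
  model <- .buildModel(params)
  state <- if (!is.null(initialState)) initialState
           else if (params@burnIn) burnIn(params)
           else wildTypeState(params)
  state <- introduceDrive(state, params)
  counts <- state@counts
  traj <- if (keepTrajectory) vector("list", params@maxGenerations + 1L)
          else NULL

  summarize <- function(counts) {
    tot <- sum(counts)
    hapFreq <- drop(colSums(counts) %*% model$hapDosage) / (2 * tot)
    resFreq <- sum(drop(colSums(counts) %*% (model$hapDosage %*%
                     model$haps$fullyResistant))) / (2 * tot)
    list(tot = tot, hapFreq = hapFreq, resFreq = resFreq)
  }

  s <- summarize(counts)
  if (keepTrajectory)
    traj[[1]] <- c(generation = 0, total = s$tot,
                   resistantFreq = s$resFreq, s$hapFreq)
  tRes <- NA_real_; tElim <- NA_real_; outcome <- "censored"
  lastFreqs <- s$hapFreq

  for (t in seq_len(params@maxGenerations)) {
    counts <- .stepCounts(counts, model, params)
    if (is.null(counts)) {
      outcome <- "elimination"; tElim <- t
      lastFreqs <- lastFreqs * 0
      break
    }
    s <- summarize(counts)
    lastFreqs <- s$hapFreq
    if (keepTrajectory)
      traj[[t + 1L]] <- c(generation = t, total = s$tot,
                          resistantFreq = s$resFreq, s$hapFreq)
    if (s$resFreq >= params@resistanceThreshold) {
      outcome <- "resistance"; tRes <- t
      break
    }
  }
  trajectory <- NULL
  if (keepTrajectory)
    trajectory <- do.call(rbind, traj[!vapply(traj, is.null, logical(1))])
  new("ReplicateOutcome", outcome = outcome, tResistance = tRes,
      tElimination = tElim, finalFreqs = lastFreqs,
      trajectory = trajectory)
}

#' Estimate the probability of resistance over a grid of population sizes
#'
#' Runs `nReps` independent replicates at each population size (each with
#' its own deterministic seed stream derived from `baseSeed`), and returns
#' the resistance fraction with an exact 95% binomial confidence interval.
#' Per-replicate outcomes are attached as attribute `"outcomes"` for
#' downstream sigmoid fitting and time-to-resistance summaries.
#'
#' @param params a [DriveParams-class] object; its `K` is overridden by
#'   each grid value.
#' @param NGrid numeric vector of population sizes (carrying capacities).
#' @param nReps replicates per population size; default 500.
#' @param baseSeed integer seed from which per-replicate seeds are derived.
#' @return data.frame with columns `N`, `nReps`, `nResistance`, `pHat`,
#'   `lower`, `upper`; attribute `"outcomes"` holds a per-replicate
#'   data.frame (`N`, `replicate`, `seed`, `outcome`, `tResistance`,
#'   `tElimination`, and haplotype frequency columns).
#' @export
resistanceProbability <- function(params, NGrid, nReps = 500,
                                  baseSeed = 1) {
  if (nReps < 1) stop("nReps must be at least 1")
  rows <- vector("list", length(NGrid))
  outs <- vector("list", length(NGrid))
  for (a in seq_along(NGrid)) {
    p <- params
    p@K <- as.numeric(NGrid[a])
    reps <- vector("list", nReps)
    for (r in seq_len(nReps)) {
      sd <- deriveSeed(baseSeed, a, r)
      o <- runReplicate(p, seed = sd)
      reps[[r]] <- data.frame(
        N = p@K, replicate = r, seed = sd, outcome = o@outcome,
        tResistance = o@tResistance, tElimination = o@tElimination,
        t(o@finalFreqs), check.names = FALSE,
        stringsAsFactors = FALSE)
    }
    outs[[a]] <- do.call(rbind, reps)
    k <- sum(outs[[a]]$outcome == "resistance")
    ci <- stats::binom.test(k, nReps)$conf.int
    rows[[a]] <- data.frame(N = p@K, nReps = nReps, nResistance = k,
                            pHat = k / nReps, lower = ci[1], upper = ci[2])
  }
  res <- do.call(rbind, rows)
  attr(res, "outcomes") <- do.call(rbind, outs)
  res
}
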