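# Female fitness, germline gamete distributions (homing, NHEJ, de novo
# mutation) and offspring genotype probabilities.
#
# In W/D germlines each cleavable (W) site of the non-drive chromosome
# independently takes one of four outcomes: homing (the whole chromosome
# becomes D), NHEJ to R, NHEJ to N, or remains intact. After conversion,
# every remaining W site of every non-drive gamete class mutates de novo to
# R with probability xi*mu and to N with probability (1-xi)*mu. Double (and
# higher) mutation terms are retained exactly; they are cheap to enumerate.

.alleleRank <- c(W = 1, R = 2, N = 3, D = 4)

.pairKey <- function(a, b) {
  swap <- .alleleRank[a] > .alleleRank[b]
  paste0(ifelse(swap, b, a), ifelse(swap, a, b))
}

# default site-pair fitness table for the given parameters
.pairFitnessTable <- function(params) {
  s <- params@s; h <- params@h; hN <- params@hN; sg <- params@sigma
  tab <- c(
    WW = 1,
    WR = 1 - sg,
    WN = 1 - hN * s,
    WD = 1 - h * s,
    RR = max(0, 1 - 2 * sg),
    RN = (1 - sg) * (1 - hN * s),
    RD = 1 - sg,
    NN = 1 - s,
    ND = 1 - s,
    DD = 1 - s)
  ov <- params@fitnessOverrides
  if (length(ov)) {
    for (nm in names(ov)) {
      a <- strsplit(nm, "")[[1]]
      if (length(a) != 2L || !all(a %in% names(.alleleRank)))
        stop("invalid fitnessOverrides name: ", nm)
      tab[.pairKey(a[1], a[2])] <- as.numeric(ov[[nm]])
    }
  }
  tab
}

#' Fitness factor of one diploid target site
#'
#' Symmetric per-site viability factor of a female carrying alleles `a` and
#' `b` at one target site. Anchor values: W/W = 1, W/D = `1 - h s`,
#' D/D = `1 - s`, W/N = `1 - hN s`, N/N = `1 - s`, W/R = `1 - sigma`.
#' Pairs involving R extend these: R/D = `1 - sigma` (the W/D cost is
#' attributed to leaky somatic cleavage of the W copy, and R is
#' uncleavable), R/R = `max(0, 1 - 2 sigma)` (additive allele costs) and
#' R/N = `(1 - sigma)(1 - hN s)`. Any entry can be replaced through
#' `fitnessOverrides` in [driveParams()].
#'
#' @param a,b character vectors of site alleles in `{W, R, N, D}`
#'   (recycled to a common length).
#' @param params a [DriveParams-class] object.
#' @return numeric vector of fitness factors in [0, 1].
#' @examples
#' p <- driveParams(m = 1, K = 1e4, sigma = 0.01)
#' sitePairFitness("W", "D", p)  # 0.7
#' @export
sitePairFitness <- function(a, b, params) {
  if (!all(c(a, b) %in% names(.alleleRank)))
    stop("unknown allele symbol; alleles are W, R, N, D")
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  unname(.pairFitnessTable(params)[.pairKey(a, b)])
}

# canonical site-allele vector of a haplotype row; D expands to m D alleles
.alleleVector <- function(hapRow, m) {
  if (hapRow$isDrive) rep("D", m)
  else c(rep("W", hapRow$nW), rep("R", hapRow$nR), rep("N", hapRow$nN))
}

#' Female fitness of every diploid genotype
#'
#' Viability of females of each genotype, as the product over the m site
#' positions of [sitePairFitness()] ("independent fitness effects" across
#' sites). The two haplotypes' canonical sorted allele vectors are aligned
#' position by position; the drive haplotype contributes a D allele at
#' every position. Alleles have no effect on male fitness.
#'
#' @param params a [DriveParams-class] object.
#' @param genotype optional character vector of genotype labels (as in
#'   [enumerateGenotypes()]); default all genotypes.
#' @return named numeric vector of fitness values in [0, 1].
#' @examples
#' p <- driveParams(m = 1, K = 1e4)
#' femaleFitness(p)[c("W/D", "D/D")]  # 0.7 0
#' @export
femaleFitness <- function(params, genotype = NULL) {
  haps <- enumerateHaplotypes(params@m)
  geno <- enumerateGenotypes(params@m)
  tab <- .pairFitnessTable(params)
  vecs <- lapply(seq_len(nrow(haps)), function(k)
    .alleleVector(haps[k, ], params@m))
  w <- vapply(seq_len(nrow(geno)), function(g) {
    prod(tab[.pairKey(vecs[[geno$i[g]]], vecs[[geno$j[g]]])])
  }, numeric(1))
  names(w) <- geno$label
  if (!is.null(genotype)) {
    if (!all(genotype %in% names(w)))
      stop("unknown genotype label: ",
           paste(setdiff(genotype, names(w)), collapse = ", "))
    w <- w[genotype]
  }
  w
}

# H x H de novo mutation kernel: each W site mutates to R w.p. xi*mu and to
# N w.p. (1-xi)*mu, independently; D does not mutate. Exact expansion.
.mutationKernel <- function(params, haps = enumerateHaplotypes(params@m)) {
  H <- nrow(haps)
  mu <- params@mu; xi <- params@xi
  M <- matrix(0, H, H, dimnames = list(haps$label, haps$label))
  key <- paste(haps$nW, haps$nR, haps$nN)
  for (k in seq_len(H)) {
    if (haps$isDrive[k]) { M[k, H] <- 1; next }
    nW <- haps$nW[k]
    for (jR in 0:nW) for (jN in 0:(nW - jR)) {
      pr <- choose(nW, jR) * choose(nW - jR, jN) *
        (xi * mu)^jR * ((1 - xi) * mu)^jN * (1 - mu)^(nW - jR - jN)
      tgt <- match(paste(nW - jR - jN, haps$nR[k] + jR, haps$nN[k] + jN),
                   key)
      M[k, tgt] <- M[k, tgt] + pr
    }
  }
  M
}

# conversion-stage gamete distribution (before de novo mutation) of a
# non-drive haplotype paired against D; returns a probability vector over
# haplotype indices. Each W site: homing eps*(1-nu), NHEJ->R eps*nu*beta,
# NHEJ->N eps*nu*(1-beta), intact 1-eps. Any homing event converts the
# whole chromosome to D.
.conversionAgainstDrive <- function(hapRow, params, haps) {
  H <- nrow(haps)
  out <- numeric(H)
  eps <- params@epsilon; nu <- params@nu; beta <- params@beta
  w <- hapRow$nW
  key <- paste(haps$nW, haps$nR, haps$nN)
  pR <- eps * nu * beta; pN <- eps * nu * (1 - beta); pW <- 1 - eps
  if (w > 0) {
    for (kR in 0:w) for (kN in 0:(w - kR)) {
      pr <- choose(w, kR) * choose(w - kR, kN) *
        pR^kR * pN^kN * pW^(w - kR - kN)
      tgt <- match(paste(w - kR - kN, hapRow$nR + kR, hapRow$nN + kN), key)
      out[tgt] <- out[tgt] + 0.5 * pr
    }
  } else {
    out[match(paste(0, hapRow$nR, hapRow$nN), key)] <- 0.5
  }
  # drive copy transmitted with prob 1/2 plus all homing outcomes
  out[H] <- 1 - sum(out)
  out
}

#' Gamete haplotype distribution of every genotype
#'
#' Probability distribution over transmitted haplotypes for each parental
#' genotype: Mendelian 1/2-1/2 transmission for non-drive genotypes, all-D
#' for D/D, and the homing/NHEJ conversion process in genotypes pairing a
#' non-drive haplotype with D, in the germlines of both sexes. The total
#' non-drive gamete fraction of such a genotype is
#' `0.5 * (1 - epsilon (1 - nu))^(m - r)` where `r` is the number of
#' resistant sites on the non-drive chromosome. De novo mutation then acts
#' on every remaining W site of every non-drive gamete class.
#'
#' @param params a [DriveParams-class] object.
#' @param genotype optional character vector of genotype labels; default
#'   all genotypes.
#' @return matrix of gamete probabilities (rows: genotypes, columns:
#'   haplotypes); each row sums to 1. If `genotype` has length 1 a named
#'   vector is returned.
#' @examples
#' p <- driveParams(m = 1, K = 1e4, mu = 0)
#' gameteDistribution(p, "W/D")  # homing-biased transmission
#' @export
gameteDistribution <- function(params, genotype = NULL) {
  haps <- enumerateHaplotypes(params@m)
  geno <- enumerateGenotypes(params@m)
  H <- nrow(haps); G <- nrow(geno)
  Mmut <- .mutationKernel(params, haps)
  conv <- matrix(0, H, H)  # haplotype-level transmission against D
  for (k in seq_len(H - 1))
    conv[k, ] <- .conversionAgainstDrive(haps[k, ], params, haps)
  out <- matrix(0, G, H, dimnames = list(geno$label, haps$label))
  for (g in seq_len(G)) {
    i <- geno$i[g]; j <- geno$j[g]
    di <- haps$isDrive[i]; dj <- haps$isDrive[j]
    pool <- numeric(H)
    if (di && dj) {
      pool[H] <- 1
    } else if (di || dj) {
      pool <- conv[if (di) j else i, ]
    } else {
      pool[i] <- pool[i] + 0.5
      pool[j] <- pool[j] + 0.5
    }
    out[g, ] <- pool %*% Mmut
  }
  if (!is.null(genotype)) {
    if (!all(genotype %in% geno$label))
      stop("unknown genotype label: ",
           paste(setdiff(genotype, geno$label), collapse = ", "))
    out <- out[genotype, , drop = length(genotype) == 1L]
  }
  out
}

#' Offspring genotype distribution from two gamete pools
#'
#' Random union of gametes: the probability of unordered genotype
#' \{i, j\} is `p_i^male p_j^female + p_j^male p_i^female` for `i != j`
#' and `p_i^male p_i^female` for `i = j`.
#'
#' @param malePool,femalePool numeric gamete probability vectors over the
#'   haplotype indices of [enumerateHaplotypes()]; each must sum to 1.
#' @param m number of target sites.
#' @return named numeric vector of probabilities over the genotypes of
#'   [enumerateGenotypes()]; sums to 1.
#' @export
offspringGenotypeDistribution <- function(malePool, femalePool, m) {
  m <- .checkM(m)
  H <- nHaplotypes(m)
  if (length(malePool) != H || length(femalePool) != H)
    stop("gamete pools must have length nHaplotypes(m) = ", H)
  if (any(malePool < 0) || any(femalePool < 0) ||
      abs(sum(malePool) - 1) > 1e-8 || abs(sum(femalePool) - 1) > 1e-8)
    stop("gamete pools must be normalized non-negative probability vectors")
  geno <- enumerateGenotypes(m)
  outer <- malePool %o% femalePool
  S <- outer + t(outer)
  p <- S[cbind(geno$i, geno$j)]
  hom <- geno$i == geno$j
  p[hom] <- p[hom] / 2
  names(p) <- geno$label
  p
}

# Precomputed per-parameter model tables used by the generation loop.
.buildModel <- function(params) {
  m <- params@m
  haps <- enumerateHaplotypes(m)
  geno <- enumerateGenotypes(m)
  H <- nrow(haps); G <- nrow(geno)
  gameteM <- gameteDistribution(params)
  wFem <- unname(femaleFitness(params))
  # genotype -> haplotype dosage (each genotype carries 2 chromosomes)
  inc <- matrix(0, G, H, dimnames = list(geno$label, haps$label))
  inc[cbind(seq_len(G), geno$i)] <- inc[cbind(seq_len(G), geno$i)] + 1
  inc[cbind(seq_len(G), geno$j)] <- inc[cbind(seq_len(G), geno$j)] + 1
  frHap <- haps$fullyResistant
  list(m = m, haps = haps, geno = geno, H = H, G = G,
       pairIdx = .genotypePairIndex(m), gameteM = gameteM, wFem = wFem,
       hapDosage = inc, frDosage = drop(inc %*% frHap),
       gi = geno$i, gj = geno$j,
       wildGenotype = 1L, ddGenotype = .genotypePairIndex(m)[H, H])
}
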