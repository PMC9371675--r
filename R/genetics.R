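# Haplotype and genotype bookkeeping for m multiplexed target sites.
#
# A haplotype is either the indivisible drive construct D, or an unordered
# multiset of m site alleles from {W, R, N} ("no positional effects", no
# recombination), stored canonically as counts (nW, nR, nN) and labelled by
# the sorted allele string with ordering W < R < N (e.g. "WRN"). Haplotypes
# are enumerated in lexicographic order of that string, with D last, so
# indices are stable across runs.

#' Enumerate haplotypes for m target sites
#'
#' Returns all `choose(m + 2, 2)` multisets of size `m` over the site
#' alleles W (wild type), R (functional resistant) and N (nonfunctional
#' resistant), plus the single drive haplotype D. Ordering is lexicographic
#' on the canonical sorted allele string (W < R < N) with D last, so the
#' all-wild-type haplotype is always first.
#'
#' @param m number of gRNAs / target sites (positive integer).
#' @return A data.frame with one row per haplotype and columns `label`,
#'   `nW`, `nR`, `nN` (site-allele counts), `isDrive`, `r` (number of
#'   resistant sites, NA for D) and `fullyResistant`.
#' @examples
#' enumerateHaplotypes(2)$label  # "WW" "WR" "WN" "RR" "RN" "NN" "D"
#' @export
enumerateHaplotypes <- function(m) {
  m <- .checkM(m)
  nW <- nR <- integer(0)
  for (w in m:0) for (r in (m - w):0) {
    nW <- c(nW, w); nR <- c(nR, r)
  }
  nN <- m - nW - nR
  label <- vapply(seq_along(nW), function(i) {
    paste(c(rep("W", nW[i]), rep("R", nR[i]), rep("N", nN[i])),
          collapse = "")
  }, character(1))
  out <- data.frame(
    label = c(label, "D"),
    nW = c(nW, NA_integer_), nR = c(nR, NA_integer_),
    nN = c(nN, NA_integer_),
    isDrive = c(rep(FALSE, length(label)), TRUE),
    stringsAsFactors = FALSE)
  out$r <- ifelse(out$isDrive, NA_integer_, out$nR + out$nN)
  out$fullyResistant <- !out$isDrive & out$r == m
  rownames(out) <- out$label
  attr(out, "m") <- m
  out
}

#' Number of haplotypes for m target sites
#' @param m number of target sites.
#' @return `choose(m + 2, 2) + 1`.
#' @export
nHaplotypes <- function(m) {
  m <- .checkM(m)
  choose(m + 2, 2) + 1
}

#' Count resistant sites of a haplotype
#'
#' The number `r` of sites carrying a resistant allele (R or N). `r` is
#' undefined for the drive haplotype, which is copied as a whole and has no
#' site structure.
#'
#' @param h character vector of haplotype labels (e.g. `"WRN"`).
#' @return integer vector of resistant-site counts.
#' @examples
#' resistantSiteCount(c("WW", "WRN", "NN"))  # 0 2 2
#' @export
resistantSiteCount <- function(h) {
  .checkLabels(h)
  if (any(h == "D"))
    stop("resistant-site count is undefined for the drive haplotype D")
  vapply(strsplit(h, ""), function(a) sum(a != "W"), integer(1))
}

#' Is a haplotype fully resistant?
#'
#' A fully resistant haplotype carries R or N at all m sites; such
#' chromosomes cannot be cleaved at any site. The drive haplotype is not a
#' resistance haplotype.
#'
#' @param h character vector of haplotype labels.
#' @param m number of target sites.
#' @return logical vector.
#' @examples
#' isFullyResistant(c("RN", "WR", "D"), m = 2)  # TRUE FALSE FALSE
#' @export
isFullyResistant <- function(h, m) {
  m <- .checkM(m)
  .checkLabels(h)
  ifelse(h == "D", FALSE,
         nchar(h) == m & vapply(strsplit(h, ""), function(a)
           all(a != "W"), logical(1)))
}

#' Enumerate diploid genotypes for m target sites
#'
#' All unordered pairs of haplotype indices, in flattened upper-triangle
#' order: (1,1), (1,2), ..., (1,H), (2,2), ..., (H,H), where H is the
#' haplotype count. Labels join the two haplotype labels with "/".
#'
#' @param m number of target sites.
#' @return A data.frame with columns `i`, `j` (haplotype indices, `i <= j`)
#'   and `label`, with `H (H + 1) / 2` rows.
#' @examples
#' nrow(enumerateGenotypes(1))  # 10
#' @export
enumerateGenotypes <- function(m) {
  m <- .checkM(m)
  haps <- enumerateHaplotypes(m)
  H <- nrow(haps)
  i <- rep(seq_len(H), times = H - seq_len(H) + 1L)
  j <- unlist(lapply(seq_len(H), function(k) k:H))
  out <- data.frame(i = i, j = j,
                    label = paste(haps$label[i], haps$label[j], sep = "/"),
                    stringsAsFactors = FALSE)
  attr(out, "m") <- m
  out
}

#' Number of diploid genotypes for m target sites
#' @param m number of target sites.
#' @return `H (H + 1) / 2` with `H = nHaplotypes(m)`.
#' @export
nGenotypes <- function(m) {
  H <- nHaplotypes(m)
  H * (H + 1) / 2
}

#' Canonical index of a haplotype label
#'
#' Maps a haplotype written in any site order (e.g. `"RW"`) to the index of
#' its canonical form (`"WR"`) in the [enumerateHaplotypes()] ordering.
#'
#' @param h character vector of haplotype labels, any site order.
#' @param m number of target sites.
#' @return integer vector of haplotype indices.
#' @export
haplotypeIndex <- function(h, m) {
  m <- .checkM(m)
  .checkLabels(h)
  haps <- enumerateHaplotypes(m)
  canon <- vapply(strsplit(h, ""), function(a) {
    if (identical(a, "D")) return("D")
    if (length(a) != m)
      stop("haplotype label has ", length(a), " sites but m = ", m)
    paste(a[order(match(a, c("W", "R", "N")))], collapse = "")
  }, character(1))
  idx <- match(canon, haps$label)
  if (anyNA(idx)) stop("unknown haplotype label: ",
                       paste(h[is.na(idx)], collapse = ", "))
  idx
}

# lookup matrix: (i, j) haplotype pair -> genotype row (upper triangle)
.genotypePairIndex <- function(m) {
  geno <- enumerateGenotypes(m)
  H <- nHaplotypes(m)
  idx <- matrix(NA_integer_, H, H)
  idx[cbind(geno$i, geno$j)] <- seq_len(nrow(geno))
  idx[cbind(geno$j, geno$i)] <- seq_len(nrow(geno))
  idx
}

.checkM <- function(m) {
  if (length(m) != 1L || is.na(m) || m < 1 || m != floor(m))
    stop("m must be a single positive integer")
  as.integer(m)
}

.checkLabels <- function(h) {
  if (!is.character(h) || !length(h))
    stop("haplotype labels must be a character vector")
  ok <- vapply(strsplit(h, ""), function(a) {
    identical(a, "D") || all(a %in% c("W", "R", "N"))
  }, logical(1))
  if (!all(ok))
    stop("invalid haplotype label: ", paste(h[!ok], collapse = ", "))
  invisible(h)
}
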