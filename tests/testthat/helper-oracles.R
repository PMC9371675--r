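# Independent oracles used across the suite. These deliberately avoid the
# package's own enumeration and gamete machinery.

# Brute-force count of distinct site-allele multisets of size m over
# {W, R, N}, plus the drive haplotype.
bruteHaplotypeCount <- function(m) {
  g <- expand.grid(rep(list(c("W", "R", "N")), m), stringsAsFactors = FALSE)
  canon <- apply(as.matrix(g), 1, function(a)
    paste(a[order(match(a, c("W", "R", "N")))], collapse = ""))
  length(unique(canon)) + 1L
}

# Monte-Carlo per-site gamete oracle for a genotype pairing a non-drive
# haplotype (given as allele character vector) against D. Simulates the
# per-site outcome process directly: choose the transmitted chromosome,
# convert each W site (homing / NHEJ-R / NHEJ-N / intact), then mutate
# remaining W sites. Returns a table of haplotype-label frequencies.
mcGameteOracle <- function(alleles, params, nDraws) {
  eps <- params@epsilon; nu <- params@nu; beta <- params@beta
  xi <- params@xi; mu <- params@mu
  m <- length(alleles)
  out <- character(nDraws)
  for (d in seq_len(nDraws)) {
    if (stats::runif(1) < 0.5) { out[d] <- "D"; next }
    a <- alleles
    wSites <- which(a == "W")
    homing <- FALSE
    for (k in wSites) {
      u <- stats::runif(1)
      if (u < eps * (1 - nu)) { homing <- TRUE; break }
      else if (u < eps * (1 - nu) + eps * nu * beta) a[k] <- "R"
      else if (u < eps) a[k] <- "N"
    }
    if (homing) { out[d] <- "D"; next }
    for (k in which(a == "W")) {
      u <- stats::runif(1)
      if (u < xi * mu) a[k] <- "R"
      else if (u < mu) a[k] <- "N"
    }
    out[d] <- paste(a[order(match(a, c("W", "R", "N")))], collapse = "")
  }
  table(out) / nDraws
}

# Per-replicate conditional resistance times from an outcomes attribute.
resistanceTimes <- function(summary) {
  oc <- attr(summary, "outcomes")
  oc$tResistance[oc$outcome == "resistance"]
}
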