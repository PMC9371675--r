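---
title: "Modelling resistance to multiplexed suppression gene drive"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling resistance to multiplexed suppression gene drive}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multiplexdrive)
```

## The problem

A CRISPR–Cas9 homing suppression drive inserts itself into a gene required
for female fertility. In W/D heterozygotes the nuclease cleaves the
wild-type (W) chromosome and, via homology-directed repair, converts most
gametes to drive (D), so the construct spreads far faster than Mendelian
inheritance and collapses the population. Resistance arises when a
chromosome acquires cleavage-blocking alleles at the target locus: either
functional (R), which preserve gene function and can sweep to fixation and
rescue the population, or nonfunctional (N), which block cleavage but are
as sterile as drive when homozygous. Multiplexing — targeting the locus
with `m` gRNAs at once — demands a resistant allele at *all* `m` sites on
one chromosome before a haplotype is protected, and is the main
anti-resistance design lever.

The package implements a stochastic Wright–Fisher model of this system
with separate sexes and density-dependent recruitment, together with the
analytic theory calibrated against such simulations: the probability that
resistance evolves before elimination follows

$$ p \;=\; 1 - e^{-N/N^*}, $$

with the effective population size $N$ measured against a critical size
$N^*$ that depends on the resistance mechanism:

* NHEJ only: $N^*_n = \dfrac{1}{4\gamma_n(\epsilon\nu\beta)^m}$, with
  $\gamma_n \approx 0.2$ independent of $m$ (resistant sites are generated
  concurrently);
* de novo single-nucleotide mutation: $N^*_d = \dfrac{1}{4\gamma_m(\xi\mu)^m}$,
  with $\gamma_m = s_b\tau^m$ ($s_b \approx 0.09$, $\tau \approx 8.5$
  generations; sites accumulate sequentially);
* standing variation equilibrated at mutation–selection balance:
  $N^*_s = \dfrac{1}{4\xi\mu\, m\,(\gamma\xi\mu/\sigma)^{m-1}
  \ln(1 + s_b/(m\sigma))}$, with $\gamma \approx 2$, $s_b \approx 0.5$ —
  note the $\sigma^{m-1}$ power law that strongly amplifies weakly
  deleterious standing variation for $m > 1$;
* both routes: $1/N^* = 1/N^*_n + 1/N^*_s$.

From these the package derives $p = 0.05$ contours, minimal gRNA numbers
(`minGuidesNhej()`, `minGuidesStanding()`, the latter with a Lambert
$W_{-1}$ closed form cross-checked against brute force), and the
amplification ratio $N^*_d/N^*_s = m\gamma^{m-1}\ln(1+s_b/(m\sigma)) /
(\sigma^{m-1}\gamma_m)$.

## Genetics

A haplotype is the drive construct D, or an unordered multiset of `m` site
alleles from {W, R, N}: no positional effects and no recombination between
the tightly linked sites, and no mosaics with D because the construct is
copied as a whole. That gives $\binom{m+2}{2}+1$ haplotypes (4, 7, 11 for
`m` = 1, 2, 3) and $H(H+1)/2$ diploid genotypes. Haplotypes are ordered
lexicographically on the canonical sorted allele string (W < R < N) with D
last; genotypes in flattened upper-triangle order. These orderings are
frozen so indices and CSV columns are stable.

## Gamete generation

In genotypes pairing a non-drive haplotype against D, each W site is cut
independently: homing with probability $\epsilon(1-\nu)$ (any homing event
converts the whole chromosome to D), NHEJ to R with $\epsilon\nu\beta$, to
N with $\epsilon\nu(1-\beta)$, intact with $1-\epsilon$. The surviving
non-drive gamete fraction is $\tfrac12[1-\epsilon(1-\nu)]^{m-r}$, where
$r$ counts resistant sites already on the chromosome — partial resistance
protects the remaining cleavable sites. Conversion occurs in the germlines
of both sexes. Afterwards every remaining W site of every non-drive gamete
class mutates de novo to R with probability $\xi\mu$ and to N with
$(1-\xi)\mu$; multi-site mutation terms are kept exactly (they are cheap),
D does not mutate, and there is no back-mutation. All of this is
precomputed once per parameter set as a genotype-by-haplotype matrix, so
the per-generation cost is independent of $N$.

## Fitness

Costs act multiplicatively across sites and are expressed as reduced
female survival to adulthood; males are unaffected (essential for a
female-fertility drive: D/D males must remain fully fit). Site-pair
factors anchor at W/W = 1, W/D = $1-hs$, W/N = $1-h_Ns$, W/R = $1-\sigma$,
and D/D = N/N = $1-s$ with $s = 1$. Pairs not fixed by those anchors are a
package design choice, exposed through `fitnessOverrides`: R/D =
$1-\sigma$ (the W/D cost is read as leaky somatic cleavage of the W copy,
and R is uncleavable), R/R = $\max(0, 1-2\sigma)$ (additive), R/N =
$(1-\sigma)(1-h_Ns)$. Because haplotypes are stored as multisets, diploid
site-pairing is ambiguous in principle; we align the two canonical sorted
allele vectors position by position, which reproduces every anchor and
differs from alternative alignments only at order $\sigma^2$.

## Demography and sampling

Recruitment is Beverton–Holt: the expected offspring total is
$M = 2R_mF_t/(1+(R_m-1)N_t/K)$, so an all-wild-type population is
stationary at $K$ and grows at rate $R_m$ per capita when rare. This
parameterization — chosen so that $K$ is the stable wild-type equilibrium —
and the default $R_m = 6$, typical of *Anopheles* suppression models, are
package choices and configurable. The
realized total is Poisson($M$) — demographic stochasticity — with a
deterministic mode (`deterministicOffspring`) for pure Wright–Fisher
checks. Offspring are then allocated in one multinomial draw over
$2G + 1$ categories: male genotypes ($\tfrac12 p_g$), surviving female
genotypes ($\tfrac12 p_g w_g$), and nonsurvivors. Elimination is declared
when either sex (or the total) reaches zero.

The multinomial draw itself is the hybrid Poisson–Gaussian sampler
(`hybridMultinomial()`): categories with expected count
$N x_k \le 10$ are drawn as independent Poissons, the rest from the
multivariate Gaussian with multinomial covariance
$\Sigma'_{ij} = N'x'_i(\delta_{ij} - x'_j)$, conditioned on the total left
after the rare block. Discretization is ours to choose: we sample all
common categories but the largest, round, clamp negatives, and give the
largest category the exact remainder (decrementing the largest counts in
the astronomically unlikely event of a negative remainder); if the rare
Poisson block ever exceeds $N$ it is redrawn, never truncated. Totals are
therefore conserved exactly, per-draw cost is $O(K)$ in the number of
categories, and populations up to $\sim 10^{12}$ (doubles stay exact to
$2^{53}$) are practical. Below `exactCutoff` ($10^6$ by default) the exact
`rmultinom()` path is used instead.

## Replicates and outcome classification

`runReplicate()` optionally equilibrates standing variation
(`burnIn = TRUE`: $\lceil 1/\sigma \rceil$ generations from all wild type;
a multiplier allows longer equilibration), releases D/D males so the drive
allele frequency among male chromosomes is `releaseFreq` (0.1 by default;
replaced males are drawn proportionally across genotypes), and iterates
generations. A replicate is classified *resistance* when the summed
frequency of fully resistant haplotypes over all adult chromosomes of both
sexes first reaches 0.95, *elimination* on population collapse, and
*censored* at `maxGenerations` (default 1000; in the regimes studied here
outcomes resolve well under 100 generations). `resistanceProbability()`
runs seed-derived independent replicate streams over an $N$ grid and
feeds `fitSigmoid()`, a one-parameter binomial maximum-likelihood fit of
$N^*$ with a profile-likelihood interval — replicate outcomes are
Bernoulli, so least squares would be the wrong objective.

## A sex-limited-selection subtlety in the burn-in

Because fitness costs act only on female survival, an autosomal R allele
experiences an effective per-generation cost of $\sigma/2$: half its
copies sit in males, which selection never sees. The pre-release
mutation–selection–drift equilibrium for `m` = 1 is therefore
Gamma(shape $4N\xi\mu$, rate $2N\sigma$), with mean $2\xi\mu/\sigma$ —
twice the unisex textbook value $\xi\mu/\sigma$ often quoted alongside a
rate of $4N\sigma$. Our simulations confirm the sex-sheltered form
(fitted shape 2.0, rate $2.0\times10^5$ against the prediction
Gamma(2.16, $2\times10^5$) at $N = 10^7$, $\sigma = 0.01$). The unit
suite asserts the model's own equilibrium; the unisex form is retained in
the acceptance checks for comparability and fails by exactly this factor
of two. Users comparing against unisex theory should read the theory's
$\sigma$ as the *effective* cost.

## What the generator does and does not emulate

Simulated conditions follow the standard study design for this system:
cleavage
$\epsilon = 0.95$ and NHEJ rate $\nu = 0.05$ (a *doublesex*-like target),
$\mu = 18\times3\times10^{-9}$ per target site per generation, $s = 1$,
$h = 0.3$, $h_N = 0.02$, release at 0.1 in males, resistance criterion
0.95. Not modelled (out of scope by design): spatial structure and
migration, recombination between target sites, off-target cleavage,
error-prone homing and gRNA loss, parental deposition, age structure, and
historical bottlenecks. Passing tests therefore speak to the idealized
well-mixed model, not to any field population.

## Problem sizes and numerical choices

The test and acceptance runs use deliberately reduced designs chosen to
keep Monte-Carlo error well inside the asserted tolerances: 200 replicates
per grid point for the $\gamma_n$ recovery (fitted values 0.20–0.22
against 0.2 across seeds), 100 replicates for conditional
time-to-resistance (mean $\approx 55$ generations), 100–150 burn-in
replicates at $N = 10^7$, and distributional sampler checks at
3000–4000 draws. Statistical assertions use 3–4$\sigma$ bands or tests at
$\alpha = 0.01$–0.001. Seeds derive deterministically from a base seed via
`deriveSeed()` (multiplicative hash modulo $2^{31}-1$), one independent
stream per replicate, so batches are reproducible and parallelizable.

Known numerical limits: totals beyond $\sim 10^{15}$ lose exactness in the
Gaussian means; `rpois` is replaced by its Gaussian limit above means of
$10^8$; the Gaussian block requires at least one common category (always
true for $N$ above the exact-mode cutoff with bounded category counts).

## Worked example

```{r example, eval = FALSE}
params <- driveParams(m = 1, K = 1, beta = 0.01, mu = 0, sigma = 0.01)
grid <- c(500, 1000, 2000, 4000, 8000, 13000)
rp <- resistanceProbability(params, grid, nReps = 200, baseSeed = 1)
fit <- fitSigmoid(rp)
impliedGamma(fit, params, "nhej")   # about 0.2
minGuidesNhej(1e9, 0.05, driveParams(m = 1, K = 1, beta = 0.01))  # 4
```
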